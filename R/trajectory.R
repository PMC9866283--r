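#' Coordinate-frame trajectory
#'
#' An ordered set of coordinate frames (Angstrom) over a fixed atom list.
#' Atoms carry role tags (`"P"` for phosphate markers, `"W"` for water
#' representative coordinates - the water oxygen - `"LIG"` for ligand
#' atoms, anything else free-form).
#'
#' @param frames list of numeric n_atoms x 3 matrices (columns x, y, z).
#' @param atoms data.frame with columns `id` and `tag`, one row per atom,
#'   order matching the frame rows.
#' @param times optional frame times (ps), metadata.
#' @return A `trajectory` list.
#' @export
trajectory <- function(frames, atoms, times = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    validation_error("frames must be a non-empty list of coordinate matrices")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    storage.mode(f) <- "double"
    dimnames(f) <- NULL
    f
  })
  na <- nrow(frames[[1]])
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (ncol(f) != 3L || nrow(f) != na)
      validation_error(sprintf(
        "frame %d has dimensions %d x %d; every frame needs %d x 3",
        k, nrow(f), ncol(f), na))
    if (any(!is.finite(f)))
      validation_error(sprintf("frame %d contains non-finite coordinates", k))
  }
  if (!is.data.frame(atoms) || !all(c("id", "tag") %in% names(atoms)) ||
      nrow(atoms) != na)
    validation_error("atoms must be a data.frame with columns id, tag and one row per atom")
  out <- list(frames = frames, atoms = atoms, times = times)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  tags <- table(x$atoms$tag)
  cat(sprintf("<trajectory> %d frames x %d atoms (%s)\n",
              length(x$frames), nrow(x$atoms),
              paste(sprintf("%s: %d", names(tags), tags), collapse = ", ")))
  invisible(x)
}

#' Read a trajectory from file
#'
#' Supported formats: a plain tabular format (`frame, atom_id, tag, x, y,
#' z`; CSV), multi-frame XYZ (tag taken from the element column) and
#' multi-model PDB (via the bio3d package; the tag is the stripped atom
#' name, so phosphates read as `"P"`).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"table"`, `"xyz"` or `"pdb"`.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("auto", "table", "xyz", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb", "table")
  }
  switch(format,
         table = read_trajectory_table(path),
         xyz = read_trajectory_xyz(path),
         pdb = read_trajectory_pdb(path))
}

read_trajectory_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "atom_id", "tag", "x", "y", "z")
  if (!all(req %in% names(df)))
    format_error(paste("tabular trajectory needs columns:",
                       paste(req, collapse = ", ")))
  sp <- split(df, df$frame)
  atoms <- data.frame(id = sp[[1]]$atom_id, tag = sp[[1]]$tag)
  frames <- lapply(sp, function(d) {
    if (!identical(d$atom_id, atoms$id))
      format_error("atom ordering differs between frames")
    as.matrix(d[c("x", "y", "z")])
  })
  trajectory(unname(frames), atoms)
}

read_trajectory_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list(); tags <- NULL; i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na <= 0L)
      format_error(sprintf("bad XYZ atom count at line %d", i))
    if (i + 1L + na > length(lines))
      format_error("truncated XYZ frame")
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(tags)) tags <- el
    else if (!identical(el, tags))
      format_error("atom ordering differs between XYZ frames")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  if (!length(frames)) format_error("no frames in XYZ file")
  trajectory(frames, data.frame(id = seq_along(tags), tag = tags))
}

read_trajectory_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    format_error("reading PDB trajectories requires the bio3d package")
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  nf <- nrow(pdb$xyz)
  na <- ncol(pdb$xyz) / 3L
  frames <- lapply(seq_len(nf), function(k)
    matrix(pdb$xyz[k, ], ncol = 3L, byrow = TRUE))
  trajectory(frames,
             data.frame(id = seq_len(na), tag = trimws(pdb$atom$elety)))
}

#' Write a trajectory in the tabular format
#'
#' @param traj a [trajectory()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  long <- do.call(rbind, lapply(seq_along(traj$frames), function(k)
    data.frame(frame = k, atom_id = traj$atoms$id, tag = traj$atoms$tag,
               x = traj$frames[[k]][, 1], y = traj$frames[[k]][, 2],
               z = traj$frames[[k]][, 3])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
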