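# Membrane trajectory metrics: time-average-reference RMSD, bilayer
# thickness from phosphate z-planes, and the padded-bounding-box solvent
# carving rule used when inserting a ligand onto a hydrated bilayer.

coords_array <- function(traj, sel) {
  mats <- lapply(traj$frames, function(f) f[sel, , drop = FALSE])
  array(unlist(mats), dim = c(sum(sel), 3L, length(mats)))
}

#' Per-frame RMSD against the time-average reference
#'
#' For each selected atom the reference position is its mean over all
#' frames; the frame RMSD is the root mean square of the atom displacements
#' from those references. No rotational or translational superposition is
#' applied - raw coordinates are compared to the time mean, so the metric
#' differs from conventional Kabsch-aligned RMSD and directly measures how
#' far atoms wander about their average positions.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param selection optional tag (or vector of tags) restricting the atom
#'   set; default all atoms.
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2L)
    validation_error("RMSD needs >= 2 frames")
  sel <- if (is.null(selection)) rep(TRUE, nrow(traj$atoms))
         else traj$atoms$tag %in% selection
  if (!any(sel))
    validation_error(sprintf("selection '%s' matches no atoms",
                             paste(selection, collapse = ",")))
  arr <- coords_array(traj, sel)
  ref <- apply(arr, c(1, 2), mean)
  vapply(seq_len(dim(arr)[3]), function(k)
    sqrt(mean(rowSums((arr[, , k] - ref)^2))), numeric(1))
}

#' Per-frame bilayer thickness from phosphate planes
#'
#' Each frame's P-tagged atoms are split into leaflets by their z position
#' relative to the per-frame median (robust to whole-membrane drift);
#' thickness is the difference of the leaflet mean z values.
#'
#' @param traj a [trajectory()] containing `"P"`-tagged atoms in both
#'   leaflets.
#' @param tag phosphate tag, default `"P"`.
#' @return Numeric vector of per-frame thickness (Angstrom).
#' @export
bilayer_thickness <- function(traj, tag = "P") {
  stopifnot(inherits(traj, "trajectory"))
  sel <- traj$atoms$tag %in% tag
  if (!any(sel))
    validation_error(sprintf("no '%s'-tagged atoms in trajectory", tag))
  vapply(traj$frames, function(f) {
    z <- f[sel, 3]
    mid <- stats::median(z)
    up <- z > mid; lo <- z < mid
    # atoms exactly on the midplane go to the lower leaflet
    lo <- lo | (z == mid)
    if (!any(up) || !any(lo & !up))
      validation_error("all P atoms fall on one side of the midplane; cannot assign leaflets")
    mean(z[up]) - mean(z[lo])
  }, numeric(1))
}

#' Carve solvent out of a ligand's padded bounding box
#'
#' Computes the ligand's axis-aligned bounding box, expands it by `pad` on
#' each side of every axis, and deletes every water whose representative
#' coordinate falls inside the expanded ranges on x AND y AND z
#' simultaneously. This clears a pocket of solvent where a ligand is placed
#' on a hydrated membrane.
#'
#' @param ligand numeric n x 3 matrix of ligand coordinates (Angstrom),
#'   non-empty.
#' @param waters numeric m x 3 matrix of water representative coordinates
#'   (one row per molecule, e.g. the oxygen position).
#' @param pad box padding per side (Angstrom), >= 0, default 2.
#' @return list with `retained` (matrix of surviving waters), `deleted_idx`
#'   (row indices of deleted waters) and `box` (the expanded 2 x 3 range
#'   matrix).
#' @export
#' @examples
#' lig <- rbind(c(0, 0, 0), c(10, 10, 10))
#' carve_solvent(lig, rbind(c(11, 5, 5), c(13, 5, 5)))$deleted_idx  # 1
carve_solvent <- function(ligand, waters, pad = 2) {
  ligand <- as.matrix(ligand); waters <- as.matrix(waters)
  if (nrow(ligand) == 0L) validation_error("ligand has no atoms")
  if (ncol(ligand) != 3L || (nrow(waters) > 0L && ncol(waters) != 3L))
    validation_error("coordinates must have 3 columns (x, y, z)")
  if (!is.numeric(pad) || length(pad) != 1L || !is.finite(pad) || pad < 0)
    domain_error("pad must be a single number >= 0")
  box <- apply(ligand, 2, range)
  box[1, ] <- box[1, ] - pad
  box[2, ] <- box[2, ] + pad
  dimnames(box) <- list(c("min", "max"), c("x", "y", "z"))
  if (nrow(waters) == 0L)
    return(list(retained = waters, deleted_idx = integer(0), box = box))
  inside <- waters[, 1] >= box[1, 1] & waters[, 1] <= box[2, 1] &
            waters[, 2] >= box[1, 2] & waters[, 2] <= box[2, 2] &
            waters[, 3] >= box[1, 3] & waters[, 3] <= box[2, 3]
  list(retained = waters[!inside, , drop = FALSE],
       deleted_idx = which(inside), box = box)
}

#' Insertion-centre coordinates of the upper membrane surface
#'
#' The (A, B, C) point above which a ligand is placed before carving:
#' A and B are the midpoints of the extreme phosphate x and y coordinates;
#' C is the midpoint between the outermost (maximum-z) phosphate and the
#' highest water along z, i.e. halfway between the upper leaflet headgroup
#' plane and the top of the water slab.
#'
#' @param frame numeric n x 3 coordinate matrix for one frame.
#' @param tags character vector of atom tags, one per row of `frame`.
#' @param p_tag,water_tag tag values for phosphates and water
#'   representative atoms, defaults `"P"` and `"W"`.
#' @return Named numeric vector `c(A, B, C)` (Angstrom).
#' @export
insertion_center <- function(frame, tags, p_tag = "P", water_tag = "W") {
  frame <- as.matrix(frame)
  if (nrow(frame) != length(tags))
    validation_error("tags must have one entry per coordinate row")
  p <- frame[tags %in% p_tag, , drop = FALSE]
  w <- frame[tags %in% water_tag, , drop = FALSE]
  if (nrow(p) == 0L) validation_error("no phosphate (P) atoms in frame")
  if (nrow(w) == 0L) validation_error("no water (W) atoms in frame")
  A <- (min(p[, 1]) + max(p[, 1])) / 2
  B <- (min(p[, 2]) + max(p[, 2])) / 2
  C <- (max(p[, 3]) + max(w[, 3])) / 2
  c(A = A, B = B, C = C)
}
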