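static_traj <- function(coords, tags, n_frames = 3) {
  trajectory(replicate(n_frames, coords, simplify = FALSE),
             data.frame(id = seq_along(tags), tag = tags))
}

test_that("RMSD of a static trajectory is zero; alternating atom gives 1", {
  coords <- matrix(rnorm(30), ncol = 3)
  expect_equal(rmsd_series(static_traj(coords, rep("P", 10))), rep(0, 3))

  # one atom alternating z = +1 / -1: time mean 0, RMSD 1 every frame
  f1 <- matrix(c(0, 0, 1), 1); f2 <- matrix(c(0, 0, -1), 1)
  traj <- trajectory(list(f1, f2, f1, f2), data.frame(id = 1, tag = "P"))
  expect_equal(rmsd_series(traj), rep(1, 4))
})

test_that("RMSD matches the brute-force double loop on random trajectories", {
  set.seed(51)
  frames <- replicate(20, matrix(rnorm(150), ncol = 3), simplify = FALSE)
  tags <- sample(c("P", "W"), 50, replace = TRUE)
  traj <- trajectory(frames, data.frame(id = 1:50, tag = tags))
  expect_equal(rmsd_series(traj), rmsd_bruteforce(frames), tolerance = 1e-12)
  sel <- which(tags == "P")
  expect_equal(rmsd_series(traj, "P"), rmsd_bruteforce(frames, sel),
               tolerance = 1e-12)
  expect_error(rmsd_series(traj, "XX"), class = "dermakin_validation_error")
})

test_that("RMSD is invariant under a rigid translation of all frames", {
  set.seed(52)
  frames <- replicate(8, matrix(rnorm(60), ncol = 3), simplify = FALSE)
  traj <- trajectory(frames, data.frame(id = 1:20, tag = rep("P", 20)))
  shifted <- trajectory(lapply(frames, function(f) sweep(f, 2, c(5, -3, 11), `+`)),
                        traj$atoms)
  expect_equal(rmsd_series(traj), rmsd_series(shifted), tolerance = 1e-10)
})

test_that("bilayer thickness from constructed leaflets, with drift invariance", {
  up <- cbind(runif(50, 0, 60), runif(50, 0, 60), 25)
  lo <- cbind(runif(50, 0, 60), runif(50, 0, 60), -25)
  coords <- rbind(up, lo)
  traj <- static_traj(coords, rep("P", 100))
  expect_equal(bilayer_thickness(traj), rep(50, 3))

  shifted <- static_traj(sweep(coords, 2, c(0, 0, 10), `+`), rep("P", 100))
  expect_equal(bilayer_thickness(shifted), rep(50, 3))

  flat <- static_traj(cbind(runif(10), runif(10), 5), rep("P", 10))
  expect_error(bilayer_thickness(flat), class = "dermakin_validation_error")
  expect_error(bilayer_thickness(static_traj(coords, rep("W", 100))),
               class = "dermakin_validation_error")
})

test_that("thickness under jitter stays within the standard-error band", {
  traj <- make_trajectory(n_lipids_per_leaflet = 100, thickness = 50,
                          n_frames = 50, jitter_sd = 1, seed = 53)
  th <- bilayer_thickness(traj)
  # per-frame SE of the leaflet-mean difference is sqrt(2/100) = 0.14
  expect_true(all(abs(th - 50) < 0.5))
  expect_equal(mean(th), 50, tolerance = 0.005)
})

test_that("solvent carving follows the padded-box AND rule", {
  lig <- rbind(c(0, 0, 0), c(10, 10, 10))
  waters <- rbind(c(11, 5, 5),    # inside padded box -> deleted
                  c(13, 5, 5),    # x outside [-2, 12] -> retained
                  c(11, 5, -3),   # z outside [-2, 12] -> retained (AND rule)
                  c(5, 5, 5))     # deep inside -> deleted
  cs <- carve_solvent(lig, waters, pad = 2)
  expect_equal(cs$deleted_idx, c(1L, 4L))
  expect_equal(nrow(cs$retained), 2)

  # pad 0 reduces to the exact bounding box
  cs0 <- carve_solvent(lig, waters, pad = 0)
  expect_equal(cs0$deleted_idx, 4L)

  # retained count is non-increasing in pad
  set.seed(54)
  w <- matrix(runif(300, -10, 20), ncol = 3)
  kept <- vapply(c(0, 1, 2, 4, 8),
                 function(p) nrow(carve_solvent(lig, w, p)$retained),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))

  expect_error(carve_solvent(lig[0, ], waters),
               class = "dermakin_validation_error")
  expect_error(carve_solvent(lig, waters, pad = -1),
               class = "dermakin_domain_error")
})

test_that("insertion centre midpoints and translation invariance", {
  p <- rbind(c(0, 5, 25), c(60, 15, 24), c(30, 0, 25), c(30, 40, -25))
  w <- rbind(c(10, 10, 40), c(20, 20, 35))
  coords <- rbind(p, w)
  tags <- c(rep("P", 4), rep("W", 2))
  ic <- insertion_center(coords, tags)
  expect_equal(unname(ic["A"]), 30)       # midpoint of P x extremes {0, 60}
  expect_equal(unname(ic["B"]), 20)       # midpoint of P y extremes {0, 40}
  expect_equal(unname(ic["C"]), 32.5)     # midpoint of top P z 25 and top water z 40

  shift <- c(7, -2, 3)
  ic2 <- insertion_center(sweep(coords, 2, shift, `+`), tags)
  expect_equal(unname(ic2), unname(ic) + shift)

  expect_error(insertion_center(w, rep("W", 2)),
               class = "dermakin_validation_error")
  expect_error(insertion_center(p, rep("P", 4)),
               class = "dermakin_validation_error")
})

test_that("trajectory readers round-trip tabular and XYZ formats", {
  traj <- make_trajectory(n_lipids_per_leaflet = 4, n_frames = 3,
                          jitter_sd = 0.5, seed = 55, n_waters = 5)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, p)
  back <- read_trajectory(p)
  expect_equal(back$frames, traj$frames, tolerance = 1e-12)
  expect_equal(back$atoms$tag, traj$atoms$tag)

  # XYZ round trip
  px <- withr::local_tempfile(fileext = ".xyz")
  lines <- unlist(lapply(traj$frames, function(f) {
    c(nrow(f), "frame",
      sprintf("%s %.10f %.10f %.10f", traj$atoms$tag, f[, 1], f[, 2], f[, 3]))
  }))
  writeLines(lines, px)
  bx <- read_trajectory(px)
  expect_equal(bx$frames, traj$frames, tolerance = 1e-9)
  expect_equal(bx$atoms$tag, traj$atoms$tag)

  writeLines(c("2", "c", "P 1 2 3"), px)
  expect_error(read_trajectory(px), class = "dermakin_format_error")
})

test_that("PDB frames load through bio3d with P tags preserved", {
  skip_if_not_installed("bio3d")
  p <- withr::local_tempfile(fileext = ".pdb")
  mk_atom <- function(serial, name, x, y, z)
    sprintf("ATOM  %5d %-4s LIG A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, 1, x, y, z, substr(name, 1, 1))
  writeLines(c("MODEL     1",
               mk_atom(1, "P", 0, 0, 25), mk_atom(2, "P", 8, 0, -25),
               "ENDMDL", "MODEL     2",
               mk_atom(1, "P", 0, 0, 26), mk_atom(2, "P", 8, 0, -26),
               "ENDMDL", "END"), p)
  traj <- read_trajectory(p)
  expect_equal(length(traj$frames), 2)
  expect_equal(traj$atoms$tag, c("P", "P"))
  expect_equal(traj$frames[[2]][1, 3], 26)
})
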