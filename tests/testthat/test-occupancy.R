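test_that("minimum inter-atomic distance matches brute force", {
  atoms <- rbind(
    data.frame(frame = 1L, group = "LIG", x = 0, y = 0, z = 0),
    data.frame(frame = 1L, group = "RES", x = 3, y = 4, z = 0))
  traj <- trajectory(atoms)
  expect_equal(min_distance_series(traj, "LIG", "RES"), 5)

  atoms$x[2] <- 0; atoms$y[2] <- 0
  expect_equal(min_distance_series(trajectory(atoms), "LIG", "RES"), 0)
  expect_error(min_distance_series(traj, "LIG", "nope"), "no atoms")

  # random 5-atom clouds over several frames vs all-pairs brute force
  set.seed(14)
  for (r in 1:5) {
    nf <- 4L
    mk <- function(g) do.call(rbind, lapply(1:nf, function(f)
      data.frame(frame = f, group = g, x = runif(5, -10, 10),
                 y = runif(5, -10, 10), z = runif(5, -10, 10))))
    a <- rbind(mk("LIG"), mk("RES"))
    tr <- trajectory(a)
    got <- min_distance_series(tr, "LIG", "RES")
    want <- vapply(1:nf, function(f) {
      L <- as.matrix(a[a$group == "LIG" & a$frame == f, c("x", "y", "z")])
      R <- as.matrix(a[a$group == "RES" & a$frame == f, c("x", "y", "z")])
      min(apply(L, 1, function(p) min(sqrt(colSums((t(R) - p)^2)))))
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("dual-cutoff occupancy applies hysteresis from an unbound start", {
  expect_equal(dual_cutoff_occupancy(c(2, 3, 4, 2))$occupancy, 0.75)
  expect_equal(dual_cutoff_occupancy(rep(5, 10))$occupancy, 0)
  expect_equal(dual_cutoff_occupancy(rep(2, 10))$occupancy, 1)
  # 3.0 A alone never initiates binding (below upper but not below lower)
  expect_equal(dual_cutoff_occupancy(c(3, 3, 3))$occupancy, 0)

  r <- dual_cutoff_occupancy(c(2, 3, 4, 2))
  expect_equal(r$bound, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(r$intervals, data.frame(start = c(1L, 4L), end = c(3L, 5L)))
  expect_error(dual_cutoff_occupancy(c(2, NA, 3)), "finite")
  expect_error(dual_cutoff_occupancy(1:3, lower = 4, upper = 3), "cutoff")
})

test_that("equal cutoffs reduce to thresholding and occupancy grows with the upper cutoff", {
  set.seed(23)
  for (r in 1:10) {
    d <- runif(60, 1, 6)
    c0 <- 3.1
    expect_equal(dual_cutoff_occupancy(d, c0, c0)$occupancy, mean(d < c0))
    prev <- -1
    for (up in c(2.5, 3.0, 3.5, 4.5, 5.5)) {
      occ <- dual_cutoff_occupancy(d, 2.5, up)$occupancy
      expect_gte(occ, prev)
      prev <- occ
    }
  }
})

test_that("generated dwell trajectories agree exactly with their analytic occupancy", {
  g <- generate_trajectory(dwell_bound = 7, dwell_unbound = 13, n_frames = 200)
  d <- min_distance_series(g$trajectory, "LIG", "RES")
  expect_equal(d, g$distances, tolerance = 1e-12)
  occ <- dual_cutoff_occupancy(d)
  expect_equal(occ$occupancy, g$analytic_occupancy)

  g <- generate_trajectory(distances = c(2.0, 3.0, 4.0, 2.0))
  expect_equal(g$analytic_occupancy, 0.75)
  expect_equal(generate_trajectory(distances = rep(2, 5))$analytic_occupancy, 1)
  expect_equal(generate_trajectory(distances = rep(5, 5))$analytic_occupancy, 0)
})

test_that("per-residue occupancy maximizes over ligand copies", {
  n <- 10L
  atoms <- rbind(
    data.frame(frame = 1:n, group = "RES", x = 0, y = 0, z = 0),
    data.frame(frame = 1:n, group = "LIG1",
               x = c(rep(2, 5), rep(6, 5)), y = 0, z = 0),
    data.frame(frame = 1:n, group = "LIG2",
               x = c(rep(6, 5), rep(2, 5)), y = 0, z = 0))
  occ <- residue_occupancy(trajectory(atoms), "RES", c("LIG1", "LIG2"))
  expect_equal(occ$occupancy, 0.5)  # max over copies, not the sum (1.0)
})

test_that("density grid conserves observations and localizes mass correctly", {
  n <- 20L
  atoms <- rbind(
    data.frame(frame = 1:n, group = "LIG", x = 0.5, y = 0.5, z = 0.5),
    data.frame(frame = 1:n, group = "RES", x = 5, y = 5, z = 5))
  g <- density_grid(trajectory(atoms), "LIG", voxel = 1)
  expect_equal(sum(g$counts), 1)          # stationary atom: one voxel, value 1
  expect_equal(max(g$counts), 1)

  # atom alternating between two voxels: half the mass in each
  atoms2 <- data.frame(frame = 1:n, group = "LIG",
                       x = rep(c(0.5, 1.5), n / 2), y = 0.5, z = 0.5)
  g2 <- density_grid(trajectory(atoms2), "LIG", voxel = 1)
  expect_equal(sort(g2$counts[g2$counts > 0]), c(0.5, 0.5))

  # conservation: total mass x frames = number of in-grid observations
  set.seed(4)
  atoms3 <- data.frame(frame = rep(1:15, each = 3), group = "LIG",
                       x = runif(45, 0, 8), y = runif(45, 0, 8),
                       z = runif(45, 0, 8))
  g3 <- density_grid(trajectory(atoms3), "LIG", voxel = 1)
  expect_equal(sum(g3$counts) * g3$n_frames, 45)
  expect_error(density_grid(trajectory(atoms3), "nope"), "empty")

  # uniform positions approach uniform per-voxel mass (law of large numbers)
  set.seed(8)
  nf <- 4000L
  atoms4 <- data.frame(frame = 1:nf, group = "LIG",
                       x = runif(nf, 0, 4), y = runif(nf, 0, 4),
                       z = runif(nf, 0, 4))
  g4 <- density_grid(trajectory(atoms4), "LIG", voxel = 1,
                     origin = c(0, 0, 0), dims = c(4L, 4L, 4L))
  expect_equal(mean(g4$counts), 1 / 64, tolerance = 1e-12)
  p <- 1 / 64
  se3 <- 3 * sqrt(p * (1 - p) / nf)
  expect_true(all(abs(g4$counts - p) < se3 + 2e-3))
})

test_that("trajectory text formats round-trip and PDB models import as frames", {
  g <- generate_trajectory(distances = c(2.1, 3.3, 4.8), seed = 2)
  path <- tempfile(fileext = ".xyz")
  write_xyz_frames(g$trajectory, path)
  back <- read_xyz_frames(path)
  expect_equal(back$n_frames, g$trajectory$n_frames)
  expect_setequal(unique(back$atoms$group), c("LIG", "RES"))
  expect_equal(min_distance_series(back, "LIG", "RES"), g$distances,
               tolerance = 1e-6)

  # two-model PDB written in code: ligand moves away from the residue
  pdb_path <- tempfile(fileext = ".pdb")
  fmt <- function(serial, name, resid, resno, x, y, z)
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, resid, resno, x, y, z)
  writeLines(c(
    "MODEL        1",
    fmt(1, "C1", "LIG", 1, 2.0, 0, 0), fmt(2, "CA", "TYR", 234, 0, 0, 0),
    "ENDMDL",
    "MODEL        2",
    fmt(1, "C1", "LIG", 1, 5.0, 0, 0), fmt(2, "CA", "TYR", 234, 0, 0, 0),
    "ENDMDL", "END"), pdb_path)
  traj <- read_trajectory_pdb(pdb_path)
  expect_equal(traj$n_frames, 2L)
  expect_equal(min_distance_series(traj, "LIG1", "TYR234"), c(2, 5),
               tolerance = 1e-6)

  # OpenDX export is parseable text with the declared item count
  grid <- density_grid(g$trajectory, "LIG", voxel = 1)
  dx <- tempfile(fileext = ".dx")
  write_dx(grid, dx)
  lines <- readLines(dx)
  expect_match(lines[1], "gridpositions")
  expect_match(lines[7], sprintf("items %d", length(grid$counts)))
})
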