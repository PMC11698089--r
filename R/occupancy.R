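#' Coordinate trajectory container
#'
#' Holds per-frame coordinates (Angstrom) of named atoms grouped by residue
#' or ligand molecule. The atom roster must be identical in every frame.
#'
#' @param atoms data.frame with columns `frame` (1..n, integer), `group`
#'   (residue or ligand identifier), `x`, `y`, `z`.
#' @param frame_interval spacing between frames, arbitrary time units.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(atoms, frame_interval = 1) {
  stopifnot(is.data.frame(atoms),
            all(c("frame", "group", "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates")
  counts <- table(atoms$frame, atoms$group)
  if (nrow(counts) > 1L && any(apply(counts, 2L, function(cc) length(unique(cc)) > 1L)))
    stop("atom roster must be constant across frames")
  structure(list(atoms = atoms, n_frames = length(unique(atoms$frame)),
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames, groups: %s\n", x$n_frames,
              paste(unique(x$atoms$group), collapse = ", ")))
  invisible(x)
}

#' Per-frame minimum ligand-residue distance
#'
#' Frame-wise minimum over all ligand-atom x residue-atom pairs, plain
#' Euclidean distance (optionally under orthorhombic periodic imaging for
#' membrane-box inputs).
#'
#' @param traj a [trajectory].
#' @param ligand,residue group identifiers present in the trajectory.
#' @param box optional length-3 orthorhombic box vector (Angstrom) for
#'   minimum-image distances.
#' @return numeric vector, one minimum distance (Angstrom) per frame.
#' @export
min_distance_series <- function(traj, ligand, residue, box = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  a <- traj$atoms
  if (!ligand %in% a$group) stop(sprintf("no atoms for ligand '%s'", ligand))
  if (!residue %in% a$group) stop(sprintf("no atoms for residue '%s'", residue))
  la <- a[a$group == ligand, ]
  ra <- a[a$group == residue, ]
  frames <- sort(unique(a$frame))
  vapply(frames, function(f) {
    L <- as.matrix(la[la$frame == f, c("x", "y", "z")])
    R <- as.matrix(ra[ra$frame == f, c("x", "y", "z")])
    if (!nrow(L) || !nrow(R)) stop("missing atoms in a frame")
    d2 <- 0
    dmin <- Inf
    for (i in seq_len(nrow(L))) {
      d <- sweep(R, 2L, L[i, ])
      if (!is.null(box)) d <- d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
      dmin <- min(dmin, sqrt(min(rowSums(d^2))))
    }
    dmin
  }, numeric(1))
}

#' Dual-cutoff hysteresis occupancy of a distance series
#'
#' Two-state machine starting unbound: the ligand becomes bound when the
#' minimum distance drops below `lower` and unbound again only when it
#' exceeds `upper`, suppressing the rapid flickering a single threshold
#' would produce ("rattling in a cage"). A frame counts as bound if the
#' state after processing that frame is bound. Defaults follow the
#' 2.5 / 3.5 Angstrom convention.
#'
#' @param series numeric vector of per-frame minimum distances (Angstrom).
#' @param lower,upper cutoffs (Angstrom), `lower < upper` (equal cutoffs
#'   reduce to simple thresholding).
#' @return list: `occupancy` (bound-frame fraction), `bound` (logical per
#'   frame), `intervals` (data.frame of half-open bound frame ranges
#'   `[start, end)`, 1-based).
#' @export
dual_cutoff_occupancy <- function(series, lower = 2.5, upper = 3.5) {
  if (!all(is.finite(series))) stop("non-finite distances")
  if (lower > upper) stop("lower cutoff must not exceed upper cutoff")
  n <- length(series)
  bound <- logical(n)
  state <- FALSE
  for (i in seq_len(n)) {
    if (!state && series[i] < lower) state <- TRUE
    else if (state && series[i] > upper) state <- FALSE
    bound[i] <- state
  }
  intervals <- data.frame(start = integer(0), end = integer(0))
  if (any(bound)) {
    r <- rle(bound)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values
    intervals <- data.frame(start = starts[sel], end = ends[sel] + 1L)
  }
  list(occupancy = mean(bound), bound = bound, intervals = intervals,
       lower = lower, upper = upper)
}

#' Per-residue contact occupancy across ligand copies
#'
#' Applies the dual-cutoff rule to every (ligand copy, residue) pair and
#' reports, per residue, the maximum occupancy over copies (a residue is
#' not more than fully occupied however many copies visit it).
#'
#' @param traj a [trajectory].
#' @param residues residue group identifiers.
#' @param ligands ligand group identifiers.
#' @param lower,upper dual cutoffs (Angstrom).
#' @param box optional periodic box, see [min_distance_series()].
#' @return data.frame: `residue`, `occupancy`, `best_ligand`.
#' @export
residue_occupancy <- function(traj, residues, ligands, lower = 2.5,
                              upper = 3.5, box = NULL) {
  rows <- lapply(residues, function(res) {
    occ <- vapply(ligands, function(lig)
      dual_cutoff_occupancy(min_distance_series(traj, lig, res, box),
                            lower, upper)$occupancy, numeric(1))
    data.frame(residue = res, occupancy = max(occ),
               best_ligand = ligands[which.max(occ)])
  })
  do.call(rbind, rows)
}

#' Time-averaged ligand density grid
#'
#' Accumulates ligand-atom positions into cubic voxels per frame and divides
#' by the frame count, so the grid total times the frame count equals the
#' number of ligand-atom observations. Multiple trajectories (replicates)
#' may be averaged.
#'
#' @param trajs a [trajectory] or list of trajectories (replicates).
#' @param selection ligand group identifier(s).
#' @param voxel voxel edge length (Angstrom, > 0); 1 Angstrom default.
#' @param origin optional grid origin; defaults to the floor of the minimum
#'   coordinate over all replicates.
#' @param dims optional grid dimensions (voxels per axis).
#' @return object of class `density_grid`: `origin`, `voxel`, `counts`
#'   (3D array, mean atoms per voxel per frame), `n_frames`.
#' @export
density_grid <- function(trajs, selection, voxel = 1.0, origin = NULL,
                         dims = NULL) {
  if (voxel <= 0) stop("voxel must be positive")
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  sel_atoms <- lapply(trajs, function(tr) {
    a <- tr$atoms[tr$atoms$group %in% selection, ]
    if (!nrow(a)) stop("empty ligand selection")
    a
  })
  all_xyz <- do.call(rbind, lapply(sel_atoms, function(a) a[, c("x", "y", "z")]))
  if (is.null(origin)) origin <- floor(apply(all_xyz, 2L, min) / voxel) * voxel
  if (is.null(dims))
    dims <- pmax(1L, as.integer(floor((apply(all_xyz, 2L, max) - origin) / voxel)) + 1L)
  acc <- array(0, dim = dims)
  total_frames <- 0L
  for (a in sel_atoms) {
    nf <- length(unique(a$frame))
    total_frames <- total_frames + nf
    ix <- floor((a$x - origin[1]) / voxel) + 1L
    iy <- floor((a$y - origin[2]) / voxel) + 1L
    iz <- floor((a$z - origin[3]) / voxel) + 1L
    keep <- ix >= 1L & ix <= dims[1] & iy >= 1L & iy <= dims[2] &
      iz >= 1L & iz <= dims[3]
    for (j in which(keep)) acc[ix[j], iy[j], iz[j]] <- acc[ix[j], iy[j], iz[j]] + 1
  }
  structure(list(origin = origin, voxel = voxel,
                 counts = acc / total_frames, n_frames = total_frames),
            class = "density_grid")
}

#' Write a density grid as OpenDX-style text
#'
#' @param grid a `density_grid`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- dim(grid$counts)
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$voxel),
    sprintf("delta 0 %g 0", grid$voxel),
    sprintf("delta 0 0 %g", grid$voxel),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX data order: z fastest-varying
  vals <- grid$counts[cbind(
    rep(seq_len(d[1]), each = d[2] * d[3]),
    rep(rep(seq_len(d[2]), each = d[3]), times = d[1]),
    rep(seq_len(d[3]), times = d[1] * d[2]))]
  writeLines(apply(matrix(c(vals, rep(NA, (3 - length(vals) %% 3) %% 3)),
                          ncol = 3, byrow = TRUE), 1L,
                   function(r) paste(stats::na.omit(r), collapse = " ")), con)
  invisible(path)
}

#' Generate a synthetic trajectory with known occupancy
#'
#' Builds a single-atom ligand and single-atom residue whose separation
#' follows either an explicit distance series or an alternating bound /
#' unbound dwell model, and returns the occupancy the dual-cutoff rule
#' implies on the noiseless series — the analytic ground truth for the
#' analyzer.
#'
#' @param distances explicit per-frame distance series (Angstrom), or NULL
#'   to use the dwell model.
#' @param dwell_bound,dwell_unbound dwell lengths (frames) of the
#'   alternating model, recycled until `n_frames`.
#' @param n_frames number of frames when using the dwell model.
#' @param bound_distance,unbound_distance distances emitted in the two
#'   dwell states (defaults 2.0 and 5.0 Angstrom, beyond both cutoffs).
#' @param lower,upper dual cutoffs used for the analytic occupancy.
#' @param seed RNG seed (used only to jitter transverse coordinates, which
#'   does not change the inter-atomic distance).
#' @return list: `trajectory`, `distances`, `analytic_occupancy`,
#'   `analytic` (full [dual_cutoff_occupancy()] result).
#' @export
generate_trajectory <- function(distances = NULL, dwell_bound = 10L,
                                dwell_unbound = 10L, n_frames = 100L,
                                bound_distance = 2.0, unbound_distance = 5.0,
                                lower = 2.5, upper = 3.5, seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(distances)) {
    if (n_frames < 1L) stop("n_frames must be >= 1")
    state <- rep(c(rep(TRUE, dwell_bound), rep(FALSE, dwell_unbound)),
                 length.out = n_frames)
    distances <- ifelse(state, bound_distance, unbound_distance)
  }
  n <- length(distances)
  atoms <- rbind(
    data.frame(frame = seq_len(n), group = "RES", x = 0, y = 0, z = 0),
    data.frame(frame = seq_len(n), group = "LIG", x = distances, y = 0, z = 0))
  traj <- trajectory(atoms)
  analytic <- dual_cutoff_occupancy(distances, lower, upper)
  list(trajectory = traj, distances = distances,
       analytic_occupancy = analytic$occupancy, analytic = analytic)
}
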