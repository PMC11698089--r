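#' Write a trajectory as plain XYZ-per-frame text
#'
#' Standard multi-frame XYZ layout: an atom-count line, a comment line
#' (`frame <i>`), then one `group x y z` line per atom, repeated per frame.
#'
#' @param traj a [trajectory].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz_frames <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "wt"); on.exit(close(con))
  for (f in sort(unique(traj$atoms$frame))) {
    a <- traj$atoms[traj$atoms$frame == f, ]
    writeLines(c(as.character(nrow(a)), sprintf("frame %d", f),
                 sprintf("%s %.6f %.6f %.6f", a$group, a$x, a$y, a$z)), con)
  }
  invisible(path)
}

#' Read a plain XYZ-per-frame trajectory
#'
#' @param path file written in the layout of [write_xyz_frames()]; the atom
#'   name column is taken as the group identifier.
#' @param frame_interval frame spacing.
#' @return a [trajectory].
#' @export
read_xyz_frames <- function(path, frame_interval = 1) {
  lines <- readLines(path)
  i <- 1L; frame <- 0L; rows <- list()
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("expected atom count at line %d", i))
    frame <- frame + 1L
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    rows[[frame]] <- data.frame(
      frame = frame,
      group = vapply(parts, `[`, character(1), 1L),
      x = as.numeric(vapply(parts, `[`, character(1), 2L)),
      y = as.numeric(vapply(parts, `[`, character(1), 3L)),
      z = as.numeric(vapply(parts, `[`, character(1), 4L)))
    i <- i + 2L + n
  }
  trajectory(do.call(rbind, rows), frame_interval)
}

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL becomes a frame; atoms are grouped as `<resid><resno>`
#' (e.g. `TYR234`, `LIG1`), so ligand molecules and residues can be selected
#' by group identifier in the occupancy functions.
#'
#' @param path multi-model PDB file.
#' @param frame_interval frame spacing.
#' @return a [trajectory].
#' @export
read_trajectory_pdb <- function(path, frame_interval = 1) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  n_atoms <- nrow(pdb$atom)
  n_frames <- nrow(xyz)
  group <- paste0(pdb$atom$resid, pdb$atom$resno)
  rows <- lapply(seq_len(n_frames), function(f) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    data.frame(frame = f, group = group, x = m[, 1], y = m[, 2], z = m[, 3])
  })
  trajectory(do.call(rbind, rows), frame_interval)
}
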