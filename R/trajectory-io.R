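#' Trajectory container
#'
#' A minimal in-memory molecular trajectory: an atom table plus a
#' frames x atoms x 3 coordinate array in angstrom, with a fixed frame
#' interval in nanoseconds.  Residue numbers are kept 1-based exactly as in
#' the source PDB; frame indices are 1-based as usual in R.
#'
#' @param atoms data.frame with columns `name`, `resname`, `resno`, `chain`.
#' @param coords numeric array of dimension `c(n_frames, n_atoms, 3)` (A).
#' @param frame_interval time between frames in ns (default 0.1).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, frame_interval = 0.1) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "resname", "resno", "chain") %in% names(atoms)))
  if (length(dim(coords)) == 2L)
    coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (dim(coords)[2] != nrow(atoms))
    stop("coords second dimension must equal number of atoms")
  if (any(!is.finite(coords)))
    stop("coordinates must be finite")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(atoms = atoms, coords = coords,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", n_frames(x), "frames,", nrow(x$atoms), "atoms,",
      "frame interval", x$frame_interval, "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Read a trajectory from a PDB topology and optional frame data
#'
#' The topology must be a PDB file.  Frames can come from a multi-model PDB
#' or from a plain whitespace-delimited text file with one `x y z` row per
#' atom, frames concatenated (atom count taken from the topology).  If
#' `frames_path` is `NULL`, the models in the topology file itself are the
#' frames.
#'
#' @param topology_path path to a PDB file.
#' @param frames_path optional path to frame data (`.pdb` or plain xyz text).
#' @param frame_interval time between frames in ns.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(topology_path, frames_path = NULL,
                            frame_interval = 0.1) {
  pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(name = pdb$atom$elety,
                      resname = pdb$atom$resid,
                      resno = pdb$atom$resno,
                      chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
                      stringsAsFactors = FALSE)
  n_atoms <- nrow(atoms)
  if (is.null(frames_path)) {
    xyz <- pdb$xyz
    coords <- xyz_to_coords(xyz, n_atoms)
  } else if (grepl("\\.pdb$", frames_path, ignore.case = TRUE)) {
    check_model_atom_counts(frames_path, n_atoms)
    fp <- bio3d::read.pdb(frames_path, multi = TRUE, verbose = FALSE)
    coords <- xyz_to_coords(fp$xyz, n_atoms)
  } else {
    vals <- scan(frames_path, what = numeric(), quiet = TRUE,
                 comment.char = "#")
    if (length(vals) %% 3L != 0L)
      stop("frame file does not contain whole xyz triples")
    n_rows <- length(vals) %/% 3L
    if (n_rows %% n_atoms != 0L)
      stop("atom-count mismatch with topology (", n_atoms,
           " atoms) at frame ", n_rows %/% n_atoms + 1L)
    m <- matrix(vals, ncol = 3, byrow = TRUE)
    coords <- array(NA_real_, dim = c(n_rows %/% n_atoms, n_atoms, 3))
    for (f in seq_len(dim(coords)[1]))
      coords[f, , ] <- m[((f - 1) * n_atoms + 1):(f * n_atoms), ]
  }
  trajectory(atoms, coords, frame_interval)
}

# bio3d rejects multi-model files with inconsistent atom counts with a
# generic message; pre-scan so the error names the offending frame.
check_model_atom_counts <- function(path, n_atoms) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM|HETATM)", lines)
  if (length(model_starts) == 0L) {
    cnt <- sum(is_atom)
    if (cnt != n_atoms)
      stop("atom-count mismatch with topology at frame 1: found ", cnt,
           ", expected ", n_atoms)
    return(invisible(TRUE))
  }
  ends <- c(model_starts[-1] - 1L, length(lines))
  for (k in seq_along(model_starts)) {
    cnt <- sum(is_atom[model_starts[k]:ends[k]])
    if (cnt != n_atoms)
      stop("atom-count mismatch with topology at frame ", k, ": found ",
           cnt, ", expected ", n_atoms)
  }
  invisible(TRUE)
}

xyz_to_coords <- function(xyz, n_atoms) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * n_atoms)
    stop("atom-count mismatch with topology at frame 1: found ",
         ncol(xyz) %/% 3L, ", expected ", n_atoms)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, n_atoms, 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  coords
}

coords_to_xyz <- function(coords) {
  nf <- dim(coords)[1]
  na <- dim(coords)[2]
  xyz <- matrix(NA_real_, nf, 3 * na)
  for (f in seq_len(nf))
    xyz[f, ] <- as.vector(t(coords[f, , ]))
  xyz
}

#' Write a trajectory to disk
#'
#' A `.pdb` extension gives a (multi-model) PDB; anything else a plain
#' whitespace-delimited xyz file, one atom per row, frames concatenated.
#' Optionally also writes a single-model topology PDB of the first frame.
#'
#' @param traj a [trajectory()].
#' @param frames_path output path for the frames.
#' @param topology_path optional output path for a topology PDB.
#' @return `frames_path`, invisibly.
#' @export
write_trajectory <- function(traj, frames_path, topology_path = NULL) {
  if (!is.null(topology_path)) write_frame_pdb(traj, 1L, topology_path)
  if (grepl("\\.pdb$", frames_path, ignore.case = TRUE)) {
    xyz <- coords_to_xyz(traj$coords)
    a <- traj$atoms
    bio3d::write.pdb(pdb = NULL, file = frames_path, xyz = xyz,
                     resno = a$resno, resid = a$resname,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     chain = a$chain)
  } else {
    m <- do.call(rbind, lapply(seq_len(n_frames(traj)),
                               function(f) traj$coords[f, , , drop = FALSE][1, , ]))
    if (dim(traj$coords)[2] == 1L)
      m <- matrix(m, ncol = 3, byrow = FALSE)
    write.table(format(m, nsmall = 6, trim = TRUE, scientific = FALSE),
                frames_path, quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(frames_path)
}

write_frame_pdb <- function(traj, frame, path) {
  a <- traj$atoms
  xyz <- as.vector(t(traj$coords[frame, , , drop = TRUE]))
  if (nrow(a) == 1L) xyz <- as.vector(traj$coords[frame, 1, ])
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain)
  invisible(path)
}

#' Write representative frames as single-model PDB files
#'
#' One PDB per requested frame.  Duplicate frame indices get an ordinal
#' suffix so every request yields its own file.
#'
#' @param traj a [trajectory()].
#' @param frame_indices integer frame indices (1-based).
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths (empty if no indices).
#' @export
write_representatives <- function(traj, frame_indices, outdir,
                                  prefix = "representative") {
  if (length(frame_indices) == 0L) return(character(0))
  frame_indices <- as.integer(frame_indices)
  if (any(frame_indices < 1L | frame_indices > n_frames(traj)))
    stop("frame index out of range (1..", n_frames(traj), ")")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frame_indices))
  seen <- integer(0)
  for (k in seq_along(frame_indices)) {
    f <- frame_indices[k]
    times_seen <- sum(seen == f)
    suffix <- if (times_seen > 0) paste0("_", times_seen + 1L) else ""
    paths[k] <- file.path(outdir,
                          sprintf("%s_frame%d%s.pdb", prefix, f, suffix))
    write_frame_pdb(traj, f, paths[k])
    seen <- c(seen, f)
  }
  paths
}
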