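# frames x 3 coordinates of one atom
atom_coords <- function(traj, atom_idx) matrix(traj$coords[, atom_idx, ], ncol = 3)

# Per-frame minimum distance between two atom sets.
min_pair_distance <- function(traj, idx_a, idx_b) {
  nf <- n_frames(traj)
  out <- rep(Inf, nf)
  for (i in idx_a) {
    ci <- atom_coords(traj, i)
    for (j in idx_b) {
      cj <- atom_coords(traj, j)
      d <- sqrt(rowSums((ci - cj)^2))
      out <- pmin(out, d)
    }
  }
  out
}

#' Inter-helix distance
#'
#' Per-frame Euclidean distance (angstrom) between the centers of geometry
#' of the C-alpha atoms of two residue spans.
#'
#' @param traj a [trajectory()].
#' @param range_a,range_b residue selections (see [select_atoms()]).
#' @return a [feature_table()] of kind `helix_distance`.
#' @export
compute_helix_distance <- function(traj, range_a, range_b) {
  cog <- function(sel) {
    idx <- select_atoms(traj, sel)
    idx <- idx[traj$atoms$name[idx] == "CA"]
    if (length(idx) == 0L)
      stop("span '", paste(sel, collapse = ","), "' contains no CA atoms")
    m <- 0
    for (i in idx) m <- m + atom_coords(traj, i)
    m / length(idx)
  }
  d <- sqrt(rowSums((cog(range_a) - cog(range_b))^2))
  lab <- paste0(paste(range_a, collapse = ","), "~",
                paste(range_b, collapse = ","))
  feature_table(matrix(d, ncol = 1), kind = "helix_distance",
                selection = lab, units = "angstrom")
}

#' Capped ligand-residue distances
#'
#' Per frame and per residue, the minimum atom-pair distance between the
#' ligand and the residue, with values above `cap` replaced by `cap`.
#'
#' @param traj a [trajectory()].
#' @param ligand atom selection for the ligand.
#' @param residues atom selection for the residues of interest.
#' @param cap capping distance in angstrom (default 12, `Inf` = uncapped).
#' @return a [feature_table()] of kind `ligand_distance`, one column per
#'   residue.
#' @export
compute_ligand_distances <- function(traj, ligand, residues, cap = 12) {
  lig <- select_atoms(traj, ligand)
  if (length(lig) == 0L) stop("ligand selection matches no atoms")
  res_idx <- select_atoms(traj, residues)
  if (length(res_idx) == 0L) stop("residue selection matches no atoms")
  groups <- split_by_residue(traj, res_idx)
  cols <- lapply(groups, function(g) pmin(min_pair_distance(traj, lig, g), cap))
  labels <- vapply(names(groups), function(key) {
    g <- groups[[key]]
    paste0(traj$atoms$resname[g[1]], key)
  }, "")
  feature_table(do.call(cbind, cols), kind = "ligand_distance",
                selection = labels, units = "angstrom")
}

#' Contact residence report
#'
#' Fraction of frames in which the minimum distance between two selections
#' stays strictly below `cutoff`; a contact is called consistent when that
#' occupancy exceeds 50%.
#'
#' @param traj a [trajectory()].
#' @param sel_a,sel_b the two atom selections.
#' @param cutoff contact cutoff in angstrom (default 4).
#' @return list with `pair`, `cutoff`, `occupancy` and `consistent`.
#' @export
residence_time <- function(traj, sel_a, sel_b, cutoff = 4) {
  if (n_frames(traj) == 0L) stop("trajectory has no frames")
  ia <- select_atoms(traj, sel_a)
  ib <- select_atoms(traj, sel_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop("empty selection in residence_time")
  d <- min_pair_distance(traj, ia, ib)
  occ <- mean(d < cutoff)
  list(pair = paste(format(sel_a), format(sel_b), sep = " ~ "),
       cutoff = cutoff, occupancy = occ, consistent = occ > 0.5)
}
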