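#' Specification of a toy branching egress channel
#'
#' A 2-D energy surface with a binding basin at the origin, a confining
#' stem along +y, and two exit branches (at x = -c and x = +c) that open
#' beyond `y_split`.  Absorbing exits sit at `y >= y_exit`, disjoint from
#' the basin.  Labelled pseudo-residue anchor points line the tunnel and
#' serve as the "residues" for capped ligand-distance features.  Lengths
#' are in angstrom, energies in units of kT.
#'
#' @param kT thermal energy (energy unit; default 1).
#' @param diffusion diffusion coefficient D (A^2 per time unit).
#' @param dt Euler-Maruyama integration step.
#' @param kx quartic channel stiffness (kT).
#' @param branch_offset half-separation c of the two branches (A).
#' @param y_split y where the channel bifurcates (A).
#' @param split_width logistic width of the bifurcation (A).
#' @param tilt constant egress force along +y (kT/A).
#' @param basin_depth depth of the binding basin (kT).
#' @param basin_sigma width of the binding basin (A).
#' @param k_wall stiffness of the lower wall (kT/A^2).
#' @param y_min position of the lower wall (A).
#' @param y_exit absorbing exit line (A); must exceed `y_split`.
#' @param well_depth depth (kT) of the attractive Gaussian wells placed
#'   at every non-basin anchor point — the discrete interaction sites a
#'   ligand visits on its way out of a tunnel (0 = smooth channel).
#' @param well_sigma width of those wells (A).
#' @param block_height optional Gaussian barrier height (kT) blocking one
#'   branch (0 = symmetric channel).
#' @param block_x,block_y,block_sigma barrier center and width (A).
#' @param anchor_points named matrix (rows = pseudo-residues, columns x,y)
#'   lining the tunnel; at least 4 required.  Default: 7 anchors covering
#'   basin, stem and both branch arms.  The absorbing exit line lies more
#'   than one distance cap (12 A) beyond the last anchors, so fully
#'   exited frames saturate every feature at the cap and form a single
#'   unbound state regardless of exit branch, as for a ligand leaving a
#'   transporter tunnel into bulk solvent.
#' @param seed integer base seed.
#' @return an object of class `channel_spec`.
#' @export
channel_spec <- function(kT = 1, diffusion = 1, dt = 0.01,
                         kx = 8, branch_offset = 3, y_split = 3.5,
                         split_width = 0.5, tilt = 0.5,
                         basin_depth = 3, basin_sigma = 1,
                         k_wall = 10, y_min = -1, y_exit = 21,
                         block_height = 0, block_x = branch_offset,
                         block_y = y_split + 3, block_sigma = 1,
                         well_depth = 2, well_sigma = 0.8,
                         anchor_points = NULL, seed = 1L) {
  if (y_exit <= y_split)
    stop("absorbing exits must lie beyond the bifurcation (y_exit > y_split)")
  if (y_exit <= 2 * basin_sigma)
    stop("absorbing exits must be disjoint from the binding basin")
  if (is.null(anchor_points)) {
    c0 <- branch_offset
    anchor_points <- rbind(basin = c(0, 0),
                           stem_low = c(0, y_split / 2),
                           stem_high = c(0, y_split),
                           left_mid = c(-c0, y_split + 2.5),
                           left_upper = c(-c0, y_split + 5),
                           right_mid = c(c0, y_split + 2.5),
                           right_upper = c(c0, y_split + 5))
  }
  anchor_points <- as.matrix(anchor_points)
  if (nrow(anchor_points) < 4) stop("at least 4 anchor points required")
  if (is.null(rownames(anchor_points)))
    rownames(anchor_points) <- paste0("anchor", seq_len(nrow(anchor_points)))
  non_basin <- anchor_points[rowSums(anchor_points^2) > 1e-9, , drop = FALSE]
  wells <- if (well_depth > 0 && nrow(non_basin) > 0)
    cbind(non_basin[, 1], non_basin[, 2], well_depth, well_sigma)
  else matrix(0, 0, 4)
  structure(list(kT = kT, diffusion = diffusion, dt = dt, kx = kx,
                 branch_offset = branch_offset, y_split = y_split,
                 split_width = split_width, tilt = tilt,
                 basin_depth = basin_depth, basin_sigma = basin_sigma,
                 k_wall = k_wall, y_min = y_min, y_exit = y_exit,
                 block_height = block_height, block_x = block_x,
                 block_y = block_y, block_sigma = block_sigma,
                 wells = wells, anchor_points = anchor_points,
                 seed = as.integer(seed)),
            class = "channel_spec")
}

#' Simulate ligand egress through the branching channel
#'
#' Overdamped Langevin dynamics (Euler-Maruyama,
#' `x <- x - D grad(U) dt / kT + sqrt(2 D dt) xi`) started in the binding
#' basin; each trajectory runs until it crosses the absorbing exit line or
#' `max_steps` is reached.  Positions are recorded every `stride` steps.
#'
#' @param spec a [channel_spec()].
#' @param n_traj number of trajectories (default 200).
#' @param max_steps maximum integration steps per trajectory (default
#'   15000).
#' @param stride recording stride in steps (default 50).
#' @return list with `coords` (list of n x 2 matrices), `ground_truth`
#'   (whose `branch_labels` is a factor `left`/`right`/`none` per
#'   trajectory) and `spec`.
#' @export
generate_channel_egress <- function(spec, n_traj = 200L, max_steps = 15000L,
                                    stride = 50L) {
  stopifnot(inherits(spec, "channel_spec"), n_traj >= 1, max_steps >= 1)
  coords <- vector("list", n_traj)
  branch <- integer(n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(derive_seed(spec$seed, i))
    x0 <- rnorm(1, 0, 0.3)
    y0 <- rnorm(1, 0, 0.3)
    sim <- simulate_egress_cpp(x0, y0, as.integer(max_steps),
                               as.integer(stride),
                               spec$dt, spec$diffusion, spec$kT,
                               spec$kx, spec$branch_offset, spec$y_split,
                               spec$split_width, spec$tilt,
                               spec$basin_depth, spec$basin_sigma,
                               spec$k_wall, spec$y_min, spec$y_exit,
                               spec$block_height, spec$block_x,
                               spec$block_y, spec$block_sigma, spec$wells)
    coords[[i]] <- sim$coords
    branch[i] <- sim$branch
  }
  gt <- list(stationary = NULL, mfpt_matrix = NULL, slow_timescales = NULL,
             branch_labels = factor(c("none", "left", "right")[branch + 1L],
                                    levels = c("left", "right", "none")))
  class(gt) <- "ground_truth"
  list(coords = coords, ground_truth = gt, spec = spec)
}

#' Capped anchor-distance features of an egress run
#'
#' Euclidean distance from the ligand position to every anchor point,
#' capped at `cap` angstrom — the same feature the pathway detector trains
#' on for real ligand trajectories.
#'
#' @param egress result of [generate_channel_egress()].
#' @param cap distance cap in angstrom (default 12).
#' @return list with `features` (a [feature_table()] over all frames,
#'   trajectories concatenated) and `lengths` (frames per trajectory).
#' @export
egress_features <- function(egress, cap = 12) {
  anchors <- egress$spec$anchor_points
  mats <- lapply(egress$coords, function(xy) {
    d <- sqrt(outer(xy[, 1], anchors[, 1], "-")^2 +
              outer(xy[, 2], anchors[, 2], "-")^2)
    pmin(d, cap)
  })
  feats <- do.call(rbind, mats)
  list(features = feature_table(feats, kind = "ligand_distance",
                                selection = rownames(anchors),
                                units = "angstrom"),
       lengths = vapply(mats, nrow, 1L))
}

#' Convert one egress trajectory to a [trajectory()] object
#'
#' Anchors become fixed CA pseudo-atoms (residues `ANC` 1..n on chain A)
#' and the ligand a single `LIG` atom (resno n+1), all in the z = 0 plane,
#' so the generic featurization and representative-structure machinery can
#' run on synthetic egress data.
#'
#' @param egress result of [generate_channel_egress()].
#' @param index trajectory index.
#' @param frame_interval ns per recorded frame.
#' @return a [trajectory()].
#' @export
egress_trajectory <- function(egress, index, frame_interval = 0.1) {
  anchors <- egress$spec$anchor_points
  xy <- egress$coords[[index]]
  n_anchor <- nrow(anchors)
  atoms <- data.frame(
    name = c(rep("CA", n_anchor), "C1"),
    resname = c(rep("ANC", n_anchor), "LIG"),
    resno = c(seq_len(n_anchor), n_anchor + 1L),
    chain = "A", stringsAsFactors = FALSE)
  nf <- nrow(xy)
  coords <- array(0, dim = c(nf, n_anchor + 1L, 3))
  for (f in seq_len(nf)) {
    coords[f, seq_len(n_anchor), 1:2] <- anchors
    coords[f, n_anchor + 1L, 1:2] <- xy[f, ]
  }
  trajectory(atoms, coords, frame_interval)
}
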