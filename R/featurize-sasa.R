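# Deterministic near-uniform unit-sphere points (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# van der Waals radius by element, inferred from the atom name.
vdw_radius <- function(names) {
  table <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8,
             F = 1.47)
  el <- toupper(substr(gsub("[0-9]", "", names), 1, 1))
  r <- unname(table[el])
  if (any(is.na(r))) {
    warning("unknown element for atom(s) ",
            paste(unique(names[is.na(r)]), collapse = ", "),
            "; using 1.5 A")
    r[is.na(r)] <- 1.5
  }
  r
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Per-frame SASA (A^2) of a residue selection, computed in the context of
#' all atoms of the trajectory: each selected atom's sphere of radius
#' r_vdw + probe is sampled with a deterministic Fibonacci point set and a
#' point counts as accessible when it lies outside every other atom's
#' expanded sphere.
#'
#' @param traj a [trajectory()].
#' @param residues atom selection whose summed SASA is reported.
#' @param probe probe radius in angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @param radii optional explicit per-atom radii (length = all atoms);
#'   overrides the element table.
#' @return a [feature_table()] of kind `sasa` (one column, A^2).
#' @export
compute_sasa <- function(traj, residues, probe = 1.4, n_points = 960,
                         radii = NULL) {
  sel <- select_atoms(traj, residues)
  if (length(sel) == 0L) stop("empty selection in compute_sasa")
  n_atoms <- nrow(traj$atoms)
  if (is.null(radii)) radii <- vdw_radius(traj$atoms$name)
  stopifnot(length(radii) == n_atoms)
  sp <- sphere_points(n_points)
  nf <- n_frames(traj)
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- matrix(traj$coords[f, , ], ncol = 3)
    total <- 0
    for (i in sel) {
      ri <- radii[i] + probe
      center <- xyz[i, ]
      others <- setdiff(seq_len(n_atoms), i)
      if (length(others) > 0) {
        dc <- sqrt(colSums((t(xyz[others, , drop = FALSE]) - center)^2))
        near <- others[dc < ri + radii[others] + probe]
      } else near <- integer(0)
      pts <- sweep(sp * ri, 2, center, "+")
      accessible <- rep(TRUE, n_points)
      for (j in near) {
        rj2 <- (radii[j] + probe)^2
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
              (pts[, 3] - xyz[j, 3])^2
        accessible <- accessible & (d2 > rj2)
        if (!any(accessible)) break
      }
      total <- total + 4 * pi * ri^2 * sum(accessible) / n_points
    }
    out[f] <- total
  }
  feature_table(matrix(out, ncol = 1), kind = "sasa",
                selection = paste(format(residues), collapse = ","),
                units = "angstrom^2")
}
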