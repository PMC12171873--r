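# Signed dihedral (degrees, (-180, 180]) for frame-stacked coordinates.
# p1..p4: n x 3 matrices.
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Residue-specific gamma atom closing the chi1 torsion N-CA-CB-gamma.
chi1_gamma_atom <- function(resname) {
  switch(resname,
         SER = "OG", THR = "OG1", CYS = "SG",
         ILE = "CG1", VAL = "CG1", "CG")
}

#' Compute chi1 sidechain dihedrals
#'
#' Signed N-CA-CB-gamma torsion in degrees, range `(-180, 180]`, one
#' column per selected residue.  Residues without a gamma atom (GLY, ALA,
#' or incomplete sidechains) are skipped with a warning.
#'
#' @param traj a [trajectory()].
#' @param residues atom selection (see [select_atoms()]) naming the
#'   residues of interest.
#' @return a [feature_table()] of kind `chi1` (units deg).
#' @export
compute_chi1 <- function(traj, residues) {
  idx <- select_atoms(traj, residues)
  if (length(idx) == 0L) stop("selection matches no atoms")
  groups <- split_by_residue(traj, idx)
  cols <- list(); labels <- character(0)
  for (key in names(groups)) {
    g <- groups[[key]]
    a <- traj$atoms[g, ]
    resname <- a$resname[1]
    gamma <- chi1_gamma_atom(resname)
    need <- c("N", "CA", "CB", gamma)
    pos <- match(need, a$name)
    if (any(is.na(pos))) {
      warning("residue ", resname, " ", key,
              " lacks chi1 atoms (", paste(need[is.na(pos)], collapse = ","),
              "); skipped")
      next
    }
    ai <- g[pos]
    at <- function(j) matrix(traj$coords[, ai[j], ], ncol = 3)
    chi <- dihedral_deg(at(1), at(2), at(3), at(4))
    chi[chi <= -180] <- chi[chi <= -180] + 360
    cols <- c(cols, list(chi))
    labels <- c(labels, paste0(resname, key))
  }
  if (length(cols) == 0L) stop("no residue in the selection has chi1 atoms")
  feature_table(do.call(cbind, cols), kind = "chi1", selection = labels,
                units = "deg")
}

#' Classify a chi1 angle into a rotamer state
#'
#' Bins centered on the canonical rotamers: trans at 180 deg, gauche(+) at
#' -60 deg, gauche(-) at +60 deg, with boundaries at 0 and +/-120 deg.
#' trans if `|chi| >= 120`; gauche(+) if `-120 < chi < 0`; gauche(-) if
#' `0 <= chi < 120`.
#'
#' @param chi1 numeric vector of angles in degrees, each in `(-180, 180]`.
#' @return character vector with values `trans`, `gauche_plus`,
#'   `gauche_minus`.
#' @export
classify_rotamer <- function(chi1) {
  stopifnot(is.numeric(chi1))
  if (any(chi1 <= -180 | chi1 > 180))
    stop("chi1 must lie in (-180, 180]")
  ifelse(abs(chi1) >= 120, "trans",
         ifelse(chi1 < 0, "gauche_plus", "gauche_minus"))
}
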