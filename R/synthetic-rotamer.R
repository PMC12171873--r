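# Place atom D given positions A, B, C, bond |CD|, angle B-C-D and torsion
# A-B-C-D (degrees): standard internal-to-Cartesian construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180   # sign matches the IUPAC torsion measured back
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Construct a toy sidechain trajectory with prescribed chi1 angles
#'
#' Builds one frame per requested angle: a four-atom N, CA, CB, CG
#' fragment (residue `LYS`, chain A, resno 1) with ideal bond lengths and
#' angles whose N-CA-CB-CG torsion equals the requested chi1.  Used as an
#' exact oracle for the dihedral code.
#'
#' @param chi1_targets numeric vector of angles in degrees, each in
#'   `(-180, 180]`.
#' @param frame_interval ns per frame.
#' @return a [trajectory()].
#' @export
generate_rotamer_toy <- function(chi1_targets, frame_interval = 0.1) {
  stopifnot(is.numeric(chi1_targets), length(chi1_targets) >= 1)
  if (any(chi1_targets <= -180 | chi1_targets > 180))
    stop("chi1 targets must lie in (-180, 180]")
  atoms <- data.frame(name = c("N", "CA", "CB", "CG"),
                      resname = "LYS", resno = 1L, chain = "A",
                      stringsAsFactors = FALSE)
  n_pos <- c(1.46 * cos(110 * pi / 180), 1.46 * sin(110 * pi / 180), 0)
  ca <- c(0, 0, 0)
  cb <- c(1.53, 0, 0)
  coords <- array(NA_real_, dim = c(length(chi1_targets), 4L, 3L))
  for (f in seq_along(chi1_targets)) {
    cg <- place_atom(n_pos, ca, cb, 1.52, 114, chi1_targets[f])
    coords[f, , ] <- rbind(n_pos, ca, cb, cg)
  }
  trajectory(atoms, coords, frame_interval)
}
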