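#' Transition count matrix
#'
#' Counts `(t, t+lag)` label pairs per trajectory; pairs never straddle a
#' trajectory boundary.  `sliding` uses every start frame, `strided` only
#' frames `1, 1+lag, 1+2*lag, ...`.
#'
#' @param labels list of integer label vectors (or a single vector).
#' @param lag lag in frames (>= 1).
#' @param n_states number of states (default: max observed label).
#' @param mode `"sliding"` (default) or `"strided"`.
#' @return integer n x n count matrix.
#' @export
count_matrix <- function(labels, lag, n_states = NULL,
                         mode = c("sliding", "strided")) {
  mode <- match.arg(mode)
  if (!is.list(labels)) labels <- list(labels)
  stopifnot(lag >= 1)
  if (is.null(n_states)) n_states <- as.integer(max(unlist(lapply(labels, max))))
  if (all(vapply(labels, length, 1L) <= lag))
    stop("every trajectory is shorter than the lag")
  counts <- matrix(0L, n_states, n_states)
  for (tr in labels) {
    nt <- length(tr) - lag
    if (nt < 1) next
    from_t <- if (mode == "sliding") seq_len(nt) else seq(1L, nt, by = lag)
    i <- tr[from_t]
    j <- tr[from_t + lag]
    tab <- tabulate((i - 1L) * n_states + j, nbins = n_states * n_states)
    counts <- counts + matrix(tab, n_states, n_states, byrow = TRUE)
  }
  counts
}

#' Estimate a transition probability matrix from counts
#'
#' Restricts to the largest strongly connected component of the count
#' graph (ergodic trimming), then row-normalizes either the raw counts
#' (`rownorm`) or the symmetrized counts `(C + t(C))/2` (`symmetrized`,
#' which yields a reversible matrix for PCCA+).
#'
#' @param counts non-negative square count matrix.
#' @param lag lag in frames the counts were taken at.
#' @param mode `"rownorm"` (default) or `"symmetrized"`.
#' @return an object of class `tpm` with fields `matrix`, `counts`,
#'   `lag`, `states` (original indices kept) and `connected`.
#' @export
estimate_tpm <- function(counts, lag = 1L, mode = c("rownorm", "symmetrized")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            all(counts >= 0))
  keep <- largest_scc(counts)
  if (length(keep) == 0L) stop("count matrix has no connected component")
  c_kept <- counts[keep, keep, drop = FALSE]
  base <- if (mode == "symmetrized") (c_kept + t(c_kept)) / 2 else c_kept
  rs <- rowSums(base)
  if (any(rs == 0)) stop("state with no outgoing counts inside the SCC")
  structure(list(matrix = base / rs, counts = c_kept, lag = lag,
                 states = keep, mode = mode,
                 connected = length(keep) == nrow(counts)),
            class = "tpm")
}

#' @export
print.tpm <- function(x, ...) {
  cat("tpm:", nrow(x$matrix), "states at lag", x$lag, "frames (",
      x$mode, if (!x$connected) ", trimmed" else "", ")\n", sep = "")
  invisible(x)
}

#' PCCA+ metastable lumping
#'
#' Lumps a reversible microstate transition matrix into `n_macro`
#' metastable macrostates using the inner-simplex PCCA+ construction on
#' the top right eigenvectors: the rows of the eigenvector matrix are
#' points near a simplex whose vertices are the most distant rows; the
#' linear map sending those vertices to the unit vectors yields fuzzy
#' memberships, which are clipped to `[0, 1]` and row-normalized.
#'
#' @param tpm a [estimate_tpm()] result (symmetrized mode recommended) or
#'   a plain reversible row-stochastic matrix.
#' @param n_macro number of macrostates (2 <= n_macro <= n_micro).
#' @param micro_labels optional per-frame microstate labels (indices into
#'   the TPM states); if given, per-frame macro labels are returned.
#' @param temperature temperature in K for the free-energy column.
#' @return an object of class `macrostate_model` with memberships,
#'   `crisp_map`, aggregated `stationary`, `free_energy` (kcal/mol,
#'   0 at the most populated state) and optional `macro_traj`.
#' @export
pcca_lump <- function(tpm, n_macro, micro_labels = NULL, temperature = 310) {
  tm <- if (inherits(tpm, "tpm")) tpm$matrix else tpm
  n <- nrow(tm)
  if (n_macro > n) stop("n_macro exceeds the number of microstates")
  if (n_macro < 2) stop("n_macro must be at least 2")
  # exactly decoupled blocks make tm reducible; a vanishing uniform
  # teleportation picks a well-defined stationary weighting without
  # perturbing the metastable structure
  pi_micro <- if (is_irreducible(tm)) stationary_distribution(tm)
              else stationary_distribution((1 - 1e-9) * tm +
                                             1e-9 / n)
  # symmetric similarity transform: real spectrum for reversible tm
  dhalf <- sqrt(pi_micro)
  s <- (tm * dhalf) / rep(dhalf, each = n)
  s <- (s + t(s)) / 2
  e <- eigen(s, symmetric = TRUE)
  psi <- e$vectors[, seq_len(n_macro), drop = FALSE] / dhalf
  # eigenvector scale is arbitrary; pin the stationary one to the constant,
  # which makes the membership rows sum to one by construction
  psi[, 1] <- 1
  chi <- pcca_inner_simplex(psi)
  chi <- pmax(chi, 0)
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  macro_pi <- as.vector(tapply(pi_micro, factor(crisp, levels = seq_len(n_macro)), sum))
  macro_pi[is.na(macro_pi)] <- 0
  fe <- free_energy(macro_pi, temperature)
  macro_traj <- if (!is.null(micro_labels)) crisp[micro_labels] else NULL
  structure(list(n_macro = n_macro, memberships = chi, crisp_map = crisp,
                 stationary = macro_pi, free_energy = fe,
                 micro_stationary = pi_micro, eigenvalues = e$values,
                 macro_traj = macro_traj, temperature = temperature),
            class = "macrostate_model")
}

# Inner-simplex vertex search (Deuflhard-Weber): pick the m rows of the
# eigenvector matrix spanning the largest simplex, map them to unit
# vectors.
pcca_inner_simplex <- function(psi) {
  n <- nrow(psi); m <- ncol(psi)
  idx <- integer(m)
  x <- psi
  # first vertex: row farthest from the centroid
  cen <- colMeans(x)
  d <- rowSums(sweep(x, 2, cen)^2)
  idx[1] <- which.max(d)
  shifted <- sweep(x, 2, x[idx[1], ])
  for (k in seq_len(m - 1) + 1) {
    # orthogonalize against span of chosen vertices, pick farthest row
    if (k > 2) {
      basis <- shifted[idx[2:(k - 1)], , drop = FALSE]
      qr_b <- qr(t(basis))
      q <- qr.Q(qr_b)
      proj <- shifted %*% q %*% t(q)
      resid <- shifted - proj
    } else resid <- shifted
    idx[k] <- which.max(rowSums(resid^2))
  }
  a <- solve(psi[idx, , drop = FALSE])
  psi %*% a
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat("macrostate_model:", x$n_macro, "macrostates\n")
  cat("stationary:", paste(signif(x$stationary, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Free energies from stationary probabilities
#'
#' `dG_i = -kB T ln(pi_i / max(pi))` in kcal/mol, so the most populated
#' ("lowest energy") state sits at 0.
#'
#' @param stationary probability vector.
#' @param temperature temperature in K (default 310).
#' @return numeric vector of free energies; zero-probability states get
#'   `Inf`.
#' @export
free_energy <- function(stationary, temperature = 310) {
  kb <- 0.0019872          # kcal/mol/K
  stopifnot(all(stationary >= 0), abs(sum(stationary) - 1) < 1e-6)
  ifelse(stationary == 0, Inf,
         -kb * temperature * log(stationary / max(stationary)))
}

#' Representative frame of a state
#'
#' The member frame closest (Euclidean) to the state's center; ties break
#' toward the lowest frame index.
#'
#' @param projected frames x dims matrix of projected coordinates.
#' @param labels per-frame state labels.
#' @param target state whose representative is sought.
#' @param center optional explicit center (default: mean of members).
#' @return integer frame index.
#' @export
representative_frame <- function(projected, labels, target, center = NULL) {
  projected <- as.matrix(projected)
  members <- which(labels == target)
  if (length(members) == 0L) stop("state ", target, " has no member frames")
  pts <- projected[members, , drop = FALSE]
  if (is.null(center)) center <- colMeans(pts)
  d2 <- rowSums(sweep(pts, 2, center)^2)
  members[which.min(d2)]
}
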