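#' Time-lagged independent component analysis
#'
#' Solves the symmetrized time-lagged generalized eigenproblem
#' `C(tau) v = lambda C(0) v` with a ridge term on `C(0)`.  Covariances are
#' accumulated per trajectory — lagged pairs never straddle a trajectory
#' boundary — and estimated reversibly: the mean and instantaneous
#' covariance average the leading and trailing windows, and the lagged
#' covariance is symmetrized.  Circular features (chi1) must be expanded
#' to cos/sin pairs beforehand (see [expand_circular()]).
#'
#' @param features list of numeric matrices (or [feature_table()]s), one
#'   per trajectory, equal column counts.
#' @param lag lag time in frames (>= 1, shorter than every trajectory).
#' @param n_components number of components to keep.
#' @param reg ridge regularization added to the diagonal of `C(0)`;
#'   default `1e-6 * trace(C0)/d`.
#' @return an object of class `tica_model` with fields `lag`, `means`,
#'   `eigenvalues` (descending, clamped to `[-1, 1]`), `components`
#'   (orthonormal under the `C(0)` metric) and `n_components`.
#' @export
fit_tica <- function(features, lag, n_components, reg = NULL) {
  mats <- lapply(features, function(f)
    if (inherits(f, "feature_table")) f$values else as.matrix(f))
  d <- ncol(mats[[1]])
  stopifnot(all(vapply(mats, ncol, 1L) == d), lag >= 1)
  if (any(vapply(mats, nrow, 1L) <= lag))
    stop("lag must be shorter than every trajectory")
  sum_x <- numeric(d); n_pairs <- 0
  s00 <- matrix(0, d, d); s0t <- matrix(0, d, d)
  for (m in mats) {
    nt <- nrow(m) - lag
    a <- m[seq_len(nt), , drop = FALSE]
    b <- m[lag + seq_len(nt), , drop = FALSE]
    sum_x <- sum_x + colSums(a) + colSums(b)
    n_pairs <- n_pairs + nt
  }
  mu <- sum_x / (2 * n_pairs)
  for (m in mats) {
    nt <- nrow(m) - lag
    a <- sweep(m[seq_len(nt), , drop = FALSE], 2, mu)
    b <- sweep(m[lag + seq_len(nt), , drop = FALSE], 2, mu)
    s00 <- s00 + crossprod(a) + crossprod(b)
    s0t <- s0t + crossprod(a, b)
  }
  c00 <- s00 / (2 * n_pairs)
  ct <- (s0t + t(s0t)) / (2 * n_pairs)
  if (is.null(reg)) reg <- 1e-6 * sum(diag(c00)) / d
  c00r <- c00 + diag(reg, d)
  ch <- chol(c00r)
  w <- backsolve(ch, diag(d))          # whitening: t(w) %*% c00r %*% w = I
  mhat <- t(w) %*% ct %*% w
  mhat <- (mhat + t(mhat)) / 2
  e <- eigen(mhat, symmetric = TRUE)
  n_components <- min(n_components, d)
  comps <- w %*% e$vectors[, seq_len(n_components), drop = FALSE]
  structure(list(lag = lag, means = mu,
                 eigenvalues = pmin(pmax(e$values, -1), 1),
                 components = comps, n_components = n_components,
                 reg = reg),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat("tica_model: lag", x$lag, "frames,", x$n_components, "components\n")
  cat("leading eigenvalues:",
      paste(signif(head(x$eigenvalues, x$n_components), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project data onto tICA components
#' @param object a `tica_model`.
#' @param newdata matrix or [feature_table()] with matching columns.
#' @param ... unused.
#' @return matrix of projected coordinates.
#' @export
predict.tica_model <- function(object, newdata, ...) {
  m <- if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
  sweep(m, 2, object$means) %*% object$components
}
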