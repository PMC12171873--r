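# Principal real matrix logarithm via eigendecomposition.  Complex
# eigenvalues in conjugate pairs are fine (the principal log is still
# real); eigenvalues on the closed negative real axis, a defective
# matrix, or a poor reconstruction return NULL and trigger the direct
# nonlinear fallback in fit_igme().
safe_logm <- function(m) {
  e <- tryCatch(eigen(m), error = function(err) NULL)
  if (is.null(e)) return(NULL)
  ev <- e$values
  if (any(Re(ev) <= 0 & abs(Im(ev)) < 1e-10)) return(NULL)
  if (any(Mod(ev) < 1e-12)) return(NULL)
  out <- tryCatch(e$vectors %*% (log(ev) * solve(e$vectors)),
                  error = function(err) NULL)
  if (is.null(out)) return(NULL)
  if (max(abs(Im(out))) > 1e-8) return(NULL)
  out <- Re(out)
  if (any(!is.finite(out))) return(NULL)
  # guard against near-defective eigenvector matrices
  if (max(abs(pracma::expm(out) - m)) > 1e-6 * max(1, max(abs(m))))
    return(NULL)
  out
}

# Clip negative entries and renormalize rows to the probability simplex.
project_stochastic <- function(m) {
  m <- pmax(m, 0)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("row of zeros after stochastic projection")
  m / rs
}

#' Estimate a transition-probability-matrix series
#'
#' Row-normalized TPMs of the same label trajectories at lags
#' `1..max_lag` frames, the input of [fit_igme()].  All states must stay
#' connected at every lag.
#'
#' @param labels list of integer label vectors.
#' @param max_lag largest lag in frames.
#' @param n_states number of states.
#' @return list of n x n matrices, element `t` at lag `t` frames.
#' @export
tpm_series <- function(labels, max_lag, n_states = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  if (is.null(n_states)) n_states <- as.integer(max(unlist(lapply(labels, max))))
  lapply(seq_len(max_lag), function(lg) {
    cm <- count_matrix(labels, lag = lg, n_states = n_states)
    rs <- rowSums(cm)
    if (any(rs == 0))
      stop("state with no outgoing counts at lag ", lg)
    cm / rs
  })
}

#' Fit the integrative generalized master equation
#'
#' Fits the long-time propagator form `T(t) = A %*% T_hat^t` by ordinary
#' least squares in log-matrix space: `ln T(t) ~ ln A + t ln T_hat`,
#' elementwise over the window `t = tau_k+1, ..., tau_k+L`.  `A` is the
#' integrated memory-kernel correction; `T_hat` (row-normalized by
#' clipping and projection) carries the corrected long-time kinetics.
#' With `L = 1` the single lag point is interpolated exactly with `A = I`.
#' If any matrix in the window lacks a real principal logarithm, the fit
#' falls back to direct nonlinear least squares on `T(t)` initialized
#' from the log-space solution on the usable lags.
#'
#' @param tpm_ser list of TPMs at lags `1..N` frames ([tpm_series()]).
#' @param tau_k memory-kernel relaxation time in frames (>= 0): lags up
#'   to `tau_k` are excluded from the fit.
#' @param L fit-window length in frames (>= 1).
#' @param lag_unit ns per frame (for reporting times in ns).
#' @return an object of class `igme_model` with fields `tau_k`, `L`,
#'   `A`, `T_hat`, `rmse` (Frobenius RMSE over the fit window) and
#'   `lag_unit`.
#' @export
fit_igme <- function(tpm_ser, tau_k, L, lag_unit = 1) {
  n_lags <- length(tpm_ser)
  stopifnot(tau_k >= 0, L >= 1)
  if (tau_k + L > n_lags)
    stop("fit window tau_k + L = ", tau_k + L,
         " exceeds available lags (", n_lags, ")")
  window <- seq(tau_k + 1, tau_k + L)
  n <- nrow(tpm_ser[[1]])
  logs <- lapply(window, function(t) safe_logm(tpm_ser[[t]]))
  ok <- !vapply(logs, is.null, TRUE)
  if (all(ok)) {
    fit <- igme_ols(logs, window, n)
  } else {
    init <- if (any(ok)) igme_ols(logs[ok], window[ok], n)
            else list(lnA = matrix(0, n, n),
                      lnT = safe_logm(tpm_ser[[1]]) %||% diag(-1e-3, n))
    fit <- igme_nls(tpm_ser, window, init)
  }
  a_mat <- pracma::expm(fit$lnA)
  t_hat <- project_stochastic(pracma::expm(fit$lnT))
  model <- structure(list(tau_k = tau_k, L = L, A = a_mat, T_hat = t_hat,
                          lag_unit = lag_unit, n_lags = n_lags),
                     class = "igme_model")
  pred <- lapply(window, function(t) predict_tpm(model, t))
  model$rmse <- sqrt(mean(vapply(seq_along(window), function(k)
    mean((pred[[k]] - tpm_ser[[window[k]]])^2), 1)))
  model
}

# Elementwise OLS of ln T(t) on t; with a single lag the intercept is
# pinned at 0 (A = I) so the point is interpolated exactly.
igme_ols <- function(logs, ts, n) {
  if (length(ts) == 1L)
    return(list(lnA = matrix(0, n, n), lnT = logs[[1]] / ts[1]))
  tbar <- mean(ts)
  dt <- ts - tbar
  sxx <- sum(dt^2)
  slope <- matrix(0, n, n); mean_y <- matrix(0, n, n)
  for (k in seq_along(ts)) {
    slope <- slope + dt[k] * logs[[k]]
    mean_y <- mean_y + logs[[k]]
  }
  slope <- slope / sxx
  mean_y <- mean_y / length(ts)
  list(lnA = mean_y - tbar * slope, lnT = slope)
}

# Direct nonlinear least squares on T(t) = expm(lnA) expm(lnT)^t.
igme_nls <- function(tpm_ser, window, init) {
  n <- nrow(tpm_ser[[1]])
  obj <- function(par) {
    lnA <- matrix(par[seq_len(n * n)], n, n)
    lnT <- matrix(par[n * n + seq_len(n * n)], n, n)
    a <- pracma::expm(lnA); th <- pracma::expm(lnT)
    sum(vapply(window, function(t)
      sum((a %*% mat_pow(th, t) - tpm_ser[[t]])^2), 1))
  }
  par0 <- c(as.vector(init$lnA), as.vector(init$lnT))
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(lnA = matrix(opt$par[seq_len(n * n)], n, n),
       lnT = matrix(opt$par[n * n + seq_len(n * n)], n, n))
}

#' @export
print.igme_model <- function(x, ...) {
  cat("igme_model: tau_k =", x$tau_k, "frames, L =", x$L,
      "frames, fit RMSE =", signif(x$rmse, 4), "\n")
  invisible(x)
}

#' Model-predicted TPM at a lag
#'
#' `A %*% T_hat^lag` for an IGME model, `T(1)^lag` for a plain Markov
#' model ([msm_model()]); entries clamped to `[0, 1]`.
#'
#' @param model an `igme_model` or `msm_model`.
#' @param lag lag in frames.
#' @return n x n matrix.
#' @export
predict_tpm <- function(model, lag) UseMethod("predict_tpm")

#' @export
predict_tpm.igme_model <- function(model, lag) {
  p <- model$A %*% mat_pow(model$T_hat, lag)
  pmin(pmax(p, 0), 1)
}

#' Plain Markov reference model
#'
#' Wraps a lag-1 TPM so it can be propagated and Chapman-Kolmogorov
#' tested alongside an IGME model.
#'
#' @param tpm_1 row-stochastic matrix at lag 1 frame.
#' @param lag_unit ns per frame.
#' @return an object of class `msm_model`.
#' @export
msm_model <- function(tpm_1, lag_unit = 1) {
  assert_stochastic(tpm_1, tol = 1e-8)
  structure(list(T_hat = tpm_1, A = diag(nrow(tpm_1)), lag_unit = lag_unit),
            class = "msm_model")
}

#' @export
predict_tpm.msm_model <- function(model, lag) {
  pmin(pmax(mat_pow(model$T_hat, lag), 0), 1)
}

#' Scan IGME hyperparameters
#'
#' Fits every feasible `(tau_k, L)` pair and ranks them by RMSE between
#' model-predicted and input TPMs over all available lags beyond
#' `tau_k` (fit window plus extrapolation).  Ties break toward the
#' smallest `tau_k`, then the smallest `L`.
#'
#' @param tpm_ser list of TPMs at lags `1..N` ([tpm_series()]).
#' @param tau_k_grid,L_grid candidate values in frames.
#' @param lag_unit ns per frame.
#' @return list with `best` (an `igme_model`) and `table` (data.frame
#'   `tau_k`, `L`, `rmse`, `fit_rmse`).
#' @export
scan_igme <- function(tpm_ser, tau_k_grid, L_grid, lag_unit = 1) {
  n_lags <- length(tpm_ser)
  grid <- expand.grid(tau_k = tau_k_grid, L = L_grid)
  grid <- grid[grid$tau_k + grid$L <= n_lags, , drop = FALSE]
  if (nrow(grid) == 0L) stop("no feasible (tau_k, L) pair")
  grid <- grid[order(grid$tau_k, grid$L), ]
  rmse_eval <- fit_rmse <- numeric(nrow(grid))
  models <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    m <- fit_igme(tpm_ser, grid$tau_k[r], grid$L[r], lag_unit)
    models[[r]] <- m
    fit_rmse[r] <- m$rmse
    eval_lags <- seq(grid$tau_k[r] + 1, n_lags)
    rmse_eval[r] <- sqrt(mean(vapply(eval_lags, function(t)
      mean((predict_tpm(m, t) - tpm_ser[[t]])^2), 1)))
  }
  tab <- cbind(grid, rmse = rmse_eval, fit_rmse = fit_rmse)
  rownames(tab) <- NULL
  # grid is pre-sorted by (tau_k, L); near-ties (within numerical noise of
  # the minimum) resolve to the most parsimonious pair
  best_i <- which(rmse_eval <= min(rmse_eval) + 1e-12)[1]
  best <- models[[best_i]]
  best$eval_rmse <- rmse_eval[best_i]
  list(best = best, table = tab)
}

#' Implied timescales of a fitted propagator
#'
#' `-dt / ln |lambda_i|` in ns from the eigenvalues of `T_hat`, slowest
#' first (stationary eigenvalue excluded).
#'
#' @param model an `igme_model` or `msm_model`.
#' @return numeric vector of timescales (ns).
#' @export
model_timescales <- function(model) {
  implied_timescales(model$T_hat, model$lag_unit)
}
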