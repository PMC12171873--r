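#' Chapman-Kolmogorov test with trajectory bootstrap
#'
#' Compares the model-propagated TPM at each test lag against the TPM
#' re-estimated directly from the data at that lag.  Uncertainty on the
#' data estimate comes from a seeded bootstrap over whole trajectories
#' (per-trajectory count matrices are resampled with replacement and
#' re-normalized); the model passes when its prediction falls inside the
#' bootstrap interval for at least 95% of matrix elements at every test
#' lag.
#'
#' @param model an `igme_model` or `msm_model`.
#' @param labels list of integer label trajectories.
#' @param test_lags integer lags (frames) to test.
#' @param n_states number of states.
#' @param n_boot bootstrap resamples (default 200).
#' @param seed integer seed for the bootstrap.
#' @param conf interval coverage (default 0.95).
#' @return an object of class `ck_report`: per-lag `model_tpm`,
#'   `data_tpm`, `lower`/`upper` intervals, `deviations`,
#'   `pass_fraction`, overall `pass`, and `degenerate` flag when fewer
#'   than two trajectories were available.
#' @export
ck_test <- function(model, labels, test_lags, n_states = NULL,
                    n_boot = 200L, seed = 1L, conf = 0.95) {
  if (!is.list(labels)) labels <- list(labels)
  if (is.null(n_states)) n_states <- as.integer(max(unlist(lapply(labels, max))))
  max_len <- max(vapply(labels, length, 1L))
  if (any(test_lags >= max_len))
    stop("test lag exceeds trajectory length")
  degenerate <- length(labels) < 2L
  if (degenerate)
    warning("fewer than 2 trajectories: bootstrap intervals are degenerate")
  alpha <- (1 - conf) / 2
  set.seed(as.integer(seed))
  per_lag <- vector("list", length(test_lags))
  names(per_lag) <- as.character(test_lags)
  for (k in seq_along(test_lags)) {
    lg <- test_lags[k]
    counts_by_traj <- lapply(labels, function(tr) {
      if (length(tr) <= lg) matrix(0L, n_states, n_states)
      else count_matrix(list(tr), lag = lg, n_states = n_states)
    })
    total <- Reduce(`+`, counts_by_traj)
    rs <- rowSums(total)
    data_tpm <- total / ifelse(rs == 0, 1, rs)
    boot <- array(NA_real_, dim = c(n_boot, n_states, n_states))
    for (b in seq_len(n_boot)) {
      pick <- sample.int(length(labels), length(labels), replace = TRUE)
      cs <- Reduce(`+`, counts_by_traj[pick])
      rsb <- rowSums(cs)
      boot[b, , ] <- cs / ifelse(rsb == 0, 1, rsb)
    }
    lower <- apply(boot, c(2, 3), quantile, probs = alpha, na.rm = TRUE)
    upper <- apply(boot, c(2, 3), quantile, probs = 1 - alpha, na.rm = TRUE)
    model_tpm <- predict_tpm(model, lg)
    eps <- 1e-12
    inside <- model_tpm >= lower - eps & model_tpm <= upper + eps
    per_lag[[k]] <- list(lag = lg, model_tpm = model_tpm,
                         data_tpm = data_tpm, lower = lower, upper = upper,
                         deviations = abs(model_tpm - data_tpm),
                         pass_fraction = mean(inside))
  }
  pf <- vapply(per_lag, function(z) z$pass_fraction, 1)
  structure(list(test_lags = test_lags, per_lag = per_lag,
                 pass_fraction = pf, pass = all(pf >= 0.95),
                 degenerate = degenerate, n_boot = n_boot, conf = conf),
            class = "ck_report")
}

#' @export
print.ck_report <- function(x, ...) {
  cat("ck_report:", if (x$pass) "PASS" else "FAIL", "\n")
  for (k in seq_along(x$test_lags))
    cat("  lag", x$test_lags[k], ": fraction inside interval",
        signif(x$pass_fraction[k], 4), "\n")
  invisible(x)
}
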