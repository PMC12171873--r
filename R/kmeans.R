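# k-means++ initial centers (seeded by the caller's RNG state).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Microstate discretization by k-means
#'
#' k-means++ initialization under a fixed seed followed by Lloyd
#' iterations (via [stats::kmeans()]) until the assignment is stationary
#' or 500 iterations are reached.  Deterministic for a fixed seed.
#'
#' @param x numeric matrix of projected coordinates (frames x dims).
#' @param k number of microstates.
#' @param seed integer seed.
#' @return an object of class `microstate_model` with fields `k`,
#'   `centers`, `labels` (1..k per frame), `inertia` and `seed`.
#' @export
fit_kmeans <- function(x, k, seed) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of points")
  set.seed(as.integer(seed))
  init <- kmeanspp_init(x, k)
  init <- init[!duplicated(init), , drop = FALSE]
  fit <- suppressWarnings(
    kmeans(x, centers = init, iter.max = 500, algorithm = "Lloyd"))
  structure(list(k = nrow(fit$centers), centers = fit$centers,
                 labels = fit$cluster, inertia = fit$tot.withinss,
                 seed = as.integer(seed)),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat("microstate_model: k =", x$k, ", inertia =", signif(x$inertia, 5), "\n")
  invisible(x)
}

#' Assign new points to the nearest microstate center
#' @param object a `microstate_model`.
#' @param newdata matrix of points.
#' @param ... unused.
#' @return integer vector of microstate labels.
#' @export
predict.microstate_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  d2 <- matrix(0, nrow(x), object$k)
  for (j in seq_len(object$k))
    d2[, j] <- rowSums(sweep(x, 2, object$centers[j, ])^2)
  max.col(-d2, ties.method = "first")
}
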