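`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that a square matrix is row-stochastic
#'
#' @param m numeric square matrix.
#' @param tol absolute tolerance on row sums.
#' @return `TRUE` invisibly; errors otherwise.
#' @keywords internal
assert_stochastic <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("expected a square matrix")
  if (any(!is.finite(m)) || any(m < -tol))
    stop("matrix entries must be finite and non-negative")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stop("rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  invisible(TRUE)
}

# Strong connectivity of the directed graph with an edge i -> j wherever
# m[i, j] > 0.
is_irreducible <- function(m) {
  g <- igraph::graph_from_adjacency_matrix((m > 0) * 1, mode = "directed")
  igraph::count_components(g, mode = "strong") == 1L
}

# Indices of the largest strongly connected component (ties: the component
# containing the lowest-index state).
largest_scc <- function(m) {
  g <- igraph::graph_from_adjacency_matrix((m > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    first_member <- vapply(best, function(b) min(which(comp$membership == b)), 1L)
    best <- best[which.min(first_member)]
  }
  which(comp$membership == best)
}

# Integer matrix power by repeated squaring.
mat_pow <- function(m, k) {
  stopifnot(k >= 0, k == round(k))
  out <- diag(nrow(m))
  p <- m
  k <- as.integer(k)
  while (k > 0) {
    if (k %% 2L == 1L) out <- out %*% p
    k <- k %/% 2L
    if (k > 0) p <- p %*% p
  }
  out
}

# Derive a per-stream seed from a base seed, staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 97L * as.integer(offset)) %% 2147483647L
}
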