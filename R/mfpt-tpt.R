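#' Mean first passage times of a discrete-time chain
#'
#' For every target state `j`, solves `(I - T[-j, -j]) m = dt * 1`; the
#' diagonal is zero.  For an IGME model the row-normalized long-time
#' propagator `T_hat` is used (the memory correction `A` only affects
#' short-time predictions).
#'
#' @param x an `igme_model`, `msm_model`, or a row-stochastic matrix.
#' @param dt time per step in ns (default: the model's `lag_unit`).
#' @return n x n matrix of MFPTs in ns.
#' @export
mfpt <- function(x, dt = NULL) {
  if (inherits(x, c("igme_model", "msm_model"))) {
    tm <- x$T_hat
    if (is.null(dt)) dt <- x$lag_unit
  } else {
    tm <- x
    if (is.null(dt)) dt <- 1
  }
  assert_stochastic(tm, tol = 1e-8)
  if (!is_irreducible(tm)) stop("transition matrix is not irreducible")
  n <- nrow(tm)
  out <- matrix(0, n, n)
  for (j in seq_len(n)) {
    keep <- setdiff(seq_len(n), j)
    m <- solve(diag(n - 1) - tm[keep, keep, drop = FALSE],
               rep(dt, n - 1))
    out[keep, j] <- m
  }
  out
}

#' Transition-path-theory net flux network
#'
#' Forward committor `q+` solves the standard linear system with
#' `q+(source) = 0`, `q+(sink) = 1`; the backward committor comes from
#' the time-reversed chain.  Gross flux
#' `f_ij = pi_i q-_i T_ij q+_j` (i != j) is antisymmetrized into the net
#' flux `max(0, f_ij - f_ji)`, and pathways are peeled off by iterative
#' bottleneck (widest-path) decomposition until less than 1% of the
#' total flux remains.
#'
#' @param tpm irreducible row-stochastic matrix (or `igme_model`, whose
#'   `T_hat` is used).
#' @param source,sink distinct state indices.
#' @param stationary optional stationary distribution (computed if NULL).
#' @return an object of class `flux_network` with `q_plus`, `q_minus`,
#'   `netflux`, `total_flux` and `pathways` (list of
#'   `list(states, capacity)` in decreasing capacity).
#' @export
tpt_flux <- function(tpm, source, sink, stationary = NULL) {
  tm <- if (inherits(tpm, c("igme_model", "msm_model"))) tpm$T_hat else tpm
  n <- nrow(tm)
  stopifnot(source != sink, source >= 1, sink >= 1, source <= n, sink <= n)
  if (!is_irreducible(tm)) stop("chain is not irreducible; sink unreachable")
  if (is.null(stationary)) stationary <- stationary_distribution(tm)
  pi_v <- stationary
  inter <- setdiff(seq_len(n), c(source, sink))
  q_plus <- numeric(n); q_plus[sink] <- 1
  if (length(inter) > 0) {
    a <- diag(length(inter)) - tm[inter, inter, drop = FALSE]
    b <- tm[inter, sink]
    q_plus[inter] <- solve(a, b)
  }
  # backward committor on the time-reversed chain
  trev <- t(tm * pi_v) / pi_v
  q_minus <- numeric(n); q_minus[source] <- 1
  if (length(inter) > 0) {
    a <- diag(length(inter)) - trev[inter, inter, drop = FALSE]
    b <- trev[inter, source]
    q_minus[inter] <- solve(a, b)
  }
  f <- (pi_v * q_minus) * tm * rep(q_plus, each = n)
  diag(f) <- 0
  netflux <- pmax(f - t(f), 0)
  total <- sum(netflux[source, ]) - sum(netflux[, source])
  pathways <- bottleneck_decomposition(netflux, source, sink, total)
  structure(list(source = source, sink = sink, q_plus = q_plus,
                 q_minus = q_minus, netflux = netflux,
                 total_flux = total, pathways = pathways),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat("flux_network:", x$source, "->", x$sink, ", total flux",
      signif(x$total_flux, 5), "\n")
  for (p in x$pathways)
    cat("  path", paste(p$states, collapse = " -> "),
        " capacity", signif(p$capacity, 4), "\n")
  invisible(x)
}

# Widest (maximum-bottleneck) path from source to sink on a non-negative
# capacity matrix; Dijkstra variant maximizing the minimum edge.
widest_path <- function(cap, source, sink) {
  n <- nrow(cap)
  width <- rep(-Inf, n); width[source] <- Inf
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & width > -Inf)
    if (length(cand) == 0L) return(NULL)
    u <- cand[which.max(width[cand])]
    if (u == sink) break
    visited[u] <- TRUE
    for (v in which(cap[u, ] > 0)) {
      w <- min(width[u], cap[u, v])
      if (w > width[v]) { width[v] <- w; prev[v] <- u }
    }
  }
  if (!is.finite(width[sink]) || width[sink] <= 0) return(NULL)
  path <- as.integer(sink)
  while (path[1] != source) path <- c(prev[path[1]], path)
  list(states = path, capacity = width[sink])
}

bottleneck_decomposition <- function(netflux, source, sink, total,
                                     frac_stop = 0.01, max_paths = 50L) {
  cap <- netflux
  remaining <- total
  out <- list()
  while (remaining > frac_stop * total && length(out) < max_paths) {
    p <- widest_path(cap, source, sink)
    if (is.null(p)) break
    out[[length(out) + 1L]] <- p
    for (k in seq_len(length(p$states) - 1))
      cap[p$states[k], p$states[k + 1]] <-
        cap[p$states[k], p$states[k + 1]] - p$capacity
    remaining <- remaining - p$capacity
  }
  out
}

#' Choose flux endpoints from a free-energy landscape
#'
#' Source is the highest-energy state, sink the lowest (the state at
#' 0 kcal/mol).  Ties resolve to the lowest index with a warning; a flat
#' landscape is rejected.
#'
#' @param fe free-energy vector (kcal/mol).
#' @return list with `source` and `sink` indices.
#' @export
select_endpoints <- function(fe) {
  stopifnot(length(fe) >= 2)
  if (max(fe) - min(fe) < .Machine$double.eps * 100)
    stop("degenerate free-energy landscape: all states equal")
  src <- which(fe == max(fe)); snk <- which(fe == min(fe))
  if (length(src) > 1 || length(snk) > 1)
    warning("tied free energies; using lowest state index")
  list(source = src[1], sink = snk[1])
}
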