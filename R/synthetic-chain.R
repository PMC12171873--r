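#' Specification of a lumped hidden Markov chain
#'
#' Defines a hidden discrete-time Markov chain together with a lumping map
#' onto macro labels.  The lumped observation of such a chain is in general
#' non-Markovian at short lag times — the situation a generalized master
#' equation is built to handle — while every kinetic quantity of interest
#' (stationary distribution, mean first passage times, slow timescales) is
#' available exactly from the hidden transition matrix by linear algebra.
#'
#' @param hidden_tpm row-stochastic transition matrix of the hidden chain.
#' @param lump_map integer vector mapping each hidden state to a macro
#'   label in `1..n_macro`; must be surjective onto at least 2 labels.
#' @param frame_interval time per step in ns (default 0.1).
#' @param seed integer base seed; per-trajectory streams are derived from it.
#' @return an object of class `hidden_chain_spec`.
#' @export
hidden_chain_spec <- function(hidden_tpm, lump_map, frame_interval = 0.1,
                              seed = 1L) {
  assert_stochastic(hidden_tpm, tol = 1e-12)
  n <- nrow(hidden_tpm)
  lump_map <- as.integer(lump_map)
  stopifnot(length(lump_map) == n, all(lump_map >= 1))
  n_macro <- max(lump_map)
  if (length(unique(lump_map)) < 2L || !setequal(unique(lump_map), seq_len(n_macro)))
    stop("lump_map must be surjective onto at least 2 macro labels")
  if (!is_irreducible(hidden_tpm))
    stop("hidden_tpm is reducible: the hidden chain must be irreducible")
  structure(list(n_hidden = n, hidden_tpm = hidden_tpm,
                 lump_map = lump_map, n_macro = n_macro,
                 frame_interval = frame_interval, seed = as.integer(seed)),
            class = "hidden_chain_spec")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of eigenvalue 1, normalized to sum to one.
#'
#' @param tpm irreducible row-stochastic matrix.
#' @return probability vector.
#' @export
stationary_distribution <- function(tpm) {
  assert_stochastic(tpm, tol = 1e-8)
  if (!is_irreducible(tpm))
    stop("transition matrix is not irreducible")
  e <- eigen(t(tpm))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stop("stationary solve produced negative entries")
  pmax(v, 0) / sum(pmax(v, 0))
}

# Exact MFPT (ns) between macro sets of the hidden chain: absorbing-set
# linear solve started from the stationary distribution restricted to the
# source macro state.
hidden_macro_mfpt <- function(hidden_tpm, lump_map, frame_interval) {
  n_macro <- max(lump_map)
  pi_h <- stationary_distribution(hidden_tpm)
  out <- matrix(0, n_macro, n_macro)
  for (b in seq_len(n_macro)) {
    target <- which(lump_map == b)
    keep <- setdiff(seq_len(nrow(hidden_tpm)), target)
    m_full <- numeric(nrow(hidden_tpm))        # expected steps to reach set b
    if (length(keep) > 0) {
      A <- diag(length(keep)) - hidden_tpm[keep, keep, drop = FALSE]
      m_full[keep] <- solve(A, rep(1, length(keep)))
    }
    for (a in seq_len(n_macro)) {
      if (a == b) next
      src <- which(lump_map == a)
      w <- pi_h[src] / sum(pi_h[src])
      out[a, b] <- sum(w * m_full[src]) * frame_interval
    }
  }
  out
}

# Implied relaxation timescales (ns) from the eigenvalues of a TPM at a
# given time step: t_i = -dt / ln |lambda_i|, slowest first, stationary
# eigenvalue excluded.
implied_timescales <- function(tpm, frame_interval) {
  lam <- eigen(tpm, only.values = TRUE)$values
  lam <- Mod(lam)
  lam <- sort(lam, decreasing = TRUE)[-1]
  lam <- pmin(lam, 1 - 1e-15)
  ifelse(lam <= 0, 0, -frame_interval / log(lam))
}

#' Sample macro-label trajectories from a lumped hidden chain
#'
#' Samples `n_traj` independent realizations of the hidden chain (each from
#' a seed derived from the spec seed), lumps them through `lump_map`, and
#' returns the macro-label trajectories together with exact ground truth
#' computed from the hidden transition matrix by direct linear solves:
#' macro stationary probabilities, macro-to-macro mean first passage times
#' (hidden chain with the target macro set absorbing), and the hidden
#' chain's implied slow timescales.
#'
#' @param spec a [hidden_chain_spec()].
#' @param n_traj number of trajectories.
#' @param n_frames frames per trajectory (>= 100).
#' @return list with `trajectories` (list of integer macro-label vectors),
#'   `hidden` (the un-lumped state sequences) and `ground_truth`.
#' @export
generate_hidden_chain <- function(spec, n_traj, n_frames) {
  stopifnot(inherits(spec, "hidden_chain_spec"), n_traj >= 1)
  if (n_frames < 100) stop("n_frames must be >= 100")
  pi_h <- stationary_distribution(spec$hidden_tpm)
  cum <- t(apply(spec$hidden_tpm, 1, cumsum))
  hidden <- vector("list", n_traj)
  trajs <- vector("list", n_traj)
  for (i in seq_len(n_traj)) {
    set.seed(derive_seed(spec$seed, i))
    start <- sample.int(spec$n_hidden, 1, prob = pi_h)
    h <- sample_chain_cpp(cum, as.integer(n_frames), start)
    hidden[[i]] <- h
    trajs[[i]] <- spec$lump_map[h]
  }
  gt <- list(
    stationary = as.vector(tapply(pi_h, spec$lump_map, sum)),
    mfpt_matrix = hidden_macro_mfpt(spec$hidden_tpm, spec$lump_map,
                                    spec$frame_interval),
    slow_timescales = implied_timescales(spec$hidden_tpm,
                                         spec$frame_interval),
    branch_labels = NULL)
  class(gt) <- "ground_truth"
  list(trajectories = trajs, hidden = hidden, ground_truth = gt)
}

#' Reference hidden chain: two fast pairs bridged by a slow hop
#'
#' A 4-state reversible birth-death chain — states 1,2 lumped to macro 1
#' and states 3,4 to macro 2 — whose within-pair exchange is fast and whose
#' inter-pair hop is slow, so the lumped 2-state observation is strongly
#' non-Markovian at short lags.
#'
#' @param fast within-pair exchange probability per step (default 0.2).
#' @param slow inter-pair hop probability per step (default 0.01).
#' @param frame_interval ns per step.
#' @param seed integer seed.
#' @return a [hidden_chain_spec()].
#' @export
two_pair_chain_spec <- function(fast = 0.2, slow = 0.01,
                                frame_interval = 0.1, seed = 1L) {
  tpm <- matrix(c(1 - fast, fast,              0,        0,
                  fast,     1 - fast - slow,   slow,     0,
                  0,        slow,              1 - fast - slow, fast,
                  0,        0,                 fast,     1 - fast),
                4, 4, byrow = TRUE)
  hidden_chain_spec(tpm, lump_map = c(1L, 1L, 2L, 2L),
                    frame_interval = frame_interval, seed = seed)
}

#' Write ground truth as delimited tables plus metadata
#' @param gt a `ground_truth` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(gt$stationary))
    write.table(data.frame(state = seq_along(gt$stationary),
                           stationary = gt$stationary),
                file.path(dir, "stationary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(gt$mfpt_matrix))
    write.table(gt$mfpt_matrix, file.path(dir, "mfpt_ns.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(gt$branch_labels))
    write.table(data.frame(trajectory = seq_along(gt$branch_labels),
                           branch = gt$branch_labels),
                file.path(dir, "branch_labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  meta <- list(slow_timescales_ns = gt$slow_timescales)
  yaml::write_yaml(meta, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
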