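# Shared fixture builders (all generated in code; nothing on disk).

# Minimal protein-like trajectory: two CA "helices" and a one-atom ligand.
toy_system <- function(n_frames = 2, lig_x = c(3.2, 15)) {
  atoms <- data.frame(name = c("CA", "CA", "C1"),
                      resname = c("ALA", "ALA", "LIG"),
                      resno = c(1L, 2L, 3L), chain = "A",
                      stringsAsFactors = FALSE)
  coords <- array(0, c(n_frames, 3, 3))
  coords[, 2, 1] <- 5
  coords[, 3, 1] <- rep_len(lig_x, n_frames)
  trajectory(atoms, coords)
}

# 4-state block transition matrix: two 2-state blocks, inter-block
# coupling eps.
block_tpm <- function(p_in = 0.1, eps = 1e-3) {
  tm <- matrix(c(1 - p_in - eps, p_in,        eps,   0,
                 p_in,       1 - p_in - eps,  0,     eps,
                 eps,        0,          1 - p_in - eps, p_in,
                 0,          eps,        p_in,  1 - p_in - eps),
               4, 4, byrow = TRUE)
  tm / rowSums(tm)
}

# 4-state two-branch chain: 1 -> {2 (p), 3 (1-p)} -> 4 -> 1.
branch_chain <- function(p = 0.7) {
  matrix(c(0, p, 1 - p, 0,
           0, 0, 0, 1,
           0, 0, 0, 1,
           1, 0, 0, 0), 4, 4, byrow = TRUE)
}

# Exact lumped macro TPM series of a hidden chain (no sampling): the
# stationary-weighted observation of T_hidden^t on the macro labels.
exact_lumped_series <- function(spec, max_lag) {
  pih <- stationary_distribution(spec$hidden_tpm)
  nm <- spec$n_macro
  lapply(seq_len(max_lag), function(t) {
    tt <- igmepath:::mat_pow(spec$hidden_tpm, t)
    m <- matrix(0, nm, nm)
    for (a in seq_len(nm)) {
      src <- which(spec$lump_map == a)
      w <- pih[src] / sum(pih[src])
      for (b in seq_len(nm))
        m[a, b] <- sum(w * rowSums(tt[src, which(spec$lump_map == b),
                                      drop = FALSE]))
    }
    m
  })
}

# Independent MFPT oracle: absorbing-chain fundamental matrix
# N = (I - Q)^{-1}, row sums give expected absorption times.
mfpt_fundamental <- function(tm, dt = 1) {
  n <- nrow(tm)
  out <- matrix(0, n, n)
  for (j in seq_len(n)) {
    q <- tm[-j, -j, drop = FALSE]
    nfund <- solve(diag(n - 1) - q)
    out[-j, j] <- rowSums(nfund) * dt
  }
  out
}

# Brute-force simple-path enumeration on a net-flux matrix; returns
# paths (vertex sequences) and their bottleneck capacities.
enumerate_paths <- function(flux, from, to) {
  paths <- list()
  recurse <- function(path) {
    u <- path[length(path)]
    if (u == to) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in which(flux[u, ] > 0))
      if (!v %in% path) recurse(c(path, v))
  }
  recurse(from)
  caps <- vapply(paths, function(p)
    min(flux[cbind(p[-length(p)], p[-1])]), 1)
  list(paths = paths, capacities = caps)
}
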