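test_that("transition counts match hand enumeration and boundary rules", {
  expect_identical(count_matrix(list(c(1L, 1L, 2L, 2L, 1L, 2L)), lag = 1),
                   matrix(c(1L, 2L, 1L, 1L), 2, 2, byrow = TRUE))
  # lag equal to length - 1: exactly one pair
  expect_identical(sum(count_matrix(list(c(1L, 2L, 1L, 2L)), lag = 3)), 1L)
  # no counts across trajectory boundaries
  two <- count_matrix(list(c(1L, 2L), c(2L, 1L)), lag = 1)
  cat_ <- count_matrix(list(c(1L, 2L, 2L, 1L)), lag = 1)
  expect_identical(two, matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE))
  expect_false(identical(two, cat_))
  expect_error(count_matrix(list(1:2), lag = 5), "shorter")
})

test_that("TPM estimation row-normalizes counts on the connected component", {
  cm <- matrix(c(1, 2, 1, 1), 2, 2, byrow = TRUE)
  tp <- estimate_tpm(cm)
  expect_equal(tp$matrix, matrix(c(1/3, 2/3, 1/2, 1/2), 2, 2, byrow = TRUE))
  # symmetric counts: rownorm and symmetrized agree
  sym <- matrix(c(4, 2, 2, 6), 2, 2)
  expect_equal(estimate_tpm(sym, mode = "rownorm")$matrix,
               estimate_tpm(sym, mode = "symmetrized")$matrix)
  # a state with no outgoing counts is trimmed away
  cm3 <- matrix(c(3, 1, 0, 1, 3, 1, 0, 0, 0), 3, 3, byrow = TRUE)
  tp3 <- estimate_tpm(cm3)
  expect_identical(tp3$states, 1:2)
  expect_false(tp3$connected)
})

test_that("TPM rows sum to one on random count matrices", {
  set.seed(10)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    cm <- matrix(rpois(n * n, 3), n, n) + diag(1, n)
    for (mode in c("rownorm", "symmetrized")) {
      tp <- estimate_tpm(cm, mode = mode)
      expect_lt(max(abs(rowSums(tp$matrix) - 1)), 1e-10)
      expect_true(all(tp$matrix >= 0 & tp$matrix <= 1))
    }
  }
})

test_that("stationary distributions match closed forms and equivariance", {
  expect_equal(stationary_distribution(matrix(c(.9, .1, .1, .9), 2, 2)),
               c(0.5, 0.5))
  expect_equal(stationary_distribution(matrix(c(.9, .1, .2, .8), 2, 2,
                                              byrow = TRUE)),
               c(2/3, 1/3))
  tm <- block_tpm(0.12, 0.02)
  perm <- c(3, 1, 4, 2)
  p <- diag(4)[perm, ]
  expect_equal(stationary_distribution(p %*% tm %*% t(p)),
               stationary_distribution(tm)[perm], tolerance = 1e-12)
  expect_error(stationary_distribution(diag(2)), "irreducible")
})

test_that("PCCA+ recovers block structure and degenerate limits", {
  lump <- pcca_lump(block_tpm(0.1, 1e-3), 2)
  expect_true(identical(lump$crisp_map, c(1L, 1L, 2L, 2L)) ||
              identical(lump$crisp_map, c(2L, 2L, 1L, 1L)))
  expect_equal(rowSums(lump$memberships), rep(1, 4), tolerance = 1e-10)
  expect_true(all(lump$memberships >= 0 & lump$memberships <= 1))
  # exact decoupling: memberships become crisp 0/1
  crisp <- pcca_lump(block_tpm(0.1, 0), 2)
  expect_equal(sort(unique(as.vector(round(crisp$memberships, 10)))), c(0, 1))
  # n_macro = n_micro: identity up to permutation
  full <- pcca_lump(block_tpm(0.1, 0.01), 4)
  expect_identical(sort(full$crisp_map), 1:4)
  expect_error(pcca_lump(block_tpm(), 5), "exceeds")
})

test_that("lumped macro TPM of sampled block data reproduces inter-block rates", {
  spec <- two_pair_chain_spec(seed = 12)
  sim <- generate_hidden_chain(spec, 2, 2e5)
  cm <- count_matrix(sim$hidden, lag = 1, n_states = 4)
  tp <- estimate_tpm(cm, mode = "symmetrized")
  lump <- pcca_lump(tp, 2)
  # PCCA+ on the sampled 4-state matrix finds the two pairs
  expect_setequal(lump$crisp_map[1:2], lump$crisp_map[1])
  expect_setequal(lump$crisp_map[3:4], lump$crisp_map[3])
  expect_false(lump$crisp_map[1] == lump$crisp_map[3])
  expect_equal(lump$stationary, c(0.5, 0.5), tolerance = 0.02)
})

test_that("free energies pin the most populated state at zero", {
  expect_equal(free_energy(c(0.5, 0.5)), c(0, 0))
  fe <- free_energy(c(0.73, 0.27), temperature = 310)
  expect_equal(fe[2], 0.0019872 * 310 * log(0.73 / 0.27), tolerance = 1e-12)
  expect_equal(fe[1], 0)
  set.seed(11)
  for (i in 1:10) {
    p <- runif(5); p <- p / sum(p)
    fe <- free_energy(p)
    expect_equal(fe[which.max(p)], 0)
    expect_true(all(fe >= 0))
  }
  expect_identical(free_energy(c(1, 0))[2], Inf)
})

test_that("representative frames minimize distance with index tie-breaks", {
  pts <- matrix(c(0, 0, 1, 0, -1, 0, 5, 5), 4, 2, byrow = TRUE)
  labels <- c(1, 1, 1, 2)
  # center of state 1 is (0,0): frame 1 wins
  expect_identical(representative_frame(pts, labels, 1), 1L)
  # single-member state
  expect_identical(representative_frame(pts, labels, 2), 4L)
  # equidistant members: lowest index
  expect_identical(representative_frame(pts, labels, 1, center = c(0.5, 0)),
                   1L)
  # center coinciding with a member
  expect_identical(representative_frame(pts, labels, 1, center = c(-1, 0)),
                   3L)
  expect_error(representative_frame(pts, labels, 3), "no member")
})
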