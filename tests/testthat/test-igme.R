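test_that("the Markovian limit is an exact fixed point of the IGME fit", {
  tm <- matrix(c(.9, .1, .2, .8), 2, 2, byrow = TRUE)
  ser <- lapply(1:20, function(t) igmepath:::mat_pow(tm, t))
  fit <- fit_igme(ser, tau_k = 3, L = 8)
  expect_lt(max(abs(fit$A - diag(2))), 1e-8)
  expect_equal(fit$T_hat, tm, tolerance = 1e-10)
  expect_lt(fit$rmse, 1e-10)
  # single-point window interpolates exactly
  one <- fit_igme(ser, tau_k = 4, L = 1)
  expect_lt(one$rmse, 1e-12)
  expect_equal(one$A, diag(2))
  expect_error(fit_igme(ser, tau_k = 15, L = 10), "exceeds")
})

test_that("the hyperparameter scan covers the grid and breaks ties to parsimony", {
  tm <- matrix(c(.85, .15, .1, .9), 2, 2, byrow = TRUE)
  ser <- lapply(1:25, function(t) igmepath:::mat_pow(tm, t))
  sc <- scan_igme(ser, tau_k_grid = 0:9, L_grid = seq(2, 11))
  expect_identical(nrow(sc$table), 100L)       # 10 x 10 models scanned
  expect_true(all(sc$table$rmse < 1e-8))
  # all pairs tie at rmse ~ 0: smallest tau_k then smallest L wins
  expect_identical(sc$best$tau_k, 0L)
  expect_identical(sc$best$L, 2L)
  expect_error(scan_igme(ser, 30, 10), "feasible")
})

test_that("IGME absorbs lumping memory that defeats the lag-1 MSM", {
  spec <- two_pair_chain_spec()
  ser <- exact_lumped_series(spec, 60)
  true_t2 <- generate_hidden_chain(spec, 1, 100)$ground_truth$slow_timescales[1]
  sc <- scan_igme(ser, 0:9, seq(5, 45, by = 5), lag_unit = 0.1)
  igme_t2 <- model_timescales(sc$best)[1]
  msm_t2 <- igmepath:::implied_timescales(ser[[1]], 0.1)[1]
  expect_lt(abs(igme_t2 - true_t2) / true_t2, 0.10)
  expect_lt(abs(igme_t2 - true_t2), abs(msm_t2 - true_t2))
  # the scan's memory time exceeds the generator's fast mixing time
  fast_t <- generate_hidden_chain(spec, 1, 100)$ground_truth$slow_timescales[2]
  expect_gt(sc$best$tau_k * 0.1, fast_t)
})

test_that("MFPT matches closed forms, equivariance and an independent oracle", {
  tm <- matrix(c(.9, .1, .2, .8), 2, 2, byrow = TRUE)
  m <- mfpt(tm, dt = 2)
  expect_equal(m, matrix(c(0, 20, 10, 0), 2, 2, byrow = TRUE))
  tm3 <- block_tpm(0.15, 0.02)
  perm <- c(2, 4, 1, 3)
  p <- diag(4)[perm, ]
  expect_equal(mfpt(p %*% tm3 %*% t(p)), mfpt(tm3)[perm, perm],
               tolerance = 1e-10)
  # dense linear solve vs fundamental-matrix computation
  expect_equal(mfpt(tm3, dt = 0.5), mfpt_fundamental(tm3, dt = 0.5),
               tolerance = 1e-10)
  expect_error(mfpt(diag(2)), "irreducible")
})

test_that("committors and flux conservation hold on the symmetric chain", {
  t3 <- matrix(c(.8, .2, 0, .2, .6, .2, 0, .2, .8), 3, 3, byrow = TRUE)
  fl <- tpt_flux(t3, 1, 3)
  expect_equal(fl$q_plus, c(0, 0.5, 1))
  expect_equal(fl$q_minus, c(1, 0.5, 0))
  out_src <- sum(fl$netflux[1, ]) - sum(fl$netflux[, 1])
  into_snk <- sum(fl$netflux[, 3]) - sum(fl$netflux[3, ])
  expect_equal(out_src, into_snk, tolerance = 1e-10)
})

test_that("TPT conservation holds on random irreducible chains", {
  set.seed(13)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    tm <- matrix(rgamma(n * n, 1), n, n)
    tm <- tm / rowSums(tm)
    src <- 1; snk <- n
    fl <- tpt_flux(tm, src, snk)
    expect_true(all(fl$q_plus >= -1e-12 & fl$q_plus <= 1 + 1e-12))
    expect_true(all(fl$q_minus >= -1e-12 & fl$q_minus <= 1 + 1e-12))
    net <- fl$netflux
    for (v in setdiff(seq_len(n), c(src, snk)))
      expect_lt(abs(sum(net[v, ]) - sum(net[, v])), 1e-10)
    expect_lt(abs((sum(net[src, ]) - sum(net[, src])) -
                  (sum(net[, snk]) - sum(net[snk, ]))), 1e-10)
  }
})

test_that("the dominant path of a 70/30 branch chain carries 70% of the flux", {
  tm <- branch_chain(0.7)
  fl <- tpt_flux(tm, 1, 4)
  oracle <- enumerate_paths(fl$netflux, 1, 4)
  best <- which.max(oracle$capacities)
  expect_identical(oracle$paths[[best]], c(1, 2, 4))
  expect_equal(oracle$capacities[best] / fl$total_flux, 0.7,
               tolerance = 0.02)
  expect_identical(fl$pathways[[1]]$states, c(1L, 2L, 4L))
  expect_equal(fl$pathways[[1]]$capacity / fl$total_flux, 0.7,
               tolerance = 0.02)
  expect_equal(fl$pathways[[2]]$capacity / fl$total_flux, 0.3,
               tolerance = 0.02)
})

test_that("flux endpoints come from the free-energy extremes", {
  ep <- select_endpoints(c(1.2, 0, 0.4))
  expect_identical(ep, list(source = 1L, sink = 2L))
  expect_error(select_endpoints(c(0.3, 0.3, 0.3)), "degenerate")
  expect_warning(select_endpoints(c(1, 1, 0)), "tied")
})

test_that("CK test passes self-consistent models and rejects shuffled ones", {
  # Markov-chain data: a model fitted to the TPM series must pass the
  # binary rule; the exact propagator (independent of the data, so its
  # deviations are pure sampling noise) must score near-complete element
  # coverage; a row-shuffled model must fail decisively at every lag.
  set.seed(14)
  tm <- matrix(rgamma(64, 2), 8, 8) + diag(20, 8)
  tm <- tm / rowSums(tm)
  spec <- hidden_chain_spec(tm, 1:8, frame_interval = 0.1, seed = 14)
  sim <- generate_hidden_chain(spec, 10, 20000)
  ser <- tpm_series(sim$trajectories, 10, n_states = 8)
  lags <- c(2L, 5L, 10L)
  fitted <- scan_igme(ser, 0:2, 3:6, lag_unit = 0.1)$best
  ck_fit <- ck_test(fitted, sim$trajectories, lags, n_states = 8, seed = 1,
                    conf = 0.99)
  expect_gt(mean(ck_fit$pass_fraction), 0.9)
  exact <- msm_model(tm, lag_unit = 0.1)
  ck_exact <- ck_test(exact, sim$trajectories, lags, n_states = 8, seed = 1,
                      conf = 0.99)
  expect_gt(mean(ck_exact$pass_fraction), 0.85)
  bad <- msm_model(ser[[1]][sample(8), ], lag_unit = 0.1)
  ck_bad <- ck_test(bad, sim$trajectories, lags, n_states = 8, seed = 1)
  expect_false(ck_bad$pass)
  expect_true(all(ck_bad$pass_fraction < 0.5))
  expect_warning(ck_test(exact, sim$trajectories[1], c(2L), n_states = 8,
                         seed = 1), "fewer than 2")
})
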