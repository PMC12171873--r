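# One small egress run + SOM shared by several blocks (built once).
som_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- channel_spec(seed = 7)
      eg <- generate_channel_egress(spec, n_traj = 80)
      ef <- egress_features(eg)
      som <- train_som(ef$features, cycles = 1500, seed = 7,
                       max_training_frames = 2000)
      cache <<- list(eg = eg, ef = ef, som = som)
    }
    cache
  }
})

test_that("a constant dataset collapses the BMU codebook onto the point", {
  x <- matrix(rep(c(3, 7, 1), each = 100), 100, 3)
  som <- train_som(x, grid = c(3, 3), cycles = 200, seed = 1)
  expect_identical(length(unique(som$bmu)), 1L)
  w <- som$codebook[som$bmu[1], ]
  expect_lt(max(abs(w - c(3, 7, 1))), 1e-6)
})

test_that("a frame equal to a codebook vector maps to that neuron", {
  fx <- som_fixture()
  som <- fx$som
  probe <- matrix(som$codebook[37, ], 1)
  expect_identical(igmepath:::som_bmu_cpp(probe, som$codebook), 37L)
})

test_that("SOM training is deterministic and its quantization error settles", {
  x <- matrix(rnorm(600), 200, 3)
  s1 <- train_som(x, grid = c(4, 4), cycles = 300, seed = 3)
  s2 <- train_som(x, grid = c(4, 4), cycles = 300, seed = 3)
  expect_identical(s1$codebook, s2$codebook)
  expect_identical(s1$bmu, s2$bmu)
  # mean quantization error over the last 10% of cycles does not rise
  last <- mean(tail(s1$qerr, 30))
  prev <- mean(s1$qerr[241:270])
  expect_lte(last, prev + 1e-8)
})

test_that("silhouette clustering finds two tight codebook groups", {
  set.seed(15)
  x <- rbind(matrix(rnorm(300, sd = 0.1), ncol = 3),
             matrix(rnorm(300, sd = 0.1) + 5, ncol = 3))
  som <- train_som(x, grid = c(4, 4), cycles = 300, seed = 2)
  cl <- cluster_neurons(som, 2:6)
  expect_identical(cl$k, 2L)
  # the two clusters coincide with the two blobs
  fc <- cl$cluster_of[som$bmu]
  expect_identical(length(unique(fc[1:100])), 1L)
  expect_identical(length(unique(fc[101:200])), 1L)
  expect_false(fc[1] == fc[101])
})

test_that("degenerate codebooks and starved grids are rejected", {
  x <- matrix(5, 50, 2)
  som <- train_som(x, grid = c(3, 3), cycles = 100, seed = 1)
  expect_error(cluster_neurons(som, 2:4), "degenerate|fewer than 3")
})

test_that("transition networks count consecutive BMU pairs per trajectory", {
  som <- list(bmu = c(4L, 4L, 9L, 2L), n_frames = 4L,
              codebook = matrix(0, 16, 2))
  class(som) <- "som_model"
  net <- build_transition_network(som, lengths = 4L)
  e <- net$edges[order(net$edges$from), ]
  expect_equal(e$from, c(4L, 9L))
  expect_equal(e$to, c(9L, 2L))
  expect_equal(e$weight, c(1L, 1L))
  expect_equal(net$self_loops$from, 4L)
  expect_equal(net$self_loops$weight, 1L)
  # boundary rule: two trajectories, no spurious cross edges
  som2 <- som; som2$bmu <- c(1L, 2L, 2L, 3L); som2$n_frames <- 4L
  net2 <- build_transition_network(som2, lengths = c(2L, 2L))
  expect_setequal(paste(net2$edges$from, net2$edges$to), c("1 2", "2 3"))
  # reversal transposes the network
  som3 <- som2; som3$bmu <- rev(som2$bmu)
  net3 <- build_transition_network(som3, lengths = c(2L, 2L))
  expect_setequal(paste(net3$edges$from, net3$edges$to),
                  paste(net2$edges$to, net2$edges$from))
  # total non-self weight equals total consecutive pairs minus self pairs
  fx <- som_fixture()
  netf <- build_transition_network(fx$som, fx$ef$lengths)
  pairs <- sum(fx$ef$lengths - 1L)
  expect_identical(sum(netf$edges$weight) + sum(netf$self_loops$weight),
                   pairs)
})

test_that("cluster heatmaps average capped distances with strict contacts", {
  som <- list(bmu = c(1L, 1L, 2L, 2L), n_frames = 4L,
              codebook = matrix(0, 4, 2), data = NULL)
  class(som) <- "som_model"
  clustering <- structure(list(cluster_of = c(1L, 2L, NA, NA), k = 2L),
                          class = "neuron_clustering")
  feats <- matrix(c(3.9, 3.9, 4.0, 4.0,
                    2.0, 6.0, 10.0, 12.0), 4, 2)
  hm <- cluster_heatmap(feats, som, clustering)
  expect_equal(hm$means, rbind(cluster1 = c(3.9, 4), cluster2 = c(4, 11)),
               ignore_attr = TRUE)
  expect_identical(unname(hm$contacts[, 1]), c(TRUE, FALSE))  # 3.9 yes, 4.0 no
  # uniform distances give uniform cells
  hm2 <- cluster_heatmap(matrix(5, 4, 2), som, clustering)
  expect_true(all(hm2$means == 5))
})

test_that("endpoints and pathways are read off the condensed network", {
  # hand-built linear 3-cluster system: bound -> mid -> unbound
  som <- list(bmu = rep(c(1L, 2L, 3L), each = 4), n_frames = 12L,
              codebook = matrix(0, 9, 2))
  class(som) <- "som_model"
  clustering <- structure(list(cluster_of = c(1L, 2L, 3L, rep(NA, 6)), k = 3L),
                          class = "neuron_clustering")
  net <- build_transition_network(som, lengths = 12L)
  feats <- matrix(rep(c(1, 5, 12), each = 4), 12, 1)
  hm <- cluster_heatmap(feats, som, clustering)
  ep <- identify_endpoints(clustering, hm, net)
  expect_identical(ep$bound, 1L)    # lowest mean distance, edge position
  expect_identical(ep$unbound, 3L)  # saturated at the cap
  pw <- extract_pathways(net, clustering, som, ep$bound, ep$unbound)
  expect_identical(length(pw$pathways), 1L)
  expect_identical(pw$pathways[[1]]$states, c(1L, 2L, 3L))
  expect_identical(pw$pathways[[1]]$support, 1L)
  # n_paths larger than available: everything returned, no error
  pw2 <- extract_pathways(net, clustering, som, 1L, 3L, n_paths = 10)
  expect_identical(length(pw2$pathways), 1L)
})

test_that("branch frames occupy disjoint neuron sets on egress data", {
  fx <- som_fixture()
  bl <- fx$eg$ground_truth$branch_labels
  xs <- do.call(rbind, fx$eg$coords)
  post <- xs[, 2] > fx$eg$spec$y_split & xs[, 2] < fx$eg$spec$y_exit - 6
  side <- ifelse(xs[, 1] < -1, "L", ifelse(xs[, 1] > 1, "R", NA))
  bmu_l <- unique(fx$som$bmu[post & side == "L" & !is.na(side)])
  bmu_r <- unique(fx$som$bmu[post & side == "R" & !is.na(side)])
  in_l <- fx$som$bmu[post & !is.na(side) & side == "L"]
  in_r <- fx$som$bmu[post & !is.na(side) & side == "R"]
  shared <- intersect(bmu_l, bmu_r)
  frac_clean <- (sum(!in_l %in% shared) + sum(!in_r %in% shared)) /
    (length(in_l) + length(in_r))
  expect_gte(frac_clean, 0.9)
})
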