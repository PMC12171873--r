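#' Train a sheet self-organizing map on ligand-distance features
#'
#' Online SOM on a non-periodic rectangular lattice (default 10 x 10):
#' each training cycle presents every (training) frame once in a seeded
#' random order, moving the best-matching unit and its Gaussian lattice
#' neighborhood toward the frame.  Learning rate and radius decay
#' linearly (defaults 0.05 -> 0.01 and half the grid diagonal -> 1).
#' The codebook is initialized from per-feature quantiles at seeded
#' uniform levels.  After training every frame is assigned its BMU.
#'
#' @param features a [feature_table()] (or matrix) of capped
#'   ligand-residue distances, frames x residues.
#' @param grid lattice dimensions, default `c(10, 10)`.
#' @param cycles training cycles (default 5000).
#' @param seed integer seed.
#' @param alpha learning-rate schedule `c(start, end)`.
#' @param radius neighborhood-radius schedule `c(start, end)`; default
#'   half the grid diagonal down to 1.
#' @param max_training_frames optional cap on the number of frames used
#'   for codebook training (a seeded subsample; BMUs are still assigned
#'   to every frame).
#' @return an object of class `som_model`: `codebook` (neurons x
#'   features), `grid`, `bmu` (per frame, 1-based, row-major over the
#'   lattice x-axis), `qerr` (mean quantization error per cycle) and the
#'   training parameters.
#' @export
train_som <- function(features, grid = c(10, 10), cycles = 5000, seed = 1L,
                      alpha = c(0.05, 0.01), radius = NULL,
                      max_training_frames = NULL) {
  x <- if (inherits(features, "feature_table")) features$values else as.matrix(features)
  if (nrow(x) < 1L) stop("no frames to train on")
  nx <- grid[1]; ny <- grid[2]; m <- nx * ny
  if (is.null(radius)) radius <- c(sqrt(nx^2 + ny^2) / 2, 1)
  set.seed(as.integer(seed))
  d <- ncol(x)
  init <- matrix(NA_real_, m, d)
  for (j in seq_len(d))
    init[, j] <- quantile(x[, j], runif(m), names = FALSE)
  xt <- x
  if (!is.null(max_training_frames) && nrow(x) > max_training_frames)
    xt <- x[sort(sample.int(nrow(x), max_training_frames)), , drop = FALSE]
  trained <- train_som_cpp(xt, as.integer(nx), as.integer(ny),
                           as.integer(cycles), init,
                           alpha[1], alpha[2], radius[1], radius[2])
  bmu <- som_bmu_cpp(x, trained$codebook)
  structure(list(codebook = trained$codebook, grid = c(nx, ny),
                 bmu = bmu, qerr = trained$qerr,
                 n_frames = nrow(x),
                 training = list(cycles = cycles, alpha = alpha,
                                 radius = radius, seed = as.integer(seed),
                                 n_training_frames = nrow(xt)),
                 features = if (inherits(features, "feature_table"))
                   features$descriptors else NULL,
                 data = x),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model:", x$grid[1], "x", x$grid[2], "sheet,",
      length(unique(x$bmu)), "occupied neurons,", x$n_frames, "frames\n")
  invisible(x)
}

#' Cluster SOM neurons by silhouette-guided Ward clustering
#'
#' Hierarchical agglomerative (Ward) clustering of the codebook vectors
#' of non-empty neurons; the number of clusters maximizes the mean
#' silhouette width over `k_range`.  Each cluster's representative
#' neuron is the member closest to the cluster centroid; each non-empty
#' neuron's representative frame is the assigned frame closest to its
#' codebook vector.
#'
#' @param som a [train_som()] result.
#' @param k_range candidate cluster counts (default 2:8), truncated to
#'   at most `n_nonempty - 1`.
#' @return an object of class `neuron_clustering`: `cluster_of` (per
#'   neuron, NA for empty neurons), `k`, `silhouette_by_k`,
#'   `representative_neuron` (per cluster) and `representative_frame`
#'   (per neuron).
#' @export
cluster_neurons <- function(som, k_range = 2:8) {
  occupied <- sort(unique(som$bmu))
  if (length(occupied) < 3L)
    stop("fewer than 3 non-empty neurons; cannot cluster")
  cb <- som$codebook[occupied, , drop = FALSE]
  dd <- dist(cb)
  if (max(dd) < 1e-12)
    stop("degenerate codebook: all occupied neurons identical")
  k_range <- k_range[k_range >= 2 & k_range <= length(occupied) - 1]
  if (length(k_range) == 0L) stop("k_range empty after truncation")
  hc <- hclust(dd, method = "ward.D2")
  sil <- vapply(k_range, function(k) {
    labs <- cutree(hc, k = k)
    mean(cluster::silhouette(labs, dd)[, "sil_width"])
  }, 1)
  k <- k_range[which.max(sil)]
  labs <- cutree(hc, k = k)
  cluster_of <- rep(NA_integer_, nrow(som$codebook))
  cluster_of[occupied] <- labs
  rep_neuron <- vapply(seq_len(k), function(cl) {
    members <- occupied[labs == cl]
    cen <- colMeans(som$codebook[members, , drop = FALSE])
    members[which.min(colSums((t(som$codebook[members, , drop = FALSE]) - cen)^2))]
  }, 1L)
  rep_frame <- rep(NA_integer_, nrow(som$codebook))
  for (u in occupied) {
    frames <- which(som$bmu == u)
    dev <- colSums((t(som$data[frames, , drop = FALSE]) - som$codebook[u, ])^2)
    rep_frame[u] <- frames[which.min(dev)]
  }
  structure(list(cluster_of = cluster_of, k = k,
                 silhouette_by_k = data.frame(k = k_range, silhouette = sil),
                 representative_neuron = rep_neuron,
                 representative_frame = rep_frame,
                 occupied = occupied),
            class = "neuron_clustering")
}

#' @export
print.neuron_clustering <- function(x, ...) {
  cat("neuron_clustering: k =", x$k, "clusters over", length(x$occupied),
      "occupied neurons\n")
  invisible(x)
}

#' Per-cluster ligand-residue distance heatmap
#'
#' Mean capped distance per cluster and residue, with residues whose
#' cluster mean falls strictly below `contact_cutoff` flagged as
#' contacts.  Empty clusters yield NaN rows.
#'
#' @param features the [feature_table()] (or matrix) the SOM was trained
#'   on.
#' @param som a [train_som()] result.
#' @param clustering a [cluster_neurons()] result.
#' @param contact_cutoff contact threshold in angstrom (default 4).
#' @return list with `means` (clusters x residues), `contacts` (logical
#'   matrix) and `empty` (logical per cluster).
#' @export
cluster_heatmap <- function(features, som, clustering, contact_cutoff = 4) {
  x <- if (inherits(features, "feature_table")) features$values else as.matrix(features)
  frame_cluster <- clustering$cluster_of[som$bmu]
  k <- clustering$k
  means <- matrix(NaN, k, ncol(x))
  for (cl in seq_len(k)) {
    rows <- which(frame_cluster == cl)
    if (length(rows) > 0)
      means[cl, ] <- colMeans(x[rows, , drop = FALSE])
  }
  colnames(means) <- colnames(x)
  rownames(means) <- paste0("cluster", seq_len(k))
  list(means = means, contacts = !is.nan(means) & means < contact_cutoff,
       empty = apply(means, 1, function(r) all(is.nan(r))))
}
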