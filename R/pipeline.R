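#' Read and validate a pipeline configuration
#'
#' YAML configuration with a mandatory integer `seed` and a
#' `frame_interval` (ns).  Lag times given in ns must convert to whole
#' frames.  See `system.file("extdata", "reference_config.yaml",
#' package = "igmepath")` for the reference parameter sets.
#'
#' @param path YAML file path.
#' @return named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a configuration list (already parsed).
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("config error: seed is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  cfg$frame_interval <- cfg$frame_interval %||% 0.1
  for (field in c("tica_lag_ns", "msm_lag_ns")) {
    v <- cfg[[field]]
    if (!is.null(v)) {
      fr <- v / cfg$frame_interval
      if (abs(fr - round(fr)) > 1e-9)
        stop("config error: ", field, " = ", v,
             " ns is not a whole number of frames at frame_interval ",
             cfg$frame_interval, " ns")
    }
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

write_artifact <- function(x, path, cfg) {
  con <- file(path, "w")
  writeLines(sprintf("# igmepath artifact | config_hash=%s | seed=%d",
                     config_hash(cfg), cfg$seed), con)
  if (is.matrix(x) || is.data.frame(x))
    suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  else writeLines(as.character(x), con)
  close(con)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

# Macro-label trajectories from the configured input.
state_model_labels <- function(cfg) {
  input <- cfg$input
  if (identical(input$type, "hidden_chain")) {
    spec <- two_pair_chain_spec(
      fast = input$fast %||% 0.2, slow = input$slow %||% 0.01,
      frame_interval = cfg$frame_interval, seed = cfg$seed)
    sim <- generate_hidden_chain(spec, input$n_traj %||% 1L,
                                 input$n_frames %||% 100000L)
    list(labels = sim$trajectories, n_macro = spec$n_macro,
         ground_truth = sim$ground_truth, projected = NULL)
  } else if (identical(input$type, "trajectory")) {
    trajs <- lapply(seq_along(input$frames), function(i)
      read_trajectory(input$topology, input$frames[[i]],
                      frame_interval = cfg$frame_interval))
    feats <- lapply(trajs, function(tr) {
      fts <- list()
      if (!is.null(input$chi1_residues))
        fts <- c(fts, list(compute_chi1(tr, input$chi1_residues)))
      for (hp in input$helix_pairs %||% list())
        fts <- c(fts, list(compute_helix_distance(tr, hp[[1]], hp[[2]])))
      expand_circular(do.call(bind_features, fts))
    })
    tica_lag <- round((cfg$tica_lag_ns %||% cfg$frame_interval) /
                        cfg$frame_interval)
    tica <- fit_tica(feats, lag = tica_lag,
                     n_components = cfg$n_components %||% 3)
    proj <- lapply(feats, function(f) predict(tica, f))
    km <- fit_kmeans(do.call(rbind, proj), cfg$k %||% 100, cfg$seed)
    lens <- vapply(proj, nrow, 1L)
    ends <- cumsum(lens); starts <- c(1L, head(ends, -1) + 1L)
    micro <- lapply(seq_along(lens), function(i) km$labels[starts[i]:ends[i]])
    msm_lag <- round((cfg$msm_lag_ns %||% cfg$frame_interval) /
                       cfg$frame_interval)
    cm <- count_matrix(micro, lag = msm_lag, n_states = km$k)
    tpm_sym <- estimate_tpm(cm, lag = msm_lag, mode = "symmetrized")
    lump <- pcca_lump(tpm_sym, cfg$n_macro %||% 3,
                      temperature = cfg$temperature %||% 310)
    macro <- lapply(micro, function(mi) {
      kept <- match(mi, tpm_sym$states)
      lump$crisp_map[kept[!is.na(kept)]]
    })
    list(labels = macro, n_macro = lump$n_macro, ground_truth = NULL,
         projected = proj, tica = tica, kmeans = km, lump = lump,
         trajectories = trajs)
  } else stop("config error: unknown input type '", input$type, "'")
}

#' Run the state-model leg of the pipeline
#'
#' Fixed stage order: featurization (or synthetic macro labels), tICA,
#' k-means, microstate MSM, PCCA+ lumping, IGME hyperparameter scan,
#' Chapman-Kolmogorov validation, MFPT and TPT net-flux pathways.  Every
#' artifact is written as TSV with a provenance header (config hash and
#' seed).
#'
#' @param cfg a [read_pipeline_config()] result (or equivalent list).
#' @param outdir output directory.
#' @return invisible list of fitted objects.
#' @export
run_state_model <- function(cfg, outdir) {
  cfg <- validate_pipeline_config(unclass(cfg))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prep <- run_stage("featurize", state_model_labels(cfg))
  labels <- prep$labels
  max_lag <- cfg$igme$max_lag_frames %||% 50L
  ser <- run_stage("tpm_series",
                   tpm_series(labels, max_lag, n_states = prep$n_macro))
  frame_ns <- cfg$frame_interval *
    round((cfg$msm_lag_ns %||% cfg$frame_interval) / cfg$frame_interval)
  tau_grid <- cfg$igme$tau_k_grid %||% 0:9
  l_grid <- cfg$igme$L_grid %||% seq(5L, 41L, by = 4L)
  scan <- run_stage("igme_scan",
                    scan_igme(ser, tau_grid, l_grid, lag_unit = frame_ns))
  best <- scan$best
  ck <- run_stage("ck_test",
                  ck_test(best, labels,
                          test_lags = cfg$igme$ck_lags %||%
                            c(5L, 10L, 20L, min(40L, max_lag)),
                          n_states = prep$n_macro, seed = cfg$seed))
  mf <- run_stage("mfpt", mfpt(best))
  pi_hat <- stationary_distribution(best$T_hat)
  fe <- free_energy(pi_hat, cfg$temperature %||% 310)
  ep <- run_stage("endpoints", select_endpoints(fe))
  flux <- run_stage("tpt", tpt_flux(best, ep$source, ep$sink))
  write_artifact(scan$table, file.path(outdir, "igme_scan.tsv"), cfg)
  write_artifact(best$T_hat, file.path(outdir, "igme_T_hat.tsv"), cfg)
  write_artifact(best$A, file.path(outdir, "igme_A.tsv"), cfg)
  write_artifact(mf, file.path(outdir, "mfpt_ns.tsv"), cfg)
  write_artifact(data.frame(state = seq_along(pi_hat),
                            stationary = pi_hat, free_energy = fe),
                 file.path(outdir, "macrostates.tsv"), cfg)
  write_artifact(flux$netflux, file.path(outdir, "netflux.tsv"), cfg)
  write_artifact(vapply(flux$pathways, function(p)
    paste(paste(p$states, collapse = "->"), signif(p$capacity, 6), sep = "\t"),
    ""), file.path(outdir, "flux_pathways.tsv"), cfg)
  ck_tab <- data.frame(lag = ck$test_lags, pass_fraction = ck$pass_fraction)
  write_artifact(ck_tab, file.path(outdir, "ck_report.tsv"), cfg)
  if (!is.null(prep$trajectories)) {
    reps <- vapply(seq_len(prep$n_macro), function(s) {
      macro_all <- unlist(prep$labels)
      proj_all <- do.call(rbind, prep$projected)
      representative_frame(proj_all, macro_all, s)
    }, 1L)
    # map global frame index back to (trajectory, frame)
    lens <- vapply(prep$projected, nrow, 1L)
    ends <- cumsum(lens); starts <- c(1L, head(ends, -1) + 1L)
    for (s in seq_along(reps)) {
      ti <- findInterval(reps[s], starts)
      write_representatives(prep$trajectories[[ti]],
                            reps[s] - starts[ti] + 1L, outdir,
                            prefix = sprintf("state%d", s))
    }
  }
  invisible(list(scan = scan, igme = best, ck = ck, mfpt = mf,
                 stationary = pi_hat, free_energy = fe, flux = flux,
                 prep = prep))
}

#' Run the pathway-detection leg of the pipeline
#'
#' Capped ligand-residue distances (cap from config, default 12 A), SOM
#' training, silhouette neuron clustering, transition network, endpoint
#' identification, pathway extraction and the per-cluster distance
#' heatmap.
#'
#' @param cfg a [read_pipeline_config()] result (or equivalent list).
#' @param outdir output directory.
#' @return invisible list of fitted objects.
#' @export
run_pathway_detection <- function(cfg, outdir) {
  cfg <- validate_pipeline_config(unclass(cfg))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cap <- cfg$som$cap %||% 12
  input <- cfg$input
  if (identical(input$type, "egress")) {
    spec <- channel_spec(seed = cfg$seed,
                         block_height = input$block_height %||% 0)
    egress <- run_stage("egress", generate_channel_egress(
      spec, input$n_traj %||% 200L, input$max_steps %||% 5000L,
      stride = input$stride %||% 25L))
    ef <- egress_features(egress, cap = cap)
    features <- ef$features; lengths <- ef$lengths
    ground_truth <- egress$ground_truth
  } else if (identical(input$type, "trajectory")) {
    if (is.null(input$ligand)) stop("config error: ligand selection missing")
    trajs <- lapply(seq_along(input$frames), function(i)
      read_trajectory(input$topology, input$frames[[i]],
                      frame_interval = cfg$frame_interval))
    fts <- lapply(trajs, function(tr) {
      if (length(select_atoms(tr, input$ligand)) == 0L)
        stop("no ligand atoms in topology")
      compute_ligand_distances(tr, input$ligand, input$residues, cap = cap)
    })
    features <- do.call(bind_rows_features, fts)
    lengths <- vapply(fts, function(f) nrow(f$values), 1L)
    ground_truth <- NULL
  } else stop("config error: unknown input type '", input$type, "'")
  if (nrow(features$values) < 2L) stop("insufficient frames")
  som <- run_stage("som", train_som(
    features, grid = cfg$som$grid %||% c(10, 10),
    cycles = cfg$som$cycles %||% 5000, seed = cfg$seed,
    max_training_frames = cfg$som$max_training_frames))
  clustering <- run_stage("cluster_neurons",
                          cluster_neurons(som, cfg$som$k_range %||% 2:8))
  network <- run_stage("network", build_transition_network(som, lengths))
  heatmap <- run_stage("heatmap",
                       cluster_heatmap(features, som, clustering))
  ep <- run_stage("endpoints",
                  identify_endpoints(clustering, heatmap, network))
  paths <- run_stage("pathways",
                     extract_pathways(network, clustering, som,
                                      ep$bound, ep$unbound,
                                      cfg$som$n_paths %||% Inf))
  assignment <- assign_pathways(paths)
  write_artifact(som$codebook, file.path(outdir, "codebook.tsv"), cfg)
  write_artifact(data.frame(frame = seq_along(som$bmu), bmu = som$bmu),
                 file.path(outdir, "bmu.tsv"), cfg)
  write_artifact(data.frame(neuron = seq_along(clustering$cluster_of),
                            cluster = clustering$cluster_of),
                 file.path(outdir, "cluster_map.tsv"), cfg)
  write_artifact(network$edges, file.path(outdir, "edges.tsv"), cfg)
  write_artifact(heatmap$means, file.path(outdir, "heatmap.tsv"), cfg)
  write_artifact(vapply(paths$pathways, function(p)
    paste(paste(p$states, collapse = "->"), p$bottleneck, p$support,
          sep = "\t"), ""), file.path(outdir, "pathways.tsv"), cfg)
  invisible(list(som = som, clustering = clustering, network = network,
                 heatmap = heatmap, endpoints = ep, pathways = paths,
                 assignment = assignment, ground_truth = ground_truth,
                 lengths = lengths))
}

# Row-bind feature tables with identical descriptors.
bind_rows_features <- function(...) {
  fts <- list(...)
  feature_table(do.call(rbind, lapply(fts, function(f) f$values)),
                kind = fts[[1]]$descriptors$kind,
                selection = fts[[1]]$descriptors$selection,
                units = fts[[1]]$descriptors$units)
}

#' Reference analysis parameters
#'
#' The parameter sets used for the three transporter systems (tICA lag,
#' component count, microstate count, MSM lag and IGME hyperparameters),
#' shipped as a YAML reference config.
#'
#' @return named list, one entry per system.
#' @export
reference_config <- function() {
  yaml::read_yaml(system.file("extdata", "reference_config.yaml",
                              package = "igmepath"))
}
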