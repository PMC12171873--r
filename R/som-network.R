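#' Neuron transition network
#'
#' Directed graph over neurons whose edge `u -> v` counts
#' consecutive-frame BMU transitions, accumulated per trajectory and
#' never across trajectory boundaries.  Self-transitions (dwelling) are
#' recorded separately and excluded from pathway search.
#'
#' @param som a [train_som()] result.
#' @param lengths integer frames per trajectory (must sum to the SOM's
#'   frame count).
#' @return an object of class `transition_network` with `edges`
#'   (data.frame `from`, `to`, `weight`), `self_loops`, the igraph
#'   `graph`, and `lengths`.
#' @export
build_transition_network <- function(som, lengths) {
  stopifnot(sum(lengths) == som$n_frames)
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  from <- integer(0); to <- integer(0)
  for (t in seq_along(lengths)) {
    if (lengths[t] < 2) next
    seq_b <- som$bmu[starts[t]:ends[t]]
    from <- c(from, seq_b[-length(seq_b)])
    to <- c(to, seq_b[-1])
  }
  key <- paste(from, to)
  tab <- table(key)
  parts <- strsplit(names(tab), " ")
  edges <- data.frame(from = as.integer(vapply(parts, `[`, "", 1)),
                      to = as.integer(vapply(parts, `[`, "", 2)),
                      weight = as.integer(tab))
  self <- edges[edges$from == edges$to, , drop = FALSE]
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = seq_len(nrow(som$codebook))))
  structure(list(edges = edges, self_loops = self, graph = g,
                 lengths = lengths),
            class = "transition_network")
}

#' @export
print.transition_network <- function(x, ...) {
  cat("transition_network:", nrow(x$edges), "directed edges,",
      sum(x$edges$weight), "non-self transitions\n")
  invisible(x)
}

# Cluster-level condensation of the neuron transition network: aggregate
# edge weights between clusters, drop intra-cluster edges.
condense_network <- function(network, clustering) {
  e <- network$edges
  fc <- clustering$cluster_of[e$from]
  tc <- clustering$cluster_of[e$to]
  keep <- !is.na(fc) & !is.na(tc) & fc != tc
  agg <- stats::aggregate(list(weight = e$weight[keep]),
                          by = list(from = fc[keep], to = tc[keep]), sum)
  w <- matrix(0, clustering$k, clustering$k)
  w[cbind(agg$from, agg$to)] <- agg$weight
  w
}

# Per-trajectory cluster sequences (runs collapsed).
cluster_sequences <- function(som, clustering, lengths) {
  ends <- cumsum(lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  lapply(seq_along(lengths), function(t) {
    cl <- clustering$cluster_of[som$bmu[starts[t]:ends[t]]]
    cl <- cl[!is.na(cl)]
    rle(cl)$values
  })
}

is_subsequence <- function(sub, seqv) {
  j <- 1L
  for (s in seqv) {
    if (s == sub[j]) {
      j <- j + 1L
      if (j > length(sub)) return(TRUE)
    }
  }
  FALSE
}

#' Identify bound and unbound endpoint clusters
#'
#' The unbound cluster has the largest mean capped distance (most
#' residues at the cap); the bound cluster has the smallest mean among
#' clusters sitting at an edge of the cluster-level network (total
#' degree at most 2), falling back to the overall minimum.  Ties break
#' to the lowest cluster label with a warning.
#'
#' @param clustering a [cluster_neurons()] result.
#' @param heatmap a [cluster_heatmap()] result.
#' @param network a [build_transition_network()] result.
#' @return list with `bound`, `unbound` and the per-cluster `mean_distance`
#'   evidence.
#' @export
identify_endpoints <- function(clustering, heatmap, network) {
  mu <- rowMeans(heatmap$means)
  if (sum(mu == max(mu, na.rm = TRUE), na.rm = TRUE) > 1)
    warning("tied unbound candidates; using lowest cluster label")
  unbound <- unname(which.max(mu))
  w <- condense_network(network, clustering)
  und <- (w + t(w)) > 0
  degree <- rowSums(und)
  edge_pos <- which(degree <= 2 & degree >= 1)
  cands <- setdiff(edge_pos, unbound)
  if (length(cands) == 0L) cands <- setdiff(seq_along(mu), unbound)
  mu_c <- mu[cands]
  if (sum(mu_c == min(mu_c, na.rm = TRUE)) > 1)
    warning("tied bound candidates; using lowest cluster label")
  bound <- unname(cands[which.min(mu_c)])
  list(bound = bound, unbound = unbound, mean_distance = mu)
}

#' Extract egress pathways from the cluster-level network
#'
#' Simple paths from the bound to the unbound cluster in the condensed
#' (cluster-level) transition network, ranked by decreasing bottleneck
#' weight (the smallest edge weight along the path).  Each path's
#' support is the number of trajectories whose run-collapsed cluster
#' sequence contains it as a subsequence.
#'
#' @param network a [build_transition_network()] result.
#' @param clustering a [cluster_neurons()] result.
#' @param som the [train_som()] result (for per-trajectory sequences).
#' @param bound,unbound endpoint cluster labels.
#' @param n_paths maximum number of pathways to return (default all).
#' @return an object of class `pathway_set`: list of pathways
#'   (`states`, `bottleneck`, `support`) plus the trajectory cluster
#'   sequences.
#' @export
extract_pathways <- function(network, clustering, som, bound, unbound,
                             n_paths = Inf) {
  w <- condense_network(network, clustering)
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "directed")
  sp <- igraph::all_simple_paths(g, from = bound, to = unbound, mode = "out")
  if (length(sp) == 0L)
    stop("no egress observed: unbound cluster unreachable from bound")
  seqs <- cluster_sequences(som, clustering, network$lengths)
  paths <- lapply(sp, function(p) {
    st <- as.integer(p)
    bn <- min(w[cbind(st[-length(st)], st[-1])])
    support <- sum(vapply(seqs, function(s) is_subsequence(st, s), TRUE))
    list(states = st, bottleneck = bn, support = support)
  })
  ord <- order(vapply(paths, function(p) p$bottleneck, 1), decreasing = TRUE)
  paths <- paths[ord]
  if (is.finite(n_paths)) paths <- head(paths, n_paths)
  structure(list(pathways = paths, bound = bound, unbound = unbound,
                 sequences = seqs),
            class = "pathway_set")
}

#' @export
print.pathway_set <- function(x, ...) {
  cat("pathway_set:", length(x$pathways), "pathways", x$bound, "->",
      x$unbound, "\n")
  for (p in x$pathways)
    cat("  ", paste(p$states, collapse = " -> "), " bottleneck",
        p$bottleneck, " support", p$support, "\n")
  invisible(x)
}

# Latest start index at which `sub` occurs as a subsequence of `seqv`
# (backward greedy), or 0 if it does not occur.  The latest match marks
# the route a trajectory was on when it finally reached the endpoint.
latest_subsequence_start <- function(sub, seqv) {
  j <- length(sub)
  for (i in rev(seq_along(seqv))) {
    if (seqv[i] == sub[j]) {
      j <- j - 1L
      if (j == 0L) return(i)
    }
  }
  0L
}

#' Assign trajectories to extracted pathways
#'
#' Each trajectory is assigned the pathway its cluster sequence contains
#' as a subsequence.  When several pathways match (e.g. a trajectory
#' that visited both branches), the one matched latest in the sequence
#' wins — that is the route the trajectory was on when it reached the
#' unbound state; remaining ties resolve to the higher-ranked pathway.
#' Trajectories matching no pathway get NA.
#'
#' @param pathways a [extract_pathways()] result.
#' @return integer vector, one pathway index (into `pathways$pathways`)
#'   per trajectory, NA when unmatched.
#' @export
assign_pathways <- function(pathways) {
  ps <- pathways$pathways
  vapply(pathways$sequences, function(s) {
    starts <- vapply(ps, function(p) latest_subsequence_start(p$states, s), 1L)
    if (all(starts == 0L)) return(NA_integer_)
    which.max(starts)   # ties: earlier (higher-ranked) pathway
  }, 1L)
}
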