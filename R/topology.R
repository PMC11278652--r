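# The 12 network-level topological features, on whole networks and on
# per-sample presence-induced subnetworks, with the group-difference tests
# used to compare them across seasons, landforms and regions.

#' Names of the 12 network-level topological features
#'
#' The canonical feature set computed by [compute_topology()] and compared
#' across seasons, landforms and regions.
#'
#' @format Character vector of length 12.
#' @export
TOPOLOGY_FEATURES <- c("node_count", "edge_count", "graph_density",
                       "transitivity", "avg_clustering", "avg_degree",
                       "degree_centralization", "avg_nn_degree",
                       "avg_path_length", "avg_betweenness", "modularity",
                       "assortativity")

#' Compute the 12 topological features of a network
#'
#' node_count, edge_count, graph_density, transitivity (global),
#' avg_clustering (mean local clustering, degree < 2 nodes contribute 0),
#' avg_degree, degree_centralization (Freeman), avg_nn_degree (mean over
#' non-isolated nodes of the mean neighbor degree), avg_path_length (over
#' connected pairs), avg_betweenness (exact, unnormalized, undirected
#' paths counted once), modularity (seeded Louvain), assortativity
#' (Pearson correlation of degrees at edge endpoints). Features undefined
#' on a degenerate graph are NA, never 0.
#'
#' @param graph Simple undirected igraph object.
#' @param seed Seed for Louvain.
#' @return One-row data.frame with the 12 feature columns.
#' @export
compute_topology <- function(graph, seed = 1L) {
  n <- igraph::vcount(graph)
  if (n == 0) stopf("cannot compute topology of an empty graph")
  m <- igraph::ecount(graph)
  out <- stats::setNames(as.list(rep(NA_real_, length(TOPOLOGY_FEATURES))),
                         TOPOLOGY_FEATURES)
  out$node_count <- n
  out$edge_count <- m
  if (n >= 2) out$graph_density <- 2 * m / (n * (n - 1))
  out$avg_degree <- 2 * m / n
  if (m > 0) {
    tr <- igraph::transitivity(graph, type = "global")
    out$transitivity <- if (is.nan(tr)) NA_real_ else tr
    out$avg_clustering <- igraph::transitivity(graph, type = "localaverage",
                                               isolates = "zero")
    deg <- igraph::degree(graph)
    knn <- igraph::knn(graph)$knn
    out$avg_nn_degree <- mean(knn[deg > 0])
    out$avg_path_length <- igraph::mean_distance(graph, unconnected = TRUE)
    out$avg_betweenness <- mean(igraph::betweenness(graph, directed = FALSE,
                                                    normalized = FALSE))
    out$modularity <- local_seed(seed,
      igraph::modularity(graph,
        igraph::membership(igraph::cluster_louvain(graph, weights = NA))))
    asst <- igraph::assortativity_degree(graph)
    out$assortativity <- if (is.nan(asst)) NA_real_ else asst
  }
  out$degree_centralization <- degree_centralization(graph)
  as.data.frame(out)
}

#' Freeman degree centralization
#'
#' sum(k_max - k_i) / ((n - 1)(n - 2)): 1 for a star, 0 for any regular
#' graph; NA (missing) for fewer than 3 nodes.
#'
#' @param graph igraph object.
#' @return Value in `[0, 1]`, or NA.
#' @export
degree_centralization <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 3) return(NA_real_)
  k <- igraph::degree(graph)
  sum(max(k) - k) / ((n - 1) * (n - 2))
}

#' Presence-induced per-sample subnetwork
#'
#' The induced subgraph on the network nodes whose abundance in the given
#' sample is > 0 (edges kept iff both endpoints are present).
#'
#' @param net Co-occurrence network (igraph, nodes named by OTU id).
#' @param table Samples x OTUs matrix.
#' @param sample_id A row name of `table`.
#' @return igraph object (possibly empty).
#' @export
extract_sample_subnetwork <- function(net, table, sample_id) {
  if (!sample_id %in% rownames(table))
    stopf("unknown sample '%s'", sample_id)
  abund <- table[sample_id, ]
  present <- names(abund)[abund > 0]
  keep <- intersect(igraph::V(net)$name, present)
  igraph::induced_subgraph(net, keep)
}

#' Topological features of every sample's subnetwork
#'
#' One row per sample; when metadata is supplied, season, landform and
#' region are carried along for grouping.
#'
#' @param net Co-occurrence network.
#' @param table Samples x OTUs matrix.
#' @param metadata Optional sample metadata.
#' @param seed Seed passed to [compute_topology()].
#' @return data.frame: sample_id, (annotations), 12 feature columns.
#' @export
per_sample_topology <- function(net, table, metadata = NULL, seed = 1L) {
  rows <- lapply(rownames(table), function(s) {
    g <- extract_sample_subnetwork(net, table, s)
    feats <- if (igraph::vcount(g) == 0) {
      as.data.frame(stats::setNames(
        as.list(rep(NA_real_, length(TOPOLOGY_FEATURES))), TOPOLOGY_FEATURES))
    } else compute_topology(g, seed = seed)
    cbind(data.frame(sample_id = s, stringsAsFactors = FALSE), feats)
  })
  out <- do.call(rbind, rows)
  if (!is.null(metadata)) {
    i <- match(out$sample_id, metadata$sample_id)
    out <- cbind(out[, "sample_id", drop = FALSE],
                 metadata[i, intersect(c("season", "landform", "region"),
                                       names(metadata)), drop = FALSE],
                 out[, TOPOLOGY_FEATURES])
    rownames(out) <- NULL
  }
  out
}

#' Group-difference tests on a per-sample feature matrix
#'
#' Two groups: two-sided Wilcoxon rank-sum with the normal approximation
#' (tie-corrected). Three or more: one-way ANOVA F test. Groups with
#' fewer than 3 samples make the comparison flagged (NA), not computed.
#'
#' @param feature_matrix data.frame from [per_sample_topology()] (feature
#'   columns are auto-detected) or any numeric data.frame.
#' @param grouping Factor/character vector, one entry per row.
#' @return data.frame(feature, test, statistic, p, stars).
#' @export
group_difference_tests <- function(feature_matrix, grouping) {
  feats <- intersect(TOPOLOGY_FEATURES, names(feature_matrix))
  if (!length(feats))
    feats <- names(feature_matrix)[vapply(feature_matrix, is.numeric, TRUE)]
  grouping <- as.factor(as.character(grouping))
  if (nlevels(grouping) < 2) stopf("need at least 2 groups")
  counts <- table(grouping)
  ok_groups <- all(counts >= 3)
  test_name <- if (nlevels(grouping) == 2) "wilcoxon" else "anova"
  rows <- lapply(feats, function(f) {
    y <- feature_matrix[[f]]
    if (!ok_groups || all(is.na(y)))
      return(data.frame(feature = f, test = test_name,
                        statistic = NA_real_, p = NA_real_, stars = "",
                        stringsAsFactors = FALSE))
    if (test_name == "wilcoxon") {
      lv <- levels(grouping)
      res <- suppressWarnings(
        stats::wilcox.test(y[grouping == lv[1]], y[grouping == lv[2]],
                           exact = FALSE, correct = TRUE))
      stat <- unname(res$statistic); p <- res$p.value
    } else {
      fit <- stats::aov(y ~ grouping)
      an <- summary(fit)[[1]]
      stat <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
    }
    data.frame(feature = f, test = test_name, statistic = stat, p = p,
               stars = p_stars(p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
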