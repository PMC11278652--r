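# From OTU table to thresholded co-occurrence network: prevalence filter,
# tie-corrected Spearman correlations with t-approximation p-values,
# Benjamini-Hochberg control, strict edge rule (rho > 0.6, q < 0.01,
# positive only), Louvain modules.

#' Prevalence filter
#'
#' Keeps OTUs present (abundance > 0) in at least `min_fraction` of the
#' samples; the boundary is inclusive (presence/n >= min_fraction). The
#' sample set is unchanged.
#'
#' @param table Samples x OTUs matrix.
#' @param min_fraction Minimum presence fraction in (0, 1].
#' @return Filtered matrix.
#' @export
filter_by_prevalence <- function(table, min_fraction = 0.30) {
  if (nrow(table) == 0) stopf("OTU table has zero samples")
  assert_otu_table(table)
  if (min_fraction <= 0 || min_fraction > 1)
    stopf("min_fraction must lie in (0, 1]")
  presence <- colMeans(table > 0)
  table[, presence >= min_fraction, drop = FALSE]
}

#' All-pairs Spearman correlations with BH-adjusted p-values
#'
#' Spearman rho is Pearson correlation of average (tie-corrected) ranks;
#' the two-sided p-value uses the large-sample t approximation with n - 2
#' degrees of freedom. OTUs constant across samples cannot be ranked
#' meaningfully and are excluded (their count is reported via message and
#' the `n_constant_dropped` attribute).
#'
#' @param table Samples x OTUs matrix with at least 5 samples and 2 OTUs.
#' @return data.frame(otu_i, otu_j, rho, p, q), one row per unordered
#'   pair (i < j in column order), with attributes `n_samples` and
#'   `n_constant_dropped`.
#' @export
spearman_correlations <- function(table) {
  assert_otu_table(table)
  n <- nrow(table)
  if (n < 5) stopf("need at least 5 samples for the t approximation (got %d)", n)
  if (ncol(table) < 2) stopf("need at least 2 OTUs")
  constant <- apply(table, 2, function(x) length(unique(x)) == 1)
  if (any(constant))
    message(sum(constant), " constant OTU(s) excluded from correlation")
  x <- table[, !constant, drop = FALSE]
  if (ncol(x) < 2) stopf("fewer than 2 non-constant OTUs")
  ranks <- apply(x, 2, rank)          # average ranks for ties
  C <- stats::cor(ranks)              # Pearson on ranks = Spearman
  iu <- which(upper.tri(C), arr.ind = TRUE)
  rho <- C[iu]
  rho <- pmin(1, pmax(-1, rho))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) == 1] <- 0
  out <- data.frame(otu_i = colnames(x)[iu[, 1]],
                    otu_j = colnames(x)[iu[, 2]],
                    rho = rho, p = p, q = benjamini_hochberg(p),
                    stringsAsFactors = FALSE)
  attr(out, "n_samples") <- n
  attr(out, "n_constant_dropped") <- sum(constant)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns FDR-adjusted q-values in the input order (delegates to
#' [stats::p.adjust()] with method "BH").
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Build the thresholded co-occurrence network
#'
#' Edge rule (both strict): rho > `rho_threshold` (positive correlations
#' only unless `use_absolute`) and q < `q_threshold`. Nodes are the OTUs
#' incident to at least one edge; isolated OTUs are dropped. Each node
#' carries its domain, phylum and mean relative abundance over the scope's
#' samples; each edge carries rho.
#'
#' @param correlations From [spearman_correlations()].
#' @param taxonomy data.frame(otu_id, domain, phylum).
#' @param table The samples x OTUs matrix the correlations came from.
#' @param rho_threshold,q_threshold Strict thresholds.
#' @param use_absolute If TRUE admit edges with |rho| > threshold.
#' @param scope Label recording which samples built the network.
#' @return igraph object with graph attribute `scope`.
#' @export
build_network <- function(correlations, taxonomy, table,
                          rho_threshold = 0.6, q_threshold = 0.01,
                          use_absolute = FALSE, scope = "both") {
  assert_taxonomy(taxonomy)
  stat <- if (use_absolute) abs(correlations$rho) else correlations$rho
  keep <- stat > rho_threshold & correlations$q < q_threshold
  edges <- correlations[keep, , drop = FALSE]
  nodes <- unique(c(edges$otu_i, edges$otu_j))
  missing_tax <- setdiff(nodes, taxonomy$otu_id)
  if (length(missing_tax))
    stopf("taxonomy missing for retained OTU(s): %s",
          paste(utils::head(missing_tax, 5), collapse = ", "))
  tax <- taxonomy[match(nodes, taxonomy$otu_id), ]
  vdf <- data.frame(name = nodes, domain = tax$domain, phylum = tax$phylum,
                    mean_abundance = colMeans(table[, nodes, drop = FALSE]),
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("otu_i", "otu_j", "rho")], directed = FALSE, vertices = vdf)
  g <- igraph::set_graph_attr(g, "scope", scope)
  g <- igraph::set_graph_attr(g, "n_edges_tested", nrow(correlations))
  g
}

#' Louvain module detection
#'
#' Runs seeded Louvain community detection on the unweighted graph,
#' relabels modules as dense integers 1, 2, ... ordered by descending
#' module size, and records the modularity value as graph attribute
#' `modularity`.
#'
#' @param net igraph object (nonempty).
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed (Louvain tie-breaking is randomized).
#' @return The network with vertex attribute `module` and graph
#'   attributes `modularity`, `n_modules`.
#' @export
detect_modules <- function(net, resolution = 1.0, seed = 1L) {
  if (igraph::vcount(net) == 0) stopf("cannot detect modules on an empty graph")
  comm <- local_seed(seed,
    igraph::cluster_louvain(net, weights = NA, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  relabel <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
  memb_dense <- as.integer(relabel[as.character(memb)])
  net <- igraph::set_vertex_attr(net, "module", value = memb_dense)
  net <- igraph::set_graph_attr(net, "modularity",
                                igraph::modularity(net, memb, weights = NULL))
  net <- igraph::set_graph_attr(net, "n_modules", length(sizes))
  net
}

#' Full pipeline: OTU table to modular co-occurrence network
#'
#' Restricts the table to the scope's samples (spring, autumn or both,
#' using the metadata's season column), optionally renormalizes each
#' domain's abundances to sum 1 per sample (the two domains being profiled
#' separately), applies the prevalence filter within the scope, computes
#' Spearman correlations, thresholds, and detects modules.
#'
#' @param table Samples x OTUs matrix.
#' @param taxonomy data.frame(otu_id, domain, phylum).
#' @param metadata Sample metadata (needed when scope is a season).
#' @param scope "spring", "autumn" or "both".
#' @param config A [run_config()].
#' @param renormalize_domains Renormalize within domains before
#'   correlation (default FALSE: use the table as given).
#' @return igraph network with modules assigned.
#' @export
build_cooccurrence_network <- function(table, taxonomy, metadata = NULL,
                                       scope = c("both", "spring", "autumn"),
                                       config = run_config(),
                                       renormalize_domains = FALSE) {
  scope <- match.arg(scope)
  if (scope != "both") {
    if (is.null(metadata)) stopf("metadata required for a seasonal scope")
    keep <- metadata$sample_id[metadata$season == scope]
    table <- table[rownames(table) %in% keep, , drop = FALSE]
    if (nrow(table) == 0) stopf("no samples in scope '%s'", scope)
  }
  if (renormalize_domains) table <- normalize_by_domain(table, taxonomy)
  filtered <- filter_by_prevalence(table, config$prevalence)
  correlations <- spearman_correlations(filtered)
  net <- build_network(correlations, taxonomy, filtered,
                       rho_threshold = config$rho_threshold,
                       q_threshold = config$q_threshold,
                       use_absolute = config$use_absolute, scope = scope)
  if (igraph::vcount(net) == 0) return(net)
  detect_modules(net, seed = config$seed)
}

#' Renormalize abundances within each domain
#'
#' Scales each sample's bacterial abundances to sum 1 and archaeal
#' abundances to sum 1 (domains profiled with separate primer sets are
#' only comparable within-domain). Samples with no nonzero abundance in a
#' domain keep their zeros.
#'
#' @param table Samples x OTUs matrix.
#' @param taxonomy data.frame(otu_id, domain, phylum).
#' @return Renormalized matrix (row sums up to 2: one per domain present).
#' @export
normalize_by_domain <- function(table, taxonomy) {
  assert_otu_table(table)
  assert_taxonomy(taxonomy)
  dom <- taxonomy$domain[match(colnames(table), taxonomy$otu_id)]
  if (anyNA(dom)) stopf("taxonomy missing for OTU(s) in table")
  out <- table
  for (d in unique(dom)) {
    cols <- which(dom == d)
    s <- rowSums(table[, cols, drop = FALSE])
    s[s == 0] <- 1
    out[, cols] <- table[, cols, drop = FALSE] / s
  }
  out
}
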