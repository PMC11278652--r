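# Observed-versus-random (O/R) phylum-pair incidence and keystone taxa.
#
# O is the fraction of the network's edges joining a given phylum pair; R
# is the fraction expected if the same number of edges were placed
# uniformly at random among the network's N nodes, which depends only on
# the phylum node counts: n1*n2/C(N,2) between distinct phyla and
# C(n1,2)/C(N,2) within one. O/R > 1 means the two phyla co-occur more
# than chance.

#' Closed-form O, R and O/R for one phylum pair
#'
#' @param n1,n2 Node counts of the two phyla (equal for an intra-phylum
#'   row).
#' @param N,M Total node and edge counts of the network.
#' @param edge_count Observed edges between the pair.
#' @param intra TRUE for an intra-phylum row.
#' @return List with O, R (percent) and ratio, all unrounded.
#' @export
incidence_from_counts <- function(n1, n2, N, M, edge_count, intra = (n1 == n2)) {
  if (M < 1 || N < 2) stopf("need at least 1 edge and 2 nodes")
  possible <- if (intra) choose(n1, 2) else n1 * n2
  if (possible == 0) stopf("phylum pair has no possible node pair")
  O <- 100 * edge_count / M
  R <- 100 * possible / choose(N, 2)
  list(O = O, R = R, ratio = O / R)
}

#' O/R incidence for every phylum pair of a network
#'
#' One row per unordered phylum pair (including same-phylum rows) with at
#' least one possible node pair; zero-edge pairs are retained with O = 0.
#' Across all rows O sums to 100 and R sums to 100.
#'
#' @param net Co-occurrence network with a `phylum` vertex attribute.
#' @return data.frame(phylum_1, phylum_2, n1, n2, edge_count, O, R,
#'   ratio).
#' @export
phylum_pair_incidence <- function(net) {
  phy <- igraph::V(net)$phylum
  if (is.null(phy) || any(is.na(phy) | !nzchar(phy)))
    stopf("every node needs a phylum label")
  N <- igraph::vcount(net)
  M <- igraph::ecount(net)
  if (N < 2 || M < 1) stopf("need at least 2 nodes and 1 edge")
  counts <- table(phy)
  phyla <- names(counts)

  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  p1 <- phy[ends[, 1]]; p2 <- phy[ends[, 2]]
  key <- paste(pmin(p1, p2), pmax(p1, p2), sep = "\r")
  edge_tab <- table(key)

  rows <- list()
  for (i in seq_along(phyla)) {
    for (j in i:length(phyla)) {
      a <- phyla[i]; b <- phyla[j]
      intra <- a == b
      n1 <- as.integer(counts[a]); n2 <- as.integer(counts[b])
      if (intra && n1 < 2) next   # no possible pair
      k <- paste(min(a, b), max(a, b), sep = "\r")
      e <- if (k %in% names(edge_tab)) as.integer(edge_tab[k]) else 0L
      inc <- incidence_from_counts(n1, n2, N, M, e, intra)
      rows[[length(rows) + 1L]] <-
        data.frame(phylum_1 = a, phylum_2 = b, n1 = n1, n2 = n2,
                   edge_count = e, O = inc$O, R = inc$R, ratio = inc$ratio,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Filter an incidence table for reporting
#'
#' Keeps rows with O > `min_o` percent and O/R > `min_ratio` (both
#' strict); intra-phylum rows are listed first, each block sorted by
#' phylum name.
#'
#' @param rows From [phylum_pair_incidence()].
#' @param min_o,min_ratio Strict report cutoffs (defaults 0.5% and 1).
#' @return Filtered, ordered data.frame.
#' @export
filter_incidence_report <- function(rows, min_o = 0.5, min_ratio = 1) {
  keep <- rows$O > min_o & rows$ratio > min_ratio
  out <- rows[keep, , drop = FALSE]
  intra <- out$phylum_1 == out$phylum_2
  out <- rbind(out[intra, ][order(out$phylum_1[intra]), ],
               out[!intra, ][order(out$phylum_1[!intra], out$phylum_2[!intra]), ])
  rownames(out) <- NULL
  out
}

#' Identify keystone taxa
#'
#' A node is a keystone iff degree > `degree_cutoff` and unnormalized
#' betweenness < `betweenness_cutoff` (both strict). An empty keystone set
#' is a valid result and still yields a full report.
#'
#' @param net Co-occurrence network.
#' @param degree_cutoff,betweenness_cutoff Strict cutoffs (study defaults
#'   100 and 5000; meaningful only at comparable network scale).
#' @return List of class `keystone_report`: `nodes` (per-node degree,
#'   betweenness, keystone flag), `by_phylum` (keystone count and summed
#'   mean relative abundance per phylum), `totals` (keystone count, and
#'   per-domain abundance fractions expressed both of the keystone total
#'   and of the network total).
#' @export
identify_keystones <- function(net, degree_cutoff = 100,
                               betweenness_cutoff = 5000) {
  deg <- igraph::degree(net)
  btw <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  nodes <- data.frame(otu_id = igraph::V(net)$name,
                      domain = igraph::V(net)$domain %||% NA_character_,
                      phylum = igraph::V(net)$phylum %||% NA_character_,
                      mean_abundance = igraph::V(net)$mean_abundance %||% NA_real_,
                      degree = as.integer(deg), betweenness = btw,
                      keystone = deg > degree_cutoff & btw < betweenness_cutoff,
                      stringsAsFactors = FALSE)
  ks <- nodes[nodes$keystone, , drop = FALSE]
  by_phylum <- if (nrow(ks)) {
    agg <- stats::aggregate(
      cbind(n_otus = rep(1L, nrow(ks)), abundance = ks$mean_abundance),
      by = list(domain = ks$domain, phylum = ks$phylum), FUN = sum)
    agg[order(-agg$n_otus), ]
  } else {
    data.frame(domain = character(), phylum = character(),
               n_otus = integer(), abundance = numeric())
  }
  ks_total <- sum(ks$mean_abundance)
  net_total <- sum(nodes$mean_abundance)
  dom_frac <- function(d, denom) {
    if (denom > 0) 100 * sum(ks$mean_abundance[ks$domain == d]) / denom
    else NA_real_
  }
  totals <- list(
    n_keystones = nrow(ks),
    abundance_fraction_of_keystones = c(
      Bacteria = dom_frac("Bacteria", ks_total),
      Archaea = dom_frac("Archaea", ks_total)),
    abundance_fraction_of_network = c(
      Bacteria = dom_frac("Bacteria", net_total),
      Archaea = dom_frac("Archaea", net_total)))
  out <- list(nodes = nodes, by_phylum = by_phylum, totals = totals)
  class(out) <- "keystone_report"
  out
}

#' Percentages of nodes by domain
#'
#' @param net Network with a `domain` vertex attribute.
#' @return Named numeric: bacterial and archaeal node percentages
#'   (summing to 100).
#' @export
node_domain_fractions <- function(net) {
  dom <- igraph::V(net)$domain
  if (is.null(dom) || any(is.na(dom)))
    stopf("every node needs a domain label")
  n <- igraph::vcount(net)
  c(Bacteria = 100 * sum(dom == "Bacteria") / n,
    Archaea = 100 * sum(dom == "Archaea") / n)
}
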