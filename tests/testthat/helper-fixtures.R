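# Shared fixtures and independent oracles for the suite.

# Build a labelled co-occurrence network from an edge data.frame and a
# taxonomy lookup, mimicking build_network() output structure.
make_labelled_net <- function(edges, taxonomy, abundance = NULL) {
  nodes <- unique(c(edges$otu_i, edges$otu_j))
  tax <- taxonomy[match(nodes, taxonomy$otu_id), ]
  if (is.null(abundance)) abundance <- rep(1 / length(nodes), length(nodes))
  vdf <- data.frame(name = nodes, domain = tax$domain, phylum = tax$phylum,
                    mean_abundance = abundance, stringsAsFactors = FALSE)
  if (is.null(edges$rho)) edges$rho <- 0.9
  igraph::graph_from_data_frame(edges[, c("otu_i", "otu_j", "rho")],
                                directed = FALSE, vertices = vdf)
}

simple_taxonomy <- function(otu_ids, phyla, domains = NULL) {
  if (is.null(domains))
    domains <- ifelse(phyla %in% c("Bathyarchaeota", "Euryarchaeota",
                                   "Thaumarchaeota", "YNPFFA"),
                      "Archaea", "Bacteria")
  data.frame(otu_id = otu_ids, domain = domains, phylum = phyla,
             stringsAsFactors = FALSE)
}

# Adjusted Rand index by pair counting (independent of any clustering lib).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Brute-force Newman modularity from an adjacency matrix and a membership
# vector: Q = sum_c (e_c/m - (d_c/2m)^2).
brute_modularity <- function(adj, membership) {
  m <- sum(adj) / 2
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    e_c <- sum(adj[idx, idx]) / 2
    d_c <- sum(adj[idx, ])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# Hand-rolled BFS shortest path (vertex sequence) on an adjacency list;
# independent oracle for betweenness on trees (paths are unique there).
bfs_path <- function(adj, s, t) {
  n <- length(adj)
  parent <- rep(NA_integer_, n)
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v == t) break
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <- TRUE
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  path <- t
  while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
  path
}

# Betweenness of every vertex of a tree by exhaustive pair-path
# enumeration (each unordered pair once; interior vertices credited).
brute_tree_betweenness <- function(edge_mat, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edge_mat))) {
    a <- edge_mat[r, 1]; b <- edge_mat[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      path <- bfs_path(adj, s, t)
      interior <- setdiff(path, c(s, t))
      btw[interior] <- btw[interior] + 1
    }
  }
  btw
}

# Small planted-module dataset used by several recovery tests.
recovery_spec <- function(seed = 11) {
  community_spec(
    n_otus = 100, n_sites = 30, seasons = c("spring", "autumn"),
    module_spec = data.frame(size = rep(25, 3), rho = 0.95),
    zero_inflation = 0, decay_length = 1000, seed = seed)
}
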