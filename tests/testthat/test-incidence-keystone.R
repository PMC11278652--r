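test_that("closed-form O/R reproduces the printed phylum-pair rows", {
  # Both-season network: N = 838 nodes, M = 16309 edges
  bathy <- incidence_from_counts(68, 68, 838, 16309, 1642, intra = TRUE)
  expect_equal(round(bathy$O, 2), 10.07)
  expect_equal(round(bathy$R, 2), 0.65)
  expect_equal(round(bathy$ratio, 2), 15.50)

  ab <- incidence_from_counts(94, 112, 838, 16309, 826, intra = FALSE)
  expect_equal(round(ab$O, 2), 5.06)
  expect_equal(round(ab$R, 2), 3.00)
  expect_equal(round(ab$ratio, 2), 1.69)

  # ratio computed on unrounded O and R: 0.93/0.08 printed, ratio 11.94
  ynp <- incidence_from_counts(68, 4, 838, 16309, 151, intra = FALSE)
  expect_equal(round(ynp$O, 2), 0.93)
  expect_equal(round(ynp$R, 2), 0.08)
  expect_equal(round(ynp$ratio, 2), 11.94)
  expect_false(isTRUE(all.equal(round(0.93 / 0.08, 2), 11.94)))

  # Spring network (N = 971, M = 22394) and autumn (N = 1071, M = 10192)
  sp <- incidence_from_counts(115, 115, 971, 22394, 4240, intra = TRUE)
  expect_equal(round(c(sp$O, sp$R, sp$ratio), 2), c(18.93, 1.39, 13.60))
  au <- incidence_from_counts(63, 63, 1071, 10192, 868, intra = TRUE)
  expect_equal(round(c(au$O, au$R, au$ratio), 2), c(8.52, 0.34, 24.99))
})

test_that("incidence rows sum to 100% in both O and R and match enumeration", {
  for (seed in 1:5) {
    g <- withr::with_seed(seed, igraph::sample_gnm(25, 60))
    phyla <- withr::with_seed(seed + 100,
      sample(c("Pa", "Pb", "Pc"), 25, replace = TRUE))
    g <- igraph::set_vertex_attr(g, "name", value = paste0("o", 1:25))
    g <- igraph::set_vertex_attr(g, "phylum", value = phyla)
    rows <- phylum_pair_incidence(g)
    expect_equal(sum(rows$O), 100, tolerance = 1e-9)
    expect_equal(sum(rows$R), 100, tolerance = 1e-9)
    expect_equal(sum(rows$edge_count), igraph::ecount(g))

    # exhaustive oracle: count edges and possible pairs by brute loops
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    for (r in seq_len(nrow(rows))) {
      ia <- which(phyla == rows$phylum_1[r])
      ib <- which(phyla == rows$phylum_2[r])
      if (rows$phylum_1[r] == rows$phylum_2[r]) {
        cnt <- sum(adj[ia, ib]) / 2
        poss <- choose(length(ia), 2)
      } else {
        cnt <- sum(adj[ia, ib])
        poss <- length(ia) * length(ib)
      }
      expect_equal(rows$edge_count[r], cnt)
      expect_equal(rows$O[r], 100 * cnt / igraph::ecount(g), tolerance = 1e-12)
      expect_equal(rows$R[r], 100 * poss / choose(25, 2), tolerance = 1e-12)
    }
  }
  # degenerate normalization: one phylum only
  g1 <- igraph::make_full_graph(4)
  g1 <- igraph::set_vertex_attr(g1, "name", value = paste0("o", 1:4))
  g1 <- igraph::set_vertex_attr(g1, "phylum", value = rep("P", 4))
  r1 <- phylum_pair_incidence(g1)
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$O, r1$R, r1$ratio), c(100, 100, 1))
})

test_that("under random edge placement the mean O/R ratio is about 1", {
  ratios <- vapply(1:200, function(seed) {
    g <- withr::with_seed(seed, igraph::sample_gnm(30, 120))
    g <- igraph::set_vertex_attr(g, "name", value = paste0("o", 1:30))
    g <- igraph::set_vertex_attr(g, "phylum",
                                 value = rep(c("Pa", "Pb"), each = 15))
    rows <- phylum_pair_incidence(g)
    rows$ratio[rows$phylum_1 == "Pa" & rows$phylum_2 == "Pb"]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("incidence report filter is strict and intra rows come first", {
  rows <- data.frame(
    phylum_1 = c("A", "B", "C", "A", "B"),
    phylum_2 = c("A", "B", "C", "B", "C"),
    n1 = 5, n2 = 5, edge_count = 1,
    O = c(0.50, 5, 0.93, 2, 0.6),
    R = c(0.25, 5.05, 0.0779, 1, 0.3),
    ratio = c(2, 0.99, 11.94, 2, 2))
  out <- filter_incidence_report(rows)
  # O = 0.50 excluded (strict), ratio 0.99 excluded
  expect_equal(nrow(out), 3)
  expect_equal(out$phylum_1, c("C", "A", "B"))
  expect_true(all(out$O > 0.5 & out$ratio > 1))
  intra <- out$phylum_1 == out$phylum_2
  expect_true(all(diff(intra) <= 0))   # intra block first
})

test_that("keystone rule is strictly degree > cutoff and betweenness < cutoff", {
  # star with 101 leaves: center degree 101, betweenness C(101,2) = 5050;
  # leaves degree 1, betweenness 0
  star <- igraph::make_star(102, mode = "undirected")
  star <- igraph::set_vertex_attr(star, "name",
                                  value = paste0("o", 1:102))
  star <- igraph::set_vertex_attr(star, "domain", value = "Bacteria")
  star <- igraph::set_vertex_attr(star, "phylum", value = "Proteobacteria")
  star <- igraph::set_vertex_attr(star, "mean_abundance",
                                  value = rep(1 / 102, 102))
  rep1 <- identify_keystones(star)   # center: degree 101 but betweenness 5050
  expect_equal(rep1$totals$n_keystones, 0)
  rep2 <- identify_keystones(star, betweenness_cutoff = 5051)
  expect_equal(rep2$totals$n_keystones, 1)
  expect_equal(rep2$nodes$otu_id[rep2$nodes$keystone], "o1")
  # degree exactly at the cutoff is not a keystone (strict >)
  rep3 <- identify_keystones(star, degree_cutoff = 101,
                             betweenness_cutoff = 5051)
  expect_equal(rep3$totals$n_keystones, 0)
  # empty result still yields a complete report
  expect_equal(nrow(rep1$nodes), 102)
  expect_equal(nrow(rep1$by_phylum), 0)
})

test_that("keystone report aggregates abundance by phylum and both denominators", {
  tax <- simple_taxonomy(paste0("o", 1:6),
                         c(rep("Proteobacteria", 3), rep("Bathyarchaeota", 3)))
  k6 <- t(utils::combn(paste0("o", 1:6), 2))
  net <- make_labelled_net(data.frame(otu_i = k6[, 1], otu_j = k6[, 2]), tax,
                           abundance = c(.1, .1, .1, .2, .2, .3))
  rep <- identify_keystones(net, degree_cutoff = 4, betweenness_cutoff = 10)
  expect_equal(rep$totals$n_keystones, 6)
  expect_equal(sum(rep$by_phylum$n_otus), 6)
  expect_equal(sum(rep$by_phylum$abundance), 1)
  expect_equal(unname(rep$totals$abundance_fraction_of_keystones["Bacteria"]), 30)
  expect_equal(unname(rep$totals$abundance_fraction_of_network["Archaea"]), 70)
})

test_that("node domain fractions always sum to 100", {
  tax <- simple_taxonomy(paste0("o", 1:4),
                         c(rep("Proteobacteria", 3), "Bathyarchaeota"))
  net <- make_labelled_net(
    data.frame(otu_i = c("o1", "o2", "o3"), otu_j = c("o2", "o3", "o4")), tax)
  fr <- node_domain_fractions(net)
  expect_equal(unname(fr), c(75, 25))
  expect_equal(sum(fr), 100, tolerance = 1e-9)
})
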