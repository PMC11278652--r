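test_that("geodetic distances are haversine on the mean Earth radius", {
  md <- data.frame(sample_id = c("a", "b", "c"),
                   latitude = c(10, 10, 0), longitude = c(20, 20, 0))
  d <- geodetic_distance_matrix(md)
  expect_equal(d["a", "b"], 0)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)

  anti <- data.frame(sample_id = c("a", "b"),
                     latitude = c(0, 0), longitude = c(0, 180))
  da <- geodetic_distance_matrix(anti)
  expect_equal(da["a", "b"], pi * 6371.0088, tolerance = 1e-6)

  miss <- data.frame(sample_id = c("a", "b"),
                     latitude = c(1, NA), longitude = c(1, 2))
  expect_error(geodetic_distance_matrix(miss), "b")
})

test_that("Bray-Curtis distances follow the hand formula and scaling rules", {
  x <- rbind(s1 = c(1, 0), s2 = c(0, 1), s3 = c(1, 0),
             s4 = c(2, 2), s5 = c(1, 1))
  d <- bray_curtis_matrix(x)
  expect_equal(d["s1", "s2"], 1)            # disjoint supports
  expect_equal(d["s1", "s3"], 0)            # identical rows
  expect_equal(d["s4", "s5"], 1 / 3)        # (|2-1|+|2-1|)/(3+3)
  expect_true(all(d >= 0 & d <= 1))

  neg <- rbind(a = c(-1, 5, 3), b = c(1, 7, 3), c = c(0, 6, 3))
  expect_error(bray_curtis_matrix(neg), "nonnegative")
  ds <- bray_curtis_matrix(neg, scale_features = TRUE)  # constant col dropped
  expect_equal(dim(ds), c(3, 3))
  expect_equal(ds["a", "a"], 0)

  zz <- rbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_warning(dz <- bray_curtis_matrix(zz), "all-zero")
  expect_equal(dz["a", "b"], 0)
})

test_that("Mantel statistic matches vegan and behaves on identities", {
  md <- data.frame(sample_id = paste0("s", 1:12),
                   latitude = seq(30, 33, length.out = 12),
                   longitude = seq(100, 110, length.out = 12))
  geo <- geodetic_distance_matrix(md)
  self <- mantel_test(geo, geo, n_permutations = 199, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 200)             # minimal attainable p

  mono <- mantel_test(geo, sqrt(geo), n_permutations = 99, seed = 1)
  expect_equal(mono$r, 1)                   # Spearman invariance

  other <- withr::with_seed(2, {
    m <- matrix(stats::runif(144), 12, 12); m <- m + t(m); diag(m) <- 0
    dimnames(m) <- list(md$sample_id, md$sample_id); m
  })
  ours <- mantel_test(geo, other, n_permutations = 199, seed = 3)
  veg <- vegan::mantel(stats::as.dist(geo), stats::as.dist(other),
                       method = "spearman", permutations = 199)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-12)

  bad <- other; rownames(bad) <- colnames(bad) <- rev(md$sample_id)
  expect_error(mantel_test(geo, bad), "mismatched")
})

test_that("Mantel type-I error is calibrated at alpha = 0.05", {
  n <- 15
  rejections <- sum(vapply(1:50, function(seed) {
    withr::with_seed(seed + 500, {
      a <- matrix(stats::runif(n * n), n, n); a <- a + t(a); diag(a) <- 0
      b <- matrix(stats::runif(n * n), n, n); b <- b + t(b); diag(b) <- 0
      mantel_test(a, b, n_permutations = 199, seed = seed)$p <= 0.05
    })
  }, logical(1)))
  # 95% binomial acceptance band for Binom(50, 0.05)
  expect_lte(rejections, stats::qbinom(0.975, 50, 0.05) + 1)
})

test_that("distance-decay: slope semantics and spatial-scale ordering", {
  md <- data.frame(sample_id = paste0("s", 1:10),
                   latitude = rep(30, 10),
                   longitude = seq(100, 109, length.out = 10))
  geo <- geodetic_distance_matrix(md)
  flat <- matrix(0.4, 10, 10); diag(flat) <- 0
  dimnames(flat) <- list(md$sample_id, md$sample_id)
  expect_warning(dd <- distance_decay_fit(geo, flat, n_permutations = 99,
                                          seed = 1), "constant")
  expect_equal(dd$slope, 0, tolerance = 1e-12)
  expect_true(is.na(dd$mantel$r))

  comm <- withr::with_seed(4, {
    m <- matrix(stats::runif(100, 0.2, 0.8), 10, 10)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(md$sample_id, md$sample_id); m
  })
  d1 <- distance_decay_fit(geo, comm, n_permutations = 9, seed = 1)
  d2 <- distance_decay_fit(2 * geo, comm, n_permutations = 9, seed = 1)
  expect_equal(d2$slope, d1$slope / 2, tolerance = 1e-12)

  # strong spatial autocorrelation (short decay length) -> steeper negative
  # decay of community similarity than near-flat autocorrelation; a 600 km
  # reach with 25 sites spaces samples 25 km apart, resolving both scales
  slopes <- vapply(c(50, 5000), function(dl) {
    spec <- community_spec(n_otus = 80, n_sites = 25, river_length = 600,
                           module_spec = data.frame(size = rep(20, 3),
                                                    rho = 0.9),
                           zero_inflation = 0, decay_length = dl, seed = 13)
    ds <- simulate_community(spec)
    sp <- ds$metadata[ds$metadata$season == "spring", ]
    g <- geodetic_distance_matrix(sp)
    bc <- bray_curtis_matrix(ds$table[sp$sample_id, ])
    fit <- distance_decay_fit(g, bc, n_permutations = 199, seed = 2)
    if (dl == 50) expect_lte(fit$mantel$p, 0.05)
    fit$slope
  }, numeric(1))
  expect_lt(slopes[1], 0)
  expect_gt(abs(slopes[1]), abs(slopes[2]))
})

test_that("environment-network correlation table: identities and null level", {
  spec <- community_spec(n_otus = 40, n_sites = 20,
                         module_spec = data.frame(size = c(15, 15),
                                                  rho = 0.9),
                         zero_inflation = 0, seed = 6)
  ds <- simulate_community(spec)
  net <- build_cooccurrence_network(ds$table, ds$taxonomy, ds$metadata,
                                    scope = "both")
  mods <- module_total_abundance(net, ds$table)
  # audited identity: module total = sum of member abundances
  m1_members <- igraph::V(net)$name[igraph::V(net)$module == 1]
  expect_equal(mods[, "module_1"],
               rowSums(ds$table[, m1_members, drop = FALSE]))

  resp <- cbind(mods, WT_copy = ds$metadata$WT)
  tabres <- env_network_correlations(ds$metadata, resp)
  wt_row <- tabres[tabres$env == "WT" & tabres$response == "WT_copy", ]
  expect_equal(wt_row$rho, 1)

  # shuffled factor: raw p < alpha at about the nominal rate
  hits <- unlist(lapply(1:20, function(seed) {
    md2 <- ds$metadata
    md2$WT <- withr::with_seed(seed, sample(md2$WT))
    t2 <- env_network_correlations(md2, mods, env_factors = "WT")
    t2$p < 0.05
  }))
  expect_lte(sum(hits), stats::qbinom(0.995, length(hits), 0.05) + 1)

  cst <- ds$metadata; cst$WT <- 5
  t3 <- env_network_correlations(cst, mods, env_factors = "WT")
  expect_true(all(is.na(t3$rho)))
})

test_that("db-RDA agrees with capscale eigenvalues and finds a planted gradient", {
  spec <- community_spec(n_otus = 60, n_sites = 20,
                         module_spec = data.frame(size = c(20, 20),
                                                  rho = 0.9),
                         zero_inflation = 0, decay_length = 500, seed = 10)
  ds <- simulate_community(spec)
  md <- ds$metadata[ds$metadata$season == "spring", ]
  tab <- ds$table[md$sample_id, ]
  # plant a gradient: composition turns over strongly along WT
  drive <- scale(md$WT)[, 1]
  tab[, 1:20] <- tab[, 1:20] * exp(outer(drive, rep(2.5, 20)))
  tab[, 21:40] <- tab[, 21:40] * exp(outer(-drive, rep(2.5, 20)))
  tab <- tab / rowSums(tab)
  facs <- c("WT", "pH", "TN", "Fe")
  res <- db_rda(tab, md, env_factors = facs, n_permutations = 399, seed = 5)
  expect_true(all(res$axis_percent >= 0 & res$axis_percent <= 100))
  expect_lte(res$r_squared, 1)
  best <- res$factors$factor[which.max(res$factors$adj_r2)]
  expect_equal(best, "WT")
  expect_lte(res$factors$p[res$factors$factor == "WT"], 0.005)

  # independent oracle: constrained eigenvalues equal vegan::capscale's
  bc <- bray_curtis_matrix(tab)
  cs <- vegan::capscale(stats::as.dist(bc) ~ WT + pH + TN + Fe, data = md)
  k <- length(res$constrained_eigenvalues)
  expect_equal(res$constrained_eigenvalues, unname(cs$CCA$eig[1:k]),
               tolerance = 1e-8)

  # relabelling invariance: same permutation of both inputs
  idx <- withr::with_seed(1, sample(nrow(tab)))
  res2 <- db_rda(tab[idx, ], md[idx, ], env_factors = facs,
                 n_permutations = 9, seed = 5)
  expect_equal(res2$constrained_eigenvalues, res$constrained_eigenvalues,
               tolerance = 1e-8)
  expect_equal(res2$factors$r2, res$factors$r2, tolerance = 1e-8)

  # collinear constraints are refused
  md$WT2 <- md$WT
  expect_error(db_rda(tab, md, env_factors = c("WT", "WT2", "pH"),
                      n_permutations = 9), "collinear")
})

test_that("a pure-noise constraint has adjusted R-squared near zero", {
  adj <- vapply(1:8, function(seed) {
    spec <- community_spec(n_otus = 40, n_sites = 16,
                           module_spec = data.frame(size = 20, rho = 0.8),
                           zero_inflation = 0, seed = seed + 40)
    ds <- simulate_community(spec)
    md <- ds$metadata[ds$metadata$season == "spring", ]
    md$noise <- withr::with_seed(seed, stats::rnorm(nrow(md)))
    tab <- ds$table[md$sample_id, ]
    res <- db_rda(tab, md, env_factors = c("noise", "pH"),
                  n_permutations = 99, seed = seed)
    res$factors$adj_r2[res$factors$factor == "noise"]
  }, numeric(1))
  expect_lt(abs(mean(adj)), 0.02)
})
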