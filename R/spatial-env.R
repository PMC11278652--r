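# Distance-decay (Mantel), environment-network correlation table, and
# distance-based redundancy analysis (db-RDA) on network-member
# communities.

#' Geodetic (great-circle) distance matrix in km
#'
#' Haversine distances on a sphere of radius 6371.0088 km. The Mantel
#' statistics downstream are Spearman-based and therefore invariant to
#' any monotone transform of distance, so the choice of geodetic model
#' does not affect them.
#'
#' @param metadata Sample metadata with latitude/longitude columns.
#' @return Symmetric matrix (km) with sample ids as dimnames and
#'   attribute `metric = "geodetic-km"`.
#' @export
geodetic_distance_matrix <- function(metadata) {
  miss <- is.na(metadata$latitude) | is.na(metadata$longitude)
  if (any(miss))
    stopf("missing coordinates for sample(s): %s",
          paste(metadata$sample_id[miss], collapse = ", "))
  pts <- cbind(metadata$longitude, metadata$latitude)
  d <- geosphere::distm(pts, fun = geosphere::distHaversine)
  d <- d * (6371.0088 / 6378.137) / 1000   # rescale default radius, m -> km
  dimnames(d) <- list(metadata$sample_id, metadata$sample_id)
  attr(d, "metric") <- "geodetic-km"
  d
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(a, b) = sum|a_i - b_i| / sum(a_i + b_i). With
#' `scale_features = TRUE` (for matrices containing negative-valued
#' features such as assortativity) each column is min-max scaled to
#' `[0, 1]` first and constant columns are dropped. A pair of all-zero
#' rows gets distance 0 with a warning.
#'
#' @param x Samples x features matrix (nonnegative unless scaling).
#' @param scale_features Min-max scale columns first.
#' @return Symmetric matrix in `[0, 1]` with attribute
#'   `metric = "bray-curtis"`.
#' @export
bray_curtis_matrix <- function(x, scale_features = FALSE) {
  x <- as.matrix(x)
  if (scale_features) {
    rng <- apply(x, 2, range, na.rm = TRUE)
    keep <- rng[2, ] > rng[1, ]
    x <- x[, keep, drop = FALSE]
    x <- sweep(sweep(x, 2, rng[1, keep], "-"), 2,
               rng[2, keep] - rng[1, keep], "/")
  } else if (any(x < 0, na.rm = TRUE)) {
    stopf("Bray-Curtis needs nonnegative values; use scale_features = TRUE")
  }
  d <- as.matrix(suppressWarnings(vegan::vegdist(x, method = "bray")))
  if (any(is.nan(d))) {
    warning("all-zero sample pair(s); their Bray-Curtis distance set to 0")
    d[is.nan(d)] <- 0
  }
  attr(d, "metric") <- "bray-curtis"
  d
}

triangle <- function(m) m[upper.tri(m)]

#' Mantel test (Spearman statistic, permutation p-value)
#'
#' r is the Spearman correlation of the two matrices' upper triangles;
#' the null distribution comes from simultaneous row/column permutations
#' of the second matrix. One-sided (positive association):
#' p = (#{r_perm >= r_obs} + 1) / (n_permutations + 1).
#'
#' @param dA,dB Aligned square distance matrices.
#' @param n_permutations Number of permutations (study default 999).
#' @param seed Integer seed.
#' @return List of class `mantel_result`: r, p, n_permutations.
#' @export
mantel_test <- function(dA, dB, n_permutations = 999, seed = 1L) {
  dA <- as.matrix(dA); dB <- as.matrix(dB)
  if (!identical(dim(dA), dim(dB)))
    stopf("distance matrices have different sizes")
  if (!is.null(rownames(dA)) && !is.null(rownames(dB)) &&
      !identical(rownames(dA), rownames(dB)))
    stopf("distance matrices have mismatched sample ids")
  n <- nrow(dA)
  if (n < 5) stopf("need at least 5 samples")
  a <- rank(triangle(dA))
  b <- rank(triangle(dB))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant distance matrix: Mantel statistic undefined")
    out <- list(r = NA_real_, p = NA_real_, n_permutations = n_permutations)
    class(out) <- "mantel_result"
    return(out)
  }
  r_obs <- stats::cor(a, b)
  r_perm <- local_seed(seed, vapply(seq_len(n_permutations), function(i) {
    idx <- sample.int(n)
    stats::cor(a, rank(triangle(dB[idx, idx])))
  }, numeric(1)))
  p <- (sum(r_perm >= r_obs) + 1) / (n_permutations + 1)
  out <- list(r = r_obs, p = p, n_permutations = n_permutations)
  class(out) <- "mantel_result"
  out
}

#' Distance-decay fit
#'
#' OLS of Bray-Curtis similarity (1 - dissimilarity) on geodetic distance
#' over all sample pairs, with the Mantel test of the two matrices
#' attached. A negative slope is the distance-decay signal.
#'
#' @param geo Geodetic distance matrix (km).
#' @param community Bray-Curtis dissimilarity matrix (community or
#'   topology-feature based).
#' @param n_permutations,seed Passed to [mantel_test()].
#' @return List of class `distance_decay`: slope (per km), intercept,
#'   mantel.
#' @export
distance_decay_fit <- function(geo, community, n_permutations = 999,
                               seed = 1L) {
  x <- triangle(as.matrix(geo))
  y <- 1 - triangle(as.matrix(community))
  if (length(unique(x)) < 3) stopf("need at least 3 distinct pairs")
  fit <- stats::lm(y ~ x)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              mantel = mantel_test(geo, community,
                                   n_permutations = n_permutations,
                                   seed = seed))
  class(out) <- "distance_decay"
  out
}

#' Per-sample total abundance of each network module
#'
#' @param net Network with `module` vertex attribute.
#' @param table Samples x OTUs matrix.
#' @return Matrix samples x modules of summed member abundances.
#' @export
module_total_abundance <- function(net, table) {
  mod <- igraph::V(net)$module
  if (is.null(mod)) stopf("network has no module assignment; run detect_modules()")
  ids <- igraph::V(net)$name
  mods <- sort(unique(mod))
  out <- sapply(mods, function(m) {
    members <- intersect(ids[mod == m], colnames(table))
    rowSums(table[, members, drop = FALSE])
  })
  colnames(out) <- sprintf("module_%d", mods)
  out
}

#' Spearman correlations between environmental factors and network
#' properties
#'
#' For every environmental factor and every response column (module total
#' abundances and/or per-sample topology features): pairwise-complete
#' Spearman rho and p, BH-adjusted q over the whole table, and the
#' fraction of significant cells (q below `alpha`). Constant factors get
#' missing rho.
#'
#' @param metadata Sample metadata holding the env factor columns.
#' @param responses Samples x responses numeric matrix/data.frame aligned
#'   with `metadata` rows (e.g. cbind of [module_total_abundance()] and
#'   feature columns of [per_sample_topology()]).
#' @param env_factors Which metadata columns to use.
#' @param alpha Significance level on q for the summary fraction.
#' @return data.frame(env, response, rho, p, q, significant) with
#'   attribute `significant_fraction`.
#' @export
env_network_correlations <- function(metadata, responses,
                                     env_factors = intersect(ENV_FACTORS,
                                                             names(metadata)),
                                     alpha = 0.05) {
  responses <- as.data.frame(responses)
  if (nrow(responses) != nrow(metadata))
    stopf("metadata and responses have different row counts")
  rows <- list()
  for (e in env_factors) {
    xe <- metadata[[e]]
    for (r in names(responses)) {
      yr <- responses[[r]]
      ok <- stats::complete.cases(xe, yr)
      if (sum(ok) < 5 || length(unique(xe[ok])) == 1 ||
          length(unique(yr[ok])) == 1) {
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(
          stats::cor.test(xe[ok], yr[ok], method = "spearman"))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      rows[[length(rows) + 1L]] <-
        data.frame(env = e, response = r, rho = rho, p = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- benjamini_hochberg(out$p[ok])
  out$significant <- !is.na(out$q) & out$q < alpha
  attr(out, "significant_fraction") <-
    if (any(ok)) mean(out$significant[ok]) else NA_real_
  out
}

#' Distance-based redundancy analysis (db-RDA)
#'
#' Bray-Curtis dissimilarities -> principal-coordinates decomposition
#' (axes with negative eigenvalues dropped) -> redundancy analysis of the
#' coordinates on standardized environmental factors. Axis variance
#' explained is each constrained eigenvalue as a fraction of the total
#' retained (real) inertia. Per-factor marginal tests fit one constraint
#' at a time: R^2, permutation p, and the permutation-adjusted
#' R^2 = 1 - (1 - R^2) / (1 - mean(R^2_perm)).
#'
#' @param community Samples x OTUs matrix (typically restricted to
#'   network-member OTUs).
#' @param env Sample metadata aligned with the community rows.
#' @param env_factors Metadata columns to use as constraints.
#' @param n_permutations Permutations for the marginal tests.
#' @param seed Integer seed.
#' @return List of class `db_rda_result`: `axis_percent` (variance
#'   explained by constrained axes 1, 2, ...), `constrained_eigenvalues`,
#'   `total_inertia`, `r_squared` (full model), `factors`
#'   (data.frame(factor, r2, adj_r2, p)), `site_scores` (samples x first
#'   two constrained axes).
#' @export
db_rda <- function(community, env,
                   env_factors = intersect(ENV_FACTORS, names(env)),
                   n_permutations = 999, seed = 1L) {
  if (length(env_factors) < 2) stopf("need at least 2 environmental factors")
  X0 <- as.matrix(env[, env_factors, drop = FALSE])
  ok <- stats::complete.cases(X0)       # listwise deletion for ordination
  X0 <- X0[ok, , drop = FALSE]
  community <- community[ok, , drop = FALSE]
  n <- nrow(community)
  if (n <= length(env_factors) + 2)
    stopf("need more samples (%d) than factors + 2 (%d)",
          n, length(env_factors) + 2)
  X <- scale(X0)
  kap <- kappa(crossprod(X) / (n - 1), exact = TRUE)
  if (!is.finite(kap) || kap > 1e8)
    stopf("collinear environmental factors (condition number %.3g): %s",
          kap, paste(env_factors, collapse = ", "))

  D <- bray_curtis_matrix(community)
  # Gower-centered double-centering, classical PCoA
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-10
  pos <- eg$values > tol
  Y <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]),
                                                sum(pos))
  total_inertia <- sum(eg$values[pos])

  constrained_ss <- function(Xc, Yc) {
    qrx <- qr(Xc)
    Yhat <- qr.fitted(qrx, Yc)
    ev <- eigen(crossprod(Yhat), symmetric = TRUE, only.values = FALSE)
    keep <- ev$values > max(ev$values, 0) * 1e-10
    list(eigenvalues = ev$values[keep],
         vectors = ev$vectors[, keep, drop = FALSE], Yhat = Yhat)
  }

  full <- constrained_ss(X, Y)
  axis_percent <- 100 * full$eigenvalues / total_inertia
  r2_full <- sum(full$eigenvalues) / total_inertia
  site_scores <- full$Yhat %*% full$vectors[, seq_len(min(2, ncol(full$vectors))),
                                            drop = FALSE]
  rownames(site_scores) <- rownames(community)

  marginal <- local_seed(seed, {
    lapply(env_factors, function(f) {
      Xf <- X[, f, drop = FALSE]
      r2 <- sum(constrained_ss(Xf, Y)$eigenvalues) / total_inertia
      r2_perm <- vapply(seq_len(n_permutations), function(i) {
        sum(constrained_ss(Xf[sample.int(n), , drop = FALSE],
                           Y)$eigenvalues) / total_inertia
      }, numeric(1))
      data.frame(factor = f, r2 = r2,
                 adj_r2 = 1 - (1 - r2) / (1 - mean(r2_perm)),
                 p = (sum(r2_perm >= r2) + 1) / (n_permutations + 1),
                 stringsAsFactors = FALSE)
    })
  })
  out <- list(axis_percent = axis_percent,
              constrained_eigenvalues = full$eigenvalues,
              total_inertia = total_inertia, r_squared = r2_full,
              factors = do.call(rbind, marginal),
              site_scores = site_scores)
  class(out) <- "db_rda_result"
  out
}

#' Restrict an OTU table to a network's member OTUs
#'
#' @param net Co-occurrence network.
#' @param table Samples x OTUs matrix.
#' @return The matrix restricted to columns that are network nodes.
#' @export
network_member_table <- function(net, table) {
  members <- intersect(colnames(table), igraph::V(net)$name)
  if (!length(members)) stopf("no network OTUs found in the table")
  table[, members, drop = FALSE]
}
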