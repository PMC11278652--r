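# Erdos-Renyi null ensembles, the small-world coefficient, and
# degree-distribution model comparison (power law vs Gaussian).

#' Sample an Erdos-Renyi G(n, m) ensemble and summarize it
#'
#' Each replicate is a uniform simple graph with exactly `n_edges` edges.
#' Per replicate: CC, the mean local clustering coefficient (nodes of
#' degree < 2 contribute 0); APL, the mean shortest-path length over
#' connected pairs; MD, Louvain modularity (seeded). The summary reports
#' ensemble means and standard deviations.
#'
#' @param n_nodes,n_edges Graph size; `n_edges` at most choose(n_nodes, 2).
#' @param n_graphs Ensemble size (the study used 1000).
#' @param seed Integer seed.
#' @return List of class `null_summary`: n_graphs, CCr, APLr, MDr and
#'   their SDs (`*_sd`). With zero edges APLr is NA (undefined, not 0).
#' @export
sample_er_ensemble <- function(n_nodes, n_edges, n_graphs = 1000, seed = 1L) {
  max_edges <- choose(n_nodes, 2)
  if (n_edges < 0 || n_edges > max_edges)
    stopf("n_edges = %d outside [0, %d]", n_edges, max_edges)
  if (n_graphs < 1) stopf("need at least one replicate")
  res <- local_seed(seed, {
    vapply(seq_len(n_graphs), function(i) {
      g <- igraph::sample_gnm(n_nodes, n_edges)
      cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
      if (is.nan(cc)) cc <- 0
      apl <- if (n_edges == 0) NA_real_ else
        igraph::mean_distance(g, unconnected = TRUE)
      md <- if (n_edges == 0) NA_real_ else
        igraph::modularity(igraph::cluster_louvain(g, weights = NA))
      c(cc = cc, apl = apl, md = md)
    }, numeric(3))
  })
  out <- list(n_graphs = n_graphs, n_nodes = n_nodes, n_edges = n_edges,
              CCr = mean(res["cc", ]), CCr_sd = stats::sd(res["cc", ]),
              APLr = mean(res["apl", ]), APLr_sd = stats::sd(res["apl", ]),
              MDr = mean(res["md", ]), MDr_sd = stats::sd(res["md", ]))
  class(out) <- "null_summary"
  out
}

#' Small-world coefficient
#'
#' sigma = (CC / CCr) / (APL / APLr): clustering relative to an equal-size
#' Erdos-Renyi ensemble over path length relative to the same ensemble.
#' sigma >> 1 indicates small-world structure.
#'
#' @param CC,APL Observed mean local clustering and average path length.
#' @param CCr,APLr Ensemble means of the same quantities.
#' @return The coefficient sigma.
#' @export
small_world_sigma <- function(CC, CCr, APL, APLr) {
  vals <- c(CC = CC, CCr = CCr, APL = APL, APLr = APLr)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all of CC, CCr, APL, APLr must be positive and finite")
  (CC / CCr) / (APL / APLr)
}

#' Degree histogram
#'
#' Observed degrees with their frequency counts and probabilities;
#' degrees with zero frequency are omitted.
#'
#' @param net igraph object (nonempty).
#' @return data.frame(degree, count, prob) with probs summing to 1.
#' @export
degree_histogram <- function(net) {
  if (igraph::vcount(net) == 0) stopf("empty graph has no degree distribution")
  k <- igraph::degree(net)
  tab <- table(k)
  data.frame(degree = as.integer(names(tab)),
             count = as.integer(tab),
             prob = as.vector(tab) / length(k))
}

#' Fit a degree-distribution model
#'
#' Nonlinear least squares of P(k) against a * k^(-gamma) (power law) or
#' A * exp(-(k - mu)^2 / (2 s^2)) (Gaussian), on raw probabilities so the
#' two models' adjusted R^2 are directly comparable. Power-law starting
#' values come from log-log OLS, Gaussian from histogram moments; on
#' non-convergence a small restart grid is tried and failure is reported
#' as a flagged fit with missing R^2.
#'
#' @param hist data.frame(degree, prob) from [degree_histogram()].
#' @param model "power_law" or "gaussian".
#' @return List of class `degree_fit`: model, parameters, r_squared,
#'   adj_r_squared (1 - (1 - R^2)(n - 1)/(n - p - 1)), n_points,
#'   converged.
#' @export
fit_degree_distribution <- function(hist, model = c("power_law", "gaussian")) {
  model <- match.arg(model)
  hist <- hist[hist$prob > 0 & hist$degree > 0, , drop = FALSE]
  n <- nrow(hist)
  n_par <- if (model == "power_law") 2L else 3L
  if (n < n_par + 2L)
    stopf("need at least %d distinct degrees for a %s fit (got %d)",
          n_par + 2L, model, n)
  k <- hist$degree
  p <- hist$prob

  if (model == "power_law") {
    ols <- stats::lm(log(p) ~ log(k))
    starts <- list(c(a = exp(stats::coef(ols)[[1]]),
                     gamma = -stats::coef(ols)[[2]]))
    starts <- c(starts, list(c(a = max(p), gamma = 1),
                             c(a = max(p), gamma = 2),
                             c(a = max(p) * mean(k), gamma = 3)))
    form <- p ~ a * k^(-gamma)
  } else {
    mu0 <- sum(k * p) / sum(p)
    s0 <- sqrt(max(sum((k - mu0)^2 * p) / sum(p), 1e-6))
    starts <- list(c(A = max(p), mu = mu0, s = s0),
                   c(A = max(p), mu = mu0, s = s0 * 2),
                   c(A = max(p) * 2, mu = mean(k), s = stats::sd(k)))
    form <- p ~ A * exp(-(k - mu)^2 / (2 * s^2))
  }

  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(k = k, p = p),
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    out <- list(model = model, parameters = NULL, r_squared = NA_real_,
                adj_r_squared = NA_real_, n_points = n, converged = FALSE)
    class(out) <- "degree_fit"
    return(out)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((p - mean(p))^2)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - n_par - 1)
  out <- list(model = model, parameters = stats::coef(fit), r_squared = r2,
              adj_r_squared = adj, n_points = n, converged = TRUE)
  class(out) <- "degree_fit"
  out
}
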