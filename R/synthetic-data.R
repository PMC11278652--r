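# Synthetic community generator. Emulates the study design the downstream
# analysis assumes: ~59 sites sampled in two seasons along a single river
# axis, two prokaryotic domains with phylum labels, block-correlated OTU
# groups (planted modules) with spatially autocorrelated latent factors,
# and season/terrain-structured environmental covariates.

#' Default phylum profile
#'
#' Phylum-level composition loosely shaped like a large-river prokaryotic
#' community: dominant Proteobacteria/Actinobacteria/Bacteroidetes among
#' bacteria, Bathyarchaeota/Euryarchaeota/Thaumarchaeota among archaea,
#' with bacteria about 2/3 of OTUs.
#'
#' @return data.frame with columns phylum, domain, fraction (sums to 1).
#' @export
default_phylum_profile <- function() {
  data.frame(
    phylum = c("Proteobacteria", "Actinobacteria", "Bacteroidetes",
               "Cyanobacteria", "Planctomycetes", "Chloroflexi",
               "Verrucomicrobia", "Gemmatimonadetes", "Acidobacteria",
               "Nitrospirae",
               "Bathyarchaeota", "Euryarchaeota", "Thaumarchaeota",
               "Woesearchaeota", "YNPFFA", "Lokiarchaeota"),
    domain = c(rep("Bacteria", 10), rep("Archaea", 6)),
    fraction = c(0.24, 0.11, 0.13, 0.05, 0.04, 0.02, 0.02, 0.01, 0.03, 0.01,
                 0.10, 0.12, 0.08, 0.02, 0.01, 0.01),
    stringsAsFactors = FALSE)
}

#' Default environmental-effect table
#'
#' Per factor: baseline level, additive autumn offset (seasonal contrast;
#' e.g. water temperature about +10.6 degC in autumn, ammonium and the
#' metals Ca/Fe/Al/Ni elevated in spring), linear along-river gradient from
#' source (0) to mouth (1), and Gaussian noise SD. Units: WT degC, pH
#' unitless, nutrients and metals mg/L.
#'
#' @return data.frame with columns factor, baseline, autumn_offset,
#'   gradient, noise_sd.
#' @export
default_env_effects <- function() {
  data.frame(
    factor = ENV_FACTORS,
    baseline = c(11.14, 8.2, 2.0, 0.25, 1.0, 1.2, 0.04, 48, 0.45, 0.35,
                 0.004, 0.0002),
    autumn_offset = c(10.57, 0, 0.3, -0.10, 0.1, 0.1, 0.01, -8, -0.15,
                      -0.12, -0.0015, 0),
    gradient = c(2.5, -0.35, 1.2, 0.20, 0.9, 1.1, 0.05, -12, 0.10, 0.15,
                 0.001, 0.0001),
    noise_sd = c(1.1, 0.12, 0.35, 0.05, 0.2, 0.25, 0.01, 4, 0.08, 0.06,
                 0.0008, 0.00005),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic river community
#'
#' @param n_otus Number of OTUs.
#' @param n_sites Number of sampling sites along the river.
#' @param seasons Season labels; each site is sampled once per season.
#' @param phylum_profile data.frame(phylum, domain, fraction); fractions
#'   must sum to 1.
#' @param module_spec data.frame(size, rho) giving member OTU count and
#'   intra-module latent correlation (in `[0,1]`) for each planted module.
#' @param zero_inflation Probability that an abundance cell is masked to an
#'   exact zero before row closure.
#' @param decay_length Spatial autocorrelation scale (km) of the latent
#'   module factors along the river.
#' @param river_length Total river length in km.
#' @param env_effects data.frame as [default_env_effects()].
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   spec including this seed.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_otus = 600, n_sites = 59,
                           seasons = c("spring", "autumn"),
                           phylum_profile = default_phylum_profile(),
                           module_spec = data.frame(size = rep(45, 8),
                                                    rho = 0.90),
                           zero_inflation = 0.20, decay_length = 1000,
                           river_length = 6000,
                           env_effects = default_env_effects(),
                           seed = 1L) {
  if (nrow(phylum_profile) == 0) stopf("phylum_profile must not be empty")
  if (abs(sum(phylum_profile$fraction) - 1) > 1e-9)
    stopf("phylum fractions must sum to 1 (got %.12f)", sum(phylum_profile$fraction))
  if (!all(phylum_profile$domain %in% DOMAINS))
    stopf("phylum_profile domains must be Bacteria or Archaea")
  if (sum(module_spec$size) > n_otus)
    stopf("module sizes sum to %d > n_otus = %d", sum(module_spec$size), n_otus)
  if (any(module_spec$rho < 0 | module_spec$rho > 1))
    stopf("intra-module correlation must lie in [0, 1]")
  if (zero_inflation < 0 || zero_inflation >= 1)
    stopf("zero_inflation must lie in [0, 1)")
  if (decay_length <= 0) stopf("decay_length must be positive")
  if (n_sites < 2) stopf("need at least 2 sites")
  spec <- list(n_otus = n_otus, n_sites = n_sites, seasons = seasons,
               phylum_profile = phylum_profile, module_spec = module_spec,
               zero_inflation = zero_inflation, decay_length = decay_length,
               river_length = river_length, env_effects = env_effects,
               seed = as.integer(seed))
  class(spec) <- "community_spec"
  spec
}

#' Assign taxonomy to synthetic OTUs
#'
#' Each OTU draws its phylum (and hence domain) from the multinomial
#' defined by the spec's phylum profile. Deterministic under the spec seed.
#'
#' @param spec A [community_spec()].
#' @return data.frame(otu_id, domain, phylum).
#' @export
generate_taxonomy <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  prof <- spec$phylum_profile
  local_seed(spec$seed + 1L, {
    idx <- sample.int(nrow(prof), spec$n_otus, replace = TRUE,
                      prob = prof$fraction)
    data.frame(otu_id = sprintf("OTU%04d", seq_len(spec$n_otus)),
               domain = prof$domain[idx], phylum = prof$phylum[idx],
               stringsAsFactors = FALSE)
  })
}

#' Generate site and sample metadata
#'
#' Sites are placed evenly along a 1-D river coordinate from source to
#' mouth; latitude/longitude are mapped monotonically along the axis so the
#' geodetic distance between the endpoints is the largest in the matrix.
#' Landform follows river position (plateau, mountain/hill, basin, plain),
#' region splits into source (upper reach) and non-source. Each
#' environmental factor is baseline + seasonal offset + terrain gradient +
#' Gaussian noise.
#'
#' @param spec A [community_spec()].
#' @return data.frame with one row per sample (site x season).
#' @export
generate_metadata <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  if (spec$n_sites < 2) stopf("need at least 2 sites")
  ns <- spec$n_sites
  pos <- seq(0, spec$river_length, length.out = ns)   # km along river
  frac <- pos / spec$river_length
  # Monotone geographic embedding roughly spanning the river's extent.
  lon <- 91 + 30 * frac
  lat <- 33 - 2 * frac
  elevation <- 5200 * exp(-3 * frac)
  landform <- cut(frac, breaks = c(-Inf, 0.06, 0.45, 0.65, Inf),
                  labels = LANDFORMS)
  region <- ifelse(frac <= 0.20, "source", "non-source")
  eff <- spec$env_effects
  local_seed(spec$seed + 2L, {
    rows <- list()
    for (season in spec$seasons) {
      env <- sapply(seq_len(nrow(eff)), function(i) {
        eff$baseline[i] +
          eff$autumn_offset[i] * (season == "autumn") +
          eff$gradient[i] * frac +
          stats::rnorm(ns, 0, eff$noise_sd[i])
      })
      colnames(env) <- eff$factor
      rows[[season]] <- data.frame(
        sample_id = sprintf("S%02d_%s", seq_len(ns), season),
        site_no = seq_len(ns), season = season,
        latitude = lat, longitude = lon, elevation = elevation,
        river_km = pos,
        landform = as.character(landform), region = region,
        env, check.names = FALSE, stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
}

# Draw one latent factor per site with covariance exp(-d/decay_length)
# along the river coordinate (exponential kernel -> valid correlation).
spatial_factor <- function(pos, decay_length) {
  S <- exp(-abs(outer(pos, pos, "-")) / decay_length)
  L <- chol(S + diag(1e-10, length(pos)))
  as.vector(t(L) %*% stats::rnorm(length(pos)))
}

#' Generate a block-correlated relative-abundance table
#'
#' Latent-factor log-normal model: per planted module one latent Gaussian
#' factor per sample (spatially autocorrelated along the river within each
#' season), member OTU log-abundances load on it with loading sqrt(rho) so
#' any two members share latent correlation rho; non-members are
#' independent noise. Optional Bernoulli zero-inflation masks cells to
#' exact zeros; each sample row is then closed to sum 1.
#'
#' @param spec A [community_spec()].
#' @param taxonomy From [generate_taxonomy()].
#' @param metadata From [generate_metadata()].
#' @return A list of class `synthetic_dataset`: `table` (samples x OTUs
#'   matrix), `taxonomy`, `metadata`, `truth` (named list: module ->
#'   member OTU ids).
#' @export
generate_abundance_table <- function(spec, taxonomy, metadata) {
  stopifnot(inherits(spec, "community_spec"))
  if (nrow(taxonomy) != spec$n_otus)
    stopf("taxonomy has %d rows but spec declares %d OTUs",
          nrow(taxonomy), spec$n_otus)
  ms <- spec$module_spec
  n_samples <- nrow(metadata)
  otu_ids <- taxonomy$otu_id
  # consecutive OTU blocks form the planted modules
  sizes <- ms$size
  starts <- cumsum(c(1, utils::head(sizes, -1)))
  truth <- lapply(seq_along(sizes), function(m)
    otu_ids[starts[m]:(starts[m] + sizes[m] - 1)])
  names(truth) <- sprintf("module_%d", seq_along(sizes))

  local_seed(spec$seed + 3L, {
    base_mu <- stats::rnorm(spec$n_otus, 0, 1)      # OTU abundance heterogeneity
    logab <- matrix(stats::rnorm(n_samples * spec$n_otus), n_samples, spec$n_otus)
    for (m in seq_along(sizes)) {
      lambda <- sqrt(ms$rho[m])
      members <- starts[m]:(starts[m] + sizes[m] - 1)
      f <- numeric(n_samples)
      for (season in unique(metadata$season)) {
        in_season <- metadata$season == season
        f[in_season] <- spatial_factor(metadata$river_km[in_season],
                                       spec$decay_length)
      }
      logab[, members] <- lambda * f +
        sqrt(1 - lambda^2) * logab[, members, drop = FALSE]
    }
    ab <- exp(sweep(logab, 2, base_mu, "+"))
    if (spec$zero_inflation > 0) {
      mask <- matrix(stats::runif(length(ab)) < spec$zero_inflation,
                     nrow(ab), ncol(ab))
      ab[mask] <- 0
    }
    ab <- ab / rowSums(ab)
    dimnames(ab) <- list(metadata$sample_id, otu_ids)
    out <- list(table = ab, taxonomy = taxonomy, metadata = metadata,
                truth = truth)
    class(out) <- "synthetic_dataset"
    out
  })
}

#' Simulate a full synthetic community dataset
#'
#' Convenience wrapper running [generate_taxonomy()],
#' [generate_metadata()] and [generate_abundance_table()] in order.
#'
#' @param spec A [community_spec()].
#' @return A `synthetic_dataset` list.
#' @export
simulate_community <- function(spec = community_spec()) {
  taxonomy <- generate_taxonomy(spec)
  metadata <- generate_metadata(spec)
  generate_abundance_table(spec, taxonomy, metadata)
}

#' Write a synthetic dataset to a directory
#'
#' Table, taxonomy and metadata as TSV; the truth module map as JSON.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(dataset$table, file.path(dir, "otu_table.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
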