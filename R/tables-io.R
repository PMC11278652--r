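# Readers and writers for the package's tabular and graph artifacts.
# One dialect everywhere: tab-separated UTF-8 text with '.' decimals.
# Readers are total: malformed input raises an error with row/column
# context, never a partially filled structure.

#' Read an OTU relative-abundance table
#'
#' Expects a tab-separated file whose first column is `sample_id` and whose
#' remaining columns are OTU ids; cells are nonnegative relative abundances.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (samples x OTUs) with sample ids as row names.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("OTU table '%s' has no OTU columns", path)
  if (names(df)[1] != "sample_id")
    stopf("OTU table '%s': first column must be 'sample_id', got '%s'",
          path, names(df)[1])
  if (nrow(df) == 0) stopf("OTU table '%s' has a header but no data rows", path)
  otu_ids <- names(df)[-1]
  if (anyDuplicated(otu_ids))
    stopf("OTU table '%s': duplicated OTU column '%s'",
          path, otu_ids[duplicated(otu_ids)][1])
  if (anyDuplicated(df$sample_id))
    stopf("OTU table '%s': duplicated sample id '%s'",
          path, df$sample_id[duplicated(df$sample_id)][1])
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) stopf("OTU table '%s': non-numeric abundance cell", path)
  rownames(values) <- df$sample_id
  assert_otu_table(values)
  values
}

#' Write an OTU table as TSV
#'
#' @param table Numeric matrix (samples x OTUs).
#' @param path Output path.
#' @export
write_otu_table <- function(table, path) {
  assert_otu_table(table)
  df <- data.frame(sample_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy map
#'
#' Tab-separated with required columns `otu_id`, `domain`, `phylum`; extra
#' columns (lower ranks) are preserved. Domain must be Bacteria or Archaea.
#'
#' @param path Path to a TSV file.
#' @return data.frame with one row per OTU.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_taxonomy(df)
  if (anyDuplicated(df$otu_id))
    stopf("taxonomy '%s': duplicated otu_id '%s'",
          path, df$otu_id[duplicated(df$otu_id)][1])
  df
}

#' Write a taxonomy map as TSV
#' @param taxonomy data.frame with otu_id, domain, phylum columns.
#' @param path Output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  assert_taxonomy(taxonomy)
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Required columns: sample_id, site_no, season, latitude, longitude,
#' elevation, landform, region, plus any of the environmental factors in
#' [ENV_FACTORS]. Season and landform labels are case-folded to the closed
#' vocabularies; empty cells become NA (flagged missing, never silently 0).
#'
#' @param path Path to a TSV file.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  required <- c("sample_id", "site_no", "season", "latitude", "longitude",
                "elevation", "landform", "region")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("metadata '%s' is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  df$season <- tolower(df$season)
  df$landform <- tolower(df$landform)
  df$region <- tolower(df$region)
  bad <- which(!df$season %in% SEASONS)
  if (length(bad))
    stopf("metadata '%s' row %d: season '%s' not in {%s}", path, bad[1],
          df$season[bad[1]], paste(SEASONS, collapse = ", "))
  bad <- which(!df$landform %in% LANDFORMS)
  if (length(bad))
    stopf("metadata '%s' row %d: landform '%s' not in {%s}", path, bad[1],
          df$landform[bad[1]], paste(LANDFORMS, collapse = ", "))
  bad <- which(!df$region %in% REGIONS)
  if (length(bad))
    stopf("metadata '%s' row %d: region '%s' not in {%s}", path, bad[1],
          df$region[bad[1]], paste(REGIONS, collapse = ", "))
  ok_lat <- is.na(df$latitude) | abs(df$latitude) <= 90
  ok_lon <- is.na(df$longitude) | abs(df$longitude) <= 180
  if (!all(ok_lat)) stopf("metadata '%s' row %d: |latitude| > 90", path, which(!ok_lat)[1])
  if (!all(ok_lon)) stopf("metadata '%s' row %d: |longitude| > 180", path, which(!ok_lon)[1])
  if (anyDuplicated(df$sample_id))
    stopf("metadata '%s': duplicated sample id '%s'",
          path, df$sample_id[duplicated(df$sample_id)][1])
  df
}

#' Write sample metadata as TSV
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write a co-occurrence network to GraphML
#'
#' Node attributes (domain, phylum, mean_abundance, module) and the edge
#' attribute rho travel with the file; GraphML keeps full double precision,
#' so correlations survive with far more than 6 significant digits.
#'
#' @param net igraph object as built by [build_network()].
#' @param path Output path.
#' @export
write_network <- function(net, path) {
  if (!igraph::is_igraph(net)) stopf("net must be an igraph object")
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Read a co-occurrence network from GraphML
#' @param path Path written by [write_network()].
#' @return igraph object.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  # GraphML readback names vertices by the stored "name" attribute already;
  # drop igraph's bookkeeping id attribute if present.
  if ("id" %in% igraph::vertex_attr_names(g))
    g <- igraph::delete_vertex_attr(g, "id")
  g
}

#' Analysis configuration with the study's default thresholds
#'
#' Defaults: prevalence 0.30 (OTU present in at least 30% of samples),
#' Spearman rho > 0.6, BH-adjusted p < 0.01, 1000 random graphs, 999
#' permutations, keystone cutoffs degree > 100 and betweenness < 5000,
#' incidence report cutoffs O > 0.5% and O/R > 1.
#'
#' @param prevalence Minimum presence fraction for the prevalence filter.
#' @param rho_threshold Spearman correlation threshold (strict, positive).
#' @param q_threshold BH-adjusted p-value threshold (strict).
#' @param n_null_graphs Erdos-Renyi ensemble size.
#' @param n_permutations Permutations for Mantel and db-RDA tests.
#' @param keystone_degree,keystone_betweenness Keystone cutoffs.
#' @param incidence_min_o,incidence_min_ratio Incidence report cutoffs.
#' @param use_absolute Admit |rho| > threshold edges (default FALSE: the
#'   positive-only rule).
#' @param seed Integer seed recorded with the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(prevalence = 0.30, rho_threshold = 0.6,
                       q_threshold = 0.01, n_null_graphs = 1000,
                       n_permutations = 999, keystone_degree = 100,
                       keystone_betweenness = 5000, incidence_min_o = 0.5,
                       incidence_min_ratio = 1, use_absolute = FALSE,
                       seed = 1L) {
  cfg <- list(prevalence = prevalence, rho_threshold = rho_threshold,
              q_threshold = q_threshold, n_null_graphs = n_null_graphs,
              n_permutations = n_permutations, keystone_degree = keystone_degree,
              keystone_betweenness = keystone_betweenness,
              incidence_min_o = incidence_min_o,
              incidence_min_ratio = incidence_min_ratio,
              use_absolute = use_absolute, seed = as.integer(seed))
  num <- cfg[setdiff(names(cfg), "use_absolute")]
  if (any(unlist(num[c("prevalence", "rho_threshold", "q_threshold",
                       "n_null_graphs", "n_permutations")]) <= 0))
    stopf("all thresholds must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @return `run_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
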