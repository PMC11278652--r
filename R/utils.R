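# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Environmental factor names used throughout the package
#'
#' Water temperature, pH, permanganate-index chemical oxygen demand,
#' ammonium and nitrate nitrogen, total nitrogen and phosphorus, and the
#' metals calcium, iron, aluminium, nickel and cadmium.
#'
#' @format Character vector of column names expected in sample metadata.
#' @export
ENV_FACTORS <- c("WT", "pH", "COD_Mn", "NH4_N", "NO3_N", "TN", "TP",
                 "Ca", "Fe", "Al", "Ni", "Cd")

DOMAINS <- c("Bacteria", "Archaea")
SEASONS <- c("spring", "autumn")
LANDFORMS <- c("plateau", "mountain/hill", "basin", "plain")
REGIONS <- c("source", "non-source")

# Evaluate expr under a local RNG seed without disturbing the caller's stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(seed, expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_otu_table <- function(table) {
  if (!is.matrix(table) || !is.numeric(table))
    stopf("OTU table must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stopf("OTU table must have sample row names and OTU column names")
  if (anyDuplicated(rownames(table)))
    stopf("duplicate sample ids: %s",
          paste(unique(rownames(table)[duplicated(rownames(table))]), collapse = ", "))
  if (anyDuplicated(colnames(table)))
    stopf("duplicate OTU ids: %s",
          paste(unique(colnames(table)[duplicated(colnames(table))]), collapse = ", "))
  if (any(table < 0, na.rm = TRUE)) stopf("OTU table contains negative abundances")
  invisible(table)
}

assert_taxonomy <- function(taxonomy) {
  required <- c("otu_id", "domain", "phylum")
  missing <- setdiff(required, names(taxonomy))
  if (length(missing))
    stopf("taxonomy is missing column(s): %s", paste(missing, collapse = ", "))
  bad <- !taxonomy$domain %in% DOMAINS
  if (any(bad))
    stopf("taxonomy row %d: domain '%s' is not one of %s",
          which(bad)[1], taxonomy$domain[which(bad)[1]],
          paste(DOMAINS, collapse = "/"))
  if (any(is.na(taxonomy$phylum) | !nzchar(taxonomy$phylum)))
    stopf("taxonomy row %d: empty phylum",
          which(is.na(taxonomy$phylum) | !nzchar(taxonomy$phylum))[1])
  invisible(taxonomy)
}

# Significance stars following the usual three-level convention.
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
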