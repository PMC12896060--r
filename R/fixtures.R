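#' Bundled reference tables from the six-city transit aerobiome survey
#'
#' Three small tables ship with the package so the bookkeeping and tiering
#' operations can be exercised against published summary numbers without
#' any download:
#'
#' * `sample_manifest`: collected/sequenced sample counts per city and
#'   year (air samples, field/lab negative controls, positive controls).
#' * `species_richness`: number of classified species per city and
#'   kingdom, post contaminant removal.
#' * `contaminant_prevalence`: the contaminant inventory (290 taxa: 265
#'   bacterial, 25 fungal) with per-taxon prevalence across all air
#'   samples. The 16 core-tier species carry their published names and
#'   tier; per-species prevalences *within* tiers are not published, so
#'   the non-anchored values are synthetic placeholders consistent with
#'   the tier counts (see the file name).
#'
#' @param which one of `"sample_manifest"`, `"species_richness"`,
#'   `"contaminant_prevalence"`.
#' @return a data frame.
#' @export
load_reference_table <- function(which = c("sample_manifest",
                                           "species_richness",
                                           "contaminant_prevalence")) {
  which <- match.arg(which)
  file <- switch(which,
                 sample_manifest = "sample_manifest.tsv",
                 species_richness = "species_richness_by_city.tsv",
                 contaminant_prevalence = "contaminant_prevalence_synthetic.tsv")
  path <- system.file("extdata", file, package = "aerocore")
  if (path == "") stop("bundled table not found: ", file)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Summarise a sample manifest
#'
#' Sums the per-year columns of a manifest table (rows = city or control
#' group, columns `y<year>`) into per-group and per-type totals.
#'
#' @param manifest data frame with columns `sample_type`, `group` and one
#'   `y<year>` column per year.
#' @return list with `per_group` (data frame `sample_type`, `group`,
#'   `total`), `per_type` (named totals by sample type) and
#'   `total_air` (air-sample grand total).
#' @export
summarize_manifest <- function(manifest) {
  year_cols <- grep("^y[0-9]{4}$", names(manifest), value = TRUE)
  if (length(year_cols) == 0) stop("manifest has no y<year> columns")
  totals <- rowSums(manifest[, year_cols, drop = FALSE], na.rm = TRUE)
  per_group <- data.frame(sample_type = manifest$sample_type,
                          group = manifest$group, total = as.integer(totals),
                          stringsAsFactors = FALSE)
  per_type <- tapply(per_group$total, per_group$sample_type, sum)
  list(per_group = per_group,
       per_type = per_type,
       total_air = as.integer(per_type[["air"]]))
}

#' Aggregate species richness over kingdoms
#'
#' Sums the kingdom columns of a per-city species-richness table into a
#' per-city total.
#'
#' @param richness data frame with a `city` column and one column per
#'   kingdom.
#' @return data frame `city`, `total` plus the kingdom columns.
#' @export
richness_totals <- function(richness) {
  kingdom_cols <- setdiff(names(richness), "city")
  total <- rowSums(richness[, kingdom_cols, drop = FALSE])
  cbind(data.frame(city = richness$city, total = as.integer(total),
                   stringsAsFactors = FALSE),
        richness[, kingdom_cols, drop = FALSE])
}
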