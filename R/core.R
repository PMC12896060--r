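#' Species prevalence at an abundance level
#'
#' For each taxon, counts the samples in which its within-sample relative
#' abundance is at or above `abundance_level`, over the decontaminated,
#' filtered raw counts (prevalence is depth-invariant by construction).
#' `abundance_level = 0` scores plain detection (count > 0).
#' `mean_abundance` averages the within-sample relative abundance over all
#' samples, zeros included.
#'
#' @param table raw [taxon_table] restricted to the samples of interest
#'   (air samples for core analyses).
#' @param abundance_level within-sample relative-abundance threshold as a
#'   fraction (e.g. 5e-5 for 0.005%, 0.01 for 1%).
#' @return data frame: `taxid`, `name`, `kingdom`, `abundance_level`,
#'   `n_present`, `n_samples`, `prevalence`, `mean_abundance`.
#' @export
species_prevalence <- function(table, abundance_level = 5e-5) {
  stopifnot(inherits(table, "taxon_table"))
  if (table$transform != "raw") {
    stop("species_prevalence expects raw counts, got ", table$transform)
  }
  stopifnot(abundance_level >= 0, abundance_level <= 1)
  totals <- rowSums(table$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(sample_ids(table)[totals == 0], collapse = ", "))
  }
  rel <- table$counts / totals
  present <- if (abundance_level == 0) table$counts > 0 else
    rel >= abundance_level
  n_present <- colSums(present)
  n_samples <- nrow(table$counts)
  data.frame(taxid = table$taxa$taxid, name = table$taxa$name,
             kingdom = table$taxa$kingdom,
             abundance_level = abundance_level,
             n_present = as.integer(n_present),
             n_samples = n_samples,
             prevalence = n_present / n_samples,
             mean_abundance = colMeans(rel),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign core / sub-core tiers from prevalence profiles
#'
#' Core: prevalence strictly above `core_prev` (default 0.97). Sub-core:
#' prevalence in the closed interval [`subcore_lo`, `core_prev`] (default
#' [0.70, 0.97]). Taxa failing the negatives prevalence gate are tier
#' `none` regardless of prevalence. Rows are ordered by prevalence
#' descending, then mean abundance descending, then taxid ascending.
#'
#' @param profiles data frame from [species_prevalence()].
#' @param gate optional data frame from [prevalence_gate()] (columns
#'   `taxid`, `passes`); NULL applies no gate.
#' @param core_prev core threshold, strict (default 0.97).
#' @param subcore_lo sub-core lower bound, inclusive (default 0.70).
#' @param scope label recorded on the report (e.g. `"global"`,
#'   `"city:Oslo"`, `"contaminant"`).
#' @return a `core_report` data frame: the profile columns plus
#'   `gate_passes`, `tier` and `ubiquitous` (prevalence exactly 1).
#' @export
assign_tiers <- function(profiles, gate = NULL, core_prev = 0.97,
                         subcore_lo = 0.70, scope = "global") {
  stopifnot(subcore_lo <= core_prev)
  passes <- if (is.null(gate)) rep(TRUE, nrow(profiles)) else {
    j <- match(profiles$taxid, gate$taxid)
    ifelse(is.na(j), FALSE, gate$passes[j])
  }
  tier <- ifelse(!passes, "none",
                 ifelse(profiles$prevalence > core_prev, "core",
                        ifelse(profiles$prevalence >= subcore_lo, "sub_core",
                               "none")))
  out <- profiles
  out$gate_passes <- passes
  out$tier <- tier
  out$ubiquitous <- profiles$prevalence == 1
  ord <- order(-out$prevalence, -out$mean_abundance, out$taxid)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scope") <- scope
  attr(out, "core_prev") <- core_prev
  attr(out, "subcore_lo") <- subcore_lo
  class(out) <- c("core_report", class(out))
  out
}

#' Local (per-city) core microbiomes
#'
#' Recomputes species prevalence within each city's air samples and tiers
#' it with the shared negatives gate (negatives are not city-specific, so
#' the gate is computed once and reused).
#'
#' @param table decontaminated, filtered raw [taxon_table] of air samples.
#' @param metadata metadata data frame covering the table's samples.
#' @param gate optional [prevalence_gate()] result.
#' @param abundance_level within-sample presence level (default 5e-5).
#' @param core_prev,subcore_lo tier thresholds as in [assign_tiers()].
#' @return named list of `core_report` objects, one per city.
#' @export
local_cores <- function(table, metadata, gate = NULL,
                        abundance_level = 5e-5, core_prev = 0.97,
                        subcore_lo = 0.70) {
  stopifnot(inherits(table, "taxon_table"))
  meta <- metadata[match(sample_ids(table), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for table sample(s)")
  by_city <- split(sample_ids(table), meta$city)
  small <- names(by_city)[lengths(by_city) < 2]
  if (length(small) > 0) {
    stop("prevalence thresholds are undefined for cities with < 2 samples: ",
         paste(small, collapse = ", "))
  }
  out <- lapply(names(by_city), function(city) {
    prof <- species_prevalence(subset_table(table, samples = by_city[[city]]),
                               abundance_level = abundance_level)
    assign_tiers(prof, gate = gate, core_prev = core_prev,
                 subcore_lo = subcore_lo, scope = paste0("city:", city))
  })
  names(out) <- names(by_city)
  out
}

#' Subset samples by Nonpareil coverage
#'
#' Keeps samples whose estimated Nonpareil coverage is strictly greater
#' than `min_coverage`; samples with missing coverage are excluded with a
#' warning.
#'
#' @param table a [taxon_table].
#' @param metadata metadata data frame with `nonpareil_coverage`.
#' @param min_coverage strict lower bound (default 0.5).
#' @return the subset [taxon_table].
#' @export
coverage_subset <- function(table, metadata, min_coverage = 0.5) {
  stopifnot(inherits(table, "taxon_table"))
  meta <- metadata[match(sample_ids(table), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("metadata missing for table sample(s)")
  cov <- meta$nonpareil_coverage
  if (any(is.na(cov))) {
    warning(sum(is.na(cov)),
            " sample(s) with missing Nonpareil coverage excluded")
  }
  keep <- !is.na(cov) & cov > min_coverage
  if (!any(keep)) stop("no samples exceed coverage ", min_coverage)
  subset_table(table, samples = sample_ids(table)[keep])
}

#' Core/sub-core tiers of the contaminant inventory
#'
#' Prevalence of each identified contaminant taxon across all samples of
#' the original (pre-removal) table, tiered with the same thresholds but
#' without the negatives gate: these are precisely the taxa the gate
#' excluded, and their prevalence structure is reported so future studies
#' can reuse it. Presence is plain detection (count > 0).
#'
#' @param table the original raw [taxon_table], before taxon removal.
#' @param contaminant_taxids taxids of the contaminant set.
#' @param core_prev,subcore_lo tier thresholds as in [assign_tiers()].
#' @return a `core_report` with scope `"contaminant"`.
#' @export
contaminant_core <- function(table, contaminant_taxids, core_prev = 0.97,
                             subcore_lo = 0.70) {
  sub <- subset_table(table, taxids = contaminant_taxids)
  prof <- species_prevalence(sub, abundance_level = 0)
  assign_tiers(prof, gate = NULL, core_prev = core_prev,
               subcore_lo = subcore_lo, scope = "contaminant")
}

#' Prevalence curve: species counts above a prevalence threshold
#'
#' For each abundance level and each prevalence threshold on a grid,
#' counts the species whose prevalence at that level is at or above the
#' threshold. The count is monotone non-increasing both in the threshold
#' and in the abundance level.
#'
#' @param table raw [taxon_table] of air samples.
#' @param abundance_levels vector of within-sample presence levels
#'   (default the four study levels 0.005%, 0.3%, 0.5%, 1%).
#' @param thresholds prevalence grid (default 0 to 1 by 0.01).
#' @return data frame: `abundance_level`, `prevalence_threshold`,
#'   `n_species`.
#' @export
prevalence_curve <- function(table,
                             abundance_levels = c(5e-5, 0.003, 0.005, 0.01),
                             thresholds = seq(0, 1, by = 0.01)) {
  out <- lapply(abundance_levels, function(lv) {
    prof <- species_prevalence(table, abundance_level = lv)
    data.frame(abundance_level = lv,
               prevalence_threshold = thresholds,
               n_species = vapply(thresholds, function(t)
                 sum(prof$prevalence >= t & prof$n_present > 0), integer(1)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
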