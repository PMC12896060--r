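#' Within-sample abundance threshold filter
#'
#' Zeroes, per sample, every taxon whose count is below `min_fraction` of
#' that sample's total classified reads (default 0.005%, i.e. 5e-5). The
#' per-sample totals used for the threshold are computed before any
#' zeroing, so the filter is idempotent. Counts exactly at the threshold
#' are kept.
#'
#' @param table raw [taxon_table].
#' @param min_fraction within-sample relative-abundance cut-off in [0,1)
#'   (default 5e-5).
#' @return a raw [taxon_table] of the same shape with sub-threshold
#'   entries set to 0.
#' @export
abundance_threshold_filter <- function(table, min_fraction = 5e-5) {
  stopifnot(inherits(table, "taxon_table"))
  if (table$transform != "raw") {
    stop("abundance filter runs on raw counts, got ", table$transform)
  }
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction >= 1) {
    stop("min_fraction must lie in [0,1)")
  }
  counts <- table$counts
  totals <- rowSums(counts)
  cut <- totals * min_fraction
  zero <- counts < cut  # strict <: counts at exactly the cut are kept
  counts[zero] <- 0L
  taxon_table(counts, table$taxa, transform = "raw")
}

#' Normalize per-sample read counts to a common total
#'
#' Scales each sample's counts so they sum to `target` (default 1e7)
#' reads. Samples with zero total stay all-zero and are recorded in the
#' `zero_samples` attribute.
#'
#' @param table raw [taxon_table].
#' @param target per-sample total after scaling (default 1e7).
#' @return a [taxon_table] with `transform = "scaled_1e7"`.
#' @export
normalize_counts <- function(table, target = 1e7) {
  stopifnot(inherits(table, "taxon_table"))
  if (table$transform != "raw") {
    stop("normalize_counts expects raw counts, got ", table$transform)
  }
  stopifnot(target > 0)
  totals <- rowSums(table$counts)
  zero <- totals == 0
  scale <- ifelse(zero, 0, target / totals)
  counts <- table$counts * scale
  out <- taxon_table(counts, table$taxa, transform = "scaled_1e7")
  attr(out, "zero_samples") <- sample_ids(table)[zero]
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero total left all-zero: ",
            paste(sample_ids(table)[zero], collapse = ", "))
  }
  out
}

#' Log10 transform of normalized counts
#'
#' Applies `log10(x + 1)` (pseudocount of one read) to a table normalized
#' to a common per-sample total, damping the influence of highly abundant
#' species. Zero stays zero.
#'
#' @param table a [taxon_table] with `transform = "scaled_1e7"`.
#' @return a [taxon_table] with `transform = "log_scaled"`.
#' @export
log_transform <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  if (table$transform != "scaled_1e7") {
    stop("log_transform expects a normalized table, got ", table$transform)
  }
  counts <- log10(table$counts + 1)
  taxon_table(counts, table$taxa, transform = "log_scaled")
}

#' Relative classified read abundance summaries
#'
#' Summarises relative read abundance either at kingdom level (all four
#' kingdoms/domains) or at species level (the `top_n` species by summed
#' reads plus a residual `"other"` row), per city or over all samples.
#' Percentages within a group sum to 100 exactly, the last row being
#' computed as the residual. Species ties are broken by ascending taxid.
#'
#' @param table raw (or filtered) [taxon_table]; decontaminated counts.
#' @param metadata metadata data frame; required for `grouping = "per_city"`.
#' @param grouping `"total"` or `"per_city"` (years and localities merged).
#' @param level `"kingdom"` or `"species"`.
#' @param top_n number of named species rows (default 20).
#' @return tidy data frame: `group`, `label`, `taxid` (NA for kingdom
#'   level and the `"other"` row), `percent`.
#' @export
relative_abundance <- function(table, metadata = NULL,
                               grouping = c("total", "per_city"),
                               level = c("kingdom", "species"),
                               top_n = 20) {
  stopifnot(inherits(table, "taxon_table"))
  grouping <- match.arg(grouping)
  level <- match.arg(level)
  groups <- if (grouping == "total") {
    list(total = sample_ids(table))
  } else {
    if (is.null(metadata)) stop("per_city grouping requires metadata")
    meta <- metadata[match(sample_ids(table), metadata$sample_id), ]
    if (anyNA(meta$sample_id)) stop("metadata missing for table sample(s)")
    split(sample_ids(table), meta$city)
  }
  out <- lapply(names(groups), function(g) {
    counts <- table$counts[groups[[g]], , drop = FALSE]
    tot <- sum(counts)
    if (tot == 0) stop("group ", g, " has zero total reads")
    if (level == "kingdom") {
      by_k <- tapply(colSums(counts),
                     factor(table$taxa$kingdom, levels = kingdom_levels), sum)
      by_k[is.na(by_k)] <- 0
      pct <- 100 * by_k / tot
      pct[length(pct)] <- 100 - sum(pct[-length(pct)])
      data.frame(group = g, label = names(by_k), taxid = NA_integer_,
                 percent = as.numeric(pct), stringsAsFactors = FALSE)
    } else {
      sums <- colSums(counts)
      ord <- order(-sums, table$taxa$taxid)
      top <- ord[seq_len(min(top_n, length(ord)))]
      pct <- 100 * sums[top] / tot
      df <- data.frame(group = g, label = table$taxa$name[top],
                       taxid = table$taxa$taxid[top],
                       percent = as.numeric(pct), stringsAsFactors = FALSE)
      rbind(df, data.frame(group = g, label = "other", taxid = NA_integer_,
                           percent = 100 - sum(df$percent),
                           stringsAsFactors = FALSE))
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
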