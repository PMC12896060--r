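#' Identify exogenous contaminant taxa from negative controls
#'
#' A taxon is called a contaminant when it is present (count > 0) in at
#' least `min_negatives` negative-control samples and its summed raw read
#' count over all pooled negatives is strictly greater than
#' `min_total_reads`. Field and lab negatives are pooled. The rule runs on
#' raw species-level counts, before any abundance filtering of the
#' negatives.
#'
#' @param table raw [taxon_table] containing the negative controls.
#' @param negative_ids sample ids of the negative controls (>= 2).
#' @param min_negatives minimum number of negatives with the taxon present
#'   (default 2).
#' @param min_total_reads raw-read total over all negatives that must be
#'   exceeded (default 10000, strict).
#' @return data frame with one row per taxon: `taxid`, `name`, `kingdom`,
#'   `n_negatives_present`, `total_negative_reads`, `is_contaminant`.
#' @export
identify_contaminants <- function(table, negative_ids, min_negatives = 2,
                                  min_total_reads = 10000) {
  stopifnot(inherits(table, "taxon_table"))
  if (table$transform != "raw") {
    stop("contaminant identification requires raw counts, got ",
         table$transform)
  }
  negative_ids <- as.character(negative_ids)
  missing <- setdiff(negative_ids, sample_ids(table))
  if (length(missing) > 0) {
    stop("negative id(s) not in table: ", paste(missing, collapse = ", "))
  }
  if (length(negative_ids) < 2) {
    stop("need at least 2 negative controls; got ", length(negative_ids))
  }
  neg <- table$counts[negative_ids, , drop = FALSE]
  n_present <- colSums(neg > 0)
  totals <- colSums(neg)
  data.frame(taxid = table$taxa$taxid,
             name = table$taxa$name,
             kingdom = table$taxa$kingdom,
             n_negatives_present = as.integer(n_present),
             total_negative_reads = as.integer(totals),
             is_contaminant = n_present >= min_negatives &
               totals > min_total_reads,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove taxa from a count table
#'
#' Drops the given taxa (typically the contaminant set) from the table and
#' reports, per sample, how many reads were removed, split by kingdom.
#' Removed plus retained totals equal the original per-sample totals
#' exactly.
#'
#' @param table raw [taxon_table].
#' @param taxids taxids to remove; ids absent from the table are ignored.
#' @return list with `table` (the pruned [taxon_table]) and `summary`
#'   (data frame: `sample_id`, `total_reads`, `removed_reads`,
#'   `removed_bacteria`, `removed_fungi`, `retained_reads`,
#'   `removed_fraction`).
#' @export
remove_taxa <- function(table, taxids) {
  stopifnot(inherits(table, "taxon_table"))
  taxids <- as.character(taxids)
  drop <- as.character(table$taxa$taxid) %in% taxids
  total <- rowSums(table$counts)
  removed_mat <- table$counts[, drop, drop = FALSE]
  removed <- rowSums(removed_mat)
  king <- table$taxa$kingdom[drop]
  removed_bact <- rowSums(removed_mat[, king == "Bacteria", drop = FALSE])
  removed_fung <- rowSums(removed_mat[, king == "Fungi", drop = FALSE])
  keep_taxa <- table$taxa[!drop, , drop = FALSE]
  rownames(keep_taxa) <- NULL
  pruned <- taxon_table(table$counts[, !drop, drop = FALSE], keep_taxa,
                        transform = table$transform)
  summary <- data.frame(sample_id = sample_ids(table),
                        total_reads = total,
                        removed_reads = removed,
                        removed_bacteria = removed_bact,
                        removed_fungi = removed_fung,
                        retained_reads = total - removed,
                        removed_fraction = ifelse(total > 0, removed / total, 0),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(table = pruned, summary = summary)
}

#' Two-proportion Z test (pooled variance, one-sided)
#'
#' Tests whether the prevalence of a taxon among air samples is greater
#' than among negative controls, using the pooled-proportion statistic
#' z = (p1 - p2) / sqrt(phat (1 - phat) (1/n1 + 1/n2)) with no continuity
#' correction and the upper-tail p-value. `passes` requires both
#' p1 > p2 and p < alpha. Degenerate inputs are flagged: equal or
#' both-empty/both-full proportions give `note = "degenerate"` and never
#' pass; a taxon absent from every negative but present in all air samples
#' passes with `note = "trivially_greater"`.
#'
#' @param x_air,n_air presence count and group size among air samples.
#' @param x_neg,n_neg presence count and group size among negatives.
#' @param alpha significance level (default 0.05).
#' @return one-row data frame: `prev_air`, `n_air`, `prev_neg`, `n_neg`,
#'   `pooled_p`, `z`, `p_value`, `passes`, `note`.
#' @export
prevalence_z_test <- function(x_air, n_air, x_neg, n_neg, alpha = 0.05) {
  stopifnot(n_air >= 1, n_neg >= 1, x_air >= 0, x_neg >= 0,
            x_air <= n_air, x_neg <= n_neg)
  p1 <- x_air / n_air
  p2 <- x_neg / n_neg
  pooled <- (x_air + x_neg) / (n_air + n_neg)
  note <- "ok"
  if (pooled %in% c(0, 1) || p1 == p2) {
    z <- if (p1 == p2) 0 else NA_real_
    p_value <- NA_real_
    passes <- FALSE
    note <- "degenerate"
    if (pooled %in% c(0, 1)) z <- NA_real_
  } else {
    z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n_air + 1 / n_neg))
    p_value <- stats::pnorm(z, lower.tail = FALSE)
    passes <- p1 > p2 && p_value < alpha
  }
  if (x_neg == 0 && x_air == n_air && n_air > 0) {
    passes <- TRUE
    note <- "trivially_greater"
  }
  data.frame(prev_air = p1, n_air = n_air, prev_neg = p2, n_neg = n_neg,
             pooled_p = pooled, z = z, p_value = p_value, passes = passes,
             note = note, stringsAsFactors = FALSE)
}

#' Prevalence gate for every taxon of a table
#'
#' Applies [prevalence_z_test()] per taxon, comparing presence (count > 0)
#' among air samples against the pooled negative controls. The gate is
#' computed once and reused across global and per-city core analyses.
#'
#' @param table raw or filtered [taxon_table] containing both air samples
#'   and negatives (raw counts).
#' @param air_ids,negative_ids sample id vectors.
#' @param alpha significance level (default 0.05).
#' @return data frame with one row per taxon (`taxid` plus the columns of
#'   [prevalence_z_test()]).
#' @export
prevalence_gate <- function(table, air_ids, negative_ids, alpha = 0.05) {
  stopifnot(inherits(table, "taxon_table"))
  air_ids <- as.character(air_ids)
  negative_ids <- as.character(negative_ids)
  stopifnot(all(air_ids %in% sample_ids(table)),
            all(negative_ids %in% sample_ids(table)))
  air <- table$counts[air_ids, , drop = FALSE]
  neg <- table$counts[negative_ids, , drop = FALSE]
  x_air <- colSums(air > 0)
  x_neg <- colSums(neg > 0)
  rows <- lapply(seq_along(x_air), function(j) {
    prevalence_z_test(x_air[j], length(air_ids), x_neg[j],
                      length(negative_ids), alpha = alpha)
  })
  out <- do.call(rbind, rows)
  cbind(data.frame(taxid = table$taxa$taxid), out)
}

#' Flag candidate cross-contaminated samples from an ordination
#'
#' A sample is a candidate when the majority of its k nearest neighbours
#' in the 2-D embedding belong to a different city. A candidate is
#' excluded only when two independent metadata signals both indicate
#' contamination: a below-detection DNA concentration and a library-plate
#' position adjacent (including diagonals, same plate) to a sample of the
#' embedding-neighbour city. Candidates lacking either signal are
#' retained.
#'
#' @param embedding data frame/matrix with sample ids as row names and two
#'   coordinate columns, covering all air samples under review.
#' @param metadata metadata data frame (see [read_metadata()]).
#' @param k number of nearest neighbours (default 10).
#' @return data frame of candidates: `sample_id`, `assigned_city`,
#'   `embedded_neighbor_city`, `dna_below_detection`,
#'   `plate_adjacent_to_neighbor_city`, `verdict`.
#' @export
flag_cross_contamination <- function(embedding, metadata, k = 10) {
  coords <- as.matrix(embedding)
  if (ncol(coords) != 2) stop("embedding must have exactly 2 columns")
  ids <- rownames(coords)
  if (is.null(ids)) stop("embedding must carry sample ids as row names")
  meta <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(meta$sample_id)) {
    stop("metadata missing for embedded sample(s)")
  }
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 embedded samples")
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  flags <- list()
  for (i in seq_len(n)) {
    nn <- order(d[i, ])[seq_len(k)]
    nn_city <- meta$city[nn]
    foreign <- nn_city != meta$city[i]
    if (sum(foreign) <= k / 2) next
    neighbor_city <- names(sort(table(nn_city[foreign]), decreasing = TRUE))[1]
    bd <- isTRUE(meta$dna_below_detection[i])
    adj <- plate_adjacent(meta$plate_position[i],
                          metadata$plate_position[metadata$city == neighbor_city])
    flags[[length(flags) + 1]] <- data.frame(
      sample_id = ids[i], assigned_city = meta$city[i],
      embedded_neighbor_city = neighbor_city,
      dna_below_detection = bd,
      plate_adjacent_to_neighbor_city = adj,
      verdict = if (bd && adj) "exclude" else "retain",
      stringsAsFactors = FALSE)
  }
  if (length(flags) == 0) {
    return(data.frame(sample_id = character(), assigned_city = character(),
                      embedded_neighbor_city = character(),
                      dna_below_detection = logical(),
                      plate_adjacent_to_neighbor_city = logical(),
                      verdict = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, flags)
}

# parse "P1:A01" (or plain "A01") into plate/row/column
parse_well <- function(x) {
  out <- data.frame(plate = NA_character_, row = NA_integer_,
                    col = NA_integer_)[rep(1, length(x)), ]
  rownames(out) <- NULL
  ok <- !is.na(x) & grepl("^([A-Za-z0-9]+:)?[A-H][0-9]{1,2}$", x)
  plate <- ifelse(grepl(":", x), sub(":.*$", "", x), "P1")
  well <- sub("^.*:", "", x)
  out$plate[ok] <- plate[ok]
  out$row[ok] <- match(substr(well[ok], 1, 1), LETTERS)
  out$col[ok] <- as.integer(substring(well[ok], 2))
  out
}

plate_adjacent <- function(pos, other_pos) {
  w <- parse_well(pos)
  if (is.na(w$row[1])) return(FALSE)
  o <- parse_well(other_pos[!is.na(other_pos)])
  o <- o[!is.na(o$row) & o$plate == w$plate[1], , drop = FALSE]
  if (nrow(o) == 0) return(FALSE)
  any(abs(o$row - w$row[1]) <= 1 & abs(o$col - w$col[1]) <= 1 &
        !(o$row == w$row[1] & o$col == w$col[1]))
}
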