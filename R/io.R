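#' Read a Kraken2 classification report as a single-sample count table
#'
#' Parses the standard 6-column Kraken2 report (percent of reads, clade
#' reads, direct reads, rank code, taxid, indented name) and keeps
#' species-rank rows. By default the clade read count is used, so reads
#' assigned below the species node (strains, subspecies) are rolled up into
#' the species total; `use = "direct"` switches to reads assigned directly
#' to the species node. Kingdom is tracked from the domain/kingdom context
#' rows of the report (Bacteria, Archaea, Viruses at rank D/R1; Fungi at
#' rank K under Eukaryota).
#'
#' @param path path to a Kraken2 report (TSV, no header).
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @param use `"clade"` (default) or `"direct"` read counts.
#' @return a single-sample raw [taxon_table].
#' @export
read_kraken_report <- function(path, sample_id = NULL,
                               use = c("clade", "direct")) {
  use <- match.arg(use)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty Kraken2 report: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    bad <- which(nf < 6)[1]
    stop("malformed Kraken2 report line ", bad, " in ", path,
         ": expected >= 6 tab-separated fields, got ", nf[bad])
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:6]))
  rank <- m[, 4]
  taxid <- suppressWarnings(as.integer(m[, 5]))
  clade <- suppressWarnings(as.numeric(m[, 2]))
  direct <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(taxid) || anyNA(clade) || anyNA(direct)) {
    bad <- which(is.na(taxid) | is.na(clade) | is.na(direct))[1]
    stop("malformed Kraken2 report line ", bad, " in ", path,
         ": non-numeric count or taxid")
  }
  name <- trimws(m[, 6])

  # walk the indented taxonomy, carrying the current kingdom context
  kingdom <- character(length(lines))
  current <- "Other"
  for (i in seq_along(lines)) {
    if (rank[i] %in% c("D", "R1", "K") || name[i] %in%
        c("Bacteria", "Archaea", "Viruses", "Fungi", "Eukaryota")) {
      current <- switch(name[i],
                        Bacteria = "Bacteria",
                        Archaea = "Archaea",
                        Viruses = "Virus",
                        Fungi = "Fungi",
                        Eukaryota = "Other",
                        current)
    }
    kingdom[i] <- current
  }

  keep <- rank == "S"
  counts_vec <- if (use == "clade") clade[keep] else direct[keep]
  taxa <- data.frame(taxid = taxid[keep], name = name[keep],
                     rank = rep("species", sum(keep)), kingdom = kingdom[keep],
                     stringsAsFactors = FALSE)
  counts <- matrix(as.integer(round(counts_vec)), nrow = 1,
                   dimnames = list(sample_id, as.character(taxa$taxid)))
  taxon_table(counts, taxa, transform = "raw")
}

#' Read a Bracken species-abundance table as a single-sample count table
#'
#' Parses the standard 7-column Bracken output (name, taxonomy_id,
#' taxonomy_lvl, kraken_assigned_reads, added_reads, new_est_reads,
#' fraction_total_reads), keeping rank "S" rows and using the re-estimated
#' read count (`new_est_reads`). If the fraction column departs from a sum
#' of 1 by more than `fraction_tol` a warning is issued. The Bracken
#' dialect carries no lineage, so kingdom defaults to `"Other"` unless a
#' `kingdom_map` (taxid -> kingdom) is supplied.
#'
#' @param path path to a Bracken table (TSV with header).
#' @param sample_id sample identifier; defaults to file name without extension.
#' @param kingdom_map optional data frame with columns `taxid`, `kingdom`.
#' @param fraction_tol tolerance on the fraction-column sum (default 0.05).
#' @return a single-sample raw [taxon_table].
#' @export
read_bracken_table <- function(path, sample_id = NULL, kingdom_map = NULL,
                               fraction_tol = 0.05) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot parse Bracken table ", path, ": ",
                             conditionMessage(e)))
  if (nrow(df) == 0) stop("empty Bracken table: ", path)
  needed <- c("name", "taxonomy_id", "taxonomy_lvl", "new_est_reads",
              "fraction_total_reads")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("Bracken table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  frac_sum <- sum(df$fraction_total_reads, na.rm = TRUE)
  if (abs(frac_sum - 1) > fraction_tol) {
    warning("Bracken fraction column sums to ", signif(frac_sum, 4),
            " (expected ~1) in ", path)
  }
  df <- df[df$taxonomy_lvl == "S", , drop = FALSE]
  kingdom <- rep("Other", nrow(df))
  if (!is.null(kingdom_map)) {
    j <- match(df$taxonomy_id, kingdom_map$taxid)
    kingdom[!is.na(j)] <- kingdom_map$kingdom[j[!is.na(j)]]
  }
  taxa <- data.frame(taxid = as.integer(df$taxonomy_id),
                     name = trimws(df$name), rank = rep("species", nrow(df)),
                     kingdom = kingdom, stringsAsFactors = FALSE)
  counts <- matrix(as.integer(round(df$new_est_reads)), nrow = 1,
                   dimnames = list(sample_id, as.character(taxa$taxid)))
  taxon_table(counts, taxa, transform = "raw")
}

sample_types <- c("air", "field_negative", "lab_negative", "positive")

#' Read a sample metadata table
#'
#' Tab-separated with header, UTF-8, missing values as empty strings.
#' Required columns: `sample_id`, `city`, `year`, `sample_type` (one of
#' `air`, `field_negative`, `lab_negative`, `positive`). Recognised
#' optional columns: `locality`, `temperature` (deg C), `humidity` (% RH),
#' `travellers`, `ground_level` (`above`/`below`), `enclosure`
#' (`enclosed`/`open`), `dna_conc` (ng/uL, or `BD` for below detection),
#' `plate_position` (e.g. `P1:A01`), `nonpareil_coverage` (fraction in
#' [0,1]). Missing optional values become NA, never silent zeros; a
#' below-detection DNA concentration is kept distinct from zero via the
#' logical `dna_below_detection` column.
#'
#' @param path path to the metadata TSV.
#' @return a data frame of per-sample records, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"), colClasses = "character")
  required <- c("sample_id", "city", "year", "sample_type")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyNA(df$sample_id) || anyDuplicated(df$sample_id)) {
    stop("sample_id must be present and unique")
  }
  bad_type <- !df$sample_type %in% sample_types
  if (any(bad_type)) {
    stop("invalid sample_type value(s): ",
         paste(unique(df$sample_type[bad_type]), collapse = ", "),
         "; allowed: ", paste(sample_types, collapse = ", "))
  }
  out <- data.frame(sample_id = df$sample_id, city = df$city,
                    year = as.integer(df$year), sample_type = df$sample_type,
                    stringsAsFactors = FALSE)
  num_col <- function(col) {
    if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else
      rep(NA_real_, nrow(df))
  }
  chr_col <- function(col, allowed = NULL) {
    x <- if (col %in% names(df)) df[[col]] else rep(NA_character_, nrow(df))
    if (!is.null(allowed)) {
      bad <- !is.na(x) & !x %in% allowed
      if (any(bad)) stop("invalid ", col, " value(s): ",
                         paste(unique(x[bad]), collapse = ", "),
                         "; allowed: ", paste(allowed, collapse = ", "))
    }
    x
  }
  out$locality <- chr_col("locality")
  out$temperature <- num_col("temperature")
  out$humidity <- num_col("humidity")
  out$travellers <- num_col("travellers")
  out$ground_level <- chr_col("ground_level", c("above", "below"))
  out$enclosure <- chr_col("enclosure", c("enclosed", "open"))
  dna_raw <- if ("dna_conc" %in% names(df)) df$dna_conc else
    rep(NA_character_, nrow(df))
  out$dna_below_detection <- !is.na(dna_raw) & toupper(dna_raw) %in% c("BD", "<LOD")
  out$dna_conc <- suppressWarnings(as.numeric(dna_raw))
  out$dna_conc[out$dna_below_detection] <- NA_real_
  out$plate_position <- chr_col("plate_position")
  out$nonpareil_coverage <- num_col("nonpareil_coverage")
  cov <- out$nonpareil_coverage
  if (any(!is.na(cov) & (cov < 0 | cov > 1))) {
    stop("nonpareil_coverage must lie in [0,1]")
  }
  out
}

#' Write a sample metadata table
#'
#' Inverse of [read_metadata()]: the `dna_below_detection` flag is folded
#' back into the `dna_conc` column as `BD`.
#'
#' @param metadata data frame as returned by [read_metadata()].
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  if ("dna_below_detection" %in% names(out)) {
    dna <- ifelse(out$dna_below_detection, "BD",
                  ifelse(is.na(out$dna_conc), "", format(out$dna_conc)))
    out$dna_conc <- dna
    out$dna_below_detection <- NULL
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write / read a taxon count table (TSV with sidecar annotation)
#'
#' The matrix is written taxa-in-rows x samples-in-columns with a leading
#' `taxid` column; taxon annotation goes to a sidecar `<path>.taxa.tsv`.
#' `read_table(write_table(x)) == x` up to storage mode.
#'
#' @param table a [taxon_table].
#' @param path output path for the count matrix.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  stopifnot(inherits(table, "taxon_table"))
  mat <- t(table$counts)
  df <- data.frame(taxid = table$taxa$taxid, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- data.frame(table$taxa, transform = table$transform)
  utils::write.table(side, paste0(path, ".taxa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  side <- utils::read.delim(paste0(path, ".taxa.tsv"), header = TRUE,
                            sep = "\t", quote = "", stringsAsFactors = FALSE)
  transform <- if ("transform" %in% names(side)) side$transform[1] else "raw"
  side$transform <- NULL
  counts <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(counts) <- as.character(df$taxid)
  if (transform == "raw") storage.mode(counts) <- "integer"
  side <- side[match(df$taxid, side$taxid), , drop = FALSE]
  taxon_table(counts, side, transform = transform)
}

#' Write / read a contaminant evidence table
#'
#' Emits the per-taxon contaminant evidence (taxid, name, kingdom, number
#' of negative controls with the taxon present, total reads over all
#' negatives, contaminant verdict) as a TSV that downstream studies can
#' reuse directly.
#'
#' @param evidence data frame from [identify_contaminants()] (annotated).
#' @param path output path.
#' @export
write_contaminants <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_contaminants
#' @export
read_contaminants <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if ("is_contaminant" %in% names(df)) {
    df$is_contaminant <- as.logical(df$is_contaminant)
  }
  df
}
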