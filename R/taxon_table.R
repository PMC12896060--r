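#' Taxon count table
#'
#' The central container of the pipeline: a samples x taxa matrix of
#' species-level classified read counts together with a taxon annotation
#' table (NCBI-style taxid, name, rank, kingdom). A `transform` tag records
#' whether the values are raw integer counts (`"raw"`), counts scaled to a
#' common per-sample total (`"scaled_1e7"`), or log10 of scaled counts
#' (`"log_scaled"`); downstream operations check the tag so raw and
#' transformed values cannot be mixed by accident.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns. Row names
#'   are sample identifiers; column names are taxids (as character).
#' @param taxa data frame with columns `taxid`, `name`, `rank`, `kingdom`,
#'   one row per column of `counts`, in the same order.
#' @param transform one of `"raw"`, `"scaled_1e7"`, `"log_scaled"`.
#'
#' @return An object of class `taxon_table`: a list with elements `counts`,
#'   `taxa` and `transform`.
#' @export
taxon_table <- function(counts, taxa, transform = "raw") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  transform <- match.arg(transform, c("raw", "scaled_1e7", "log_scaled"))
  taxa <- as.data.frame(taxa)
  required <- c("taxid", "name", "rank", "kingdom")
  missing_cols <- setdiff(required, names(taxa))
  if (length(missing_cols) > 0) {
    stop("taxon annotation lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  taxa$kingdom <- norm_kingdom(taxa$kingdom)
  if (nrow(taxa) != ncol(counts)) {
    stop("taxon annotation has ", nrow(taxa), " rows but counts has ",
         ncol(counts), " columns")
  }
  if (anyDuplicated(taxa$taxid)) stop("duplicate taxids in taxon annotation")
  if (is.null(rownames(counts))) stop("counts must have sample ids as row names")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (transform == "raw" && any(counts != floor(counts))) {
    stop("raw counts must be integers")
  }
  colnames(counts) <- as.character(taxa$taxid)
  rownames(taxa) <- NULL
  structure(list(counts = counts, taxa = taxa, transform = transform),
            class = "taxon_table")
}

kingdom_levels <- c("Archaea", "Bacteria", "Fungi", "Virus", "Other")

norm_kingdom <- function(x) {
  x <- as.character(x)
  x[x %in% c("Viruses", "viral")] <- "Virus"
  x[is.na(x) | !(x %in% kingdom_levels)] <- "Other"
  x
}

#' @export
print.taxon_table <- function(x, ...) {
  cat("taxon_table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa [", x$transform, "]\n", sep = "")
  tab <- table(factor(x$taxa$kingdom, levels = kingdom_levels))
  cat("kingdoms:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$counts)

#' Sample identifiers of a taxon table
#' @param table a [taxon_table]
#' @return character vector of sample ids.
#' @export
sample_ids <- function(table) rownames(table$counts)

#' Per-sample total classified reads
#' @param table a [taxon_table]
#' @return named numeric vector of row sums.
#' @export
sample_totals <- function(table) rowSums(table$counts)

#' Subset a taxon table
#'
#' @param table a [taxon_table]
#' @param samples sample ids (or logical/integer index) to keep; NULL keeps all.
#' @param taxids taxids to keep; NULL keeps all.
#' @return a [taxon_table] with the selected rows/columns, annotation aligned.
#' @export
subset_table <- function(table, samples = NULL, taxids = NULL) {
  stopifnot(inherits(table, "taxon_table"))
  counts <- table$counts
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, rownames(counts))
      if (length(missing) > 0) {
        stop("unknown sample id(s): ", paste(missing, collapse = ", "))
      }
    }
    counts <- counts[samples, , drop = FALSE]
  }
  taxa <- table$taxa
  if (!is.null(taxids)) {
    keep <- match(as.character(taxids), as.character(taxa$taxid))
    if (anyNA(keep)) {
      stop("unknown taxid(s): ",
           paste(taxids[is.na(keep)], collapse = ", "))
    }
    counts <- counts[, keep, drop = FALSE]
    taxa <- taxa[keep, , drop = FALSE]
    rownames(taxa) <- NULL
  }
  taxon_table(counts, taxa, transform = table$transform)
}

#' Merge single-sample (or multi-sample) taxon tables
#'
#' Takes the union of taxa over all input tables; a taxon absent from a
#' sample gets count 0. Per-sample totals are conserved exactly (integer
#' arithmetic). Annotation conflicts for a shared taxid (differing name or
#' kingdom) keep the first occurrence with a warning.
#'
#' @param tables list of [taxon_table] objects with raw counts.
#' @return a merged raw [taxon_table].
#' @export
merge_tables <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  for (t in tables) {
    if (!inherits(t, "taxon_table")) stop("all inputs must be taxon_table objects")
    if (t$transform != "raw") stop("merge_tables expects raw count tables")
  }
  ids <- unlist(lapply(tables, sample_ids))
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) across tables: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  all_taxa <- do.call(rbind, lapply(tables, function(t) t$taxa))
  first <- !duplicated(all_taxa$taxid)
  taxa <- all_taxa[first, , drop = FALSE]
  dup <- all_taxa[!first, , drop = FALSE]
  if (nrow(dup) > 0) {
    ref <- taxa[match(dup$taxid, taxa$taxid), ]
    bad <- dup$name != ref$name | dup$kingdom != ref$kingdom
    if (any(bad)) {
      warning("conflicting annotation for taxid(s) ",
              paste(unique(dup$taxid[bad]), collapse = ", "),
              "; keeping first occurrence")
    }
  }
  taxa <- taxa[order(taxa$taxid), , drop = FALSE]
  rownames(taxa) <- NULL
  tax_key <- as.character(taxa$taxid)
  counts <- matrix(0L, nrow = length(ids), ncol = nrow(taxa),
                   dimnames = list(ids, tax_key))
  for (t in tables) {
    j <- match(as.character(t$taxa$taxid), tax_key)
    counts[sample_ids(t), j] <- t$counts
  }
  storage.mode(counts) <- "integer"
  taxon_table(counts, taxa, transform = "raw")
}
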