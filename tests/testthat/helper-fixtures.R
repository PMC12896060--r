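# fixtures are built in code at test time; nothing binary ships with the tests

# a Kraken2-style report: root/domains, 3 bacterial species (one with a
# strain row so clade != direct), 1 fungal species, plus G/F rank rows
write_kraken_fixture <- function(path) {
  lines <- c(
    "100.00\t5000\t0\tR\t1\troot",
    " 80.00\t4000\t10\tD\t2\t  Bacteria",
    " 40.00\t2000\t0\tG\t1350\t    Enterococcus",
    " 24.00\t1200\t1200\tS\t1351\t      Enterococcus faecalis",
    " 16.00\t800\t600\tS\t1352\t      Enterococcus faecium",
    "  4.00\t200\t200\tS1\t99999\t        Enterococcus faecium strain X",
    " 10.00\t500\t500\tS\t1280\t    Staphylococcus aureus",
    " 19.00\t950\t0\tD\t2759\t  Eukaryota",
    " 19.00\t950\t0\tK\t4751\t    Fungi",
    " 19.00\t950\t0\tF\t5042\t      Aspergillaceae",
    " 19.00\t950\t950\tS\t5061\t        Aspergillus niger")
  writeLines(lines, path)
  path
}

write_bracken_fixture <- function(path, bad_fraction = FALSE) {
  frac <- if (bad_fraction) c(0.9, 0.3) else c(0.6, 0.4)
  df <- data.frame(
    name = c("Enterococcus faecalis", "Aspergillus niger", "Enterococcus"),
    taxonomy_id = c(1351L, 5061L, 1350L),
    taxonomy_lvl = c("S", "S", "G"),
    kraken_assigned_reads = c(1100L, 900L, 10L),
    added_reads = c(100L, 50L, 0L),
    new_est_reads = c(1200L, 950L, 10L),
    fraction_total_reads = c(frac, 0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small random raw table; optionally with designated negative samples
random_table <- function(n_samples = 8, n_taxa = 50, seed = 1,
                         lambda = 30) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_taxa, lambda) *
                     rbinom(n_samples * n_taxa, 1, 0.6),
                   nrow = n_samples,
                   dimnames = list(sprintf("S%03d", seq_len(n_samples)), NULL))
  taxa <- data.frame(taxid = seq_len(n_taxa) + 1000L,
                     name = paste0("sp", seq_len(n_taxa)),
                     rank = "species",
                     kingdom = sample(c("Bacteria", "Fungi"), n_taxa,
                                      replace = TRUE))
  # keep every sample non-empty
  counts[, 1] <- counts[, 1] + 1L
  storage.mode(counts) <- "integer"
  taxon_table(counts, taxa)
}
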