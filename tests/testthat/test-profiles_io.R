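test_that("Kraken2 report parsing keeps species rows with clade counts and kingdom context", {
  path <- withr::local_tempfile(fileext = ".kreport")
  write_kraken_fixture(path)
  tt <- read_kraken_report(path, sample_id = "S1")
  # hand-parsed expectation: 4 species rows, clade-read convention
  expect_equal(ncol(tt$counts), 4)
  expect_equal(as.vector(tt$counts[1, as.character(c(1351, 1352, 1280, 5061))]),
               c(1200L, 800L, 500L, 950L))
  expect_equal(tt$taxa$kingdom[match(c(1351, 5061), tt$taxa$taxid)],
               c("Bacteria", "Fungi"))
  # direct-read convention excludes the strain roll-up
  td <- read_kraken_report(path, sample_id = "S1", use = "direct")
  expect_equal(as.vector(td$counts[1, "1352"]), 600L)
})

test_that("Kraken2 reports with no species rows or malformed lines are handled", {
  path <- withr::local_tempfile(fileext = ".kreport")
  writeLines(c("100.00\t50\t0\tR\t1\troot",
               " 50.00\t25\t25\tG\t1350\t  Enterococcus"), path)
  tt <- read_kraken_report(path)
  expect_equal(ncol(tt$counts), 0)

  writeLines(c("100.00\t50\t0\tR\t1\troot", "not a report line"), path)
  expect_error(read_kraken_report(path), "line 2")
  writeLines(character(0), path)
  expect_error(read_kraken_report(path), "empty")
})

test_that("Bracken tables use re-estimated species reads and validate fractions", {
  path <- withr::local_tempfile(fileext = ".bracken")
  write_bracken_fixture(path)
  tt <- read_bracken_table(path, sample_id = "B1")
  expect_equal(ncol(tt$counts), 2)  # only rank S kept
  expect_equal(as.vector(tt$counts[1, c("1351", "5061")]), c(1200L, 950L))
  write_bracken_fixture(path, bad_fraction = TRUE)
  expect_warning(read_bracken_table(path), "fraction")
})

test_that("merging tables takes the taxon union and conserves per-sample totals", {
  p1 <- withr::local_tempfile(fileext = ".kreport")
  p2 <- withr::local_tempfile(fileext = ".bracken")
  write_kraken_fixture(p1); write_bracken_fixture(p2)
  t1 <- read_kraken_report(p1, sample_id = "A")
  t2 <- read_bracken_table(p2, sample_id = "B", kingdom_map = t1$taxa)
  merged <- merge_tables(list(t1, t2))
  expect_setequal(merged$taxa$taxid, union(t1$taxa$taxid, t2$taxa$taxid))
  expect_equal(sample_totals(merged)[["A"]], sample_totals(t1)[["A"]])
  expect_equal(sample_totals(merged)[["B"]], sample_totals(t2)[["B"]])
  # absent taxon in a sample reads as zero
  expect_equal(unname(merged$counts["B", "1280"]), 0L)
  expect_error(merge_tables(list(t1, t1)), "duplicate sample")
})

test_that("two disjoint single-taxon samples merge into a 2x2 table with zeros off-diagonal", {
  mk <- function(id, taxid) {
    taxon_table(matrix(5L, 1, 1, dimnames = list(id, NULL)),
                data.frame(taxid = taxid, name = paste0("t", taxid),
                           rank = "species", kingdom = "Bacteria"))
  }
  m <- merge_tables(list(mk("X", 11L), mk("Y", 22L)))
  expect_equal(dim(m$counts), c(2, 2))
  expect_equal(as.vector(m$counts), c(5L, 0L, 0L, 5L))
})

test_that("metadata reader enforces required fields and keeps missing values missing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcity\tyear\tsample_type\ttemperature\tdna_conc",
               "s1\tOslo\t2018\tair\t21.5\t0.8",
               "s2\tOslo\t2018\tair\t\tBD",
               "s3\tOslo\t2018\tfield_negative\t\t"), path)
  md <- read_metadata(path)
  expect_equal(md$temperature, c(21.5, NA, NA))
  expect_true(md$dna_below_detection[2])
  expect_false(md$dna_below_detection[3])
  expect_true(is.na(md$dna_conc[2]))  # below detection is not zero

  writeLines(c("sample_id\tcity\tyear\tsample_type",
               "s1\tOslo\t2018\tnegative"), path)
  expect_error(read_metadata(path), "field_negative")
})

test_that("metadata city tallies match a hand count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcity\tyear\tsample_type",
               paste0("s", 1:6, "\t", c("Oslo", "Oslo", "Denver", "London",
                                        "Denver", "Oslo"), "\t2019\tair")),
             path)
  md <- read_metadata(path)
  expect_equal(as.vector(table(md$city)[c("Denver", "London", "Oslo")]),
               c(2L, 1L, 3L))
})

test_that("reader/writer pairs round-trip tables, metadata and contaminant evidence", {
  tt <- random_table(n_samples = 4, n_taxa = 12, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(tt, path)
  back <- read_table(path)
  expect_equal(back$counts, tt$counts)
  expect_equal(back$taxa, tt$taxa)
  expect_equal(back$transform, tt$transform)

  # normalized tables round-trip with their transform tag
  nt <- normalize_counts(tt)
  write_table(nt, path)
  expect_equal(read_table(path)$transform, "scaled_1e7")

  ev <- identify_contaminants(tt, c("S001", "S002"), min_total_reads = 10)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_contaminants(ev, cpath)
  expect_equal(read_contaminants(cpath), ev)

  sim <- generate_synthetic(clear_margin_config(seed = 9))
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_metadata(sim$metadata, mpath)
  md <- read_metadata(mpath)
  expect_equal(md$sample_id, sim$metadata$sample_id)
  expect_equal(md$dna_below_detection, sim$metadata$dna_below_detection)
  expect_equal(md$nonpareil_coverage, sim$metadata$nonpareil_coverage,
               tolerance = 1e-6)
})

test_that("tables never hold negative counts or duplicate identifiers", {
  taxa <- data.frame(taxid = c(1L, 1L), name = c("a", "b"),
                     rank = "species", kingdom = "Bacteria")
  m <- matrix(1L, 2, 2, dimnames = list(c("x", "y"), NULL))
  expect_error(taxon_table(m, taxa), "duplicate taxid")
  taxa$taxid <- 1:2
  m[1, 1] <- -1L
  expect_error(taxon_table(m, taxa), "negative")
  rownames(m) <- c("x", "x"); m[1, 1] <- 1L
  expect_error(taxon_table(m, taxa), "duplicate sample")
})
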