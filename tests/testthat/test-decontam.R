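make_neg_fixture <- function(neg_counts) {
  # 3 negatives + 1 air sample carrying one taxon with the given negatives
  counts <- matrix(0L, 4, 1, dimnames = list(c("N1", "N2", "N3", "A1"), NULL))
  counts[1:3, 1] <- as.integer(neg_counts)
  counts[4, 1] <- 100L
  taxon_table(counts, data.frame(taxid = 1L, name = "t", rank = "species",
                                 kingdom = "Bacteria"))
}

test_that("the contaminant rule is >= 2 negatives and strictly > 10,000 reads", {
  ev <- identify_contaminants(make_neg_fixture(c(6000, 5000, 0)),
                              c("N1", "N2", "N3"))
  expect_true(ev$is_contaminant)          # 2 negatives, 11,000 reads
  ev <- identify_contaminants(make_neg_fixture(c(10000, 0, 0)),
                              c("N1", "N2", "N3"))
  expect_false(ev$is_contaminant)         # only 1 negative
  ev <- identify_contaminants(make_neg_fixture(c(5000, 5000, 0)),
                              c("N1", "N2", "N3"))
  expect_false(ev$is_contaminant)         # total exactly 10,000: not >
  expect_error(identify_contaminants(make_neg_fixture(c(1, 1, 1)), "N1"),
               "at least 2")
  nt <- normalize_counts(make_neg_fixture(c(1, 1, 1)))
  expect_error(identify_contaminants(nt, c("N1", "N2")), "raw")
})

test_that("contaminant calls equal brute-force enumeration on random fixtures", {
  for (seed in 1:20) {
    tt <- random_table(n_samples = 10, n_taxa = 50, seed = seed,
                       lambda = 4000)
    neg <- sample_ids(tt)[1:4]
    ev <- identify_contaminants(tt, neg)
    # independent oracle: literal per-taxon enumeration
    brute <- vapply(seq_len(ncol(tt$counts)), function(j) {
      pres <- 0L; tot <- 0L
      for (s in neg) {
        x <- tt$counts[s, j]
        if (x > 0) pres <- pres + 1L
        tot <- tot + x
      }
      pres >= 2L && tot > 10000L
    }, logical(1))
    expect_identical(ev$is_contaminant, brute)
  }
})

test_that("taxon removal conserves reads exactly and reports kingdom splits", {
  tt <- random_table(n_samples = 6, n_taxa = 30, seed = 2)
  drop <- tt$taxa$taxid[c(3, 7, 20)]
  res <- remove_taxa(tt, drop)
  expect_equal(res$summary$removed_reads + res$summary$retained_reads,
               res$summary$total_reads)
  expect_equal(unname(sample_totals(res$table)),
               res$summary$retained_reads)
  king <- tt$taxa$kingdom[match(drop, tt$taxa$taxid)]
  expect_equal(res$summary$removed_bacteria + res$summary$removed_fungi,
               res$summary$removed_reads)  # fixture is Bacteria/Fungi only

  ident <- remove_taxa(tt, integer(0))
  expect_equal(ident$table$counts, tt$counts)
  allgone <- remove_taxa(tt, tt$taxa$taxid)
  expect_equal(ncol(allgone$table$counts), 0)
  expect_true(all(allgone$summary$removed_fraction == 1))
})

test_that("removal summary fraction matches the truth-set tally on synthetic data", {
  cm <- clear_margin_sim()
  truth <- cm$sim$truth$contaminant_taxids
  res <- remove_taxa(cm$air_table, truth)
  is_con <- cm$air_table$taxa$taxid %in% truth
  direct <- rowSums(cm$air_table$counts[, is_con, drop = FALSE]) /
    rowSums(cm$air_table$counts)
  expect_equal(unname(res$summary$removed_fraction), unname(direct))
})

test_that("the two-proportion Z statistic matches the closed form and flags degeneracies", {
  r <- prevalence_z_test(90, 100, 10, 20)
  expect_equal(r$pooled_p, 100 / 120)
  expect_equal(r$z, 4.3818, tolerance = 1e-4)  # hand-computed pooled formula
  expect_true(r$passes)

  same <- prevalence_z_test(5, 10, 10, 20)
  expect_equal(same$z, 0)
  expect_false(same$passes)
  expect_equal(same$note, "degenerate")

  wrong_dir <- prevalence_z_test(5, 100, 18, 20)
  expect_lt(wrong_dir$z, 0)
  expect_false(wrong_dir$passes)

  empty <- prevalence_z_test(0, 10, 0, 20)
  expect_false(empty$passes)
  expect_equal(empty$note, "degenerate")

  triv <- prevalence_z_test(10, 10, 0, 20)
  expect_true(triv$passes)
  expect_equal(triv$note, "trivially_greater")
})

test_that("the Z statistic is antisymmetric and exact against the formula", {
  set.seed(5)
  for (i in 1:50) {
    n1 <- sample(5:200, 1); n2 <- sample(5:50, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    r <- prevalence_z_test(x1, n1, x2, n2)
    if (r$note != "ok") next
    p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
    zref <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    expect_equal(r$z, zref, tolerance = 1e-12)
    swapped <- prevalence_z_test(x2, n2, x1, n1)
    expect_equal(swapped$z, -r$z, tolerance = 1e-12)
  }
})

test_that("the prevalence gate re-admits genuine air species while contaminants are removed first", {
  cfg <- clear_margin_config(seed = 6, n_contaminants_in_air = 3)
  sim <- generate_synthetic(cfg)
  md <- sim$metadata
  neg <- md$sample_id[md$sample_type %in% c("field_negative", "lab_negative")]
  air <- md$sample_id[md$sample_type == "air"]
  ev <- identify_contaminants(sim$table, neg)
  # exclusion-first: air-resident contaminants are still called and removed
  expect_true(all(sim$truth$contaminants_in_air_taxids %in%
                    ev$taxid[ev$is_contaminant]))
  gate <- prevalence_gate(sim$table, air, neg)
  # contaminants present in (nearly) all negatives never pass the gate
  called <- gate[gate$taxid %in% sim$truth$contaminant_taxids, ]
  expect_true(all(!called$passes | called$prev_neg < called$prev_air))
  # planted core species pass: ubiquitous in air, sparse in negatives
  core1 <- sim$truth$city_core_taxids[[1]]
  g1 <- gate[gate$taxid %in% core1, ]
  expect_true(all(g1$passes))
})

test_that("cross-contamination verdicts require embedding candidacy plus both metadata signals", {
  # two tight city clusters; one Oslo-labelled sample sits inside the London cluster
  set.seed(8)
  n <- 12
  coords <- rbind(matrix(rnorm(2 * n, 0, 0.1), ncol = 2),
                  matrix(rnorm(2 * n, 10, 0.1), ncol = 2))
  ids <- sprintf("s%02d", seq_len(2 * n))
  rownames(coords) <- ids
  meta <- data.frame(sample_id = ids,
                     city = c(rep("Oslo", n), rep("London", n)),
                     dna_below_detection = FALSE,
                     plate_position = sprintf("P1:%s%02d",
                                              rep(LETTERS[1:3], each = 8),
                                              rep(1:8, 3)),
                     stringsAsFactors = FALSE)
  # own-city neighbourhood: no flags
  expect_equal(nrow(flag_cross_contamination(coords, meta, k = 5)), 0)

  # move one Oslo sample into the London cluster: candidate, retained
  coords["s01", ] <- c(10, 10)
  fl <- flag_cross_contamination(coords, meta, k = 5)
  expect_equal(fl$sample_id, "s01")
  expect_equal(fl$embedded_neighbor_city, "London")
  expect_equal(fl$verdict, "retain")

  # below-detection DNA alone still retains
  meta$dna_below_detection[1] <- TRUE
  meta$plate_position[1] <- "P2:A01"  # different plate: not adjacent
  expect_equal(flag_cross_contamination(coords, meta, k = 5)$verdict, "retain")

  # both signals: excluded
  meta$plate_position[1] <- "P1:B04"  # adjacent to London wells on plate 1
  meta$plate_position[13] <- "P1:B05"
  fl <- flag_cross_contamination(coords, meta, k = 5)
  expect_equal(fl$verdict, "exclude")
  expect_true(fl$dna_below_detection && fl$plate_adjacent_to_neighbor_city)
})
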