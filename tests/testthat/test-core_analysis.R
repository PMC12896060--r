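flat_table <- function(rel, n_samples, depth = 1e5) {
  # every sample identical, taxon j at relative abundance rel[j]
  row <- as.integer(round(rel * depth))
  counts <- matrix(rep(row, each = n_samples), nrow = n_samples,
                   dimnames = list(sprintf("s%02d", seq_len(n_samples)), NULL))
  taxa <- data.frame(taxid = seq_along(rel), name = paste0("t", seq_along(rel)),
                     rank = "species", kingdom = "Bacteria")
  taxon_table(counts, taxa)
}

test_that("presence at an abundance level thresholds within-sample relative abundance", {
  tt <- flat_table(c(0.01, 0.004, 0.986), n_samples = 5)
  p <- species_prevalence(tt, abundance_level = 0.005)
  expect_equal(p$prevalence, c(1, 0, 1))  # 1% in, 0.4% out at the 0.5% level
  p2 <- species_prevalence(tt, abundance_level = 0.05)
  expect_equal(p2$prevalence, c(0, 0, 1))
  expect_equal(p$mean_abundance, c(0.01, 0.004, 0.986), tolerance = 1e-12)
})

test_that("a 48-sample fixture with one absence gives prevalence 47/48", {
  tt <- flat_table(c(0.5, 0.5), n_samples = 48)
  counts <- tt$counts
  counts[1, 1] <- 0L
  tt <- taxon_table(counts, tt$taxa)
  p <- species_prevalence(tt, abundance_level = 5e-5)
  expect_equal(p$prevalence[1], 47 / 48)
  expect_equal(round(p$prevalence[1], 4), 0.9792)
})

test_that("tier assignment honours strict core and closed sub-core boundaries and the gate", {
  prof <- data.frame(taxid = 1:4, name = paste0("t", 1:4), kingdom = "Bacteria",
                     abundance_level = 5e-5,
                     n_present = c(98, 98, 97, 60), n_samples = 100,
                     prevalence = c(0.98, 0.98, 0.97, 0.60),
                     mean_abundance = c(0.1, 0.1, 0.05, 0.01))
  gate <- data.frame(taxid = 1:4, passes = c(TRUE, FALSE, TRUE, TRUE))
  rep <- assign_tiers(prof, gate = gate)
  tier <- setNames(rep$tier, rep$taxid)
  expect_equal(tier[["1"]], "core")
  expect_equal(tier[["2"]], "none")      # gated out despite prevalence 0.98
  expect_equal(tier[["3"]], "sub_core")  # exactly 0.97 falls in the sub-core
  expect_equal(tier[["4"]], "none")
  # tiers partition the taxa
  expect_true(all(rep$tier %in% c("core", "sub_core", "none")))
})

test_that("local cores recover the planted city core sets exactly", {
  cm <- clear_margin_sim()
  lc <- local_cores(cm$decontaminated, cm$metadata, gate = cm$gate)
  for (city in names(cm$sim$truth$city_core_taxids)) {
    expect_identical(sort(lc[[city]]$taxid[lc[[city]]$tier == "core"]),
                     sort(cm$sim$truth$city_core_taxids[[city]]),
                     label = paste("core set for", city))
  }
  # a species confined to one city is core nowhere else
  core1 <- cm$sim$truth$city_core_taxids[[1]]
  other <- names(lc)[-1]
  for (city in other) {
    expect_false(any(core1 %in% lc[[city]]$taxid[lc[[city]]$tier == "core"]))
  }
  # no global core with disjoint city pools
  gl <- assign_tiers(species_prevalence(cm$decontaminated), gate = cm$gate)
  expect_equal(sum(gl$tier == "core"), 0)
})

test_that("cities with fewer than two samples are rejected for local cores", {
  cm <- clear_margin_sim()
  keep <- c(cm$air_ids[1], cm$air_ids[cm$metadata$city[
    match(cm$air_ids, cm$metadata$sample_id)] != cm$metadata$city[
      match(cm$air_ids[1], cm$metadata$sample_id)]])
  tab <- subset_table(cm$decontaminated, samples = keep)
  expect_error(local_cores(tab, cm$metadata), "< 2 samples")
})

test_that("coverage subsetting is strict and warns on missing coverage", {
  tt <- flat_table(c(0.4, 0.6), n_samples = 10)
  md <- data.frame(sample_id = sample_ids(tt),
                   city = "x", year = 2018, sample_type = "air",
                   nonpareil_coverage = c(0.50, 0.51, 0.7, 0.9, 0.3, 0.2,
                                          0.55, NA, 0.49, 0.62))
  expect_warning(sub <- coverage_subset(tt, md), "missing")
  expect_setequal(sample_ids(sub), c("s02", "s03", "s04", "s07", "s10"))
  expect_false("s01" %in% sample_ids(sub))  # exactly 0.50 excluded
})

test_that("contaminant tiers count presence before removal without the gate", {
  tt <- flat_table(c(0.2, 0.3, 0.5), n_samples = 20)
  counts <- tt$counts
  counts[1:5, 2] <- 0L   # taxon 2 in 75% of samples
  counts[1:15, 3] <- 0L
  tt <- taxon_table(counts, tt$taxa)
  rep <- contaminant_core(tt, contaminant_taxids = 1:3)
  tier <- setNames(rep$tier, rep$taxid)
  expect_equal(tier[["1"]], "core")
  expect_true(rep$ubiquitous[rep$taxid == 1])
  expect_equal(tier[["2"]], "sub_core")
  expect_equal(tier[["3"]], "none")
  # oracle: brute-force presence counts
  expect_equal(rep$n_present[order(rep$taxid)],
               unname(colSums(counts > 0)))
})

test_that("prevalence and core-set size are monotone in the abundance level", {
  cm <- clear_margin_sim()
  levels <- c(5e-5, 0.003, 0.005, 0.01)
  profs <- lapply(levels, function(lv)
    species_prevalence(cm$decontaminated, abundance_level = lv))
  for (i in seq_len(length(levels) - 1)) {
    expect_true(all(profs[[i]]$prevalence >= profs[[i + 1]]$prevalence))
    expect_gte(sum(profs[[i]]$prevalence > 0.97),
               sum(profs[[i + 1]]$prevalence > 0.97))
  }
  curve <- prevalence_curve(cm$decontaminated, abundance_levels = levels)
  for (lv in levels) {
    sub <- curve[curve$abundance_level == lv, ]
    expect_true(all(diff(sub$n_species) <= 0))
  }
  # 0 threshold counts all species observed at the level; >1 counts none
  wide <- prevalence_curve(cm$decontaminated, abundance_levels = 5e-5,
                           thresholds = c(0, 1.01))
  expect_equal(wide$n_species[1],
               sum(profs[[1]]$n_present > 0))
  expect_equal(wide$n_species[2], 0)
})

test_that("coverage subsetting reduces prevalence and raises mean abundance qualitatively", {
  # low-depth samples make noisier presence calls: drop them and sub-core
  # membership shrinks while detected species' mean abundance grows
  cfg <- clear_margin_config(seed = 13, depth_sdlog = 1.2,
                             samples_per_city_year = 10)
  sim <- generate_synthetic(cfg)
  md <- sim$metadata
  air <- md$sample_id[md$sample_type == "air"]
  airtab <- subset_table(sim$table, samples = air)
  hi <- coverage_subset(airtab, md, min_coverage = 0.5)
  p_all <- species_prevalence(airtab, abundance_level = 0.005)
  p_hi <- species_prevalence(hi, abundance_level = 0.005)
  shared <- intersect(p_all$taxid[p_all$n_present > 0],
                      p_hi$taxid[p_hi$n_present > 0])
  expect_lt(nrow(hi$counts), nrow(airtab$counts))
  expect_gte(mean(p_hi$mean_abundance[match(shared, p_hi$taxid)]),
             mean(p_all$mean_abundance[match(shared, p_all$taxid)]))
})
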