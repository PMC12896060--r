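# generator configuration with unambiguous margins: every planted
# contaminant far exceeds the negatives read rule, no contaminant is a
# genuine air-pool member, and planted cores sit well above the base
# abundance level -- the regime in which recovery must be exact
clear_margin_config <- function(seed = 1L, ...) {
  defaults <- list(n_contaminants = 15, n_contaminants_in_air = 0,
                   depth_meanlog = log(2e6), abundance_shape = 1.0,
                   samples_per_city_year = 6, n_cities = 4,
                   n_species_shared = 60, n_species_city_specific = 20,
                   core_species_per_city = 6,
                   negative_background_fraction = 0.005, seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# heavier objects shared across test files, built once per run
.cache <- new.env(parent = emptyenv())
cached <- function(key, make) {
  if (!exists(key, envir = .cache)) assign(key, make(), envir = .cache)
  get(key, envir = .cache)
}

# study-condition simulation with a planted humidity effect, decontaminated
humidity_sim <- function() {
  cached("humidity_sim", function() {
    cfg <- synthetic_config(samples_per_city_year = 8, n_cities = 5,
                            humidity_effect_size = 8, seed = 3)
    sim <- generate_synthetic(cfg)
    md <- sim$metadata
    neg <- md$sample_id[md$sample_type %in% c("field_negative", "lab_negative")]
    air <- md$sample_id[md$sample_type == "air"]
    ev <- identify_contaminants(sim$table, neg)
    dec <- remove_taxa(abundance_threshold_filter(
      subset_table(sim$table, samples = air)), ev$taxid[ev$is_contaminant])
    scores <- pca_scores(log_transform(normalize_counts(dec$table)), k = 10)
    list(sim = sim, metadata = md, decontaminated = dec$table,
         scores = scores)
  })
}

# the clear-margin simulation and its decontaminated air table
clear_margin_sim <- function() {
  cached("clear_margin_sim", function() {
    sim <- generate_synthetic(clear_margin_config(seed = 1L))
    md <- sim$metadata
    neg <- md$sample_id[md$sample_type %in% c("field_negative", "lab_negative")]
    air <- md$sample_id[md$sample_type == "air"]
    ev <- identify_contaminants(sim$table, neg)
    airtab <- subset_table(sim$table, samples = air)
    filt <- abundance_threshold_filter(airtab)
    dec <- remove_taxa(filt, ev$taxid[ev$is_contaminant])
    gate <- prevalence_gate(sim$table, air, neg)
    list(sim = sim, metadata = md, neg_ids = neg, air_ids = air,
         evidence = ev, air_table = airtab, decontaminated = dec$table,
         removal = dec$summary, gate = gate)
  })
}
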