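#!/usr/bin/env Rscript
# Step 5 -- core microbiome inference: global and per-city species
# prevalence at four abundance levels (0.005%, 0.3%, 0.5%, 1%), tiering
# (core > 97%, sub-core 70-97%) under the negatives prevalence gate, the
# high-coverage (> 50% Nonpareil) rerun, and the contaminant core tables.

library(aerocore)

tab <- read_table("results/clean_counts.tsv")
full <- read_table("results/data/counts.tsv")
md <- read_metadata("results/data/metadata.tsv")
gate <- read.delim("results/prevalence_gate.tsv")
contam <- read_contaminants("results/contaminants.tsv")
air <- md$sample_id[md$sample_type == "air"]

levels <- c(5e-5, 0.003, 0.005, 0.01)
global <- do.call(rbind, lapply(levels, function(lv) {
  rep <- assign_tiers(species_prevalence(tab, abundance_level = lv),
                      gate = gate)
  cbind(scope = "global", rep)
}))
base <- global[global$abundance_level == 5e-5, ]
message("global core: ", sum(base$tier == "core"), " species; sub-core: ",
        sum(base$tier == "sub_core"), " species (base abundance level)")

hi <- coverage_subset(tab, md, min_coverage = 0.5)
hi_rep <- assign_tiers(species_prevalence(hi, abundance_level = 5e-5),
                       gate = gate)
message("high-coverage subset (", nrow(hi$counts), " samples): sub-core ",
        sum(hi_rep$tier == "sub_core"), " species")

locals <- local_cores(tab, md, gate = gate)
local_df <- do.call(rbind, lapply(names(locals), function(city)
  cbind(scope = paste0("city:", city), locals[[city]])))
for (city in names(locals)) {
  message("local core, ", city, ": ",
          sum(locals[[city]]$tier == "core"), " species")
}

ccore <- contaminant_core(subset_table(full, samples = air), contam$taxid)
message("contaminant tiers over all air samples before removal: ",
        sum(ccore$tier == "core"), " core (",
        sum(ccore$ubiquitous), " ubiquitous), ",
        sum(ccore$tier == "sub_core"), " sub-core")

curve <- prevalence_curve(tab, abundance_levels = levels)

write.table(rbind(global, local_df, cbind(scope = "contaminant", ccore)),
            "results/core_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(scope = "coverage>0.5", hi_rep),
            "results/core_report_high_coverage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(curve, "results/prevalence_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/{core_report,core_report_high_coverage,prevalence_curve}.tsv")
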