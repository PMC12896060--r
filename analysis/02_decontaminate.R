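#!/usr/bin/env Rscript
# Step 2 -- identify exogenous contaminants from the pooled negative
# controls (>= 2 negatives, > 10,000 reads), remove them from the air
# samples after the 0.005% abundance filter, and compute the per-taxon
# prevalence gate reused by the core analyses.

library(aerocore)

tab <- read_table("results/data/counts.tsv")
md <- read_metadata("results/data/metadata.tsv")
neg <- md$sample_id[md$sample_type %in% c("field_negative", "lab_negative")]
air <- md$sample_id[md$sample_type == "air"]

evidence <- identify_contaminants(tab, neg)
called <- evidence$taxid[evidence$is_contaminant]
message(sum(evidence$is_contaminant), " of ", nrow(evidence),
        " taxa called contaminant (",
        sum(evidence$is_contaminant & evidence$kingdom == "Bacteria"),
        " bacterial, ",
        sum(evidence$is_contaminant & evidence$kingdom == "Fungi"), " fungal)")

air_tab <- abundance_threshold_filter(subset_table(tab, samples = air))
dec <- remove_taxa(air_tab, called)
message("mean contaminant read fraction in air samples: ",
        round(100 * mean(dec$summary$removed_fraction), 1), "% (range ",
        round(100 * min(dec$summary$removed_fraction), 1), "-",
        round(100 * max(dec$summary$removed_fraction), 1), "%)")

gate <- prevalence_gate(tab, air, neg)

dir.create("results", showWarnings = FALSE)
write_contaminants(evidence[evidence$is_contaminant, ],
                   "results/contaminants.tsv")
write_table(dec$table, "results/clean_counts.tsv")
write.table(dec$summary, "results/removal_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gate, "results/prevalence_gate.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/{contaminants,clean_counts,removal_summary,prevalence_gate}.tsv")
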