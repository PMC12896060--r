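#!/usr/bin/env Rscript
# Step 1 -- generate the synthetic multi-city aerobiome dataset.
# Emits the merged species count table, sample metadata and planted truth
# under results/data/, in the same TSV dialects the loaders read.

library(aerocore)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 101)
sim <- generate_synthetic(cfg)

write_table(sim$table, file.path(out_dir, "counts.tsv"))
write_metadata(sim$metadata, file.path(out_dir, "metadata.tsv"))
saveRDS_path <- file.path(out_dir, "truth.json")
jsonlite::write_json(list(
  contaminant_taxids = sim$truth$contaminant_taxids,
  contaminants_in_air_taxids = sim$truth$contaminants_in_air_taxids,
  city_core_taxids = sim$truth$city_core_taxids),
  saveRDS_path, auto_unbox = FALSE)

n_air <- sum(sim$metadata$sample_type == "air")
n_neg <- sum(sim$metadata$sample_type %in% c("field_negative", "lab_negative"))
message("simulated ", n_air, " air samples across ",
        length(unique(sim$metadata$city[sim$metadata$sample_type == "air"])),
        " cities and ", length(cfg$years), " years, plus ", n_neg,
        " negative controls")
message("planted ", length(sim$truth$contaminant_taxids),
        " contaminant taxa at a mean read fraction of ",
        cfg$contaminant_read_fraction_mean)
message("wrote ", out_dir, "/{counts.tsv,metadata.tsv,truth.json}")
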