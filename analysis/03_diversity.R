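#!/usr/bin/env Rscript
# Step 3 -- normalization (1e7 reads/sample), log10(x+1) transform, alpha
# diversity with Tukey HSD letters per city, UMAP beta-diversity
# ordination, cross-contamination review, and abundance summaries.

library(aerocore)

tab <- read_table("results/clean_counts.tsv")
md <- read_metadata("results/data/metadata.tsv")
meta_air <- md[match(sample_ids(tab), md$sample_id), ]

lg <- log_transform(normalize_counts(tab))

h <- shannon_index(tab)
tl <- tukey_letters(h, meta_air$city)
message("Shannon H by city (groups sharing a letter are not significantly different):")
for (i in seq_len(nrow(tl$letters))) {
  message(sprintf("  %-12s H = %.3f  %s", tl$letters$group[i],
                  tl$letters$mean[i], tl$letters$letters[i]))
}

emb <- embed_samples(lg, method = "umap", seed = 42)
purity <- knn_purity(emb, meta_air$city)
message("UMAP city k-NN purity: ", round(purity, 3))

flags <- flag_cross_contamination(emb, md)
message(nrow(flags), " cross-contamination candidate(s); excluded: ",
        sum(flags$verdict == "exclude"))

king <- relative_abundance(tab, md, grouping = "per_city", level = "kingdom")
spec <- relative_abundance(tab, md, grouping = "total", level = "species")

write.table(data.frame(sample_id = names(h), shannon = h),
            "results/alpha_diversity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tl$letters, "results/tukey_letters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(emb), emb),
            "results/umap_embedding.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(flags, "results/cross_contamination.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(rbind(king, spec), "results/relative_abundance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/{alpha_diversity,tukey_letters,umap_embedding,",
        "cross_contamination,relative_abundance}.tsv")
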