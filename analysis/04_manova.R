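#!/usr/bin/env Rscript
# Step 4 -- significance of city, year, environmental and human factors:
# top-10 PC scores of the log table as dependent variables, covariates
# binarised (25 degC / 65% RH / 100 travellers), forward-stepwise MANOVA
# on Pillai's trace at the 0.001 inclusion threshold with CITY
# interactions for environmental terms.

library(aerocore)

tab <- read_table("results/clean_counts.tsv")
md <- read_metadata("results/data/metadata.tsv")

pc <- pca_scores(log_transform(normalize_counts(tab)), k = 10)
message("top 10 PCs explain ",
        round(100 * pc$total_variance_explained, 1), "% of variance")

model <- manova_forward_select(pc$scores, md)
print(model)

write.table(model$steps, "results/manova_steps.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(model$terms, "results/manova_terms.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote results/{manova_steps,manova_terms}.tsv")
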