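#!/usr/bin/env Rscript
# Step 6: asymmetry catalogue.
#
# Combines the two 8-cell experiments into the catalogue of
# asymmetrically distributed RNAs (union of the four directional sets
# with overlap bookkeeping), checks cross-experiment consistency, and
# assigns each member a temporal group against the early-vs-late classes.

suppressMessages(library(asymma))

out <- "results"
ecto <- read_tsv_schema(file.path(out, "results_ecto.tsv"), schema = "results")
meso <- read_tsv_schema(file.path(out, "results_meso.tsv"), schema = "results")
el <- read_tsv_schema(file.path(out, "results_early_late.tsv"),
                      schema = "results")
cls <- read_tsv_schema(file.path(out, "classification.tsv"),
                       schema = "classification")

cat6 <- build_catalogue(ecto, meso, alpha = 0.05)
cat6 <- classify_temporal(cat6, el, cls)
cons <- consistency_check(cat6)

s <- cat6$summary
message("directional sets: ", paste(names(s$set_sizes), s$set_sizes,
                                    sep = "=", collapse = ", "))
message("raw sum ", s$raw_sum, ", found in both ", s$n_found_in_both,
        ", union ", s$union_size)
message("temporal groups: ", paste(names(s$group_sizes),
                                   as.vector(s$group_sizes),
                                   sep = "=", collapse = ", "))
message(sprintf("max early-late fold change in catalogue: %.1f-fold",
                s$max_fold_change))
message(sprintf("cross-experiment consistency: %d/%d ecto-enriched, %d/%d meso-enriched confirmed",
                length(cons$ecto_enriched_confirmed), cons$n_ecto_enriched,
                length(cons$meso_enriched_confirmed), cons$n_meso_enriched))
write_tsv_schema(cat6$table, file.path(out, "catalogue.tsv"),
                 schema = "catalogue")
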