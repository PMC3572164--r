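#!/usr/bin/env Rscript
# Step 7: GO-term overrepresentation.
#
# Fisher's exact overrepresentation of GO terms in the maternally
# enriched set and in the asymmetry catalogue, each against the full
# target universe, with the fold-overrepresentation statistic.

suppressMessages(library(asymma))

out <- "results"
ann <- read_tsv_schema("results/sim/annotation.tsv", schema = "annotation")
cls <- read_tsv_schema(file.path(out, "classification.tsv"),
                       schema = "classification")
cat7 <- read_tsv_schema(file.path(out, "catalogue.tsv"), schema = "catalogue")

universe <- cls$target_id
for (set in list(
  list(name = "maternal", ids = cls$target_id[cls$class == "maternal_enriched"]),
  list(name = "asymmetric", ids = cat7$target_id))) {
  res <- fisher_enrich(set$ids, universe, ann, alpha = 0.05)
  write_tsv_schema(res, file.path(out, paste0("go_", set$name, ".tsv")),
                   schema = "enrichment")
  message(set$name, ": ", sum(res$significant), " of ", nrow(res),
          " terms overrepresented at p < 0.05")
}
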