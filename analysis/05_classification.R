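#!/usr/bin/env Rscript
# Step 5: expression threshold and maternal/zygotic classes.
#
# Derives the expression A-cutoff (antisense control mean + 3 SD) from the
# early-vs-late experiment and classifies every target as maternally
# enriched, zygotically enriched, equally expressed or unexpressed.

suppressMessages(library(asymma))

out <- "results"
el <- read_tsv_schema(file.path(out, "results_early_late.tsv"),
                      schema = "results")
ctrl <- read_tsv_schema(file.path(out, "control_A.tsv"))

th <- derive_threshold(ctrl$A, sd_multiplier = 3)
message(sprintf("control mean A = %.2f, SD = %.2f -> cutoff %.2f",
                th$control_mean, th$control_sd, th$cutoff))

expressed <- classify_expressed(el, th)
cls <- classify_maternal_zygotic(el, expressed)
write_tsv_schema(cls, file.path(out, "classification.tsv"),
                 schema = "classification",
                 provenance = sprintf("a_cutoff: %.4f", th$cutoff))
counts <- table(cls$class)
message(sum(expressed$expressed), " expressed targets; ",
        counts[["maternal_enriched"]], " maternally enriched, ",
        counts[["zygotic_enriched"]], " zygotically enriched, ",
        counts[["equal"]], " equal; ",
        sum(expressed$low_expressed_significant),
        " significant but below the A-cutoff")
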