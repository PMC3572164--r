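#!/usr/bin/env Rscript
# Step 4: moderated differential expression.
#
# Collapses technical replicates, fits the oriented one-sample linear
# model per target, applies empirical-Bayes moderation (1% prior
# proportion of differentially expressed targets) and the
# Benjamini-Yekutieli correction. Writes one results table per experiment
# in the (logFC, AveExpr, t, P.Value, adj.P.Val, B) layout.

suppressMessages(library(asymma))

out <- "results"
for (e in c("early_late", "ecto", "meso")) {
  tab <- read_tsv_schema(file.path(out, paste0("expression_", e, ".tsv")))
  design <- read_tsv_schema(file.path(out, paste0("design_kept_", e, ".tsv")),
                            schema = "design")
  M <- as.matrix(tab[, paste0("M_", design$array_id)])
  A <- as.matrix(tab[, paste0("A_", design$array_id)])
  dimnames(M) <- dimnames(A) <- list(tab$target_id, design$array_id)
  fit <- fit_experiment(list(M = M, A = A, design = design))
  res <- fit$table[, c("target_id", "logFC", "AveExpr", "t", "P.Value",
                       "adj.P.Val", "B")]
  write_tsv_schema(res, file.path(out, paste0("results_", e, ".tsv")),
                   schema = "results",
                   provenance = sprintf("prior d0: %.3f; prior s2: %.5f",
                                        fit$prior$d0, fit$prior$s02))
  calls <- call_significant(fit, 0.05)
  message(e, ": ", length(calls$up), " enriched / ", length(calls$down),
          " depleted at adjusted p < 0.05")
}
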