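#!/usr/bin/env Rscript
# Step 1: simulate the study.
#
# Generates one synthetic three-experiment study at a 2000-target scale
# (kept below the 6386-target array so the whole workflow reruns in a few
# minutes): probe-level two-color scans for the early-vs-late, ectoderm-
# vs-rest and mesoderm-vs-rest experiments, plus target/probe/EST
# sequences with 25 planted cross-hybridizing probes and 10 EST-rescuable
# probes, and a synthetic GO annotation. Everything is written as plain
# TSV/FASTA under results/sim/.

suppressMessages(library(asymma))

seed <- 101
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_study(2000, seed = seed)
prov <- sprintf("seed: %d", seed)

write_tsv_schema(study$truth, file.path(out, "truth.tsv"),
                 schema = "truth", provenance = prov)
write_tsv_schema(study$annotation, file.path(out, "annotation.tsv"),
                 schema = "annotation", provenance = prov)

for (e in names(study$experiments)) {
  sim <- study$experiments[[e]]
  write_tsv_schema(sim$design, file.path(out, paste0("design_", e, ".tsv")),
                   schema = "design", provenance = prov)
  for (a in names(sim$scans))
    write_tsv_schema(sim$scans[[a]], file.path(out, paste0("scan_", a, ".tsv")),
                     schema = "scan", provenance = prov)
  message(e, ": ", length(sim$scans), " arrays, ",
          nrow(sim$scans[[1]]), " spots/array")
}

# sequences are tied to the early-late experiment's probe set; the three
# experiments share the physical array design in spirit, so one FASTA set
# serves the mapping step
probes <- study$experiments$early_late$probes
seqs <- generate_sequences(probes, n_crosshyb = 25, n_rescue = 10,
                           seed = seed + 1)
write_fasta(seqs$targets, file.path(out, "targets.fasta"))
write_fasta(seqs$probes, file.path(out, "probes.fasta"))
write_fasta(seqs$ests, file.path(out, "ests.fasta"))
write_tsv_schema(seqs$est_membership, file.path(out, "est_membership.tsv"),
                 schema = "est_membership", provenance = prov)
write_tsv_schema(seqs$probe_info, file.path(out, "probe_info.tsv"),
                 provenance = prov)

message("planted truth: ",
        sum(study$truth$class_label == "maternal_degraded"), " maternal, ",
        sum(study$truth$class_label == "zygotic"), " zygotic, ",
        sum(study$truth$class_label == "constant"), " constant, ",
        sum(study$truth$asymmetric), " asymmetric")
message("wrote ", out)
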