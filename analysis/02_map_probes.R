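#!/usr/bin/env Rscript
# Step 2: map probes to targets.
#
# Maps every probe oligo against the target contigs (Hamming distance <= 2,
# both strands), discards cross-hybridizing probes, then re-maps the
# non-unique and unmapped probes against the raw ESTs to rescue probes
# whose sequence was trimmed during contig assembly ("_ext" targets).
# Writes the retained probe-target map used by all later steps.

suppressMessages(library(asymma))

sim <- "results/sim"
probes <- read_fasta(file.path(sim, "probes.fasta"))
targets <- read_fasta(file.path(sim, "targets.fasta"))
ests <- read_fasta(file.path(sim, "ests.fasta"))
memb <- read_tsv_schema(file.path(sim, "est_membership.tsv"),
                        schema = "est_membership")
info <- read_tsv_schema(file.path(sim, "probe_info.tsv"))

map <- map_probes(probes, targets, max_mismatches = 2,
                  control_probes = info$probe_id[info$is_control])
flt <- filter_cross_hybridizing(map)
message("first round: ", flt$counts[["retained"]], " retained, ",
        flt$counts[["discarded"]], " discarded as cross-hybridizing, ",
        flt$counts[["unmapped"]], " unmapped, ",
        flt$counts[["controls"]], " antisense controls")

second <- c(flt$discarded, flt$unmapped)
rescued <- rescue_second_round(probes[second], ests, memb,
                               max_mismatches = 2)
message("second round: ", nrow(rescued), " probes rescued to _ext targets")

retained <- rbind(
  cbind(flt$retained[, c("probe_id", "target_id", "position", "strand",
                         "mismatches", "uniqueness")]),
  rescued[, c("probe_id", "target_id", "position", "strand",
              "mismatches", "uniqueness")])
controls <- flt$controls
controls$uniqueness <- "control"
out_map <- rbind(retained,
                 controls[!is.na(controls$target_id),
                          c("probe_id", "target_id", "position", "strand",
                            "mismatches", "uniqueness")])
write_tsv_schema(out_map, file.path(sim, "probe_map.tsv"), schema = "map",
                 provenance = sprintf("max_mismatches: %d", 2))
message("wrote ", file.path(sim, "probe_map.tsv"))
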