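test_that("exact planted probes map uniquely; planted duplicates are multi", {
  targets <- c(t1 = "ACGTACGTAGGCTATTACGGATCGGATTACA",
               t2 = "TTGACCATGGACCATTTACGGACCATGATCA")
  probes <- c(p1 = substr(targets[["t1"]], 3, 14),
              p2 = substr(targets[["t2"]], 5, 16),
              p3 = substr(targets[["t1"]], 10, 21))
  map <- map_probes(probes, targets, max_mismatches = 0)
  expect_setequal(unique(map$uniqueness[map$probe_id %in% c("p1", "p2", "p3")]),
                  "unique")

  # plant p1's sequence into t2 as well -> multi
  targets2 <- targets
  targets2[["t2"]] <- paste0(targets2[["t2"]], probes[["p1"]])
  map2 <- map_probes(probes, targets2, max_mismatches = 0)
  expect_equal(unique(map2$uniqueness[map2$probe_id == "p1"]), "multi")

  expect_error(map_probes(character(0), targets), "empty probe set")
  expect_error(map_probes(c(px = "ACGRACGTACGT"), targets),
               "non-nucleotide")
})

test_that("mapping equals the exhaustive-offset oracle on random instances", {
  set.seed(42)
  for (rep in seq_len(50)) {
    inst <- random_instance(n_probes = sample(5:20, 1),
                            n_targets = sample(2:5, 1))
    mm <- sample(0:3, 1)
    got <- map_probes(inst$probes, inst$targets, max_mismatches = mm)
    got <- got[!is.na(got$target_id),
               c("probe_id", "target_id", "position", "strand", "mismatches")]
    want <- brute_map(inst$probes, inst$targets, mm)
    key <- function(d) sort(with(d, paste(probe_id, target_id, position,
                                          strand, mismatches)))
    expect_identical(key(got), key(want))
  }
})

test_that("strand symmetry: reverse-complementing targets flips strands", {
  set.seed(7)
  inst <- random_instance(12, 4)
  map_f <- map_probes(inst$probes, inst$targets, 1)
  rc <- setNames(revcomp_chr(unlist(inst$targets)), names(inst$targets))
  map_r <- map_probes(inst$probes, rc, 1)
  len <- nchar(inst$probes[1])
  tlen <- nchar(inst$targets[1])
  a <- map_f[!is.na(map_f$target_id), ]
  b <- map_r[!is.na(map_r$target_id), ]
  b$strand <- ifelse(b$strand == "+", "-", "+")
  b$position <- tlen - b$position - len
  key <- function(d) sort(paste(d$probe_id, d$target_id, d$position,
                                d$strand, d$mismatches))
  expect_identical(key(a), key(b))
})

test_that("cross-hybridization filter partitions the probe set", {
  tr <- generate_truth(60, seed = 1)
  sim <- simulate_scan(tr, array_layout(n_antisense_controls = 10),
                       noise_model(), "early_late", seed = 2)
  seqs <- generate_sequences(sim$probes, n_crosshyb = 20, seed = 3)
  ctrl <- seqs$probe_info$probe_id[seqs$probe_info$is_control]
  map <- map_probes(seqs$probes, seqs$targets, max_mismatches = 0,
                    control_probes = ctrl)
  flt <- filter_cross_hybridizing(map)
  # planted cross-hybridizers are exactly the discarded probes
  expect_setequal(flt$discarded,
                  seqs$probe_info$probe_id[seqs$probe_info$planted_crosshyb])
  expect_equal(unname(flt$counts["discarded"]), 20)
  # retained + discarded + unmapped partitions the expression probes
  all_expr <- setdiff(names(seqs$probes), ctrl)
  expect_setequal(c(unique(flt$retained$probe_id), flt$discarded,
                    flt$unmapped), all_expr)
  expect_false(any(flt$discarded %in% flt$retained$probe_id))
  # no retained probe has more than one target
  expect_true(all(tapply(flt$retained$target_id, flt$retained$probe_id,
                         function(x) length(unique(x))) == 1))
  # antisense controls place on the minus strand
  expect_true(all(flt$controls$strand == "-", na.rm = TRUE))

  # with no cross-hybridizers, nothing is discarded
  seqs0 <- generate_sequences(sim$probes, n_crosshyb = 0, seed = 3)
  map0 <- map_probes(seqs0$probes, seqs0$targets, 0, control_probes = ctrl)
  expect_equal(length(filter_cross_hybridizing(map0)$discarded), 0)
})

test_that("second-round rescue recovers probes unique to one contig's ESTs", {
  tr <- generate_truth(30, seed = 5)
  sim <- simulate_scan(tr, array_layout(n_antisense_controls = 0),
                       noise_model(), "early_late", seed = 6)
  seqs <- generate_sequences(sim$probes, n_rescue = 4, seed = 7)
  rescue_ids <- seqs$probe_info$probe_id[seqs$probe_info$planted_rescue]
  add <- rescue_second_round(seqs$probes[rescue_ids], seqs$ests,
                             seqs$est_membership, max_mismatches = 0)
  expect_equal(nrow(add), 4)
  expect_true(all(add$uniqueness == "rescued"))
  expect_true(all(grepl("_ext$", add$target_id)))

  # a probe matching ESTs of two contigs stays discarded
  amb <- Biostrings::DNAStringSet(c(pamb = paste(
    rep("ACGT", 5), collapse = "")))
  ests <- Biostrings::DNAStringSet(c(
    e1 = paste0("TTTT", as.character(amb[[1]]), "GGGG"),
    e2 = paste0("CCCC", as.character(amb[[1]]), "AAAA")))
  memb <- data.frame(est_id = c("e1", "e2"),
                     contig_id = c("c1", "c2"), stringsAsFactors = FALSE)
  expect_equal(nrow(rescue_second_round(amb, ests, memb, 0)), 0)

  # single-contig membership rescues with the _ext suffix
  memb1 <- data.frame(est_id = c("e1", "e2"), contig_id = "c1",
                      stringsAsFactors = FALSE)
  add1 <- rescue_second_round(amb, ests, memb1, 0)
  expect_equal(add1$target_id, "c1_ext")

  # EST without membership: warning, treated as its own singleton target
  expect_warning(
    orphan <- rescue_second_round(amb, ests[1], memb[0, ], 0),
    "membership")
  expect_equal(orphan$target_id, "e1_ext")
})

test_that("assembly summary reports contig/singleton/target arithmetic", {
  memb <- data.frame(
    est_id = paste0("e", 1:10),
    contig_id = c("c1", "c1", "c2", "c2", "c2", paste0("s", 1:5)),
    stringsAsFactors = FALSE)
  s <- assembly_summary(memb)
  expect_equal(unname(s["n_contigs"]), 2)
  expect_equal(unname(s["n_singletons"]), 5)
  expect_equal(unname(s["n_targets"]), 7)
  expect_equal(unname(s["n_ests"]), 10)
})
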