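test_that("truth tables plant the requested class composition", {
  tr <- generate_truth(6386, seed = 1)
  expect_equal(sum(tr$class_label == "maternal_degraded"), 690)
  expect_equal(sum(tr$class_label == "zygotic"), 568)
  expect_equal(sum(tr$class_label == "constant"), 236)
  expect_equal(sum(tr$expressed), 690 + 568 + 236)
  expect_equal(sum(tr$asymmetric), 129)
  # class labels consistent with planted fold changes
  expect_true(all(tr$true_logfc_early_late[tr$class_label ==
                                             "maternal_degraded"] < 0))
  expect_true(all(tr$true_logfc_early_late[tr$class_label == "zygotic"] > 0))
  expect_true(all(tr$true_logfc_early_late[tr$class_label == "constant"] == 0))

  # null case: nothing planted anywhere
  tr0 <- generate_truth(100, frac_maternal = 0, frac_zygotic = 0,
                        frac_constant = 0, frac_asymmetric = 0, seed = 1)
  expect_true(all(tr0$true_logfc_early_late == 0))
  expect_true(all(tr0$true_logfc_ecto == 0))
  expect_true(all(tr0$true_logfc_meso == 0))

  expect_error(generate_truth(10, frac_maternal = 0.7, frac_zygotic = 0.4),
               "sum to more than 1")
  expect_error(generate_truth(10, effect_size = 0), "effect_size")
})

test_that("generation is deterministic in the seed", {
  expect_identical(generate_truth(200, seed = 1), generate_truth(200, seed = 1))
  expect_false(identical(generate_truth(200, seed = 1),
                         generate_truth(200, seed = 2)))
  tr <- generate_truth(50, seed = 3)
  lay <- array_layout(n_antisense_controls = 10)
  s1 <- simulate_scan(tr, lay, noise_model(), "early_late", seed = 9)
  s2 <- simulate_scan(tr, lay, noise_model(), "early_late", seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_scan(tr, lay, noise_model(), "early_late", seed = 10)
  expect_false(identical(s1$scans[[1]]$fg_ch1, s3$scans[[1]]$fg_ch1))
})

test_that("spot intensities honour the planted signal model", {
  # symmetric channels, no distortions: median raw M over spots ~ 0
  tr <- generate_truth(300, frac_maternal = 0, frac_zygotic = 0,
                       frac_constant = 1, frac_asymmetric = 0, seed = 2)
  quiet <- noise_model(bg_mean = 0, bg_sd = 1e-6, dye_bias_amplitude = 0,
                       printtip_curvature_amplitude = 0, array_scale_sd = 0,
                       bio_sd = 0)
  lay <- array_layout(probes_per_target = c("1" = 1),
                      spots_per_probe = c("4" = 1),
                      n_antisense_controls = 20)
  sim <- simulate_scan(tr, lay, quiet, "early_late", seed = 5)
  sc <- sim$scans[[1]]
  expr_spot <- !sim$spots$is_control
  rawM <- log2(sc$fg_ch2[expr_spot] / sc$fg_ch1[expr_spot])
  expect_lt(abs(median(rawM)), 0.1)

  # planted maternal effect of 1: mean raw M (zyg/mat orientation) ~ -1,
  # Monte-Carlo over >= 10^4 spot draws
  tr1 <- generate_truth(400, frac_maternal = 1, frac_zygotic = 0,
                        frac_constant = 0, frac_asymmetric = 0,
                        effect_size = 1, jitter = 0,
                        asym_el_fold_range = NULL, seed = 4)
  lay1 <- array_layout(n_arrays = 8, probes_per_target = c("2" = 1),
                       spots_per_probe = c("2" = 1),
                       n_antisense_controls = 0)
  sim1 <- simulate_scan(tr1, lay1, quiet, "early_late", seed = 6)
  Ms <- unlist(lapply(seq_len(8), function(a) {
    sc <- sim1$scans[[a]]
    m <- log2(sc$fg_ch2 / sc$fg_ch1)
    if (sim1$design$dye_orientation[a] == "swap") -m else m
  }))
  expect_gte(length(Ms), 1e4)
  expect_lt(abs(mean(Ms) - (-1)), 0.05)

  # antisense control spots carry background only: mean foreground ~ mu
  nz <- noise_model(bg_mean = 120, bg_sd = 20)
  tr2 <- generate_truth(100, seed = 8)
  lay2 <- array_layout(n_antisense_controls = 150,
                       spots_per_probe = c("2" = 1))
  sim2 <- simulate_scan(tr2, lay2, nz, "early_late", seed = 12)
  ctrl <- sim2$spots$is_control
  fg <- c(sim2$scans[[1]]$fg_ch1[ctrl], sim2$scans[[1]]$fg_ch2[ctrl])
  expect_lt(abs(mean(fg) - 120), 5)
  expect_lt(abs(sd(fg) - 20), 3)

  expect_error(simulate_scan(tr2, lay2, noise_model(bg_sd = -1)), "bg_sd")
})

test_that("generated sequences embed probes, cross-hybridizers and rescues", {
  tr <- generate_truth(40, seed = 1)
  lay <- array_layout(n_antisense_controls = 8)
  sim <- simulate_scan(tr, lay, noise_model(), "early_late", seed = 2)
  seqs <- generate_sequences(sim$probes, n_crosshyb = 5, n_rescue = 3,
                             seed = 3)
  info <- seqs$probe_info
  expect_equal(sum(info$planted_crosshyb), 5)
  expect_equal(sum(info$planted_rescue), 3)

  # every expression probe is an exact substring of >= 1 target
  expr_ids <- info$probe_id[!info$is_control & !info$planted_rescue]
  tg <- as.character(seqs$targets)
  for (p in expr_ids) {
    hits <- vapply(tg, function(s)
      grepl(as.character(seqs$probes[[p]]), s, fixed = TRUE), logical(1))
    expect_gte(sum(hits), 1)
  }
  # cross-hybridizers occur in >= 2 targets
  for (p in info$probe_id[info$planted_crosshyb]) {
    hits <- vapply(tg, function(s)
      grepl(as.character(seqs$probes[[p]]), s, fixed = TRUE), logical(1))
    expect_gte(sum(hits), 2)
  }
  # rescue probes absent from contigs but present in an EST
  est <- as.character(seqs$ests)
  for (p in info$probe_id[info$planted_rescue]) {
    expect_false(any(vapply(tg, function(s)
      grepl(as.character(seqs$probes[[p]]), s, fixed = TRUE), logical(1))))
    expect_true(any(vapply(est, function(s)
      grepl(as.character(seqs$probes[[p]]), s, fixed = TRUE), logical(1))))
  }
})

test_that("normexp simulation helper matches its stated parameters", {
  d <- simulate_normexp_data(2e4, mu = 80, sigma = 20, alpha = 1 / 300,
                             seed = 1)
  expect_lt(abs(mean(d$bg) - 80), 1)
  expect_lt(abs(sd(d$bg) - 20), 0.5)
  expect_lt(abs(mean(d$signal) - 300), 10)
  expect_error(simulate_normexp_data(10, sigma = 0), "sigma")
})
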