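test_that("normexp correction is positive and recovers known parameters", {
  d <- simulate_normexp_data(1e4, mu = 100, sigma = 25, alpha = 1 / 450,
                             seed = 2)
  res <- normexp_correct(d$fg, d$bg, offset = 50)
  expect_true(all(res$signal > 0))
  # estimated parameters near truth (fg - bg has mean 0, sd sigma*sqrt(2))
  expect_lt(abs(res$par[["sigma"]] - 25 * sqrt(2)) / (25 * sqrt(2)), 0.25)
  expect_lt(abs(res$par[["alpha"]] - 450) / 450, 0.1)
  # corrected means track true signal means within 5%
  expect_lt(abs(mean(res$signal - 50) - mean(d$signal)) / mean(d$signal),
            0.05)
  expect_error(normexp_correct(rep(100, 5), rep(40, 5)), "zero variance")
  expect_error(normexp_correct(1:3, 1:4), "same length")
})

test_that("M/A values follow their definition and dye-swap symmetry", {
  ma <- compute_MA(450, 450)
  expect_equal(ma$M, 0)
  expect_equal(round(ma$A, 1), 8.8)
  expect_equal(compute_MA(100, 200)$M, 1)      # numerator pool doubled
  f <- compute_MA(c(120, 300), c(240, 150), "forward")
  s <- compute_MA(c(120, 300), c(240, 150), "swap")
  expect_equal(s$M, -f$M)
  expect_equal(s$A, f$A)
  expect_error(compute_MA(-1, 10), "positive")
})

test_that("print-tip loess removes planted intensity-dependent bias", {
  # constant M is its own fit: residuals all zero
  set.seed(1)
  A <- runif(500, 6, 14)
  tips <- rep(1:2, length.out = 500)
  expect_equal(printtip_loess(rep(2, 500), A, tips), rep(0, 500),
               tolerance = 1e-8)

  # planted quadratic bias: post-normalization slope of M on A below 0.01
  bias <- 0.5 * ((A - 10) / 4)^2
  M <- bias + rnorm(500, 0, 0.1)
  Mn <- printtip_loess(M, A, tips)
  expect_lt(abs(coef(lm(Mn ~ A))[2]), 0.01)

  # opposite curvature per tip group, flattened independently
  M2 <- ifelse(tips == 1, bias, -bias) + rnorm(500, 0, 0.05)
  Mn2 <- printtip_loess(M2, A, tips)
  for (g in 1:2) {
    i <- tips == g
    expect_lt(abs(coef(lm(Mn2[i] ~ A[i] + I(A[i]^2)))[3]), 0.02)
    expect_lt(abs(mean(Mn2[i])), 0.05)
  }

  # undersized group falls back to whole-array fit with a warning
  expect_warning(printtip_loess(M, A, c(rep(1, 490), rep(2, 10))),
                 "falling back")
})

test_that("A-quantile normalization matches the sort/average/unsort oracle", {
  set.seed(3)
  A <- matrix(rnorm(12, 10), 3, 4)
  expect_equal(aquantile_normalize(A), quantile_norm_oracle(A),
               ignore_attr = TRUE)
  # identical arrays are a fixed point
  same <- matrix(rep(sort(rnorm(10)), 3), 10, 3)
  expect_equal(aquantile_normalize(same), same, ignore_attr = TRUE)
  # per-array quantiles identical to machine precision afterwards
  B <- matrix(rexp(200), 50, 4)
  Bn <- aquantile_normalize(B)
  for (j in 2:4)
    expect_equal(sort(Bn[, j]), sort(Bn[, 1]), tolerance = 1e-12)
  # re-running on its own output changes nothing
  expect_equal(aquantile_normalize(Bn), Bn, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(aquantile_normalize(B[, 1, drop = FALSE]), "two arrays")
})

test_that("replicate-spot averaging is the flag-aware arithmetic mean", {
  sp <- data.frame(probe_id = c("a", "a", "a", "b"),
                   M = c(1, 2, 3, 5), A = c(4, 5, 6, 7),
                   flag = c(0, 0, 0, 0))
  out <- average_replicate_spots(sp)
  expect_equal(out$M[out$probe_id == "a"], 2)
  expect_equal(out$M[out$probe_id == "b"], 5)   # single spot: identity
  # flagged spots excluded before averaging
  sp$flag[3] <- 1
  expect_equal(average_replicate_spots(sp)$M[1], 1.5)
  # random instance equals the plain mean oracle
  set.seed(4)
  sp2 <- data.frame(probe_id = sample(letters[1:5], 60, TRUE),
                    M = rnorm(60), A = rnorm(60), flag = 0)
  out2 <- average_replicate_spots(sp2)
  want <- tapply(sp2$M, factor(sp2$probe_id, unique(sp2$probe_id)), mean)
  expect_equal(out2$M, as.vector(want[out2$probe_id]))
})

test_that("median polish matches the reference implementation", {
  # 1 x n matrix: identity on the probe's values
  m1 <- matrix(c(1.2, -0.5, 3), 1, 3)
  expect_equal(medianpolish_summarize(m1), drop(m1))
  # additive matrix: column effects recovered exactly up to centering
  r <- c(0, 1, 2); cc <- c(5, 6, 7, 8)
  add <- outer(r, cc, "+")
  expect_equal(unname(medianpolish_summarize(add)), cc + median(r))
  # robust to a gross outlier, unlike the mean
  set.seed(5)
  base <- outer(rnorm(4, 0, 0.01), rnorm(5, 2, 0.5), "+")
  dirty <- base; dirty[2, 3] <- dirty[2, 3] + 50
  mp_clean <- medianpolish_summarize(base, eps = 1e-9, maxiter = 50)
  mp_dirty <- medianpolish_summarize(dirty, eps = 1e-9, maxiter = 50)
  expect_lt(max(abs(mp_dirty - mp_clean)), 0.05)
  expect_gt(max(abs(colMeans(dirty) - colMeans(base))), 1)
  # agreement with stats::medpolish on 100 random matrices
  for (i in seq_len(100)) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    z <- matrix(rnorm(nr * nc), nr, nc)
    ref <- stats::medpolish(z, eps = 1e-9, maxiter = 200, trace.iter = FALSE)
    got <- median_polish(z, eps = 1e-9, maxiter = 200)
    expect_equal(got$overall, ref$overall, tolerance = 1e-6)
    expect_equal(got$col, ref$col, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(got$row, ref$row, tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_warning(medianpolish_summarize(matrix(c(NA, NA, 1, 2), 2, 2,
                                               byrow = TRUE)),
                 "all-missing")
})

test_that("array QC flags a corrupted array and keeps sound ones", {
  study <- small_study(seed = 21)
  sim <- study$experiments$early_late
  # corrupt one array: replace intensities with pure noise
  sc <- sim$scans[[3]]
  set.seed(9)
  sc$fg_ch1 <- runif(nrow(sc), 0, 65000)
  sc$fg_ch2 <- runif(nrow(sc), 0, 65000)
  sim$scans[[3]] <- sc
  pm <- sim$probes[!sim$probes$is_control, c("probe_id", "target_id")]
  ctrl <- sim$probes$probe_id[sim$probes$is_control]
  expect_message(
    expr <- preprocess_experiment(sim$scans, sim$design, pm, ctrl),
    "failing QC")
  expect_false("early_late_a3" %in% colnames(expr$M))
  expect_equal(ncol(expr$M), 7)
  expect_equal(nrow(expr$design), 7)
})

test_that("dye-swap arrays agree after orientation resolution", {
  study <- small_study(seed = 31)
  run_expr <- preprocess_experiment(
    study$experiments$early_late$scans,
    study$experiments$early_late$design,
    study$experiments$early_late$probes[
      !study$experiments$early_late$probes$is_control,
      c("probe_id", "target_id")],
    study$experiments$early_late$probes$probe_id[
      study$experiments$early_late$probes$is_control])
  fwd <- run_expr$design$dye_orientation == "forward"
  m_f <- rowMeans(run_expr$M[, fwd, drop = FALSE], na.rm = TRUE)
  m_s <- rowMeans(run_expr$M[, !fwd, drop = FALSE], na.rm = TRUE)
  planted <- study$truth$true_logfc_early_late[
    match(rownames(run_expr$M), study$truth$target_id)]
  keep <- study$truth$expressed[match(rownames(run_expr$M),
                                      study$truth$target_id)]
  # both orientations estimate the same biology
  expect_gt(cor(m_f[keep], m_s[keep]), 0.8)
  expect_lt(abs(mean(m_f[keep] - m_s[keep])), 0.2)
})
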