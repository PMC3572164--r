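make_expr <- function(M, A = NULL, bio_rep = NULL) {
  if (is.null(A)) A <- matrix(10, nrow(M), ncol(M), dimnames = dimnames(M))
  if (is.null(bio_rep)) bio_rep <- seq_len(ncol(M))
  list(M = M, A = A,
       design = data.frame(array_id = colnames(M) %||%
                             as.character(seq_len(ncol(M))),
                           bio_rep = bio_rep))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the oriented one-sample fit gives closed-form estimates", {
  M <- rbind(t1 = c(1, 1, 1, 1), t2 = c(0.8, 1.2, 1.0, 1.0))
  colnames(M) <- paste0("a", 1:4)
  fit <- fit_linear_model(make_expr(M))
  expect_equal(unname(fit$coefficients[, 1]), c(1, 1))
  expect_equal(unname(fit$sigma[1]^2), 0)
  expect_equal(unname(fit$sigma[2]^2), sum((M[2, ] - 1)^2) / 3)
  expect_equal(unname(fit$df.residual), c(3, 3))
  # negating both M and the orientation leaves the estimate unchanged
  fit_neg <- fit_linear_model(make_expr(-M))
  expect_equal(fit_neg$coefficients[, 1], -fit$coefficients[, 1])
  expect_equal(fit_neg$sigma, fit$sigma)
  # technical replicates collapse by mean within biological replicate
  Mt <- rbind(t1 = c(0, 2, 1, 1, 4, 0))
  expect_equal(unname(collapse_tech_reps(Mt, c(1, 1, 2, 2, 3, 3))[1, ]),
               c(1, 1, 2))
})

test_that("moderation shrinks toward the prior and handles the equal-variance limit", {
  set.seed(6)
  M <- matrix(rnorm(200 * 4, 0, 0.5), 200, 4,
              dimnames = list(paste0("t", 1:200), paste0("a", 1:4)))
  # identical residual variance for every target: no shrinkage needed
  M_eq <- t(scale(t(M))) * 0.5 + rowMeans(M)   # every row sd = 0.5
  fit <- fit_linear_model(make_expr(M_eq))
  mod <- ebayes_moderate(fit)
  expect_equal(mod$prior$d0, 1e7)              # treated as infinite
  expect_equal(mod$prior$s02, 0.25, tolerance = 1e-6)
  # complete pooling: t = beta / (s0 * stdev_unscaled)
  expect_equal(mod$table$t,
               mod$table$logFC / (sqrt(0.25) * mod$table$stdev_unscaled),
               tolerance = 1e-6)

  # monotonicity: raising one target's |logFC| at fixed variance never
  # removes its call
  M2 <- M_eq
  M2[7, ] <- M2[7, ] + 5
  mod2 <- ebayes_moderate(fit_linear_model(make_expr(M2)))
  expect_lt(mod2$table$adj.P.Val[7], mod$table$adj.P.Val[7])
  called_before <- mod$table$target_id[mod$table$adj.P.Val < 0.05]
  called_after <- mod2$table$target_id[mod2$table$adj.P.Val < 0.05]
  expect_true(all(setdiff(called_before, "t7") %in% called_after))
})

test_that("null moderated t follows its reference t distribution", {
  set.seed(8)
  n <- 5000
  M <- matrix(rnorm(n * 6, 0, 1), n, 6,
              dimnames = list(paste0("t", 1:n), paste0("a", 1:6)))
  mod <- ebayes_moderate(fit_linear_model(make_expr(M)))
  df_total <- min(mod$prior$d0, 1e6) + 5
  ks <- suppressWarnings(stats::ks.test(mod$table$t,
                                        function(q) stats::pt(q, df_total)))
  expect_gt(ks$p.value, 0.01)
})

test_that("Benjamini-Yekutieli adjustment matches the step-up definition", {
  expect_equal(adjust_benjamini_yekutieli(0.2), 0.2)   # m = 1: identity
  # hand-computed step-up: c(3) = 1 + 1/2 + 1/3
  expect_equal(adjust_benjamini_yekutieli(c(0.01, 0.02, 0.03)),
               rep(3 * (1 + 1/2 + 1/3) * 0.01, 3))
  expect_error(adjust_benjamini_yekutieli(c(0.1, 1.2)), "0, 1")
  set.seed(10)
  for (i in seq_len(1000)) {
    p <- runif(sample(1:50, 1))
    got <- adjust_benjamini_yekutieli(p)
    expect_equal(got, by_stepup(p), tolerance = 1e-12)
    # BY is never below BH
    expect_true(all(got >= p.adjust(p, "BH") - 1e-12))
  }
})

test_that("significance calls split by direction and respect alpha", {
  tab <- make_fit_table(paste0("t", 1:10), up = c("t1", "t2"), down = "t9")
  calls <- call_significant(tab, 0.05)
  expect_setequal(calls$up, c("t1", "t2"))
  expect_setequal(calls$down, "t9")
  expect_equal(lengths(call_significant(tab, 0)), c(up = 0, down = 0))
  empty <- make_fit_table(character(0))
  expect_equal(lengths(call_significant(empty)), c(up = 0, down = 0))
})
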