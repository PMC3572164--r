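# Per-target dye-swap linear model with empirical-Bayes moderated
# statistics and Benjamini-Yekutieli multiple-testing correction. Each
# experiment compares exactly two sample pools, and M values are already
# sign-resolved to the biological orientation during preprocessing, so the
# linear model reduces to an intercept-only (one-sample) fit on oriented M.

#' Collapse technical replicates within biological replicates
#'
#' Averages the per-array columns belonging to the same biological
#' replicate, preventing pseudo-replication in the model fit.
#'
#' @param mat targets x arrays matrix.
#' @param bio_rep biological replicate id of each array (column).
#' @return targets x biological-replicates matrix.
#' @export
collapse_tech_reps <- function(mat, bio_rep) {
  stopifnot(ncol(mat) == length(bio_rep))
  reps <- unique(bio_rep)
  out <- matrix(NA_real_, nrow(mat), length(reps),
                dimnames = list(rownames(mat), paste0("bio", reps)))
  for (j in seq_along(reps))
    out[, j] <- rowMeans(mat[, bio_rep == reps[j], drop = FALSE],
                         na.rm = TRUE)
  out
}

#' Fit the per-target linear model
#'
#' Least-squares intercept-only fit of oriented M values across biological
#' replicates, one model per target; the coefficient is the average log2
#' fold change. Technical replicates are collapsed by mean first. A values
#' are carried along so that the average expression (AveExpr) accompanies
#' each fit.
#'
#' @param expr a `target_expression` object (from
#'   [preprocess_experiment()]), or a list with elements `M`, `A`
#'   (targets x arrays) and `design` (with `bio_rep`).
#' @return an [limma::MArrayLM-class] fit with per-target coefficient,
#'   unscaled standard error, residual variance and degrees of freedom.
#' @export
fit_linear_model <- function(expr) {
  Mb <- collapse_tech_reps(expr$M, expr$design$bio_rep)
  Ab <- collapse_tech_reps(expr$A, expr$design$bio_rep)
  if (ncol(Mb) < 2)
    stop("need at least two biological replicates after collapsing")
  ma <- methods::new("MAList", list(M = Mb, A = Ab))
  limma::lmFit(ma, design = matrix(1, ncol(Mb), 1,
                                   dimnames = list(NULL, "logFC")))
}

#' Empirical-Bayes moderation of the per-target fits
#'
#' Shrinks per-target residual variances toward a common prior estimated
#' by matching moments of log s^2, and computes moderated t, moderated F,
#' two-sided p-values and the log-odds of differential expression (B) under
#' a prior probability `proportion` that a target is differentially
#' expressed. Benjamini-Yekutieli adjusted p-values are appended.
#'
#' @param fit result of [fit_linear_model()].
#' @param proportion prior probability of differential expression
#'   (default 0.01).
#' @return list of class `model_fit`: `table` (data.frame with columns
#'   `target_id`, `logFC`, `AveExpr`, `t`, `P.Value`, `adj.P.Val`, `B`,
#'   `F`, `s2`, `df_residual`, `stdev_unscaled`) and `prior` (`d0`, `s02`,
#'   `proportion`, `v0`).
#' @export
ebayes_moderate <- function(fit, proportion = 0.01) {
  eb <- limma::eBayes(fit, proportion = proportion)
  d0 <- eb$df.prior
  if (!is.finite(d0)) d0 <- 1e7   # complete-pooling safeguard
  tab <- data.frame(
    target_id = rownames(eb$coefficients),
    logFC = eb$coefficients[, 1],
    AveExpr = eb$Amean,
    t = eb$t[, 1],
    P.Value = eb$p.value[, 1],
    adj.P.Val = adjust_benjamini_yekutieli(eb$p.value[, 1]),
    B = eb$lods[, 1],
    F = eb$F,
    s2 = eb$sigma^2,
    df_residual = eb$df.residual,
    stdev_unscaled = eb$stdev.unscaled[, 1],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 prior = list(d0 = d0, s02 = eb$s2.prior,
                              proportion = proportion,
                              v0 = eb$var.prior)),
            class = "model_fit")
}

#' Benjamini-Yekutieli step-up adjustment
#'
#' FDR correction valid under arbitrary dependence: the Benjamini-Hochberg
#' adjustment inflated by the harmonic-number factor c(m) = sum_{k<=m} 1/k,
#' with the usual step-up monotonicity enforcement.
#'
#' @param p vector of raw p-values in \[0, 1\] (NAs preserved).
#' @return adjusted p-values.
#' @export
adjust_benjamini_yekutieli <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BY")
}

#' Call significant targets in both directions
#'
#' @param fits a `model_fit` or its `table`.
#' @param alpha adjusted-p threshold.
#' @return list with character vectors `up` (logFC > 0, adj. p < alpha) and
#'   `down` (logFC < 0).
#' @export
call_significant <- function(fits, alpha = 0.05) {
  tab <- if (inherits(fits, "model_fit")) fits$table else fits
  sig <- !is.na(tab$adj.P.Val) & tab$adj.P.Val < alpha
  list(up = tab$target_id[sig & tab$logFC > 0],
       down = tab$target_id[sig & tab$logFC < 0])
}

#' Fit, moderate and adjust one experiment in a single call
#'
#' @param expr a `target_expression` object.
#' @param proportion prior proportion of differentially expressed targets.
#' @return `model_fit` object.
#' @export
fit_experiment <- function(expr, proportion = 0.01) {
  ebayes_moderate(fit_linear_model(expr), proportion = proportion)
}
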