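# Negative-control expression thresholding and maternal/zygotic
# classification. The detection cutoff is derived exclusively from the
# antisense control probes: background-only measurements whose A-value
# distribution defines what "not expressed" looks like on the array.

#' Derive the expression A-cutoff from antisense controls
#'
#' Cutoff = control mean + `sd_multiplier` x control SD (sample SD, n-1
#' denominator). Requires at least 10 control values for a stable
#' estimate.
#'
#' @param control_A per-control-probe mean A values.
#' @param sd_multiplier number of SDs above the mean (default 3).
#' @return object of class `expression_threshold`: list with
#'   `control_mean`, `control_sd`, `cutoff`, `n_controls`.
#' @export
derive_threshold <- function(control_A, sd_multiplier = 3) {
  control_A <- control_A[is.finite(control_A)]
  if (length(control_A) < 10)
    stop("need at least 10 antisense control values to derive a ",
         "reliable expression threshold (got ", length(control_A), ")")
  m <- mean(control_A)
  s <- sd(control_A)
  structure(list(control_mean = m, control_sd = s,
                 cutoff = m + sd_multiplier * s,
                 n_controls = length(control_A)),
            class = "expression_threshold")
}

#' Flag expressed targets by the control-derived A-cutoff
#'
#' A target is expressed when its average A meets or exceeds the cutoff
#' (boundary counts as expressed). Targets below the cutoff that are
#' nevertheless significant at `alpha` are retained and labelled as the
#' low-expressed-but-significant stratum rather than silently dropped.
#'
#' @param fits `model_fit` (or its table) from the early-vs-late
#'   experiment, whose A values define the cutoff scale.
#' @param threshold an [derive_threshold()] result.
#' @param alpha adjusted-p threshold for the low-expressed stratum label.
#' @return data.frame (`target_id`, `avg_A`, `expressed`,
#'   `low_expressed_significant`).
#' @export
classify_expressed <- function(fits, threshold, alpha = 0.05) {
  tab <- if (inherits(fits, "model_fit")) fits$table else fits
  expressed <- tab$AveExpr >= threshold$cutoff
  sig <- !is.na(tab$adj.P.Val) & tab$adj.P.Val < alpha
  data.frame(target_id = tab$target_id,
             avg_A = tab$AveExpr,
             expressed = expressed,
             low_expressed_significant = !expressed & sig,
             stringsAsFactors = FALSE)
}

#' Classify targets as maternally/zygotically enriched, equal or unexpressed
#'
#' Among expressed targets, the sign of the fold change (orientation
#' M = log2(zygotic pool / maternal pool)) together with significance at
#' `alpha` decides the class: negative and significant = maternally
#' enriched, positive and significant = zygotically enriched, expressed
#' but not significant = equal; targets below the expression cutoff are
#' unexpressed. The four classes partition the target set.
#'
#' @param fits early-vs-late `model_fit` or its table.
#' @param expressed result of [classify_expressed()].
#' @param alpha adjusted-p threshold.
#' @return data.frame (schema `classification`): `target_id`, `avg_A`,
#'   `class`, `expressed_flag`, `low_expressed_significant`.
#' @export
classify_maternal_zygotic <- function(fits, expressed, alpha = 0.05) {
  tab <- if (inherits(fits, "model_fit")) fits$table else fits
  stopifnot(identical(tab$target_id, expressed$target_id))
  sig <- !is.na(tab$adj.P.Val) & tab$adj.P.Val < alpha
  cls <- ifelse(!expressed$expressed, "unexpressed",
         ifelse(sig & tab$logFC < 0, "maternal_enriched",
         ifelse(sig & tab$logFC > 0, "zygotic_enriched", "equal")))
  data.frame(target_id = tab$target_id,
             avg_A = expressed$avg_A,
             class = cls,
             expressed_flag = expressed$expressed,
             low_expressed_significant = expressed$low_expressed_significant,
             stringsAsFactors = FALSE)
}
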