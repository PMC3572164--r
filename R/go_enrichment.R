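# Fisher's exact GO-term overrepresentation analysis with the
# fold-overrepresentation statistic: the percentage of study-set targets
# annotated with a term over the percentage in the reference set.

#' GO-term overrepresentation by Fisher's exact test
#'
#' For every term annotated to at least one reference target, tests
#' overrepresentation of the term in the study set against the reference
#' with a one-sided Fisher's exact test on the 2x2 table of study
#' membership x term membership. Unannotated targets count in the set
#' totals. Annotations are used as given (no GO-graph ancestor
#' propagation). By default raw p-values are compared against `alpha`; a
#' Benjamini-Hochberg adjustment can be switched on with `adjust`.
#'
#' @param study character vector of study-set target ids (must be a subset
#'   of `reference`).
#' @param reference character vector of reference-set target ids
#'   (including the study set).
#' @param annotation data.frame (`target_id`, `go_id`).
#' @param alpha significance threshold.
#' @param adjust apply Benjamini-Hochberg adjustment before thresholding.
#' @return data.frame (schema `enrichment`): `go_id`, `study_count`,
#'   `study_size`, `ref_count`, `ref_size`, `fold_overrep`, `p`,
#'   `significant`, ordered by p.
#' @export
fisher_enrich <- function(study, reference, annotation, alpha = 0.05,
                          adjust = FALSE) {
  study <- unique(study)
  reference <- unique(reference)
  extra <- setdiff(study, reference)
  if (length(extra))
    stop("study set is not a subset of the reference set: ",
         paste(head(extra, 5), collapse = ", "))
  ann <- annotation[annotation$target_id %in% reference, , drop = FALSE]
  empty <- data.frame(go_id = character(), study_count = integer(),
                      study_size = integer(), ref_count = integer(),
                      ref_size = integer(), fold_overrep = numeric(),
                      p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(ann) == 0) return(empty)
  n_study <- length(study)
  n_ref <- length(reference)
  by_term <- split(unique(ann)$target_id, unique(ann)$go_id)
  res <- lapply(names(by_term), function(term) {
    hits <- by_term[[term]]
    a <- sum(study %in% hits)            # study & term
    K <- length(hits)                    # reference & term
    tb <- matrix(c(a, n_study - a,
                   K - a, (n_ref - n_study) - (K - a)), 2, 2)
    p <- fisher.test(tb, alternative = "greater")$p.value
    data.frame(go_id = term, study_count = a, study_size = n_study,
               ref_count = K, ref_size = n_ref,
               fold_overrep = (a / n_study) / (K / n_ref),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  crit <- if (adjust) p.adjust(out$p, method = "BH") else out$p
  out$significant <- crit < alpha
  out <- out[order(out$p, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
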