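# Combining the two 8-cell-stage experiments (ectoderm progenitors vs rest,
# mesoderm progenitors vs rest) into a catalogue of asymmetrically
# distributed RNAs, with cross-experiment consistency checks and temporal
# classification against the early-vs-late experiment.

#' Build the asymmetric-RNA catalogue from the two 8-cell experiments
#'
#' Extracts the four directional significant sets (enriched/depleted in
#' each dissected pool; depletion in the dissected pool is enrichment in
#' the complementary pool of blastomeres), forms their union with overlap
#' bookkeeping, and records per-target provenance. A target is
#' `found_in_both` when it is significant (either direction) in both
#' experiments.
#'
#' @param ecto_fits,meso_fits `model_fit` objects (or tables) of the two
#'   experiments, fitted on the same target universe.
#' @param alpha adjusted-p threshold.
#' @return object of class `asym_catalogue`: list with `table` (one row per
#'   union member: directional flags, `found_in_both`, fold changes and
#'   adjusted p from both experiments) and `summary` (set sizes, raw sum,
#'   duplicates, union size).
#' @export
build_catalogue <- function(ecto_fits, meso_fits, alpha = 0.05) {
  et <- if (inherits(ecto_fits, "model_fit")) ecto_fits$table else ecto_fits
  mt <- if (inherits(meso_fits, "model_fit")) meso_fits$table else meso_fits
  if (!setequal(et$target_id, mt$target_id)) {
    diff <- union(setdiff(et$target_id, mt$target_id),
                  setdiff(mt$target_id, et$target_id))
    stop("experiments were fitted on different target universes; ",
         "symmetric difference: ", paste(head(diff, 10), collapse = ", "),
         if (length(diff) > 10) " ...")
  }
  mt <- mt[match(et$target_id, mt$target_id), , drop = FALSE]
  e_call <- call_significant(et, alpha)
  m_call <- call_significant(mt, alpha)
  sets <- list(ecto_enriched = e_call$up, ecto_depleted = e_call$down,
               meso_enriched = m_call$up, meso_depleted = m_call$down)
  members <- Reduce(union, sets)
  in_e <- members %in% c(sets$ecto_enriched, sets$ecto_depleted)
  in_m <- members %in% c(sets$meso_enriched, sets$meso_depleted)
  ei <- match(members, et$target_id)
  mi <- match(members, mt$target_id)
  tab <- data.frame(
    target_id = members,
    ecto_enriched = members %in% sets$ecto_enriched,
    ecto_depleted = members %in% sets$ecto_depleted,
    meso_enriched = members %in% sets$meso_enriched,
    meso_depleted = members %in% sets$meso_depleted,
    found_in_both = in_e & in_m,
    logFC_ecto = et$logFC[ei], adj_p_ecto = et$adj.P.Val[ei],
    logFC_meso = mt$logFC[mi], adj_p_meso = mt$adj.P.Val[mi],
    stringsAsFactors = FALSE)
  sizes <- lengths(sets)
  summary <- list(set_sizes = sizes,
                  raw_sum = sum(sizes),
                  n_found_in_both = sum(tab$found_in_both),
                  union_size = length(members))
  structure(list(table = tab, summary = summary, alpha = alpha),
            class = "asym_catalogue")
}

#' Cross-experiment consistency of the asymmetry calls
#'
#' The dissected pool of one experiment is contained in the complementary
#' ("rest") pool of the other, so a truly ectoderm-enriched RNA should be
#' depleted in the mesoderm-experiment's dissected pool, and vice versa.
#' Reports, for each direction, how many enriched targets reappear in the
#' corresponding pool of the other experiment.
#'
#' @param catalogue an `asym_catalogue`.
#' @return list with per-direction counts, identities and fractions.
#' @export
consistency_check <- function(catalogue) {
  tab <- catalogue$table
  ecto_in_meso <- tab$target_id[tab$ecto_enriched & tab$meso_depleted]
  meso_in_ecto <- tab$target_id[tab$meso_enriched & tab$ecto_depleted]
  n_ecto <- sum(tab$ecto_enriched)
  n_meso <- sum(tab$meso_enriched)
  list(ecto_enriched_confirmed = ecto_in_meso,
       meso_enriched_confirmed = meso_in_ecto,
       n_ecto_enriched = n_ecto,
       n_meso_enriched = n_meso,
       frac_ecto_confirmed = if (n_ecto) length(ecto_in_meso) / n_ecto else NA,
       frac_meso_confirmed = if (n_meso) length(meso_in_ecto) / n_meso else NA)
}

#' Assign each catalogue member a temporal expression group
#'
#' Cross-references the asymmetric RNAs with the early-vs-late experiment:
#' maternally enriched members form the `maternal_degraded` group,
#' zygotically enriched members the `zygotic` group, expressed
#' non-significant members the `constant` group, and members below the
#' expression A-cutoff remain `unassigned_low_A`. The groups partition the
#' catalogue. The maximum early-vs-late fold change among assigned members
#' is reported.
#'
#' @param catalogue an `asym_catalogue`.
#' @param el_fits early-vs-late `model_fit` or its table.
#' @param classification result of [classify_maternal_zygotic()].
#' @return the catalogue with `temporal_group`, `logFC_early_late` and
#'   `adj_p_early_late` columns added to its table and `group_sizes` /
#'   `max_fold_change` added to its summary.
#' @export
classify_temporal <- function(catalogue, el_fits, classification) {
  tab <- catalogue$table
  el <- if (inherits(el_fits, "model_fit")) el_fits$table else el_fits
  ci <- match(tab$target_id, classification$target_id)
  ei <- match(tab$target_id, el$target_id)
  if (anyNA(ci) || anyNA(ei))
    stop("catalogue members missing from the early-vs-late results")
  grp <- c(maternal_enriched = "maternal_degraded",
           zygotic_enriched = "zygotic",
           equal = "constant",
           unexpressed = "unassigned_low_A")[classification$class[ci]]
  tab$temporal_group <- unname(grp)
  tab$logFC_early_late <- el$logFC[ei]
  tab$adj_p_early_late <- el$adj.P.Val[ei]
  catalogue$table <- tab
  assigned <- tab$temporal_group != "unassigned_low_A"
  catalogue$summary$group_sizes <-
    table(factor(tab$temporal_group,
                 levels = c("maternal_degraded", "constant", "zygotic",
                            "unassigned_low_A")))
  catalogue$summary$max_fold_change <-
    if (any(assigned)) 2^max(abs(tab$logFC_early_late[assigned])) else NA_real_
  catalogue
}
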