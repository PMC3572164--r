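# End-to-end drivers: simulate a three-experiment study, run the full
# analysis chain on it, summarize the result, and estimate the empirical
# false discovery rate of the calling procedure on null-plus-spike
# simulations.

derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a complete three-experiment study
#'
#' Generates one truth table and probe-level scans for the three
#' experiments of the study design (early-vs-late embryos, ectoderm
#' progenitors vs rest, mesoderm progenitors vs rest), plus a synthetic
#' GO annotation table.
#'
#' @param n_targets number of targets.
#' @param layout an [array_layout()] shared by the experiments.
#' @param noise a [noise_model()].
#' @param seed master seed; all per-experiment seeds derive from it.
#' @param ... further arguments passed to [generate_truth()].
#' @return list: `truth`, `experiments` (named list of
#'   [simulate_scan()] results sharing one physical layout), `annotation`,
#'   `layout`, `noise`.
#' @export
simulate_study <- function(n_targets, layout = array_layout(),
                           noise = noise_model(), seed = 1, ...) {
  seeds <- derive_seeds(seed, 6)
  truth <- generate_truth(n_targets, seed = seeds[1], ...)
  # one physical array design shared by all three experiments
  phys <- with_seed(seeds[5], realize_spots(truth, layout))
  experiments <- list(
    early_late = simulate_scan(truth, layout, noise, "early_late",
                               seeds[2], phys = phys),
    ecto = simulate_scan(truth, layout, noise, "ecto", seeds[3],
                         phys = phys),
    meso = simulate_scan(truth, layout, noise, "meso", seeds[4],
                         phys = phys))
  annotation <- generate_annotation(truth$target_id, seed = seeds[6])
  list(truth = truth, experiments = experiments, annotation = annotation,
       layout = layout, noise = noise)
}

#' Run the full analysis chain on a simulated (or assembled) study
#'
#' Preprocesses each experiment, fits the moderated-statistics model,
#' derives the expression threshold from the early-vs-late antisense
#' controls, classifies targets as maternally/zygotically enriched,
#' builds the asymmetry catalogue from the two 8-cell experiments, and
#' classifies its members by temporal group.
#'
#' @param study result of [simulate_study()], or a list of the same shape
#'   assembled from files.
#' @param config a [pipeline_config()].
#' @param proportion prior proportion of differentially expressed targets.
#' @return list: `expr` (per-experiment `target_expression`), `fits`
#'   (per-experiment `model_fit`), `threshold`, `expressed`,
#'   `classification`, `catalogue`, `consistency`, `config`.
#' @export
run_study <- function(study, config = pipeline_config(), proportion = 0.01) {
  expr <- list(); fits <- list()
  for (e in names(study$experiments)) {
    sim <- study$experiments[[e]]
    probe_map <- sim$probes[!sim$probes$is_control,
                            c("probe_id", "target_id"), drop = FALSE]
    controls <- sim$probes$probe_id[sim$probes$is_control]
    expr[[e]] <- preprocess_experiment(sim$scans, sim$design, probe_map,
                                       control_probes = controls,
                                       config = config)
    fits[[e]] <- fit_experiment(expr[[e]], proportion = proportion)
  }
  threshold <- derive_threshold(expr$early_late$control_A,
                                config$sd_multiplier)
  expressed <- classify_expressed(fits$early_late, threshold, config$alpha)
  classification <- classify_maternal_zygotic(fits$early_late, expressed,
                                              config$alpha)
  catalogue <- build_catalogue(fits$ecto, fits$meso, config$alpha)
  catalogue <- classify_temporal(catalogue, fits$early_late, classification)
  list(expr = expr, fits = fits, threshold = threshold,
       expressed = expressed, classification = classification,
       catalogue = catalogue, consistency = consistency_check(catalogue),
       config = config)
}

#' Summarize a pipeline run
#'
#' Collects the headline arithmetic of a run: expression threshold, class
#' counts and maternal fraction from the early-vs-late experiment, the
#' four directional set sizes with their raw sum, duplicate count and
#' union size, the temporal-group partition, the maximum early-vs-late
#' fold change in the catalogue, and the cross-experiment consistency
#' fractions.
#'
#' @param run result of [run_study()].
#' @return named list of summary quantities.
#' @export
study_report <- function(run) {
  cls <- table(factor(run$classification$class,
                      levels = c("maternal_enriched", "zygotic_enriched",
                                 "equal", "unexpressed")))
  n_expressed <- sum(run$expressed$expressed)
  list(
    a_cutoff = run$threshold$cutoff,
    n_targets = nrow(run$classification),
    n_expressed = n_expressed,
    class_counts = cls,
    n_enriched_either = unname(cls["maternal_enriched"] +
                                 cls["zygotic_enriched"]),
    maternal_fraction_pct = 100 * unname(cls["maternal_enriched"]) /
      nrow(run$classification),
    n_low_expressed_significant = sum(run$expressed$low_expressed_significant),
    asymmetry = run$catalogue$summary,
    consistency = run$consistency[c("frac_ecto_confirmed",
                                    "frac_meso_confirmed")])
}

#' Empirical FDR of the moderated-t + Benjamini-Yekutieli call
#'
#' Simulates many independent null-plus-spike experiments at the study's
#' design (dye-swap arrays, probe-level Gaussian-plus-exponential noise),
#' runs each through the full chain (background correction, normalization,
#' fit, moderation, BY adjustment, calling at `alpha`) and reports the
#' mean false discovery proportion with its Monte-Carlo standard error.
#' Planted targets split evenly between the two directions at |log2 fold
#' change| = `effect`.
#'
#' @param n_experiments number of simulated experiments.
#' @param n_targets total targets per experiment.
#' @param n_planted number of planted differentially expressed targets.
#' @param effect |log2 fold change| of planted targets.
#' @param frac_null_expressed fraction of targets that are expressed but
#'   unchanged; the remaining null targets sit at background level,
#'   mirroring the array's composition where most targets are below the
#'   detection threshold. All null targets (expressed or not) count toward
#'   false discoveries.
#' @param layout array layout; defaults to eight dye-swap arrays with
#'   single-spotted single-probe targets (the summarization steps are
#'   exercised but reduce to identities, keeping large replications fast).
#' @param noise a [noise_model()].
#' @param alpha adjusted-p calling threshold.
#' @param seed master seed.
#' @return list: `fdp` (per-experiment false discovery proportions),
#'   `mean_fdr`, `mc_se`, `mean_power`, `mean_calls`, `n_experiments`.
#' @export
estimate_fdr <- function(n_experiments = 200, n_targets = 6300,
                         n_planted = 300, effect = 1.5,
                         frac_null_expressed = 0.19,
                         layout = array_layout(
                           probes_per_target = c("1" = 1),
                           spots_per_probe = c("1" = 1),
                           n_antisense_controls = 0),
                         noise = noise_model(), alpha = 0.05, seed = 1) {
  seeds <- matrix(derive_seeds(seed, 2 * n_experiments), ncol = 2)
  fdp <- power <- calls <- numeric(n_experiments)
  config <- pipeline_config(alpha = alpha)
  for (i in seq_len(n_experiments)) {
    truth <- generate_truth(
      n_targets,
      frac_maternal = (n_planted / 2) / n_targets,
      frac_zygotic = (n_planted / 2) / n_targets,
      frac_constant = frac_null_expressed,
      frac_asymmetric = 0, effect_size = effect, jitter = 0,
      seed = seeds[i, 1])
    sim <- simulate_scan(truth, layout, noise, "early_late", seeds[i, 2])
    probe_map <- sim$probes[!sim$probes$is_control,
                            c("probe_id", "target_id"), drop = FALSE]
    expr <- preprocess_experiment(sim$scans, sim$design, probe_map,
                                  config = config)
    fit <- fit_experiment(expr)
    called <- unlist(call_significant(fit, alpha), use.names = FALSE)
    null_ids <- truth$target_id[truth$true_logfc_early_late == 0]
    fdp[i] <- if (length(called)) sum(called %in% null_ids) / length(called)
              else 0
    power[i] <- sum(!(called %in% null_ids)) / n_planted
    calls[i] <- length(called)
  }
  list(fdp = fdp, mean_fdr = mean(fdp),
       mc_se = sd(fdp) / sqrt(n_experiments),
       mean_power = mean(power), mean_calls = mean(calls),
       n_experiments = n_experiments)
}
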