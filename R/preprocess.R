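# From raw per-spot two-channel intensities to one normalized (M, A) pair
# per target per array. Fixed pipeline order: normexp background correction
# -> M/A computation with dye-swap resolution -> print-tip loess -> A-quantile
# between-array normalization -> replicate-spot averaging -> median-polish
# summarization of multi-probe targets.

#' Normexp background correction
#'
#' Models observed foreground minus background as exponential true signal
#' plus Gaussian noise and returns the posterior mean of the signal given
#' the observation, plus `offset`. Parameters are estimated from the data
#' by maximum likelihood (saddle-point approximated); all corrected values
#' are strictly positive.
#'
#' @param fg,bg foreground and background intensities (same length).
#' @param offset intensity offset added after correction (default 50).
#' @return list with `signal` (corrected intensities) and `par` (named
#'   vector `mu`, `sigma`, `alpha`; `alpha` is the exponential signal mean).
#' @export
normexp_correct <- function(fg, bg, offset = 50) {
  if (length(fg) != length(bg)) stop("fg and bg must have the same length")
  if (offset < 0) stop("offset must be >= 0")
  x <- fg - bg
  if (!is.finite(sd(x, na.rm = TRUE)) || sd(x, na.rm = TRUE) == 0)
    stop("degenerate intensity data: fg - bg has zero variance; ",
         "cannot estimate the background model")
  fit <- limma::normexp.fit(x, method = "saddle")
  sig <- limma::normexp.signal(fit$par, x) + offset
  list(signal = sig,
       par = c(mu = fit$par[1], sigma = exp(fit$par[2]),
               alpha = exp(fit$par[3])))
}

#' Per-spot M and A values with dye-swap resolution
#'
#' M is the log2 ratio of the biological numerator pool over the
#' denominator pool; on `forward` arrays the numerator pool was labelled in
#' channel 2, on `swap` arrays in channel 1, so M is sign-resolved to a
#' uniform biological orientation. A = (log2(ch1) + log2(ch2)) / 2 is
#' unaffected by the swap.
#'
#' @param ch1,ch2 corrected intensities of channels 1 and 2 (must be > 0).
#' @param dye_orientation `"forward"` or `"swap"`.
#' @return data.frame with columns `M` and `A`.
#' @export
compute_MA <- function(ch1, ch2, dye_orientation = c("forward", "swap")) {
  dye_orientation <- match.arg(dye_orientation)
  if (any(ch1 <= 0 | ch2 <= 0, na.rm = TRUE))
    stop("intensities must be strictly positive (background-correct first)")
  M <- log2(ch2) - log2(ch1)
  if (dye_orientation == "swap") M <- -M
  data.frame(M = M, A = (log2(ch1) + log2(ch2)) / 2)
}

#' Print-tip loess normalization
#'
#' Within each print-tip group, subtracts a robust local-linear loess fit
#' of M on A, removing intensity-dependent dye bias and pin-specific
#' curvature. Groups smaller than `min_spots` fall back to the whole-array
#' fit with a warning.
#'
#' @param M,A per-spot values.
#' @param printtip print-tip group of each spot.
#' @param span loess span.
#' @param iterations robustifying iterations.
#' @param min_spots minimum group size for a groupwise fit.
#' @return normalized M vector.
#' @export
printtip_loess <- function(M, A, printtip, span = 0.3, iterations = 4,
                           min_spots = 20) {
  stopifnot(length(M) == length(A), length(M) == length(printtip))
  out <- rep(NA_real_, length(M))
  global <- NULL
  for (g in unique(printtip)) {
    i <- which(printtip == g)
    if (sum(is.finite(M[i]) & is.finite(A[i])) < min_spots) {
      warning("print-tip group ", g, " has fewer than ", min_spots,
              " spots; falling back to whole-array loess")
      if (is.null(global))
        global <- limma::loessFit(M, A, span = span,
                                  iterations = iterations)$residuals
      out[i] <- global[i]
    } else {
      out[i] <- limma::loessFit(M[i], A[i], span = span,
                                iterations = iterations)$residuals
    }
  }
  out
}

#' Between-array A-quantile normalization
#'
#' Forces every array's A-value distribution onto the across-array mean
#' quantile vector, preserving within-array ranks; M values are untouched
#' by design (call on the A matrix only). Missing values are interpolated
#' by rank.
#'
#' @param A numeric matrix, spots/targets x arrays (>= 2 arrays).
#' @return normalized matrix of the same shape.
#' @export
aquantile_normalize <- function(A) {
  A <- as.matrix(A)
  if (ncol(A) < 2) stop("need at least two arrays")
  if (any(colSums(is.finite(A)) == 0))
    stop("array with no finite A values")
  limma::normalizeQuantiles(A, ties = TRUE)
}

#' Average replicate spots of identical probes
#'
#' Collapses multiply-spotted probes to one M and A value per probe using
#' the arithmetic mean; spots with a nonzero flag are excluded first.
#'
#' @param spots data.frame with columns `probe_id`, `M`, `A`, and
#'   optionally `flag`.
#' @return data.frame (`probe_id`, `M`, `A`, `n_spots`), one row per probe.
#' @export
average_replicate_spots <- function(spots) {
  stopifnot(all(c("probe_id", "M", "A") %in% names(spots)))
  if ("flag" %in% names(spots)) spots <- spots[spots$flag == 0, , drop = FALSE]
  ids <- unique(spots$probe_id)
  f <- factor(spots$probe_id, levels = ids)
  data.frame(probe_id = ids,
             M = as.numeric(tapply(spots$M, f, mean, na.rm = TRUE)),
             A = as.numeric(tapply(spots$A, f, mean, na.rm = TRUE)),
             n_spots = as.integer(table(f)),
             stringsAsFactors = FALSE)
}

#' Tukey median polish
#'
#' Alternately sweeps row and column medians out of a matrix until the sum
#' of absolute residuals stabilizes (relative change below `eps`) or
#' `maxiter` is reached; ties in medians resolve to the midpoint (the
#' sample median). Missing cells are ignored.
#'
#' @param z numeric matrix.
#' @param eps convergence tolerance on the relative change of the total
#'   absolute residual.
#' @param maxiter maximum number of sweeps.
#' @return list with `overall`, `row`, `col`, `residuals`, `iter`,
#'   `converged`.
#' @export
median_polish <- function(z, eps = 0.01, maxiter = 10L) {
  z <- as.matrix(z)
  nr <- nrow(z); nc <- ncol(z)
  t <- 0; r <- numeric(nr); cl <- numeric(nc)
  oldsum <- 0; converged <- FALSE; it <- 0L
  for (it in seq_len(maxiter)) {
    rdelta <- apply(z, 1L, median, na.rm = TRUE)
    z <- z - matrix(rdelta, nr, nc)
    r <- r + rdelta
    delta <- median(cl, na.rm = TRUE)
    cl <- cl - delta
    t <- t + delta
    cdelta <- apply(z, 2L, median, na.rm = TRUE)
    z <- z - matrix(cdelta, nr, nc, byrow = TRUE)
    cl <- cl + cdelta
    delta <- median(r, na.rm = TRUE)
    r <- r - delta
    t <- t + delta
    newsum <- sum(abs(z), na.rm = TRUE)
    converged <- newsum == 0 || abs(newsum - oldsum) < eps * newsum
    if (converged) break
    oldsum <- newsum
  }
  list(overall = t, row = r, col = cl, residuals = z, iter = it,
       converged = converged)
}

#' Summarize a probe-level matrix into one value per array
#'
#' Runs median polish on the probes-by-arrays matrix of one target and
#' returns overall effect + per-array column effect. Single-probe targets
#' reduce to their probe values; all-missing probe rows are dropped with a
#' warning.
#'
#' @param mat probes x arrays matrix (M or A values of one target).
#' @param eps,maxiter convergence settings passed to [median_polish()].
#' @return numeric vector, one summarized value per array.
#' @export
medianpolish_summarize <- function(mat, eps = 0.01, maxiter = 10L) {
  mat <- as.matrix(mat)
  allna <- rowSums(is.finite(mat)) == 0
  if (any(allna)) {
    warning(sum(allna), " all-missing probe row(s) dropped")
    mat <- mat[!allna, , drop = FALSE]
  }
  if (nrow(mat) == 0) return(rep(NA_real_, ncol(mat)))
  if (nrow(mat) == 1) return(drop(mat))
  mp <- median_polish(mat, eps = eps, maxiter = maxiter)
  setNames(mp$overall + mp$col, colnames(mat))
}

#' Array quality control by correlation with the experiment consensus
#'
#' Computes, for each array, the squared Pearson correlation of its spot
#' log2 intensity (A) profile with the across-array median profile.
#' Replicate arrays of a sound experiment reproduce each other's intensity
#' profiles; arrays whose R-squared falls below `r2_threshold` are marked
#' for exclusion, mirroring the discard of low-R-squared arrays at feature
#' extraction.
#'
#' @param A spots x arrays matrix of A values (needs >= 3 arrays for a
#'   meaningful consensus).
#' @param r2_threshold minimum squared correlation to keep an array.
#' @return data.frame (`array_id`, `r2`, `keep`).
#' @export
qc_arrays <- function(A, r2_threshold = 0.8) {
  A <- as.matrix(A)
  consensus <- apply(A, 1L, median, na.rm = TRUE)
  r2 <- apply(A, 2L, function(x)
    suppressWarnings(cor(x, consensus, use = "complete.obs"))^2)
  data.frame(array_id = colnames(A) %||% as.character(seq_len(ncol(A))),
             r2 = r2, keep = r2 >= r2_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preprocess one experiment's scans to target-level expression
#'
#' Runs the full within/between-array normalization chain on a set of
#' two-color scans and summarizes probes into targets: normexp background
#' correction per channel, M/A computation with dye-swap resolution,
#' print-tip loess, array QC, A-quantile between-array normalization,
#' replicate-spot averaging per probe, and median-polish summarization per
#' target (applied to the M matrix and A matrix separately). Flagged spots
#' are set to missing immediately after M/A computation. Antisense control
#' probes are kept out of target summarization; their per-probe mean A
#' values are returned for expression thresholding.
#'
#' @param scans named list of per-array spot tables (schema `scan`).
#' @param design design table (schema `design`) with one row per scan.
#' @param probe_map data.frame with columns `probe_id`, `target_id` for the
#'   retained expression probes (e.g. `filter_cross_hybridizing()$retained`
#'   plus any rescued additions).
#' @param control_probes character vector of antisense control probe ids.
#' @param config a [pipeline_config()].
#' @return object of class `target_expression`: list with target x array
#'   matrices `M` and `A`, the post-QC `design`, per-control-probe mean A
#'   values `control_A`, and the `qc` table.
#' @export
preprocess_experiment <- function(scans, design, probe_map,
                                  control_probes = character(),
                                  config = pipeline_config()) {
  stopifnot(length(scans) == nrow(design))
  if (is.null(names(scans))) names(scans) <- design$array_id
  spot_M <- spot_A <- NULL
  for (a in seq_along(scans)) {
    sc <- scans[[a]]
    c1 <- normexp_correct(sc$fg_ch1, sc$bg_ch1, config$normexp_offset)$signal
    c2 <- normexp_correct(sc$fg_ch2, sc$bg_ch2, config$normexp_offset)$signal
    ma <- compute_MA(c1, c2, design$dye_orientation[a])
    ma[sc$flag != 0, ] <- NA
    ma$M <- printtip_loess(ma$M, ma$A, sc$printtip, span = config$loess_span)
    if (is.null(spot_M)) {
      spot_M <- matrix(NA_real_, nrow(sc), length(scans),
                       dimnames = list(sc$spot_id, names(scans)))
      spot_A <- spot_M
    }
    spot_M[, a] <- ma$M
    spot_A[, a] <- ma$A
  }
  qc <- qc_arrays(spot_A, config$qc_r2)
  if (!all(qc$keep)) {
    message("dropping ", sum(!qc$keep), " array(s) failing QC: ",
            paste(qc$array_id[!qc$keep], collapse = ", "))
    spot_M <- spot_M[, qc$keep, drop = FALSE]
    spot_A <- spot_A[, qc$keep, drop = FALSE]
    design <- design[qc$keep, , drop = FALSE]
  }
  spot_A <- aquantile_normalize(spot_A)

  probe_ids <- scans[[1]]$probe_id
  probe_M <- probe_A <- NULL
  for (a in seq_len(ncol(spot_M))) {
    pv <- average_replicate_spots(data.frame(
      probe_id = probe_ids, M = spot_M[, a], A = spot_A[, a],
      flag = 0L, stringsAsFactors = FALSE))
    if (is.null(probe_M)) {
      probe_M <- matrix(NA_real_, nrow(pv), ncol(spot_M),
                        dimnames = list(pv$probe_id, colnames(spot_M)))
      probe_A <- probe_M
    }
    probe_M[, a] <- pv$M
    probe_A[, a] <- pv$A
  }

  ctrl <- intersect(rownames(probe_A), control_probes)
  control_A <- rowMeans(probe_A[ctrl, , drop = FALSE], na.rm = TRUE)

  pm <- probe_map[probe_map$probe_id %in% rownames(probe_M) &
                    !(probe_map$probe_id %in% control_probes),
                  c("probe_id", "target_id")]
  pm <- unique(pm)
  targets <- unique(pm$target_id)
  M <- matrix(NA_real_, length(targets), ncol(probe_M),
              dimnames = list(targets, colnames(probe_M)))
  A <- M
  by_target <- split(pm$probe_id, pm$target_id)
  single <- names(by_target)[lengths(by_target) == 1L]
  if (length(single)) {   # single-probe targets reduce to their probe values
    rows <- unlist(by_target[single], use.names = FALSE)
    M[single, ] <- probe_M[rows, , drop = FALSE]
    A[single, ] <- probe_A[rows, , drop = FALSE]
  }
  for (tg in setdiff(names(by_target), single)) {
    rows <- by_target[[tg]]
    M[tg, ] <- medianpolish_summarize(probe_M[rows, , drop = FALSE])
    A[tg, ] <- medianpolish_summarize(probe_A[rows, , drop = FALSE])
  }
  structure(list(M = M, A = A, design = design, control_A = control_A,
                 qc = qc),
            class = "target_expression")
}
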