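# Synthetic probe-level two-color array experiments with planted truth.
#
# The generator emulates the study design this pipeline targets: three
# dye-swap experiments (early-vs-late embryos, ectoderm-progenitors-vs-rest,
# mesoderm-progenitors-vs-rest) on a custom oligo array with multi-probe
# targets, multiply-spotted probes, and antisense negative-control probes.
# Spot intensities follow the generative dual of normexp background
# correction: Gaussian background plus exponential signal.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Noise model for simulated spot intensities
#'
#' Foreground intensity of an expressed spot is a Gaussian background draw
#' (`bg_mean`, `bg_sd`) plus an exponential signal draw whose mean is the
#' target's per-channel linear-scale expression level; the separate
#' background columns carry independent Gaussian draws. The two channels'
#' signal draws share a Gaussian copula with correlation `channel_cor`,
#' reflecting that both dyes hybridize to the same deposited spot; marginals
#' remain exponential. Dye bias and print-tip curvature are smooth (quadratic
#' in expected A) log2-scale distortions of the channel ratio, and
#' `array_scale_sd` jitters each array's overall log2 brightness.
#'
#' @param signal_rate rate (1/mean intensity) of the generic exponential
#'   signal used by [simulate_normexp_data()]; default mean 450 RFU.
#' @param bg_mean,bg_sd Gaussian background mean and SD (RFU).
#' @param dye_bias_amplitude peak log2 dye bias across the intensity range.
#' @param printtip_curvature_amplitude peak log2 per-print-tip curvature;
#'   sign alternates between tip groups.
#' @param array_scale_sd SD of the per-array global log2 scale shift.
#' @param channel_cor copula correlation of the two channels' signal draws.
#' @param bio_sd SD (log2) of the per-biological-replicate fold-change
#'   deviation around the planted fold change.
#' @param saturation scanner ceiling (RFU); foreground intensities are
#'   clipped here, emulating the 0-65000 dynamic range of the scan.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(signal_rate = 1 / 450, bg_mean = 100, bg_sd = 25,
                        dye_bias_amplitude = 0.4,
                        printtip_curvature_amplitude = 0.3,
                        array_scale_sd = 0.2, channel_cor = 0.9,
                        bio_sd = 0.15, saturation = 65000) {
  if (!is.numeric(bg_sd) || bg_sd <= 0) stop("bg_sd must be > 0")
  if (!is.numeric(signal_rate) || signal_rate <= 0)
    stop("signal_rate must be > 0")
  if (channel_cor < 0 || channel_cor >= 1)
    stop("channel_cor must lie in [0, 1)")
  structure(list(signal_rate = signal_rate, bg_mean = bg_mean, bg_sd = bg_sd,
                 dye_bias_amplitude = dye_bias_amplitude,
                 printtip_curvature_amplitude = printtip_curvature_amplitude,
                 array_scale_sd = array_scale_sd, channel_cor = channel_cor,
                 bio_sd = bio_sd, saturation = saturation),
            class = "noise_model")
}

#' Array layout for one simulated experiment
#'
#' Defaults mirror the study design: eight two-color arrays per experiment
#' organised as four biological replicates with two technical replicates
#' each, half of the arrays dye-swapped, four print-tip groups, mostly
#' multi-probe targets, a fraction of probes spotted twice, and 181
#' antisense negative-control probes.
#'
#' @param n_arrays number of arrays.
#' @param n_bio number of biological replicates (must divide `n_arrays`).
#' @param printtip_groups number of print-tip groups.
#' @param probes_per_target named probability vector over probe counts.
#' @param spots_per_probe named probability vector over spot counts.
#' @param n_antisense_controls number of antisense control probes.
#' @return object of class `array_layout`.
#' @export
array_layout <- function(n_arrays = 8, n_bio = 4, printtip_groups = 4,
                         probes_per_target = c("1" = 0.35, "2" = 0.45, "3" = 0.20),
                         spots_per_probe = c("1" = 0.8, "2" = 0.2),
                         n_antisense_controls = 181) {
  if (n_arrays < 2) stop("need at least two arrays")
  if (n_arrays %% n_bio != 0)
    stop("n_bio must divide n_arrays")
  for (d in list(probes_per_target, spots_per_probe)) {
    if (is.null(names(d)) || abs(sum(d) - 1) > 1e-8 || any(d < 0))
      stop("count distributions must be named non-negative vectors summing to 1")
  }
  structure(list(n_arrays = n_arrays, n_bio = n_bio,
                 printtip_groups = printtip_groups,
                 probes_per_target = probes_per_target,
                 spots_per_probe = spots_per_probe,
                 n_antisense_controls = n_antisense_controls),
            class = "array_layout")
}

#' Generate a planted truth table
#'
#' Plants per-target fold changes for the three experiments. Class
#' fractions default to the proportions observed on a 6386-target array:
#' 690 maternally enriched, 568 zygotically enriched, 236 expressed at
#' constant level, remainder unexpressed. Asymmetric (8-cell) effects are
#' planted on `frac_asymmetric` of the targets, drawn across temporal
#' classes with weights `asym_class_weights` (default composition
#' 65:12:17:35); `frac_asym_both` of them are planted in both 8-cell
#' experiments with biologically consistent opposite signs (enrichment in
#' the dissected pool of one experiment is depletion in the other
#' experiment's complementary pool).
#'
#' Fold changes are in log2 units with the orientation M = log2(late/early)
#' for the temporal experiment and M = log2(dissected pool/rest) for the
#' two 8-cell experiments; maternally enriched targets therefore carry a
#' negative `true_logfc_early_late`.
#'
#' @param n_targets number of targets.
#' @param frac_maternal,frac_zygotic,frac_constant fractions of targets in
#'   the maternally-enriched, zygotically-enriched and constant-expressed
#'   classes; the remainder is unexpressed.
#' @param frac_asymmetric fraction of targets with a planted 8-cell
#'   asymmetry.
#' @param effect_size |log2 fold change| of planted effects.
#' @param jitter SD of log2 jitter added to planted effect sizes.
#' @param base_range range of baseline log2 expression levels.
#' @param asym_class_weights unnormalized weights over classes for
#'   asymmetric target sampling.
#' @param frac_asym_both fraction of asymmetric targets planted in both
#'   8-cell experiments.
#' @param asym_el_fold_range linear-scale fold-change range for the
#'   early-late effect of asymmetric maternally-degraded targets, drawn
#'   uniformly in log; emulates the observed stratum of asymmetric maternal
#'   RNAs with very high early-late fold changes (10- to 180-fold). Set to
#'   NULL to keep the generic `effect_size` for these targets.
#' @param seed RNG seed; fixed seed fixes the table.
#' @return data.frame truth table; columns `target_id`,
#'   `true_logfc_early_late`, `true_logfc_ecto`, `true_logfc_meso`,
#'   `expressed`, `class_label`, plus bookkeeping columns `base_log2`,
#'   `asymmetric`, `asym_experiment`.
#' @export
generate_truth <- function(n_targets,
                           frac_maternal = 690 / 6386,
                           frac_zygotic = 568 / 6386,
                           frac_constant = 236 / 6386,
                           frac_asymmetric = 129 / 6386,
                           effect_size = 2, jitter = 0.25,
                           base_range = c(8, 14.5),
                           asym_class_weights = c(maternal_degraded = 65,
                                                  constant = 12,
                                                  zygotic = 17,
                                                  unexpressed = 35),
                           frac_asym_both = 10 / 129,
                           asym_el_fold_range = c(10, 180),
                           seed = NULL) {
  fr <- c(frac_maternal, frac_zygotic, frac_constant)
  if (any(fr < 0) || any(fr > 1) || frac_asymmetric < 0 || frac_asymmetric > 1)
    stop("fractions must lie in [0, 1]")
  if (sum(fr) > 1 + 1e-12)
    stop("class fractions sum to more than 1")
  if (effect_size <= 0) stop("effect_size must be > 0")
  with_seed(seed, {
    id <- sprintf("Contig%05d", seq_len(n_targets))
    n_mat <- round(frac_maternal * n_targets)
    n_zyg <- round(frac_zygotic * n_targets)
    n_con <- round(frac_constant * n_targets)
    cls <- rep("unexpressed", n_targets)
    pick <- sample.int(n_targets)
    cls[pick[seq_len(n_mat)]] <- "maternal_degraded"
    cls[pick[n_mat + seq_len(n_zyg)]] <- "zygotic"
    cls[pick[n_mat + n_zyg + seq_len(n_con)]] <- "constant"
    eff <- function(n, sign) sign * pmax(0.25,
      effect_size + if (jitter > 0) rnorm(n, 0, jitter) else 0)
    lel <- numeric(n_targets)
    lel[cls == "maternal_degraded"] <- eff(sum(cls == "maternal_degraded"), -1)
    lel[cls == "zygotic"] <- eff(sum(cls == "zygotic"), +1)

    n_asym <- round(frac_asymmetric * n_targets)
    asym_id <- character(0)
    if (n_asym > 0) {
      w <- asym_class_weights / sum(asym_class_weights)
      want <- round(w * n_asym)
      # keep total fixed despite rounding
      while (sum(want) > n_asym) want[which.max(want)] <- want[which.max(want)] - 1L
      while (sum(want) < n_asym) want[which.min(want)] <- want[which.min(want)] + 1L
      for (cl in names(want)) {
        pool <- id[cls == cl & !(id %in% asym_id)]
        k <- min(want[[cl]], length(pool))
        asym_id <- c(asym_id, sample(pool, k))
      }
      short <- n_asym - length(asym_id)
      if (short > 0)
        asym_id <- c(asym_id, sample(setdiff(id, asym_id), short))
    }
    asym <- id %in% asym_id
    asym_exp <- rep("", n_targets)
    if (length(asym_id)) {
      n_both <- round(frac_asym_both * length(asym_id))
      shuffled <- sample(asym_id)
      grp <- rep(c("ecto", "meso"), length.out = length(shuffled))
      if (n_both > 0) grp[seq_len(n_both)] <- "both"
      asym_exp[match(shuffled, id)] <- grp
    }
    le <- lm <- numeric(n_targets)
    i_e <- asym_exp %in% c("ecto", "both")
    i_m <- asym_exp %in% c("meso", "both")
    sgn <- sample(c(-1, 1), n_targets, replace = TRUE)
    le[i_e] <- eff(sum(i_e), sgn[i_e])
    lm[i_m] <- eff(sum(i_m), sgn[i_m])
    both <- asym_exp == "both"
    lm[both] <- -le[both] * ifelse(le[both] != 0, 1, 0)

    # asymmetric maternal RNAs carry very high early-late fold changes
    if (!is.null(asym_el_fold_range)) {
      i_hi <- asym & cls == "maternal_degraded"
      if (any(i_hi))
        lel[i_hi] <- -log2(exp(runif(sum(i_hi),
                                     log(asym_el_fold_range[1]),
                                     log(asym_el_fold_range[2]))))
    }

    data.frame(target_id = id,
               true_logfc_early_late = lel,
               true_logfc_ecto = le,
               true_logfc_meso = lm,
               expressed = cls != "unexpressed",
               class_label = cls,
               base_log2 = runif(n_targets, base_range[1], base_range[2]),
               asymmetric = asym,
               asym_experiment = asym_exp,
               stringsAsFactors = FALSE)
  })
}

# Draw counts from a named probability vector.
draw_counts <- function(dist, n) {
  vals <- as.integer(names(dist))
  if (length(vals) == 1L) return(rep(vals, n))
  as.integer(sample(vals, n, replace = TRUE, prob = dist))
}

# Physical probe/spot layout realized once per experiment: which probes
# exist, how often each is spotted, and in which print-tip group.
realize_spots <- function(truth, layout) {
  n_probes <- draw_counts(layout$probes_per_target, nrow(truth))
  probe <- data.frame(
    probe_id = paste0(rep(truth$target_id, n_probes), "_p",
                      sequence(n_probes)),
    target_id = rep(truth$target_id, n_probes),
    is_control = FALSE, stringsAsFactors = FALSE)
  if (layout$n_antisense_controls > 0) {
    src <- sample(probe$probe_id, layout$n_antisense_controls,
                  replace = layout$n_antisense_controls > nrow(probe))
    probe <- rbind(probe, data.frame(
      probe_id = sprintf("as_%s", src),
      target_id = NA_character_, is_control = TRUE,
      stringsAsFactors = FALSE))
  }
  n_spots <- draw_counts(layout$spots_per_probe, nrow(probe))
  spots <- data.frame(
    probe_id = rep(probe$probe_id, n_spots),
    target_id = rep(probe$target_id, n_spots),
    is_control = rep(probe$is_control, n_spots),
    stringsAsFactors = FALSE)
  spots <- spots[sample.int(nrow(spots)), , drop = FALSE]
  spots$spot_id <- sprintf("s%05d", seq_len(nrow(spots)))
  spots$printtip <- rep_len(seq_len(layout$printtip_groups), nrow(spots))
  rownames(spots) <- NULL
  list(probes = probe, spots = spots)
}

#' Simulate a two-color scan set for one experiment
#'
#' Realizes a physical probe/spot layout once, then draws per-array spot
#' intensities under the noise model. Expressed spots carry foreground =
#' Gaussian background + exponential signal with mean
#' 2^(per-channel log2 level); antisense control spots (and spots of
#' unexpressed targets) carry background only. Dye bias and per-print-tip
#' curvature distort the channel ratio smoothly in intensity; dye-swapped
#' arrays exchange which pool is measured in which channel.
#'
#' The biological orientation is: channel of the "numerator" pool over the
#' "denominator" pool, with numerator = late/zygotic (early-late
#' experiment) or the dissected progenitor pool (8-cell experiments).
#'
#' @param truth truth table from [generate_truth()].
#' @param layout an [array_layout()].
#' @param noise a [noise_model()].
#' @param experiment one of `"early_late"`, `"ecto"`, `"meso"`.
#' @param seed RNG seed.
#' @param phys optional pre-realized physical layout (as returned in the
#'   `probes`/`spots` elements); experiments hybridized to the same array
#'   design should share one, as [simulate_study()] arranges.
#' @return list with `scans` (list of per-array spot data.frames, schema
#'   `scan`), `design` (schema `design`), `probes` (probe/target table) and
#'   `spots` (spot layout).
#' @export
simulate_scan <- function(truth, layout = array_layout(),
                          noise = noise_model(),
                          experiment = c("early_late", "ecto", "meso"),
                          seed = NULL, phys = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(layout, "array_layout"), inherits(noise, "noise_model"))
  if (noise$bg_sd <= 0) stop("bg_sd must be > 0")
  pools <- switch(experiment,
                  early_late = c(den = "early", num = "late"),
                  ecto = c(den = "rest", num = "ecto"),
                  meso = c(den = "rest", num = "meso"))
  lfc_col <- paste0("true_logfc_",
                    if (experiment == "early_late") "early_late" else experiment)
  with_seed(seed, {
    if (is.null(phys)) phys <- realize_spots(truth, layout)
    spots <- phys$spots
    n <- nrow(spots)
    ti <- match(spots$target_id, truth$target_id)
    lfc <- truth[[lfc_col]][ti]
    base <- truth$base_log2[ti]
    # a spot carries signal if its target is expressed in this experiment:
    # globally expressed targets always; unexpressed targets only where an
    # 8-cell asymmetry was planted for them (low-A-but-significant stratum)
    on <- !spots$is_control &
      (truth$expressed[ti] | (experiment != "early_late" & lfc != 0))
    on[is.na(on)] <- FALSE
    lfc[!on | is.na(lfc)] <- 0
    base[!on | is.na(base)] <- -Inf   # 2^-Inf = 0 signal

    mid <- mean(range(truth$base_log2))
    half <- max(diff(range(truth$base_log2)) / 2, 1)
    quad <- ((ifelse(is.finite(base), base, mid) - mid) / half)^2
    tipsign <- rep_len(c(1, -1), layout$printtip_groups)
    curve <- noise$printtip_curvature_amplitude * tipsign[spots$printtip] * quad
    dyebias <- noise$dye_bias_amplitude * quad

    n_arr <- layout$n_arrays
    orientation <- rep_len(c("forward", "swap"), n_arr)
    bio <- rep(seq_len(layout$n_bio), each = n_arr / layout$n_bio)
    tech <- sequence(rep(n_arr / layout$n_bio, layout$n_bio))
    design <- data.frame(
      array_id = sprintf("%s_a%d", experiment, seq_len(n_arr)),
      experiment = experiment,
      sample_ch1 = ifelse(orientation == "forward", pools["den"], pools["num"]),
      sample_ch2 = ifelse(orientation == "forward", pools["num"], pools["den"]),
      dye_orientation = orientation, bio_rep = bio, tech_rep = tech,
      stringsAsFactors = FALSE)

    bio_dev <- matrix(rnorm(nrow(truth) * layout$n_bio, 0, noise$bio_sd),
                      nrow(truth), layout$n_bio)
    scans <- vector("list", n_arr)
    names(scans) <- design$array_id
    for (a in seq_len(n_arr)) {
      g <- rnorm(1, 0, noise$array_scale_sd)
      l_a <- lfc + ifelse(on, bio_dev[cbind(ti, bio[a])], 0)
      x_num <- base + l_a / 2 + g
      x_den <- base - l_a / 2 + g
      if (orientation[a] == "forward") {       # ch1 = den, ch2 = num
        x1 <- x_den; x2 <- x_num
      } else {
        x1 <- x_num; x2 <- x_den
      }
      # dye bias + print-tip curvature inflate ch2 relative to ch1
      x1 <- x1 - (dyebias + curve) / 2
      x2 <- x2 + (dyebias + curve) / 2
      z1 <- rnorm(n)
      z2 <- noise$channel_cor * z1 +
        sqrt(1 - noise$channel_cor^2) * rnorm(n)
      # exponential quantile transform of the copula normals, in log space
      # so extreme z stay finite
      s1 <- -pnorm(z1, lower.tail = FALSE, log.p = TRUE) * 2^x1
      s2 <- -pnorm(z2, lower.tail = FALSE, log.p = TRUE) * 2^x2
      scans[[a]] <- data.frame(
        spot_id = spots$spot_id, probe_id = spots$probe_id,
        printtip = spots$printtip, flag = 0L,
        fg_ch1 = pmin(noise$saturation,
                      pmax(0, rnorm(n, noise$bg_mean, noise$bg_sd) + s1)),
        bg_ch1 = pmax(0, rnorm(n, noise$bg_mean, noise$bg_sd)),
        fg_ch2 = pmin(noise$saturation,
                      pmax(0, rnorm(n, noise$bg_mean, noise$bg_sd) + s2)),
        bg_ch2 = pmax(0, rnorm(n, noise$bg_mean, noise$bg_sd)),
        stringsAsFactors = FALSE)
    }
    list(scans = scans, design = design, probes = phys$probes, spots = spots)
  })
}

#' Simulate foreground/background pairs from a known normexp model
#'
#' Draws `n` spots whose foreground is Gaussian background (mean `mu`,
#' SD `sigma`) plus exponential signal with rate `alpha`, and an
#' independent Gaussian background column; used to check background
#' correction parameter recovery against known truth.
#'
#' @param n number of spots.
#' @param mu,sigma,alpha background mean/SD and exponential signal rate.
#' @param seed RNG seed.
#' @return data.frame with columns `fg`, `bg`, `signal` (the true draws).
#' @export
simulate_normexp_data <- function(n, mu = 100, sigma = 25, alpha = 1 / 450,
                                  seed = NULL) {
  if (sigma <= 0 || alpha <= 0) stop("sigma and alpha must be > 0")
  with_seed(seed, {
    s <- rexp(n, alpha)
    data.frame(fg = rnorm(n, mu, sigma) + s,
               bg = rnorm(n, mu, sigma),
               signal = s)
  })
}

#' Generate target, probe and EST sequences consistent with a probe table
#'
#' Builds random target contigs containing each expression probe as an
#' exact 60-mer substring, emits antisense control probes as reverse
#' complements of expression probes, and optionally plants
#' cross-hybridizing probes (the probe's sequence appended to a second
#' target, so it maps ambiguously) and second-round-rescuable probes
#' (present only in a raw EST of exactly one contig, mirroring sequence
#' trimmed during contig assembly).
#'
#' @param probes probe table (`probe_id`, `target_id`, `is_control`) as
#'   produced by [simulate_scan()].
#' @param probe_length oligo length (nt).
#' @param n_crosshyb number of planted multi-target probes.
#' @param n_rescue number of planted EST-rescuable probes (added to the
#'   probe set with ids `rescue_*`).
#' @param ests_per_target expected number of raw ESTs per contig.
#' @param seed RNG seed.
#' @return list: `targets`, `probes`, `ests` (DNAStringSet), `est_membership`
#'   (data.frame est_id/contig_id), `probe_info` (planted flags per probe).
#' @export
generate_sequences <- function(probes, probe_length = 60, n_crosshyb = 0,
                               n_rescue = 0, ests_per_target = 2,
                               seed = NULL) {
  expr_probes <- probes[!probes$is_control, , drop = FALSE]
  if (n_crosshyb > nrow(expr_probes))
    stop("n_crosshyb exceeds the number of expression probes")
  with_seed(seed, {
    rand_seq <- function(n) {
      vapply(n, function(len)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), character(1))
    }
    tids <- unique(expr_probes$target_id)
    npt <- table(factor(expr_probes$target_id, levels = tids))
    tlen <- 120 + as.integer(npt) * (probe_length + 60)
    if (any(tlen <= probe_length)) stop("probe_length exceeds a target length")
    targets <- rand_seq(tlen)
    names(targets) <- tids
    probe_seq <- character(nrow(expr_probes))
    names(probe_seq) <- expr_probes$probe_id
    for (i in seq_along(tids)) {
      k <- npt[i]
      ids <- expr_probes$probe_id[expr_probes$target_id == tids[i]]
      seg <- floor(tlen[i] / k)
      for (j in seq_len(k)) {
        off <- (j - 1) * seg + sample.int(seg - probe_length, 1)
        probe_seq[ids[j]] <- substr(targets[i], off + 1, off + probe_length)
      }
    }
    # cross-hybridizers: append the probe's 60-mer to one other target
    ch <- character(0)
    if (n_crosshyb > 0) {
      ch <- sample(expr_probes$probe_id, n_crosshyb)
      for (p in ch) {
        own <- expr_probes$target_id[expr_probes$probe_id == p]
        other <- sample(setdiff(tids, own), 1)
        targets[other] <- paste0(targets[other], probe_seq[p])
      }
    }
    # raw ESTs: substrings of each contig, plus per-contig trimmed flank
    est_id <- character(0); est_seq <- character(0); est_tgt <- character(0)
    for (i in seq_along(tids)) {
      k <- max(1L, stats::rpois(1, ests_per_target - 1) + 1L)
      for (j in seq_len(k)) {
        len <- sample(seq(probe_length + 20, tlen[i]), 1)
        off <- sample.int(tlen[i] - len + 1, 1)
        est_id <- c(est_id, sprintf("%s_est%d", tids[i], j))
        est_seq <- c(est_seq, substr(targets[i], off, off + len - 1))
        est_tgt <- c(est_tgt, tids[i])
      }
    }
    rescue_seq <- character(0)
    if (n_rescue > 0) {
      hosts <- sample(tids, n_rescue, replace = n_rescue > length(tids))
      for (r in seq_len(n_rescue)) {
        pid <- sprintf("rescue_%03d", r)
        pseq <- rand_seq(probe_length)
        rescue_seq[pid] <- pseq
        est_id <- c(est_id, sprintf("%s_trim%d", hosts[r], r))
        est_seq <- c(est_seq, paste0(rand_seq(40), pseq, rand_seq(40)))
        est_tgt <- c(est_tgt, hosts[r])
      }
    }
    ctrl <- probes[probes$is_control, , drop = FALSE]
    ctrl_seq <- character(0)
    if (nrow(ctrl)) {
      src <- sub("^as_", "", ctrl$probe_id)
      ok <- src %in% names(probe_seq)
      src[!ok] <- sample(names(probe_seq), sum(!ok), replace = TRUE)
      ctrl_seq <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(probe_seq[src])))
      names(ctrl_seq) <- ctrl$probe_id
    }
    all_probes <- c(probe_seq, ctrl_seq, rescue_seq)
    probe_info <- data.frame(
      probe_id = names(all_probes),
      is_control = names(all_probes) %in% ctrl$probe_id,
      planted_crosshyb = names(all_probes) %in% ch,
      planted_rescue = grepl("^rescue_", names(all_probes)),
      stringsAsFactors = FALSE)
    list(targets = Biostrings::DNAStringSet(targets),
         probes = Biostrings::DNAStringSet(all_probes),
         ests = Biostrings::DNAStringSet(setNames(est_seq, est_id)),
         est_membership = data.frame(est_id = est_id, contig_id = est_tgt,
                                     stringsAsFactors = FALSE),
         probe_info = probe_info)
  })
}

#' Generate a random target-to-GO annotation table
#'
#' Assigns each target a Poisson number of terms from a small synthetic GO
#' vocabulary; optionally enriches one term inside a given target subset.
#'
#' @param target_ids character vector of targets.
#' @param n_terms vocabulary size.
#' @param mean_terms mean number of terms per target.
#' @param enrich optional list(`go_id`, `targets`, `prob`): members of
#'   `targets` additionally receive `go_id` with probability `prob`.
#' @param seed RNG seed.
#' @return data.frame (`target_id`, `go_id`), one row per assignment.
#' @export
generate_annotation <- function(target_ids, n_terms = 25, mean_terms = 1.5,
                                enrich = NULL, seed = NULL) {
  with_seed(seed, {
    vocab <- sprintf("GO:%07d", seq_len(n_terms))
    k <- stats::rpois(length(target_ids), mean_terms)
    ann <- data.frame(
      target_id = rep(target_ids, k),
      go_id = unlist(lapply(k, function(m) sample(vocab, m))),
      stringsAsFactors = FALSE)
    if (!is.null(enrich)) {
      hit <- enrich$targets[runif(length(enrich$targets)) < enrich$prob]
      ann <- rbind(ann, data.frame(target_id = hit, go_id = enrich$go_id,
                                   stringsAsFactors = FALSE))
    }
    unique(ann[order(ann$target_id, ann$go_id), , drop = FALSE])
  })
}
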