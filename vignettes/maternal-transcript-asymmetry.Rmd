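---
title: "Detecting asymmetrically inherited maternal transcripts with two-color arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting asymmetrically inherited maternal transcripts with two-color arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In embryos with a total, unequal and invariant early cleavage, the
blastomeres of the 8-cell stage are already committed to single germ
layers, while the zygotic genome is still silent. Whatever instructs
those early fates must therefore be maternally provided, and a natural
candidate mechanism is the asymmetric distribution of maternal RNAs to
the progenitor cells. `asymma` implements a complete analysis chain for
custom two-color expression microarrays designed to test this: it takes
probe-level scans from three dye-swap experiments —

1. **early vs late**: pooled RNA from pre-transcription embryos against
   RNA from transcriptionally active stages, identifying maternally and
   zygotically enriched transcripts;
2. **ectoderm progenitors vs rest of the 8-cell embryo**;
3. **mesoderm progenitors vs rest of the 8-cell embryo**;

— and produces a catalogue of asymmetrically distributed RNAs,
cross-referenced with the temporal (maternal/zygotic) classes.

## The measurement model and pipeline

A two-color spot yields foreground and background intensities in two
channels. Throughout, `M = log2(num/den)` is the fold change of the
biological numerator pool (the late pool, or the dissected progenitor
pool) over the denominator pool, and `A` is the average log2 intensity.
On dye-swapped arrays the pools exchange channels and M is sign-resolved
back to the biological orientation.

The processing order is fixed:

1. **normexp background correction** (`normexp_correct`, offset 50).
   Observed `fg - bg` is modelled as exponential signal plus Gaussian
   noise; the correction is the posterior mean of the signal given the
   observation, which is always positive, plus an offset of 50 that
   deliberately damps fold changes of near-background signals.
   Parameters are estimated per channel by (saddle-point) maximum
   likelihood.
2. **M/A computation with dye-swap resolution** (`compute_MA`).
3. **print-tip loess** (`printtip_loess`): within each print-tip group, a
   robust local-linear fit of M on A (tricube weights, span 0.3, 4
   robustifying iterations — the established defaults for this
   normalization) is subtracted, removing intensity-dependent dye bias
   and pin-specific curvature. Groups below 20 usable spots fall back to
   the whole-array fit.
4. **A-quantile normalization** (`aquantile_normalize`): every array's A
   distribution is forced onto the across-array mean quantile vector; M
   is untouched.
5. **replicate-spot averaging** (`average_replicate_spots`): multiply
   spotted probes are collapsed by the arithmetic mean, after excluding
   flagged spots.
6. **median-polish summarization** (`medianpolish_summarize`): the
   probes-by-arrays matrix of each multi-probe target is decomposed by
   Tukey's median polish (convergence when the total absolute residual
   changes by less than 1% or after 10 sweeps; median ties resolve to the
   midpoint), applied separately to M and A; the target value per array
   is overall effect plus column effect. Whether to polish M/A or
   per-channel log intensities is a genuinely open choice; M/A is used
   because all downstream inference operates on M and A.

Array QC sits between steps 3 and 4: each array's spot A profile is
correlated with the across-array median profile and arrays with
R² < 0.8 are dropped, mirroring the discard of low-R² arrays at feature
extraction. The profile correlation (rather than, say, a within-array
channel correlation) is used because replicate arrays of a sound
experiment reproduce each other's intensity profiles even when many
targets are strongly differential between the channels.

### Inference

Each experiment compares exactly two pools, so after orientation
resolution the per-target linear model is an intercept-only fit on M
across biological replicates (`fit_linear_model`); technical replicates
are first collapsed by mean within their biological replicate, the
simplest contract that avoids pseudo-replication (intra-block
correlation modelling is out of scope). Empirical-Bayes moderation
(`ebayes_moderate`) shrinks the per-target variances toward a prior
estimated by matching moments of log s²; moderated t, F, two-sided p and
the log-odds B (prior proportion of differentially expressed targets:
1%) follow. When the prior degrees of freedom diverge they are clamped
at 10⁷ and treated as infinite (complete pooling). Multiple testing uses
Benjamini–Yekutieli (`adjust_benjamini_yekutieli`), the FDR step-up
valid under arbitrary dependence; calls are made at adjusted p < 0.05 in
both directions.

### Expression threshold and classes

Antisense control probes measure background-only signal; the expression
cutoff is their mean A plus 3 sample standard deviations (n−1
denominator; `derive_threshold`), computed from the early-vs-late
experiment where the threshold is defined. A target at exactly the
cutoff counts as expressed (documented convention). Whether "expressed"
should additionally require statistical significance is ambiguous;
`classify_expressed` applies the A-cutoff alone but labels the
significant-below-cutoff stratum (`low_expressed_significant`) instead
of dropping it, so both readings are recoverable. Among expressed
targets, the sign of the fold change with significance decides
maternal/zygotic enrichment; expressed non-significant targets are
"equal" (`classify_maternal_zygotic`).

### Asymmetry catalogue

`build_catalogue` takes the four directional significant sets of the two
8-cell experiments (depletion in a dissected pool is enrichment in the
complementary pool) and forms their union with explicit overlap
bookkeeping; "found in both" means the same target id is significant in
any direction in both experiments. `consistency_check` counts
ectoderm-enriched targets reappearing as depleted in the mesoderm
experiment (whose "rest" pool contains the ectoderm progenitors), and
vice versa. `classify_temporal` assigns each member a temporal group
from the early-vs-late classes — maternal_degraded, constant, zygotic,
or unassigned_low_A for members below the expression cutoff — and the
groups partition the catalogue by construction.

### GO overrepresentation

`fisher_enrich` runs a one-sided Fisher's exact test per term on the
2×2 table of study × term membership, with the fold-overrepresentation
statistic (study percentage over reference percentage). Only
overrepresentation is tested, the reference set is an explicit parameter
(different comparisons legitimately use different references), raw
p-values are thresholded at 0.05 by default (a BH adjustment is
available but off, for fidelity to the blast2go-style convention), and
annotations are used as given without GO-graph ancestor propagation.

## The synthetic data generator

The generator (`generate_truth`, `simulate_scan`, `generate_sequences`)
is first-class, tested code: it defines the study conditions under which
the pipeline's statistical behaviour is demonstrated.

* **Truth** (`generate_truth`): class fractions default to the observed
  array composition — 690/6386 maternally enriched, 568/6386 zygotically
  enriched, 236/6386 constant, the rest unexpressed — with 129/6386
  asymmetric targets drawn across temporal classes in the observed
  65:12:17:35 proportions, 10/129 of them planted in both 8-cell
  experiments with biologically consistent opposite signs. Planted
  effects are ±`effect_size` (default 2) log2 units with 0.25 jitter,
  except that asymmetric maternally-degraded targets carry early–late
  fold changes drawn uniform-in-log between 10- and 180-fold, emulating
  the observed stratum of asymmetric maternal RNAs with very large
  early–late changes.
* **Intensities** (`simulate_scan`): foreground = Gaussian background
  (mean 100, SD 25 RFU) + exponential signal with mean
  2^(per-channel log2 level) — the generative dual of the normexp
  correction — clipped at the 65000-RFU scanner ceiling; background
  columns are independent Gaussian draws; antisense controls and
  unexpressed targets are background-only. The two channels' signal
  draws share a Gaussian copula (correlation 0.9, marginals exactly
  exponential), reflecting that both dyes hybridize to the same physical
  spot. Dye bias (0.4 log2) and per-tip curvature (±0.3 log2) are
  quadratic in expected A; arrays get a global log2 scale jitter
  (SD 0.2) and biological replicates a per-target fold-change deviation
  (SD 0.15 log2).
* **Baseline levels** are uniform on log2 [8, 14.5] (≈256–23000 RFU).
  The band is calibrated to the printed intensity scale of the assay —
  detection limit around 450 RFU on a 0–65000 scale — so that expressed
  targets sit above the ~100-RFU background (where the offset of 50
  would otherwise crush fold changes) and only ~1% of spot draws
  saturate, as on a well-tuned scanner.
* **Layout** (`array_layout`): 8 arrays per experiment (4 biological ×
  2 technical replicates), half dye-swapped, 4 print-tip groups, 35/45/20%
  of targets with 1/2/3 probes, 20% of probes spotted twice, 181
  antisense controls.
* **Sequences** (`generate_sequences`): random contigs containing each
  probe as an exact 60-mer substring; cross-hybridizers are appended to a
  second target; rescuable probes exist only in a raw EST of one contig
  (sequence "trimmed during assembly"); antisense controls are reverse
  complements of expression probes.

All randomness flows through explicit seeds (`with_seed` restores the
global RNG state), so every emitted byte is reproducible.

### What the generator does not emulate

Spatial artifacts beyond print-tip curvature (scratches, gradients),
image-level effects, sequence-dependent hybridization efficiency,
cross-hybridization at the *intensity* level (cross-hybridizing probes
are planted in the sequences, not in the signal), and probe-level
saturation chemistry. Passing tests therefore demonstrate the pipeline's
correctness and calibration under a faithful but idealized noise model,
not performance on any particular real scan set.

## Known limitations, surfaced honestly

* **Loess under massive differential expression.** In the early-vs-late
  comparison ~84% of *expressed* targets are truly differential, so at
  high intensity the "most genes unchanged" assumption of loess fails
  and part of the planted effect is absorbed into the trend estimate.
  This attenuates early–late fold-change estimates (it is a property of
  the method itself, not of this implementation); directional calls and
  classes remain correct because effects are planted well above the
  shrunken noise floor.
* **Saturation compresses the top fold changes.** A planted 180-fold
  change is recovered as a few tens-fold because its bright channel
  clips at the scanner ceiling; the catalogue reports the recovered
  maximum.
* **The QC statistic presumes the array's typical composition.** The
  consensus-profile R² draws its discriminating power from the wide
  intensity spread of a realistic array (a large sub-threshold cluster
  plus expressed targets across several log2 units). On a hypothetical
  array where nearly every target is expressed, per-spot noise lowers
  profile correlations toward the 0.8 threshold and sound arrays could
  be flagged; the threshold is a `pipeline_config` knob for such
  designs.
* **Small arrays starve the loess.** Below roughly a thousand spots per
  array the per-tip local fits become unstable in the sparsely populated
  high-intensity range; simulation scales in tests are chosen at or
  above that.

## Problem sizes used in the packaged analyses

The `analysis/` workflow runs at a 2000-target scale (minutes on one
core). The recovery demonstration uses the full 6386-target array
design; FDR calibration uses 200 replicate experiments of 6300 targets
(6000 null + 300 planted at |log2 FC| = 1.5) on the fast single-probe
layout, where the summarization steps reduce to identities. These sizes
are the package's own choices for routine reruns.

## A minimal session

```{r example}
library(asymma)

study <- simulate_study(2000, seed = 101)
run <- run_study(study)
study_report(run)

# probe mapping from sequences
seqs <- generate_sequences(study$experiments$early_late$probes,
                           n_crosshyb = 25, seed = 102)
map <- map_probes(seqs$probes, seqs$targets, max_mismatches = 2)
filter_cross_hybridizing(map)$counts

# GO overrepresentation of the maternal set
maternal <- run$classification$target_id[
  run$classification$class == "maternal_enriched"]
head(fisher_enrich(maternal, run$classification$target_id,
                   study$annotation))
```
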