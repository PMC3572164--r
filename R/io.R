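#' @importFrom utils read.delim write.table head modifyList
#' @importFrom stats rnorm rexp runif rbinom median mad sd quantile approx
#'   lm coef p.adjust fisher.test pnorm qnorm complete.cases setNames aggregate
NULL

# Required columns for each tab-delimited artifact the pipeline reads/writes.
asymma_schemas <- list(
  scan        = c("spot_id", "probe_id", "printtip", "flag",
                  "fg_ch1", "bg_ch1", "fg_ch2", "bg_ch2"),
  design      = c("array_id", "experiment", "sample_ch1", "sample_ch2",
                  "dye_orientation", "bio_rep", "tech_rep"),
  map         = c("probe_id", "target_id", "position", "strand",
                  "mismatches", "uniqueness"),
  est_membership = c("est_id", "contig_id"),
  truth       = c("target_id", "true_logfc_early_late", "true_logfc_ecto",
                  "true_logfc_meso", "expressed", "class_label"),
  annotation  = c("target_id", "go_id"),
  results     = c("target_id", "logFC", "AveExpr", "t", "P.Value",
                  "adj.P.Val", "B"),
  classification = c("target_id", "avg_A", "class", "expressed_flag"),
  catalogue   = c("target_id", "ecto_enriched", "ecto_depleted",
                  "meso_enriched", "meso_depleted", "found_in_both",
                  "temporal_group"),
  enrichment  = c("go_id", "study_count", "study_size", "ref_count",
                  "ref_size", "fold_overrep", "p", "significant")
)

#' Write a typed tab-delimited table with a provenance header
#'
#' Writes `x` as a TSV whose first lines are `#`-prefixed provenance
#' comments (package version plus any caller-supplied key/value lines).
#' Stripping the comment lines leaves a plain machine-parseable table.
#' Floating-point columns are printed with 6 significant digits so that
#' repeated runs under the same seed produce byte-identical files.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param schema optional name of a known schema (see `names(asymma_schemas)`);
#'   when given, the table must contain the schema's columns and they are
#'   placed first, in schema order.
#' @param provenance character vector of extra provenance lines (e.g.
#'   `"seed: 7"`); must be deterministic if byte-reproducibility is wanted.
#' @return `path`, invisibly.
#' @export
write_tsv_schema <- function(x, path, schema = NULL, provenance = character()) {
  stopifnot(is.data.frame(x))
  if (!is.null(schema)) {
    cols <- asymma_schemas[[schema]]
    if (is.null(cols)) stop("unknown schema: ", schema)
    missing <- setdiff(cols, names(x))
    if (length(missing))
      stop("table for schema '", schema, "' is missing column(s): ",
           paste(missing, collapse = ", "))
    x <- x[, c(cols, setdiff(names(x), cols)), drop = FALSE]
  }
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], function(v) signif(v, 6))
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c(sprintf("# asymma %s", as.character(utils::packageVersion("asymma"))),
              if (!is.null(schema)) sprintf("# schema: %s", schema),
              sprintf("# %s", provenance))
  writeLines(header, con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a typed tab-delimited table, validating required columns
#'
#' @param path file written by [write_tsv_schema()] (leading `#` comment
#'   lines are ignored).
#' @param schema optional schema name; required columns are checked.
#' @return data.frame.
#' @export
read_tsv_schema <- function(path, schema = NULL) {
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!is.null(schema)) {
    cols <- asymma_schemas[[schema]]
    if (is.null(cols)) stop("unknown schema: ", schema)
    missing <- setdiff(cols, names(x))
    if (length(missing))
      stop("file '", path, "' is missing required column(s) for schema '",
           schema, "': ", paste(missing, collapse = ", "))
  }
  x
}

#' Read a FASTA file into a DNAStringSet
#'
#' Sequences are uppercased; `N` is preserved. Duplicate record
#' identifiers are an error.
#'
#' @param path FASTA file.
#' @return [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA identifiers in '", path, "': ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write a DNAStringSet (or named character vector) as FASTA
#'
#' @param x sequences; must have unique names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("sequences must carry unique names")
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable constants of the pipeline with their defaults:
#' the significance threshold (`alpha`), normexp offset, loess span,
#' the negative-control standard-deviation multiplier for the expression
#' cutoff, and the probe-mapping mismatch tolerance.
#'
#' @param alpha adjusted-p significance threshold.
#' @param normexp_offset intensity offset added after background correction.
#' @param loess_span span of the print-tip loess fit.
#' @param sd_multiplier number of control SDs above the control mean that
#'   defines the expression A-cutoff.
#' @param max_mismatches Hamming-distance tolerance for probe mapping.
#' @param qc_r2 minimum squared correlation with the experiment consensus
#'   for an array to be kept.
#' @param ... further named settings stored verbatim (seeds, paths, layout).
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(alpha = 0.05, normexp_offset = 50,
                            loess_span = 0.3, sd_multiplier = 3,
                            max_mismatches = 2, qc_r2 = 0.8, ...) {
  cfg <- c(list(alpha = alpha, normexp_offset = normexp_offset,
                loess_span = loess_span, sd_multiplier = sd_multiplier,
                max_mismatches = max_mismatches, qc_r2 = qc_r2),
           list(...))
  for (f in c("alpha", "normexp_offset", "loess_span", "sd_multiplier",
              "max_mismatches", "qc_r2")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("config field '", f, "' must be a single non-negative number")
  }
  if (cfg$alpha > 1) stop("alpha must lie in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' Plain-text round trip: `write_config()` writes a parseable R literal,
#' `read_config()` restores it losslessly.
#'
#' @param config a [pipeline_config()] object.
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  writeLines(deparse(unclass(config)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- eval(parse(file = path))
  do.call(pipeline_config, cfg)
}
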