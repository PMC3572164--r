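# Probe-to-target mapping with cross-hybridization filtering and
# second-round EST rescue. Matching model: Hamming distance (no indels) on
# either strand, N counting as a mismatch; only probes hitting exactly one
# target are retained for expression analysis.

check_alphabet <- function(x, what) {
  af <- Biostrings::alphabetFrequency(x)
  bad <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                    drop = FALSE]) > 0
  if (any(bad))
    stop("non-nucleotide characters (outside A/C/G/T/N) in ", what, ": ",
         paste(head(names(x)[bad], 5), collapse = ", "))
  invisible(TRUE)
}

# All placements of each probe on each subject sequence, both strands,
# Hamming distance <= max_mismatches. Positions are 0-based on the subject's
# plus strand.
match_probe_set <- function(probes, subjects, max_mismatches) {
  hits <- vector("list", length(probes) * 2L)
  h <- 0L
  for (i in seq_along(probes)) {
    p <- probes[[i]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") p else Biostrings::reverseComplement(p)
      m <- Biostrings::vmatchPattern(pat, subjects,
                                     max.mismatch = max_mismatches,
                                     fixed = TRUE)
      starts <- Biostrings::startIndex(m)
      for (j in seq_along(subjects)) {
        st <- starts[[j]]
        if (is.null(st) || !length(st)) next
        st <- st[st >= 1 & st + length(pat) - 1L <= length(subjects[[j]])]
        if (!length(st)) next
        mm <- vapply(st, function(s)
          Biostrings::neditStartingAt(pat, subjects[[j]], starting.at = s,
                                      fixed = TRUE), integer(1))
        keep <- mm <= max_mismatches
        if (!any(keep)) next
        h <- h + 1L
        hits[[h]] <- data.frame(
          probe_id = names(probes)[i],
          target_id = names(subjects)[j],
          position = st[keep] - 1L, strand = strand,
          mismatches = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (h == 0L)
    return(data.frame(probe_id = character(), target_id = character(),
                      position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, hits[seq_len(h)])
}

#' Map probe oligos to target contigs
#'
#' Reports every placement of every probe on every target with Hamming
#' distance at most `max_mismatches`, on either strand, and classifies each
#' probe by the number of distinct targets it hits: `unique` (1), `multi`
#' (>1), or `unmapped` (0). Probes listed in `control_probes` (antisense
#' negative controls) are tagged and are expected to place on the minus
#' strand; they are never treated as expression probes downstream.
#'
#' @param probes named [Biostrings::DNAStringSet] (or named character) of
#'   probe oligos.
#' @param targets named [Biostrings::DNAStringSet] of target contigs.
#' @param max_mismatches maximum Hamming distance (N counts as a mismatch).
#' @param control_probes character vector of antisense control probe ids.
#' @return data.frame with columns `probe_id`, `target_id`, `position`
#'   (0-based), `strand`, `mismatches`, `uniqueness`, `is_control`; one row
#'   per placement plus one `unmapped` row per probe without placements.
#' @export
map_probes <- function(probes, targets, max_mismatches = 2,
                       control_probes = character()) {
  if (is.character(probes)) probes <- Biostrings::DNAStringSet(probes)
  if (is.character(targets)) targets <- Biostrings::DNAStringSet(targets)
  if (length(probes) == 0) stop("empty probe set")
  if (is.null(names(probes)) || is.null(names(targets)))
    stop("probes and targets must be named")
  check_alphabet(probes, "probes")
  check_alphabet(targets, "targets")
  if (max(Biostrings::width(probes)) > min(Biostrings::width(targets)))
    stop("probe length exceeds the shortest target length")
  map <- match_probe_set(probes, targets, max_mismatches)
  ntarg <- tapply(map$target_id, map$probe_id,
                  function(x) length(unique(x)))
  cls <- setNames(rep("unmapped", length(probes)), names(probes))
  cls[names(ntarg)] <- ifelse(ntarg > 1, "multi", "unique")
  missing <- setdiff(names(probes), map$probe_id)
  if (length(missing))
    map <- rbind(map, data.frame(probe_id = missing, target_id = NA_character_,
                                 position = NA_integer_, strand = NA_character_,
                                 mismatches = NA_integer_,
                                 stringsAsFactors = FALSE))
  map$uniqueness <- cls[map$probe_id]
  map$is_control <- map$probe_id %in% control_probes
  rownames(map) <- NULL
  map[order(map$probe_id, map$target_id, map$position), , drop = FALSE]
}

#' Discard cross-hybridizing probes
#'
#' Partitions the (non-control) probes of a map into uniquely mapping
#' probes (retained), multi-target probes (discarded as potential
#' cross-hybridizers) and unmapped probes.
#'
#' @param map probe-target map from [map_probes()].
#' @return list: `retained` (map rows of unique expression probes),
#'   `discarded`, `unmapped` (character vectors of probe ids), `controls`
#'   (map rows of control probes) and `counts`.
#' @export
filter_cross_hybridizing <- function(map) {
  ctrl <- map[map$is_control, , drop = FALSE]
  expr <- map[!map$is_control, , drop = FALSE]
  per_probe <- unique(expr[, c("probe_id", "uniqueness")])
  retained <- expr[expr$uniqueness == "unique", , drop = FALSE]
  discarded <- per_probe$probe_id[per_probe$uniqueness == "multi"]
  unmapped <- per_probe$probe_id[per_probe$uniqueness == "unmapped"]
  list(retained = retained, discarded = discarded, unmapped = unmapped,
       controls = ctrl,
       counts = c(retained = length(unique(retained$probe_id)),
                  discarded = length(discarded),
                  unmapped = length(unmapped),
                  controls = length(unique(ctrl$probe_id))))
}

#' Second-round rescue of non-unique probes against raw ESTs
#'
#' Probes discarded or unmapped in the first round are re-mapped against
#' the raw (pre-assembly) ESTs; a probe whose EST hits all belong to
#' exactly one contig is rescued, with its target set to that contig's
#' identifier suffixed `"_ext"`. ESTs absent from the membership table are
#' treated as singleton targets of their own id, with a warning.
#'
#' @param probes named DNAStringSet of the probes to rescue.
#' @param ests named DNAStringSet of raw ESTs.
#' @param est_membership data.frame (`est_id`, `contig_id`).
#' @param max_mismatches Hamming tolerance.
#' @return data.frame of map additions (`probe_id`, `target_id`, `position`,
#'   `strand`, `mismatches`, `uniqueness = "rescued"`, `est_id`).
#' @export
rescue_second_round <- function(probes, ests, est_membership,
                                max_mismatches = 2) {
  empty <- data.frame(probe_id = character(), target_id = character(),
                      position = integer(), strand = character(),
                      mismatches = integer(), uniqueness = character(),
                      est_id = character(), stringsAsFactors = FALSE)
  if (length(probes) == 0) return(empty)
  if (is.character(probes)) probes <- Biostrings::DNAStringSet(probes)
  orphan <- setdiff(names(ests), est_membership$est_id)
  if (length(orphan)) {
    warning(length(orphan), " EST(s) without contig membership; ",
            "treated as singleton targets")
    est_membership <- rbind(est_membership,
                            data.frame(est_id = orphan, contig_id = orphan,
                                       stringsAsFactors = FALSE))
  }
  hits <- match_probe_set(probes, ests, max_mismatches)
  if (!nrow(hits)) return(empty)
  hits$contig_id <- est_membership$contig_id[match(hits$target_id,
                                                   est_membership$est_id)]
  res <- lapply(split(hits, hits$probe_id), function(h) {
    if (length(unique(h$contig_id)) != 1L) return(NULL)
    best <- h[which.min(h$mismatches), , drop = FALSE]
    data.frame(probe_id = best$probe_id,
               target_id = paste0(best$contig_id, "_ext"),
               position = best$position, strand = best$strand,
               mismatches = best$mismatches, uniqueness = "rescued",
               est_id = best$target_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Summarize an EST-to-contig assembly membership table
#'
#' @param est_membership data.frame (`est_id`, `contig_id`).
#' @return named vector: number of ESTs, ESTs in multi-EST contigs, contigs
#'   (>= 2 ESTs), singletons, and total targets (contigs + singletons).
#' @export
assembly_summary <- function(est_membership) {
  sizes <- table(est_membership$contig_id)
  c(n_ests = nrow(est_membership),
    n_ests_in_contigs = sum(sizes[sizes >= 2]),
    n_contigs = sum(sizes >= 2),
    n_singletons = sum(sizes == 1),
    n_targets = sum(sizes >= 2) + sum(sizes == 1))
}
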