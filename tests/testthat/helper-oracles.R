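# Independent reference implementations used to cross-check the package:
# exhaustive-offset probe mapping, Benjamini-Yekutieli step-up by
# definition, hypergeometric tail enumeration, and sort/average/unsort
# quantile normalization.

revcomp_chr <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# every placement of every probe on every target, both strands, by direct
# character comparison at every offset
brute_map <- function(probes, targets, max_mm) {
  rows <- list()
  for (p in names(probes)) {
    pl <- nchar(probes[[p]])
    pats <- c("+" = probes[[p]], "-" = revcomp_chr(probes[[p]]))
    for (tg in names(targets)) {
      tseq <- strsplit(targets[[tg]], "")[[1]]
      for (st in c("+", "-")) {
        pat <- strsplit(pats[[st]], "")[[1]]
        for (off in 0:(length(tseq) - pl)) {
          mm <- sum(pat != tseq[(off + 1):(off + pl)])
          if (mm <= max_mm)
            rows[[length(rows) + 1]] <- data.frame(
              probe_id = p, target_id = tg, position = off, strand = st,
              mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(probe_id = character(), target_id = character(),
                      position = integer(), strand = character(),
                      mismatches = integer()))
  do.call(rbind, rows)
}

random_instance <- function(n_probes, n_targets, probe_len = 12,
                            target_len = 60) {
  targets <- setNames(vapply(seq_len(n_targets), function(i)
    paste(sample(c("A", "C", "G", "T"), target_len, TRUE), collapse = ""),
    character(1)), paste0("t", seq_len(n_targets)))
  probes <- setNames(character(n_probes), paste0("p", seq_len(n_probes)))
  for (i in seq_len(n_probes)) {
    if (runif(1) < 0.7) {           # planted substring, possibly mutated
      tg <- sample(n_targets, 1)
      off <- sample(target_len - probe_len + 1, 1)
      s <- substr(targets[[tg]], off, off + probe_len - 1)
      if (runif(1) < 0.5) {
        pos <- sample(probe_len, 1)
        substr(s, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.3) s <- revcomp_chr(s)
      probes[i] <- s
    } else {
      probes[i] <- paste(sample(c("A", "C", "G", "T"), probe_len, TRUE),
                         collapse = "")
    }
  }
  list(probes = probes, targets = targets)
}

# Benjamini-Yekutieli step-up straight from the definition
by_stepup <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj <- pmin(1, m * cm * p[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper-tail hypergeometric probability by direct enumeration
hyper_tail <- function(a, K, n_study, N) {
  ks <- a:min(K, n_study)
  sum(choose(K, ks) * choose(N - K, n_study - ks)) / choose(N, n_study)
}

# sort/average/unsort quantile normalization (no ties, no NAs)
quantile_norm_oracle <- function(mat) {
  sorted <- apply(mat, 2, sort)
  target <- rowMeans(sorted)
  out <- mat
  for (j in seq_len(ncol(mat))) out[, j] <- target[rank(mat[, j])]
  out
}
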