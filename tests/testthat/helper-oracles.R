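# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different computational routes than the package
# (direct log-factorial enumeration, lm(), brute force) so agreement is a
# genuine cross-check.

# Hardy-Weinberg exact p by direct enumeration: conditional probability of
# each heterozygote count from the closed-form multinomial / hypergeometric
# expression, P(h | n, nA) = n! 2^h / (nAA! h! naa!) * nA! na! / (2n)!
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n - nA
  h_all <- seq.int(nA %% 2, min(nA, na), by = 2)
  logp <- vapply(h_all, function(h) {
    naa_h <- (nA - h) / 2
    nbb_h <- (na - h) / 2
    lfactorial(n) + h * log(2) - lfactorial(naa_h) - lfactorial(h) -
      lfactorial(nbb_h) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_Aa, h_all)
  sum(p[p <= p[obs] * (1 + 1e-9)])
}

# minimal panel builder: dosage matrix + evenly spaced loci on one chromosome
make_panel <- function(dosage, chrom = "chr1", ref = "A", alt = "G",
                       pos = NULL, groups = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  loci <- data.frame(chrom = rep_len(chrom, m), pos = pos,
                     ref = rep_len(ref, m), alt = rep_len(alt, m))
  samples <- data.frame(
    accession_id = sprintf("S%02d", seq_len(nrow(dosage))),
    group = if (is.null(groups)) NA_character_ else groups)
  geno_panel(dosage, loci, samples)
}

# panel whose substitution classes are fixed: n_ts transition sites and
# n_tv transversion sites spread over the ordered classes
make_spectrum_panel <- function(n_ts, n_tv) {
  ts_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  tv_pairs <- list(c("A", "C"), c("A", "T"), c("C", "A"), c("C", "G"),
                   c("G", "C"), c("G", "T"), c("T", "A"), c("T", "G"))
  pick <- function(pairs, n) {
    idx <- rep_len(seq_along(pairs), n)
    do.call(rbind, lapply(pairs[idx], function(p) {
      data.frame(ref = p[1], alt = p[2])
    }))
  }
  sub <- rbind(pick(ts_pairs, n_ts), pick(tv_pairs, n_tv))
  m <- nrow(sub)
  loci <- data.frame(chrom = "chr1", pos = seq_len(m) * 10L,
                     ref = sub$ref, alt = sub$alt)
  geno_panel(matrix(0L, 2, m), loci)
}

# genotypes drawn with inbreeding coefficient F at given allele frequencies
sim_inbred_dosage <- function(n, p, F) {
  m <- length(p)
  probs <- cbind(het = 2 * p * (1 - p) * (1 - F),
                 alt = p^2 + F * p * (1 - p))
  d <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    u <- stats::runif(n)
    d[, j] <- ifelse(u < probs[j, "alt"], 2L,
                     ifelse(u < probs[j, "alt"] + probs[j, "het"], 1L, 0L))
  }
  d
}

# double-loop pair resolution count (a pair is resolved when some locus has
# both calls present and different) -- the slow independent route
count_resolved_pairs_loop <- function(dosage, loci_idx) {
  n <- nrow(dosage)
  cnt <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (l in loci_idx) {
        a <- dosage[i, l]
        b <- dosage[j, l]
        if (!is.na(a) && !is.na(b) && a != b) {
          cnt <- cnt + 1L
          break
        }
      }
    }
  }
  cnt
}

# map predicted cluster labels onto true labels by the best permutation and
# return the resulting accuracy
best_label_accuracy <- function(predicted, truth) {
  lv_p <- unique(predicted)
  lv_t <- unique(truth)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (pm in perms(lv_t)) {
    mapping <- stats::setNames(pm[seq_along(lv_p)], lv_p)
    acc <- mean(mapping[as.character(predicted)] == truth)
    best <- max(best, acc)
  }
  best
}
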