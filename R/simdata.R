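#' Configure a synthetic germplasm panel
#'
#' Parameters of the synthetic-panel generator. The defaults emulate a
#' three-group tree germplasm collection: two diverged source populations
#' and their interspecific hybrids, with roughly a third of the accessions
#' carrying mixed ancestry, a minor-allele-frequency spectrum that straddles
#' the 0.05 screening cutoff, and a low uniform missing-call rate.
#'
#' @param n_samples number of accessions (>= 2).
#' @param n_loci number of biallelic SNP loci (>= 1).
#' @param n_pops number of source populations (default 3).
#' @param divergence Balding-Nichols drift parameter F in `[0, 1)`; each
#'   population's allele frequency is drawn from
#'   `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the ancestral frequency `p`
#'   (`F = 0` means identical populations).
#' @param admixed_fraction proportion of samples with Dirichlet-distributed
#'   mixed ancestry instead of a single source population.
#' @param maf_range range of ancestral minor-allele frequencies, within
#'   `(0, 0.5]`.
#' @param missing_rate uniform probability that a genotype call is missing.
#' @param n_causal number of causal loci planted for quantitative traits.
#' @param n_chrom number of chromosomes the loci are spread over.
#' @param seed integer seed driving all randomness of the generator.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 200, n_loci = 500, n_pops = 3,
                       divergence = 0.1, admixed_fraction = 1 / 3,
                       maf_range = c(0.02, 0.5), missing_rate = 0.02,
                       n_causal = 3, n_chrom = 8, seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples), n_loci = as.integer(n_loci),
              n_pops = as.integer(n_pops), divergence = divergence,
              admixed_fraction = admixed_fraction, maf_range = maf_range,
              missing_rate = missing_rate, n_causal = as.integer(n_causal),
              n_chrom = as.integer(n_chrom), seed = as.integer(seed))
  if (cfg$n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (cfg$n_loci < 1) stop("n_loci must be >= 1", call. = FALSE)
  if (cfg$n_pops < 1) stop("n_pops must be >= 1", call. = FALSE)
  if (divergence < 0 || divergence >= 1) {
    stop("divergence must be in [0, 1)", call. = FALSE)
  }
  if (admixed_fraction < 0 || admixed_fraction > 1) {
    stop("admixed_fraction must be in [0, 1]", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# the 12 ordered ref->alt substitution classes
SUBSTITUTION_CLASSES <- {
  nt <- c("A", "C", "G", "T")
  p <- expand.grid(ref = nt, alt = nt, stringsAsFactors = FALSE)
  p <- p[p$ref != p$alt, c("ref", "alt")]
  p[order(p$ref, p$alt), ]
}

#' Simulate a three-population admixed genotype panel
#'
#' Draws a diploid dosage matrix under a Balding-Nichols population model:
#' ancestral allele frequencies are uniform on `maf_range`, each source
#' population drifts around them with parameter `divergence`, unadmixed
#' samples draw genotypes binomially from their population's frequencies,
#' and admixed samples draw each of their two allele copies from a source
#' population chosen by their Dirichlet ancestry vector. Missing calls are
#' planted uniformly at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return A list with elements
#'   * `panel`: a [geno_panel()] whose sample `group` is `"pop<k>"` for
#'     unadmixed samples and `"admixed"` otherwise;
#'   * `truth`: ground-truth record with `ancestry` (samples x populations
#'     proportions), `pop_freqs` (loci x populations), `ancestral_freqs`,
#'     `causal_loci` (locus indices) and `causal_effects` (trait units per
#'     alt allele).
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_samples = 20, n_loci = 50, seed = 7))
#' sim$panel
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    m <- config$n_loci
    K <- config$n_pops
    F <- config$divergence

    p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    pop_freqs <- matrix(rep(p0, K), nrow = m)
    if (F > 0) {
      a <- p0 * (1 - F) / F
      b <- (1 - p0) * (1 - F) / F
      for (k in seq_len(K)) {
        pop_freqs[, k] <- stats::rbeta(m, a, b)
      }
    }

    n_adm <- round(config$admixed_fraction * n)
    admixed <- rep(FALSE, n)
    if (n_adm > 0) admixed[sample.int(n, n_adm)] <- TRUE
    pop_of <- rep_len(seq_len(K), n) # round-robin source population
    ancestry <- matrix(0, n, K)
    ancestry[cbind(seq_len(n), pop_of)] <- 1
    if (any(admixed) && K > 1) {
      g <- matrix(stats::rgamma(sum(admixed) * K, shape = 1), ncol = K)
      ancestry[admixed, ] <- g / rowSums(g)
    }

    dosage <- matrix(0L, n, m)
    for (i in seq_len(n)) {
      if (!admixed[i]) {
        dosage[i, ] <- stats::rbinom(m, 2L, pop_freqs[, pop_of[i]])
      } else {
        # each of the two allele copies picks its source population
        src1 <- sample.int(K, m, replace = TRUE, prob = ancestry[i, ])
        src2 <- sample.int(K, m, replace = TRUE, prob = ancestry[i, ])
        f1 <- pop_freqs[cbind(seq_len(m), src1)]
        f2 <- pop_freqs[cbind(seq_len(m), src2)]
        dosage[i, ] <- (stats::runif(m) < f1) + (stats::runif(m) < f2)
      }
    }
    if (config$missing_rate > 0) {
      dosage[stats::runif(n * m) < config$missing_rate] <- NA_integer_
    }

    chrom <- sort(sample.int(config$n_chrom, m, replace = TRUE))
    pos <- integer(m)
    for (cc in unique(chrom)) {
      k <- sum(chrom == cc)
      pos[chrom == cc] <- sort(sample.int(5e7, k))
    }
    sub <- SUBSTITUTION_CLASSES[sample.int(12, m, replace = TRUE), ]
    loci <- tibble::tibble(chrom = paste0("chr", chrom), pos = pos,
                           ref = sub$ref, alt = sub$alt)
    samples <- tibble::tibble(
      accession_id = sprintf("ACC%04d", seq_len(n)),
      group = ifelse(admixed, "admixed", paste0("pop", pop_of))
    )
    panel <- geno_panel(dosage, loci, samples)

    n_causal <- min(config$n_causal, m)
    causal <- sort(sample.int(m, n_causal))
    effects <- stats::rnorm(n_causal, mean = 1, sd = 0.25)
    truth <- list(ancestry = ancestry, pop_freqs = pop_freqs,
                  ancestral_freqs = p0, causal_loci = causal,
                  causal_effects = effects)
    list(panel = panel, truth = truth)
  })
}

# hard-filter thresholds shared by the generator and the filter stage
HARD_FILTER_THRESHOLDS <- list(QD = 2.0, MQ = 40.0, FS = 60.0, SOR = 3.0,
                               MQRankSum = -12.5, ReadPosRankSum = -8.0)

#' Simulate per-site and per-genotype QC annotations
#'
#' Generates the INFO-style site metrics (QD, MQ, FS, SOR, MQRankSum,
#' ReadPosRankSum) and per-genotype GQ/DP that the hard-filter cascade
#' consumes. A chosen fraction of sites is planted to violate exactly one
#' hard-filter criterion so that the cascade's behaviour is fully known.
#'
#' @param panel a [geno_panel()].
#' @param fail_fraction fraction of sites (rounded to a count) planted to
#'   fail the hard filter; in `[0, 1)`.
#' @param seed integer seed.
#' @return A `variant_annotations` list with `site` (tibble of per-site
#'   metrics), `gq` and `dp` (samples x loci integer matrices), and
#'   `planted_fail` (indices of the planted-fail sites).
#' @export
simulate_annotations <- function(panel, fail_fraction = 0, seed = 1) {
  stopifnot(inherits(panel, "geno_panel"))
  if (fail_fraction < 0 || fail_fraction >= 1) {
    stop("fail_fraction must be in [0, 1)", call. = FALSE)
  }
  m <- ncol(panel$dosage)
  n <- nrow(panel$dosage)
  with_seed(seed, {
    site <- tibble::tibble(
      id = panel$loci$id,
      QD = stats::runif(m, 15, 35),
      MQ = stats::runif(m, 50, 60),
      FS = stats::runif(m, 0, 10),
      SOR = stats::runif(m, 0.5, 2.0),
      MQRankSum = stats::rnorm(m, 0, 1.5),
      ReadPosRankSum = stats::rnorm(m, 0, 1.5)
    )
    n_fail <- round(fail_fraction * m)
    planted <- integer(0)
    if (n_fail > 0) {
      planted <- sort(sample.int(m, n_fail))
      crit <- sample(names(HARD_FILTER_THRESHOLDS), n_fail, replace = TRUE)
      for (k in seq_len(n_fail)) {
        j <- planted[k]
        site[[crit[k]]][j] <- switch(crit[k],
          QD = stats::runif(1, 0, 1.9),
          MQ = stats::runif(1, 10, 39),
          FS = stats::runif(1, 61, 100),
          SOR = stats::runif(1, 3.1, 6),
          MQRankSum = stats::runif(1, -20, -12.6),
          ReadPosRankSum = stats::runif(1, -15, -8.1))
      }
    }
    gq <- matrix(pmin(99L, 30L + stats::rpois(n * m, 40L)), n, m)
    dp <- matrix(stats::rpois(n * m, 30L) + 3L, n, m)
    dimnames(gq) <- dimnames(dp) <- dimnames(panel$dosage)
    structure(list(site = site, gq = gq, dp = dp, planted_fail = planted),
              class = "variant_annotations")
  })
}

#' @export
print.variant_annotations <- function(x, ...) {
  cat("<variant_annotations> ", nrow(x$site), " sites, ",
      nrow(x$gq), " samples; planted hard-filter failures: ",
      length(x$planted_fail), "\n", sep = "")
  invisible(x)
}

#' Simulate coded phenotypic traits
#'
#' Builds a trait table in the style of a germplasm survey: one quantitative
#' trait per causal architecture (genetic value = sum of planted effects
#' times dosage, plus Gaussian noise scaled so the realized genetic variance
#' fraction equals `heritability`) and a set of coded categorical traits
#' drawn from given class frequencies.
#'
#' @param panel a [geno_panel()].
#' @param truth the `truth` record from [simulate_panel()].
#' @param heritability proportion of trait variance explained by the planted
#'   loci, in `[0, 1]`; 0 gives a pure-noise trait, 1 a noise-free one.
#' @param n_categorical number of coded categorical traits.
#' @param class_freqs class-frequency vector recycled over the categorical
#'   traits (codes are `1..k`).
#' @param quant_name name of the quantitative trait column.
#' @param seed integer seed.
#' @return A tibble with `accession_id`, the quantitative trait, and
#'   categorical traits `cat01`, `cat02`, ...
#' @export
simulate_phenotypes <- function(panel, truth, heritability = 0.5,
                                n_categorical = 5,
                                class_freqs = c(0.5, 0.3, 0.2),
                                quant_name = "growth", seed = 1) {
  stopifnot(inherits(panel, "geno_panel"))
  if (heritability < 0 || heritability > 1) {
    stop("heritability must be in [0, 1]", call. = FALSE)
  }
  if (length(truth$causal_loci) &&
      max(truth$causal_loci) > ncol(panel$dosage)) {
    stop("causal loci missing from the panel", call. = FALSE)
  }
  n <- nrow(panel$dosage)
  with_seed(seed, {
    d <- impute_dosage(panel)[, truth$causal_loci, drop = FALSE]
    g <- as.numeric(d %*% truth$causal_effects)
    var_g <- stats::var(g)
    if (heritability == 0 || var_g == 0) {
      y <- stats::rnorm(n)
    } else if (heritability == 1) {
      y <- g
    } else {
      sd_e <- sqrt(var_g * (1 - heritability) / heritability)
      y <- g + stats::rnorm(n, 0, sd_e)
    }
    out <- tibble::tibble(accession_id = panel$samples$accession_id)
    out[[quant_name]] <- y
    if (n_categorical > 0) {
      k <- length(class_freqs)
      for (j in seq_len(n_categorical)) {
        out[[sprintf("cat%02d", j)]] <-
          sample.int(k, n, replace = TRUE, prob = class_freqs)
      }
    }
    out
  })
}
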