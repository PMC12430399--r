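#' Allele frequencies at a locus
#'
#' The alternate-allele frequency is computed from non-missing genotypes:
#' `p_alt = (het + 2 * hom_alt) / (2 * n_called)`.
#'
#' @param panel a [geno_panel()].
#' @param locus locus index or id.
#' @return Named numeric vector `c(ref = ..., alt = ...)` summing to 1.
#' @export
allele_freqs <- function(panel, locus) {
  stopifnot(inherits(panel, "geno_panel"))
  if (is.character(locus)) locus <- match(locus, panel$loci$id)
  d <- panel$dosage[, locus]
  d <- d[!is.na(d)]
  if (!length(d)) stop("locus has no non-missing genotypes", call. = FALSE)
  p_alt <- sum(d) / (2 * length(d))
  c(ref = 1 - p_alt, alt = p_alt)
}

# vectorized per-locus components used by locus_stats and group_diversity
locus_stat_components <- function(dosage) {
  n_called <- colSums(!is.na(dosage))
  p_alt <- ifelse(n_called > 0, colSums(dosage, na.rm = TRUE) / (2 * n_called),
                  NA_real_)
  ho <- ifelse(n_called > 0, colSums(dosage == 1L, na.rm = TRUE) / n_called,
               NA_real_)
  list(n_called = unname(n_called), p = unname(p_alt), ho = unname(ho))
}

# Botstein PIC for a biallelic locus with allele frequencies (p, q)
pic_biallelic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Per-locus genetic diversity indices
#'
#' Computes, for every locus, the seven standard codominant-marker
#' polymorphism indices: observed allele number (Na), effective allele
#' number (`Ne = 1 / sum(p_i^2)`), observed heterozygosity (Ho, fraction of
#' heterozygous calls), expected heterozygosity (`He = 1 - sum(p_i^2)`),
#' polymorphic information content (Botstein's
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`), Shannon's index over
#' alleles (`H' = -sum(p_i * ln(p_i))`, nats), and Nei's gene diversity
#' (equal to He for a biallelic locus). All indices use non-missing
#' genotypes only.
#'
#' @param panel a [geno_panel()].
#' @return A tibble with one row per locus: `id`, `chrom`, `pos`, `p`
#'   (alt-allele frequency), `Na`, `Ne`, `Ho`, `He`, `PIC`, `H_prime`,
#'   `Nei`, `n_called`.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_samples = 40, n_loci = 20, seed = 2))
#' locus_stats(sim$panel)
locus_stats <- function(panel) {
  stopifnot(inherits(panel, "geno_panel"))
  cmp <- locus_stat_components(panel$dosage)
  if (any(cmp$n_called == 0)) {
    stop("locus with no non-missing genotypes: ",
         panel$loci$id[which(cmp$n_called == 0)[1]], call. = FALSE)
  }
  p <- cmp$p
  q <- 1 - p
  sum_p2 <- p^2 + q^2
  na <- (p > 0) + (q > 0)
  he <- 1 - sum_p2
  hp <- -ifelse(p > 0, p * log(p), 0) - ifelse(q > 0, q * log(q), 0)
  tibble::tibble(
    id = panel$loci$id, chrom = panel$loci$chrom, pos = panel$loci$pos,
    p = p, Na = as.integer(na), Ne = 1 / sum_p2, Ho = cmp$ho, He = he,
    PIC = pic_biallelic(p), H_prime = hp, Nei = he, n_called = cmp$n_called
  )
}

#' Per-group genetic diversity report
#'
#' Means of the seven per-locus diversity indices within each sample group,
#' computed on the group's own allele frequencies (not pooled). Groups with
#' fewer than two samples are skipped with a warning.
#'
#' @param panel a [geno_panel()].
#' @param groups optional group labels overriding `panel$samples$group`.
#' @return A tibble with one row per group: `group`, `n_samples`, and the
#'   mean of `Na`, `Ne`, `Ho`, `He`, `PIC`, `H_prime`, `Nei` across loci.
#' @export
group_diversity <- function(panel, groups = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  if (is.null(groups)) groups <- panel$samples$group
  groups <- as.character(groups)
  out <- list()
  for (g in unique(groups[!is.na(groups)])) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      warning("group '", g, "' has fewer than 2 samples; skipped",
              call. = FALSE)
      next
    }
    ls <- locus_stats(panel[idx, ])
    out[[g]] <- tibble::tibble(
      group = g, n_samples = length(idx),
      Na = mean(ls$Na), Ne = mean(ls$Ne), Ho = mean(ls$Ho),
      He = mean(ls$He), PIC = mean(ls$PIC), H_prime = mean(ls$H_prime),
      Nei = mean(ls$Nei)
    )
  }
  dplyr::bind_rows(out)
}

#' Summary statistics for phenotypic traits
#'
#' Per-trait maximum, minimum, mean, population standard deviation
#' (divide-by-n), coefficient of variation (`CV = SD / mean * 100`, percent)
#' and Shannon diversity over class relative frequencies
#' (`H' = -sum(P_i * ln(P_i))`, nats). Coded categorical traits use their
#' observed classes directly; traits declared continuous are binned into
#' equal-width bins for H' only.
#'
#' @param traits trait table: a data frame with `accession_id` plus one
#'   column per trait.
#' @param trait optional single trait name; default summarizes all.
#' @param continuous character vector of trait names treated as continuous.
#' @param n_bins number of equal-width bins for continuous traits' H'.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return A tibble with `trait`, `maximum`, `minimum`, `mean`, `sd`, `cv`,
#'   `H_prime`, `n`.
#' @export
#' @examples
#' tr <- data.frame(accession_id = paste0("S", 1:6),
#'                  leaf_color = c(3, 3, 3, 3, 3, 3),
#'                  height = c(1.2, 0.9, 1.5, 1.1, 1.3, 1.0))
#' trait_summary(tr, continuous = "height")
trait_summary <- function(traits, trait = NULL, continuous = character(),
                          n_bins = 10, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  traits <- tibble::as_tibble(traits)
  cols <- setdiff(names(traits), "accession_id")
  if (!is.null(trait)) {
    if (!trait %in% cols) stop("unknown trait: ", trait, call. = FALSE)
    cols <- trait
  }
  rows <- lapply(cols, function(nm) {
    x <- traits[[nm]]
    x <- x[!is.na(x)]
    if (!length(x)) stop("trait '", nm, "' is entirely missing",
                         call. = FALSE)
    n <- length(x)
    mu <- mean(x)
    s <- stats::sd(x)
    if (is.na(s)) s <- 0
    if (sd_type == "population") s <- s * sqrt((n - 1) / n)
    cv <- if (s == 0) 0 else if (mu == 0) NA_real_ else s / mu * 100
    cls <- if (nm %in% continuous && s > 0) {
      cut(x, breaks = n_bins, include.lowest = TRUE)
    } else {
      x
    }
    p_i <- as.numeric(table(cls)) / n
    p_i <- p_i[p_i > 0]
    hp <- if (s == 0) 0 else -sum(p_i * log(p_i))
    tibble::tibble(trait = nm, maximum = max(x), minimum = min(x),
                   mean = mu, sd = s, cv = cv, H_prime = hp, n = n)
  })
  dplyr::bind_rows(rows)
}

#' Pearson correlation matrix of traits
#'
#' Pairwise-complete Pearson correlations between trait columns. Constant
#' traits yield `NA` entries (flagged with a warning) rather than errors.
#'
#' @param traits trait table (`accession_id` plus trait columns).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
trait_correlations <- function(traits) {
  traits <- tibble::as_tibble(traits)
  x <- as.matrix(traits[setdiff(names(traits), "accession_id")])
  if (nrow(x) < 3) stop("need at least 3 samples", call. = FALSE)
  const <- apply(x, 2, function(v) stats::sd(v, na.rm = TRUE) == 0)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  if (any(const, na.rm = TRUE)) {
    warning("constant trait(s) give undefined correlations: ",
            paste(colnames(x)[which(const)], collapse = ", "),
            call. = FALSE)
  }
  r
}

#' Principal component analysis of standardized traits
#'
#' PCA on zero-mean, unit-variance trait columns. Constant traits are
#' dropped (with a message) before standardization.
#'
#' @param traits trait table (`accession_id` plus trait columns).
#' @return An object of class `trait_pca` with `scores` (tibble),
#'   `loadings` (matrix), `explained` (percent variance per component) and
#'   `dropped` (names of constant traits).
#' @export
pheno_pca <- function(traits) {
  traits <- tibble::as_tibble(traits)
  ids <- traits$accession_id
  x <- as.matrix(traits[setdiff(names(traits), "accession_id")])
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    message("dropping constant trait(s): ", paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least 2 non-constant traits", call. = FALSE)
  z <- scale(x)
  pc <- pca_core(z)
  scores <- tibble::as_tibble(pc$scores, .name_repair = "minimal")
  names(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores <- dplyr::bind_cols(tibble::tibble(accession_id = ids), scores)
  structure(list(scores = scores, loadings = pc$loadings,
                 explained = pc$explained, dropped = dropped),
            class = "trait_pca")
}

# shared SVD core with deterministic sign fixing: for each component the
# largest-magnitude loading is made positive
pca_core <- function(z) {
  sv <- svd(z)
  r <- sum(sv$d > max(sv$d) * 1e-10)
  d <- sv$d[seq_len(r)]
  u <- sv$u[, seq_len(r), drop = FALSE]
  v <- sv$v[, seq_len(r), drop = FALSE]
  flip <- vapply(seq_len(r), function(k) {
    j <- which.max(abs(v[, k]))
    sign(v[j, k])
  }, numeric(1))
  flip[flip == 0] <- 1
  u <- sweep(u, 2, flip, `*`)
  v <- sweep(v, 2, flip, `*`)
  expl <- 100 * d^2 / sum(sv$d^2)
  scores <- sweep(u, 2, d, `*`)
  rownames(v) <- colnames(z)
  colnames(v) <- colnames(scores) <- paste0("PC", seq_len(r))
  list(scores = scores, loadings = v, explained = expl)
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("<trait_pca> ", nrow(x$scores), " samples, ", nrow(x$loadings),
      " traits\n  PC1-PC2 explain ",
      sprintf("%.2f%%", sum(x$explained[1:min(2, length(x$explained))])),
      " of the variance\n", sep = "")
  invisible(x)
}

#' Membership-function D-value scoring
#'
#' Comprehensive germplasm score: each trait is rescaled to a membership
#' value `u = (x - min) / (max - min)` (reversed for smaller-is-better
#' traits) and the D-value is the weighted mean of memberships, in `[0, 1]`.
#'
#' @param traits trait table (`accession_id` plus trait columns).
#' @param weights named non-negative weights over scored traits (normalized
#'   to sum to 1); default equal weights over all trait columns.
#' @param direction named character vector, `"larger"` (default) or
#'   `"smaller"`, per scored trait.
#' @return A tibble with `accession_id` and `D`, sorted as input.
#' @export
membership_D <- function(traits, weights = NULL, direction = NULL) {
  traits <- tibble::as_tibble(traits)
  cols <- setdiff(names(traits), "accession_id")
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(cols), length(cols)), cols)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  weights <- weights / sum(weights)
  scored <- names(weights)[weights > 0]
  dir <- stats::setNames(rep("larger", length(scored)), scored)
  if (!is.null(direction)) dir[names(direction)] <- direction
  u <- matrix(0, nrow(traits), length(scored),
              dimnames = list(NULL, scored))
  for (nm in scored) {
    x <- traits[[nm]]
    rng <- range(x, na.rm = TRUE)
    if (rng[1] == rng[2]) {
      stop("constant trait with nonzero weight: ", nm, call. = FALSE)
    }
    ui <- (x - rng[1]) / (rng[2] - rng[1])
    if (dir[[nm]] == "smaller") ui <- 1 - ui
    u[, nm] <- ui
  }
  tibble::tibble(accession_id = traits$accession_id,
                 D = as.numeric(u %*% weights[scored]))
}
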