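#' Single-marker general linear model association scan
#'
#' For each SNP, ordinary least squares of the trait on an intercept plus
#' the additive dosage (0/1/2), over complete cases. The two-sided p-value
#' comes from the t distribution with `n_used - 2` degrees of freedom.
#' SNPs monomorphic among the complete cases are reported with `NA`
#' statistics rather than dropped.
#'
#' @param panel a [geno_panel()].
#' @param trait per-sample trait values: a numeric vector aligned with the
#'   panel's samples, or a data frame with `accession_id` and one trait
#'   column (named via `trait_name`).
#' @param trait_name column to use when `trait` is a data frame; defaults
#'   to its single non-id column.
#' @param min_cases minimum complete cases per SNP (default 3).
#' @return A `gwas_result` tibble: `snp_id`, `chrom`, `pos`, `beta`, `se`,
#'   `t`, `p`, `n_used`, plus attribute `trait`.
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_samples = 60, n_loci = 80, seed = 3))
#' ph <- simulate_phenotypes(sim$panel, sim$truth, heritability = 0.6)
#' head(glm_scan(sim$panel, ph, trait_name = "growth"))
glm_scan <- function(panel, trait, trait_name = NULL, min_cases = 3) {
  stopifnot(inherits(panel, "geno_panel"))
  if (is.data.frame(trait)) {
    cols <- setdiff(names(trait), "accession_id")
    if (is.null(trait_name)) {
      if (length(cols) != 1) {
        stop("supply `trait_name` (table has ", length(cols), " traits)",
             call. = FALSE)
      }
      trait_name <- cols
    }
    y <- trait[[trait_name]][match(panel$samples$accession_id,
                                   trait$accession_id)]
  } else {
    y <- as.numeric(trait)
    if (is.null(trait_name)) trait_name <- "trait"
  }
  if (length(y) != nrow(panel$dosage)) {
    stop("trait length does not match the panel", call. = FALSE)
  }
  if (stats::sd(y, na.rm = TRUE) == 0) {
    stop("trait is constant", call. = FALSE)
  }

  d <- panel$dosage
  storage.mode(d) <- "double"
  obs <- !is.na(d) & !is.na(y) # complete cases per SNP
  x <- d
  x[!obs] <- 0
  ym <- matrix(y, nrow(d), ncol(d))
  ym[!obs] <- 0
  n <- colSums(obs)
  sx <- colSums(x)
  sy <- colSums(ym)
  sxx <- colSums(x^2)
  sxy <- colSums(x * ym)
  syy <- colSums(ym^2)
  ssx <- sxx - sx^2 / n
  ssy <- syy - sy^2 / n
  sxy_c <- sxy - sx * sy / n
  ok <- n >= min_cases & ssx > 0
  beta <- ifelse(ok, sxy_c / ssx, NA_real_)
  rss <- pmax(0, ssy - beta^2 * ssx)
  df <- n - 2
  se <- ifelse(ok & df > 0, sqrt(rss / df / ssx), NA_real_)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  p[!is.na(p) & p == 0] <- .Machine$double.xmin
  out <- tibble::tibble(
    snp_id = panel$loci$id, chrom = panel$loci$chrom, pos = panel$loci$pos,
    beta = unname(beta), se = unname(se), t = unname(tval), p = unname(p),
    n_used = as.integer(unname(n))
  )
  attr(out, "trait") <- trait_name
  class(out) <- c("gwas_result", class(out))
  out
}

#' Filter association results to significant hits with tier labels
#'
#' Keeps SNPs with `p` strictly below the threshold, labeling each with the
#' finest tier among `p < 0.001` and `p < 0.0001` it satisfies. Hits are
#' sorted by trait, then ascending p, with ties broken by chromosome and
#' position.
#'
#' @param results a `gwas_result` (or row-bound tibble of several, with a
#'   `trait` column).
#' @param threshold significance threshold (default `1e-3`, strict `<`).
#' @return A tibble of hits with a `tier` column.
#' @export
significant_hits <- function(results, threshold = 1e-3) {
  if (!nrow(results)) stop("no association results", call. = FALSE)
  res <- tibble::as_tibble(results)
  if (!"trait" %in% names(res)) {
    res$trait <- attr(results, "trait") %||% "trait"
  }
  hits <- res[!is.na(res$p) & res$p < threshold, ]
  hits$tier <- ifelse(hits$p < 1e-4, "p < 0.0001", "p < 0.001")
  hits[order(hits$trait, hits$p, hits$chrom, hits$pos), ]
}

#' Expected vs observed quantiles for a QQ plot
#'
#' Observed p-values sorted ascending against uniform expected quantiles
#' `i / (m + 1)`, both on the -log10 scale.
#'
#' @param results a `gwas_result`.
#' @return A tibble of `expected` and `observed` -log10 p.
#' @export
qq_data <- function(results) {
  p <- results$p[!is.na(results$p)]
  if (!length(p)) stop("no defined p-values", call. = FALSE)
  m <- length(p)
  tibble::tibble(
    expected = -log10(seq_len(m) / (m + 1)),
    observed = -log10(sort(p))
  )
}

#' Cumulative genome coordinates for a Manhattan plot
#'
#' Lays SNPs on a cumulative genome axis: chromosomes in natural order,
#' each offset by the preceding chromosomes' maximum positions, with an
#' alternating parity flag for coloring.
#'
#' @param results a `gwas_result`.
#' @return A tibble of `snp_id`, `chrom`, `pos`, `coord` (cumulative bp),
#'   `neg_log10_p` and `parity`.
#' @export
manhattan_data <- function(results) {
  res <- tibble::as_tibble(results)
  key <- suppressWarnings(as.numeric(sub("^chr", "", res$chrom)))
  chroms <- unique(res$chrom[order(if (anyNA(key)) rank(res$chrom) else key,
                                   res$pos)])
  offs <- c(0, cumsum(vapply(chroms, function(cc) {
    max(res$pos[res$chrom == cc])
  }, numeric(1))))
  names(offs) <- c(chroms, "_end")
  i <- match(res$chrom, chroms)
  tibble::tibble(
    snp_id = res$snp_id, chrom = res$chrom, pos = res$pos,
    coord = unname(res$pos + offs[i]),
    neg_log10_p = -log10(res$p),
    parity = i %% 2L
  )
}

#' @export
#' @importFrom generics glance
generics::glance

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @method tidy gwas_result
tidy.gwas_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$trait <- attr(x, "trait")
  out[, c("trait", "snp_id", "chrom", "pos", "beta", "se", "t", "p",
          "n_used")]
}

#' @export
#' @method glance gwas_result
glance.gwas_result <- function(x, ...) {
  p <- x$p[!is.na(x$p)]
  chisq <- stats::qchisq(1 - p, df = 1)
  tibble::tibble(
    n_snps = nrow(x),
    n_tested = length(p),
    n_hits_1e3 = sum(p < 1e-3),
    n_hits_1e4 = sum(p < 1e-4),
    lambda_gc = stats::median(chisq) / stats::qchisq(0.5, df = 1),
    min_p = if (length(p)) min(p) else NA_real_
  )
}

#' @export
#' @method tidy geno_pca
tidy.geno_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained),
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

#' @export
#' @method glance geno_pca
glance.geno_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores),
                 n_components = sum(grepl("^PC", names(x$scores))),
                 pc1_pct = x$explained[1],
                 pc2_pct = if (length(x$explained) > 1) x$explained[2]
                           else NA_real_)
}

#' @export
#' @method tidy trait_pca
tidy.trait_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained),
                 explained = x$explained,
                 cumulative = cumsum(x$explained))
}

#' @export
#' @method glance trait_pca
glance.trait_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$scores),
                 n_traits = nrow(x$loadings),
                 pc1_2_pct = sum(x$explained[seq_len(min(2,
                   length(x$explained)))]))
}
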