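#' Principal component analysis of genotypes
#'
#' Missing dosages are mean-imputed per locus, columns are centered (not
#' scaled) and the decomposition is computed by SVD. Component signs are
#' fixed deterministically by making the largest-magnitude loading of each
#' component positive.
#'
#' @param panel a [geno_panel()].
#' @param n_components number of components to keep.
#' @return An object of class `geno_pca`: `scores` (tibble with
#'   `accession_id`, `group`, `PC1`, ...), `loadings` (loci x components),
#'   `explained` (percent variance per component, over the full spectrum).
#' @export
#' @examples
#' sim <- simulate_panel(sim_config(n_samples = 30, n_loci = 100, seed = 4))
#' pc <- geno_pca(sim$panel)
#' head(pc$scores)
geno_pca <- function(panel, n_components = 10) {
  stopifnot(inherits(panel, "geno_panel"))
  if (nrow(panel$dosage) < 2) stop("need >= 2 samples", call. = FALSE)
  d <- impute_dosage(panel)
  poly <- apply(d, 2, function(v) stats::var(v) > 0)
  if (sum(poly) < 2) stop("need >= 2 polymorphic loci", call. = FALSE)
  z <- scale(d[, poly, drop = FALSE], center = TRUE, scale = FALSE)
  pc <- pca_core(z)
  k <- min(n_components, ncol(pc$scores))
  scores <- tibble::as_tibble(pc$scores[, seq_len(k), drop = FALSE],
                              .name_repair = "minimal")
  names(scores) <- paste0("PC", seq_len(k))
  scores <- dplyr::bind_cols(
    tibble::tibble(accession_id = panel$samples$accession_id,
                   group = panel$samples$group),
    scores)
  structure(list(scores = scores,
                 loadings = pc$loadings[, seq_len(k), drop = FALSE],
                 explained = pc$explained),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat("<geno_pca> ", nrow(x$scores), " samples\n  PC1 ",
      sprintf("%.2f%%", x$explained[1]), ", PC2 ",
      sprintf("%.2f%%", ifelse(length(x$explained) > 1, x$explained[2], 0)),
      " of total genetic variance\n", sep = "")
  invisible(x)
}

#' Euclidean UPGMA clustering of samples
#'
#' Pairwise Euclidean distances on mean-imputed dosages followed by
#' average-linkage (UPGMA) hierarchical clustering. The result is
#' ultrametric; leaf heights equal half the cophenetic distance.
#'
#' @param panel a [geno_panel()].
#' @return A list of class `upgma_tree`: `hclust` (the merge tree), `phylo`
#'   (an [ape::as.phylo()] tree with branch lengths) and `newick` (the
#'   serialized tree).
#' @export
distance_upgma <- function(panel) {
  stopifnot(inherits(panel, "geno_panel"))
  if (nrow(panel$dosage) < 2) stop("need >= 2 samples", call. = FALSE)
  if (anyDuplicated(panel$samples$accession_id)) {
    stop("duplicate sample ids", call. = FALSE)
  }
  d <- impute_dosage(panel)
  rownames(d) <- panel$samples$accession_id
  hc <- stats::hclust(stats::dist(d, method = "euclidean"),
                      method = "average")
  ph <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = ph,
                 newick = ape::write.tree(ph)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("<upgma_tree> ", length(x$phylo$tip.label), " tips; root height ",
      sprintf("%.4f", max(x$hclust$height) / 2), "\n", sep = "")
  invisible(x)
}

#' Pairwise composite LD on the densest chromosome
#'
#' Selects the chromosome with the most loci, takes its first `max_markers`
#' loci in position order, and computes pairwise r-squared as the squared
#' Pearson correlation of dosage vectors over pairwise-complete samples
#' (the composite, phase-free convention). Pairs involving a locus that is
#' monomorphic among the complete cases are skipped.
#'
#' @param panel a [geno_panel()].
#' @param max_markers maximum number of loci used (default 1000).
#' @return A tibble of `locus_a`, `locus_b`, `distance` (bp) and `r2`.
#' @export
ld_scan <- function(panel, max_markers = 1000) {
  stopifnot(inherits(panel, "geno_panel"))
  tab <- table(panel$loci$chrom)
  dense <- names(tab)[which.max(tab)]
  idx <- which(panel$loci$chrom == dense)
  idx <- idx[order(panel$loci$pos[idx])]
  idx <- utils::head(idx, max_markers)
  if (length(idx) < 2) {
    stop("need >= 2 loci on the densest chromosome", call. = FALSE)
  }
  d <- panel$dosage[, idx, drop = FALSE]
  storage.mode(d) <- "double"
  r <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))
  pos <- panel$loci$pos[idx]
  ids <- panel$loci$id[idx]
  ut <- which(upper.tri(r), arr.ind = TRUE)
  out <- tibble::tibble(
    locus_a = ids[ut[, 1]], locus_b = ids[ut[, 2]],
    distance = abs(pos[ut[, 2]] - pos[ut[, 1]]),
    r2 = r[ut]^2
  )
  dropped <- sum(is.na(out$r2))
  if (dropped) {
    message(dropped, " pair(s) skipped (monomorphic among complete cases)")
  }
  out[!is.na(out$r2), ]
}

#' Bin an LD scan into a decay curve
#'
#' @param pairs a tibble from [ld_scan()].
#' @param bin_width physical bin width in base pairs.
#' @return A tibble of `midpoint` (bp), `mean_r2` and `n_pairs`; empty bins
#'   are omitted.
#' @export
ld_decay <- function(pairs, bin_width = 1000) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (!nrow(pairs)) stop("no LD pairs", call. = FALSE)
  bin <- floor(pairs$distance / bin_width)
  dplyr::summarise(
    dplyr::group_by(dplyr::mutate(pairs, .bin = bin), .data$.bin),
    midpoint = (.data$.bin[1] + 0.5) * bin_width,
    mean_r2 = mean(.data$r2),
    n_pairs = dplyr::n(),
    .groups = "drop"
  )[, c("midpoint", "mean_r2", "n_pairs")]
}

#' Evanno delta-K model selection
#'
#' Post-processes a table of replicate log-likelihoods from an external
#' Bayesian clustering run over a consecutive grid of K. For interior K,
#' the second difference of the replicate-mean log-likelihood is divided by
#' the replicate standard deviation:
#' `delta_K = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`. The best K maximizes
#' delta-K; K values with zero replicate spread have undefined delta-K and
#' are excluded from the argmax.
#'
#' @param logliks a data frame with columns `K`, `rep`, `loglik`, or a
#'   matrix with one row per K (rownames = K) and one column per replicate.
#' @return An `evanno` object: tibble with `K`, `n_rep`, `mean_L`, `sd_L`,
#'   `L_prime`, `L_doubleprime_abs`, `delta_K`, plus attribute `best_K`
#'   (`NA` when no delta-K is defined and positive).
#' @export
#' @examples
#' ll <- expand.grid(K = 1:5, rep = 1:3)
#' ll$loglik <- -c(200, 150, 100, 95, 93)[ll$K] + rnorm(nrow(ll))
#' evanno_delta_k(ll)
evanno_delta_k <- function(logliks) {
  if (is.matrix(logliks)) {
    logliks <- tibble::tibble(
      K = rep(as.integer(rownames(logliks)), ncol(logliks)),
      rep = rep(seq_len(ncol(logliks)), each = nrow(logliks)),
      loglik = as.numeric(logliks)
    )
  }
  logliks <- tibble::as_tibble(logliks)
  stopifnot(all(c("K", "loglik") %in% names(logliks)))
  ks <- sort(unique(logliks$K))
  if (length(ks) < 3) stop("need >= 3 K values", call. = FALSE)
  if (!all(diff(ks) == 1)) stop("K grid must be consecutive", call. = FALSE)
  agg <- dplyr::summarise(dplyr::group_by(logliks, .data$K),
                          n_rep = dplyr::n(),
                          mean_L = mean(.data$loglik),
                          sd_L = stats::sd(.data$loglik), .groups = "drop")
  agg <- agg[order(agg$K), ]
  if (any(agg$n_rep < 2)) stop("need >= 2 replicates per K", call. = FALSE)
  n <- nrow(agg)
  lp <- c(NA, diff(agg$mean_L))
  lpp <- rep(NA_real_, n)
  lpp[2:(n - 1)] <- abs(agg$mean_L[3:n] - 2 * agg$mean_L[2:(n - 1)] +
                          agg$mean_L[1:(n - 2)])
  dk <- lpp / agg$sd_L
  dk[agg$sd_L == 0] <- NA_real_
  out <- dplyr::bind_cols(agg, tibble::tibble(
    L_prime = lp, L_doubleprime_abs = lpp, delta_K = dk))
  best <- if (all(is.na(dk)) || max(dk, na.rm = TRUE) == 0) {
    NA_integer_
  } else {
    out$K[which.max(dk)]
  }
  attr(out, "best_K") <- best
  class(out) <- c("evanno", class(out))
  out
}

#' @export
#' @rdname evanno_delta_k
#' @param x an `evanno` object.
best_k <- function(x) attr(x, "best_K")
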