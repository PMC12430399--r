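#' Filter thresholds for the SNP quality cascade
#'
#' Returns the threshold set used by [site_filters()]. The defaults are the
#' conventional hard-filter cutoffs for short-read SNV calls plus the
#' population-genetic screens applied downstream: genotype missing rate
#' below 20%, minor allele frequency strictly above 0.05, Hardy-Weinberg
#' exact-test p at or above 1e-4, biallelic sites only, genotype-quality
#' masking below GQ 30, at most 1% missing genotypes after masking, and a
#' mean site depth within 3-100x.
#'
#' @param QD,MQ,FS,SOR,MQRankSum,ReadPosRankSum hard-filter cutoffs; a site
#'   fails when `QD < 2`, `MQ < 40`, `FS > 60`, `SOR > 3`,
#'   `MQRankSum < -12.5` or `ReadPosRankSum < -8` (strict inequalities).
#' @param max_missing maximum genotype missing rate (exclusive).
#' @param min_maf minimum minor allele frequency (exclusive).
#' @param min_hwe_p sites with Hardy-Weinberg exact p below this are removed.
#' @param biallelic_only drop non-biallelic records.
#' @param min_gq genotypes with GQ below this are masked to missing.
#' @param max_missing_post maximum missing rate after GQ masking (exclusive).
#' @param depth_range inclusive range for the per-site mean depth.
#' @return A named list of thresholds (class `filter_thresholds`).
#' @export
filter_thresholds <- function(QD = 2.0, MQ = 40.0, FS = 60.0, SOR = 3.0,
                              MQRankSum = -12.5, ReadPosRankSum = -8.0,
                              max_missing = 0.20, min_maf = 0.05,
                              min_hwe_p = 1e-4, biallelic_only = TRUE,
                              min_gq = 30, max_missing_post = 0.01,
                              depth_range = c(3, 100)) {
  th <- list(QD = QD, MQ = MQ, FS = FS, SOR = SOR, MQRankSum = MQRankSum,
             ReadPosRankSum = ReadPosRankSum, max_missing = max_missing,
             min_maf = min_maf, min_hwe_p = min_hwe_p,
             biallelic_only = isTRUE(biallelic_only), min_gq = min_gq,
             max_missing_post = max_missing_post, depth_range = depth_range)
  if (max_missing < 0 || max_missing > 1 || max_missing_post < 0 ||
      max_missing_post > 1) {
    stop("missing-rate thresholds must be in [0, 1]", call. = FALSE)
  }
  if (min_maf < 0 || min_maf >= 0.5) {
    stop("min_maf must be in [0, 0.5)", call. = FALSE)
  }
  if (min_hwe_p < 0 || min_hwe_p > 1) {
    stop("min_hwe_p must be in [0, 1]", call. = FALSE)
  }
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2]) {
    stop("depth_range must be an increasing pair", call. = FALSE)
  }
  class(th) <- "filter_thresholds"
  th
}

#' Hard-filter sites on their variant-call QC metrics
#'
#' Applies the six-criterion hard filter. A site fails when any metric lies
#' beyond its cutoff (strict inequalities); a missing metric means the
#' criterion is not evaluable and that criterion passes.
#'
#' @param annotations a `variant_annotations` object (or its `site` tibble).
#' @param thresholds a [filter_thresholds()].
#' @return A tibble with `id`, `pass`, and `reasons` (comma-joined names of
#'   violated criteria, `""` when passing).
#' @export
hard_filter_sites <- function(annotations, thresholds = filter_thresholds()) {
  site <- if (inherits(annotations, "variant_annotations")) {
    annotations$site
  } else {
    tibble::as_tibble(annotations)
  }
  viol <- cbind(
    QD = !is.na(site$QD) & site$QD < thresholds$QD,
    MQ = !is.na(site$MQ) & site$MQ < thresholds$MQ,
    FS = !is.na(site$FS) & site$FS > thresholds$FS,
    SOR = !is.na(site$SOR) & site$SOR > thresholds$SOR,
    MQRankSum = !is.na(site$MQRankSum) &
      site$MQRankSum < thresholds$MQRankSum,
    ReadPosRankSum = !is.na(site$ReadPosRankSum) &
      site$ReadPosRankSum < thresholds$ReadPosRankSum
  )
  reasons <- apply(viol, 1, function(r) paste(colnames(viol)[r],
                                              collapse = ","))
  tibble::tibble(id = site$id, pass = rowSums(viol) == 0, reasons = reasons)
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact conditional test of Hardy-Weinberg genotype proportions.
#' Given the observed allele counts and sample size, the p-value sums the
#' conditional probabilities of every heterozygote count whose probability
#' does not exceed that of the observed count. Probabilities are computed by
#' the standard recurrence over heterozygote counts, so the test is exact
#' for any sample size.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectorized).
#' @return p-value(s) in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(10, 0, 0)   # monomorphic: p = 1
#' hwe_exact_test(25, 50, 25) # perfectly in equilibrium
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  ln <- max(length(n_AA), length(n_Aa), length(n_aa))
  n_AA <- rep_len(as.integer(n_AA), ln)
  n_Aa <- rep_len(as.integer(n_Aa), ln)
  n_aa <- rep_len(as.integer(n_aa), ln)
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  if (any(n_AA + n_Aa + n_aa == 0)) {
    stop("at least one genotype is required", call. = FALSE)
  }
  vapply(seq_len(ln), function(i) {
    hwe_exact_one(n_AA[i], n_Aa[i], n_aa[i])
  }, numeric(1))
}

# probabilities via the recurrence
#   P(h + 2) / P(h) = 4 * nAA(h) * naa(h) / ((h + 1) * (h + 2))
# over heterozygote counts h sharing the parity of the minor allele count
hwe_exact_one <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  n_minor <- min(nA, 2L * n - nA)
  if (n_minor == 0L) return(1)
  h_min <- if (n_minor %% 2L == 0L) 0L else 1L
  h_vals <- seq.int(h_min, n_minor, by = 2L)
  logw <- numeric(length(h_vals))
  for (k in seq_along(h_vals)[-1]) {
    h <- h_vals[k - 1]
    nAA_h <- (n_minor - h) / 2
    naa_h <- n - nAA_h - h
    logw[k] <- logw[k - 1] +
      log(4 * nAA_h * naa_h) - log((h + 1) * (h + 2))
  }
  w <- exp(logw - max(logw))
  p_h <- w / sum(w)
  obs <- match(n_Aa, h_vals)
  if (is.na(obs)) stop("inconsistent genotype counts", call. = FALSE)
  min(1, sum(p_h[p_h <= p_h[obs] * (1 + 1e-9)]))
}

#' Apply the full SNP filter cascade
#'
#' Runs the quality cascade in order: (1) the six-metric hard filter;
#' (2) site screens on missing rate, minor allele frequency, Hardy-Weinberg
#' exact p and biallelic status; (3) masking of genotypes with low GQ to
#' missing; (4) removal of sites whose post-masking missing rate exceeds the
#' strict cutoff; (5) removal of sites whose mean non-missing depth falls
#' outside the accepted range. MAF and Hardy-Weinberg statistics use
#' non-missing genotypes only. Boundary semantics are strict as printed
#' (e.g. MAF exactly at the cutoff is removed).
#'
#' @param panel a [geno_panel()].
#' @param annotations optional `variant_annotations`; when `NULL` the
#'   hard-filter, GQ and depth stages pass everything through.
#' @param thresholds a [filter_thresholds()].
#' @return A list with `panel` (the filtered [geno_panel()], with GQ-masked
#'   genotypes set to missing) and `report` (a `filter_report`).
#' @export
site_filters <- function(panel, annotations = NULL,
                         thresholds = filter_thresholds()) {
  stopifnot(inherits(panel, "geno_panel"))
  if (!inherits(thresholds, "filter_thresholds")) {
    stop("`thresholds` must come from filter_thresholds()", call. = FALSE)
  }
  m <- ncol(panel$dosage)
  keep <- rep(TRUE, m)
  reasons <- vector("list", m)
  add_reason <- function(idx, why) {
    for (j in idx) reasons[[j]] <<- c(reasons[[j]], why)
    invisible(NULL)
  }
  stages <- list()
  note <- function(stage, criterion, removed) {
    stages[[length(stages) + 1]] <<-
      tibble::tibble(stage = stage, criterion = criterion,
                     n_removed = length(removed))
  }

  # (1) hard filter on site QC metrics
  if (!is.null(annotations)) {
    hf <- hard_filter_sites(annotations, thresholds)
    bad <- which(!hf$pass & keep)
    add_reason(bad, paste0("hard_filter:", hf$reasons[bad]))
    keep[bad] <- FALSE
    note("hard_filter", "QD/MQ/FS/SOR/MQRankSum/ReadPosRankSum", bad)
  } else {
    note("hard_filter", "QD/MQ/FS/SOR/MQRankSum/ReadPosRankSum", integer(0))
  }

  d <- panel$dosage
  n_missing <- colSums(is.na(d))
  n_called <- nrow(d) - n_missing

  # (2a) genotype missing rate
  miss_rate <- n_missing / nrow(d)
  bad <- which(keep & !(miss_rate < thresholds$max_missing))
  add_reason(bad, "missing_rate")
  keep[bad] <- FALSE
  note("site_screen", sprintf("missing rate < %g", thresholds$max_missing),
       bad)

  # (2b) minor allele frequency (non-missing genotypes only), strict >
  alt_count <- colSums(d, na.rm = TRUE)
  p_alt <- ifelse(n_called > 0, alt_count / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  bad <- which(keep & !(ifelse(is.na(maf), FALSE, maf > thresholds$min_maf)))
  add_reason(bad, "maf")
  keep[bad] <- FALSE
  note("site_screen", sprintf("MAF > %g", thresholds$min_maf), bad)

  # (2c) Hardy-Weinberg exact test
  n_het <- colSums(d == 1L, na.rm = TRUE)
  n_hom_alt <- colSums(d == 2L, na.rm = TRUE)
  n_hom_ref <- n_called - n_het - n_hom_alt
  hwe_p <- rep(NA_real_, m)
  todo <- which(keep & n_called > 0)
  if (length(todo)) {
    hwe_p[todo] <- hwe_exact_test(n_hom_ref[todo], n_het[todo],
                                  n_hom_alt[todo])
  }
  bad <- which(keep & !is.na(hwe_p) & hwe_p < thresholds$min_hwe_p)
  add_reason(bad, "hwe")
  keep[bad] <- FALSE
  note("site_screen", sprintf("HWE p >= %g", thresholds$min_hwe_p), bad)

  # (2d) biallelic SNVs only
  if (thresholds$biallelic_only) {
    biall <- if ("biallelic" %in% names(panel$loci)) {
      panel$loci$biallelic
    } else {
      nchar(panel$loci$ref) == 1 & nchar(panel$loci$alt) == 1 &
        panel$loci$ref != panel$loci$alt
    }
    bad <- which(keep & !biall)
    add_reason(bad, "not_biallelic")
    keep[bad] <- FALSE
    note("site_screen", "biallelic only", bad)
  }

  # (3) GQ masking + (4) post-masking missing rate, strict >
  masked <- 0L
  if (!is.null(annotations) && !all(is.na(annotations$gq))) {
    mask <- !is.na(annotations$gq) & annotations$gq < thresholds$min_gq
    masked <- sum(mask & !is.na(d))
    d[mask] <- NA_integer_
  }
  post_miss <- colSums(is.na(d)) / nrow(d)
  bad <- which(keep & post_miss > thresholds$max_missing_post)
  add_reason(bad, "missing_after_gq_mask")
  keep[bad] <- FALSE
  note("gq_mask", sprintf("post-mask missing <= %g (GQ >= %g; %d calls masked)",
                          thresholds$max_missing_post, thresholds$min_gq,
                          masked),
       bad)

  # (5) mean site depth within range (inclusive)
  if (!is.null(annotations) && !all(is.na(annotations$dp))) {
    dp <- annotations$dp
    dp_mean <- colMeans(dp, na.rm = TRUE)
    bad <- which(keep & !(is.nan(dp_mean) |
                            (dp_mean >= thresholds$depth_range[1] &
                               dp_mean <= thresholds$depth_range[2])))
    add_reason(bad, "depth")
    keep[bad] <- FALSE
    note("depth", sprintf("mean DP in [%g, %g]", thresholds$depth_range[1],
                          thresholds$depth_range[2]), bad)
  } else {
    note("depth", sprintf("mean DP in [%g, %g]", thresholds$depth_range[1],
                          thresholds$depth_range[2]), integer(0))
  }

  removed <- which(!keep)
  fail_reasons <- tibble::tibble(
    id = panel$loci$id[removed],
    reasons = vapply(reasons[removed], paste, character(1), collapse = ",")
  )
  out <- panel[, which(keep)]
  out$dosage <- d[, which(keep), drop = FALSE]
  report <- structure(list(
    n_input = m,
    stages = dplyr::bind_rows(stages),
    n_output = sum(keep),
    fail_reasons = fail_reasons
  ), class = "filter_report")
  list(panel = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", x$n_input, " sites in, ", x$n_output,
      " retained\n", sep = "")
  st <- x$stages
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-12s %-45s removed %d\n", st$stage[i], st$criterion[i],
                st$n_removed[i]))
  }
  invisible(x)
}

#' @export
#' @rdname site_filters
#' @param report a `filter_report`.
#' @param path file path for the JSON serialization.
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(
    list(n_input = report$n_input, n_output = report$n_output,
         stages = report$stages, fail_reasons = report$fail_reasons),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
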