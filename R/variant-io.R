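#' Read a VCF into a genotype panel
#'
#' Parses a VCFv4.x file (via \pkg{vcfR}) into the dosage representation
#' used throughout the pipeline. Diploid GT fields map `0/0 -> 0`,
#' `0/1`/`1/0 -> 1`, `1/1 -> 2` and `./. -> NA`; phased separators (`|`)
#' are accepted and treated as unphased. Multiallelic records are retained
#' and flagged in the locus table (column `biallelic`), never silently
#' split. Site INFO metrics (QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum)
#' and per-genotype GQ/DP are returned as annotations; absent metrics are
#' stored as `NA`.
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param samples optional sample-metadata data frame (`accession_id`,
#'   `group`) joined onto the panel's sample table.
#' @return A list with `panel` (a [geno_panel()]) and `annotations`
#'   (a `variant_annotations`).
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  m <- nrow(fix)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field", call. = FALSE)

  gt <- gsub("\\|", "/", gt_raw)
  ploidy_bad <- !is.na(gt) & !grepl("^[0-9.]+/[0-9.]+$", gt)
  if (any(ploidy_bad)) {
    stop("non-diploid genotype call(s), e.g. ",
         gt[which(ploidy_bad)[1]], call. = FALSE)
  }
  a1 <- sub("/.*", "", gt)
  a2 <- sub(".*/", "", gt)
  num <- suppressWarnings(as.integer(a1) + as.integer(a2))
  dosage <- t(matrix(num, nrow = nrow(gt))) # gt is loci x samples
  if (any(!is.na(dosage) & dosage > 2)) {
    # alt alleles beyond the first come from multiallelic records; keep the
    # dosage of "any alt" capped is wrong -- mark missing instead
    dosage[!is.na(dosage) & dosage > 2] <- NA_integer_
  }

  loci <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  loci$biallelic <- !grepl(",", loci$alt) &
    nchar(loci$ref) == 1 & nchar(loci$alt) == 1
  loci$alt1 <- sub(",.*", "", loci$alt)
  loci <- tibble::tibble(chrom = loci$chrom, pos = loci$pos, ref = loci$ref,
                         alt = loci$alt1, biallelic = loci$biallelic)

  smp <- tibble::tibble(accession_id = colnames(gt), group = NA_character_)
  if (!is.null(samples)) {
    samples <- tibble::as_tibble(samples)
    smp$group <- samples$group[match(smp$accession_id, samples$accession_id)]
  }
  panel <- geno_panel(dosage, loci, smp)

  info_of <- function(key) {
    x <- suppressWarnings(vcfR::extract.info(v, element = key, as.numeric = TRUE))
    if (is.null(x)) rep(NA_real_, m) else as.numeric(x)
  }
  fmt_of <- function(key) {
    x <- tryCatch(vcfR::extract.gt(v, element = key, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(x)) {
      matrix(NA_integer_, nrow(dosage), m, dimnames = dimnames(dosage))
    } else {
      x <- t(x)
      if (all(is.na(x) | x == round(x))) storage.mode(x) <- "integer"
      x
    }
  }
  site <- tibble::tibble(
    id = panel$loci$id,
    QD = info_of("QD"), MQ = info_of("MQ"), FS = info_of("FS"),
    SOR = info_of("SOR"), MQRankSum = info_of("MQRankSum"),
    ReadPosRankSum = info_of("ReadPosRankSum")
  )
  ann <- structure(list(site = site, gq = fmt_of("GQ"), dp = fmt_of("DP"),
                        planted_fail = NULL),
                   class = "variant_annotations")
  list(panel = panel, annotations = ann)
}

#' Write a genotype panel as VCFv4.2
#'
#' Serializes the panel (and, when given, its QC annotations) as a plain-text
#' VCFv4.2 file with `GT:GQ:DP` genotype fields and the hard-filter INFO
#' metrics. Loci must be sorted by (chromosome, position); the output
#' round-trips through [read_vcf()].
#'
#' @param panel a [geno_panel()].
#' @param annotations optional `variant_annotations` matching the panel.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, annotations = NULL, path) {
  stopifnot(inherits(panel, "geno_panel"))
  ord <- locus_order(panel$loci)
  if (!identical(ord, seq_len(nrow(panel$loci)))) {
    stop("loci are not in (chromosome, position) order", call. = FALSE)
  }
  if (!is.null(annotations) &&
      nrow(annotations$site) != ncol(panel$dosage)) {
    stop("annotations do not match the panel", call. = FALSE)
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=germid",
    paste0("##INFO=<ID=", c("QD", "MQ", "FS", "SOR", "MQRankSum",
                            "ReadPosRankSum"),
           ",Number=1,Type=Float,Description=\"Site QC metric\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$accession_id), collapse = "\t")
  )
  m <- ncol(panel$dosage)
  gt_tok <- c("0/0", "0/1", "1/1")
  body <- character(m)
  for (j in seq_len(m)) {
    lo <- panel$loci[j, ]
    if (is.null(annotations)) {
      info <- "."
      gq <- rep(".", nrow(panel$dosage))
      dp <- gq
    } else {
      s <- annotations$site[j, ]
      keys <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
      vals <- vapply(keys, function(k) as.numeric(s[[k]]), numeric(1))
      keep <- !is.na(vals)
      info <- if (any(keep)) {
        paste(paste0(keys[keep], "=", format(vals[keep], trim = TRUE,
                                             scientific = FALSE)),
              collapse = ";")
      } else "."
      gq <- ifelse(is.na(annotations$gq[, j]), ".", annotations$gq[, j])
      dp <- ifelse(is.na(annotations$dp[, j]), ".", annotations$dp[, j])
    }
    d <- panel$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_tok[d + 1L])
    body[j] <- paste(c(lo$chrom, lo$pos, lo$id, lo$ref, lo$alt, ".", "PASS",
                       info, "GT:GQ:DP", paste(gt, gq, dp, sep = ":")),
                     collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Classify a biallelic substitution as transition or transversion
#'
#' Purine-purine (A<->G) and pyrimidine-pyrimidine (C<->T) changes are
#' transitions; the remaining eight ordered pairs are transversions.
#'
#' @param ref,alt single nucleotides in `A`, `C`, `G`, `T` (vectorized).
#' @return Character vector of `"transition"` / `"transversion"`.
#' @export
#' @examples
#' classify_substitution("A", "G")
#' classify_substitution(c("A", "C"), c("T", "G"))
classify_substitution <- function(ref, alt) {
  nt <- c("A", "C", "G", "T")
  if (!all(ref %in% nt) || !all(alt %in% nt)) {
    stop("ref and alt must be single nucleotides A/C/G/T", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  pur <- c("A", "G")
  ifelse((ref %in% pur) == (alt %in% pur), "transition", "transversion")
}

#' Tally the substitution spectrum of a panel
#'
#' Counts each of the 12 ordered ref->alt SNV classes and reports the
#' transition/transversion (Ts/Tv) ratio, the standard variant-call quality
#' heuristic. With zero transversions the ratio is undefined (`NA`), not an
#' error.
#'
#' @param panel a [geno_panel()] of biallelic SNVs.
#' @return A `substitution_spectrum` list: `classes` (tibble of the 12
#'   ordered classes with counts and type), `n_transitions`,
#'   `n_transversions`, `tstv`, `n_loci`.
#' @export
substitution_spectrum <- function(panel) {
  stopifnot(inherits(panel, "geno_panel"))
  loci <- panel$loci
  if (any(nchar(loci$ref) != 1 | nchar(loci$alt) != 1 |
          loci$ref == loci$alt)) {
    stop("spectrum requires biallelic SNVs", call. = FALSE)
  }
  cls <- SUBSTITUTION_CLASSES
  key <- paste(loci$ref, loci$alt, sep = ">")
  all_keys <- paste(cls$ref, cls$alt, sep = ">")
  counts <- as.integer(table(factor(key, levels = all_keys)))
  type <- classify_substitution(cls$ref, cls$alt)
  n_ts <- sum(counts[type == "transition"])
  n_tv <- sum(counts[type == "transversion"])
  structure(list(
    classes = tibble::tibble(ref = cls$ref, alt = cls$alt, type = type,
                             count = counts),
    n_transitions = n_ts, n_transversions = n_tv,
    tstv = if (n_tv > 0) n_ts / n_tv else NA_real_,
    n_loci = nrow(loci)
  ), class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat("<substitution_spectrum> ", x$n_loci, " SNVs: ",
      x$n_transitions, " transitions, ", x$n_transversions,
      " transversions", sep = "")
  if (is.na(x$tstv)) cat(" (Ts/Tv undefined)\n")
  else cat(sprintf(" (Ts/Tv = %.4f)\n", x$tstv))
  invisible(x)
}
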