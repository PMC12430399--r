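#' Genotype panel
#'
#' The backbone container of the pipeline: a samples x loci matrix of
#' alternate-allele dosages (0, 1, 2 or `NA` for a missing call) together
#' with locus metadata and sample metadata. All downstream stages (filtering,
#' diversity, structure, association, core-set selection, fingerprinting)
#' consume and return this object.
#'
#' @param dosage integer matrix, samples in rows and loci in columns; entries
#'   in `{0, 1, 2, NA}`. Row names are taken as accession ids when
#'   `samples` is not supplied.
#' @param loci a data frame with one row per locus and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt`. An `id` column (`"chrom_pos"`) is added
#'   when absent.
#' @param samples a data frame with columns `accession_id` and `group`
#'   (group may be `NA` when unknown).
#'
#' @return An object of class `geno_panel`: a list with elements `dosage`,
#'   `loci` (tibble) and `samples` (tibble).
#' @export
#' @examples
#' pan <- geno_panel(
#'   dosage = rbind(A1 = c(0L, 1L), A2 = c(2L, NA)),
#'   loci = data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                     ref = c("A", "C"), alt = c("G", "T"))
#' )
#' pan
geno_panel <- function(dosage, loci, samples = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  loci <- tibble::as_tibble(loci)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  if (!"id" %in% names(loci)) {
    loci$id <- paste(sub("^chr", "", loci$chrom), loci$pos, sep = "_")
  }
  if (is.null(samples)) {
    ids <- rownames(dosage)
    if (is.null(ids)) ids <- sprintf("S%03d", seq_len(nrow(dosage)))
    samples <- tibble::tibble(accession_id = ids, group = NA_character_)
  }
  samples <- tibble::as_tibble(samples)
  stopifnot("accession_id" %in% names(samples))
  if (!"group" %in% names(samples)) samples$group <- NA_character_
  if (nrow(samples) != nrow(dosage)) {
    stop("`samples` has ", nrow(samples), " rows but `dosage` has ",
         nrow(dosage), call. = FALSE)
  }
  if (nrow(loci) != ncol(dosage)) {
    stop("`loci` has ", nrow(loci), " rows but `dosage` has ",
         ncol(dosage), " columns", call. = FALSE)
  }
  if (anyDuplicated(samples$accession_id)) {
    stop("duplicate accession ids: ",
         paste(unique(samples$accession_id[duplicated(samples$accession_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  ord_ok <- !is.unsorted(order(loci$chrom, loci$pos))
  rownames(dosage) <- samples$accession_id
  colnames(dosage) <- loci$id
  structure(list(dosage = dosage, loci = loci, samples = samples),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat("<geno_panel> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " loci\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  chromosomes: %d | missing calls: %.2f%%\n",
              length(unique(x$loci$chrom)), 100 * miss))
  grp <- table(x$samples$group, useNA = "ifany")
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel by samples and/or loci
#'
#' @param x a [geno_panel()].
#' @param i sample index (integer, logical, or accession ids).
#' @param j locus index (integer, logical, or locus ids).
#' @param ... unused.
#' @return A `geno_panel` restricted to the selected rows/columns.
#' @export
`[.geno_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$samples$accession_id)
  if (is.character(j)) j <- match(j, x$loci$id)
  geno_panel(x$dosage[i, j, drop = FALSE], x$loci[j, , drop = FALSE],
             x$samples[i, , drop = FALSE])
}

# per-locus mean imputation of missing dosages; returns a numeric matrix
impute_dosage <- function(panel) {
  d <- panel$dosage
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- mu[idx[, 2]]
  d
}

# order of loci by (chrom, pos); chromosomes sorted naturally when numeric
locus_order <- function(loci) {
  key <- suppressWarnings(as.numeric(sub("^chr", "", loci$chrom)))
  if (anyNA(key)) order(loci$chrom, loci$pos) else order(key, loci$pos)
}

# run code with a private RNG state seeded from `seed`
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}
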