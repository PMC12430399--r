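#' Fingerprint codes over a set of loci
#'
#' Concatenates each sample's genotype tokens (`0/0`, `0/1`, `1/1`, `./.`
#' for a missing call) at the given loci. Tokens are always emitted in
#' genomic order (chromosome, position), regardless of the order the loci
#' were selected in.
#'
#' @param panel a [geno_panel()].
#' @param loci locus ids (or indices) to fingerprint on.
#' @param sep token separator in the rendered code string (default `"|"`).
#' @return A tibble of `accession_id` and `code`.
#' @export
#' @examples
#' pan <- geno_panel(rbind(A = c(0L, 1L), B = c(2L, 1L)),
#'                   data.frame(chrom = "chr1", pos = c(5L, 9L),
#'                              ref = "A", alt = "G"))
#' fingerprint_codes(pan, c("1_5", "1_9"))
fingerprint_codes <- function(panel, loci, sep = "|") {
  stopifnot(inherits(panel, "geno_panel"))
  if (!length(loci)) stop("no loci given", call. = FALSE)
  if (is.character(loci)) {
    j <- match(loci, panel$loci$id)
    if (anyNA(j)) {
      stop("unknown locus id(s): ", paste(loci[is.na(j)], collapse = ", "),
           call. = FALSE)
    }
  } else {
    j <- as.integer(loci)
  }
  j <- j[locus_order(panel$loci[j, ])]
  tok <- c("0/0", "0/1", "1/1")
  d <- panel$dosage[, j, drop = FALSE]
  codes <- apply(d, 1, function(r) {
    paste(ifelse(is.na(r), "./.", tok[r + 1L]), collapse = sep)
  })
  tibble::tibble(accession_id = panel$samples$accession_id,
                 code = unname(codes))
}

# which currently-unresolved pairs does locus j resolve? a pair counts only
# when both genotypes are non-missing and differ
pairs_resolved_by <- function(dosage_col, i1, i2) {
  a <- dosage_col[i1]
  b <- dosage_col[i2]
  !is.na(a) & !is.na(b) & a != b
}

# all confounded pairs for a locus set; returns logical over pair list
resolved_by_set <- function(dosage, j_set, i1, i2) {
  res <- rep(FALSE, length(i1))
  for (j in j_set) {
    res <- res | pairs_resolved_by(dosage[, j], i1, i2)
  }
  res
}

#' Greedy selection of a minimal core SNP marker set
#'
#' Greedy set cover over sample pairs: starting from the empty set, each
#' iteration adds the candidate locus resolving the largest number of
#' currently-confounded sample pairs (a pair is resolved only when both
#' genotypes are non-missing and differ at some selected locus). Ties break
#' by higher PIC, then by genomic position. Selection stops when every pair
#' is resolved or no candidate resolves any remaining pair; a final pruning
#' pass removes any locus whose removal leaves the resolved pair set
#' unchanged, yielding a non-redundant set. Samples that remain mutually
#' indistinguishable are reported as `unresolved_groups`.
#'
#' @param panel a [geno_panel()].
#' @param candidates candidate locus ids or indices (default: all loci).
#' @return A `core_marker_set`: `markers` (tibble in selection order with
#'   `id`, `chrom`, `pos`, `pic`, `gain`), `size`, `unresolved_groups`
#'   (list of accession-id character vectors, empty on full resolution),
#'   `resolution_rate`.
#' @export
greedy_core_select <- function(panel, candidates = NULL) {
  stopifnot(inherits(panel, "geno_panel"))
  n <- nrow(panel$dosage)
  if (n < 2) stop("need >= 2 samples", call. = FALSE)
  if (is.null(candidates)) candidates <- seq_len(ncol(panel$dosage))
  if (is.character(candidates)) {
    candidates <- match(candidates, panel$loci$id)
  }
  candidates <- as.integer(candidates)
  if (!length(candidates) || anyNA(candidates)) {
    stop("empty or unknown candidate set", call. = FALSE)
  }

  d <- panel$dosage
  pr <- utils::combn(n, 2)
  i1 <- pr[1, ]
  i2 <- pr[2, ]
  n_pairs <- length(i1)
  unresolved <- rep(TRUE, n_pairs)

  ls <- locus_stats(panel)
  pic <- ls$PIC
  ckey <- suppressWarnings(as.numeric(sub("^chr", "",
                                          panel$loci$chrom[candidates])))
  if (anyNA(ckey)) ckey <- rank(panel$loci$chrom[candidates])
  cpos <- panel$loci$pos[candidates]

  selected <- integer(0)
  gains <- integer(0)
  remaining <- candidates
  rem_key <- ckey
  rem_pos <- cpos
  while (any(unresolved) && length(remaining)) {
    idx_un1 <- i1[unresolved]
    idx_un2 <- i2[unresolved]
    gain <- vapply(remaining, function(j) {
      sum(pairs_resolved_by(d[, j], idx_un1, idx_un2))
    }, numeric(1))
    if (max(gain) == 0) break
    best <- which(gain == max(gain))
    if (length(best) > 1) { # tie-break: PIC desc, then chrom, pos
      o <- order(-pic[remaining[best]], rem_key[best], rem_pos[best])
      best <- best[o[1]]
    }
    j <- remaining[best]
    newly <- pairs_resolved_by(d[, j], i1, i2) & unresolved
    unresolved <- unresolved & !newly
    selected <- c(selected, j)
    gains <- c(gains, sum(newly))
    keep <- seq_along(remaining) != best
    remaining <- remaining[keep]
    rem_key <- rem_key[keep]
    rem_pos <- rem_pos[keep]
  }

  # pruning pass: drop any locus whose removal preserves the resolved set
  if (length(selected) > 1) {
    target <- resolved_by_set(d, selected, i1, i2)
    k <- 1
    while (k <= length(selected)) {
      trial <- selected[-k]
      if (length(trial) &&
          identical(resolved_by_set(d, trial, i1, i2), target)) {
        gains <- gains[-k]
        selected <- trial
      } else {
        k <- k + 1
      }
    }
  }

  final_res <- if (length(selected)) {
    resolved_by_set(d, selected, i1, i2)
  } else {
    rep(FALSE, n_pairs)
  }
  groups <- list()
  if (any(!final_res)) {
    g <- igraph_free_components(i1[!final_res], i2[!final_res], n)
    groups <- lapply(g, function(ix) panel$samples$accession_id[ix])
  }
  structure(list(
    markers = tibble::tibble(
      id = panel$loci$id[selected], chrom = panel$loci$chrom[selected],
      pos = panel$loci$pos[selected], pic = pic[selected],
      gain = as.integer(gains)),
    size = length(selected),
    unresolved_groups = groups,
    resolution_rate = mean(final_res)
  ), class = "core_marker_set")
}

# connected components over unresolved pairs without pulling in igraph:
# union-find over sample indices
igraph_free_components <- function(i1, i2, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(i1)) {
    a <- find(i1[k])
    b <- find(i2[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  touched <- unique(c(i1, i2))
  comp <- split(touched, roots[touched])
  comp[vapply(comp, length, integer(1)) > 1]
}

#' @export
print.core_marker_set <- function(x, ...) {
  cat("<core_marker_set> ", x$size, " markers; resolution rate ",
      sprintf("%.4f", x$resolution_rate), "\n", sep = "")
  if (length(x$unresolved_groups)) {
    cat("  unresolved groups:",
        paste(vapply(x$unresolved_groups, paste, character(1),
                     collapse = "/"), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Exhaustive minimal discriminating set (verification oracle)
#'
#' Tests candidate subsets in increasing size order and returns the first
#' subset under which all sample pairs are resolved. Feasibility guards
#' (`<= 20` candidates, `<= 12` samples) keep the enumeration exhaustive
#' but tractable; exceeding them is an error, not an approximation.
#'
#' @param panel a [geno_panel()].
#' @param candidates candidate locus ids or indices (default all).
#' @param max_size largest subset size tried.
#' @return A list with `loci` (indices into the panel, or `NULL` when no
#'   subset of size `<= max_size` resolves all pairs) and `size`.
#' @export
brute_force_min_set <- function(panel, candidates = NULL,
                                max_size = length(candidates)) {
  stopifnot(inherits(panel, "geno_panel"))
  if (is.null(candidates)) candidates <- seq_len(ncol(panel$dosage))
  if (is.character(candidates)) {
    candidates <- match(candidates, panel$loci$id)
  }
  n <- nrow(panel$dosage)
  if (length(candidates) > 20 || n > 12) {
    stop("exhaustive search guard: <= 20 candidates and <= 12 samples",
         call. = FALSE)
  }
  if (is.null(max_size) || !length(max_size)) max_size <- length(candidates)
  pr <- utils::combn(n, 2)
  i1 <- pr[1, ]
  i2 <- pr[2, ]
  d <- panel$dosage
  for (size in seq_len(min(max_size, length(candidates)))) {
    subs <- utils::combn(candidates, size)
    for (k in seq_len(ncol(subs))) {
      if (all(resolved_by_set(d, subs[, k], i1, i2))) {
        return(list(loci = subs[, k], size = size))
      }
    }
  }
  list(loci = NULL, size = NA_integer_)
}

#' Discrimination report over fingerprint codes
#'
#' Groups samples by identical code string and reports the pairwise
#' resolution rate (resolved pairs / total pairs).
#'
#' @param codes a tibble from [fingerprint_codes()].
#' @return A list with `duplicate_groups` (list of accession-id vectors
#'   sharing a code) and `resolution_rate`.
#' @export
discrimination_report <- function(codes) {
  if (!nrow(codes)) stop("no codes", call. = FALSE)
  n <- nrow(codes)
  grp <- split(codes$accession_id, codes$code)
  dup <- unname(grp[vapply(grp, length, integer(1)) > 1])
  total <- n * (n - 1) / 2
  confounded <- sum(vapply(dup, function(g) {
    k <- length(g)
    k * (k - 1) / 2
  }, numeric(1)))
  list(duplicate_groups = dup,
       resolution_rate = if (total > 0) 1 - confounded / total else 1)
}
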