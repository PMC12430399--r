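# QR symbol construction and read-back (byte mode, error-correction level M).
#
# Implements the model-2 QR symbology: GF(256) Reed-Solomon parity,
# per-version error-correction block structure, function-pattern layout,
# format/version BCH codes, mask 0, and the zigzag data placement. The
# decoder inverts the same construction (and verifies the Reed-Solomon
# parity) so rendered images can be audited byte-for-byte.

# ---- GF(256) arithmetic (primitive polynomial x^8+x^4+x^3+x^2+1) ----

qr_gf <- local({
  exp_t <- integer(512)
  log_t <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp_t[i + 1L] <- x
    log_t[x + 1L] <- i
    x <- bitwShiftL(x, 1)
    if (x >= 256L) x <- bitwXor(x, 285L)
  }
  exp_t[256:510] <- exp_t[1:255]
  list(exp = exp_t, log = log_t)
})

gf_mul <- function(a, b) {
  out <- integer(length(a))
  nz <- a != 0L & b != 0L
  out[nz] <- qr_gf$exp[(qr_gf$log[a[nz] + 1L] + qr_gf$log[b[nz] + 1L]) %%
                         255L + 1L]
  out
}

# Reed-Solomon parity of `n_ec` codewords for a data codeword vector
rs_parity <- function(data, n_ec) {
  gen <- 1L
  for (i in 0:(n_ec - 1)) {
    # gen <- gen * (x - alpha^i)
    a <- qr_gf$exp[i + 1L]
    new <- integer(length(gen) + 1L)
    new[seq_along(gen)] <- bitwXor(new[seq_along(gen)], gf_mul(gen, rep(a, length(gen))))
    new[seq_along(gen) + 1L] <- bitwXor(new[seq_along(gen) + 1L], gen)
    gen <- new
  }
  gen <- rev(gen) # highest power first
  buf <- c(as.integer(data), integer(n_ec))
  for (i in seq_along(data)) {
    f <- buf[i]
    if (f != 0L) {
      buf[i:(i + n_ec)] <- bitwXor(buf[i:(i + n_ec)],
                                   gf_mul(gen, rep(f, n_ec + 1L)))
    }
  }
  buf[(length(data) + 1L):(length(data) + n_ec)]
}

# ---- per-version constants ----

# error-correction blocks at level M: ec codewords per block, then
# (blocks x data codewords) for group 1 and group 2
RS_BLOCKS_M <- matrix(c(
  10, 1, 16, 0, 0,   16, 1, 28, 0, 0,   26, 1, 44, 0, 0,   18, 2, 32, 0, 0,
  24, 2, 43, 0, 0,   16, 4, 27, 0, 0,   18, 4, 31, 0, 0,   22, 2, 38, 2, 39,
  22, 3, 36, 2, 37,  26, 4, 43, 1, 44,  30, 1, 50, 4, 51,  22, 6, 36, 2, 37,
  22, 8, 37, 1, 38,  24, 4, 40, 5, 41,  24, 5, 41, 5, 42,  28, 7, 45, 3, 46,
  28, 10, 46, 1, 47, 26, 9, 43, 4, 44,  26, 3, 44, 11, 45, 26, 3, 41, 13, 42,
  26, 17, 42, 0, 0,  28, 17, 46, 0, 0,  28, 4, 47, 14, 48, 28, 6, 45, 14, 46,
  28, 8, 47, 13, 48, 28, 19, 46, 4, 47, 28, 22, 45, 3, 46, 28, 3, 45, 23, 46,
  28, 21, 45, 7, 46, 28, 19, 47, 10, 48, 28, 2, 46, 29, 47, 28, 10, 46, 23, 47,
  28, 14, 46, 21, 47, 28, 14, 46, 23, 47, 28, 12, 47, 26, 48, 28, 6, 47, 34, 48,
  28, 29, 46, 14, 47, 28, 13, 46, 32, 47, 28, 40, 47, 7, 48, 28, 18, 47, 31, 48
), ncol = 5, byrow = TRUE,
  dimnames = list(NULL, c("ec", "b1", "dc1", "b2", "dc2")))

ALIGN_POS <- list(
  integer(0), c(6, 18), c(6, 22), c(6, 26), c(6, 30), c(6, 34),
  c(6, 22, 38), c(6, 24, 42), c(6, 26, 46), c(6, 28, 50), c(6, 30, 54),
  c(6, 32, 58), c(6, 34, 62), c(6, 26, 46, 66), c(6, 26, 48, 70),
  c(6, 26, 50, 74), c(6, 30, 54, 78), c(6, 30, 56, 82), c(6, 30, 58, 86),
  c(6, 34, 62, 90), c(6, 28, 50, 72, 94), c(6, 26, 50, 74, 98),
  c(6, 30, 54, 78, 102), c(6, 28, 54, 80, 106), c(6, 32, 58, 84, 110),
  c(6, 30, 58, 86, 114), c(6, 34, 62, 90, 118), c(6, 26, 50, 74, 98, 122),
  c(6, 30, 54, 78, 102, 126), c(6, 26, 52, 78, 104, 130),
  c(6, 30, 56, 82, 108, 134), c(6, 34, 60, 86, 112, 138),
  c(6, 30, 58, 86, 114, 142), c(6, 34, 62, 90, 118, 146),
  c(6, 30, 54, 78, 102, 126, 150), c(6, 24, 50, 76, 102, 128, 154),
  c(6, 28, 54, 80, 106, 132, 158), c(6, 32, 58, 84, 110, 136, 162),
  c(6, 26, 54, 82, 110, 138, 166), c(6, 30, 58, 86, 114, 142, 170)
)

qr_size <- function(version) 17L + 4L * version

# layout template: matrix of module values for function patterns (0/1) and
# a logical mask of function/reserved modules (TRUE = not a data module)
qr_template <- function(version) {
  s <- qr_size(version)
  mod <- matrix(0L, s, s)
  fun <- matrix(FALSE, s, s)

  place_finder <- function(r, c) { # top-left corner (1-indexed)
    for (dr in 0:6) for (dc in 0:6) {
      v <- as.integer(dr %in% c(0, 6) || dc %in% c(0, 6) ||
                        (dr %in% 2:4 && dc %in% 2:4))
      mod[r + dr, c + dc] <<- v
    }
    r0 <- max(1, r - 1); r1 <- min(s, r + 7)
    c0 <- max(1, c - 1); c1 <- min(s, c + 7)
    fun[r0:r1, c0:c1] <<- TRUE # finder + separator
  }
  place_finder(1, 1)
  place_finder(1, s - 6)
  place_finder(s - 6, 1)

  for (k in 9:(s - 8)) { # timing patterns
    v <- as.integer(k %% 2 == 1)
    mod[7, k] <- v; mod[k, 7] <- v
    fun[7, k] <- TRUE; fun[k, 7] <- TRUE
  }

  ap <- ALIGN_POS[[version]]
  for (r in ap) for (c in ap) {
    # skip patterns overlapping the three finder corners
    if ((r < 9 && c < 9) || (r < 9 && c > s - 10) || (r > s - 10 && c < 9)) next
    for (dr in -2:2) for (dc in -2:2) {
      v <- as.integer(max(abs(dr), abs(dc)) != 1)
      mod[r + 1 + dr, c + 1 + dc] <- v
      fun[r + 1 + dr, c + 1 + dc] <- TRUE
    }
  }

  # format info areas (reserved; filled later) + dark module
  fun[9, c(1:9, (s - 7):s)] <- TRUE
  fun[c(1:9, (s - 7):s), 9] <- TRUE
  mod[s - 7, 9] <- 1L # dark module
  if (version >= 7) { # version info areas
    fun[1:6, (s - 10):(s - 8)] <- TRUE
    fun[(s - 10):(s - 8), 1:6] <- TRUE
  }
  list(mod = mod, fun = fun, size = s)
}

# zigzag traversal of data modules; returns 2-column matrix of (row, col)
qr_traversal <- function(fun) {
  s <- nrow(fun)
  pos <- matrix(0L, sum(!fun), 2)
  k <- 0L
  upward <- TRUE
  x <- s # 1-indexed rightmost column
  while (x > 0) {
    if (x == 7) x <- 6 # skip the vertical timing column
    rows <- if (upward) s:1 else 1:s
    for (r in rows) {
      for (c in c(x, x - 1L)) {
        if (c >= 1 && !fun[r, c]) {
          k <- k + 1L
          pos[k, ] <- c(r, c)
        }
      }
    }
    upward <- !upward
    x <- x - 2L
  }
  pos
}

qr_data_codewords <- function(version) {
  b <- RS_BLOCKS_M[version, ]
  unname(b["b1"] * b["dc1"] + b["b2"] * b["dc2"])
}

# consistency audit: block-table codeword totals must match the symbol
# geometry (data modules / 8) for every version
qr_geometry_audit <- function(versions = 1:40) {
  ok <- vapply(versions, function(v) {
    tpl <- qr_template(v)
    bits <- sum(!tpl$fun)
    b <- RS_BLOCKS_M[v, ]
    total <- qr_data_codewords(v) + b["ec"] * (b["b1"] + b["b2"])
    bits %/% 8 == total && (bits %% 8) %in% c(0, 3, 4, 7)
  }, logical(1))
  stats::setNames(ok, versions)
}

mask_fun <- function(id) {
  switch(id + 1L,
    function(r, c) (r + c) %% 2 == 0,
    function(r, c) r %% 2 == 0,
    function(r, c) c %% 3 == 0,
    function(r, c) (r + c) %% 3 == 0,
    function(r, c) (r %/% 2 + c %/% 3) %% 2 == 0,
    function(r, c) (r * c) %% 2 + (r * c) %% 3 == 0,
    function(r, c) ((r * c) %% 2 + (r * c) %% 3) %% 2 == 0,
    function(r, c) ((r + c) %% 2 + (r * c) %% 3) %% 2 == 0)
}

# 15-bit format word (BCH 15,5) for level M and a mask id; MSB first
qr_format_bits <- function(mask_id) {
  data <- bitwOr(bitwShiftL(0L, 3L), mask_id) # level M = 00
  v <- bitwShiftL(data, 10L)
  g <- 1335L # generator 10100110111
  for (i in 14:10) {
    if (bitwAnd(v, bitwShiftL(1L, i)) != 0L) {
      v <- bitwXor(v, bitwShiftL(g, i - 10L))
    }
  }
  word <- bitwXor(bitwOr(bitwShiftL(data, 10L), v), 21522L) # XOR mask
  as.integer(bitwAnd(bitwShiftR(word, 14:0), 1L))
}

# 18-bit version word (BCH 18,6); MSB first
qr_version_bits <- function(version) {
  v <- bitwShiftL(version, 12L)
  g <- 7973L # generator 1111100100101
  for (i in 17:12) {
    if (bitwAnd(v, bitwShiftL(1L, i)) != 0L) {
      v <- bitwXor(v, bitwShiftL(g, i - 12L))
    }
  }
  word <- bitwOr(bitwShiftL(version, 12L), v)
  as.integer(bitwAnd(bitwShiftR(word, 17:0), 1L))
}

# format info module coordinates (1-indexed), MSB (bit 14) first
qr_format_coords <- function(s) {
  copy1 <- cbind(
    r = c(9, 9, 9, 9, 9, 9, 9, 9, 8, 6, 5, 4, 3, 2, 1),
    c = c(1, 2, 3, 4, 5, 6, 8, 9, 9, 9, 9, 9, 9, 9, 9))
  copy2 <- cbind(
    r = c(s, s - 1, s - 2, s - 3, s - 4, s - 5, s - 6,
          rep(9, 8)),
    c = c(rep(9, 7), s - 7, s - 6, s - 5, s - 4, s - 3, s - 2, s - 1, s))
  list(copy1 = copy1, copy2 = copy2)
}

# ---- encoding ----

qr_bitstream <- function(payload_raw, version) {
  len <- length(payload_raw)
  cnt_bits <- if (version <= 9) 8L else 16L
  cap_bits <- qr_data_codewords(version) * 8L
  bits <- c(c(0L, 1L, 0L, 0L), # byte mode
            as.integer(bitwAnd(bitwShiftR(len, (cnt_bits - 1L):0L), 1L)))
  if (len) {
    b <- as.integer(payload_raw)
    bits <- c(bits, as.integer(vapply(b, function(x) {
      bitwAnd(bitwShiftR(x, 7:0), 1L)
    }, integer(8))))
  }
  if (length(bits) > cap_bits) return(NULL)
  bits <- c(bits, integer(min(4L, cap_bits - length(bits)))) # terminator
  if (length(bits) %% 8L) bits <- c(bits, integer(8L - length(bits) %% 8L))
  n_pad <- (cap_bits - length(bits)) %/% 8L
  if (n_pad > 0) {
    pads <- rep(c(236L, 17L), length.out = n_pad)
    bits <- c(bits, as.integer(vapply(pads, function(x) {
      bitwAnd(bitwShiftR(x, 7:0), 1L)
    }, integer(8))))
  }
  bits
}

bits_to_bytes <- function(bits) {
  m <- matrix(bits[seq_len(8 * (length(bits) %/% 8))], nrow = 8)
  as.integer(2^(7:0) %*% m)
}

# split data codewords into blocks, compute parity, interleave
qr_interleave <- function(data_cw, version) {
  b <- RS_BLOCKS_M[version, ]
  sizes <- c(rep(b["dc1"], b["b1"]), rep(b["dc2"], b["b2"]))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  blocks <- lapply(seq_along(sizes), function(j) data_cw[starts[j]:ends[j]])
  ec <- lapply(blocks, rs_parity, n_ec = b["ec"])
  inter <- function(lst) {
    mx <- max(vapply(lst, length, integer(1)))
    out <- integer(0)
    for (i in seq_len(mx)) {
      for (bl in lst) if (i <= length(bl)) out <- c(out, bl[i])
    }
    out
  }
  c(inter(blocks), inter(ec))
}

qr_deinterleave <- function(codewords, version) {
  b <- RS_BLOCKS_M[version, ]
  sizes <- c(rep(b["dc1"], b["b1"]), rep(b["dc2"], b["b2"]))
  nb <- length(sizes)
  data_blocks <- lapply(sizes, function(k) integer(k))
  k <- 1L
  for (i in seq_len(max(sizes))) {
    for (j in seq_len(nb)) {
      if (i <= sizes[j]) {
        data_blocks[[j]][i] <- codewords[k]
        k <- k + 1L
      }
    }
  }
  ec_blocks <- lapply(seq_len(nb), function(j) integer(b["ec"]))
  for (i in seq_len(b["ec"])) {
    for (j in seq_len(nb)) {
      ec_blocks[[j]][i] <- codewords[k]
      k <- k + 1L
    }
  }
  list(data = data_blocks, ec = ec_blocks)
}

#' Encode text as a QR module matrix
#'
#' Byte-mode encoding at error-correction level M with mask pattern 0
#' (fixed for reproducibility; the mask id is recorded in the symbol's
#' format information as usual). The smallest version whose level-M data
#' capacity holds the payload is chosen automatically.
#'
#' @param text character scalar (encoded as UTF-8).
#' @return A list with `matrix` (logical; `TRUE` = dark module) and
#'   `version`.
#' @export
qr_encode <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) stop("payload is empty", call. = FALSE)
  payload <- charToRaw(enc2utf8(text))
  version <- NA_integer_
  bits <- NULL
  for (v in 1:40) {
    bits <- qr_bitstream(payload, v)
    if (!is.null(bits)) {
      version <- v
      break
    }
  }
  if (is.na(version)) {
    stop("payload of ", length(payload),
         " bytes exceeds QR capacity at level M (max ",
         qr_data_codewords(40) - 3, " bytes)", call. = FALSE)
  }
  tpl <- qr_template(version)
  s <- tpl$size
  mod <- tpl$mod
  cw <- qr_interleave(bits_to_bytes(bits), version)
  stream <- as.integer(vapply(cw, function(x) {
    bitwAnd(bitwShiftR(x, 7:0), 1L)
  }, integer(8)))
  pos <- qr_traversal(tpl$fun)
  stream <- c(stream, integer(nrow(pos) - length(stream))) # remainder bits
  mk <- mask_fun(0L)
  for (k in seq_len(nrow(pos))) {
    r <- pos[k, 1]; c <- pos[k, 2]
    v <- stream[k]
    if (mk(r - 1L, c - 1L)) v <- 1L - v
    mod[r, c] <- v
  }
  fb <- qr_format_bits(0L)
  fc <- qr_format_coords(s)
  mod[fc$copy1] <- fb
  mod[fc$copy2] <- fb
  if (version >= 7) {
    vb <- rev(qr_version_bits(version)) # LSB first in placement order
    for (i in 0:17) {
      r <- i %/% 3L; c <- i %% 3L
      mod[r + 1L, s - 10L + c] <- vb[i + 1L]
      mod[s - 10L + c, r + 1L] <- vb[i + 1L]
    }
  }
  list(matrix = mod == 1L, version = version)
}

#' Write a QR module matrix as a PNG image
#'
#' @param mat logical module matrix from [qr_encode()].
#' @param path output PNG path.
#' @param scale pixels per module.
#' @param border quiet-zone width in modules.
#' @return `path`, invisibly.
#' @export
qr_write_png <- function(mat, path, scale = 4, border = 4) {
  s <- nrow(mat)
  img <- matrix(1, s + 2 * border, s + 2 * border)
  img[border + seq_len(s), border + seq_len(s)] <- 1 - mat
  img <- img[rep(seq_len(nrow(img)), each = scale),
             rep(seq_len(ncol(img)), each = scale)]
  png::writePNG(img, path)
  invisible(path)
}

#' Decode a QR PNG written by this package
#'
#' Reads the module grid back from the image (auto-detecting scale and
#' quiet zone from the finder pattern), validates the format word, removes
#' the mask, reverses the placement and block interleaving, re-computes the
#' Reed-Solomon parity of every block and requires an exact match, then
#' parses the byte-mode segment.
#'
#' @param path PNG path.
#' @return The decoded text (UTF-8).
#' @export
qr_decode_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  dark <- img < 0.5
  rows <- which(apply(dark, 1, any))
  cols <- which(apply(dark, 2, any))
  if (!length(rows)) stop("no dark modules in image", call. = FALSE)
  r0 <- min(rows); c0 <- min(cols)
  run <- 0L
  while (dark[r0, c0 + run]) run <- run + 1L # finder edge = 7 modules
  scale <- run / 7
  size <- round((max(cols) - c0 + 1) / scale)
  centers <- round(c0 - 1 + (seq_len(size) - 0.5) * scale)
  centers_r <- round(r0 - 1 + (seq_len(size) - 0.5) * scale)
  mat <- dark[centers_r, centers]
  qr_decode_matrix(mat)
}

#' @rdname qr_decode_png
#' @param mat logical module matrix (`TRUE` = dark).
#' @export
qr_decode_matrix <- function(mat) {
  s <- nrow(mat)
  version <- (s - 17L) %/% 4L
  if (s != qr_size(version)) stop("matrix size is not a QR size",
                                  call. = FALSE)
  fc <- qr_format_coords(s)
  fbits <- as.integer(mat[fc$copy1])
  mask_id <- NA_integer_
  for (m in 0:7) { # level M only
    if (identical(qr_format_bits(m), fbits)) {
      mask_id <- m
      break
    }
  }
  if (is.na(mask_id)) stop("format information is invalid", call. = FALSE)
  tpl <- qr_template(version)
  pos <- qr_traversal(tpl$fun)
  mk <- mask_fun(mask_id)
  bits <- integer(nrow(pos))
  for (k in seq_len(nrow(pos))) {
    r <- pos[k, 1]; c <- pos[k, 2]
    v <- as.integer(mat[r, c])
    if (mk(r - 1L, c - 1L)) v <- 1L - v
    bits[k] <- v
  }
  cw <- bits_to_bytes(bits)
  blocks <- qr_deinterleave(cw, version)
  n_ec <- RS_BLOCKS_M[version, "ec"]
  for (j in seq_along(blocks$data)) {
    if (!identical(as.integer(rs_parity(blocks$data[[j]], n_ec)),
                   as.integer(blocks$ec[[j]]))) {
      stop("Reed-Solomon parity mismatch in block ", j, call. = FALSE)
    }
  }
  data <- unlist(blocks$data)
  bits <- as.integer(vapply(data, function(x) {
    bitwAnd(bitwShiftR(x, 7:0), 1L)
  }, integer(8)))
  mode <- sum(bits[1:4] * c(8, 4, 2, 1))
  if (mode != 4) stop("unsupported QR mode: ", mode, call. = FALSE)
  cnt_bits <- if (version <= 9) 8L else 16L
  len <- sum(bits[4 + seq_len(cnt_bits)] * 2^((cnt_bits - 1):0))
  payload_bits <- bits[4 + cnt_bits + seq_len(8 * len)]
  out <- rawToChar(as.raw(bits_to_bytes(payload_bits)))
  Encoding(out) <- "UTF-8"
  out
}
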