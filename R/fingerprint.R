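#' Assemble per-accession fingerprint records
#'
#' Joins each sample's core-marker fingerprint code with its phenotypic
#' trait values into one record per accession. Missing trait values are
#' rendered with the explicit token `"NA"` at payload time, never dropped
#' silently. Samples present in the codes but absent from the trait table
#' are an error naming the offenders.
#'
#' @param codes a tibble from [fingerprint_codes()].
#' @param traits trait table with `accession_id` plus trait columns.
#' @param payload_version payload grammar label embedded in QR payloads.
#' @return A `fingerprint_records` tibble: `accession_id`, `code`, then one
#'   column per trait.
#' @export
build_records <- function(codes, traits, payload_version = "GFPv1") {
  codes <- tibble::as_tibble(codes)
  traits <- tibble::as_tibble(traits)
  missing_ids <- setdiff(codes$accession_id, traits$accession_id)
  if (length(missing_ids)) {
    stop("sample(s) missing from the trait table: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::left_join(codes, traits, by = "accession_id")
  attr(out, "payload_version") <- payload_version
  class(out) <- c("fingerprint_records", class(out))
  out
}

# reserved characters are percent-encoded so the payload grammar stays
# unambiguous for arbitrary ids and trait names
payload_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("\n", "%0A", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  gsub(":", "%3A", x, fixed = TRUE)
}

payload_unescape <- function(x) {
  x <- gsub("%3A", ":", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%0A", "\n", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Canonical QR payload for one fingerprint record
#'
#' Deterministic, lossless text serialization of a record: a versioned
#' header line, then `id=`, `fp=` and `traits=` lines (traits as
#' `name:value` pairs joined by `;`). Numeric trait values are rendered
#' with up to 15 significant digits; reserved characters in ids and names
#' are percent-encoded. [parse_qr_payload()] inverts the encoding exactly,
#' and re-encoding a parsed payload is byte-identical (canonical form).
#'
#' @param record one row of a [build_records()] table (or the table plus
#'   `which` selecting the row).
#' @param which row index when `record` has several rows.
#' @return A character scalar payload.
#' @export
qr_payload <- function(record, which = 1) {
  version <- attr(record, "payload_version") %||% "GFPv1"
  rec <- tibble::as_tibble(record)[which, ]
  trait_cols <- setdiff(names(rec), c("accession_id", "code"))
  fmt <- function(v) {
    if (is.na(v)) return("NA")
    if (is.numeric(v)) format(v, digits = 15, trim = TRUE,
                              scientific = FALSE)
    else payload_escape(as.character(v))
  }
  traits <- vapply(trait_cols, function(nm) {
    paste0(payload_escape(nm), ":", fmt(rec[[nm]]))
  }, character(1))
  paste0(version, "\n",
         "id=", payload_escape(rec$accession_id), "\n",
         "fp=", rec$code, "\n",
         "traits=", paste(traits, collapse = ";"))
}

#' @rdname qr_payload
#' @param payload a payload string produced by [qr_payload()].
#' @return `parse_qr_payload()`: a list with `payload_version`, `id`,
#'   `code` and `traits` (named character vector).
#' @export
parse_qr_payload <- function(payload) {
  lines <- strsplit(payload, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4 || !startsWith(lines[2], "id=") ||
      !startsWith(lines[3], "fp=") || !startsWith(lines[4], "traits=")) {
    stop("malformed fingerprint payload", call. = FALSE)
  }
  traits <- character(0)
  body <- sub("^traits=", "", lines[4])
  if (nzchar(body)) {
    kv <- strsplit(strsplit(body, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    traits <- stats::setNames(
      vapply(kv, function(p) payload_unescape(p[2]), character(1)),
      vapply(kv, function(p) payload_unescape(p[1]), character(1)))
  }
  list(payload_version = lines[1],
       id = payload_unescape(sub("^id=", "", lines[2])),
       code = sub("^fp=", "", lines[3]),
       traits = traits)
}

#' Render a payload as a QR image and verify it by decoding
#'
#' Writes the payload as a PNG QR symbol (error-correction level M), then
#' decodes the written image and asserts byte-equality with the input. A
#' payload too large for the symbology is a capacity error naming the
#' limit.
#'
#' @param payload character scalar from [qr_payload()].
#' @param out output PNG path.
#' @param scale pixels per module.
#' @return Invisibly, a list with `ok` (TRUE), `version` and `path`;
#'   decoding failure is an error, not a value.
#' @export
render_and_verify_qr <- function(payload, out, scale = 4) {
  if (!is.character(payload) || length(payload) != 1 || !nzchar(payload)) {
    stop("payload must be a non-empty string", call. = FALSE)
  }
  enc <- qr_encode(payload)
  qr_write_png(enc$matrix, out, scale = scale)
  back <- qr_decode_png(out)
  if (!identical(back, enc2utf8(payload))) {
    stop("decoded payload differs from input for ", out, call. = FALSE)
  }
  invisible(list(ok = TRUE, version = enc$version, path = out))
}

#' Export the one-code-one-image fingerprint map
#'
#' Writes one verified QR image per accession plus a spreadsheet-compatible
#' CSV table (accession id, fingerprint code, image file name). File names
#' are derived deterministically from accession ids.
#'
#' @param records a [build_records()] table.
#' @param out_dir output directory (created if needed).
#' @param scale pixels per module for the images.
#' @return Invisibly, a tibble with `accession_id`, `code`, `image`.
#' @export
export_map <- function(records, out_dir, scale = 4) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$accession_id[i]
    img <- paste0(gsub("[^A-Za-z0-9_.-]", "_", id), ".png")
    render_and_verify_qr(qr_payload(records, which = i),
                         file.path(out_dir, img), scale = scale)
    tibble::tibble(accession_id = id, code = records$code[i], image = img)
  })
  map <- dplyr::bind_rows(rows)
  utils::write.csv(map, file.path(out_dir, "fingerprint_map.csv"),
                   row.names = FALSE)
  invisible(map)
}
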