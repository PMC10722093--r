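#' Marker report columns, in output order
#'
#' @format character vector of column names.
#' @keywords internal
REPORT_COLUMNS <- c(
  "marker_id", "contig", "pos", "type", "allele_a", "allele_b",
  "left_primer", "right_primer", "left_tm", "right_tm", "product_size",
  "enzyme", "digested_allele", "fragments_a", "fragments_b", "tag_status",
  "product_seq")

#' Assemble one marker report row
#'
#' @param marker_id unique marker identifier.
#' @param contig,pos locus (1-based position of the variant's first REF base).
#' @param type one of `"INDEL"`, `"CAPS"`, `"SNP"`.
#' @param allele_a,allele_b the two grouped allele strings.
#' @param left_primer,right_primer designed oligos 5'->3' (tags included).
#' @param left_tm,right_tm melting temperatures, deg C (rounded to 2 dp).
#' @param product_size amplicon size in bp.
#' @param enzyme,digested_allele CAPS only: enzyme name and which group
#'   allele (`"A"`/`"B"`) it digests; empty strings otherwise.
#' @param fragments_a,fragments_b CAPS only: integer vectors of digestion
#'   fragment sizes for each allele-realized product.
#' @param tag_status SNP only: `"CS-tagged"` or similar; else empty.
#' @param product_seq reference-allele-realized amplicon sequence.
#' @return a one-row `data.frame` in report column order.
#' @export
markerReportRow <- function(marker_id, contig, pos, type, allele_a, allele_b,
                            left_primer, right_primer, left_tm, right_tm,
                            product_size, enzyme = "", digested_allele = "",
                            fragments_a = integer(0),
                            fragments_b = integer(0), tag_status = "",
                            product_seq = "") {
  data.frame(
    marker_id = marker_id, contig = contig, pos = as.integer(pos),
    type = type, allele_a = allele_a, allele_b = allele_b,
    left_primer = left_primer, right_primer = right_primer,
    left_tm = round(as.numeric(left_tm), 2),
    right_tm = round(as.numeric(right_tm), 2),
    product_size = as.integer(product_size),
    enzyme = enzyme, digested_allele = digested_allele,
    fragments_a = paste(fragments_a, collapse = ","),
    fragments_b = paste(fragments_b, collapse = ","),
    tag_status = tag_status, product_seq = product_seq,
    stringsAsFactors = FALSE)
}

# parse a comma-joined fragment field back into an integer vector
parseFragments <- function(x) {
  if (is.na(x) || x == "") integer(0) else as.integer(strsplit(x, ",")[[1]])
}

#' Validate marker report rows
#'
#' Checks the report-row invariants: CAPS rows carry a non-empty enzyme name,
#' at least 2 fragments for the digested allele and exactly 1 for the other,
#' and fragment sizes summing to the product size; all rows have positive
#' product size.
#'
#' @param rows a marker report `data.frame`.
#' @return invisibly `TRUE`; stops with a message on violation.
#' @export
validateReportRows <- function(rows) {
  stopifnot(is.data.frame(rows))
  missingCols <- setdiff(REPORT_COLUMNS, names(rows))
  if (length(missingCols))
    stop("report rows missing column(s): ", paste(missingCols, collapse = ", "))
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (r$product_size < 1L)
      stop("row ", i, ": non-positive product size")
    if (r$type == "CAPS") {
      if (!nzchar(r$enzyme))
        stop("row ", i, ": CAPS row without enzyme name")
      fa <- parseFragments(r$fragments_a)
      fb <- parseFragments(r$fragments_b)
      cut <- if (r$digested_allele == "A") fa else fb
      uncut <- if (r$digested_allele == "A") fb else fa
      if (length(cut) < 2L)
        stop("row ", i, ": digested allele must yield >= 2 fragments")
      if (length(uncut) != 1L)
        stop("row ", i, ": undigested allele must yield exactly 1 fragment")
    }
  }
  invisible(TRUE)
}

#' Write the tab-delimited marker report
#'
#' Header line plus one TSV line per row; fragment lists comma-joined,
#' empty strings for non-applicable fields. [readMarkerReport()] re-parses
#' the file losslessly.
#'
#' @param rows a marker report `data.frame` (see [markerReportRow()]).
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMarkerReport <- function(rows, path) {
  validateReportRows(rows)
  rows <- rows[, REPORT_COLUMNS, drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write report to ", path, ": ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(REPORT_COLUMNS, collapse = "\t"), con)
  if (nrow(rows)) {
    fmt <- rows
    fmt$left_tm <- formatC(rows$left_tm, format = "f", digits = 2)
    fmt$right_tm <- formatC(rows$right_tm, format = "f", digits = 2)
    writeLines(do.call(paste, c(as.list(fmt), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a marker report back into a data.frame
#'
#' @param path path to a TSV written by [writeMarkerReport()].
#' @return the report `data.frame`.
#' @export
readMarkerReport <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL, quote = "",
                          comment.char = "")
  if (!nrow(df)) {
    df <- df[, REPORT_COLUMNS, drop = FALSE]
  }
  df$pos <- as.integer(df$pos)
  df$left_tm <- as.numeric(df$left_tm)
  df$right_tm <- as.numeric(df$right_tm)
  df$product_size <- as.integer(df$product_size)
  df
}
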