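# Internal coordinate convention: 0-based half-open everywhere inside the
# package; conversion to/from 1-based (VCF, FASTA slicing, report output)
# happens only at the I/O boundary.

# slice a character sequence with 0-based half-open coordinates
slice0 <- function(seq, start0, end0) {
  if (end0 <= start0) return("")
  substr(seq, start0 + 1L, end0)
}

IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRWSMKVHDBN"

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character vectors (IUPAC codes honored). Used internally
#' where converting through `DNAString` would dominate runtime.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr(IUPAC_FROM, IUPAC_TO, x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# fraction of G/C among A/C/G/T (N ignored in the denominator)
gcFraction <- function(x) {
  ch <- strsplit(toupper(x), "", fixed = TRUE)
  vapply(ch, function(v) {
    acgt <- v %in% c("A", "C", "G", "T")
    if (!any(acgt)) return(NA_real_)
    sum(v %in% c("G", "C")) / sum(acgt)
  }, numeric(1))
}

#' GC content of a sequence, in percent
#'
#' @param x character vector of nucleotide strings.
#' @return numeric vector, percent GC among unambiguous bases.
#' @export
#' @examples
#' gcPercent("ATGC")  # 50
gcPercent <- function(x) 100 * gcFraction(x)

# merge an exclusion IRanges, collapsing overlapping/adjacent regions and
# comma-joining their reasons; returns sorted disjoint IRanges with mcols$reason
mergeExclusions <- function(ir) {
  if (length(ir) == 0L) return(ir)
  ord <- order(IRanges::start(ir), IRanges::end(ir))
  ir <- ir[ord]
  red <- IRanges::reduce(ir, with.revmap = TRUE)
  reason <- vapply(S4Vectors::mcols(red)$revmap, function(idx) {
    paste(sort(unique(unlist(strsplit(
      S4Vectors::mcols(ir)$reason[idx], ",", fixed = TRUE)))), collapse = ",")
  }, character(1))
  S4Vectors::mcols(red) <- S4Vectors::DataFrame(reason = reason)
  red
}

# clip an IRanges to [0, len) given template length (ranges stored 0-based via
# start0 = start(ir); we keep IRanges with start = start0, width)
clipRanges0 <- function(start0, end0, lo, hi) {
  s <- pmax(start0, lo)
  e <- pmin(end0, hi)
  keep <- e > s
  list(start0 = s[keep], end0 = e[keep], keep = keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
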