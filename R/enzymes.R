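#' Load a restriction enzyme table
#'
#' Reads a TSV of enzyme definitions: `name<TAB>site<TAB>cut_offset`, where
#' `site` is the recognition motif in IUPAC code (degenerate bases allowed)
#' and `cut_offset` the top-strand cut position in bp from the site start
#' (0..site length). Lines starting with `#` are skipped.
#'
#' @param path path to the table; the default is the curated table of common
#'   4- and 6-cutters shipped with the package.
#' @return a `data.frame` with columns `name`, `site`, `cut_offset`.
#' @export
#' @examples
#' head(loadEnzymes())
loadEnzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                           package = "markerforge")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"),
                          comment.char = "#")
  names(df) <- c("name", "site", "cut_offset")
  df$site <- toupper(df$site)
  bad <- !grepl(sprintf("^[%s]{4,}$", IUPAC_FROM), df$site)
  if (any(bad))
    stop("invalid recognition site for enzyme(s): ",
         paste(df$name[bad], collapse = ", "),
         " (sites must be >= 4 IUPAC letters)")
  if (any(df$cut_offset < 0L | df$cut_offset > nchar(df$site)))
    stop("cut_offset out of range for enzyme(s): ",
         paste(df$name[df$cut_offset < 0L |
                         df$cut_offset > nchar(df$site)], collapse = ", "))
  if (anyDuplicated(df$name))
    stop("duplicate enzyme name(s) in table")
  df
}

# per-strand recognition-site hits; returns data.frame(start0, strand).
# Degenerate (IUPAC) letters in the site match their base sets; N or any
# ambiguity code in the scanned sequence never matches (fixed subject).
scanSiteHits <- function(seq, site) {
  subj <- if (methods::is(seq, "DNAString")) seq else Biostrings::DNAString(seq)
  fw <- Biostrings::matchPattern(Biostrings::DNAString(site), subj,
                                 fixed = "subject")
  rcSite <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(site)))
  hits <- data.frame(start0 = IRanges::start(fw) - 1L,
                     strand = rep("+", length(fw)),
                     stringsAsFactors = FALSE)
  if (rcSite != toupper(as.character(site))) {
    rv <- Biostrings::matchPattern(Biostrings::DNAString(rcSite), subj,
                                   fixed = "subject")
    hits <- rbind(hits, data.frame(start0 = IRanges::start(rv) - 1L,
                                   strand = rep("-", length(rv)),
                                   stringsAsFactors = FALSE))
  }
  hits[order(hits$start0, hits$strand), , drop = FALSE]
}

#' Scan a sequence for restriction-site matches
#'
#' Reports every offset where the enzyme's IUPAC recognition site matches
#' the forward strand or where its reverse complement does (i.e. the site on
#' the bottom strand). Palindromic sites are reported once per position.
#' `N` (or any ambiguity code) in the scanned sequence never matches.
#'
#' @param seq nucleotide string (or `DNAString`) over A/C/G/T/N.
#' @param enzyme one row of an enzyme table, or a list with `site`.
#' @return sorted integer vector of 0-based match start offsets.
#' @export
#' @examples
#' scanSites("TTGAATTCTT", list(name = "EcoRI", site = "GAATTC"))  # 2
scanSites <- function(seq, enzyme) {
  sort(unique(scanSiteHits(seq, enzyme$site)$start0))
}

#' Predict restriction digestion fragment sizes
#'
#' Cuts the product at every recognition-site occurrence: top-strand cut at
#' `start + cut_offset` for forward-strand sites and at
#' `start + site length - cut_offset` for bottom-strand sites. Cuts falling
#' on the product ends are ignored (they produce no new fragment). Fragment
#' lengths are returned 5'->3' and always sum to the product length.
#'
#' @param product_seq the amplicon sequence as amplified (allele-realized).
#' @param enzyme one row of an enzyme table (needs `site`, `cut_offset`).
#' @return integer vector of fragment lengths.
#' @export
predictFragments <- function(product_seq, enzyme) {
  L <- nchar(product_seq)
  hits <- scanSiteHits(product_seq, enzyme$site)
  siteLen <- nchar(enzyme$site)
  cuts <- ifelse(hits$strand == "+",
                 hits$start0 + enzyme$cut_offset,
                 hits$start0 + siteLen - enzyme$cut_offset)
  cuts <- sort(unique(cuts[cuts > 0L & cuts < L]))
  as.integer(diff(c(0L, cuts, L)))
}
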