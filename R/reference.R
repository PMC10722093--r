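#' Load a reference genome from FASTA
#'
#' Reads a FASTA file into a named [Biostrings::DNAStringSet], preserving
#' record order. Sequences are case-folded to uppercase and IUPAC ambiguity
#' codes other than A/C/G/T are normalized to N (primer design treats any
#' ambiguous base as unusable). Contig names are the first whitespace-
#' delimited token of each header.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return a [Biostrings::DNAStringSet], one element per contig, alphabet
#'   restricted to A/C/G/T/N.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 demo", "acgtACGT"), fa)
#' loadReference(fa)
loadReference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("reference FASTA has no records: ", path)
  nm <- sub("\\s.*$", "", names(raw))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicate contig name(s) in reference: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(raw))
  bad <- grepl(sprintf("[^%s]", IUPAC_FROM), seqs)
  if (any(bad)) {
    offending <- nm[bad][1]
    ch <- regmatches(seqs[bad][1],
                     regexpr(sprintf("[^%s]", IUPAC_FROM), seqs[bad][1]))
    stop("non-nucleotide character '", ch, "' in record '", offending, "'")
  }
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for contig '", nm[which(nchar(seqs) == 0L)[1]], "'")
  # fold ambiguity codes (non-ACGT IUPAC) to N
  seqs <- chartr("RYSWKMBDHV", strrep("N", 10), seqs)
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- nm
  ref
}

# 0-based half-open slice of one contig, as character
refSlice <- function(ref, contig, start0, end0) {
  as.character(Biostrings::subseq(ref[[contig]], start0 + 1L, end0))
}
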