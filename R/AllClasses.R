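#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
NULL

#' GroupPair: two sample groups fixed for distinct alleles
#'
#' A pair of disjoint, non-empty sample sets in which every member of
#' `groupA` is homozygous for allele index `alleleA` and every member of
#' `groupB` homozygous for a different allele `alleleB` at one variant site.
#' Allele indices follow VCF convention (0 = REF, 1 = first ALT, ...).
#'
#' @slot groupA,groupB character vectors of sample names.
#' @slot alleleA,alleleB integer allele indices, `alleleA != alleleB`.
#' @exportClass GroupPair
setClass("GroupPair",
  representation(groupA = "character", groupB = "character",
                 alleleA = "integer", alleleB = "integer"))

setValidity("GroupPair", function(object) {
  msg <- character(0)
  if (length(object@groupA) == 0L || length(object@groupB) == 0L)
    msg <- c(msg, "both groups must be non-empty")
  if (length(intersect(object@groupA, object@groupB)) > 0L)
    msg <- c(msg, "groups must be disjoint")
  if (length(object@alleleA) != 1L || length(object@alleleB) != 1L ||
      is.na(object@alleleA) || is.na(object@alleleB) ||
      object@alleleA == object@alleleB)
    msg <- c(msg, "allele indices must be single, distinct integers")
  if (length(msg)) msg else TRUE
})

GroupPair <- function(groupA, groupB, alleleA, alleleB) {
  new("GroupPair", groupA = as.character(groupA), groupB = as.character(groupB),
      alleleA = as.integer(alleleA), alleleB = as.integer(alleleB))
}

setMethod("show", "GroupPair", function(object) {
  cat(sprintf("GroupPair: allele %d {%s} vs allele %d {%s}\n",
              object@alleleA, paste(object@groupA, collapse = ","),
              object@alleleB, paste(object@groupB, collapse = ",")))
})

#' VariantSet: parsed multi-sample VCF records
#'
#' In-memory representation of the genotyped variant records needed for
#' marker design: position, REF/ALT allele strings (multi-allelic records kept
#' un-split) and the per-sample genotype allele-index pair. Phased and
#' unphased separators are equivalent; missing genotypes are `NA`.
#'
#' @slot contig character vector, contig per record.
#' @slot pos integer vector, 1-based position of the first REF base.
#' @slot ref character vector of REF alleles.
#' @slot alt list of character vectors of ALT alleles.
#' @slot gt1,gt2 integer matrices (records x samples) of allele indices,
#'   `NA` for missing.
#' @slot samples character vector of sample names (matrix column order).
#' @slot skipped named integer, counts of records skipped on read
#'   (`noGT`, `symbolic`).
#' @exportClass VariantSet
setClass("VariantSet",
  representation(contig = "character", pos = "integer", ref = "character",
                 alt = "list", gt1 = "matrix", gt2 = "matrix",
                 samples = "character", skipped = "integer"))

setValidity("VariantSet", function(object) {
  n <- length(object@pos)
  if (length(object@contig) != n || length(object@ref) != n ||
      length(object@alt) != n)
    return("contig/pos/ref/alt lengths differ")
  if (n > 0L && (nrow(object@gt1) != n || nrow(object@gt2) != n))
    return("genotype matrices must have one row per record")
  if (ncol(object@gt1) != length(object@samples) ||
      ncol(object@gt2) != length(object@samples))
    return("genotype matrices must have one column per sample")
  TRUE
})

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet: %d sites x %d samples (%d skipped: %s)\n",
              length(object@pos), length(object@samples),
              sum(object@skipped),
              paste(names(object@skipped), object@skipped,
                    sep = "=", collapse = ", ")))
})

setMethod("length", "VariantSet", function(x) length(x@pos))

#' DepthTrack: per-position read depth over the reference
#'
#' Pooled read depth queryable at any reference position; positions absent
#' from the track report depth 0. Built from a depth TSV or one or more
#' indexed BAM files (pooled as the per-position minimum across files, the
#' conservative choice for low-depth masking).
#'
#' @slot cov named list of integer [S4Vectors::Rle-class] vectors, one per
#'   contig.
#' @exportClass DepthTrack
setClass("DepthTrack", representation(cov = "list"))

setValidity("DepthTrack", function(object) {
  if (length(object@cov) && is.null(names(object@cov)))
    return("coverage list must be named by contig")
  TRUE
})

setMethod("show", "DepthTrack", function(object) {
  cat(sprintf("DepthTrack: %d contig(s): %s\n", length(object@cov),
              paste(names(object@cov), collapse = ", ")))
})

#' TargetSeq: the variant plus 20-bp flanks, realized per allele
#'
#' The target sequence a marker amplicon must contain: the variant span plus
#' `flank` reference bases on each side, realized separately for the two
#' grouped alleles (the realizations differ only within the allele span).
#'
#' @slot contig contig name.
#' @slot start0,end0 0-based half-open reference interval covered
#'   (flanks + REF-allele span).
#' @slot up,down flanking reference sequence (may be shorter than requested
#'   at contig edges, then `clipped` is `TRUE`).
#' @slot alleleA,alleleB the two grouped allele strings.
#' @slot idxA,idxB their allele indices.
#' @slot clipped logical flag set when a flank was clipped by a contig edge.
#' @exportClass TargetSeq
setClass("TargetSeq",
  representation(contig = "character", start0 = "integer", end0 = "integer",
                 up = "character", down = "character",
                 alleleA = "character", alleleB = "character",
                 idxA = "integer", idxB = "integer", clipped = "logical"))

setMethod("show", "TargetSeq", function(object) {
  cat(sprintf("TargetSeq %s:[%d,%d) alleles %s/%s%s\n", object@contig,
              object@start0, object@end0, object@alleleA, object@alleleB,
              if (object@clipped) " [edge-clipped]" else ""))
})

#' DesignTemplate: masked genomic window handed to the design engine
#'
#' The target interval extended by 500 bp on each side (reference-realized),
#' carrying the mandatory target sub-interval and the excluded regions that
#' primers must not overlap. All coordinates in `targetStart`/`targetEnd` and
#' `excluded` are template-local and 0-based half-open.
#'
#' @slot contig contig name.
#' @slot start0,end0 genomic interval (0-based half-open).
#' @slot seq reference-realized template sequence.
#' @slot targetStart,targetEnd target sub-interval in template coordinates.
#' @slot excluded [IRanges::IRanges-class] of excluded regions (start =
#'   template offset, 0-based), disjoint and sorted, with a `reason` metadata
#'   column (`variant`, `low_depth`, `rejected_primer`,
#'   `same_enzyme_site_trim`).
#' @slot clipped logical, `TRUE` when the 500-bp extension hit a contig edge.
#' @exportClass DesignTemplate
setClass("DesignTemplate",
  representation(contig = "character", start0 = "integer", end0 = "integer",
                 seq = "character", targetStart = "integer",
                 targetEnd = "integer", excluded = "IRanges",
                 clipped = "logical"))

setValidity("DesignTemplate", function(object) {
  len <- nchar(object@seq)
  if (object@end0 - object@start0 != len)
    return("sequence length must match the genomic interval")
  if (object@targetStart < 0L || object@targetEnd > len ||
      object@targetStart >= object@targetEnd)
    return("target sub-interval must lie within the template")
  if (length(object@excluded)) {
    if (min(IRanges::start(object@excluded)) < 0L ||
        max(IRanges::end(object@excluded)) > len)
      return("excluded regions out of template bounds")
    if (S4Vectors::isNotSorted(IRanges::start(object@excluded)) ||
        any(IRanges::width(IRanges::pintersect(
          object@excluded[-1], object@excluded[-length(object@excluded)],
          resolve.empty = "start.x")) > 0L))
      return("excluded regions must be sorted and disjoint")
  }
  TRUE
})

setMethod("show", "DesignTemplate", function(object) {
  cat(sprintf(
    "DesignTemplate %s:[%d,%d) (%d bp), target [%d,%d), %d excluded region(s)%s\n",
    object@contig, object@start0, object@end0, nchar(object@seq),
    object@targetStart, object@targetEnd, length(object@excluded),
    if (object@clipped) " [edge-clipped]" else ""))
})

#' PrimerPair: a designed left/right primer pair
#'
#' Left primer binds the template forward strand; the right primer is the
#' reverse complement of its template footprint. Footprint coordinates are
#' template-local, 0-based half-open, and refer to the genomic (untagged)
#' part of each oligo; 5' tags (e.g. CS1/CS2) are prepended to the sequences
#' only.
#'
#' @slot leftSeq,rightSeq oligo sequences 5'->3' (tags included when set).
#' @slot tagFwd,tagRev the 5' tag sequences applied ("" when untagged).
#' @slot leftStart,leftEnd,rightStart,rightEnd template footprints.
#' @slot leftTm,rightTm melting temperatures (deg C) of the genomic parts.
#' @slot productSize amplicon length in bp.
#' @slot penalty engine penalty (lower is better).
#' @slot iteration redesign iteration at which the pair was accepted.
#' @slot status character, design/check status notes.
#' @exportClass PrimerPair
setClass("PrimerPair",
  representation(leftSeq = "character", rightSeq = "character",
                 tagFwd = "character", tagRev = "character",
                 leftStart = "integer", leftEnd = "integer",
                 rightStart = "integer", rightEnd = "integer",
                 leftTm = "numeric", rightTm = "numeric",
                 productSize = "integer", penalty = "numeric",
                 iteration = "integer", status = "character"))

setValidity("PrimerPair", function(object) {
  if (object@leftEnd <= object@leftStart ||
      object@rightEnd <= object@rightStart)
    return("primer footprints must be non-empty")
  if (object@rightEnd - object@leftStart != object@productSize)
    return("product size must equal rightEnd - leftStart")
  TRUE
})

setMethod("show", "PrimerPair", function(object) {
  cat(sprintf(
    "PrimerPair: %s (Tm %.1f) / %s (Tm %.1f), product %d bp, penalty %.2f\n",
    object@leftSeq, object@leftTm, object@rightSeq, object@rightTm,
    object@productSize, object@penalty))
})
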