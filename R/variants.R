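#' Read genotyped variant records from a multi-sample VCF
#'
#' Loads the records of a VCF (v4.x, plain or bgzipped) restricted to the
#' requested samples, keeping multi-allelic records un-split. Only the GT
#' FORMAT field is used; phased (`|`) and unphased (`/`) separators are
#' treated identically. Records where no requested sample carries a GT value
#' are skipped, as are records with symbolic alleles (`<DEL>`, breakends):
#' the marker method needs literal allele sequences. Skips are counted and
#' reported with a warning.
#'
#' @param path path to the VCF file.
#' @param samples character vector of sample names to keep; `NULL` (default)
#'   keeps all header samples.
#' @return a [VariantSet-class].
#' @export
readVariants <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  hdr <- VariantAnnotation::scanVcfHeader(path)
  hdrSamples <- VariantAnnotation::samples(hdr)
  if (!"GT" %in% rownames(VariantAnnotation::geno(hdr)))
    stop("VCF has no GT field in FORMAT; genotypes are required")
  if (is.null(samples)) samples <- hdrSamples
  missing <- setdiff(samples, hdrSamples)
  if (length(missing))
    stop("sample(s) not in VCF header: ", paste(missing, collapse = ", "))

  param <- VariantAnnotation::ScanVcfParam(fixed = "ALT", info = NA,
                                           geno = "GT", samples = samples)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown", param = param)
  n <- nrow(vcf)
  gtChar <- VariantAnnotation::geno(vcf)$GT
  if (n > 0L && is.null(dim(gtChar))) gtChar <- matrix(gtChar, nrow = n)
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  altList <- lapply(rr$ALT, function(a) as.character(a))

  # symbolic / breakend alleles cannot be realized into a template
  symbolic <- vapply(altList, function(a)
    any(grepl("[][<>]", a)), logical(1))
  # records with no usable GT among the requested samples
  missingGT <- c(".", "./.", ".|.", "")
  hasGT <- if (n == 0L) logical(0) else
    apply(gtChar, 1L, function(g) any(!is.na(g) & !(g %in% missingGT)))
  keep <- !symbolic & hasGT
  nSkipNoGT <- sum(!hasGT & !symbolic)
  nSkipSym <- sum(symbolic)
  if (nSkipNoGT + nSkipSym > 0L)
    warning(sprintf("skipped %d record(s) without GT and %d with symbolic alleles",
                    nSkipNoGT, nSkipSym))

  gtChar <- gtChar[keep, , drop = FALSE]
  parsed <- parseGT(gtChar)
  new("VariantSet",
      contig = contig[keep], pos = as.integer(pos[keep]), ref = ref[keep],
      alt = altList[keep], gt1 = parsed$a1, gt2 = parsed$a2,
      samples = as.character(samples),
      skipped = c(noGT = nSkipNoGT, symbolic = nSkipSym))
}

# parse a character GT matrix into two integer allele-index matrices
parseGT <- function(gtChar) {
  d <- dim(gtChar)
  flat <- as.vector(gtChar)
  flat[is.na(flat) | flat == ""] <- "."
  parts <- strsplit(flat, "[/|]")
  a1 <- vapply(parts, function(p) {
    if (length(p) < 1L || p[1] == ".") NA_integer_ else
      suppressWarnings(as.integer(p[1]))
  }, integer(1))
  a2 <- vapply(parts, function(p) {
    k <- if (length(p) >= 2L) p[length(p)] else p[1]  # haploid: duplicate
    if (is.na(k) || k == ".") NA_integer_ else suppressWarnings(as.integer(k))
  }, integer(1))
  list(a1 = matrix(a1, nrow = d[1], ncol = d[2], dimnames = dimnames(gtChar)),
       a2 = matrix(a2, nrow = d[1], ncol = d[2], dimnames = dimnames(gtChar)))
}

#' @describeIn VariantSet-class sample names carried by the set.
#' @param object a `VariantSet`.
#' @export
setMethod("sampleNames", "VariantSet", function(object) object@samples)

#' Extract one variant site as a plain record
#'
#' @param vs a [VariantSet-class].
#' @param i record index.
#' @return a list with elements `contig`, `pos` (1-based), `pos0`, `ref`,
#'   `alts`, `alleles` (REF first), and `gt` (2 x samples integer matrix of
#'   allele indices, `NA` = missing).
#' @export
variantSite <- function(vs, i) {
  stopifnot(i >= 1L, i <= length(vs))
  gt <- rbind(vs@gt1[i, ], vs@gt2[i, ])
  colnames(gt) <- vs@samples
  list(contig = vs@contig[i], pos = vs@pos[i], pos0 = vs@pos[i] - 1L,
       ref = vs@ref[i], alts = vs@alt[[i]],
       alleles = c(vs@ref[i], vs@alt[[i]]), gt = gt)
}

# indices of sites on `contig` overlapping [start0, end0), excluding `not`
sitesInWindow <- function(vs, contig, start0, end0, not = integer(0)) {
  refEnd0 <- vs@pos - 1L + nchar(vs@ref)
  idx <- which(vs@contig == contig & (vs@pos - 1L) < end0 & refEnd0 > start0)
  setdiff(idx, not)
}
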