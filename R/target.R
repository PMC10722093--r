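#' Extract the target sequence around a grouped variant
#'
#' Slices the reference around the variant to cover `flank` bases upstream
#' and downstream of the variant span (20 by default), and realizes the
#' sequence for each grouped allele by substituting the allele string into
#' the reference slice. Flanks clipped by a contig edge set the `clipped`
#' flag rather than failing.
#'
#' @param ref reference genome ([Biostrings::DNAStringSet]).
#' @param site variant site record (see [variantSite()]).
#' @param pair a [GroupPair-class] naming the two alleles.
#' @param flank flank width in bp (default 20).
#' @return a [TargetSeq-class].
#' @export
extractTarget <- function(ref, site, pair, flank = 20L) {
  clen <- Biostrings::width(ref)[match(site$contig, names(ref))]
  if (is.na(clen)) stop("contig not in reference: ", site$contig)
  refLen <- nchar(site$ref)
  if (site$pos0 < 0L || site$pos0 + refLen > clen)
    stop("variant outside contig bounds at ", site$contig, ":", site$pos)
  s0 <- max(0L, site$pos0 - flank)
  e0 <- min(clen, site$pos0 + refLen + flank)
  up <- refSlice(ref, site$contig, s0, site$pos0)
  down <- refSlice(ref, site$contig, site$pos0 + refLen, e0)
  alleles <- site$alleles
  iA <- pair@alleleA
  iB <- pair@alleleB
  if (iA + 1L > length(alleles) || iB + 1L > length(alleles))
    stop("group allele index exceeds the site's allele count")
  new("TargetSeq", contig = site$contig, start0 = as.integer(s0),
      end0 = as.integer(e0), up = up, down = down,
      alleleA = alleles[iA + 1L], alleleB = alleles[iB + 1L],
      idxA = iA, idxB = iB,
      clipped = (nchar(up) < flank) || (nchar(down) < flank))
}

#' @describeIn realizedSeq allele-realized target sequence
#'   (flank + allele + flank).
#' @param allele `"A"` or `"B"`, which grouped allele to realize.
#' @export
setMethod("realizedSeq", "TargetSeq", function(x, allele = c("A", "B"), ...) {
  allele <- match.arg(allele)
  paste0(x@up, if (allele == "A") x@alleleA else x@alleleB, x@down)
})

#' InDel marker screen: allele length difference within a size window
#'
#' @param alleleA,alleleB the two grouped allele strings.
#' @param size_min,size_max inclusive window for the absolute length
#'   difference, in bp.
#' @return `TRUE` when the difference falls inside the window.
#' @export
screenIndel <- function(alleleA, alleleB, size_min, size_max) {
  stopifnot(size_min >= 1L, size_max >= size_min)
  d <- abs(nchar(alleleA) - nchar(alleleB))
  d >= size_min && d <= size_max
}

#' CAPS marker screen: differential restriction digestion of the two alleles
#'
#' For each enzyme, counts recognition sites in the two allele-realized
#' target sequences (variant span plus identical 20-bp flanks, so any count
#' difference is caused by the allele itself). An enzyme qualifies when it
#' cuts one realized allele at least once and the other not at all.
#'
#' @param target a [TargetSeq-class].
#' @param enzymes enzyme table `data.frame` (see [loadEnzymes()]).
#' @return a `data.frame` with columns `name`, `site`, `cut_offset`,
#'   `digested_allele` (`"A"` or `"B"`); zero rows when no enzyme
#'   discriminates.
#' @export
screenCaps <- function(target, enzymes) {
  seqA <- realizedSeq(target, "A")
  seqB <- realizedSeq(target, "B")
  keep <- integer(0)
  digested <- character(0)
  for (k in seq_len(nrow(enzymes))) {
    enz <- enzymes[k, ]
    nA <- length(scanSites(seqA, enz))
    nB <- length(scanSites(seqB, enz))
    if (nA >= 1L && nB == 0L) {
      keep <- c(keep, k)
      digested <- c(digested, "A")
    } else if (nB >= 1L && nA == 0L) {
      keep <- c(keep, k)
      digested <- c(digested, "B")
    }
  }
  out <- enzymes[keep, , drop = FALSE]
  out$digested_allele <- digested
  rownames(out) <- NULL
  out
}

#' SNP marker screen: both grouped alleles are single, distinct bases
#'
#' The grouped allele pair decides, not REF/ALT: a multi-allelic record
#' grouped on two single-base ALT alleles passes.
#'
#' @param site variant site record.
#' @param pair a [GroupPair-class].
#' @return `TRUE` for a usable SNP allele pair.
#' @export
screenSnp <- function(site, pair) {
  a <- site$alleles[pair@alleleA + 1L]
  b <- site$alleles[pair@alleleB + 1L]
  nchar(a) == 1L && nchar(b) == 1L && a != b
}
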