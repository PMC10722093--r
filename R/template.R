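#' Build the extended design template around a target
#'
#' Extends the target interval by `flank` bases (500 by default) on each
#' side, clipped to the contig, and slices the reference over that window.
#' The target sub-interval is recorded in template coordinates as the
#' mandatory amplified region.
#'
#' @param ref reference genome ([Biostrings::DNAStringSet]).
#' @param target a [TargetSeq-class].
#' @param flank extension width in bp (default 500).
#' @return a [DesignTemplate-class] with no excluded regions yet.
#' @export
buildTemplate <- function(ref, target, flank = 500L) {
  clen <- Biostrings::width(ref)[match(target@contig, names(ref))]
  s0 <- max(0L, target@start0 - flank)
  e0 <- min(clen, target@end0 + flank)
  new("DesignTemplate", contig = target@contig,
      start0 = as.integer(s0), end0 = as.integer(e0),
      seq = refSlice(ref, target@contig, s0, e0),
      targetStart = as.integer(target@start0 - s0),
      targetEnd = as.integer(target@end0 - s0),
      excluded = IRanges::IRanges(),
      clipped = target@clipped ||
        (s0 > target@start0 - flank) || (e0 < target@end0 + flank))
}

# append exclusion region(s) (template coords, 0-based half-open) and merge
addExclusions <- function(tmpl, start0, end0, reason) {
  len <- nchar(tmpl@seq)
  cl <- clipRanges0(as.integer(start0), as.integer(end0), 0L, len)
  if (!length(cl$start0)) return(tmpl)
  add <- IRanges::IRanges(start = cl$start0, width = cl$end0 - cl$start0)
  S4Vectors::mcols(add) <- S4Vectors::DataFrame(
    reason = rep(reason, length.out = length(add))[cl$keep])
  tmpl@excluded <- mergeExclusions(c(tmpl@excluded, add))
  tmpl
}

#' Mask nearby segregating variants on a template
#'
#' Every other variant site overlapping the template whose genotypes are not
#' monomorphic across the grouped samples (union of both groups) is excluded
#' from primer placement, covering its REF span plus a 1-bp guard on each
#' side. Heterozygous or missing genotypes count as polymorphic. Sites
#' segregating only among unselected samples do not mask: primers must bind
#' identically in the assayed material only.
#'
#' @param tmpl a [DesignTemplate-class].
#' @param nearby list of variant site records overlapping the template
#'   (excluding the marker site itself).
#' @param pair the marker's [GroupPair-class].
#' @return the template with updated exclusions (reason `"variant"`).
#' @export
maskVariants <- function(tmpl, nearby, pair) {
  grouped <- c(pair@groupA, pair@groupB)
  for (site in nearby) {
    gt <- site$gt[, intersect(grouped, colnames(site$gt)), drop = FALSE]
    if (ncol(gt) == 0L) next
    alleles <- unique(as.vector(gt))
    poly <- anyNA(alleles) || length(alleles) > 1L
    if (!poly) next
    s0 <- site$pos0 - tmpl@start0 - 1L
    e0 <- site$pos0 + nchar(site$ref) - tmpl@start0 + 1L
    tmpl <- addExclusions(tmpl, s0, e0, "variant")
  }
  tmpl
}

#' Mask low-read-depth regions on a template
#'
#' Every maximal run of template positions with pooled depth below
#' `min_depth` becomes an excluded region. With `min_depth` 0 the template
#' is returned unchanged (depth is never negative).
#'
#' @param tmpl a [DesignTemplate-class].
#' @param depth a [DepthTrack-class].
#' @param min_depth minimum acceptable depth (inclusive).
#' @return the template with updated exclusions (reason `"low_depth"`).
#' @export
maskLowDepth <- function(tmpl, depth, min_depth) {
  stopifnot(min_depth >= 0L)
  if (min_depth == 0L) return(tmpl)
  d <- depthVector(depth, tmpl@contig, tmpl@start0, tmpl@end0)
  low <- d < min_depth
  if (!any(low)) return(tmpl)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  addExclusions(tmpl, starts[r$values], ends[r$values], "low_depth")
}

#' @describeIn realizedSeq allele-realized template sequence: the reference
#'   slice with the grouped allele substituted at the marker span.
#' @param target the [TargetSeq-class] the template was built from.
#' @export
setMethod("realizedSeq", "DesignTemplate",
          function(x, target, allele = c("A", "B"), ...) {
  allele <- match.arg(allele)
  vStart <- x@targetStart + nchar(target@up)            # template coords
  vEnd <- x@targetEnd - nchar(target@down)
  paste0(slice0(x@seq, 0L, vStart),
         if (allele == "A") target@alleleA else target@alleleB,
         slice0(x@seq, vEnd, nchar(x@seq)))
})

#' Trim a CAPS template to a unique cut site
#'
#' Scans the digested-allele-realized template for the marker's enzyme. If
#' recognition sites other than the target-locus site are found, the
#' template is shortened so that the nearest flanking extra site on each
#' side (and everything beyond it) is removed; after trimming exactly one
#' site remains, guaranteeing a single cut in any amplicon.
#'
#' @param tmpl a [DesignTemplate-class].
#' @param enzyme one row of an enzyme table.
#' @param target the marker's [TargetSeq-class].
#' @param digested_allele `"A"` or `"B"`, the allele the enzyme cuts.
#' @return the (possibly shortened) template, or `NULL` when a unique cut
#'   site cannot be achieved (more than one site inside the target region,
#'   or the trimmed template can no longer contain the target).
#' @export
trimCapsTemplate <- function(tmpl, enzyme, target,
                             digested_allele = c("A", "B")) {
  digested_allele <- match.arg(digested_allele)
  realized <- realizedSeq(tmpl, target, digested_allele)
  alleleSeq <- if (digested_allele == "A") target@alleleA else target@alleleB
  refSpan <- (tmpl@targetEnd - nchar(target@down)) -
             (tmpl@targetStart + nchar(target@up))
  delta <- nchar(alleleSeq) - refSpan           # realized-vs-template shift
  tEndR <- tmpl@targetEnd + delta               # target end, realized coords
  hits <- scanSites(realized, enzyme)
  L <- nchar(enzyme$site)
  inTarget <- hits + L > tmpl@targetStart & hits < tEndR
  if (sum(inTarget) != 1L) return(NULL)
  leftExtra <- hits[hits + L <= tmpl@targetStart]
  rightExtra <- hits[hits >= tEndR]
  newStart <- if (length(leftExtra)) max(leftExtra) + L else 0L
  newEndR <- if (length(rightExtra)) min(rightExtra) else nchar(realized)
  newEnd <- newEndR - delta                     # back to template coords
  if (length(leftExtra) == 0L && length(rightExtra) == 0L) return(tmpl)

  out <- tmpl
  out@start0 <- tmpl@start0 + as.integer(newStart)
  out@end0 <- tmpl@start0 + as.integer(newEnd)
  out@seq <- slice0(tmpl@seq, newStart, newEnd)
  out@targetStart <- tmpl@targetStart - as.integer(newStart)
  out@targetEnd <- tmpl@targetEnd - as.integer(newStart)
  if (out@targetStart < 0L || out@targetEnd > nchar(out@seq)) return(NULL)
  # shift and clip exclusions into the trimmed window
  if (length(tmpl@excluded)) {
    s <- IRanges::start(tmpl@excluded) - as.integer(newStart)
    e <- IRanges::end(tmpl@excluded) + 1L - as.integer(newStart)
    reason <- S4Vectors::mcols(tmpl@excluded)$reason
    cl <- clipRanges0(s, e, 0L, nchar(out@seq))
    out@excluded <- IRanges::IRanges()
    if (length(cl$start0)) {
      keep <- IRanges::IRanges(start = cl$start0,
                               width = cl$end0 - cl$start0)
      S4Vectors::mcols(keep) <- S4Vectors::DataFrame(reason = reason[cl$keep])
      out@excluded <- keep
    }
  }
  # post-condition: exactly one site in the trimmed realized template
  reHits <- scanSites(realizedSeq(out, target, digested_allele), enzyme)
  if (length(reHits) != 1L)
    stop("internal error: CAPS trim did not leave a unique cut site")
  out
}
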