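#' Universal amplicon-sequencing tag sequences (CS1/CS2)
#'
#' The common 22-nt adapter tags prepended to locus-specific primers so a
#' second PCR can attach sequencing adapters and indices.
#'
#' @rdname tags
#' @export
CS1_TAG <- "ACACTGACGACATGGTTCTACA"

#' @rdname tags
#' @export
CS2_TAG <- "TACGGTAGCAGAGACTTGGTCT"

#' Prepend 5' tag sequences to a primer pair
#'
#' Tags go on the 5' end of each oligo; genomic footprints, Tm of the
#' genomic parts and product size are unchanged. Empty tags leave the pair
#' untouched.
#'
#' @param pair a [PrimerPair-class].
#' @param tag_fwd,tag_rev tag sequences for the left and right primer.
#' @return the tagged [PrimerPair-class].
#' @export
addTags <- function(pair, tag_fwd = CS1_TAG, tag_rev = CS2_TAG) {
  core <- untaggedSeqs(pair)
  pair@tagFwd <- toupper(tag_fwd)
  pair@tagRev <- toupper(tag_rev)
  pair@leftSeq <- paste0(pair@tagFwd, core$left)
  pair@rightSeq <- paste0(pair@tagRev, core$right)
  pair
}

# genomic (untagged) oligo parts
untaggedSeqs <- function(pair) {
  list(left = substr(pair@leftSeq, nchar(pair@tagFwd) + 1L,
                     nchar(pair@leftSeq)),
       right = substr(pair@rightSeq, nchar(pair@tagRev) + 1L,
                      nchar(pair@rightSeq)))
}

#' Design a specific, structure-clean primer pair with iterative redesign
#'
#' Drives the full design loop: take the engine's best candidate on the
#' masked template; if it has a facing off-target pair within 10 kb or fails
#' the secondary-structure filter, add both primer footprints to the
#' excluded regions (reason `"rejected_primer"`) and redesign. Stops at the
#' first pair passing both checks, when the engine yields no candidates, or
#' at the iteration cap. In SNP mode the tags are applied before the
#' structure check (tags can form dimers) but off-target matching uses the
#' genomic parts.
#'
#' @param tmpl a [DesignTemplate-class].
#' @param params a [designParams()] list.
#' @param ref reference genome, for the specificity scan.
#' @param mode `"indel"`, `"caps"` or `"snp"`.
#' @param tag_fwd,tag_rev 5' tags applied in SNP mode.
#' @param max_product off-target facing-pair span limit, bp.
#' @return a list of class `DesignResult` with elements `pair` (the accepted
#'   [PrimerPair-class], or `NULL` on exhaustion), `reason` (`"accepted"`,
#'   `"no_candidates"` or `"iteration_cap"`), `iterations` (iterations
#'   consumed) and `template` (the final template, including
#'   `rejected_primer` exclusions accumulated during redesign).
#' @export
designWithRedesign <- function(tmpl, params = designParams(), ref,
                               mode = c("indel", "caps", "snp"),
                               tag_fwd = CS1_TAG, tag_rev = CS2_TAG,
                               max_product = 10000L) {
  mode <- match.arg(mode)
  targetInterval <- list(contig = tmpl@contig, start0 = tmpl@start0,
                         end0 = tmpl@end0)
  result <- function(pair, reason, it) {
    structure(list(pair = pair, reason = reason, iterations = it,
                   template = tmpl), class = "DesignResult")
  }
  for (it in seq.int(0L, params$maxIterations)) {
    cands <- designCandidates(tmpl, params)
    if (!length(cands)) return(result(NULL, "no_candidates", it))
    cand <- cands[[1]]
    cand@iteration <- it
    reject <- FALSE
    ot <- findOffTargets(cand, ref, targetInterval, max_product)
    if (nrow(ot)) {
      reject <- TRUE
    } else {
      if (mode == "snp" && (nzchar(tag_fwd) || nzchar(tag_rev)))
        cand <- addTags(cand, tag_fwd, tag_rev)
      if (hasSecondaryStructure(cand, params)) reject <- TRUE
    }
    if (reject) {
      tmpl <- addExclusions(tmpl,
                            c(cand@leftStart, cand@rightStart),
                            c(cand@leftEnd, cand@rightEnd),
                            "rejected_primer")
      next
    }
    cand@status <- "accepted"
    return(result(cand, "accepted", it))
  }
  result(NULL, "iteration_cap", params$maxIterations)
}
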