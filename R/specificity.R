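# Genome-wide binding sites of one primer.
#
# 3'-anchored near-exact matching, mirroring PCR extension chemistry: the
# primer's 3'-terminal `seedLen` bases must match exactly (found with a
# fast exact scan), and the remaining 5' bases may carry at most
# `maxMismatch` mismatches. Returns data.frame(contig, start0, end0, strand):
# strand "+" = primer sequence on the plus strand, 3' end at end0 - 1;
# strand "-" = primer binds as its reverse complement, 3' end at start0.
primerBindingSites <- function(primer, ref, seedLen = 15L, maxMismatch = 2L) {
  primer <- toupper(primer)
  n <- nchar(primer)
  if (n < seedLen) stop("primer shorter than the specificity seed (", seedLen, " bp)")
  seedFw <- substr(primer, n - seedLen + 1L, n)
  rc <- revcomp(primer)
  seedRv <- substr(rc, 1L, seedLen)
  out <- list()
  for (ctg in names(ref)) {
    subj <- ref[[ctg]]
    clen <- length(subj)
    fw <- Biostrings::matchPattern(seedFw, subj, fixed = TRUE)
    for (s in IRanges::start(fw)) {          # 1-based seed start
      full0 <- (s - 1L) - (n - seedLen)      # full-match start, 0-based
      if (full0 < 0L) next
      head5 <- as.character(Biostrings::subseq(subj, full0 + 1L,
                                               full0 + n - seedLen))
      if (hammingDist(head5, substr(primer, 1L, n - seedLen)) <= maxMismatch)
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, start0 = full0, end0 = full0 + n, strand = "+",
          stringsAsFactors = FALSE)
    }
    rv <- Biostrings::matchPattern(seedRv, subj, fixed = TRUE)
    for (s in IRanges::start(rv)) {
      full0 <- s - 1L
      if (full0 + n > clen) next
      tail5 <- as.character(Biostrings::subseq(subj, full0 + seedLen + 1L,
                                               full0 + n))
      if (hammingDist(tail5, substr(rc, seedLen + 1L, n)) <= maxMismatch)
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, start0 = full0, end0 = full0 + n, strand = "-",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start0 = integer(0),
                      end0 = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

hammingDist <- function(a, b) {
  if (nchar(a) == 0L) return(0L)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Find potential off-target amplicons for a primer pair
#'
#' Enumerates genome-wide binding sites of both primers on both strands
#' (3'-anchored near-exact matching; exact 3'-terminal 15-mer, at most 2
#' mismatches in the 5' remainder) and reports every facing site
#' combination — a plus-strand hit upstream of a minus-strand hit, 3' ends
#' pointing at each other — whose implied product is at most `max_product`
#' bp (10 kb by default, the span within which a spurious facing pair is
#' considered amplifiable). The intended product — the facing pair whose
#' two binding sites both overlap the target interval — is excluded;
#' chimeric pairs with only one anchor at the locus are reported.
#'
#' @param pair a [PrimerPair-class] (genomic, untagged parts are used).
#' @param ref reference genome ([Biostrings::DNAStringSet]).
#' @param target_interval list with `contig`, `start0`, `end0`: the genomic
#'   interval of the design template; facing pairs overlapping it are the
#'   intended product.
#' @param max_product largest implied off-target product, bp.
#' @return data.frame with one row per off-target hit: `contig`,
#'   `plus_start0`, `plus_end0`, `minus_start0`, `minus_end0`,
#'   `plus_primer` (`"left"`/`"right"`), `product`.
#' @export
findOffTargets <- function(pair, ref, target_interval, max_product = 10000L) {
  corePair <- untaggedSeqs(pair)
  hitsL <- primerBindingSites(corePair$left, ref)
  hitsR <- primerBindingSites(corePair$right, ref)
  combos <- rbind(facingCombos(hitsL, hitsR, "left", max_product),
                  facingCombos(hitsR, hitsL, "right", max_product))
  if (!nrow(combos)) return(combos)
  # the intended product is the pair whose two binding sites both lie at
  # the target locus; a facing pair with only one anchor at the locus is a
  # genuine chimeric off-target
  onTarget <- function(s0, e0)
    combos$contig == target_interval$contig &
      s0 < target_interval$end0 & e0 > target_interval$start0
  intended <- onTarget(combos$plus_start0, combos$plus_end0) &
    onTarget(combos$minus_start0, combos$minus_end0)
  combos <- combos[!intended, , drop = FALSE]
  rownames(combos) <- NULL
  combos[order(combos$contig, combos$plus_start0, combos$minus_end0), ,
         drop = FALSE]
}

# facing combinations with `plusHits` of primer `plusName` on "+" and the
# other primer's hits on "-"
facingCombos <- function(plusHits, minusHits, plusName, max_product) {
  p <- plusHits[plusHits$strand == "+", , drop = FALSE]
  m <- minusHits[minusHits$strand == "-", , drop = FALSE]
  empty <- data.frame(contig = character(0), plus_start0 = integer(0),
                      plus_end0 = integer(0), minus_start0 = integer(0),
                      minus_end0 = integer(0), plus_primer = character(0),
                      product = integer(0), stringsAsFactors = FALSE)
  if (!nrow(p) || !nrow(m)) return(empty)
  g <- expand.grid(i = seq_len(nrow(p)), j = seq_len(nrow(m)))
  g <- g[p$contig[g$i] == m$contig[g$j], , drop = FALSE]
  if (!nrow(g)) return(empty)
  product <- m$end0[g$j] - p$start0[g$i]
  keep <- product > 0L & product <= max_product
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) return(empty)
  data.frame(contig = p$contig[g$i],
             plus_start0 = p$start0[g$i], plus_end0 = p$end0[g$i],
             minus_start0 = m$start0[g$j], minus_end0 = m$end0[g$j],
             plus_primer = plusName, product = product[keep],
             stringsAsFactors = FALSE)
}
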