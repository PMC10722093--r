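#' Primer design parameters
#'
#' Bundles the tunable constraints of the design engine. Defaults are a
#' conventional PCR design window: 18-25 nt primers (optimum 20), Tm 55-65
#' deg C (optimum 60), GC 20-80%, product 120-300 bp.
#'
#' @param productMin,productMax amplicon size window, bp.
#' @param tmMin,tmOpt,tmMax primer melting temperature window, deg C.
#' @param lenMin,lenOpt,lenMax primer length window, nt.
#' @param gcMin,gcMax primer GC content window, percent.
#' @param maxIterations redesign iteration cap for [designWithRedesign()].
#' @param maxCandidatesPerSide candidate primers kept per side before
#'   pairing (by individual penalty).
#' @param maxPairs maximum pairs returned by [designCandidates()].
#' @param dimerRunMax,hairpinStemMax,hairpinLoopMin secondary-structure
#'   thresholds, see [hasSecondaryStructure()].
#' @param wTm,wLen,wTmDiff penalty weights: deviation from optimal Tm,
#'   deviation from optimal length, and left/right Tm difference.
#' @return a list of class `DesignParams`.
#' @export
designParams <- function(productMin = 120L, productMax = 300L,
                         tmMin = 55, tmOpt = 60, tmMax = 65,
                         lenMin = 18L, lenOpt = 20L, lenMax = 25L,
                         gcMin = 20, gcMax = 80,
                         maxIterations = 10L,
                         maxCandidatesPerSide = 120L, maxPairs = 50L,
                         dimerRunMax = 8L, hairpinStemMax = 8L,
                         hairpinLoopMin = 3L,
                         wTm = 1, wLen = 0.2, wTmDiff = 0.5) {
  stopifnot(productMin <= productMax, tmMin <= tmOpt, tmOpt <= tmMax,
            lenMin <= lenOpt, lenOpt <= lenMax, lenMin >= 15L)
  structure(list(productMin = as.integer(productMin),
                 productMax = as.integer(productMax),
                 tmMin = tmMin, tmOpt = tmOpt, tmMax = tmMax,
                 lenMin = as.integer(lenMin), lenOpt = as.integer(lenOpt),
                 lenMax = as.integer(lenMax),
                 gcMin = gcMin, gcMax = gcMax,
                 maxIterations = as.integer(maxIterations),
                 maxCandidatesPerSide = as.integer(maxCandidatesPerSide),
                 maxPairs = as.integer(maxPairs),
                 dimerRunMax = as.integer(dimerRunMax),
                 hairpinStemMax = as.integer(hairpinStemMax),
                 hairpinLoopMin = as.integer(hairpinLoopMin),
                 wTm = wTm, wLen = wLen, wTmDiff = wTmDiff),
            class = "DesignParams")
}

# enumerate single-side candidates on a template.
# side "left": footprints [s,e) with e <= targetStart;
# side "right": footprints with s >= targetEnd (primer = revcomp of slice;
# Tm/GC are strand-symmetric so computed on the slice).
# exclMask: logical per template position (TRUE = excluded).
# returns data.frame(start0, end0, tm, gc, penalty) sorted by penalty.
enumerateSide <- function(tmpl, params, side, exclMask, tm) {
  len <- nchar(tmpl@seq)
  ch <- strsplit(tmpl@seq, "", fixed = TRUE)[[1]]
  cumExcl <- c(0L, cumsum(as.integer(exclMask)))
  cumGC <- c(0L, cumsum(as.integer(ch %in% c("G", "C"))))
  lens <- seq.int(params$lenMin, params$lenMax)
  if (side == "left") {
    ends <- seq_len(tmpl@targetStart)          # e in 1..targetStart
    grid <- expand.grid(e = ends, L = lens)
    grid$s <- grid$e - grid$L
  } else {
    starts <- if (tmpl@targetEnd > len - params$lenMin) integer(0) else
      seq.int(tmpl@targetEnd, len - params$lenMin)
    grid <- expand.grid(s = starts, L = lens)
    grid$e <- grid$s + grid$L
  }
  grid <- grid[grid$s >= 0L & grid$e <= len, , drop = FALSE]
  if (!nrow(grid)) return(grid)
  # excluded-region overlap and GC, O(1) per candidate via cumsums
  nExcl <- cumExcl[grid$e + 1L] - cumExcl[grid$s + 1L]
  grid <- grid[nExcl == 0L, , drop = FALSE]
  if (!nrow(grid)) return(grid)
  gc <- 100 * (cumGC[grid$e + 1L] - cumGC[grid$s + 1L]) / grid$L
  keep <- gc >= params$gcMin & gc <= params$gcMax
  grid <- grid[keep, , drop = FALSE]
  gc <- gc[keep]
  if (!nrow(grid)) return(grid)
  tmv <- tm(grid$s, grid$e)
  keep <- !is.na(tmv) & tmv >= params$tmMin & tmv <= params$tmMax
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(grid)
  out <- data.frame(start0 = grid$s, end0 = grid$e, tm = tmv[keep],
                    gc = gc[keep])
  out$penalty <- params$wTm * abs(out$tm - params$tmOpt) +
    params$wLen * abs((out$end0 - out$start0) - params$lenOpt)
  out <- out[order(out$penalty, out$start0, out$end0), , drop = FALSE]
  utils::head(out, params$maxCandidatesPerSide)
}

#' Design candidate primer pairs on a masked template
#'
#' Exhaustively enumerates left and right primers that lie outside every
#' excluded region, flank the mandatory target sub-interval, and satisfy the
#' length, GC and Tm windows; pairs them under the product-size window and
#' returns pairs ordered by ascending penalty (deviation from optimal Tm and
#' length plus a left/right Tm-difference term).
#'
#' @param tmpl a [DesignTemplate-class] with merged exclusions.
#' @param params a [designParams()] list.
#' @return list of [PrimerPair-class], best first; empty when no pair
#'   satisfies the constraints.
#' @export
designCandidates <- function(tmpl, params = designParams()) {
  len <- nchar(tmpl@seq)
  exclMask <- rep(FALSE, len)
  if (length(tmpl@excluded)) {
    for (k in seq_along(tmpl@excluded)) {
      s <- IRanges::start(tmpl@excluded)[k]
      w <- IRanges::width(tmpl@excluded)[k]
      exclMask[seq.int(s + 1L, s + w)] <- TRUE
    }
  }
  tm <- tmProfile(tmpl@seq)
  left <- enumerateSide(tmpl, params, "left", exclMask, tm)
  if (!nrow(left)) return(list())
  right <- enumerateSide(tmpl, params, "right", exclMask, tm)
  if (!nrow(right)) return(list())

  # pair under the product window: product = right end - left start
  cross <- expand.grid(i = seq_len(nrow(left)), j = seq_len(nrow(right)))
  prod <- right$end0[cross$j] - left$start0[cross$i]
  keep <- prod >= params$productMin & prod <= params$productMax
  cross <- cross[keep, , drop = FALSE]
  prod <- prod[keep]
  if (!nrow(cross)) return(list())
  pen <- left$penalty[cross$i] + right$penalty[cross$j] +
    params$wTmDiff * abs(left$tm[cross$i] - right$tm[cross$j])
  ord <- order(pen, prod, left$start0[cross$i], right$end0[cross$j])
  ord <- utils::head(ord, params$maxPairs)

  lapply(ord, function(k) {
    i <- cross$i[k]
    j <- cross$j[k]
    leftSeq <- slice0(tmpl@seq, left$start0[i], left$end0[i])
    rightSeq <- revcomp(slice0(tmpl@seq, right$start0[j], right$end0[j]))
    new("PrimerPair", leftSeq = leftSeq, rightSeq = rightSeq,
        tagFwd = "", tagRev = "",
        leftStart = as.integer(left$start0[i]),
        leftEnd = as.integer(left$end0[i]),
        rightStart = as.integer(right$start0[j]),
        rightEnd = as.integer(right$end0[j]),
        leftTm = left$tm[i], rightTm = right$tm[j],
        productSize = as.integer(prod[k]), penalty = pen[k],
        iteration = 0L, status = "candidate")
  })
}
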