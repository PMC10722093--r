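# Longest contiguous antiparallel complementary run between two oligos
# (both written 5'->3'): equals the longest common substring between `a`
# and revcomp(b). Ungapped, run-length scoring in the classic primer-design
# ALIGN style.
dimerRun <- function(a, b) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  y <- strsplit(revcomp(toupper(b)), "", fixed = TRUE)[[1]]
  n <- length(x)
  m <- length(y)
  best <- 0L
  # scan all diagonals of the (n x m) match matrix
  for (off in seq.int(-(m - 1L), n - 1L)) {
    i <- max(1L, 1L + off):min(n, m + off)
    j <- i - off
    eq <- x[i] == y[j]
    if (any(eq)) {
      r <- rle(eq)
      best <- max(best, max(r$lengths[r$values]))
    }
  }
  best
}

# Longest hairpin stem: max k such that a[i..i+k-1] base-pairs (antiparallel)
# with a[j-k+1..j] inside the same strand with loop length >= minLoop.
# DP on outer pair (i, j): L[i,j] = 1 + L[i+1, j-1] when a[i] pairs a[j].
hairpinStem <- function(a, minLoop = 3L) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  n <- length(x)
  if (n < 2L * 1L + minLoop) return(0L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pair <- outer(x, x, function(p, q) {
    cc <- unname(comp[q])
    !is.na(cc) & p == cc
  })
  L <- matrix(0L, n, n)
  best <- 0L
  for (span in seq.int(minLoop + 1L, n - 1L)) {   # span = j - i
    for (i in seq_len(n - span)) {
      j <- i + span
      if (pair[i, j]) {
        inner <- if (i + 1L <= j - 1L) L[i + 1L, j - 1L] else 0L
        k <- 1L + inner
        # stem of length k needs loop (j - k) - (i + k) + 1 >= minLoop
        while (k > 1L && (j - i + 1L - 2L * k) < minLoop) k <- k - 1L
        L[i, j] <- k
        best <- max(best, k)
      }
    }
  }
  best
}

#' Secondary-structure filter for a primer pair
#'
#' Fails a pair when either oligo can fold into a hairpin (complementary
#' stem of `hairpinStemMax` or more bases enclosing a loop of at least
#' `hairpinLoopMin`), or when either self-dimer or the cross-dimer contains
#' a contiguous antiparallel complementary run of `dimerRunMax` or more
#' bases. Checks run on the full synthesized oligos — 5' tags included when
#' present, since tags can themselves form dimers.
#'
#' @param pair a [PrimerPair-class].
#' @param params a [designParams()] list supplying the thresholds.
#' @return `TRUE` when a disqualifying structure is found.
#' @export
hasSecondaryStructure <- function(pair, params = designParams()) {
  l <- pair@leftSeq
  r <- pair@rightSeq
  if (dimerRun(l, l) >= params$dimerRunMax) return(TRUE)
  if (dimerRun(r, r) >= params$dimerRunMax) return(TRUE)
  if (dimerRun(l, r) >= params$dimerRunMax) return(TRUE)
  if (hairpinStem(l, params$hairpinLoopMin) >= params$hairpinStemMax)
    return(TRUE)
  if (hairpinStem(r, params$hairpinLoopMin) >= params$hairpinStemMax)
    return(TRUE)
  FALSE
}
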