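# Nearest-neighbor duplex thermodynamics (SantaLucia 1998 unified
# parameters). dH in kcal/mol, dS in cal/(mol K). The table is
# duplex-symmetric: a sequence and its reverse complement share parameters,
# so the Tm of a right primer equals the Tm of its template footprint.

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# terminal initiation: G/C end vs A/T end
INIT_DH <- c(GC = 0.1, AT = 2.3)
INIT_DS <- c(GC = -2.8, AT = 4.1)
R_GAS <- 1.987  # cal/(mol K)

# effective monovalent cation concentration (mM), von Ahsen et al. 2001
saltEquivalent <- function(mono_mM, dival_mM, dntp_mM) {
  mono_mM + 120 * sqrt(pmax(0, dival_mM - dntp_mM))
}

#' Primer melting temperature (nearest-neighbor model)
#'
#' Duplex Tm from SantaLucia (1998) unified nearest-neighbor parameters with
#' the salt correction applied to the entropy term
#' (`dS + 0.368 (N-1) ln[Na+eq]`) and divalent cations folded into an
#' equivalent monovalent concentration. Defaults match common PCR design
#' practice: 50 nM oligo, 50 mM monovalent, 1.5 mM Mg2+, 0.6 mM dNTP.
#'
#' @param seq character vector of primer sequences (A/C/G/T).
#' @param conc_nM oligo concentration in nM.
#' @param mono_mM monovalent cation concentration in mM.
#' @param dival_mM divalent cation concentration in mM.
#' @param dntp_mM total dNTP concentration in mM.
#' @return numeric vector of melting temperatures in deg C.
#' @export
#' @examples
#' primerTm("AGCGGATAACAATTTCACACAGGA")
primerTm <- function(seq, conc_nM = 50, mono_mM = 50, dival_mM = 1.5,
                     dntp_mM = 0.6) {
  vapply(toupper(seq), function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(ch)
    if (n < 2L || any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
    steps <- paste0(ch[-n], ch[-1])
    endClass <- ifelse(ch[c(1L, n)] %in% c("G", "C"), "GC", "AT")
    dH <- sum(NN_DH[steps]) + sum(INIT_DH[endClass])
    dS <- sum(NN_DS[steps]) + sum(INIT_DS[endClass])
    naEq <- saltEquivalent(mono_mM, dival_mM, dntp_mM) / 1000
    dS <- dS + 0.368 * (n - 1) * log(naEq)
    1000 * dH / (dS + R_GAS * log(conc_nM * 1e-9 / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# Cumulative dH/dS profile along a template string for O(1) windowed Tm.
# Returns a closure tm(start0, end0) over 0-based half-open windows; windows
# containing N give NA.
tmProfile <- function(seq, conc_nM = 50, mono_mM = 50, dival_mM = 1.5,
                      dntp_mM = 0.6) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  steps <- if (n >= 2L) paste0(ch[-n], ch[-1]) else character(0)
  dh <- NN_DH[steps]
  ds <- NN_DS[steps]
  bad <- is.na(dh)
  dh[bad] <- 0
  ds[bad] <- 0
  cumH <- c(0, cumsum(dh))
  cumS <- c(0, cumsum(ds))
  cumBadStep <- c(0, cumsum(as.integer(bad)))
  isGC <- ch %in% c("G", "C")
  naEq <- saltEquivalent(mono_mM, dival_mM, dntp_mM) / 1000
  logNa <- log(naEq)
  logC <- log(conc_nM * 1e-9 / 4)
  function(start0, end0) {
    len <- end0 - start0
    dH <- cumH[end0] - cumH[start0 + 1L] +
      ifelse(isGC[start0 + 1L], INIT_DH["GC"], INIT_DH["AT"]) +
      ifelse(isGC[end0], INIT_DH["GC"], INIT_DH["AT"])
    dS <- cumS[end0] - cumS[start0 + 1L] +
      ifelse(isGC[start0 + 1L], INIT_DS["GC"], INIT_DS["AT"]) +
      ifelse(isGC[end0], INIT_DS["GC"], INIT_DS["AT"]) +
      0.368 * (len - 1) * logNa
    tm <- 1000 * dH / (dS + R_GAS * logC) - 273.15
    nBad <- cumBadStep[end0] - cumBadStep[start0 + 1L]
    tm[nBad > 0L] <- NA_real_
    unname(tm)
  }
}
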