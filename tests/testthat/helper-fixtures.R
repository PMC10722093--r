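# Shared test builders: everything is generated in code at test time.

# in-memory variant site record (same shape as variantSite())
mkSite <- function(contig = "c1", pos = 101L, ref = "A", alts = "T",
                   gt = c(s1 = "0/0", s2 = "1/1")) {
  parts <- strsplit(unname(gt), "[/|]")
  idx <- function(k) vapply(parts, function(p) {
    v <- p[min(k, length(p))]
    if (v == ".") NA_integer_ else as.integer(v)
  }, integer(1))
  m <- rbind(idx(1), idx(2))
  colnames(m) <- names(gt)
  list(contig = contig, pos = as.integer(pos), pos0 = as.integer(pos) - 1L,
       ref = ref, alts = alts, alleles = c(ref, alts), gt = m)
}

writeTempFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(seqs[[nm]], con)
  }
  path
}

# minimal VCF writer: rows = data.frame(contig, pos, ref, alt, gt...) where
# gt columns are named by sample
writeTempVcf <- function(rows, samples, path = tempfile(fileext = ".vcf"),
                         contigLen = 100000L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ctg in unique(rows$contig))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ctg, contigLen), con)
  writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  for (i in seq_len(nrow(rows))) {
    gts <- vapply(samples, function(s) as.character(rows[[s]][i]),
                  character(1))
    writeLines(paste(c(rows$contig[i], rows$pos[i], ".", rows$ref[i],
                       rows$alt[i], ".", "PASS", ".", "GT", gts),
                     collapse = "\t"), con)
  }
  path
}

# random string free of a motif (and its reverse complement)
randSeqNoSite <- function(n, site) {
  for (k in 1:200) {
    s <- randSeq(n)
    if (!grepl(site, s, fixed = TRUE) &&
        !grepl(revcompChr(site), s, fixed = TRUE)) return(s)
  }
  stop("could not build a site-free sequence")
}

# random A/C/G/T string
randSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcompChr <- function(x) {
  vapply(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x),
                  "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# --- independent oracles ------------------------------------------------

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# expand an IUPAC motif into every concrete sequence it denotes
iupacExpand <- function(site) {
  sets <- IUPAC_SETS[strsplit(site, "", fixed = TRUE)[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# brute-force restriction scan: expand both strands' motifs and run fixed
# string search for each expansion
oracleScanSites <- function(seq, site) {
  pats <- unique(c(iupacExpand(site), iupacExpand(revcompChr(site))))
  hits <- integer(0)
  for (p in pats) {
    # lookahead so overlapping occurrences are all reported
    m <- gregexpr(paste0("(?=", p, ")"), seq, perl = TRUE)[[1]]
    if (m[1] != -1L) hits <- c(hits, as.integer(m) - 1L)
  }
  sort(unique(hits))
}

# brute-force allele-pair grouping: directly test every allele pair
oracleGroupAuto <- function(site) {
  a1 <- site$gt[1, ]
  a2 <- site$gt[2, ]
  hom <- ifelse(!is.na(a1) & !is.na(a2) & a1 == a2, a1, NA_integer_)
  names(hom) <- colnames(site$gt)
  maxA <- length(site$alleles) - 1L
  out <- list()
  for (i in 0:maxA) for (j in 0:maxA) {
    if (i >= j) next
    gi <- names(hom)[!is.na(hom) & hom == i]
    gj <- names(hom)[!is.na(hom) & hom == j]
    if (length(gi) && length(gj))
      out[[length(out) + 1L]] <- list(groupA = sort(gi), groupB = sort(gj),
                                      alleleA = i, alleleB = j)
  }
  out
}

groupPairToList <- function(gp) {
  list(groupA = sort(gp@groupA), groupB = sort(gp@groupB),
       alleleA = as.integer(gp@alleleA), alleleB = as.integer(gp@alleleB))
}

# exhaustive sliding-window primer binding-site scan implementing the
# 3'-anchored rule directly on character vectors
oracleBindingSites <- function(primer, seqStr, contig = "ctg1",
                               seedLen = 15L, maxMismatch = 2L) {
  n <- nchar(primer)
  pv <- strsplit(primer, "", fixed = TRUE)[[1]]
  rv <- strsplit(revcompChr(primer), "", fixed = TRUE)[[1]]
  sv <- strsplit(seqStr, "", fixed = TRUE)[[1]]
  L <- length(sv)
  out <- list()
  for (s0 in 0:(L - n)) {
    win <- sv[(s0 + 1):(s0 + n)]
    mmF <- win != pv
    if (!any(mmF[(n - seedLen + 1):n]) && sum(mmF) <= maxMismatch)
      out[[length(out) + 1L]] <- data.frame(contig = contig, start0 = s0,
                                            end0 = s0 + n, strand = "+")
    mmR <- win != rv
    if (!any(mmR[1:seedLen]) && sum(mmR) <= maxMismatch)
      out[[length(out) + 1L]] <- data.frame(contig = contig, start0 = s0,
                                            end0 = s0 + n, strand = "-")
  }
  if (!length(out))
    return(data.frame(contig = character(0), start0 = integer(0),
                      end0 = integer(0), strand = character(0)))
  do.call(rbind, out)
}

# facing-pair oracle over two binding-site tables
oracleOffTargets <- function(hitsL, hitsR, targetInterval,
                             maxProduct = 10000L) {
  res <- list()
  combos <- list(list(p = hitsL, m = hitsR), list(p = hitsR, m = hitsL))
  for (cm in combos) {
    p <- cm$p[cm$p$strand == "+", , drop = FALSE]
    m <- cm$m[cm$m$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(p))) for (j in seq_len(nrow(m))) {
      if (p$contig[i] != m$contig[j]) next
      prod <- m$end0[j] - p$start0[i]
      if (prod <= 0L || prod > maxProduct) next
      pOn <- p$contig[i] == targetInterval$contig &&
        p$start0[i] < targetInterval$end0 &&
        p$end0[i] > targetInterval$start0
      mOn <- m$contig[j] == targetInterval$contig &&
        m$start0[j] < targetInterval$end0 &&
        m$end0[j] > targetInterval$start0
      if (pOn && mOn) next   # the intended on-target product
      res[[length(res) + 1L]] <- data.frame(
        contig = p$contig[i], plus_start0 = p$start0[i],
        minus_end0 = m$end0[j], product = prod)
    }
  }
  if (!length(res))
    return(data.frame(contig = character(0), plus_start0 = integer(0),
                      minus_end0 = integer(0), product = integer(0)))
  u <- unique(do.call(rbind, res))
  u[order(u$contig, u$plus_start0, u$minus_end0), , drop = FALSE]
}

# synthetic valid report rows for round-trip tests
randomReportRows <- function(n) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    type <- c("INDEL", "CAPS", "SNP")[1L + (i %% 3L)]
    caps <- type == "CAPS"
    ps <- sample(150:300, 1)
    cut <- sample(40:(ps - 40), 1)
    markerReportRow(
      marker_id = sprintf("m%03d", i), contig = "c1", pos = 1000L + i * 37L,
      type = type, allele_a = "A", allele_b = if (type == "INDEL") "ATTTT"
      else "T",
      left_primer = randSeq(20), right_primer = randSeq(22),
      left_tm = 55 + i / 10, right_tm = 60 - i / 10, product_size = ps,
      enzyme = if (caps) "EcoRI" else "",
      digested_allele = if (caps) "A" else "",
      fragments_a = if (caps) c(cut, ps - cut) else integer(0),
      fragments_b = if (caps) ps else integer(0),
      tag_status = if (type == "SNP") "CS-tagged" else "",
      product_seq = randSeq(ps))
  }))
}
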