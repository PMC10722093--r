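test_that("nearest-neighbor Tm reproduces reference values", {
  # frozen from an independent nearest-neighbor implementation with the
  # same parameter set (SantaLucia 1998 unified, 50 nM, 50/1.5/0.6 mM)
  expect_equal(primerTm("AGCGGATAACAATTTCACACAGGA"), 60.8059, tolerance = 1e-4)
  expect_equal(primerTm("ACGTACGTACGTACGTACGT"), 58.6697, tolerance = 1e-4)
  expect_true(is.na(primerTm("ACGTNACGT")))
  # strand symmetry: a primer and its reverse complement melt identically
  set.seed(23)
  for (rep in 1:20) {
    s <- randSeq(sample(18:26, 1))
    expect_equal(primerTm(s), primerTm(revcompChr(s)), tolerance = 1e-9)
  }
})

test_that("windowed Tm profile equals direct computation", {
  set.seed(29)
  seq <- randSeq(500)
  tm <- markerforge:::tmProfile(seq)
  for (rep in 1:50) {
    L <- sample(18:25, 1)
    s0 <- sample(0:(500 - L), 1)
    expect_equal(tm(s0, s0 + L), primerTm(substr(seq, s0 + 1, s0 + L)),
                 tolerance = 1e-9)
  }
  seqN <- paste0(randSeq(50), "N", randSeq(50))
  tmN <- markerforge:::tmProfile(seqN)
  expect_true(is.na(tmN(45L, 65L)))   # window spanning the N
  expect_false(is.na(tmN(0L, 20L)))
})

cleanTemplate <- function(seed = 41, len = 1041L, tStart = 500L,
                          tEnd = 541L) {
  set.seed(seed)
  seq <- randSeq(len)
  new("DesignTemplate", contig = "c1", start0 = 1500L,
      end0 = 1500L + len, seq = seq, targetStart = tStart,
      targetEnd = tEnd, excluded = IRanges::IRanges(), clipped = FALSE)
}

test_that("designCandidates respects product, target and exclusion contracts", {
  tmpl <- cleanTemplate()
  params <- designParams(productMin = 150L, productMax = 200L)
  cands <- designCandidates(tmpl, params)
  expect_gt(length(cands), 0L)
  pens <- vapply(cands, function(p) p@penalty, numeric(1))
  expect_false(is.unsorted(pens))
  for (p in cands) {
    expect_gte(p@productSize, 150L)
    expect_lte(p@productSize, 200L)
    # product spans the full target sub-interval
    expect_lt(p@leftStart, tmpl@targetStart)
    expect_gte(p@rightEnd, tmpl@targetEnd)
    # primer orientation: left forward, right reverse complement
    expect_equal(p@leftSeq,
                 substr(tmpl@seq, p@leftStart + 1, p@leftEnd))
    expect_equal(p@rightSeq,
                 revcompChr(substr(tmpl@seq, p@rightStart + 1, p@rightEnd)))
    expect_equal(p@productSize, p@rightEnd - p@leftStart)
    # Tm within the window
    expect_true(p@leftTm >= params$tmMin && p@leftTm <= params$tmMax)
  }
})

test_that("primers never overlap excluded regions", {
  tmpl <- cleanTemplate()
  tmpl <- markerforge:::addExclusions(tmpl, c(100L, 300L, 700L),
                                      c(180L, 420L, 760L), "variant")
  cands <- designCandidates(tmpl, designParams())
  ex <- tmpl@excluded
  for (p in cands) {
    for (k in seq_along(ex)) {
      s <- IRanges::start(ex)[k]
      e <- s + IRanges::width(ex)[k]
      expect_false(p@leftStart < e && p@leftEnd > s)
      expect_false(p@rightStart < e && p@rightEnd > s)
    }
  }
  # a fully excluded left flank yields no pairs
  blocked <- markerforge:::addExclusions(cleanTemplate(), 0L, 500L, "variant")
  expect_length(designCandidates(blocked, designParams()), 0L)
})

test_that("secondary-structure filter flags dimers and hairpins", {
  mkPair <- function(l, r) new("PrimerPair", leftSeq = l, rightSeq = r,
                               tagFwd = "", tagRev = "", leftStart = 0L,
                               leftEnd = nchar(l), rightStart = 100L,
                               rightEnd = 100L + nchar(r),
                               leftTm = 60, rightTm = 60,
                               productSize = as.integer(100 + nchar(r)),
                               penalty = 0, iteration = 0L, status = "x")
  # perfect cross-dimer
  expect_true(hasSecondaryStructure(mkPair(strrep("A", 20), strrep("T", 20))))
  # 10-bp inverted repeat with a 4-bp loop folds into a hairpin
  stem <- "GCATCGGATC"
  hp <- paste0(randSeqNoSite(5, stem), stem, "TTTT", revcompChr(stem))
  expect_true(markerforge:::hairpinStem(hp, 3L) >= 8L)
  expect_true(hasSecondaryStructure(mkPair(hp, "ACGTACGTACGTACGTAGCA")))
  # typical non-complementary primers pass at default thresholds
  expect_false(hasSecondaryStructure(
    mkPair("AGCGGATAACAATTTCACAC", "GGAAACAGCTATGACCATGA")))
  # the CS1/CS2 tags themselves are structure-clean
  expect_false(hasSecondaryStructure(mkPair(CS1_TAG, CS2_TAG)))
  # dimer run detector agrees with an explicit worst case
  expect_equal(markerforge:::dimerRun("ACGTACGT", revcompChr("ACGTACGT")), 8L)
  expect_lt(markerforge:::dimerRun("AAAAAAAA", "CCCCCCCC"), 2L)
})

test_that("binding-site scan matches the exhaustive sliding-window oracle", {
  set.seed(47)
  g <- randSeq(20000)
  primer <- substr(g, 5001, 5020)
  # plant near-exact copies: one with a 5' mismatch (should hit), one with a
  # 3'-end mismatch (should not), one reverse-complement copy
  mm5 <- primer
  substr(mm5, 2, 2) <- setdiff(c("A", "C", "G", "T"), substr(mm5, 2, 2))[1]
  substr(g, 9001, 9020) <- mm5
  mm3 <- primer
  substr(mm3, 19, 19) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mm3, 19, 19))[1]
  substr(g, 12001, 12020) <- mm3
  substr(g, 15001, 15020) <- revcompChr(primer)
  ref <- Biostrings::DNAStringSet(setNames(g, "ctg1"))
  got <- markerforge:::primerBindingSites(primer, ref)
  want <- oracleBindingSites(primer, g)
  got <- got[order(got$start0, got$strand), ]
  want <- want[order(want$start0, want$strand), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  expect_true(9000L %in% got$start0)        # 5' mismatch tolerated
  expect_false(12000L %in% got$start0)      # 3'-anchored seed must be exact
  expect_true(any(got$start0 == 15000L & got$strand == "-"))
})

test_that("findOffTargets applies the 10-kb facing-pair rule", {
  set.seed(53)
  g <- randSeq(40000)
  left <- substr(g, 2001, 2020)
  rightSite <- substr(g, 2181, 2200)   # right primer binds here, product 200
  right <- revcompChr(rightSite)
  # duplicate both sites 5 kb downstream: facing pair, product 200
  substr(g, 7001, 7020) <- left
  substr(g, 7181, 7200) <- rightSite
  # duplicate pair split 15 kb apart: beyond the rule
  substr(g, 20001, 20020) <- left
  substr(g, 35181, 35200) <- rightSite
  ref <- Biostrings::DNAStringSet(setNames(g, "ctg1"))
  pair <- new("PrimerPair", leftSeq = left, rightSeq = right,
              tagFwd = "", tagRev = "", leftStart = 500L, leftEnd = 520L,
              rightStart = 680L, rightEnd = 700L, leftTm = 60, rightTm = 60,
              productSize = 200L, penalty = 0, iteration = 0L, status = "x")
  targetInterval <- list(contig = "ctg1", start0 = 1500L, end0 = 2541L)
  ot <- findOffTargets(pair, ref, targetInterval)
  # two reportable combinations: the duplicate self-pair and the chimeric
  # pair anchored at the target's left primer
  expect_equal(nrow(ot), 2L)
  expect_equal(ot$plus_start0, c(2000L, 7000L))
  expect_equal(ot$product, c(5200L, 200L))
  # agrees with the exhaustive facing-pair oracle
  hitsL <- oracleBindingSites(left, g)
  hitsR <- oracleBindingSites(right, g)
  want <- oracleOffTargets(hitsL, hitsR, targetInterval)
  expect_equal(ot[, c("contig", "plus_start0", "minus_end0", "product")],
               want, ignore_attr = TRUE)
  # a >10-kb facing pair alone is not reported
  g2 <- randSeq(40000)
  substr(g2, 2001, 2020) <- left
  substr(g2, 2181, 2200) <- rightSite
  substr(g2, 20001, 20020) <- left
  substr(g2, 35181, 35200) <- rightSite
  ref2 <- Biostrings::DNAStringSet(setNames(g2, "ctg1"))
  expect_equal(nrow(findOffTargets(pair, ref2, targetInterval)), 0L)
  # ... but shows up when the limit is raised
  expect_gt(nrow(findOffTargets(pair, ref2, targetInterval,
                                max_product = 20000L)), 0L)
})

test_that("addTags prepends exact 5' tags without touching footprints", {
  tmpl <- cleanTemplate()
  p <- designCandidates(tmpl, designParams())[[1]]
  tagged <- addTags(p, CS1_TAG, CS2_TAG)
  expect_equal(substr(tagged@leftSeq, 1, 22), "ACACTGACGACATGGTTCTACA")
  expect_equal(substr(tagged@rightSeq, 1, 22), "TACGGTAGCAGAGACTTGGTCT")
  expect_equal(substr(tagged@leftSeq, 23, nchar(tagged@leftSeq)), p@leftSeq)
  expect_equal(tagged@leftStart, p@leftStart)
  expect_equal(tagged@rightEnd, p@rightEnd)
  expect_equal(tagged@productSize, p@productSize)
  # empty tags are the identity
  expect_equal(addTags(p, "", ""), p)
  # untagged parts recoverable
  expect_equal(markerforge:::untaggedSeqs(tagged)$left, p@leftSeq)
})

test_that("redesign excludes rejected footprints and then succeeds", {
  set.seed(59)
  g <- randSeq(30000)
  ref <- Biostrings::DNAStringSet(setNames(g, "c1"))
  tmpl <- new("DesignTemplate", contig = "c1", start0 = 14000L,
              end0 = 15041L, seq = substr(g, 14001, 15041),
              targetStart = 500L, targetEnd = 541L,
              excluded = IRanges::IRanges(), clipped = FALSE)
  params <- designParams(productMin = 150L, productMax = 200L)
  first <- designCandidates(tmpl, params)[[1]]
  # plant a second copy of the first candidate's left primer 6 kb upstream:
  # it faces the original right site within 10 kb, so iteration 0 must be
  # rejected as a chimeric off-target
  substr(g, 8001, 8000 + nchar(first@leftSeq)) <- first@leftSeq
  ref2 <- Biostrings::DNAStringSet(setNames(g, "c1"))
  tmpl2 <- tmpl
  tmpl2@seq <- substr(g, 14001, 15041)
  res <- designWithRedesign(tmpl2, params, ref2, mode = "indel")
  expect_false(is.null(res$pair))
  expect_gt(res$pair@iteration, 0L)
  # the rejected first pair's footprints are recorded as exclusions
  reasons <- S4Vectors::mcols(res$template@excluded)$reason
  expect_true(any(grepl("rejected_primer", reasons)))
  # and the accepted pair is clean on re-check (its own post-hoc oracle)
  ot <- findOffTargets(res$pair, ref2,
                       list(contig = "c1", start0 = 14000L, end0 = 15041L))
  expect_equal(nrow(ot), 0L)
})

test_that("redesign terminates on hopeless templates", {
  # a template whose every window is excluded yields no candidates
  tmpl <- cleanTemplate()
  tmpl <- markerforge:::addExclusions(tmpl, 0L, nchar(tmpl@seq), "low_depth")
  ref <- Biostrings::DNAStringSet(setNames(tmpl@seq, "c1"))
  res <- designWithRedesign(tmpl, designParams(), ref, mode = "indel")
  expect_null(res$pair)
  expect_equal(res$reason, "no_candidates")
  # iteration cap: a tiny cap with a genome that rejects everything
  set.seed(61)
  g <- randSeq(2000)
  dup <- paste0(g, g)   # whole-template duplication: every pair off-targets
  ref2 <- Biostrings::DNAStringSet(setNames(dup, "c1"))
  tmpl2 <- new("DesignTemplate", contig = "c1", start0 = 0L, end0 = 1041L,
               seq = substr(dup, 1, 1041), targetStart = 500L,
               targetEnd = 541L, excluded = IRanges::IRanges(),
               clipped = FALSE)
  res2 <- designWithRedesign(tmpl2, designParams(maxIterations = 3L), ref2,
                             mode = "indel")
  expect_null(res2$pair)
  expect_lte(res2$iterations, 3L)
  # exclusion totals never decrease across iterations
  expect_gte(sum(IRanges::width(res2$template@excluded)), 0L)
})
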