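refFromSeq <- function(seq, name = "c1")
  Biostrings::DNAStringSet(setNames(seq, name))

test_that("extractTarget covers the variant plus 20-bp flanks", {
  set.seed(3)
  g <- randSeq(10000)
  ref <- refFromSeq(g)
  pair <- GroupPair("s1", "s2", 0L, 1L)
  # SNP at 0-based 100 -> interval [80, 121), length 41
  site <- mkSite(pos = 101L, ref = substr(g, 101, 101),
                 alts = "T", gt = c(s1 = "0/0", s2 = "1/1"))
  tg <- extractTarget(ref, site, pair)
  expect_equal(c(tg@start0, tg@end0), c(80L, 121L))
  expect_equal(nchar(realizedSeq(tg, "A")), 41L)
  expect_false(tg@clipped)
  expect_equal(realizedSeq(tg, "A"), substr(g, 81, 121))
  # near the contig edge the flank clips and flags
  edge <- mkSite(pos = 6L, ref = substr(g, 6, 6), alts = "T",
                 gt = c(s1 = "0/0", s2 = "1/1"))
  tgE <- extractTarget(ref, edge, pair)
  expect_equal(tgE@start0, 0L)
  expect_true(tgE@clipped)
  # 4-bp deletion: realized lengths 20+4+20 and 20+1+20
  del <- mkSite(pos = 101L, ref = substr(g, 101, 104),
                alts = substr(g, 101, 101), gt = c(s1 = "0/0", s2 = "1/1"))
  tgD <- extractTarget(ref, del, pair)
  expect_equal(nchar(realizedSeq(tgD, "A")), 44L)
  expect_equal(nchar(realizedSeq(tgD, "B")), 41L)
  # realizations differ only within the allele span
  expect_equal(tgD@up, substr(g, 81, 100))
  expect_equal(tgD@down, substr(g, 105, 124))
})

test_that("screenIndel applies the size window to length differences", {
  expect_true(screenIndel("A", "ATTTT", 3, 50))
  expect_false(screenIndel("A", "AT", 3, 50))
  expect_false(screenIndel("ACG", "TGA", 1, 50))   # substitution, diff 0
  expect_true(screenIndel("A", "ATTT", 3, 3))      # min = max gives exact
  expect_false(screenIndel("A", strrep("AT", 30), 3, 50))
  expect_error(screenIndel("A", "AT", 0, 5))
})

test_that("screenCaps requires strictly differential digestion", {
  enzymes <- loadEnzymes()
  up <- randSeqNoSite(20, "GAATTC")
  down <- randSeqNoSite(20, "GAATTC")
  mk <- function(aA, aB) new("TargetSeq", contig = "c1", start0 = 80L,
                             end0 = 121L, up = up, down = down,
                             alleleA = aA, alleleB = aB, idxA = 0L,
                             idxB = 1L, clipped = FALSE)
  # allele A completes GAATTC across the variant, B does not
  tg <- mk("GAATTC", "GAACTC")
  hits <- screenCaps(tg, enzymes[enzymes$name == "EcoRI", ])
  expect_equal(hits$name, "EcoRI")
  expect_equal(hits$digested_allele, "A")
  # symmetric: swapping alleles swaps the digested label only
  hits2 <- screenCaps(mk("GAACTC", "GAATTC"),
                      enzymes[enzymes$name == "EcoRI", ])
  expect_equal(hits2$name, "EcoRI")
  expect_equal(hits2$digested_allele, "B")
  # both alleles cut -> not differential
  expect_equal(nrow(screenCaps(mk("GAATTC", "GAATTC"),
                               enzymes[enzymes$name == "EcoRI", ])), 0L)
  # empty enzyme table
  expect_equal(nrow(screenCaps(tg, enzymes[0, ])), 0L)
  # reported candidates re-scan clean on the undigested allele
  full <- screenCaps(tg, enzymes)
  for (k in seq_len(nrow(full))) {
    other <- realizedSeq(tg, setdiff(c("A", "B"),
                                     full$digested_allele[k]))
    expect_length(scanSites(other, full[k, ]), 0L)
  }
})

test_that("screenSnp decides on the grouped allele pair, not REF/ALT", {
  expect_true(screenSnp(mkSite(ref = "A", alts = "T"),
                        GroupPair("s1", "s2", 0L, 1L)))
  expect_false(screenSnp(mkSite(ref = "A", alts = "AT"),
                         GroupPair("s1", "s2", 0L, 1L)))
  # multi-allelic grouped on the two single-base ALTs
  tri <- mkSite(ref = "AT", alts = c("C", "G"),
                gt = c(s1 = "1/1", s2 = "2/2"))
  expect_true(screenSnp(tri, GroupPair("s1", "s2", 1L, 2L)))
  expect_false(screenSnp(tri, GroupPair("s1", "s2", 0L, 1L)))
})
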