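setupTemplate <- function(seed = 5, glen = 10000L, pos = 2021L) {
  set.seed(seed)
  g <- randSeq(glen)
  ref <- Biostrings::DNAStringSet(setNames(g, "c1"))
  pair <- GroupPair("s1", "s2", 0L, 1L)
  site <- mkSite(pos = pos, ref = substr(g, pos, pos), alts = "T",
                 gt = c(s1 = "0/0", s2 = "1/1"))
  tg <- extractTarget(ref, site, pair)
  list(g = g, ref = ref, pair = pair, site = site, tg = tg,
       tmpl = buildTemplate(ref, tg))
}

test_that("buildTemplate extends the target by 500 bp and slices the reference", {
  s <- setupTemplate()
  expect_equal(c(s$tg@start0, s$tg@end0), c(2000L, 2041L))
  expect_equal(c(s$tmpl@start0, s$tmpl@end0), c(1500L, 2541L))
  expect_equal(nchar(s$tmpl@seq), 1041L)
  expect_equal(s$tmpl@seq, substr(s$g, 1501, 2541))
  expect_equal(c(s$tmpl@targetStart, s$tmpl@targetEnd), c(500L, 541L))
  expect_false(s$tmpl@clipped)
  # clipping at the contig start flags the template
  e <- setupTemplate(pos = 101L)
  expect_equal(e$tmpl@start0, 0L)
  expect_true(e$tmpl@clipped)
})

test_that("maskVariants excludes segregating neighbors with a 1-bp guard", {
  s <- setupTemplate()
  nearby <- list(
    mkSite(pos = 1531L, ref = substr(s$g, 1531, 1531), alts = "T",
           gt = c(s1 = "0/0", s2 = "1/1")),       # segregates between groups
    mkSite(pos = 1600L, ref = substr(s$g, 1600, 1600), alts = "C",
           gt = c(s1 = "0/0", s2 = "0/0")),       # monomorphic in groups
    mkSite(pos = 1700L, ref = substr(s$g, 1700, 1700), alts = "G",
           gt = c(s1 = "0/1", s2 = "0/0")))       # het counts as polymorphic
  m <- maskVariants(s$tmpl, nearby, s$pair)
  expect_equal(IRanges::start(m@excluded), c(29L, 198L))
  expect_equal(IRanges::width(m@excluded), c(3L, 3L))
  expect_equal(S4Vectors::mcols(m@excluded)$reason, c("variant", "variant"))
  # no neighbors: unchanged
  expect_length(maskVariants(s$tmpl, list(), s$pair)@excluded, 0L)
  # masking is idempotent
  expect_equal(maskVariants(m, nearby, s$pair)@excluded, m@excluded)
})

test_that("maskLowDepth turns sub-threshold runs into exclusions", {
  s <- setupTemplate()
  f <- tempfile()
  # uniform 30 with a zero hole at genomic [1510, 1516) (template [10,16))
  writeLines(c("c1\t1\t10000\t30", "c1\t1511\t1516\t0"), f)
  d <- loadDepth(f)
  m <- maskLowDepth(s$tmpl, d, 5L)
  expect_equal(IRanges::start(m@excluded), 10L)
  expect_equal(IRanges::width(m@excluded), 6L)
  expect_equal(S4Vectors::mcols(m@excluded)$reason, "low_depth")
  # uniform coverage above threshold: nothing
  f2 <- tempfile()
  writeLines("c1\t1\t10000\t30", f2)
  expect_length(maskLowDepth(s$tmpl, loadDepth(f2), 5L)@excluded, 0L)
  # threshold 0 is vacuous
  expect_length(maskLowDepth(s$tmpl, d, 0L)@excluded, 0L)
})

test_that("exclusions stay disjoint, sorted and in bounds after masking", {
  s <- setupTemplate()
  tmpl <- markerforge:::addExclusions(s$tmpl, c(50L, 40L, 900L, -10L),
                                      c(60L, 55L, 2000L, 5L), "variant")
  ex <- tmpl@excluded
  expect_true(all(diff(IRanges::start(ex)) > 0))
  expect_true(all(IRanges::start(ex) >= 0))
  expect_true(all(IRanges::end(ex) < nchar(tmpl@seq)))
  # overlapping input ranges were merged; out-of-bounds input was clipped
  expect_equal(IRanges::start(ex), c(0L, 40L, 900L))
  expect_equal(IRanges::width(ex), c(5L, 20L, 141L))
})

test_that("trimCapsTemplate leaves exactly one recognition site", {
  set.seed(9)
  enzymes <- loadEnzymes()
  ecoRI <- enzymes[enzymes$name == "EcoRI", ]
  # genome free of EcoRI sites, then plant: extra site 200 bp upstream of a
  # target-site SNP, and one 150 bp downstream
  g <- randSeqNoSite(6000, "GAATTC")
  planted <- g
  substr(planted, 2801, 2806) <- "GAATTC"   # extra upstream site
  substr(planted, 3001, 3006) <- "GAATTC"   # target site (variant in it)
  substr(planted, 3151, 3156) <- "GAATTC"   # extra downstream site
  ref <- Biostrings::DNAStringSet(setNames(planted, "c1"))
  pair <- GroupPair("s1", "s2", 0L, 1L)
  site <- mkSite(pos = 3003L, ref = "A", alts = "C",
                 gt = c(s1 = "0/0", s2 = "1/1"))
  tg <- extractTarget(ref, site, pair)
  expect_equal(screenCaps(tg, ecoRI)$digested_allele, "A")
  tmpl <- buildTemplate(ref, tg)
  expect_length(scanSites(realizedSeq(tmpl, tg, "A"), ecoRI), 3L)
  trimmed <- trimCapsTemplate(tmpl, ecoRI, tg, "A")
  # left edge just downstream of the upstream extra site, right edge at the
  # downstream extra site's start
  expect_equal(trimmed@start0, 2806L)
  expect_equal(trimmed@end0, 3150L)
  expect_length(scanSites(realizedSeq(trimmed, tg, "A"), ecoRI), 1L)
  # target sub-interval preserved and in bounds
  expect_equal(trimmed@targetEnd - trimmed@targetStart, 41L)
  expect_equal(slice0(trimmedSeq <- trimmed@seq, trimmed@targetStart,
                      trimmed@targetEnd),
               substr(planted, trimmed@start0 + trimmed@targetStart + 1L,
                      trimmed@start0 + trimmed@targetEnd))
  # no extra sites: unchanged
  g2 <- randSeqNoSite(3000, "GAATTC")
  substr(g2, 1501, 1506) <- "GAATTC"
  ref2 <- Biostrings::DNAStringSet(setNames(g2, "c1"))
  site2 <- mkSite(pos = 1503L, ref = "A", alts = "C",
                  gt = c(s1 = "0/0", s2 = "1/1"))
  tg2 <- extractTarget(ref2, site2, pair)
  tmpl2 <- buildTemplate(ref2, tg2)
  expect_equal(trimCapsTemplate(tmpl2, ecoRI, tg2, "A"), tmpl2)
})

test_that("scan-trim-rescan holds over random extra-site layouts", {
  set.seed(17)
  enzymes <- loadEnzymes()
  ecoRI <- enzymes[enzymes$name == "EcoRI", ]
  pair <- GroupPair("s1", "s2", 0L, 1L)
  for (rep in 1:10) {
    g <- randSeqNoSite(5000, "GAATTC")
    center <- 2500L
    substr(g, center + 1L, center + 6L) <- "GAATTC"
    extras <- sample(c(0:2), 2, replace = TRUE)   # per side
    offs <- c(-sample(60:450, extras[1]), sample(60:450, extras[2]))
    for (o in offs) substr(g, center + o + 1L, center + o + 6L) <- "GAATTC"
    ref <- Biostrings::DNAStringSet(setNames(g, "c1"))
    site <- mkSite(pos = center + 3L, ref = "A", alts = "C",
                   gt = c(s1 = "0/0", s2 = "1/1"))
    if (substr(g, center + 3L, center + 3L) != "A") next
    tg <- extractTarget(ref, site, pair)
    if (nrow(screenCaps(tg, ecoRI)) != 1L) next  # overlapping plants
    trimmed <- trimCapsTemplate(buildTemplate(ref, tg), ecoRI, tg, "A")
    expect_false(is.null(trimmed))
    expect_length(scanSites(realizedSeq(trimmed, tg, "A"), ecoRI), 1L)
  }
})
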