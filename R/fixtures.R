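# All fixture randomness flows from one seed; the global RNG state is
# restored on exit so fixture generation never perturbs a caller's stream.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic reference genome
#'
#' Random i.i.d. nucleotide sequence at a chosen GC fraction, reproducible
#' for a fixed seed. Exact duplication blocks can be planted (for off-target
#' scenarios) by copying a source interval over a destination interval.
#'
#' @param n_contigs number of contigs (named `ctg1`, `ctg2`, ...).
#' @param length contig length in bp (recycled across contigs).
#' @param gc GC fraction.
#' @param seed integer seed.
#' @param duplications optional list of `list(contig, src_start0, length,
#'   dest_start0)` entries; each copies `length` bp from `src_start0` over
#'   `dest_start0` (0-based) on `contig`.
#' @param fasta optional path; when given the genome is also written as
#'   FASTA.
#' @return a [Biostrings::DNAStringSet]; planted duplications are recorded
#'   in `metadata(x)$duplications`.
#' @export
makeGenome <- function(n_contigs = 1L, length = 200000L, gc = 0.5, seed = 1L,
                       duplications = NULL, fasta = NULL) {
  stopifnot(length >= 2000L)
  seqs <- withSeed(seed, {
    lens <- rep_len(as.integer(length), n_contigs)
    lapply(lens, function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    })
  })
  names(seqs) <- paste0("ctg", seq_len(n_contigs))
  for (d in duplications) {
    ctg <- d$contig %||% "ctg1"
    block <- slice0(seqs[[ctg]], d$src_start0, d$src_start0 + d$length)
    substr(seqs[[ctg]], d$dest_start0 + 1L, d$dest_start0 + d$length) <- block
  }
  ref <- Biostrings::DNAStringSet(unlist(seqs))
  S4Vectors::metadata(ref)$duplications <- duplications
  if (!is.null(fasta)) Biostrings::writeXStringSet(ref, fasta)
  ref
}

# genotype columns for a pattern over the sample list
patternGT <- function(pattern, samples) {
  n <- length(samples)
  half <- ceiling(n / 2)
  switch(pattern,
    split = c(rep("0/0", half), rep("1/1", n - half)),
    monomorphic = rep("0/0", n),
    het = rep("0/1", n),
    stop("unknown genotype pattern: ", pattern))
}

# build an in-memory site record for truth screening
syntheticSite <- function(contig, pos1, ref, alt, gtStrings, samples) {
  parts <- strsplit(gtStrings, "[/|]")
  toIdx <- function(k) vapply(parts, function(p) {
    v <- p[min(k, length(p))]
    if (v == ".") NA_integer_ else as.integer(v)
  }, integer(1))
  gt <- rbind(toIdx(1), toIdx(2))
  colnames(gt) <- samples
  list(contig = contig, pos = pos1, pos0 = pos1 - 1L, ref = ref,
       alts = alt, alleles = c(ref, alt), gt = gt)
}

#' Plant variants into a synthetic genome and emit a VCF plus truth table
#'
#' Executes a planting plan: SNPs (optionally engineered so that the
#' reference allele carries a restriction site the alternate destroys),
#' insertions and deletions, each with a genotype pattern over the samples
#' (`split` = first half homozygous REF, second half homozygous ALT;
#' `monomorphic`; `het`). The reference may be edited (site engineering), so
#' the returned genome must be used downstream. The truth table records, per
#' locus, whether each marker type should recover it under the stated
#' settings, computed from the planting construction plus the package's own
#' screening rules (grouping, InDel size window, differential digestion).
#' CAPS recoverability additionally requires that the unique-cut-site trim
#' succeeds and that the trimmed template still admits a candidate pair
#' under the design windows — frequent cutters can trim the template below
#' the product-size window.
#'
#' @param ref genome from [makeGenome()].
#' @param plan `data.frame` with columns `type` (`snp`/`ins`/`del`),
#'   `pattern` (`split`/`monomorphic`/`het`), `enzyme` (enzyme name to
#'   engineer a CAPS site, or `""`), `len` (indel length, 0 for SNPs), and
#'   optionally `neutral` (logical: force the SNP to create no differential
#'   enzyme site).
#' @param samples character vector of sample names.
#' @param seed integer seed.
#' @param vcf output VCF path.
#' @param enzymes enzyme table used for truth screening.
#' @param params [designParams()] assumed by the truth table's CAPS
#'   feasibility check (see Details).
#' @param indel_window InDel size window assumed by the truth table.
#' @param margin,spacing first-locus offset and inter-locus spacing, bp
#'   (used when `positions` is not given).
#' @param positions optional explicit 0-based positions, one per plan row.
#' @return list with `ref` (edited genome), `vcf` (path) and `truth`
#'   (`data.frame`: `id`, `contig`, `pos`, `type`, `pattern`, `ref`, `alt`,
#'   `enzyme`, `indel_ok`, `caps_ok`, `snp_ok`, `note`).
#' @export
plantVariants <- function(ref, plan, samples = paste0("s", 1:4), seed = 1L,
                          vcf, enzymes = loadEnzymes(),
                          params = designParams(),
                          indel_window = c(3L, 50L),
                          margin = 1000L, spacing = 6000L,
                          positions = NULL) {
  n <- nrow(plan)
  contig <- names(ref)[1]
  clen <- Biostrings::width(ref)[1]
  if (is.null(positions))
    positions <- margin + (seq_len(n) - 1L) * spacing
  stopifnot(length(positions) == n)
  if (any(positions > clen - margin))
    stop("genome too short for ", n, " loci at spacing ", spacing)
  if (n > 1L && any(diff(positions) < 60L))
    stop("overlapping plantings: positions must be ascending and at least ",
         "60 bp apart")
  seqStr <- as.character(ref[[contig]])
  rows <- vector("list", n)

  truth <- withSeed(seed, {
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n)) {
      p <- plan[i, ]
      pos0 <- positions[i]
      refAllele <- altAllele <- NA_character_
      if (p$type == "snp" && nzchar(p$enzyme)) {
        enz <- enzymes[enzymes$name == p$enzyme, ]
        if (nrow(enz) != 1L) stop("unknown enzyme: ", p$enzyme)
        eng <- engineerCapsSite(seqStr, pos0, enz)
        seqStr <- eng$seq
        pos0 <- eng$pos0
        refAllele <- eng$ref
        altAllele <- eng$alt
      } else if (p$type == "snp") {
        refAllele <- substr(seqStr, pos0 + 1L, pos0 + 1L)
        altChoices <- setdiff(bases, refAllele)
        altAllele <- altChoices[1]
        if (isTRUE(p$neutral)) {
          # force: no enzyme discriminates the two realized alleles
          for (b in altChoices) {
            cand <- snpTruthSite(seqStr, contig, pos0, refAllele, b,
                                 p$pattern, samples)
            pr <- groupAuto(cand)
            if (!length(pr)) { altAllele <- b; break }
            tg <- extractTarget(dnaSS(seqStr, contig), cand, pr[[1]])
            if (nrow(screenCaps(tg, enzymes)) == 0L) { altAllele <- b; break }
          }
        }
      } else if (p$type == "del") {
        refAllele <- substr(seqStr, pos0 + 1L, pos0 + 1L + p$len)
        altAllele <- substr(refAllele, 1L, 1L)
      } else if (p$type == "ins") {
        refAllele <- substr(seqStr, pos0 + 1L, pos0 + 1L)
        altAllele <- paste0(refAllele,
                            paste(sample(bases, p$len, replace = TRUE),
                                  collapse = ""))
      } else stop("unknown planting type: ", p$type)

      gt <- patternGT(p$pattern, samples)
      site <- syntheticSite(contig, pos0 + 1L, refAllele, altAllele, gt,
                            samples)
      pairs <- groupAuto(site)
      grouped <- length(pairs) > 0L
      capsOk <- FALSE
      capsEnzyme <- ""
      indelOk <- FALSE
      snpOk <- FALSE
      if (grouped) {
        pr <- pairs[[1]]
        tg <- extractTarget(dnaSS(seqStr, contig), site, pr)
        hits <- screenCaps(tg, enzymes)
        capsOk <- nrow(hits) > 0L
        if (capsOk) {
          capsEnzyme <- hits$name[1]
          # a frequent cutter can force the unique-cut-site trim to shrink
          # the template below what the product-size window needs; mirror
          # the trim and check that the geometric/thermodynamic constraints
          # still admit a candidate pair
          genomeSS <- dnaSS(seqStr, contig)
          tmpl <- trimCapsTemplate(buildTemplate(genomeSS, tg),
                                   hits[1, ], tg, hits$digested_allele[1])
          capsOk <- !is.null(tmpl) &&
            length(designCandidates(tmpl, params)) > 0L
          if (!capsOk) capsEnzyme <- ""
        }
        indelOk <- screenIndel(tg@alleleA, tg@alleleB,
                               indel_window[1], indel_window[2])
        snpOk <- screenSnp(site, pr)
      }
      rows[[i]] <- data.frame(
        id = sprintf("L%02d", i), contig = contig, pos = pos0 + 1L,
        type = p$type, pattern = p$pattern, ref = refAllele,
        alt = altAllele, enzyme = capsEnzyme, indel_ok = indelOk,
        caps_ok = capsOk, snp_ok = snpOk, note = "",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })

  refOut <- Biostrings::DNAStringSet(stats::setNames(seqStr, contig))
  writeFixtureVcf(vcf, contig, clen, truth, samples,
                  vapply(seq_len(n), function(i)
                    paste(patternGT(plan$pattern[i], samples),
                          collapse = "\t"), character(1)))
  list(ref = refOut, vcf = vcf, truth = truth)
}

dnaSS <- function(seqStr, contig)
  Biostrings::DNAStringSet(stats::setNames(seqStr, contig))

# embed enzyme recognition site at pos0 and pick the SNP that destroys it:
# returns edited sequence, variant pos0, ref base (site base) and alt base.
# Retries at small shifts until the reference-realized target carries
# exactly one site and the alternate-realized target none.
engineerCapsSite <- function(seqStr, pos0, enz) {
  siteLen <- nchar(enz$site)
  stopifnot(grepl("^[ACGT]+$", enz$site))  # engineering needs a concrete site
  for (shift in seq(0L, 300L, by = 60L)) {
    p0 <- pos0 + shift
    cand <- seqStr
    substr(cand, p0 + 1L, p0 + siteLen) <- enz$site
    for (off in seq_len(siteLen) - 1L) {
      refBase <- substr(enz$site, off + 1L, off + 1L)
      for (b in setdiff(c("A", "C", "G", "T"), refBase)) {
        v0 <- p0 + off
        up <- slice0(cand, v0 - 20L, v0)
        down <- slice0(cand, v0 + 1L, v0 + 21L)
        refTarget <- paste0(up, refBase, down)
        altTarget <- paste0(up, b, down)
        if (length(scanSites(refTarget, enz)) == 1L &&
            length(scanSites(altTarget, enz)) == 0L)
          return(list(seq = cand, pos0 = v0, ref = refBase, alt = b))
      }
    }
  }
  stop("could not engineer a clean CAPS site near position ", pos0)
}

snpTruthSite <- function(seqStr, contig, pos0, refAllele, altAllele,
                         pattern, samples) {
  syntheticSite(contig, pos0 + 1L, refAllele, altAllele,
                patternGT(pattern, samples), samples)
}

writeFixtureVcf <- function(path, contig, clen, truth, samples, gtLines) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, clen),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  truth$contig, truth$pos, truth$id, truth$ref, truth$alt,
                  gtLines)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a uniform depth track with zero-depth holes
#'
#' @param ref the genome (for contig names and lengths).
#' @param base_depth depth everywhere outside the holes.
#' @param holes list of `list(contig, start0, end0)` zero-depth intervals
#'   (0-based half-open).
#' @param path output TSV path
#'   (`contig<TAB>start1<TAB>end1<TAB>depth` dialect).
#' @return invisibly, the path.
#' @export
makeDepth <- function(ref, base_depth = 30L, holes = list(), path) {
  lines <- sprintf("%s\t1\t%d\t%d", names(ref), Biostrings::width(ref),
                   base_depth)
  for (h in holes)
    lines <- c(lines, sprintf("%s\t%d\t%d\t0", h$contig %||% names(ref)[1],
                              h$start0 + 1L, h$end0))
  writeLines(lines, path)
  invisible(path)
}

#' Standard mixed fixture: 30 planted loci on a 200-kb genome
#'
#' Generates the package's reference study fixture: a seeded 200-kb contig
#' carrying 10 planted InDel loci (7 recoverable in a 3-50 bp window, 3
#' not), 10 CAPS loci (7 engineered restriction-site SNPs, 3 not
#' recoverable) and 10 SNP loci (7 clean homozygous splits; a monomorphic
#' site, an all-heterozygous site, and a split SNP buried in a zero-depth
#' hole), plus a uniform depth-30 track with the hole. Truth flags reflect
#' recoverability when the pipeline runs with the depth track and a minimum
#' depth of 5.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return list with paths `fasta`, `vcf`, `depth`, `truth_path`, the truth
#'   `data.frame`, and the edited genome `ref`.
#' @export
fixtureMixed <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plan <- data.frame(
    type = c(rep("del", 4), rep("ins", 3), "del", "ins", "del",
             rep("snp", 10),
             rep("snp", 10)),
    pattern = c(rep("split", 7), "split", "split", "monomorphic",
                rep("split", 7), "het", "monomorphic", "split",
                rep("split", 7), "monomorphic", "het", "split"),
    enzyme = c(rep("", 10),
               "EcoRI", "BamHI", "HindIII", "EcoRV", "XbaI", "PstI", "SalI",
               "HindIII", "", "",
               rep("", 10)),
    len = c(4L, 5L, 6L, 10L, 8L, 12L, 15L, 1L, 2L, 5L,
            rep(0L, 20)),
    neutral = c(rep(FALSE, 10),
                rep(FALSE, 8), TRUE, FALSE,
                rep(TRUE, 10)),
    stringsAsFactors = FALSE)

  genome <- makeGenome(1L, 200000L, gc = 0.5, seed = seed)
  vcfPath <- file.path(dir, "variants.vcf")
  planted <- plantVariants(genome, plan, samples = paste0("s", 1:4),
                           seed = seed + 1L, vcf = vcfPath)
  truth <- planted$truth

  # the last SNP locus sits in a zero-depth hole: unrecoverable in every
  # mode once depth masking (min depth 5) is active
  holeLocus <- nrow(truth)
  holePos0 <- truth$pos[holeLocus] - 1L
  holes <- list(list(contig = truth$contig[holeLocus],
                     start0 = holePos0 - 700L, end0 = holePos0 + 700L))
  truth$indel_ok[holeLocus] <- FALSE
  truth$caps_ok[holeLocus] <- FALSE
  truth$snp_ok[holeLocus] <- FALSE
  truth$note[holeLocus] <- "low_depth"

  fastaPath <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(planted$ref, fastaPath)
  depthPath <- file.path(dir, "depth.tsv")
  makeDepth(planted$ref, base_depth = 30L, holes = holes, path = depthPath)
  truthPath <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fastaPath, vcf = vcfPath, depth = depthPath,
       truth_path = truthPath, truth = truth, ref = planted$ref)
}
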