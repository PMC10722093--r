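#' Assemble a validated pipeline configuration
#'
#' Collects and checks every knob of the marker-design pipeline. Either
#' auto-grouping (default) or one user-specified group pair may be active.
#'
#' @param vcf,ref paths to the multi-sample VCF and the reference FASTA it
#'   was called against.
#' @param out output report path (TSV); a run-summary JSON and a config
#'   sidecar JSON are written next to it.
#' @param marker_type `"indel"`, `"caps"` or `"snp"`.
#' @param samples samples to analyze (`NULL` = all in the VCF header).
#' @param group_a,group_b user-specified groups (both `NULL` = auto-group).
#' @param depth optional depth source: BAM path(s) or a depth TSV.
#' @param min_depth depth threshold for masking (active only with `depth`).
#' @param indel_min,indel_max InDel allele-length-difference window, bp.
#' @param enzymes enzyme table for CAPS mode (see [loadEnzymes()]).
#' @param target_flank,template_flank target and template flank widths, bp
#'   (20 and 500 by default).
#' @param params a [designParams()] list.
#' @param tag_fwd,tag_rev 5' tags for SNP mode ([CS1_TAG]/[CS2_TAG]
#'   defaults; set both `""` to disable tagging).
#' @param max_product off-target facing-pair span limit, bp.
#' @return a validated config list of class `MarkerConfig`.
#' @export
markerConfig <- function(vcf, ref, out,
                         marker_type = c("indel", "caps", "snp"),
                         samples = NULL, group_a = NULL, group_b = NULL,
                         depth = NULL, min_depth = 0L,
                         indel_min = 3L, indel_max = 50L,
                         enzymes = loadEnzymes(),
                         target_flank = 20L, template_flank = 500L,
                         params = designParams(),
                         tag_fwd = CS1_TAG, tag_rev = CS2_TAG,
                         max_product = 10000L) {
  marker_type <- match.arg(marker_type)
  if (xor(is.null(group_a), is.null(group_b)))
    stop("give both --group-a and --group-b, or neither (auto-group)")
  if (!file.exists(vcf)) stop("VCF not found: ", vcf)
  if (!file.exists(ref)) stop("reference FASTA not found: ", ref)
  if (!is.null(depth) && !all(file.exists(depth)))
    stop("depth source not found: ", depth)
  if (min_depth < 0L) stop("min_depth must be >= 0")
  if (indel_min < 1L || indel_max < indel_min)
    stop("bad InDel size window [", indel_min, ", ", indel_max, "]")
  structure(list(vcf = vcf, ref = ref, out = out,
                 marker_type = marker_type, samples = samples,
                 group_a = group_a, group_b = group_b, depth = depth,
                 min_depth = as.integer(min_depth),
                 indel_min = as.integer(indel_min),
                 indel_max = as.integer(indel_max), enzymes = enzymes,
                 target_flank = as.integer(target_flank),
                 template_flank = as.integer(template_flank),
                 params = params, tag_fwd = tag_fwd, tag_rev = tag_rev,
                 max_product = as.integer(max_product)),
            class = "MarkerConfig")
}

#' Run the marker-design pipeline
#'
#' Streams variants through grouping, marker-type screening, template
#' construction with exclusion masking, CAPS template trimming, the
#' iterative design loop with specificity and structure checks, SNP
#' tagging, and report writing. The run is deterministic: identical inputs
#' and config produce byte-identical reports.
#'
#' @param config a [markerConfig()] list.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the report `data.frame` (`report`), the
#'   per-stage `counters`, and output `paths`. Stage counters satisfy
#'   `designed + rejected + exhausted = screened_in`.
#' @export
runPipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "MarkerConfig"))
  say <- function(...) if (!quiet) message(...)
  ref <- loadReference(config$ref)
  vs <- suppressWarnings(readVariants(config$vcf, config$samples))
  track <- if (!is.null(config$depth)) loadDepth(config$depth) else NULL
  say("loaded ", length(vs), " variant site(s), ",
      length(sampleNames(vs)), " sample(s)")

  counters <- c(sites_seen = length(vs), grouped = 0L, screened_in = 0L,
                designed = 0L, rejected = 0L, exhausted = 0L)
  rows <- list()

  for (i in seq_len(length(vs))) {
    site <- variantSite(vs, i)
    pairs <- if (!is.null(config$group_a))
      Filter(Negate(is.null),
             list(groupUser(site, config$group_a, config$group_b)))
    else groupAuto(site)
    if (!length(pairs)) next
    counters["grouped"] <- counters["grouped"] + 1L

    for (pair in pairs) {
      target <- extractTarget(ref, site, pair, config$target_flank)
      enzyme <- NULL
      digested <- ""
      if (config$marker_type == "indel") {
        if (!screenIndel(target@alleleA, target@alleleB,
                         config$indel_min, config$indel_max)) next
      } else if (config$marker_type == "caps") {
        hits <- screenCaps(target, config$enzymes)
        if (!nrow(hits)) next
        enzyme <- hits[1, ]
        digested <- enzyme$digested_allele
      } else {
        if (!screenSnp(site, pair)) next
      }
      counters["screened_in"] <- counters["screened_in"] + 1L

      tmpl <- buildTemplate(ref, target, config$template_flank)
      nearby <- lapply(sitesInWindow(vs, tmpl@contig, tmpl@start0,
                                     tmpl@end0, not = i),
                       function(k) variantSite(vs, k))
      tmpl <- maskVariants(tmpl, nearby, pair)
      if (!is.null(track) && config$min_depth > 0L)
        tmpl <- maskLowDepth(tmpl, track, config$min_depth)
      if (config$marker_type == "caps") {
        tmpl <- trimCapsTemplate(tmpl, enzyme, target, digested)
        if (is.null(tmpl)) {
          counters["rejected"] <- counters["rejected"] + 1L
          next
        }
      }

      res <- designWithRedesign(tmpl, config$params, ref,
                                mode = config$marker_type,
                                tag_fwd = config$tag_fwd,
                                tag_rev = config$tag_rev,
                                max_product = config$max_product)
      if (is.null(res$pair)) {
        counters["exhausted"] <- counters["exhausted"] + 1L
        say(site$contig, ":", site$pos, " design exhausted (", res$reason, ")")
        next
      }
      counters["designed"] <- counters["designed"] + 1L
      rows[[length(rows) + 1L]] <-
        assembleRow(site, pair, target, tmpl, res$pair, config,
                    enzyme, digested)
    }
  }

  report <- if (length(rows)) do.call(rbind, rows) else
    utils::read.table(text = paste(REPORT_COLUMNS, collapse = "\t"),
                      header = TRUE, sep = "\t",
                      colClasses = "character")
  writeMarkerReport(report, config$out)
  writeRunSidecars(config, counters, nrow(report))
  say("done: ", nrow(report), " marker(s) -> ", config$out)
  invisible(list(report = report, counters = counters,
                 paths = c(report = config$out)))
}

# build one report row from an accepted design
assembleRow <- function(site, pair, target, tmpl, primer, config,
                        enzyme, digested) {
  prodRef <- slice0(tmpl@seq, primer@leftStart, primer@rightEnd)
  typeLabel <- c(indel = "INDEL", caps = "CAPS",
                 snp = "SNP")[config$marker_type]
  fragsA <- integer(0)
  fragsB <- integer(0)
  if (config$marker_type == "caps") {
    prodA <- realizedProduct(tmpl, target, primer, "A")
    prodB <- realizedProduct(tmpl, target, primer, "B")
    fragsA <- predictFragments(prodA, enzyme)
    fragsB <- predictFragments(prodB, enzyme)
  }
  tagStatus <- if (config$marker_type == "snp" &&
                   (nzchar(config$tag_fwd) || nzchar(config$tag_rev)))
    "CS-tagged" else ""
  markerReportRow(
    marker_id = sprintf("%s_%d_%s", site$contig, site$pos, typeLabel),
    contig = site$contig, pos = site$pos, type = typeLabel,
    allele_a = target@alleleA, allele_b = target@alleleB,
    left_primer = primer@leftSeq, right_primer = primer@rightSeq,
    left_tm = primer@leftTm, right_tm = primer@rightTm,
    product_size = primer@productSize,
    enzyme = if (is.null(enzyme)) "" else enzyme$name,
    digested_allele = digested,
    fragments_a = fragsA, fragments_b = fragsB,
    tag_status = tagStatus, product_seq = prodRef)
}

# allele-realized amplicon for fragment prediction
realizedProduct <- function(tmpl, target, primer, allele) {
  vStart <- tmpl@targetStart + nchar(target@up)
  vEnd <- tmpl@targetEnd - nchar(target@down)
  alleleSeq <- if (allele == "A") target@alleleA else target@alleleB
  paste0(slice0(tmpl@seq, primer@leftStart, vStart),
         alleleSeq,
         slice0(tmpl@seq, vEnd, primer@rightEnd))
}

writeRunSidecars <- function(config, counters, n_rows) {
  base <- tools::file_path_sans_ext(config$out)
  cfg <- config
  cfg$enzymes <- NULL
  cfg$params <- unclass(cfg$params)
  jsonlite::write_json(unclass(cfg), paste0(base, ".config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  jsonlite::write_json(c(as.list(counters), list(markers_reported = n_rows)),
                       paste0(base, ".summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
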