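#' Load a read-depth track
#'
#' Builds a [DepthTrack-class] from either one or more indexed BAM files or a
#' depth TSV. BAM depth is computed by pileup; when several BAM files are
#' given the track is pooled as the per-position minimum across files — the
#' conservative choice when the track is later used to mask low-depth
#' regions. The TSV dialect is `contig<TAB>start(1-based)<TAB>end(inclusive)
#' <TAB>depth`, one interval per line, `#` comments allowed.
#'
#' @param path path(s): `.bam` files (each needs a `.bai` index) or a single
#'   depth TSV.
#' @return a [DepthTrack-class]; positions absent from the input have
#'   depth 0.
#' @export
loadDepth <- function(path) {
  if (all(grepl("\\.bam$", path, ignore.case = TRUE))) {
    tracks <- lapply(path, loadDepthBam)
    return(poolMin(tracks))
  }
  if (length(path) != 1L)
    stop("give either BAM file(s) or a single depth TSV")
  loadDepthTsv(path)
}

loadDepthTsv <- function(path) {
  if (!file.exists(path)) stop("depth file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  cov <- list()
  maxEnd <- integer(0)
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L)
      stop("malformed depth line ", i, ": expected 4 tab-separated fields")
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    d <- suppressWarnings(as.integer(f[4]))
    if (anyNA(c(s, e, d)) || s < 1L || e < s || d < 0L)
      stop("malformed depth line ", i, ": bad interval or depth")
    rows[[k]] <- list(contig = f[1], s = s, e = e, d = d)
  }
  for (r in rows) {
    end <- maxEnd[r$contig]
    maxEnd[r$contig] <- max(r$e, if (is.na(end)) 0L else end)
  }
  vecs <- lapply(maxEnd, function(n) integer(n))
  for (r in rows) vecs[[r$contig]][r$s:r$e] <- r$d
  new("DepthTrack", cov = lapply(vecs, S4Vectors::Rle))
}

loadDepthBam <- function(path) {
  if (!file.exists(path)) stop("BAM not found: ", path)
  bai <- paste0(path, ".bai")
  bai2 <- sub("\\.bam$", ".bai", path, ignore.case = TRUE)
  if (!file.exists(bai) && !file.exists(bai2))
    stop("BAM is not indexed (no .bai found): ", path)
  p <- Rsamtools::pileup(path,
    scanBamParam = Rsamtools::ScanBamParam(),
    pileupParam = Rsamtools::PileupParam(max_depth = 100000L,
      min_base_quality = 0L, min_mapq = 0L, min_nucleotide_depth = 1L,
      distinguish_strands = FALSE, distinguish_nucleotides = FALSE))
  cov <- list()
  for (ctg in unique(as.character(p$seqnames))) {
    sub <- p[p$seqnames == ctg, ]
    v <- integer(max(sub$pos))
    v[sub$pos] <- sub$count
    cov[[ctg]] <- S4Vectors::Rle(v)
  }
  new("DepthTrack", cov = cov)
}

# per-position minimum across tracks (union of contigs; absent contig = 0)
poolMin <- function(tracks) {
  if (length(tracks) == 1L) return(tracks[[1]])
  contigs <- unique(unlist(lapply(tracks, function(t) names(t@cov))))
  cov <- list()
  for (ctg in contigs) {
    vs <- lapply(tracks, function(t) {
      v <- t@cov[[ctg]]
      if (is.null(v)) S4Vectors::Rle(integer(0)) else v
    })
    n <- max(vapply(vs, length, integer(1)))
    padded <- lapply(vs, function(v)
      c(as.integer(v), integer(n - length(v))))
    cov[[ctg]] <- S4Vectors::Rle(do.call(pmin, padded))
  }
  new("DepthTrack", cov = cov)
}

#' @describeIn depthAt depth lookup on a `DepthTrack`; 0 outside the track.
#' @export
setMethod("depthAt", "DepthTrack", function(x, contig, pos0) {
  v <- x@cov[[contig]]
  out <- integer(length(pos0))
  if (is.null(v)) return(out)
  inb <- pos0 >= 0L & pos0 < length(v)
  out[inb] <- as.integer(v[pos0[inb] + 1L])
  out
})

# depth vector over [start0, end0) of one contig, 0-padded beyond the track
depthVector <- function(track, contig, start0, end0) {
  depthAt(track, contig, seq.int(start0, end0 - 1L))
}
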