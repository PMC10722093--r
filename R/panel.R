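#' Filter marker rows for a multiplex amplicon panel
#'
#' Keeps rows whose amplicon GC content and product size fall inside the
#' given windows. GC is computed over the full predicted amplicon (primers
#' included, 5' tags excluded), i.e. the `product_seq` column. With
#' `require_homozygosity` the two grouped alleles must be defined and
#' distinct (grouping already guarantees every reported row derives from
#' samples fixed for each allele, so this drops only malformed rows).
#' Row order is preserved; the filter is idempotent.
#'
#' @param rows marker report `data.frame`.
#' @param gc_min,gc_max amplicon GC window, percent (defaults 40-60).
#' @param size_min,size_max product size window, bp (defaults 150-175).
#' @param require_homozygosity logical flag.
#' @return the filtered `data.frame`.
#' @export
filterPanel <- function(rows, gc_min = 40, gc_max = 60,
                        size_min = 150L, size_max = 175L,
                        require_homozygosity = TRUE) {
  if (!nrow(rows)) return(rows)
  gc <- gcPercent(rows$product_seq)
  keep <- !is.na(gc) & gc >= gc_min & gc <= gc_max &
    rows$product_size >= size_min & rows$product_size <= size_max
  if (require_homozygosity)
    keep <- keep & nzchar(rows$allele_a) & nzchar(rows$allele_b) &
      rows$allele_a != rows$allele_b
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Thin markers to a minimum genomic spacing
#'
#' Greedy left-to-right selection per contig: keep the first marker, then
#' the next marker at least `interval` bp downstream of the last kept one,
#' and so on. Rows must be sorted by contig then position.
#'
#' @param rows marker report `data.frame`, sorted by contig and position.
#' @param interval minimum spacing in bp (e.g. `2e6` for ~2-Mb panels);
#'   0 keeps everything.
#' @return the selected rows.
#' @export
spaceMarkers <- function(rows, interval) {
  if (!nrow(rows) || interval <= 0) return(rows)
  keep <- logical(nrow(rows))
  lastPos <- NULL
  lastContig <- NULL
  for (i in seq_len(nrow(rows))) {
    if (is.null(lastContig) || rows$contig[i] != lastContig ||
        rows$pos[i] - lastPos >= interval) {
      keep[i] <- TRUE
      lastContig <- rows$contig[i]
      lastPos <- rows$pos[i]
    }
  }
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
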