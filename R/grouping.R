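# Homozygous allele index per sample: the common allele when both calls
# agree and are present, else NA (heterozygous or missing).
homAlleles <- function(site) {
  a1 <- site$gt[1, ]
  a2 <- site$gt[2, ]
  ifelse(!is.na(a1) & !is.na(a2) & a1 == a2, a1, NA_integer_)
}

#' Group samples by a user-specified split
#'
#' Tests whether the two user-claimed sample sets are fixed for distinct
#' alleles at a site: every member of `groupA` homozygous for one allele,
#' every member of `groupB` homozygous for a different allele, and no member
#' heterozygous or missing (a user-claimed sample with an unusable genotype
#' vetoes the site).
#'
#' @param site a variant site record (see [variantSite()]).
#' @param groupA,groupB disjoint, non-empty character vectors of sample
#'   names present at the site.
#' @return a [GroupPair-class], or `NULL` when the split is not fixed.
#' @export
groupUser <- function(site, groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  absent <- setdiff(c(groupA, groupB), colnames(site$gt))
  if (length(absent))
    stop("sample(s) not present at site: ", paste(absent, collapse = ", "))
  hom <- homAlleles(site)
  names(hom) <- colnames(site$gt)
  ha <- hom[groupA]
  hb <- hom[groupB]
  if (anyNA(ha) || anyNA(hb)) return(NULL)
  if (length(unique(ha)) != 1L || length(unique(hb)) != 1L) return(NULL)
  if (ha[1] == hb[1]) return(NULL)
  GroupPair(groupA, groupB, ha[1], hb[1])
}

#' Enumerate all homozygous allele-pair groupings of a site
#'
#' Auto-group mode: for every unordered pair of alleles (i, j) with at least
#' one sample homozygous for each, emits a [GroupPair-class] containing all
#' samples homozygous for i versus all samples homozygous for j.
#' Heterozygous and missing samples belong to neither group. Pairs are
#' returned in ascending (i, j) order; the result does not depend on sample
#' order.
#'
#' @param site a variant site record (see [variantSite()]).
#' @return a (possibly empty) list of [GroupPair-class] objects.
#' @export
groupAuto <- function(site) {
  hom <- homAlleles(site)
  names(hom) <- colnames(site$gt)
  present <- sort(unique(hom[!is.na(hom)]))
  if (length(present) < 2L) return(list())
  out <- list()
  for (i in seq_len(length(present) - 1L)) {
    for (j in seq.int(i + 1L, length(present))) {
      ai <- present[i]
      aj <- present[j]
      out[[length(out) + 1L]] <- GroupPair(
        sort(names(hom)[!is.na(hom) & hom == ai]),
        sort(names(hom)[!is.na(hom) & hom == aj]),
        ai, aj)
    }
  }
  out
}
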