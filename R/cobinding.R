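# Co-occupancy between peak sets: pairwise overlap fractions and the
# three-way Venn partition over merged atoms.

#' Fraction of query peaks co-bound by a reference set
#'
#' @param query,reference `GRanges` peak sets.
#' @return List: `n_query`, `n_overlapping` (query peaks sharing >= 1 bp
#'   with any reference peak), `fraction` (unrounded), `percent` (rounded
#'   to 1 decimal). With an empty query, `fraction`/`percent` are `NA` and
#'   `defined` is `FALSE`.
#' @examples
#' q <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 501), width = 100))
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 60))
#' cobind_fraction(q, r)  # 1 of 2 -> 50.0%
#' @export
cobind_fraction <- function(query, reference) {
  n_query <- length(query)
  ov <- overlaps_any(query, reference)
  if (n_query == 0) {
    return(list(n_query = 0L, n_overlapping = 0L, fraction = NA_real_,
                percent = NA_real_, defined = FALSE))
  }
  frac <- ov$count / n_query
  list(n_query = n_query, n_overlapping = ov$count, fraction = frac,
       percent = round(100 * frac, 1), defined = TRUE)
}

#' Three-way Venn counts over merged atoms
#'
#' All three peak sets are pooled and merged into atoms (connected
#' components of >= 1 bp overlap across the union); each atom is classified
#' by which input sets contribute at least one overlapping peak. A wide
#' peak in one set bridging two peaks of another yields a single atom, so
#' the counts are atom counts, not input peak counts.
#'
#' @param a,b,c `GRanges` peak sets.
#' @param labels Names for the three sets in the output.
#' @return Named integer vector of atom counts for the 7 membership
#'   classes (`"a"`, `"b"`, `"c"`, `"a+b"`, `"a+c"`, `"b+c"`, `"a+b+c"`
#'   under default labels).
#' @export
three_way_venn <- function(a, b, c, labels = c("a", "b", "c")) {
  stopifnot(length(labels) == 3)
  # suppress the informational seqlevel-union warning: sets legitimately
  # may cover different chromosomes
  pooled <- suppressWarnings(
    base::c(granges_clean(a), granges_clean(b), granges_clean(c)))
  atoms <- GenomicRanges::reduce(pooled, min.gapwidth = 0L,
                                 ignore.strand = TRUE)
  in_a <- GenomicRanges::countOverlaps(atoms, a, ignore.strand = TRUE) > 0
  in_b <- GenomicRanges::countOverlaps(atoms, b, ignore.strand = TRUE) > 0
  in_c <- GenomicRanges::countOverlaps(atoms, c, ignore.strand = TRUE) > 0
  member <- cbind(in_a, in_b, in_c)
  classes <- apply(member, 1, function(m) paste(labels[m], collapse = "+"))
  all_classes <- c(labels,
                   paste(labels[c(1, 1, 2)], labels[c(2, 3, 3)], sep = "+"),
                   paste(labels, collapse = "+"))
  counts <- table(factor(classes, levels = all_classes))
  stats::setNames(as.integer(counts), all_classes)
}
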