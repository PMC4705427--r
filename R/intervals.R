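#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom BiocGenerics start end width strand sort
NULL

#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' closed convention of [GenomicRanges::GRanges] on read, so an interval
#' written as `start=100, end=200` covers the same 100 bases either way.
#'
#' @param path Path to a tab-separated BED file without header. Three to six
#'   columns are accepted (chrom, start, end, name, score, strand); extra
#'   columns are ignored.
#' @return A `GRanges`; `name` and `score` columns become metadata columns
#'   when present.
#' @details Malformed rows (non-numeric coordinates, `end <= start`) abort
#'   with an error naming the offending line, so a bad input cannot silently
#'   truncate a peak set.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  start <- suppressWarnings(as.numeric(df[[2]]))
  end <- suppressWarnings(as.numeric(df[[3]]))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad) > 0) {
    stop("malformed interval in ", path, " at line ", bad[1],
         ": '", paste(unlist(df[bad[1], 1:3]), collapse = "\t"),
         "' (require 0 <= start < end)")
  }
  gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(start + 1, end))
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- df[[4]]
  if (ncol(df) >= 5) {
    sc <- suppressWarnings(as.numeric(df[[5]]))
    S4Vectors::mcols(gr)$score <- sc
  }
  if (ncol(df) >= 6) {
    st <- df[[6]]
    st[!st %in% c("+", "-")] <- "*"
    BiocGenerics::strand(gr) <- st
  }
  gr
}

#' Write a GRanges as a sorted BED file
#'
#' Output is 0-based half-open, tab-separated, no header, sorted by
#' (chrom, start, end). `name`/`score` metadata columns and strand are
#' written when present (BED6), otherwise BED3.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  gr <- sort_peaks(gr)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  has_strand <- any(as.character(BiocGenerics::strand(gr)) != "*")
  if (!is.null(mc$name) || !is.null(mc$score) || has_strand) {
    df$name <- if (is.null(mc$name)) "." else as.character(mc$name)
    df$score <- if (is.null(mc$score)) 0 else mc$score
    if (has_strand) df$strand <- as.character(BiocGenerics::strand(gr))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chromosome-sizes TSV
#'
#' @param path TSV with columns chrom, size (no header).
#' @return Named integer vector of sizes.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}

#' Sort a peak set by (chrom, start, end)
#'
#' @param gr A `GRanges`.
#' @return The sorted `GRanges`.
#' @export
sort_peaks <- function(gr) {
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Merge two-condition peak calls into a single region set
#'
#' Peaks from the two conditions are pooled and every connected component of
#' intervals overlapping by at least 1 bp is replaced by its envelope
#' (minimum start to maximum end). Bookended intervals (end of one equal to
#' start of the next in 0-based half-open coordinates) share no base and are
#' not merged. Each merged region records which input set(s) contributed.
#'
#' @param a,b `GRanges` peak sets for the two conditions (strand ignored).
#' @return A sorted, non-overlapping `GRanges` with metadata columns
#'   `region_id`, `in_a`, `in_b` (logical contribution flags) and `source`
#'   (`"a"`, `"b"` or `"both"`).
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
#' merge_two_condition_peaks(a, b)  # one region: chr1 101-300
#' @export
merge_two_condition_peaks <- function(a, b) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
  pooled <- suppressWarnings(c(granges_clean(a), granges_clean(b)))
  merged <- GenomicRanges::reduce(pooled, min.gapwidth = 0L,
                                  ignore.strand = TRUE)
  merged <- sort_peaks(merged)
  in_a <- GenomicRanges::countOverlaps(merged, a, ignore.strand = TRUE) > 0
  in_b <- GenomicRanges::countOverlaps(merged, b, ignore.strand = TRUE) > 0
  S4Vectors::mcols(merged)$region_id <- sprintf("region_%05d",
                                                seq_along(merged))
  S4Vectors::mcols(merged)$in_a <- in_a
  S4Vectors::mcols(merged)$in_b <- in_b
  S4Vectors::mcols(merged)$source <- ifelse(in_a & in_b, "both",
                                            ifelse(in_a, "a", "b"))
  merged
}

# strip metadata and strand so reduce() pools freely
granges_clean <- function(gr) {
  gr <- GenomicRanges::granges(gr)
  BiocGenerics::strand(gr) <- "*"
  gr
}

#' Flag query peaks that overlap a reference set
#'
#' A query interval is flagged `TRUE` iff it shares at least 1 bp with at
#' least one reference interval.
#'
#' @param query,reference `GRanges` peak sets.
#' @return A list with `hits` (logical, one per query) and `count`
#'   (number of `TRUE` flags). An empty reference yields all-`FALSE`.
#' @export
overlaps_any <- function(query, reference) {
  hits <- GenomicRanges::countOverlaps(query, reference,
                                       ignore.strand = TRUE) > 0
  list(hits = unname(hits), count = sum(hits))
}

#' Resize regions to a fixed width about their midpoints
#'
#' Each interval is replaced by a `width`-bp window centred on its midpoint
#' (floor of (start + end)/2 in 0-based coordinates). Windows whose left
#' edge would fall below position 0 are shifted right to start at 0,
#' preserving the width; an optional chromosome-size vector clamps the right
#' edge the same way.
#'
#' @param gr A `GRanges`.
#' @param width Target width in bp (> 0).
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   right-edge clamping.
#' @return A `GRanges` of equal length, every interval exactly `width` bp.
#' @export
resize_to_fixed_width <- function(gr, width, chrom_sizes = NULL) {
  stopifnot(width > 0)
  width <- as.integer(width)
  s0 <- BiocGenerics::start(gr) - 1L          # 0-based start
  e0 <- BiocGenerics::end(gr)                 # 0-based exclusive end
  mid <- (s0 + e0) %/% 2L
  new_s0 <- mid - width %/% 2L
  new_s0 <- pmax(new_s0, 0L)
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[as.character(GenomicRanges::seqnames(gr))]
    over <- !is.na(lim) & (new_s0 + width > lim)
    new_s0[over] <- pmax(as.integer(lim[over]) - width, 0L)
  }
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(new_s0 + 1L,
                                                 new_s0 + width))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}
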