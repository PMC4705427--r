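# Per-region read counting and length/depth normalisation. The unit of the
# normalised score is reads per kb of region per million mapped reads.

#' Count reads overlapping each merged region
#'
#' A read is counted for a region iff the read interval shares at least 1 bp
#' with the region; a read spanning two regions counts once in each
#' (intersect semantics). The library size is the total number of reads in
#' the input, overlapping a region or not.
#'
#' @param regions A merged, sorted `GRanges` (no two regions overlap).
#' @param reads Read positions as a `GRanges` (single-base reads are valid
#'   1 bp intervals).
#' @return List with `counts` (integer per region) and `library_size`.
#' @export
count_reads <- function(regions, reads) {
  check_merged(regions)
  counts <- GenomicRanges::countOverlaps(regions, reads,
                                         ignore.strand = TRUE)
  list(counts = unname(counts), library_size = length(reads))
}

check_merged <- function(regions) {
  if (length(regions) > 1) {
    red <- GenomicRanges::reduce(regions, min.gapwidth = 0L,
                                 ignore.strand = TRUE)
    if (length(red) != length(regions)) {
      stop("region set must be merged (non-overlapping); call ",
           "merge_two_condition_peaks() first")
    }
    if (!identical(BiocGenerics::order(regions), seq_along(regions))) {
      stop("region set must be sorted; call sort_peaks() first")
    }
  }
  invisible(TRUE)
}

#' Normalise raw region counts for length and sequencing depth
#'
#' score = raw * (1e6 / library_size) * (1e3 / length_bp), i.e. reads per
#' kb per million mapped reads.
#'
#' @param raw Non-negative integer counts.
#' @param library_size Total mapped reads (> 0).
#' @param lengths Region lengths in bp.
#' @return Numeric scores, same length as `raw`.
#' @export
normalize_counts <- function(raw, library_size, lengths) {
  if (length(library_size) != 1 || library_size <= 0) {
    stop("library_size must be a single positive count; got ",
         library_size)
  }
  stopifnot(all(raw >= 0), all(lengths > 0))
  raw * (1e6 / library_size) * (1e3 / lengths)
}

#' Score histone reads over fixed-width windows
#'
#' Each region is resized to `width` bp about its midpoint before counting,
#' so broad histone signal is compared over a constant footprint;
#' normalisation uses the fixed width as the region length.
#'
#' @inheritParams count_reads
#' @param width Window width in bp (default 800).
#' @param chrom_sizes Optional chromosome sizes for edge clamping.
#' @return List with `counts`, `norm`, `library_size` and the resized
#'   `windows`.
#' @export
score_histone_regions <- function(regions, reads, width = 800,
                                  chrom_sizes = NULL) {
  check_merged(regions)
  windows <- resize_to_fixed_width(regions, width, chrom_sizes)
  counts <- GenomicRanges::countOverlaps(windows, reads,
                                         ignore.strand = TRUE)
  lib <- length(reads)
  norm <- if (lib > 0) normalize_counts(counts, lib, rep(width, length(counts)))
          else rep(NA_real_, length(counts))
  list(counts = unname(counts), norm = unname(norm), library_size = lib,
       windows = windows)
}

#' Build the per-region coverage matrix across assays and conditions
#'
#' For each assay/condition read set, counts reads per merged region (over
#' fixed-width midpoint windows for histone assays) and normalises for
#' region length and library size. This matrix is the substrate for all
#' region grouping.
#'
#' @param regions Merged, sorted `GRanges` with a `region_id` metadata
#'   column (as produced by [merge_two_condition_peaks()]).
#' @param reads Named list of read `GRanges`; names `"<assay>_<condition>"`,
#'   e.g. `pu1_minus`, `h3k27ac_plus`.
#' @param histone_assays Assay names scored over fixed-width windows.
#' @param histone_width Window width for histone assays (bp).
#' @param chrom_sizes Optional chromosome sizes for window clamping.
#' @return A data.frame with region coordinates and, per read set, columns
#'   `raw_<name>` and `norm_<name>`; library sizes in
#'   `attr(, "library_sizes")`.
#' @export
coverage_matrix <- function(regions, reads,
                            histone_assays = "h3k27ac",
                            histone_width = 800,
                            chrom_sizes = NULL) {
  check_merged(regions)
  rid <- S4Vectors::mcols(regions)$region_id
  if (is.null(rid)) rid <- sprintf("region_%05d", seq_along(regions))
  out <- data.frame(
    region_id = rid,
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = BiocGenerics::start(regions) - 1L,
    end = BiocGenerics::end(regions),
    stringsAsFactors = FALSE)
  lens <- BiocGenerics::width(regions)
  lib_sizes <- list()
  for (nm in names(reads)) {
    assay <- sub("_[^_]+$", "", nm)
    if (assay %in% histone_assays) {
      sc <- score_histone_regions(regions, reads[[nm]], histone_width,
                                  chrom_sizes)
      raw <- sc$counts
      lib <- sc$library_size
      norm <- if (lib > 0) sc$norm else rep(NA_real_, length(raw))
    } else {
      cr <- count_reads(regions, reads[[nm]])
      raw <- cr$counts
      lib <- cr$library_size
      norm <- if (lib > 0) normalize_counts(raw, lib, lens)
              else rep(NA_real_, length(raw))
    }
    out[[paste0("raw_", nm)]] <- raw
    out[[paste0("norm_", nm)]] <- norm
    lib_sizes[[nm]] <- lib
  }
  attr(out, "library_sizes") <- lib_sizes
  out
}

#' Write a coverage matrix and its library sizes to TSV
#'
#' @param cov Result of [coverage_matrix()].
#' @param path Counts TSV path; library sizes are written next to it with a
#'   `.libsizes.tsv` suffix.
#' @return `path` invisibly.
#' @export
write_coverage_matrix <- function(cov, path) {
  utils::write.table(cov, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  libs <- attr(cov, "library_sizes")
  utils::write.table(
    data.frame(read_set = names(libs),
               library_size = unlist(libs, use.names = FALSE)),
    paste0(path, ".libsizes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
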