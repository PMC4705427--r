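# Shared constructors and independent brute-force oracles. The oracles work
# base-by-base on a small coordinate space and never call the interval code
# they are used to check.

# GRanges from 0-based half-open coordinates (BED convention)
gr0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

# 0-based half-open data.frame view of a GRanges, sorted
as_bed_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_peakset <- function(n, chroms = c("chrA", "chrB"), genome = 10000,
                           max_width = 200) {
  ch <- sample(chroms, n, replace = TRUE)
  s <- sample.int(genome - max_width, n, replace = TRUE) - 1L
  w <- sample.int(max_width, n, replace = TRUE)
  gr0(ch, s, s + w)
}

# per-base occupancy oracle: union of any number of sets -> merged
# intervals. Works in doubled coordinates, marking only the interior
# positions 2*start+1 .. 2*end-1 of each interval, so intervals sharing a
# real base stay connected while bookended intervals (end == next start)
# leave an unmarked even position between them and are kept apart.
oracle_merge <- function(sets, chroms = c("chrA", "chrB"),
                         genome = 20000) {
  out <- list()
  for (ch in chroms) {
    occ <- logical(2 * genome + 1)
    for (s in sets) {
      df <- as_bed_df(s)
      df <- df[df$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(df))) {
        occ[(2 * df$start[i] + 2):(2 * df$end[i])] <- TRUE  # 1-indexed
      }
    }
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[ch]] <- data.frame(chrom = ch,
                              start = (starts[keep] - 2L) %/% 2L,
                              end = ends[keep] %/% 2L,
                              stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# quadratic all-pairs overlap oracle (>= 1 shared base, half-open)
oracle_overlap_flags <- function(query, reference) {
  q <- data.frame(chrom = as.character(GenomicRanges::seqnames(query)),
                  start = BiocGenerics::start(query) - 1L,
                  end = BiocGenerics::end(query))
  r <- data.frame(chrom = as.character(GenomicRanges::seqnames(reference)),
                  start = BiocGenerics::start(reference) - 1L,
                  end = BiocGenerics::end(reference))
  vapply(seq_len(nrow(q)), function(i) {
    any(r$chrom == q$chrom[i] & r$end > q$start[i] & q$end[i] > r$start)
  }, logical(1))
}

# per-base three-way Venn oracle: atoms of the union classified by
# contributing sets
oracle_venn <- function(a, b, c, labels = c("a", "b", "c"),
                        chroms = c("chrA", "chrB"), genome = 20000) {
  atoms <- oracle_merge(list(a, b, c), chroms, genome)
  sets <- list(a, b, c)
  classes <- vapply(seq_len(nrow(atoms)), function(i) {
    atom <- gr0(atoms$chrom[i], atoms$start[i], atoms$end[i])
    m <- vapply(sets, function(s) any(oracle_overlap_flags(atom, s)),
                logical(1))
    paste(labels[m], collapse = "+")
  }, character(1))
  all_classes <- c(labels,
                   paste(labels[c(1, 1, 2)], labels[c(2, 3, 3)], sep = "+"),
                   paste(labels, collapse = "+"))
  out <- table(factor(classes, levels = all_classes))
  stats::setNames(as.integer(out), all_classes)
}

# build a peak set of n_query disjoint peaks of which exactly n_hit overlap
# a reference set; used for printed-percentage arithmetic
peakset_with_hits <- function(n_query, n_hit, chrom = "chr1",
                              spacing = 1000, width = 100) {
  s <- (seq_len(n_query) - 1L) * spacing
  query <- gr0(chrom, s, s + width)
  ref <- if (n_hit == 0) GenomicRanges::GRanges() else
    gr0(chrom, s[seq_len(n_hit)] + width %/% 2,
        s[seq_len(n_hit)] + width %/% 2 + 10L)
  list(query = query, reference = ref)
}

# minimal coverage-matrix data.frame built directly from score columns
make_cov <- function(norm_tf_minus, norm_tf_plus, norm_hist_minus,
                     norm_hist_plus, raw_hist_plus,
                     region_id = sprintf("region_%05d",
                                         seq_along(norm_tf_minus))) {
  data.frame(region_id = region_id,
             chrom = "chr1",
             start = (seq_along(norm_tf_minus) - 1L) * 1000L,
             end = (seq_along(norm_tf_minus) - 1L) * 1000L + 500L,
             norm_pu1_minus = norm_tf_minus, norm_pu1_plus = norm_tf_plus,
             norm_h3k27ac_minus = norm_hist_minus,
             norm_h3k27ac_plus = norm_hist_plus,
             raw_h3k27ac_plus = raw_hist_plus,
             stringsAsFactors = FALSE)
}

# tiny annotation: genes at given 0-based [start,end) with strand
make_annotation <- function(chrom, start, end, strand,
                            gene_id = sprintf("g%02d", seq_along(start)),
                            promoter_window = c(1000, 200)) {
  genes <- data.frame(gene_id = gene_id, chrom = chrom, start = start,
                      end = end, strand = strand, stringsAsFactors = FALSE)
  genes$tss <- ifelse(strand == "+", genes$start, genes$end - 1L)
  up <- promoter_window[1]; down <- promoter_window[2]
  ps <- ifelse(strand == "+", genes$tss - up, genes$tss - down + 1L)
  pe <- ifelse(strand == "+", genes$tss + down, genes$tss + up + 1L)
  ps <- pmax(ps, 0L)
  promoters <- gr0(genes$chrom, ps, pe)
  S4Vectors::mcols(promoters)$name <- genes$gene_id
  list(genes = genes, promoters = promoters)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
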