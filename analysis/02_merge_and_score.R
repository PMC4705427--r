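#!/usr/bin/env Rscript
# Stage 2: merge the TF peak calls across the two conditions and build the
# normalised coverage matrix over the merged regions (histone reads are
# scored over 800 bp midpoint windows).

suppressMessages(library(peaksig))

peaks_minus <- read_bed("results/fixtures/peaks_pu1_minus.bed")
peaks_plus <- read_bed("results/fixtures/peaks_pu1_plus.bed")
regions <- merge_two_condition_peaks(peaks_minus, peaks_plus)
message(length(peaks_minus), " + ", length(peaks_plus),
        " peaks merge into ", length(regions), " regions (",
        sum(S4Vectors::mcols(regions)$source == "both"), " shared, ",
        sum(S4Vectors::mcols(regions)$source == "b"), " induction-only)")

read_sets <- c("pu1_minus", "pu1_plus", "cebpa_minus", "cebpa_plus",
               "h3k27ac_minus", "h3k27ac_plus")
reads <- lapply(read_sets, function(nm)
  read_bed(sprintf("results/fixtures/reads_%s.bed", nm)))
names(reads) <- read_sets

cov <- coverage_matrix(regions, reads)
write_coverage_matrix(cov, "results/coverage_matrix.tsv")
# BED name = region id; score encodes the contribution flags (1 = first
# condition only, 2 = second only, 3 = both)
out <- regions
S4Vectors::mcols(out) <- NULL
S4Vectors::mcols(out)$name <- S4Vectors::mcols(regions)$region_id
S4Vectors::mcols(out)$score <- S4Vectors::mcols(regions)$in_a +
  2 * S4Vectors::mcols(regions)$in_b
write_bed(out, "results/merged_regions.bed")
message("coverage matrix: ", nrow(cov), " regions x ",
        sum(grepl("^raw_", names(cov))), " read sets -> ",
        "results/coverage_matrix.tsv")
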