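#!/usr/bin/env Rscript
# Stage 3: classify merged regions into functional groups from the TF and
# histone fold changes, and summarise global binding: the condition Venn,
# the mean per-region fold increase, and the TF-histone coupling.

suppressMessages(library(peaksig))

regions <- read_bed("results/merged_regions.bed")
S4Vectors::mcols(regions)$region_id <- S4Vectors::mcols(regions)$name
S4Vectors::mcols(regions)$in_a <- S4Vectors::mcols(regions)$score %in% c(1, 3)
S4Vectors::mcols(regions)$in_b <- S4Vectors::mcols(regions)$score %in% c(2, 3)
cov <- utils::read.table("results/coverage_matrix.tsv", header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)

groups <- classify_regions(cov)
utils::write.table(groups, "results/region_groups.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("group sizes: ",
        paste(names(attr(groups, "sizes")), attr(groups, "sizes"),
              sep = "=", collapse = ", "))

summary <- global_binding_summary(cov, regions)
corr <- tf_histone_correlation(cov)
message(sprintf("mean fold increase %.2f; TF~histone r = %.3f (p = %.2g, n = %d)",
                summary$mean_fold_increase, corr$r, corr$p_value, corr$n))
jsonlite::write_json(list(binding_summary = summary, correlation = corr),
                     "results/binding_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
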