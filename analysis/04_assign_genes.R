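#!/usr/bin/env Rscript
# Stage 4: assign merged regions to genes (promoter > intragenic >
# intergenic within 50 kb of either flank) and summarise the genomic
# distribution of each region group.

suppressMessages(library(peaksig))

regions <- read_bed("results/merged_regions.bed")
S4Vectors::mcols(regions)$region_id <- S4Vectors::mcols(regions)$name
genes <- read_annotation("results/fixtures/annotation.tsv")
promoters <- read_bed("results/fixtures/promoters.bed")
groups <- utils::read.table("results/region_groups.tsv", header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)

assignments <- assign_regions(regions, genes, promoters)
utils::write.table(assignments, "results/gene_assignments.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

dist <- distribution_summary(assignments, groups)
print(dist)
utils::write.table(dist, "results/genomic_distribution.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (g in c("I", "II", "III")) {
  writeLines(genes_for_group(assignments, groups, g),
             sprintf("results/group_%s_genes.txt", g))
}
message("gene sets: ",
        paste(c("I", "II", "III"), vapply(c("I", "II", "III"), function(g)
          length(genes_for_group(assignments, groups, g)), integer(1)),
          sep = "=", collapse = ", "))
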