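#!/usr/bin/env Rscript
# Stage 6: co-binding between the induced-TF region groups and the
# co-factor peak set -- pairwise overlap percentages and the three-way
# Venn over merged atoms.

suppressMessages(library(peaksig))

regions <- read_bed("results/merged_regions.bed")
S4Vectors::mcols(regions)$region_id <- S4Vectors::mcols(regions)$name
groups <- utils::read.table("results/region_groups.tsv", header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
cebpa <- read_bed("results/fixtures/peaks_cebpa_plus.bed")
pu1_minus <- read_bed("results/fixtures/peaks_pu1_minus.bed")
pu1_plus <- read_bed("results/fixtures/peaks_pu1_plus.bed")

by_group <- function(g)
  regions[S4Vectors::mcols(regions)$region_id %in%
            groups$region_id[groups$group == g]]
cob <- list(
  groupI_at_cebpa = cobind_fraction(by_group("I"), cebpa),
  groupII_at_cebpa = cobind_fraction(by_group("II"), cebpa),
  groupIII_at_cebpa = cobind_fraction(by_group("III"), cebpa),
  venn = as.list(three_way_venn(pu1_minus, pu1_plus, cebpa,
                                labels = c("pu1_minus", "pu1_plus",
                                           "cebpa"))))
for (g in c("groupI_at_cebpa", "groupII_at_cebpa", "groupIII_at_cebpa")) {
  message(sprintf("%s: %d/%d (%.1f%%)", g, cob[[g]]$n_overlapping,
                  cob[[g]]$n_query, cob[[g]]$percent))
}
jsonlite::write_json(cob, "results/cobinding.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
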