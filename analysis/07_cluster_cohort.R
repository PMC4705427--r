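#!/usr/bin/env Rscript
# Stage 7: stratify a labelled synthetic cohort by the target-gene
# signature -- correlation-distance average-linkage clustering with
# gene-resampling bootstrap support, cluster composition and marker
# expression per cluster.

suppressMessages(library(peaksig))

cfg <- default_config(seed = 1)
sig <- readLines("results/target_genes.txt")
co <- generate_labeled_cohort(
  n_samples = cfg$cohort$n_samples, n_clusters = cfg$cohort$n_clusters,
  signature_genes = sig, separation = cfg$cohort$separation,
  label_table = as.matrix(as.data.frame(cfg$cohort$label_table)),
  marker_gene = cfg$cohort$marker_gene, seed = cfg$seed + 3,
  dir = "results/fixtures")

cl <- cluster_by_signature(co$expr, sig, k = cfg$cluster_k,
                           n_boot = cfg$cohort$n_boot, seed = cfg$seed + 4)
print(cl)
write_newick(cl, "results/cohort_dendrogram.nwk")
utils::write.table(data.frame(sample_id = names(cl$labels),
                              cluster = cl$labels),
                   "results/cohort_clusters.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

sm <- summarize_clusters(cl, co$expr, co$metadata,
                         marker_gene = cfg$cohort$marker_gene)
message("marker-argmax cluster: ", sm$marker$argmax_cluster)
for (v in unique(sm$composition$value)) {
  cid <- sm$marker$argmax_cluster
  low <- which.min(sm$marker$means)
  enr <- label_enrichment_fraction(cl, co$metadata, "karyotype", v, low)
  message(sprintf("%s in lowest-marker cluster %d: %d/%d (%.1f%%)",
                  v, low, enr$count, enr$total, enr$percent))
}
jsonlite::write_json(
  list(sizes = as.list(sm$sizes),
       marker_means = as.list(sm$marker$means),
       composition = sm$composition),
  "results/cohort_summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
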