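#!/usr/bin/env Rscript
# Stage 5: simulate the induction microarray (up-regulation planted in
# genes linked only to Group I regions), call differential expression,
# compare the expression response across groups, and derive the
# high-confidence target-gene signature.

suppressMessages(library(peaksig))

cfg <- default_config(seed = 1)
genes <- read_annotation("results/fixtures/annotation.tsv")
group_genes <- lapply(stats::setNames(nm = c("I", "II", "III")), function(g)
  readLines(sprintf("results/group_%s_genes.txt", g)))

exclusive_i <- setdiff(group_genes$I, union(group_genes$II, group_genes$III))
up_planted <- utils::head(exclusive_i, 25)
ex <- generate_expression_matrix(
  n_genes = nrow(genes),
  n_samples_per_condition = cfg$expression$n_samples_per_condition,
  n_up_genes = length(up_planted),
  effect_log2fc = cfg$expression$effect_log2fc,
  noise_sd = cfg$expression$noise_sd, seed = cfg$seed + 2,
  gene_ids = genes$gene_id, up_gene_ids = up_planted,
  dir = "results/fixtures")

de <- call_de(ex$expr, ex$design$condition,
              alpha = cfg$expression$alpha, fc_min = cfg$expression$fc_min)
utils::write.table(de, "results/de_table.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message(sum(de$significant), " significant probes of ", nrow(de),
        " (", length(up_planted), " planted)")

resp <- group_expression_response(de, group_genes)
print(resp$means); print(resp$tests)
jsonlite::write_json(resp, "results/group_expression_response.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

target <- derive_target_set(group_genes$I, de)
print(target)
writeLines(target$genes, "results/target_genes.txt")
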