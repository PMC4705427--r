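#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study -- a gene annotation with
# promoters, a two-condition / three-assay binding experiment with planted
# Group I/II/III regions, and their read pileups. All fixtures and the
# planted truth are written under results/fixtures/.

suppressMessages(library(peaksig))

cfg <- default_config(seed = 1)
dir.create("results/fixtures", showWarnings = FALSE, recursive = TRUE)

ann <- generate_annotation(n_genes = cfg$annotation$n_genes,
                           genome_size = cfg$annotation$genome_size,
                           promoter_window = cfg$annotation$promoter_window,
                           seed = cfg$seed, dir = "results/fixtures")
message(nrow(ann$genes), " genes placed on ",
        length(unique(ann$genes$chrom)), " chromosomes")

bexp <- generate_binding_experiment(
  n_regions_per_group = unlist(cfg$binding$n_regions_per_group),
  depth = cfg$binding$depth, fold_pu1 = cfg$binding$fold_pu1,
  fold_h3k27ac = cfg$binding$fold_h3k27ac,
  placement = cfg$binding$placement, annotation = ann,
  genome_size = cfg$annotation$genome_size,
  hist_abs_min = cfg$thresholds$hist_abs_min,
  seed = cfg$seed + 1, dir = "results/fixtures")
message("planted regions per group: ",
        paste(names(table(bexp$truth$group)), table(bexp$truth$group),
              sep = "=", collapse = ", "))
message("library sizes: ",
        paste(names(bexp$library_sizes), unlist(bexp$library_sizes),
              sep = "=", collapse = ", "))
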