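# End-to-end orchestration over synthetic fixtures: simulate -> merge ->
# count -> classify -> assign -> DE -> target set -> co-binding ->
# signature clustering, with a run manifest for reproducibility. Every
# paper-unstated constant lives in the config with its default.

#' Default pipeline configuration
#'
#' A nested list with one block per stage; override any entry and pass to
#' [run_pipeline()]. All randomness derives from `seed`.
#'
#' @param seed Master integer seed.
#' @return Configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    annotation = list(n_genes = 300, genome_size = 5e6,
                      promoter_window = c(1000, 200)),
    binding = list(n_regions_per_group = list(I = 100, II = 140, III = 60),
                   depth = 50, fold_pu1 = 8, fold_h3k27ac = 8,
                   placement = "group_biased"),
    thresholds = list(fc_tf_min = 4, fc_hist_min = 4, hist_abs_min = 50,
                      no_change_band = 2, pseudocount = 1),
    histone_width = 800,
    gene_max_dist = 50000,
    expression = list(n_samples_per_condition = 3, effect_log2fc = 1.2,
                      noise_sd = 0.15, alpha = 0.05, fc_min = 1.2),
    cohort = list(n_samples = 60, n_clusters = 3, separation = 2,
                  n_boot = 100,
                  marker_gene = "Spi1",
                  # rows are clusters (1 = lowest marker expression):
                  # the low-marker cluster is translocation-rich, the
                  # high-marker cluster carries mostly normal karyotypes
                  label_table = data.frame(t_15_17 = c(20, 2, 1),
                                           t_8_21 = c(12, 5, 1),
                                           normal = c(2, 10, 12))),
    cluster_k = 3)
}

# YAML deserialises vectors and matrices as (nested) lists; coerce the
# handful of structured fields back so a config round-trips through a file
normalize_config <- function(config) {
  config$annotation$promoter_window <-
    as.numeric(unlist(config$annotation$promoter_window))
  nr <- unlist(config$binding$n_regions_per_group)
  if (is.null(names(nr)) && length(nr) == 3) {
    names(nr) <- c("I", "II", "III")  # canonical order if YAML lost names
  }
  config$binding$n_regions_per_group <- nr
  if (!is.null(config$binding$region_width)) {
    config$binding$region_width <-
      as.numeric(unlist(config$binding$region_width))
  }
  lt <- config$cohort$label_table
  if (is.list(lt)) {   # plain list or data.frame: columns are label values
    config$cohort$label_table <- as.matrix(as.data.frame(lt))
  }
  config
}

validate_config <- function(config) {
  th <- config$thresholds
  if (any(unlist(th) <= 0)) stop("config error: thresholds must be > 0")
  do.call(group_thresholds, th)  # full invariant check
  if (config$binding$fold_pu1 <= 1 || config$binding$fold_h3k27ac <= 1) {
    stop("config error: planted folds must be > 1")
  }
  if (config$cluster_k < 2) stop("config error: cluster_k must be >= 2")
  invisible(TRUE)
}

#' Run the full pipeline on synthetic data
#'
#' Generates the fixtures, executes all analysis stages in dependency
#' order, writes every intermediate and result file under `outdir`, and
#' records a manifest (config, seeds, package version, per-stage row
#' counts). Re-running with the same config and outdir reproduces
#' byte-identical outputs.
#'
#' @param config Configuration list from [default_config()], or a path to
#'   a YAML file holding one.
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- normalize_config(config)
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[peaksig] ", ...)
  seed <- config$seed
  counts <- list()

  say("simulate: annotation (", config$annotation$n_genes, " genes)")
  ann <- generate_annotation(
    n_genes = config$annotation$n_genes,
    genome_size = config$annotation$genome_size,
    promoter_window = config$annotation$promoter_window,
    seed = seed, dir = file.path(outdir, "fixtures"))

  say("simulate: binding experiment")
  bexp <- do.call(generate_binding_experiment, c(
    config$binding,
    list(seed = seed + 1, annotation = ann,
         genome_size = config$annotation$genome_size,
         hist_abs_min = config$thresholds$hist_abs_min,
         dir = file.path(outdir, "fixtures"))))

  say("merge + count: TF peaks across conditions")
  regions <- merge_two_condition_peaks(bexp$peaks$pu1$minus,
                                       bexp$peaks$pu1$plus)
  cov <- coverage_matrix(regions, bexp$reads,
                         histone_width = config$histone_width)
  write_coverage_matrix(cov, file.path(outdir, "coverage_matrix.tsv"))
  counts$regions <- nrow(cov)

  say("classify: ", nrow(cov), " merged regions")
  th <- do.call(group_thresholds, config$thresholds)
  groups <- classify_regions(cov, thresholds = th)
  utils::write.table(groups, file.path(outdir, "region_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$group_sizes <- as.list(attr(groups, "sizes"))
  say("  group sizes: ", paste(names(counts$group_sizes),
                               unlist(counts$group_sizes),
                               sep = "=", collapse = ", "))
  summary <- global_binding_summary(cov, regions,
                                    pseudocount = th$pseudocount)
  corr <- tf_histone_correlation(cov, pseudocount = th$pseudocount)

  say("assign: regions to genes")
  assignments <- assign_regions(regions, ann$genes, ann$promoters,
                                max_dist = config$gene_max_dist)
  utils::write.table(assignments, file.path(outdir, "gene_assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dist_sum <- distribution_summary(assignments, groups)
  counts$assignments <- nrow(assignments)

  say("differential expression")
  group_gene_sets <- lapply(stats::setNames(nm = c("I", "II", "III")),
                            function(g) genes_for_group(assignments,
                                                        groups, g))
  ex_cfg <- config$expression
  # up-regulation is planted in genes linked to Group I regions only, so
  # the group-wise expression contrast and the derived target set are
  # non-trivial; genes shared with Groups II/III would dilute the contrast
  exclusive_i <- setdiff(group_gene_sets$I,
                         union(group_gene_sets$II, group_gene_sets$III))
  if (length(exclusive_i) < 5) exclusive_i <- group_gene_sets$I
  up_candidates <- utils::head(exclusive_i, 25)
  exprs <- generate_expression_matrix(
    n_genes = nrow(ann$genes),
    n_samples_per_condition = ex_cfg$n_samples_per_condition,
    n_up_genes = length(up_candidates),
    effect_log2fc = ex_cfg$effect_log2fc, noise_sd = ex_cfg$noise_sd,
    seed = seed + 2, gene_ids = ann$genes$gene_id,
    up_gene_ids = up_candidates,
    dir = file.path(outdir, "fixtures"))
  de <- call_de(exprs$expr, exprs$design$condition,
                alpha = ex_cfg$alpha, fc_min = ex_cfg$fc_min)
  utils::write.table(de, file.path(outdir, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts$de_significant <- sum(de$significant)
  response <- group_expression_response(de, group_gene_sets)

  say("target gene set")
  target <- derive_target_set(group_gene_sets$I, de)
  writeLines(target$genes, file.path(outdir, "target_genes.txt"))
  counts$target_genes <- length(target$genes)

  say("co-binding")
  rid_by_group <- split(groups$region_id, groups$group)
  region_gr <- function(ids) regions[S4Vectors::mcols(regions)$region_id
                                     %in% ids]
  cebpa <- bexp$peaks$cebpa$plus
  cobind <- list(
    groupI_vs_cebpa = cobind_fraction(region_gr(rid_by_group$I), cebpa),
    groupIII_vs_cebpa = cobind_fraction(region_gr(rid_by_group$III), cebpa),
    venn = as.list(three_way_venn(bexp$peaks$pu1$minus,
                                  bexp$peaks$pu1$plus, cebpa,
                                  labels = c("pu1_minus", "pu1_plus",
                                             "cebpa"))))

  say("signature clustering of the labelled cohort")
  co_cfg <- config$cohort
  sig <- if (length(target$genes) >= 2) target$genes else group_gene_sets$I
  cohort <- generate_labeled_cohort(
    n_samples = co_cfg$n_samples, n_clusters = co_cfg$n_clusters,
    signature_genes = sig, separation = co_cfg$separation,
    label_table = co_cfg$label_table, seed = seed + 3,
    marker_gene = co_cfg$marker_gene,
    dir = file.path(outdir, "fixtures"))
  clust <- cluster_by_signature(cohort$expr, sig, k = config$cluster_k,
                                n_boot = co_cfg$n_boot, seed = seed + 4)
  write_newick(clust, file.path(outdir, "cohort_dendrogram.nwk"))
  utils::write.table(
    data.frame(sample_id = names(clust$labels), cluster = clust$labels),
    file.path(outdir, "cohort_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  clu_sum <- summarize_clusters(clust, cohort$expr, cohort$metadata,
                                marker_gene = co_cfg$marker_gene)
  counts$cohort_samples <- length(clust$labels)

  say("write summary + manifest")
  results <- list(binding_summary = summary, correlation = corr,
                  group_sizes = counts$group_sizes,
                  distribution = dist_sum,
                  expression_response = response,
                  target_provenance = target$provenance,
                  cobinding = cobind,
                  cluster_sizes = as.list(clu_sum$sizes),
                  marker = if (is.null(clu_sum$marker)) NULL else
                    list(gene = clu_sum$marker$gene,
                         argmax_cluster = clu_sum$marker$argmax_cluster))
  jsonlite::write_json(results, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("peaksig")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(annotation = ann, binding = bexp, regions = regions,
                 coverage = cov, groups = groups,
                 assignments = assignments, de = de,
                 group_gene_sets = group_gene_sets, target = target,
                 cobinding = cobind, cohort = cohort, clustering = clust,
                 cluster_summary = clu_sum, results = results,
                 manifest = manifest))
}
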