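# Differential expression and its integration with the region groups.
# The DE contract is deliberately simple: quantile normalisation, per-probe
# equal-variance t-test on log2 intensities, Benjamini-Hochberg adjustment,
# and a significance call of adjusted p <= 0.05 with fold change > 1.2 in
# either direction.

#' Quantile-normalise the columns of an expression matrix
#'
#' Thin wrapper over [limma::normalizeQuantiles()]; afterwards every
#' column has an identical sorted value vector.
#'
#' @param expr Numeric matrix (genes x samples).
#' @return Normalised matrix with the original dimnames.
#' @export
quantile_normalize <- function(expr) {
  out <- limma::normalizeQuantiles(as.matrix(expr))
  dimnames(out) <- dimnames(expr)
  out
}

#' Call differentially expressed probes between two conditions
#'
#' Columns are quantile-normalised, then each probe is tested with an
#' equal-variance two-sample t-test on log2 intensities; p-values are BH
#' adjusted across tested probes. A probe is significant iff
#' `p_adj <= alpha` and its linear fold change exceeds `fc_min` in either
#' direction (`|log2fc| > log2(fc_min)`).
#'
#' @param expr Numeric matrix (probes x samples), log2 scale.
#' @param condition Character vector over columns with exactly two levels;
#'   `levels[1]` is the reference (uninduced) condition.
#' @param levels The two condition labels, reference first.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param fc_min Linear fold-change cutoff (default 1.2).
#' @param detection_p Optional probes x samples matrix of detection
#'   p-values; probes with `detection_p >= detection_cut` in all samples are
#'   dropped before testing. Absent matrix keeps all probes.
#' @param detection_cut Detection cutoff (default 0.01).
#' @param normalize Quantile-normalise first (default TRUE).
#' @return A data.frame per probe: `gene_id`, `log2fc` (induced minus
#'   reference mean), `p_raw`, `p_adj`, `significant`, `direction`.
#' @export
call_de <- function(expr, condition, levels = c("minus", "plus"),
                    alpha = 0.05, fc_min = 1.2,
                    detection_p = NULL, detection_cut = 0.01,
                    normalize = TRUE) {
  expr <- as.matrix(expr)
  stopifnot(length(condition) == ncol(expr))
  if (!all(condition %in% levels) || length(levels) != 2) {
    stop("condition must take exactly the two values in `levels`")
  }
  n1 <- sum(condition == levels[1]); n2 <- sum(condition == levels[2])
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per condition")
  if (!is.null(detection_p)) {
    drop <- rowSums(detection_p >= detection_cut) == ncol(detection_p)
    expr <- expr[!drop, , drop = FALSE]
  }
  if (normalize) expr <- quantile_normalize(expr)

  x1 <- expr[, condition == levels[1], drop = FALSE]
  x2 <- expr[, condition == levels[2], drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2); v2 <- rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2
  sp2 <- (v1 + v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m2 - m1) / se
  p_raw <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p_raw[se == 0 & m1 == m2] <- 1   # constant probes carry no evidence
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  log2fc <- m2 - m1
  significant <- !is.na(p_adj) & p_adj <= alpha &
    abs(log2fc) > log2(fc_min)
  data.frame(gene_id = rownames(expr), log2fc = log2fc, p_raw = p_raw,
             p_adj = p_adj, significant = significant,
             direction = ifelse(log2fc >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Collapse probe-level DE results to genes
#'
#' When several probes map to one gene, the probe with the smallest
#' adjusted p-value represents the gene.
#'
#' @param de Result of [call_de()].
#' @param probe_to_gene Optional data.frame (`probe_id`, `gene_id`) when
#'   `de$gene_id` holds probe ids; by default rows are already genes.
#' @return A DE data.frame with one row per gene.
#' @export
collapse_probes <- function(de, probe_to_gene = NULL) {
  if (!is.null(probe_to_gene)) {
    mapped <- probe_to_gene$gene_id[match(de$gene_id,
                                          probe_to_gene$probe_id)]
    de <- de[!is.na(mapped), , drop = FALSE]
    de$gene_id <- mapped[!is.na(mapped)]
  }
  de <- de[order(de$p_adj), ]
  de <- de[!duplicated(de$gene_id), ]
  de[order(de$gene_id), ]
}

#' Compare expression response across region groups
#'
#' Among genes significant on the array, computes the mean linear fold
#' change of the genes linked to each region group and a Mann-Whitney test
#' of group I against each other group (on log2 fold changes). A gene
#' linked to several groups contributes to each of them.
#'
#' @param de Gene-level DE table ([call_de()] / [collapse_probes()]).
#' @param group_genes Named list of gene-id sets, e.g.
#'   `list(I = ..., II = ..., III = ...)`.
#' @param reference Group compared against the others (default `"I"`).
#' @return List with `means` (data.frame group, n, mean_fold_change) and
#'   `tests` (data.frame group, p_value vs the reference group). Groups
#'   with no significant genes are absent from `means`.
#' @export
group_expression_response <- function(de, group_genes, reference = "I") {
  sig <- de[de$significant, ]
  per_group <- lapply(group_genes, function(gs) {
    sig$log2fc[sig$gene_id %in% gs]
  })
  keep <- vapply(per_group, length, integer(1)) > 0
  means <- data.frame(
    group = names(per_group)[keep],
    n = vapply(per_group[keep], length, integer(1)),
    mean_fold_change = vapply(per_group[keep],
                              function(x) mean(2^x), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  tests <- NULL
  if (reference %in% names(per_group)[keep]) {
    others <- setdiff(names(per_group)[keep], reference)
    tests <- data.frame(
      group = others,
      p_value = vapply(others, function(g) {
        stats::wilcox.test(per_group[[reference]], per_group[[g]],
                           exact = FALSE)$p.value
      }, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  list(means = means, tests = tests)
}

#' Derive the high-confidence target-gene set
#'
#' Intersects the genes linked to a region group with the genes called
#' significantly up-regulated on the array.
#'
#' @param group_genes Character vector of gene ids linked to the group.
#' @param de Gene-level DE table.
#' @return List of class `target_gene_set`: `genes` (sorted ids) and
#'   `provenance` (`group_gene_count`, `up_gene_count`,
#'   `intersection_count`).
#' @export
derive_target_set <- function(group_genes, de) {
  up <- de$gene_id[de$significant & de$direction == "up"]
  genes <- sort(intersect(unique(group_genes), up))
  structure(list(genes = genes,
                 provenance = list(group_gene_count = length(unique(group_genes)),
                                   up_gene_count = length(up),
                                   intersection_count = length(genes))),
            class = "target_gene_set")
}

#' @export
print.target_gene_set <- function(x, ...) {
  p <- x$provenance
  cat("Target gene set:", p$intersection_count, "genes (",
      p$group_gene_count, "group genes ∩", p$up_gene_count,
      "up-regulated )\n")
  invisible(x)
}
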