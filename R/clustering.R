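# Signature-restricted hierarchical clustering of expression datasets.
# Distance between samples is 1 - Pearson correlation computed over the
# signature genes; agglomeration is average linkage; node support comes
# from an ordinary bootstrap that resamples signature genes with
# replacement and scores how often each original node's sample bipartition
# reappears.

#' Cluster samples by a gene signature
#'
#' @param expr Numeric matrix (genes x samples).
#' @param signature Character vector of signature gene ids, or a
#'   `target_gene_set` from [derive_target_set()].
#' @param k Number of clusters to cut (>= 2).
#' @param n_boot Bootstrap replicates for node support (0 skips the
#'   bootstrap; the rest of the result is then fully deterministic).
#' @param seed Integer RNG seed for the bootstrap.
#' @return An object of class `cluster_result`: `hclust` (the merge tree),
#'   `k`, `labels` (cluster id per sample), `bootstrap_support` (per
#'   internal node, in merge order), `signature_used`,
#'   `signature_missing`, `n_boot`, `seed`.
#' @export
cluster_by_signature <- function(expr, signature, k, n_boot = 100,
                                 seed = 1) {
  if (inherits(signature, "target_gene_set")) signature <- signature$genes
  stopifnot(k >= 2, n_boot >= 0)
  expr <- as.matrix(expr)
  present <- intersect(signature, rownames(expr))
  missing <- setdiff(signature, rownames(expr))
  if (length(present) < 2) {
    stop("fewer than 2 signature genes present in the matrix; missing: ",
         paste(missing, collapse = ", "))
  }
  sub <- expr[present, , drop = FALSE]
  hc <- correlation_hclust(sub)
  labels <- stats::cutree(hc, k = k)

  support <- rep(NA_real_, nrow(hc$merge))
  if (n_boot > 0) {
    orig_keys <- bipartition_keys(hc)
    hits <- numeric(length(orig_keys))
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        idx <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
        bhc <- correlation_hclust(sub[idx, , drop = FALSE])
        bkeys <- bipartition_keys(bhc)
        hits <- hits + (orig_keys %in% bkeys)
      }
    })
    support <- hits / n_boot
  }
  structure(list(hclust = hc, k = k, labels = labels,
                 bootstrap_support = support,
                 signature_used = present, signature_missing = missing,
                 n_boot = n_boot, seed = seed),
            class = "cluster_result")
}

correlation_hclust <- function(sub) {
  cm <- suppressWarnings(stats::cor(sub))
  if (anyNA(cm)) {
    # a zero-variance sample over the (resampled) signature: treat as
    # uncorrelated rather than aborting the replicate
    cm[is.na(cm)] <- 0
    diag(cm) <- 1
  }
  stats::hclust(stats::as.dist(1 - cm), method = "average")
}

# canonical key of each internal node's sample bipartition: the lexicually
# smaller of (clade tips, complement tips), both sorted
bipartition_keys <- function(hc) {
  tips <- hc$labels
  members <- clade_members(hc)
  vapply(members, function(m) {
    a <- paste(sort(tips[m]), collapse = "|")
    b <- paste(sort(tips[-m]), collapse = "|")
    if (a < b) a else b
  }, character(1))
}

clade_members <- function(hc) {
  m <- hc$merge
  out <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    l <- if (m[i, 1] < 0) -m[i, 1] else out[[m[i, 1]]]
    r <- if (m[i, 2] < 0) -m[i, 2] else out[[m[i, 2]]]
    out[[i]] <- sort(c(l, r))
  }
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Signature clustering:", length(x$labels), "samples,",
      length(x$signature_used), "signature genes, k =", x$k, "\n")
  print(table(cluster = x$labels))
  if (x$n_boot > 0) {
    cat("bootstrap node support (", x$n_boot, " replicates): median ",
        round(stats::median(x$bootstrap_support), 2), "\n", sep = "")
  }
  invisible(x)
}

#' Summarise cluster sizes, marker expression and label composition
#'
#' @param result A `cluster_result`.
#' @param expr The expression matrix the clustering used.
#' @param metadata data.frame with `sample_id` and categorical label
#'   columns (karyotype, FAB, cell type, ...), covering all samples.
#' @param marker_gene Optional gene whose per-cluster mean expression is
#'   reported (e.g. the inducing factor); absent from the matrix ->
#'   warning, no marker field.
#' @return List of class `cluster_summary`: `sizes`, `marker` (gene,
#'   per-cluster means, `argmax_cluster`) and `composition` (data.frame
#'   label, value, cluster, count, fraction-of-value-total).
#' @export
summarize_clusters <- function(result, expr, metadata, marker_gene = NULL) {
  labels <- result$labels
  samples <- names(labels)
  if (!all(samples %in% metadata$sample_id)) {
    stop("metadata does not cover all clustered samples")
  }
  md <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  sizes <- table(cluster = labels)

  marker <- NULL
  if (!is.null(marker_gene)) {
    if (!marker_gene %in% rownames(expr)) {
      warning("marker gene ", marker_gene, " absent from the matrix")
    } else {
      mm <- tapply(as.numeric(expr[marker_gene, samples]), labels, mean)
      marker <- list(gene = marker_gene, means = mm,
                     argmax_cluster = as.integer(names(which.max(mm))))
    }
  }

  label_cols <- setdiff(names(md), "sample_id")
  comp <- do.call(rbind, lapply(label_cols, function(lc) {
    tab <- table(value = md[[lc]], cluster = labels)
    totals <- rowSums(tab)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    df$label <- lc
    df$count <- df$Freq
    df$fraction <- df$Freq / totals[df$value]
    df[, c("label", "value", "cluster", "count", "fraction")]
  }))
  structure(list(sizes = sizes, marker = marker, composition = comp),
            class = "cluster_summary")
}

#' Enrichment of one label value in one cluster
#'
#' Reports how many of all samples carrying `label_value` fall in
#' `cluster_id`, as count/total and a percent rounded to 1 decimal.
#'
#' @param labels Cluster labels named by sample (or a `cluster_result`).
#' @param metadata data.frame with `sample_id` and the label column.
#' @param label_col Name of the label column.
#' @param label_value Label value of interest.
#' @param cluster_id Cluster of interest.
#' @return List: `count`, `total`, `percent`.
#' @export
label_enrichment_fraction <- function(labels, metadata, label_col,
                                      label_value, cluster_id) {
  if (inherits(labels, "cluster_result")) labels <- labels$labels
  if (!label_col %in% names(metadata)) {
    stop("unknown label column: ", label_col)
  }
  md <- metadata[match(names(labels), metadata$sample_id), , drop = FALSE]
  has <- md[[label_col]] == label_value
  if (!any(has)) stop("label value not present in metadata: ", label_value)
  count <- sum(has & labels == cluster_id)
  total <- sum(has)
  list(count = count, total = total, percent = round(100 * count / total, 1))
}

#' Write a cluster dendrogram as Newick with support node labels
#'
#' @param result A `cluster_result`.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_newick <- function(result, path) {
  phy <- ape::as.phylo(result$hclust)
  keys <- bipartition_keys(result$hclust)
  sup <- result$bootstrap_support
  # map hclust merge nodes to phylo internal nodes via their tip sets
  ntip <- length(phy$tip.label)
  node_tips <- phylo_node_tips(phy)
  phy$node.label <- vapply(seq_along(node_tips), function(j) {
    tipset <- sort(phy$tip.label[node_tips[[j]]])
    a <- paste(tipset, collapse = "|")
    b <- paste(sort(setdiff(phy$tip.label, tipset)), collapse = "|")
    key <- if (a < b) a else b
    i <- match(key, keys)
    if (is.na(i) || is.na(sup[i])) "" else format(sup[i], digits = 3)
  }, character(1))
  ape::write.tree(phy, file = path)
  invisible(path)
}

phylo_node_tips <- function(phy) {
  ntip <- length(phy$tip.label)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  tips <- vector("list", phy$Nnode)
  descend <- function(node) {
    if (node <= ntip) return(node)
    got <- tips[[node - ntip]]
    if (!is.null(got)) return(got)
    res <- unlist(lapply(children[[as.character(node)]], descend))
    tips[[node - ntip]] <<- res
    res
  }
  descend(ntip + 1L)
  tips
}
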