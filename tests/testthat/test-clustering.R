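well_separated_cohort <- function(seed, n_samples = 24, k = 2) {
  generate_labeled_cohort(n_samples = n_samples, n_clusters = k,
                          signature_genes = sprintf("s%02d", 1:40),
                          separation = 5, seed = seed, noise_sd = 0.5)
}

test_that("well-separated planted clusters are recovered exactly with
           confident support at the planted split", {
  co <- well_separated_cohort(seed = 61)
  cl <- cluster_by_signature(co$expr, sprintf("s%02d", 1:40), k = 2,
                             n_boot = 60, seed = 1)
  expect_equal(ari(cl$labels, co$truth$cluster_labels), 1)

  # the internal node carrying the two-cluster bipartition is stable
  keys <- peaksig:::bipartition_keys(cl$hclust)
  side <- names(cl$labels)[cl$labels == 1]
  other <- names(cl$labels)[cl$labels == 2]
  a <- paste(sort(side), collapse = "|")
  b <- paste(sort(other), collapse = "|")
  split_key <- if (a < b) a else b
  node <- match(split_key, keys)
  expect_false(is.na(node))
  expect_gte(cl$bootstrap_support[node], 0.95)
})

test_that("zero separation yields no recoverable structure", {
  aris <- vapply(1:20, function(s) {
    co <- generate_labeled_cohort(n_samples = 24, n_clusters = 2,
                                  signature_genes = sprintf("s%02d", 1:40),
                                  separation = 0, seed = 100 + s,
                                  noise_sd = 1)
    cl <- cluster_by_signature(co$expr, sprintf("s%02d", 1:40), k = 2,
                               n_boot = 0)
    ari(cl$labels, co$truth$cluster_labels)
  }, numeric(1))
  expect_lt(mean(aris), 0.1)
})

test_that("duplicated samples always co-cluster", {
  co <- well_separated_cohort(seed = 62, n_samples = 10)
  expr <- co$expr
  dup <- expr[, rep(seq_len(ncol(expr)), each = 2)]
  colnames(dup) <- paste0(rep(colnames(expr), each = 2), c("_a", "_b"))
  cl <- cluster_by_signature(dup, sprintf("s%02d", 1:40), k = 5, n_boot = 0)
  pairs <- matrix(cl$labels, nrow = 2)
  expect_true(all(pairs[1, ] == pairs[2, ]))
})

test_that("clustering is invariant to per-sample affine rescaling", {
  co <- well_separated_cohort(seed = 63)
  cl1 <- cluster_by_signature(co$expr, sprintf("s%02d", 1:40), k = 2,
                              n_boot = 0)
  scaled <- sweep(co$expr, 2, runif(ncol(co$expr), 0.5, 2), `*`)
  scaled <- sweep(scaled, 2, runif(ncol(co$expr), -3, 3), `+`)
  cl2 <- cluster_by_signature(scaled, sprintf("s%02d", 1:40), k = 2,
                              n_boot = 0)
  expect_equal(ari(cl1$labels, cl2$labels), 1)
})

test_that("with n_boot = 0 the result is deterministic and missing
           signature genes are tolerated down to two", {
  co <- well_separated_cohort(seed = 64)
  sig <- c(sprintf("s%02d", 1:40), "absent_1", "absent_2")
  cl1 <- cluster_by_signature(co$expr, sig, k = 2, n_boot = 0)
  cl2 <- cluster_by_signature(co$expr, sig, k = 2, n_boot = 0)
  expect_identical(cl1$labels, cl2$labels)
  expect_identical(cl1$hclust$merge, cl2$hclust$merge)
  expect_setequal(cl1$signature_missing, c("absent_1", "absent_2"))

  expect_error(cluster_by_signature(co$expr, c("absent_1", "absent_2", "s01"),
                                    k = 2),
               "fewer than 2 signature genes")
})

test_that("cluster summaries report sizes, marker argmax and label
           fractions that sum to one", {
  lt <- matrix(c(10, 1, 1, 10), nrow = 2,
               dimnames = list(NULL, c("kA", "kB")))
  co <- generate_labeled_cohort(n_samples = 30, n_clusters = 2,
                                signature_genes = sprintf("s%02d", 1:40),
                                separation = 5, label_table = lt,
                                seed = 65, noise_sd = 0.5,
                                marker_gene = "Spi1",
                                marker_means = c(2, 8))
  cl <- cluster_by_signature(co$expr, sprintf("s%02d", 1:40), k = 2,
                             n_boot = 0)
  sm <- summarize_clusters(cl, co$expr, co$metadata, marker_gene = "Spi1")
  expect_identical(sum(sm$sizes), 30L)
  # marker-high planted cluster is the argmax cluster
  truth_marker_cluster <- cl$labels[names(which(
    co$truth$cluster_labels == 2))][1]
  expect_identical(sm$marker$argmax_cluster,
                   as.integer(truth_marker_cluster))
  sums <- tapply(sm$composition$fraction, sm$composition$value, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  expect_warning(summarize_clusters(cl, co$expr, co$metadata,
                                    marker_gene = "nope"), "absent")
})

test_that("label enrichment reproduces printed-style percentages", {
  labels <- stats::setNames(c(rep(1, 40), rep(2, 30), rep(3, 30)),
                            sprintf("s%03d", 1:100))
  karyo <- rep("other", 100)
  karyo[c(1:21, 45, 46)] <- "t_15_17"          # 21 of 23 in cluster 1
  md <- data.frame(sample_id = sprintf("s%03d", 1:100), karyotype = karyo,
                   stringsAsFactors = FALSE)
  enr <- label_enrichment_fraction(labels, md, "karyotype", "t_15_17", 1)
  expect_identical(enr$count, 21L)
  expect_identical(enr$total, 23L)
  expect_equal(enr$percent, 91.3)

  karyo2 <- rep("other", 100)
  karyo2[c(1:20, 41:55)] <- "t_8_21"           # 20 of 35 in cluster 1
  md2 <- data.frame(sample_id = sprintf("s%03d", 1:100), karyotype = karyo2,
                    stringsAsFactors = FALSE)
  enr2 <- label_enrichment_fraction(labels, md2, "karyotype", "t_8_21", 1)
  expect_equal(enr2$percent, 57.1)

  # label absent from a cluster: 0.0%
  expect_equal(label_enrichment_fraction(labels, md, "karyotype",
                                         "t_15_17", 3)$percent, 0)
  expect_error(label_enrichment_fraction(labels, md, "nope", "x", 1),
               "unknown label")
})

test_that("the Newick export carries tips and support labels", {
  co <- well_separated_cohort(seed = 66, n_samples = 12)
  cl <- cluster_by_signature(co$expr, sprintf("s%02d", 1:40), k = 2,
                             n_boot = 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cl, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, names(cl$labels))
  expect_true(any(suppressWarnings(as.numeric(phy$node.label)) >= 0.95,
                  na.rm = TRUE))
})
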