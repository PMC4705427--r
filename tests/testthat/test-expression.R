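test_that("quantile normalisation equalises column distributions exactly", {
  set.seed(41)
  m <- matrix(rnorm(500 * 6, 8, 1), nrow = 500,
              dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:6)))
  m[, 4:6] <- m[, 4:6] + 0.5   # global shift to be removed
  qn <- quantile_normalize(m)
  ref <- sort(qn[, 1])
  for (j in 2:6) expect_equal(sort(qn[, j]), ref, ignore_attr = TRUE)
  expect_identical(dimnames(qn), dimnames(m))
})

test_that("identical conditions yield no significant probes", {
  set.seed(42)
  half <- matrix(rnorm(300 * 3, 8, 0.5), nrow = 300)
  m <- cbind(half, half)
  rownames(m) <- sprintf("g%03d", 1:300)
  de <- call_de(m, rep(c("minus", "plus"), each = 3))
  expect_identical(sum(de$significant), 0L)
})

test_that("the fold-change filter vetoes significant p-values below 1.2x", {
  set.seed(43)
  # strong but tiny shift: highly significant p, fold < 1.2
  n <- 40
  m <- matrix(rnorm(50 * 2 * n, 8, 0.05), nrow = 50)
  cond <- rep(c("minus", "plus"), each = n)
  m[1, cond == "plus"] <- m[1, cond == "plus"] + 0.1   # fold 2^0.1 = 1.07
  rownames(m) <- sprintf("g%02d", 1:50)
  de <- call_de(m, cond, normalize = FALSE)
  expect_lt(de$p_adj[1], 0.01)
  expect_false(de$significant[1])
})

test_that("planted effects are recovered with FDR-consistent false
           discoveries", {
  # with df = 4 the per-probe variance estimate is noisy, so a plain
  # (unmoderated) t-test leaves the weakest-variance draws undetected;
  # ~75-80% recovery is the analytic expectation at these settings
  ex <- generate_expression_matrix(n_genes = 5000,
                                   n_samples_per_condition = 3,
                                   n_up_genes = 100, effect_log2fc = 1,
                                   noise_sd = 0.1, seed = 44)
  de <- call_de(ex$expr, ex$design$condition)
  called_up <- de$gene_id[de$significant & de$direction == "up"]
  expect_gte(length(intersect(called_up, ex$truth$de_gene_ids)), 70)
  false_pos <- setdiff(de$gene_id[de$significant], ex$truth$de_gene_ids)
  # BH at 5%: false discoveries should be a small minority of the calls
  expect_lte(length(false_pos), 0.1 * sum(de$significant))
  # more replicates restore near-complete recovery of the same effect
  ex10 <- generate_expression_matrix(n_genes = 5000,
                                     n_samples_per_condition = 10,
                                     n_up_genes = 100, effect_log2fc = 1,
                                     noise_sd = 0.1, seed = 44)
  de10 <- call_de(ex10$expr, ex10$design$condition)
  up10 <- de10$gene_id[de10$significant & de10$direction == "up"]
  expect_gte(length(intersect(up10, ex10$truth$de_gene_ids)), 99)
})

test_that("a global-null permutation stays within the FDR guarantee", {
  set.seed(45)
  fracs <- replicate(60, {
    m <- matrix(rnorm(800 * 6, 8, 0.3), nrow = 800,
                dimnames = list(sprintf("g%03d", 1:800), NULL))
    cond <- sample(rep(c("minus", "plus"), each = 3))
    mean(call_de(m, cond)$significant)
  })
  expect_lte(mean(fracs), 0.05 + 3 * sqrt(0.05 * 0.95 / 800))
})

test_that("detection-p filtering drops only all-undetected probes", {
  set.seed(46)
  m <- matrix(rnorm(20 * 6, 8, 0.2), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  det <- matrix(0, nrow = 20, ncol = 6)
  det[3, ] <- 0.5           # undetected everywhere -> dropped
  det[4, 1] <- 0.5          # undetected in one sample -> kept
  de <- call_de(m, rep(c("minus", "plus"), each = 3), detection_p = det)
  expect_false("g03" %in% de$gene_id)
  expect_true("g04" %in% de$gene_id)
})

test_that("probe collapse keeps the most significant probe per gene", {
  de <- data.frame(gene_id = c("p1", "p2", "p3"),
                   log2fc = c(1, 2, 0.5),
                   p_raw = c(0.01, 0.001, 0.2),
                   p_adj = c(0.02, 0.003, 0.4),
                   significant = c(TRUE, TRUE, FALSE),
                   direction = "up", stringsAsFactors = FALSE)
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("gX", "gX", "gY"),
                    stringsAsFactors = FALSE)
  out <- collapse_probes(de, map)
  expect_identical(out$gene_id, c("gX", "gY"))
  expect_equal(out$log2fc[out$gene_id == "gX"], 2)
})

test_that("group response separates a planted Group I signal and stays
           null otherwise", {
  set.seed(47)
  null_de <- function(n) data.frame(
    gene_id = sprintf("g%04d", 1:n),
    log2fc = rnorm(n, 0, 0.3), p_raw = 0.01, p_adj = 0.01,
    significant = TRUE, direction = "up", stringsAsFactors = FALSE)

  # same null for all groups: non-significant contrast in >= 95% of seeds
  pvals <- replicate(40, {
    de <- null_de(300)
    gg <- list(I = sprintf("g%04d", 1:100),
               II = sprintf("g%04d", 101:200),
               III = sprintf("g%04d", 201:300))
    min(group_expression_response(de, gg)$tests$p_value)
  })
  expect_gte(mean(pvals > 0.01), 0.95)

  # planted 1.8x in Group I genes
  de <- null_de(300)
  de$log2fc[1:100] <- rnorm(100, log2(1.8), 0.1)
  gg <- list(I = sprintf("g%04d", 1:100), II = sprintf("g%04d", 101:200),
             III = sprintf("g%04d", 201:300))
  res <- group_expression_response(de, gg)
  m <- res$means
  expect_gt(m$mean_fold_change[m$group == "I"],
            max(m$mean_fold_change[m$group != "I"]))
  expect_true(all(res$tests$p_value < 1e-3))

  # a gene shared between groups contributes to both means
  gg_shared <- list(I = "g0001", II = "g0001")
  res2 <- group_expression_response(de, gg_shared)
  expect_equal(res2$means$mean_fold_change[1],
               res2$means$mean_fold_change[2])
})

test_that("the target set is the exact intersection with up-regulated
           genes", {
  de <- data.frame(gene_id = sprintf("g%02d", 1:20),
                   log2fc = c(rep(1, 10), rep(-1, 10)),
                   p_raw = 0.001, p_adj = c(rep(0.01, 15), rep(0.5, 5)),
                   significant = c(rep(TRUE, 10), rep(TRUE, 5), rep(FALSE, 5)),
                   direction = c(rep("up", 10), rep("down", 10)),
                   stringsAsFactors = FALSE)
  ts <- derive_target_set(sprintf("g%02d", 6:12), de)
  expect_identical(ts$genes, sprintf("g%02d", 6:10))  # up & significant only
  expect_identical(ts$provenance$intersection_count, 5L)
  expect_identical(ts$provenance$group_gene_count, 7L)

  empty <- derive_target_set(c("zz1", "zz2"), de)
  expect_length(empty$genes, 0)

  # always a subset of both inputs
  set.seed(48)
  for (i in 1:10) {
    gg <- sample(de$gene_id, 8)
    ts_i <- derive_target_set(gg, de)
    up <- de$gene_id[de$significant & de$direction == "up"]
    expect_true(all(ts_i$genes %in% gg))
    expect_true(all(ts_i$genes %in% up))
    expect_identical(sort(ts_i$genes), sort(intersect(gg, up)))
  }
})
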