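test_that("fold_change evaluates the pseudocounted ratio", {
  expect_equal(fold_change(10, 10, 1), 1)
  expect_equal(fold_change(0, 0, 1), 1)
  expect_equal(fold_change(3, 15, 1), 4)
  expect_true(all(is.finite(fold_change(c(0, 5, 1e6), c(1e6, 0, 0)))))
})

test_that("threshold object enforces its invariants", {
  expect_error(group_thresholds(fc_tf_min = 0), "> 0")
  expect_error(group_thresholds(no_change_band = 4, fc_tf_min = 4),
               "no_change_band")
})

test_that("the three-criterion cascade reproduces the printed examples", {
  cov <- make_cov(norm_tf_minus = c(10, 10, 50),
                  norm_tf_plus = c(80, 80, 55),
                  norm_hist_minus = c(20, 100, 10),
                  norm_hist_plus = c(160, 110, 10),
                  raw_hist_plus = c(160, 110, 10))
  res <- classify_regions(cov)
  expect_identical(res$group, c("I", "II", "III"))
  expect_identical(unname(as.integer(attr(res, "sizes"))),
                   c(1L, 1L, 1L, 0L))
})

test_that("groups are mutually exclusive and invariant to relabelling and
           common library rescaling", {
  set.seed(14)
  n <- 400L
  cov <- make_cov(norm_tf_minus = runif(n, 0, 100),
                  norm_tf_plus = runif(n, 0, 400),
                  norm_hist_minus = runif(n, 0, 100),
                  norm_hist_plus = runif(n, 0, 400),
                  raw_hist_plus = rpois(n, 60))
  res <- classify_regions(cov)
  expect_identical(sum(as.integer(attr(res, "sizes"))), n)

  shuffled <- cov[sample.int(n), ]
  res2 <- classify_regions(shuffled)
  expect_identical(table(res$group), table(res2$group))

  # rescaling both conditions' normalised scores by one factor would mean
  # a common library-size change; only fold changes with pseudocounts can
  # move, so rescale the pseudocount identically to confirm exact
  # invariance of the pure ratio criterion
  scaled <- cov
  for (cl in grep("^norm_", names(cov), value = TRUE)) {
    scaled[[cl]] <- cov[[cl]] * 2
  }
  th2 <- group_thresholds(pseudocount = 2)
  res3 <- classify_regions(scaled, thresholds = th2)
  expect_identical(res$group, res3$group)
})

test_that("missing assay columns raise a configuration error", {
  cov <- make_cov(1, 2, 3, 4, 5)
  cov$norm_h3k27ac_plus <- NULL
  expect_error(classify_regions(cov), "norm_h3k27ac_plus")
})

test_that("classification recovers planted labels: exactly on noise-free
           means, >= 99% under Poisson noise", {
  # noise-free: use the planted means directly as counts
  n <- c(I = 60, II = 60, III = 60)
  grp <- rep(names(n), n)
  tfm <- rep(40, sum(n)); tfp <- ifelse(grp %in% c("I", "II"), 320, 40)
  hm <- rep(40, sum(n)); hp <- ifelse(grp == "I", 320, 40)
  cov <- make_cov(tfm, tfp, hm, hp, raw_hist_plus = hp)
  expect_identical(classify_regions(cov)$group, grp)

  # Poisson noise end-to-end through read counting
  b <- generate_binding_experiment(
    n_regions_per_group = c(I = 150, II = 150, III = 150), depth = 30,
    fold_pu1 = 8, fold_h3k27ac = 8, seed = 15, genome_size = 4e6)
  regions <- merge_two_condition_peaks(b$peaks$pu1$minus, b$peaks$pu1$plus)
  cov <- coverage_matrix(regions, b$reads)
  called <- classify_regions(cov)
  truth_id <- match_planted_regions(b$regions, regions)
  called_grp <- called$group[match(truth_id, called$region_id)]
  expect_gte(mean(called_grp == b$truth$group), 0.99)
})

test_that("global binding summary counts the Venn partition and the mean
           per-region fold", {
  far_read <- gr0("chr1", 9000, 9050)   # keeps library size positive
  a <- gr0("chr1", c(0, 1000, 2000), c(100, 1100, 2100))
  m <- merge_two_condition_peaks(a, a)
  cov <- coverage_matrix(m, list(pu1_minus = far_read,
                                 pu1_plus = far_read),
                         histone_assays = character(0))
  s <- global_binding_summary(cov, m)
  expect_identical(s[c("n_new", "n_lost")], list(n_new = 0L, n_lost = 0L))
  expect_identical(s$n_shared, 3L)
  expect_equal(s$mean_fold_increase, 1)  # no reads in regions: all folds 1

  b <- gr0("chr1", c(1050, 5000), c(1150, 5100))
  m2 <- merge_two_condition_peaks(a, b)
  cov2 <- coverage_matrix(m2, list(pu1_minus = far_read,
                                   pu1_plus = far_read),
                          histone_assays = character(0))
  s2 <- global_binding_summary(cov2, m2)
  expect_identical(s2$n_shared, 1L)   # a2 and b1 merge
  expect_identical(s2$n_new, 1L)      # chr1:5000 only in b
  expect_identical(s2$n_lost, 2L)     # a1, a3 only in a
})

test_that("planted eightfold induction yields a mean Group I fold near 8", {
  b <- generate_binding_experiment(
    n_regions_per_group = c(I = 200, II = 10, III = 10), depth = 100,
    fold_pu1 = 8, fold_h3k27ac = 8, seed = 16, genome_size = 4e6)
  regions <- merge_two_condition_peaks(b$peaks$pu1$minus, b$peaks$pu1$plus)
  cov <- coverage_matrix(regions, b$reads)
  truth_id <- match_planted_regions(b$regions, regions)
  i_rows <- match(truth_id[b$truth$group == "I"], cov$region_id)
  fc <- fold_change(cov$norm_pu1_minus[i_rows], cov$norm_pu1_plus[i_rows])
  expect_lt(abs(mean(fc) - 8) / 8, 0.05)
})

test_that("TF-histone correlation: identity gives r = 1, independence
           stays near 0, coupling stays high", {
  base <- make_cov(norm_tf_minus = rep(10, 100),
                   norm_tf_plus = 10 * 2^seq(0, 3, length.out = 100),
                   norm_hist_minus = rep(10, 100),
                   norm_hist_plus = 10 * 2^seq(0, 3, length.out = 100),
                   raw_hist_plus = rep(100, 100))
  expect_equal(tf_histone_correlation(base)$r, 1, tolerance = 1e-6)

  set.seed(17)
  r_null <- replicate(50, {
    n <- 2000
    cov <- make_cov(rpois(n, 50), rpois(n, 50), rpois(n, 50),
                    rpois(n, 50), rpois(n, 50))
    abs(tf_histone_correlation(cov)$r)
  })
  expect_lt(unname(quantile(r_null, 0.95)), 0.05)

  set.seed(18)
  mu <- exp(rnorm(1000, 3, 1))
  cov <- make_cov(rpois(1000, 50), rpois(1000, 50 * mu),
                  rpois(1000, 50), rpois(1000, 50 * mu),
                  rpois(1000, 100))
  expect_gte(tf_histone_correlation(cov)$r, 0.9)
})

test_that("zero-variance fold vectors report an undefined correlation", {
  cov <- make_cov(rep(10, 5), rep(10, 5), c(1, 5, 2, 8, 3),
                  c(9, 2, 4, 1, 7), rep(10, 5))
  expect_warning(res <- tf_histone_correlation(cov), "zero-variance")
  expect_true(is.na(res$r))
})
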