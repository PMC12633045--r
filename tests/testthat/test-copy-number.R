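test_that("read-depth estimator is linear through the reference", {
  # sample RPM equal to reference RPM -> the reference copy number
  expect_equal(estimate_from_reads(5000, 1e6, 5000, 1e6), 1100)
  expect_equal(estimate_from_reads(0, 1e6, 5000, 1e6), 0)
  expect_equal(estimate_from_reads(2500, 1e6, 5000, 1e6), 550)
  # linearity under library-size differences
  expect_equal(estimate_from_reads(1000, 2e6, 5000, 1e7), 1100)
  expect_error(estimate_from_reads(10, 0, 5000, 1e6), "positive")
  expect_error(estimate_from_reads(10, 1e6, 0, 1e6), "positive")
})

test_that("blot estimator scales signal ratios to the reference", {
  expect_equal(estimate_from_blot(2, 1, ref_ratio = 2), 1100)
  expect_equal(estimate_from_blot(0, 1, ref_ratio = 2), 0)
  expect_equal(estimate_from_blot(4, 1, ref_ratio = 2), 2200)
  # triplicates averaged at the ratio level; bad control slots excluded
  expect_equal(estimate_from_blot(c(2, 4, 99), c(1, 2, 0), ref_ratio = 2),
               1100)
  expect_true(is.na(estimate_from_blot(c(1, 1), c(0, 0), ref_ratio = 2)))
  expect_error(estimate_from_blot(1, 1, ref_ratio = 0), "positive")
})

test_that("standard curve refits its own generating line exactly", {
  masses <- c(190, 19, 1.9, 0.19, 0.019)
  slope_true <- -1 / log10(2)  # perfect doubling chemistry, -3.3219
  ct <- 24 + slope_true * log10(masses)
  curve <- fit_standard_curve(masses, ct)
  expect_equal(curve$slope, slope_true, tolerance = 1e-10)
  expect_equal(curve$intercept, 24, tolerance = 1e-10)
  expect_equal(curve$r2, 1)
  expect_error(fit_standard_curve(rep(1.9, 5), ct), "degenerate")
  expect_error(fit_standard_curve(masses[1:2], ct[1:2]), "at least 3")
})

test_that("noisy standard curves recover the true slope within its CI", {
  masses <- c(190, 19, 1.9, 0.19, 0.019)
  slope_true <- -1 / log10(2)
  set.seed(41)
  hits <- vapply(1:200, function(i) {
    ct <- 24 + slope_true * log10(masses) + rnorm(5, sd = 0.3)
    fit <- lm(ct ~ log10(masses))
    ci <- confint(fit)[2, ]
    curve <- fit_standard_curve(masses, ct)
    expect_equal(curve$slope, unname(coef(fit)[2]))
    ci[1] <= slope_true && slope_true <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.9)  # nominal 95% coverage
})

test_that("qPCR quantification inverts the dilution chemistry", {
  masses <- c(190, 19, 1.9, 0.19, 0.019)
  ct <- 24 - log10(masses) / log10(2)
  curve <- fit_standard_curve(masses, ct)
  ct_ref <- 24 - log10(1.9) / log10(2)
  # sample indistinguishable from the reference input -> reference copies
  expect_equal(quantify_qpcr(ct_ref, curve, 1.9), 1100, tolerance = 1e-8)
  # one perfect-efficiency cycle earlier: twice the template
  expect_equal(quantify_qpcr(ct_ref - 1, curve, 1.9), 2200, tolerance = 1e-6)
  # unamplifiable sample
  expect_equal(quantify_qpcr(Inf, curve, 1.9), 0)
  bad <- curve
  bad$slope <- 0
  expect_error(quantify_qpcr(30, bad, 1.9), "non-zero")
})

test_that("PCA composite handles rank-1, isotropic and sign-flip cases", {
  # perfectly collinear estimates: PC1 carries all the variance
  x <- rnorm(20, 1000, 300)
  m <- cbind(a = x, b = 2 * x, c = 0.5 * x)
  rownames(m) <- paste0("s", 1:20)
  res <- integrate_pca(m)
  expect_equal(res$var_explained[1], 1)
  expect_equal(sum(res$var_explained), 1)
  expect_true(all(diff(res$var_explained) <= 1e-12))
  # independent equal-variance columns: each component near 1/3
  set.seed(7)
  m2 <- matrix(rnorm(3 * 3000), ncol = 3,
               dimnames = list(paste0("s", 1:3000), c("a", "b", "c")))
  res2 <- integrate_pca(m2)
  expect_true(all(abs(res2$var_explained - 1 / 3) < 0.05))
  # flipping all inputs leaves |scores| unchanged; the k rule restores sign
  k <- setNames(x / 1000 + rnorm(20, sd = 0.01), rownames(m))
  m_noisy <- m + rnorm(60, sd = 20)
  r1 <- integrate_pca(m_noisy, k)
  r2 <- integrate_pca(-m_noisy, k)
  expect_equal(abs(r1$scores), abs(r2$scores), tolerance = 1e-8)
  expect_gt(cor(r1$scores, k[names(r1$scores)]), 0)
  expect_gt(cor(r2$scores, k[names(r2$scores)]), 0)
  expect_error(integrate_pca(m[1:2, ]), "at least 3")
})

test_that("noiseless assays are inverted exactly by every quantifier", {
  p <- simulate_panel(noiseless_config())
  prof <- copy_number_profiles(p$reads, p$blot, p$qpcr, p$standards)
  i <- match(p$truth$strain, prof$strain)
  expect_equal(prof$est_illumina[i], p$truth$true_copies, tolerance = 1e-9)
  expect_equal(prof$est_blot[i], p$truth$true_copies, tolerance = 1e-9)
  expect_equal(prof$est_qpcr[i], p$truth$true_copies, tolerance = 1e-9)
})

test_that("estimates regress on truth with slope 1 at moderate noise", {
  # noise is multiplicative, so recovery is tested on the log scale where
  # it is homoskedastic: the power-law exponent of est vs truth must be 1.
  # Slopes are averaged over independent panels and tested against 1 at
  # 3 standard errors of that mean.
  slopes <- sapply(13:18, function(s) {
    cfg <- sim_config(n_strains = 90, noise_illumina = 0.1, noise_blot = 0.1,
                      noise_qpcr = 0.1, n_snps = 10, seed = s)
    p <- simulate_panel(cfg)
    prof <- copy_number_profiles(p$reads, p$blot, p$qpcr, p$standards)
    i <- match(p$truth$strain, prof$strain)
    vapply(c("est_illumina", "est_blot", "est_qpcr"), function(col) {
      unname(coef(lm(log(prof[[col]][i]) ~ log(p$truth$true_copies)))[2])
    }, numeric(1))
  })
  for (r in rownames(slopes)) {
    se <- sd(slopes[r, ]) / sqrt(ncol(slopes))
    expect_lt(abs(mean(slopes[r, ]) - 1), 3 * se + 0.01)
  }
})

test_that("assay estimates agree across methods as on the real panel", {
  cfg <- sim_config(n_strains = 90, seed = 13L)
  p <- simulate_panel(cfg)
  prof <- copy_number_profiles(p$reads, p$blot, p$qpcr, p$standards)
  # strong positive rank correlation between the three methods
  expect_gt(cor(prof$est_illumina, prof$est_blot, method = "spearman",
                use = "complete.obs"), 0.6)
  expect_gt(cor(prof$est_illumina, prof$est_qpcr, method = "spearman",
                use = "complete.obs"), 0.6)
  expect_gt(cor(prof$est_blot, prof$est_qpcr, method = "spearman",
                use = "complete.obs"), 0.6)
})

test_that("profiles propagate missing assays and flag sensitivity", {
  p <- simulate_panel(noiseless_config())
  qpcr <- p$qpcr[p$qpcr$strain != p$truth$strain[1], ]
  prof <- copy_number_profiles(p$reads, p$blot, qpcr, p$standards)
  r1 <- prof[prof$strain == p$truth$strain[1], ]
  expect_true(is.na(r1$est_qpcr))
  expect_true(is.na(r1$pc1))  # PC1 only for complete triplets
  expect_false(any(is.na(prof$pc1[!is.na(prof$est_qpcr)])))
  expect_identical(prof$sensitive,
                   unname(prof$est_illumina >= 100))
})
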