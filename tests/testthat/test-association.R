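make_snp_table <- function(n_sites, n_strains, seed = 1) {
  set.seed(seed)
  geno <- t(replicate(n_sites, rbinom(n_strains, 1, runif(1, 0.1, 0.5))))
  colnames(geno) <- paste0("s", seq_len(n_strains))
  sites <- data.frame(site = paste0("snp", seq_len(n_sites)), chrom = "2L",
                      pos = seq_len(n_sites) * 1000,
                      stringsAsFactors = FALSE)
  rownames(geno) <- sites$site
  list(sites = sites, geno = geno)
}

test_that("site filters apply the frequency and missingness rules", {
  geno <- rbind(
    ok = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1),
    low_maf = c(rep(0, 9), 1),                  # maf 0.1 boundary: kept
    rare = c(rep(0, 10)),                       # monomorphic: removed
    miss = c(0, 1, NA, NA, 0, 1, 0, 1, 0, 1),   # 20% missing: removed
    edge_miss = c(0, 1, NA, 1, 0, 1, 0, 1, 0, 1))  # 10%: kept
  colnames(geno) <- paste0("s", 1:10)
  sites <- data.frame(site = rownames(geno), chrom = "X", pos = 1:5)
  f <- filter_sites(sites, geno, maf_min = 0.1, missing_max = 0.1)
  expect_setequal(f$sites$site, c("ok", "low_maf", "edge_miss"))
  # a site just under the frequency threshold is removed
  g2 <- matrix(c(rep(0, 91), rep(1, 9)), nrow = 1)  # maf 0.09
  colnames(g2) <- paste0("s", 1:100)
  s2 <- data.frame(site = "a", chrom = "X", pos = 1)
  expect_equal(nrow(filter_sites(s2, g2)$sites), 0)
})

test_that("Bonferroni thresholds scale with the retained site count", {
  tab <- make_snp_table(200, 30)
  y <- setNames(rnorm(30, 0.9, 0.05), colnames(tab$geno))
  sc <- assoc_scan(tab$sites, tab$geno, y)
  expect_equal(attr(sc, "genomewide_threshold"), 0.05 / 200)
  expect_equal(attr(sc, "suggestive_threshold"), 1 / 200)
  # at the study's scale the same rule gives the printed cutoff
  expect_equal(0.05 / 1283850, 3.895e-08, tolerance = 1e-3)
})

test_that("a constant phenotype yields no spurious associations", {
  tab <- make_snp_table(50, 20)
  y <- setNames(rep(0.8, 20), colnames(tab$geno))
  sc <- assoc_scan(tab$sites, tab$geno, y)
  expect_true(all(is.na(sc$p_g)))
  expect_true(all(abs(sc$beta_g) < 1e-12, na.rm = TRUE))
  expect_false(any(sc$pass_genomewide))
})

test_that("a planted large-effect site tops the scan and passes Bonferroni", {
  n <- 90
  tab <- make_snp_table(201, n, seed = 5)
  set.seed(6)
  g_causal <- tab$geno[201, ]
  y <- 0.55 + 0.4 * g_causal + rnorm(n, sd = 0.05)
  names(y) <- colnames(tab$geno)
  sc <- assoc_scan(tab$sites, tab$geno, y)
  expect_equal(which.min(sc$p_g), 201L)
  expect_true(sc$pass_genomewide[201])
  expect_gt(sc$beta_g[201], 0.3)
})

test_that("interaction model reports both effects and handles collinearity", {
  n <- 60
  tab <- make_snp_table(20, n, seed = 9)
  set.seed(10)
  cv <- setNames(rnorm(n, 1000, 300), colnames(tab$geno))
  g <- tab$geno[1, ]
  y <- setNames(0.6 + 0.1 * g + 2e-4 * cv + 3e-4 * g * cv + rnorm(n, 0.02),
                colnames(tab$geno))
  sc <- assoc_scan(tab$sites, tab$geno, y, covariate = cv,
                   model = "interaction")
  expect_true(all(c("beta_int", "p_int") %in% names(sc)))
  expect_false(is.na(sc$p_int[1]))
  # genotype collinear with the covariate: that site's p is missing
  cv2 <- setNames(as.numeric(tab$geno[2, ]), colnames(tab$geno))
  sc2 <- assoc_scan(tab$sites, tab$geno, y, covariate = cv2,
                    model = "interaction")
  expect_true(is.na(sc2$p_g[2]))
})

test_that("type-I error at nominal 0.05 stays within its binomial envelope", {
  n_sites <- 10000
  n <- 90
  set.seed(77)
  geno <- t(replicate(n_sites, rbinom(n, 1, runif(1, 0.1, 0.5))))
  colnames(geno) <- paste0("s", 1:n)
  sites <- data.frame(site = paste0("snp", 1:n_sites), chrom = "3L",
                      pos = 1:n_sites)
  y <- setNames(rnorm(n, 0.9, 0.1), colnames(geno))  # independent of geno
  sc <- assoc_scan(sites, geno, y)
  rate <- mean(sc$p_g < 0.05, na.rm = TRUE)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sites))
})

test_that("site order does not affect per-site results", {
  tab <- make_snp_table(80, 25, seed = 12)
  y <- setNames(rnorm(25, 0.85, 0.08), colnames(tab$geno))
  sc1 <- assoc_scan(tab$sites, tab$geno, y)
  set.seed(13)
  perm <- sample(80)
  sc2 <- assoc_scan(tab$sites[perm, ], tab$geno[perm, ], y)
  sc2 <- sc2[match(sc1$site, sc2$site), ]
  expect_equal(sc1$p_g, sc2$p_g)
  expect_equal(sc1$beta_g, sc2$beta_g)
})

test_that("copy-number covariate removes copies-mediated signal", {
  # panel with suppressors disabled isolates the copies -> k pathway;
  # pericentric tag sites associate strongly, and conditioning on the
  # composite copy estimate removes them from genome-wide significance
  cfg <- sim_config(seed = 11, p_sup_X = 0, p_sup_2 = 0, p_sup_3 = 0)
  p <- simulate_panel(cfg)
  est <- drive_estimates(p$crosses)
  dg <- est$design == "DGRP-X"
  kdg <- setNames(est$k[dg], est$strain[dg])
  flt <- filter_sites(p$snp_sites, p$snp_geno)
  sc0 <- assoc_scan(flt$sites, flt$geno, kdg)
  prof <- copy_number_profiles(p$reads, p$blot, p$qpcr, p$standards,
                               k_reference = kdg)
  pc1 <- setNames(prof$pc1, prof$strain)
  sc1 <- assoc_scan(flt$sites, flt$geno, kdg, covariate = pc1)
  tag <- flt$sites$class == "copy_tag"
  med0 <- median(-log10(sc0$p_g[tag]), na.rm = TRUE)
  med1 <- median(-log10(sc1$p_g[tag]), na.rm = TRUE)
  expect_gt(sum(sc0$pass_genomewide[tag]), 0)
  expect_equal(sum(sc1$pass_genomewide[tag]), 0)
  expect_lt(med1, med0)
})

test_that("QQ and Manhattan exports are well-formed", {
  # uniform null p-values hug the diagonal
  set.seed(30)
  n <- 2000
  rows <- data.frame(site = paste0("s", 1:n),
                     chrom = rep(c("2L", "2R"), each = n / 2),
                     pos = rep(seq_len(n / 2) * 100, 2),
                     p_g = runif(n))
  ex <- export_manhattan_qq(rows)
  ks <- ks.test(rows$p_g, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(max(abs(ex$qq$expected - ex$qq$observed)), 1)
  # cumulative coordinates strictly increase across the chromosome boundary
  expect_true(all(diff(ex$manhattan$cum_pos) > 0))
  # p = 1 maps to zero height
  one <- export_manhattan_qq(data.frame(site = "a", chrom = "X", pos = 5,
                                        p_g = 1))
  expect_equal(one$manhattan$neglog10p, 0)
})
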