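test_that("phenotype partition uses the strict 0.9 threshold", {
  part <- partition_phenotypes(c(0.55, 0.9, 0.95, 0.89, 1.0))
  expect_identical(part$suppressed, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(part$fraction_suppressed, 0.4)
  expect_error(partition_phenotypes(c(0.5, NA)), "defined")
})

test_that("noiseless recombinants map the locus to its flanking markers", {
  mp <- (1:15) * 1e6
  mm <- data.frame(marker = sprintf("m%02d", 1:15), chrom = "X", pos = mp)
  set.seed(55)
  n <- 200
  xo <- runif(n, min(mp), max(mp))
  ori <- runif(n) < 0.5
  gmat <- make_recombinants(xo, ori, mp)
  locus <- 7.4e6  # between markers 7 and 8
  sup <- ifelse(locus < xo, gmat[, 7] == "donor", gmat[, 8] == "donor")
  res <- map_interval(gmat, mm, sup)
  expect_equal(res$interval$start, 7e6)
  expect_equal(res$interval$end, 8e6)
  expect_equal(res$score, 0)
  expect_length(res$discordant, 0)
  expect_false(res$ambiguous)
})

test_that("planted discordant recombinants set the minimum score", {
  # 239 recombinants, locus between markers 11 and 12; flip 4 labels to
  # suppressed-without-locus and 3 to locus-without-suppression
  mp <- c(1.0, 2.5, 4.0, 5.5, 7.0, 8.5, 10.0, 11.5, 13.0, 14.5, 15.5,
          16.0, 17.5, 19.0, 21.0) * 1e6
  mm <- data.frame(marker = sprintf("m%02d", 1:15), chrom = "X", pos = mp)
  set.seed(99)
  n <- 239
  xo <- runif(n, min(mp), max(mp))
  ori <- runif(n) < 0.5
  gmat <- make_recombinants(xo, ori, mp)
  locus <- 15.8e6
  carrier <- ifelse(locus < xo, gmat[, 11] == "donor", gmat[, 12] == "donor")
  labels <- carrier
  flip_to_sup <- head(which(!carrier), 4)
  flip_to_unsup <- head(which(carrier), 3)
  labels[flip_to_sup] <- TRUE
  labels[flip_to_unsup] <- FALSE
  res <- map_interval(gmat, mm, labels)
  expect_equal(res$score, 7)
  expect_equal(res$interval$start, 15.5e6)
  expect_equal(res$interval$end, 16.0e6)
  expect_setequal(res$discordant, c(flip_to_sup, flip_to_unsup))
})

test_that("a single marker degenerates to an ambiguous tie", {
  gmat <- matrix(c("donor", "recipient", "donor"), ncol = 1)
  mm <- data.frame(marker = "m1", chrom = "X", pos = 5e6)
  res <- map_interval(gmat, mm, c(TRUE, FALSE, TRUE))
  expect_equal(res$score, 0)
  expect_true(res$ambiguous)
  expect_equal(res$interval$start, res$interval$end)
})

test_that("interval search matches the brute-force oracle", {
  set.seed(123)
  for (trial in 1:12) {
    n_mark <- sample(3:20, 1)
    n_rec <- sample(c(50, 200, 500), 1)
    mp <- sort(sample.int(22e6, n_mark))
    xo <- runif(n_rec, min(mp), max(mp))
    ori <- runif(n_rec) < 0.5
    gmat <- make_recombinants(xo, ori, mp)
    # noisy labels and missing genotypes
    locus <- runif(1, min(mp), max(mp))
    nearest_left <- findInterval(locus, mp)
    carrier <- ifelse(locus < xo, gmat[, max(nearest_left, 1)] == "donor",
                      gmat[, min(nearest_left + 1, n_mark)] == "donor")
    labels <- xor(carrier, runif(n_rec) < 0.1)
    gmat[matrix(runif(length(gmat)) < 0.05, nrow(gmat))] <- NA
    keep <- rowSums(!is.na(gmat)) > 0
    gmat <- gmat[keep, , drop = FALSE]
    labels <- labels[keep]
    mm <- data.frame(marker = paste0("m", seq_len(n_mark)), chrom = "X",
                     pos = mp)
    res <- map_interval(gmat, mm, labels)
    orc <- oracle_min_discordance(gmat, mp, labels)
    expect_equal(res$score, orc$min_score)
    # optimal placements found by the oracle lie inside the reported span
    expect_true(all(orc$argmin >= res$interval$start - 0.5 &
                      orc$argmin <= res$interval$end + 0.5))
  }
})

test_that("masking genotypes never raises the optimal score", {
  set.seed(321)
  mp <- (1:10) * 2e6
  mm <- data.frame(marker = paste0("m", 1:10), chrom = "X", pos = mp)
  xo <- runif(150, min(mp), max(mp))
  ori <- runif(150) < 0.5
  gmat <- make_recombinants(xo, ori, mp)
  labels <- xor(gmat[, 5] == "donor", runif(150) < 0.15)
  base <- map_interval(gmat, mm, labels)$score
  for (i in 1:10) {
    masked <- gmat
    masked[matrix(runif(length(gmat)) < i / 20, nrow(gmat))] <- NA
    keep <- rowSums(!is.na(masked)) > 0
    s <- map_interval(masked[keep, , drop = FALSE], mm,
                      labels[keep])$score
    expect_lte(s, base)
  }
})

test_that("segregation test is exact, symmetric and extreme-safe", {
  expect_equal(marker_segregation_test(133, 239),
               binom.test(133, 239, 0.5)$p.value)
  n <- 100
  expect_equal(marker_segregation_test(50, n), 1)
  expect_equal(marker_segregation_test(30, n),
               marker_segregation_test(70, n))
  expect_lt(marker_segregation_test(239, 239), 1e-60)
  expect_error(marker_segregation_test(5, 3), "invalid")
})

test_that("fertility comparison recovers a planted two-fold difference", {
  set.seed(44)
  n_off <- c(round(rnorm(120, 225, 50)), round(rnorm(110, 104, 50)))
  labels <- rep(c(TRUE, FALSE), c(120, 110))
  r <- fertility_compare(n_off, labels)
  expect_lt(abs(r$mean_suppressed - 225), 2 * 50 / sqrt(120))
  expect_lt(abs(r$mean_unsuppressed - 104), 2 * 50 / sqrt(110))
  expect_lt(r$p, 0.001)
  expect_gt(r$ratio, 1.8)
  # identical groups: no signal
  same <- fertility_compare(rep(c(100, 110), 10), rep(c(TRUE, FALSE), each = 10))
  expect_equal(same$ratio, 1)
  expect_gt(same$p, 0.9)
  expect_error(fertility_compare(1:5, rep(TRUE, 5)), "non-empty")
})

test_that("haplotype filter keeps only private focal-allele sites", {
  strains <- c("focal", "ref", paste0("free", 1:3), paste0("xsup", 1:4))
  sites <- data.frame(site = paste0("v", 1:6), chrom = "X",
                      pos = c(15.55e6, 15.6e6, 15.7e6, 15.8e6, 15.9e6, 17e6))
  geno <- matrix(0L, 6, length(strains), dimnames = list(sites$site, strains))
  geno["v1", "focal"] <- 1L                       # private to focal
  geno["v2", c("focal", "free2")] <- 1L           # leaks into suppressor-free
  geno["v3", c("focal", paste0("xsup", 1:4))] <- 1L  # tags all X-sup strains
  geno["v4", ] <- 0L                              # no difference from ref
  geno["v5", c("focal", "xsup1")] <- 1L
  geno["v6", c("focal", paste0("xsup", 1:4))] <- 1L  # outside the region
  region <- list(chrom = "X", start = 15.5e6, end = 16.0e6)
  r <- haplotype_filter(sites, geno, "focal", "ref", paste0("free", 1:3),
                        paste0("xsup", 1:4), region)
  expect_setequal(r$candidates$site, c("v1", "v3", "v5"))
  expect_equal(r$candidates$carrier_fraction[r$candidates$site == "v3"], 1)
  expect_equal(r$candidates$carrier_fraction[r$candidates$site == "v1"], 0)
  expect_true(r$shared_above_threshold)
  # without the fully shared haplotype sites the flag drops
  r2 <- haplotype_filter(sites[c(1, 5), ], geno[c("v1", "v5"), , drop = FALSE],
                         "focal", "ref", paste0("free", 1:3),
                         paste0("xsup", 1:4), region)
  expect_false(r2$shared_above_threshold)
  # empty region: no candidates, flag false
  r3 <- haplotype_filter(sites, geno, "focal", "ref", paste0("free", 1:3),
                         paste0("xsup", 1:4),
                         list(chrom = "X", start = 1, end = 2))
  expect_equal(nrow(r3$candidates), 0)
  expect_false(r3$shared_above_threshold)
  expect_error(haplotype_filter(sites, geno, "nope", "ref", "free1",
                                "xsup1", region), "absent")
})

test_that("intervals convert correctly to BED coordinates", {
  bed <- interval_to_bed(data.frame(chrom = "X", start = 15638203,
                                    end = 15989595), "SuX")
  expect_equal(bed$start, 15638202)  # 0-based half-open
  expect_equal(bed$end, 15989595)
})
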