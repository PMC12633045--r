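# Synthetic panel generator: every input class of the pipeline from one
# explicit generative model, fully reproducible from the master seed.

# qPCR chemistry constants used by the generator: perfect doubling per cycle
# (slope -1/log10(2) per 10-fold dilution) and an arbitrary machine offset.
QPCR_SLOPE <- -1 / log10(2)
QPCR_INTERCEPT <- 24
QPCR_INPUT_NG <- 1.9
QPCR_STANDARD_NG <- c(190, 19, 1.9, 0.19, 0.019)
REF_STRAIN <- "Iso1"
REF_COPIES <- 1100

#' Simulate a DGRP-style panel: truth, crosses, assays, SNPs
#'
#' Draws latent strain genotypes (true Rsp copies, per-chromosome suppressor
#' strengths), then generates every observable the pipeline consumes:
#' reciprocal-cross offspring counts under the "DGRP-X" and "NoX" designs,
#' the three copy-number assay tables (read counts, slot-blot signals, qPCR
#' Ct values with the reference standard curve), and a haploid SNP matrix
#' containing background sites, a haplotype tagging X-suppressor carriers,
#' and pericentric chromosome-2 sites tagging high-copy Rsp alleles.
#'
#' Per replicate male, total offspring is negative binomial with mean
#' `mean_offspring` (times `fertility_factor` if his sperm are rescued by
#' suppression, i.e. expected k < 0.9) and SD-marked offspring is binomial
#' with the male's true k from [drive_model()]. Assay noise is multiplicative
#' lognormal at the configured CV; with CV = 0 an assay emits its exact
#' expectation, so each quantifier inverts the generator exactly.
#'
#' @param config A [sim_config()].
#' @return List with `truth`, `crosses`, `reads`, `blot`, `qpcr`,
#'   `standards`, `snp_sites`, `snp_geno` (sites x strains 0/1/NA matrix),
#'   and the echoed `config`.
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- child_seeds(config$seed, 6L)
  truth <- sim_truth(config, seeds[1])
  qpcr <- sim_qpcr(truth, config, seeds[5])
  snps <- sim_snps(truth, config, seeds[6])
  list(truth = truth,
       crosses = sim_crosses(truth, config, seeds[2]),
       reads = sim_reads(truth, config, seeds[3]),
       blot = sim_blot(truth, config, seeds[4]),
       qpcr = qpcr$samples,
       standards = qpcr$standards,
       snp_sites = snps$sites,
       snp_geno = snps$geno,
       config = config)
}

sim_truth <- function(config, seed) {
  set.seed(seed)
  n <- config$n_strains
  id <- sprintf("RAL%03d", seq_len(n))
  copies <- round(stats::rlnorm(n, config$rsp_log_mean, config$rsp_log_sd))
  draw_s <- function(p) {
    carrier <- stats::runif(n) < p
    s <- stats::runif(n, config$sup_strength_range[1], config$sup_strength_range[2])
    ifelse(carrier, s, 0)
  }
  sup_X <- draw_s(config$p_sup_X)
  sup_2 <- draw_s(config$p_sup_2)
  sup_3 <- draw_s(config$p_sup_3)
  k_dgrpx <- vapply(seq_len(n), function(i) {
    drive_model(copies[i], c(sup_X[i], sup_2[i], sup_3[i]), config$c50)
  }, numeric(1))
  k_nox <- vapply(seq_len(n), function(i) {
    drive_model(copies[i], c(sup_2[i], sup_3[i]), config$c50)
  }, numeric(1))
  data.frame(strain = id, true_copies = copies,
             sup_X = sup_X, sup_2 = sup_2, sup_3 = sup_3,
             true_k_dgrpx = k_dgrpx, true_k_nox = k_nox,
             stringsAsFactors = FALSE)
}

sim_crosses <- function(truth, config, seed) {
  set.seed(seed)
  designs <- c("DGRP-X", "NoX")
  out <- expand.grid(strain = truth$strain, design = designs,
                     replicate = seq_len(config$n_replicates),
                     stringsAsFactors = FALSE)
  out <- out[order(out$strain, out$design, out$replicate), ]
  i <- match(out$strain, truth$strain)
  true_k <- ifelse(out$design == "DGRP-X", truth$true_k_dgrpx[i],
                   truth$true_k_nox[i])
  suppressed <- true_k < 0.9
  mu <- config$mean_offspring * config$fertility_factor^suppressed
  total <- stats::rnbinom(nrow(out), size = config$dispersion, mu = mu)
  n_sd <- stats::rbinom(nrow(out), total, true_k)
  out$n_sd <- n_sd
  out$n_wt <- total - n_sd
  rownames(out) <- NULL
  attr(out, "out.attrs") <- NULL
  out
}

sim_reads <- function(truth, config, seed) {
  set.seed(seed)
  strain <- c(truth$strain, REF_STRAIN)
  copies <- c(truth$true_copies, REF_COPIES)
  noise <- lognoise(length(copies), config$noise_illumina)
  noise[strain == REF_STRAIN] <- 1  # the reference is the calibration anchor
  lambda <- copies * config$depth * noise
  reads <- lambda
  if (config$noise_illumina > 0) {
    smp <- strain != REF_STRAIN
    reads[smp] <- stats::rpois(sum(smp), lambda[smp])
  }
  data.frame(strain = strain, rsp_reads = reads,
             total_mapped = config$total_mapped, stringsAsFactors = FALSE)
}

sim_blot <- function(truth, config, seed) {
  set.seed(seed)
  strain <- c(truth$strain, REF_STRAIN)
  copies <- c(truth$true_copies, REF_COPIES)
  out <- expand.grid(strain = strain, slot = 1:3, stringsAsFactors = FALSE)
  out <- out[order(match(out$strain, strain), out$slot), ]
  cp <- copies[match(out$strain, strain)]
  noise1 <- lognoise(nrow(out), config$noise_blot)
  noise2 <- lognoise(nrow(out), config$noise_blot)
  ref <- out$strain == REF_STRAIN  # reference slots anchor the scale
  noise1[ref] <- noise2[ref] <- 1
  # chemiluminescence scale is arbitrary; the loading control normalises it out
  out$signal_rsp <- cp / 1000 * noise1
  out$signal_rp49 <- noise2
  rownames(out) <- NULL
  attr(out, "out.attrs") <- NULL
  out
}

sim_qpcr <- function(truth, config, seed) {
  set.seed(seed)
  # standards are calibration anchors: exact chemistry line, so the fitted
  # curve recovers the generating slope/intercept and the quantifier is
  # unbiased in expectation (sample Cts below carry the assay noise)
  std <- expand.grid(mass_ng = QPCR_STANDARD_NG, replicate = 1:3)
  std$ct <- QPCR_INTERCEPT + QPCR_SLOPE * log10(std$mass_ng)
  strain <- c(truth$strain, REF_STRAIN)
  copies <- c(truth$true_copies, REF_COPIES)
  smp <- expand.grid(strain = strain, replicate = 1:3, stringsAsFactors = FALSE)
  smp <- smp[order(match(smp$strain, strain), smp$replicate), ]
  cp <- copies[match(smp$strain, strain)]
  noise <- lognoise(nrow(smp), config$noise_qpcr)
  noise[smp$strain == REF_STRAIN] <- 1
  eq_mass <- QPCR_INPUT_NG * cp / REF_COPIES * noise
  smp$ct <- QPCR_INTERCEPT + QPCR_SLOPE * log10(eq_mass)
  rownames(smp) <- NULL
  attr(smp, "out.attrs") <- NULL
  std <- std[, c("mass_ng", "replicate", "ct")]
  attr(std, "out.attrs") <- NULL
  list(standards = std, samples = smp)
}

sim_snps <- function(truth, config, seed) {
  set.seed(seed)
  n <- config$n_strains
  chroms <- c("X", "2L", "2R", "3L", "3R")
  n_bg <- config$n_snps
  bg <- data.frame(chrom = sample(chroms, n_bg, replace = TRUE),
                   pos = sample.int(23e6, n_bg, replace = TRUE),
                   class = "background", stringsAsFactors = FALSE)
  sup_tag <- data.frame(chrom = "X",
                        pos = sort(round(stats::runif(config$n_sup_tag_snps,
                                                      15.6e6, 16.0e6))),
                        class = "sup_tag", stringsAsFactors = FALSE)
  copy_tag <- data.frame(chrom = "2R",
                         pos = sort(round(stats::runif(config$n_copy_tag_snps,
                                                       1e6, 3e6))),
                         class = "copy_tag", stringsAsFactors = FALSE)
  sites <- rbind(bg, sup_tag, copy_tag)
  ord <- order(match(sites$chrom, chroms), sites$pos)
  sites <- sites[ord, ]
  sites$site <- sprintf("%s_%d", sites$chrom, sites$pos)
  # de-duplicate colliding coordinates
  dup <- duplicated(sites$site)
  if (any(dup)) {
    sites$pos[dup] <- sites$pos[dup] + seq_len(sum(dup))
    sites$site <- sprintf("%s_%d", sites$chrom, sites$pos)
    sites <- sites[order(match(sites$chrom, chroms), sites$pos), ]
  }
  geno <- matrix(NA_integer_, nrow(sites), n,
                 dimnames = list(sites$site, truth$strain))
  high_copy <- truth$true_copies > stats::median(truth$true_copies)
  for (j in seq_len(nrow(sites))) {
    g <- switch(sites$class[j],
      background = stats::rbinom(n, 1, stats::runif(1, config$maf_range[1],
                                                    config$maf_range[2])),
      sup_tag = as.integer(truth$sup_X > 0),
      copy_tag = {
        flip <- stats::runif(n) < config$tag_flip_rate
        as.integer(xor(high_copy, flip))
      })
    geno[j, ] <- g
  }
  miss <- matrix(stats::runif(length(geno)) < config$missing_rate,
                 nrow(geno), ncol(geno))
  geno[miss] <- NA_integer_
  rownames(sites) <- NULL
  list(sites = sites[, c("site", "chrom", "pos", "class")], geno = geno)
}

#' Simulate recombinant X chromosomes for suppressor mapping
#'
#' Generates recombinants between a donor X carrying a major suppressor at
#' `sup_locus_pos` and a recipient X marked with `y` at the telomeric
#' (proximal-coordinate) end. Each recombinant receives a single crossover
#' uniform on the marker span, with the donor segment equally likely on
#' either side. Marker genotypes follow the side of the crossover; the
#' y-marker state is TRUE when the telomeric end is recipient-derived;
#' suppressor presence follows the genotype at the true locus. Drive
#' strength and offspring counts are then drawn under [drive_model()] and
#' the negative-binomial fertility model (suppressed males produce
#' `fertility_factor`-fold more offspring).
#'
#' @param config A [sim_config()]; uses `n_recombinants`,
#'   `marker_positions`, `sup_locus_pos`, `rec_sup_strength`,
#'   `rec_target_copies`, offspring parameters and `seed`.
#' @return Data frame with one row per recombinant: marker genotype columns
#'   (`"donor"`/`"recipient"`), `y_marker`, counts, `k`, and truth columns
#'   (`true_sup`, `true_k`, `true_crossover`).
#' @export
simulate_recombinants <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  mp <- config$marker_positions
  if (config$sup_locus_pos < min(mp) || config$sup_locus_pos > max(mp)) {
    stop("sup_locus_pos lies outside the marker span")
  }
  set.seed(child_seeds(config$seed, 7L)[7])
  n <- config$n_recombinants
  xo <- stats::runif(n, min(mp), max(mp))
  donor_left <- stats::runif(n) < 0.5
  side_state <- function(pos) {
    # parent of origin at a coordinate given crossover and orientation
    left <- outer(xo, pos, ">")  # TRUE when coordinate is left of crossover
    ifelse(left == donor_left, "donor", "recipient")
  }
  gmat <- side_state(mp)
  colnames(gmat) <- sprintf("m%02d", seq_along(mp))
  sup_state <- side_state(config$sup_locus_pos)[, 1]
  true_sup <- sup_state == "donor"
  y_marker <- gmat[, 1] == "recipient"  # telomeric end follows marker 1 side
  s <- ifelse(true_sup, config$rec_sup_strength, 0)
  true_k <- vapply(s, function(si) {
    drive_model(config$rec_target_copies, si, config$c50)
  }, numeric(1))
  mu <- config$mean_offspring * config$fertility_factor^true_sup
  total <- stats::rnbinom(n, size = config$dispersion, mu = mu)
  n_sd <- stats::rbinom(n, total, true_k)
  out <- data.frame(recombinant = sprintf("rec%03d", seq_len(n)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(gmat, stringsAsFactors = FALSE))
  out$y_marker <- y_marker
  out$n_sd <- n_sd
  out$n_wt <- total - n_sd
  out$n_offspring <- total
  out$k <- ifelse(total > 0, n_sd / total, NA_real_)
  out$true_sup <- true_sup
  out$true_k <- true_k
  out$true_crossover <- xo
  out
}

#' Marker map matching [simulate_recombinants()] output
#' @param config A [sim_config()].
#' @return Data frame: marker id, chromosome, 1-based position.
#' @export
recombinant_marker_map <- function(config = sim_config()) {
  data.frame(marker = sprintf("m%02d", seq_along(config$marker_positions)),
             chrom = "X", pos = config$marker_positions,
             stringsAsFactors = FALSE)
}
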