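#' Configuration for the synthetic DGRP-style panel generator
#'
#' Collects every modelling choice behind the synthetic panel in one
#' validated object. The defaults emulate the study conditions of a
#' 90-strain inbred panel crossed reciprocally to a driving SD stock:
#' lognormal Rsp copy numbers centred near the ~1100-copy reference allele
#' with a small insensitive tail, X-linked suppressor carrier frequency
#' ~52%, second/third-chromosome dominant suppressor frequencies 39%/25%,
#' overdispersed offspring counts around 104 per male, and a 2.16-fold
#' fertility gain for suppressed (sperm-rescued) males.
#'
#' @param n_strains Number of panel strains.
#' @param rsp_log_mean,rsp_log_sd Meanlog/sdlog of the lognormal true Rsp
#'   copy-number distribution (copies, rounded to integer).
#' @param p_sup_X,p_sup_2,p_sup_3 Per-chromosome suppressor carrier
#'   probabilities in \[0, 1\].
#' @param sup_strength_range Interval in \[0, 1\] from which each carried
#'   suppressor's strength `s` is drawn uniformly.
#' @param c50 Half-saturation copies of the drive sensitivity curve.
#' @param mean_offspring Expected offspring per unsuppressed male.
#' @param dispersion Negative-binomial size parameter of offspring counts
#'   (smaller = more overdispersed).
#' @param fertility_factor Multiplier on expected offspring for suppressed
#'   males (whose sensitive-sperm are rescued); default 2.16 (~225/104).
#' @param depth Sequencing depth scaler: expected Rsp-mapped reads per
#'   repeat copy.
#' @param total_mapped Total mapped reads per strain library (constant).
#' @param noise_illumina,noise_blot,noise_qpcr Multiplicative measurement
#'   noise CVs per assay; 0 makes that assay exactly deterministic.
#' @param n_replicates Cross replicates (single males) per strain x design.
#' @param n_recombinants Recombinant X chromosomes to generate.
#' @param marker_positions Ordered 1-based bp positions of the X genotyping
#'   markers (strictly increasing). The default is 15 markers evenly spaced
#'   at 1.5 Mb across the X, laid out so the suppressor locus sits mid-gap:
#'   a mapping study places its markers to bracket the candidate region,
#'   and the minimum-discordance scorer is best calibrated when inter-marker
#'   intervals have comparable widths (unequal gaps discount wider intervals
#'   through the ambiguous-flank rule).
#' @param sup_locus_pos True X suppressor coordinate (bp).
#' @param rec_sup_strength Strength of the major X suppressor segregating in
#'   the recombinants (chosen so the k modes sit near 0.55 and 1.0).
#' @param rec_target_copies Rsp copies of the sensitive target chromosome in
#'   the recombinant drive assays (reference-like allele).
#' @param n_snps,maf_range,missing_rate Background SNP matrix parameters.
#' @param n_sup_tag_snps Tightly linked X sites marking sup_X carriers.
#' @param n_copy_tag_snps Pericentric chromosome-2 sites tagging high-copy
#'   Rsp alleles (they carry association signal only through copy number).
#' @param tag_flip_rate Per-strain probability that a copy-tag site's allele
#'   disagrees with the copy-number class (imperfect linkage).
#' @param seed Master RNG seed; all child streams derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 90,
                       rsp_log_mean = log(800),
                       rsp_log_sd = 1.0,
                       p_sup_X = 0.52,
                       p_sup_2 = 0.39,
                       p_sup_3 = 0.25,
                       sup_strength_range = c(0.5, 1),
                       c50 = 50,
                       mean_offspring = 104,
                       dispersion = 5,
                       fertility_factor = 2.16,
                       depth = 100,
                       total_mapped = 2e7,
                       noise_illumina = 0.2,
                       noise_blot = 0.3,
                       noise_qpcr = 0.3,
                       n_replicates = 8,
                       n_recombinants = 239,
                       marker_positions = 15.05e6 + 1.5e6 * (-9:5),
                       sup_locus_pos = 15.8e6,
                       rec_sup_strength = 0.9,
                       rec_target_copies = 1100,
                       n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.05,
                       n_sup_tag_snps = 15,
                       n_copy_tag_snps = 15,
                       tag_flip_rate = 0.1,
                       seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              rsp_log_mean = rsp_log_mean, rsp_log_sd = rsp_log_sd,
              p_sup_X = p_sup_X, p_sup_2 = p_sup_2, p_sup_3 = p_sup_3,
              sup_strength_range = sup_strength_range, c50 = c50,
              mean_offspring = mean_offspring, dispersion = dispersion,
              fertility_factor = fertility_factor,
              depth = depth, total_mapped = total_mapped,
              noise_illumina = noise_illumina, noise_blot = noise_blot,
              noise_qpcr = noise_qpcr,
              n_replicates = as.integer(n_replicates),
              n_recombinants = as.integer(n_recombinants),
              marker_positions = marker_positions,
              sup_locus_pos = sup_locus_pos,
              rec_sup_strength = rec_sup_strength,
              rec_target_copies = rec_target_copies,
              n_snps = as.integer(n_snps), maf_range = maf_range,
              missing_rate = missing_rate,
              n_sup_tag_snps = as.integer(n_sup_tag_snps),
              n_copy_tag_snps = as.integer(n_copy_tag_snps),
              tag_flip_rate = tag_flip_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("sim_config: ", msg)
  probs <- c(cfg$p_sup_X, cfg$p_sup_2, cfg$p_sup_3, cfg$missing_rate,
             cfg$tag_flip_rate)
  chk(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  chk(cfg$rsp_log_sd >= 0, "rsp_log_sd must be >= 0")
  chk(all(c(cfg$n_strains, cfg$n_replicates, cfg$n_recombinants,
            cfg$n_snps) >= 1L), "n_* must be >= 1")
  chk(length(cfg$sup_strength_range) == 2 &&
        all(cfg$sup_strength_range >= 0 & cfg$sup_strength_range <= 1) &&
        diff(cfg$sup_strength_range) >= 0,
      "sup_strength_range must be an ordered interval within [0, 1]")
  chk(length(cfg$maf_range) == 2 && all(cfg$maf_range >= 0) &&
        all(cfg$maf_range <= 0.5) && diff(cfg$maf_range) >= 0,
      "maf_range must be an ordered interval within [0, 0.5]")
  chk(all(diff(cfg$marker_positions) > 0),
      "marker_positions must be strictly increasing")
  chk(all(c(cfg$c50, cfg$mean_offspring, cfg$dispersion, cfg$depth,
            cfg$total_mapped, cfg$noise_illumina, cfg$noise_blot,
            cfg$noise_qpcr) >= 0), "rates and noise CVs must be >= 0")
  chk(cfg$fertility_factor > 0, "fertility_factor must be positive")
  if (cfg$sup_locus_pos < min(cfg$marker_positions) ||
      cfg$sup_locus_pos > max(cfg$marker_positions)) {
    cfg$sup_locus_terminal <- TRUE
  } else {
    cfg$sup_locus_terminal <- FALSE
  }
  cfg
}

# Deterministic child seeds so each output table has its own stream.
child_seeds <- function(seed, n = 10L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# E[mult] = 1 lognormal multiplicative noise at a given CV; CV = 0 -> exactly 1.
lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
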