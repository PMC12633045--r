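# Population-level suppressor frequency summaries.

# Nearest-integer percent, ties away from zero (base round() is banker's).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percent of a count over a denominator, nearest integer
#' @param n,total Counts.
#' @return Integer percent (ties rounded away from zero).
#' @export
pct <- function(n, total) as.integer(round_half_up(100 * n / total))

#' Panel-level suppressor census
#'
#' Aggregates per-strain suppressor calls into counts and percentages.
#' Percentages are reported over the strains with a sensitive Rsp target
#' (`n_tested`): on an insensitive target, SD cannot kill sperm, so
#' suppression is unobservable there and those strains are excluded from
#' the frequency denominators. Counts over all strains are also returned.
#'
#' @param calls [suppressor_calls()] output.
#' @return List of class `census_summary` with counts (`n_strains`,
#'   `n_insensitive`, `n_tested`, `n_any_sup`, `n_autosomal`,
#'   `n_x_linked`, `n_x_strong`, `n_y_linked`) and integer percentages
#'   over `n_tested` (`pct_any_sup`, `pct_autosomal`, `pct_x_linked`,
#'   `pct_x_strong`).
#' @export
summarize_census <- function(calls) {
  insens <- isTRUE_vec(calls$rsp_insensitive)
  tested <- !insens
  out <- list(
    n_strains = nrow(calls),
    n_insensitive = sum(insens),
    n_tested = sum(tested),
    n_any_sup = sum(isTRUE_vec(calls$any_suppressor[tested])),
    n_autosomal = sum(isTRUE_vec(calls$autosomal[tested])),
    n_x_linked = sum(isTRUE_vec(calls$x_linked[tested])),
    n_x_strong = sum(isTRUE_vec(calls$x_strong[tested])),
    n_y_linked = sum(isTRUE_vec(calls$y_linked[tested])))
  out$pct_any_sup <- pct(out$n_any_sup, out$n_tested)
  out$pct_autosomal <- pct(out$n_autosomal, out$n_tested)
  out$pct_x_linked <- pct(out$n_x_linked, out$n_tested)
  out$pct_x_strong <- pct(out$n_x_strong, out$n_tested)
  class(out) <- "census_summary"
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.census_summary <- function(x, ...) {
  cat(sprintf("Suppressor census over %d strains (%d Rsp-insensitive excluded)\n",
              x$n_strains, x$n_insensitive))
  cat(sprintf("  any suppressor : %d/%d (%d%%)\n", x$n_any_sup, x$n_tested,
              x$pct_any_sup))
  cat(sprintf("  autosomal      : %d/%d (%d%%)\n", x$n_autosomal, x$n_tested,
              x$pct_autosomal))
  cat(sprintf("  X-linked       : %d/%d (%d%%), strong (dk>0.1): %d\n",
              x$n_x_linked, x$n_tested, x$pct_x_linked, x$n_x_strong))
  cat(sprintf("  Y-linked       : %d\n", x$n_y_linked))
  invisible(x)
}

#' Chromosome-level suppressor frequency (product estimator)
#'
#' Estimates the population frequency of suppressing copies of one autosome
#' as the product of two proportions: the fraction of panel strains with
#' dominant autosomal suppressors, times the fraction of extracted
#' chromosomes of that arm that suppressed in a common background:
#' `freq = p_autosomal * n_suppressing / n_extracted`. A parametric
#' bootstrap CI (resampling both binomial proportions at their observed
#' values) quantifies the fragility of the small extraction denominators;
#' the CI is an extension beyond the point estimate itself.
#'
#' @param p_autosomal Fraction of strains with dominant autosomal
#'   suppressors, in \[0, 1\].
#' @param n_suppressing,n_extracted Extracted chromosomes that suppressed /
#'   tested (`n_extracted >= 1`).
#' @param n_autosomal_denom Denominator behind `p_autosomal` (strains),
#'   used for the bootstrap.
#' @param n_boot Bootstrap replicates (default 10000); 0 skips the CI.
#' @param conf CI level (default 0.95).
#' @param seed Optional RNG seed for the bootstrap.
#' @return List: `frequency` (point estimate in \[0, 1\]), `percent`
#'   (nearest-integer percent), `ci` (two quantiles of the bootstrap
#'   product, or NULL).
#' @export
chromosome_frequency <- function(p_autosomal, n_suppressing, n_extracted,
                                 n_autosomal_denom = 88, n_boot = 10000,
                                 conf = 0.95, seed = NULL) {
  if (n_extracted < 1) stop("`n_extracted` must be >= 1")
  if (p_autosomal < 0 || p_autosomal > 1) stop("`p_autosomal` not in [0, 1]")
  if (n_suppressing < 0 || n_suppressing > n_extracted) {
    stop("`n_suppressing` must lie in [0, n_extracted]")
  }
  freq <- p_autosomal * n_suppressing / n_extracted
  ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    p1 <- stats::rbinom(n_boot, n_autosomal_denom, p_autosomal) /
      n_autosomal_denom
    p2 <- stats::rbinom(n_boot, n_extracted, n_suppressing / n_extracted) /
      n_extracted
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(p1 * p2, c(a, 1 - a)))
  }
  list(frequency = freq, percent = as.integer(round_half_up(100 * freq)),
       ci = ci)
}
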