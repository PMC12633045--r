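# Drive-strength (k) quantification from cross offspring counts and
# reciprocal-cross classification of suppressor architecture.

#' Drop under-counted replicates
#'
#' Keeps replicates whose total offspring strictly exceeds `min_offspring`
#' (a replicate with exactly `min_offspring` offspring is dropped).
#'
#' @param records Data frame with `n_sd` and `n_wt` columns.
#' @param min_offspring Threshold (default 40).
#' @return The filtered data frame (possibly empty).
#' @export
replicate_filter <- function(records, min_offspring = 40) {
  keep <- (records$n_sd + records$n_wt) > min_offspring
  records[keep, , drop = FALSE]
}

#' Drive strength k from one offspring count pair
#'
#' `k = n_sd / (n_sd + n_wt)`: the proportion of a male's offspring that
#' inherit the SD-marked chromosome. 0.5 is the Mendelian expectation;
#' 1.0 is complete drive.
#'
#' @param n_sd,n_wt SD-marked and wildtype offspring counts (vectorised).
#' @return k in \[0, 1\].
#' @export
compute_k <- function(n_sd, n_wt) {
  if (any(n_sd < 0 | n_wt < 0)) stop("offspring counts must be >= 0")
  total <- n_sd + n_wt
  if (any(total == 0)) stop("undefined k: zero total offspring")
  n_sd / total
}

#' Pool replicates into one strain-level drive estimate
#'
#' The representative k is count-pooled over replicates
#' (`sum(n_sd) / sum(total)`), not the mean of replicate k values; the
#' standard error is computed across replicate-level k values, matching
#' the usual mean-k +/- SE display.
#'
#' @param records Filtered replicates for one strain x design.
#' @return One-row data frame: `k`, `se`, `n_offspring`, `n_replicates`.
#' @export
pool_strain <- function(records) {
  if (!nrow(records)) stop("no replicates to pool")
  total <- records$n_sd + records$n_wt
  kr <- compute_k(records$n_sd, records$n_wt)
  se <- if (length(kr) > 1) stats::sd(kr) / sqrt(length(kr)) else NA_real_
  data.frame(k = sum(records$n_sd) / sum(total), se = se,
             n_offspring = sum(total), n_replicates = nrow(records))
}

#' Reciprocal-cross comparison for X-linked suppression
#'
#' One-tailed two-sample t-test on per-replicate k values with alternative
#' mean k(NoX) > mean k(DGRP-X): males that inherit the panel X drive less
#' when that X carries a suppressor. Welch's unequal-variance form by
#' default; `pooled_variance = TRUE` restores the classic equal-variance
#' test. When the t statistic is degenerate (zero variance in both
#' designs), the comparison falls back to the one-sided exact test on the
#' pooled 2x2 count table (method `"exact"`).
#'
#' @param records Filtered replicates for one strain, both designs, with a
#'   `design` column coded `"DGRP-X"` / `"NoX"`.
#' @param pooled_variance Use the equal-variance t-test.
#' @param reverse Test the opposite direction (k(DGRP-X) > k(NoX)), used
#'   for the Y-linked check.
#' @return List: `delta_k` (pooled k(NoX) - pooled k(DGRP-X)), `p`,
#'   `method` (`"t"` or `"exact"`, `NA` if undecidable), `n_dgrpx`,
#'   `n_nox`.
#' @export
compare_reciprocal <- function(records, pooled_variance = FALSE,
                               reverse = FALSE) {
  dg <- records[records$design == "DGRP-X", , drop = FALSE]
  nx <- records[records$design == "NoX", , drop = FALSE]
  out <- list(delta_k = NA_real_, p = NA_real_, method = NA_character_,
              n_dgrpx = nrow(dg), n_nox = nrow(nx))
  if (!nrow(dg) || !nrow(nx)) return(out)
  out$delta_k <- pool_strain(nx)$k - pool_strain(dg)$k
  if (nrow(dg) < 2 || nrow(nx) < 2) return(out)
  k_dg <- compute_k(dg$n_sd, dg$n_wt)
  k_nx <- compute_k(nx$n_sd, nx$n_wt)
  alt_hi <- if (reverse) k_dg else k_nx
  alt_lo <- if (reverse) k_nx else k_dg
  if (stats::sd(alt_hi) > 0 || stats::sd(alt_lo) > 0) {
    out$p <- stats::t.test(alt_hi, alt_lo, alternative = "greater",
                           var.equal = pooled_variance)$p.value
    out$method <- "t"
  } else {
    # all replicate k identical in both designs: exact test on pooled counts
    tab <- rbind(c(sum(nx$n_sd), sum(nx$n_wt)),
                 c(sum(dg$n_sd), sum(dg$n_wt)))
    if (reverse) tab <- tab[2:1, ]
    out$p <- stats::fisher.test(tab, alternative = "greater")$p.value
    out$method <- "exact"
  }
  out
}

#' Classify one strain's suppressor architecture
#'
#' Applies the reciprocal-cross decision rules. Strains whose Rsp allele is
#' insensitive (< 100 copies) are flagged `rsp_insensitive` and carry no
#' suppressor calls (low k there reflects the target, not suppression).
#' Otherwise: any suppressor iff pooled k(DGRP-X) < `k_threshold`;
#' autosomal iff pooled k(NoX) < `k_threshold`; X-linked iff the one-tailed
#' reciprocal test is significant at `alpha`; a strong X suppressor
#' additionally lowers k by more than `strong_delta`; Y-linked iff the
#' reverse-direction test is significant (expected never under this design).
#'
#' @param estimates List with pooled `k_dgrpx`, `k_nox` and the
#'   [compare_reciprocal()] results `cmp` (forward) and `cmp_rev`.
#' @param sensitive Logical Rsp sensitivity of the strain (NA = unknown:
#'   classification proceeds, `rsp_insensitive` stays NA).
#' @param k_threshold Suppressor-presence threshold on pooled k (default 0.9).
#' @param alpha Significance level for the reciprocal tests (default 0.05).
#' @param strong_delta Minimum k reduction for a "strong" X call (default 0.1).
#' @return One-row data frame of flags and supporting statistics.
#' @export
classify_strain <- function(estimates, sensitive, k_threshold = 0.9,
                            alpha = 0.05, strong_delta = 0.1) {
  insens <- if (is.na(sensitive)) NA else !sensitive
  cmp <- estimates$cmp
  cmp_rev <- estimates$cmp_rev
  call_sup <- isTRUE(!insens) || is.na(insens)
  x_linked <- call_sup && !is.na(cmp$p) && cmp$p < alpha
  out <- data.frame(
    rsp_insensitive = insens,
    any_suppressor = call_sup && !is.na(estimates$k_dgrpx) &&
      estimates$k_dgrpx < k_threshold,
    autosomal = call_sup && !is.na(estimates$k_nox) &&
      estimates$k_nox < k_threshold,
    x_linked = x_linked,
    x_strong = x_linked && !is.na(cmp$delta_k) && cmp$delta_k > strong_delta,
    y_linked = call_sup && !is.na(cmp_rev$p) && cmp_rev$p < alpha,
    p_x = cmp$p, p_y = cmp_rev$p, delta_k = cmp$delta_k,
    method = cmp$method, stringsAsFactors = FALSE)
  if (isTRUE(insens)) {
    out$any_suppressor <- out$autosomal <- out$x_linked <-
      out$x_strong <- out$y_linked <- FALSE
  }
  out
}

#' Strain-level drive estimates for a whole cross table
#'
#' Applies the replicate filter, then pools counts per strain x design.
#'
#' @param crosses Data frame: `strain`, `design`, `replicate`, `n_sd`,
#'   `n_wt`.
#' @param min_offspring Replicate filter threshold (default 40, strict).
#' @return Data frame: strain, design, k, se, n_offspring, n_replicates.
#'   Strain x design cells with no surviving replicate are absent.
#' @export
drive_estimates <- function(crosses, min_offspring = 40) {
  f <- replicate_filter(crosses, min_offspring)
  if (!nrow(f)) return(data.frame(strain = character(), design = character(),
                                  k = numeric(), se = numeric(),
                                  n_offspring = integer(),
                                  n_replicates = integer(),
                                  stringsAsFactors = FALSE))
  parts <- split(f, list(f$strain, f$design), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    cbind(data.frame(strain = d$strain[1], design = d$design[1],
                     stringsAsFactors = FALSE), pool_strain(d))
  }))
  rownames(out) <- NULL
  out[order(out$strain, out$design), ]
}

#' Suppressor calls for every strain in a cross table
#'
#' Full per-strain classification: replicate filtering, pooled estimates
#' per design, forward and reverse reciprocal tests, and the decision
#' rules of [classify_strain()]. A Benjamini-Hochberg adjusted column for
#' the X-linked p-values is emitted alongside (the per-strain alpha rule
#' itself is uncorrected, matching the assay's design).
#'
#' @param crosses Cross count table (`strain`, `design`, `replicate`,
#'   `n_sd`, `n_wt`).
#' @param profiles Optional [copy_number_profiles()] output (or any data
#'   frame with `strain` and logical `sensitive`); when absent, Rsp
#'   sensitivity is unknown for all strains.
#' @param k_threshold,alpha,strong_delta,min_offspring,pooled_variance
#'   Passed through to the underlying rules.
#' @return Data frame, one row per strain with both designs estimated:
#'   flags, p-values (`p_x`, `p_x_bh`, `p_y`), `delta_k`, pooled
#'   `k_dgrpx`/`k_nox`.
#' @export
suppressor_calls <- function(crosses, profiles = NULL, k_threshold = 0.9,
                             alpha = 0.05, strong_delta = 0.1,
                             min_offspring = 40, pooled_variance = FALSE) {
  f <- replicate_filter(crosses, min_offspring)
  strains <- sort(unique(f$strain))
  rows <- lapply(strains, function(s) {
    d <- f[f$strain == s, , drop = FALSE]
    dg <- d[d$design == "DGRP-X", , drop = FALSE]
    nx <- d[d$design == "NoX", , drop = FALSE]
    if (!nrow(dg) || !nrow(nx)) return(NULL)
    est <- list(k_dgrpx = pool_strain(dg)$k, k_nox = pool_strain(nx)$k,
                cmp = compare_reciprocal(d, pooled_variance),
                cmp_rev = compare_reciprocal(d, pooled_variance,
                                             reverse = TRUE))
    sens <- NA
    if (!is.null(profiles)) {
      m <- match(s, profiles$strain)
      if (!is.na(m)) sens <- profiles$sensitive[m]
    }
    cbind(data.frame(strain = s, k_dgrpx = est$k_dgrpx, k_nox = est$k_nox,
                     stringsAsFactors = FALSE),
          classify_strain(est, sens, k_threshold, alpha, strong_delta))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_x_bh <- stats::p.adjust(out$p_x, method = "BH")
  rownames(out) <- NULL
  out
}
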