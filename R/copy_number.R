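# Rsp copy-number estimation from three orthogonal assays, plus the PCA
# composite. All three estimators are linear in their raw signal and scaled
# to a reference allele of known copy number (default 1100).

#' Copy number from Rsp-mapped read counts (RPM normalisation)
#'
#' Scales the sample's reads-per-million mapped at the Rsp locus by the
#' reference strain's RPM, assuming read depth at the locus is linear in
#' repeat copy number: `copies = ref_copies * RPM_sample / RPM_ref`.
#'
#' @param rsp_reads,total_mapped Sample Rsp-mapped reads and total mapped
#'   reads (vectorised over samples).
#' @param ref_rsp_reads,ref_total_mapped Same for the reference library.
#' @param ref_copies Reference Rsp copy number (default 1100).
#' @return Estimated copies (non-negative).
#' @export
estimate_from_reads <- function(rsp_reads, total_mapped,
                                ref_rsp_reads, ref_total_mapped,
                                ref_copies = 1100) {
  if (any(total_mapped <= 0, na.rm = TRUE) || ref_total_mapped <= 0 ||
      ref_rsp_reads <= 0) {
    stop("total mapped reads and reference reads must be positive")
  }
  if (any(rsp_reads < 0, na.rm = TRUE)) stop("read counts must be >= 0")
  ref_copies * (rsp_reads / total_mapped) /
    (ref_rsp_reads / ref_total_mapped)
}

#' Copy number from slot-blot signal ratios
#'
#' The Rsp probe signal of each slot is normalised to its Rp49
#' loading-control signal; replicate slots are averaged at the ratio level;
#' the mean ratio is then scaled by the reference strain's mean ratio and
#' multiplied by the reference copy number.
#'
#' @param signal_rsp,signal_rp49 Per-slot probe and loading-control signals
#'   for one strain (equal-length vectors; slots with a non-positive control
#'   signal are excluded).
#' @param ref_ratio Reference strain's mean Rsp/Rp49 ratio (> 0).
#' @param ref_copies Reference copy number (default 1100).
#' @return Estimated copies, or `NA` if every slot is excluded.
#' @export
estimate_from_blot <- function(signal_rsp, signal_rp49, ref_ratio,
                               ref_copies = 1100) {
  if (!is.finite(ref_ratio) || ref_ratio <= 0) {
    stop("`ref_ratio` must be positive")
  }
  ok <- is.finite(signal_rsp) & is.finite(signal_rp49) & signal_rp49 > 0
  if (!any(ok)) return(NA_real_)
  ref_copies * mean(signal_rsp[ok] / signal_rp49[ok]) / ref_ratio
}

#' Fit a qPCR standard curve
#'
#' Least-squares line `Ct = slope * log10(mass) + intercept` over serial
#' dilutions of reference genomic DNA (at least three points; perfect
#' doubling chemistry corresponds to slope -3.3219 per 10-fold).
#'
#' @param dilution_masses Input DNA masses (same unit throughout; > 0).
#' @param ct_values Paired threshold cycles.
#' @return List of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   and the input points.
#' @export
fit_standard_curve <- function(dilution_masses, ct_values) {
  stopifnot(length(dilution_masses) == length(ct_values))
  ok <- is.finite(dilution_masses) & is.finite(ct_values)
  dilution_masses <- dilution_masses[ok]
  ct_values <- ct_values[ok]
  if (length(dilution_masses) < 3) stop("need at least 3 dilution points")
  if (any(dilution_masses <= 0)) stop("dilution masses must be positive")
  x <- log10(dilution_masses)
  if (stats::var(x) == 0) stop("degenerate standard curve: all masses equal")
  fit <- stats::lm(ct_values ~ x)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((ct_values - mean(ct_values))^2)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r2 = if (sst > 0) 1 - ssr / sst else NA_real_,
              masses = dilution_masses, ct = ct_values)
  class(out) <- "standard_curve"
  out
}

#' Copy number from a qPCR threshold cycle
#'
#' Converts a sample Ct to a reference-DNA mass equivalent through the
#' standard curve, then scales by the mass equivalent the reference allele
#' would give at the same input mass:
#' `copies = ref_copies * 10^((ct - intercept)/slope) / ref_mass_equivalent`.
#'
#' @param ct Threshold cycle (vectorised); `Inf` maps to 0 copies.
#' @param curve A [fit_standard_curve()] result.
#' @param ref_mass_equivalent Reference mass equivalent at the assay's input
#'   mass (the input mass itself when the standards are reference DNA).
#' @param ref_copies Reference copy number (default 1100).
#' @return Estimated copies.
#' @export
quantify_qpcr <- function(ct, curve, ref_mass_equivalent, ref_copies = 1100) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) || curve$slope == 0) {
    stop("standard curve slope must be non-zero")
  }
  if (!is.finite(ref_mass_equivalent) || ref_mass_equivalent <= 0) {
    stop("`ref_mass_equivalent` must be positive")
  }
  mass_eq <- 10^((ct - curve$intercept) / curve$slope)
  ref_copies * mass_eq / ref_mass_equivalent
}

#' PCA composite of the three copy-number estimates
#'
#' Principal-component decomposition of the centered, unit-variance matrix
#' of per-strain estimates; strains with any missing estimate are excluded
#' (complete cases only). PC1 scores are sign-flipped when their correlation
#' with a per-strain drive-strength reference is negative, so higher scores
#' always mean more copies / stronger drive.
#'
#' @param estimates Numeric matrix or data frame, strains x methods
#'   (rownames = strain ids).
#' @param k_reference Optional named vector of per-strain k used only to
#'   orient the PC1 sign; with no reference, PC1 is oriented to load
#'   positively on the first column.
#' @return List: `scores` (named PC1 scores for complete-case strains),
#'   `var_explained` (fractions, one per component, summing to 1),
#'   `loadings`, `n_used`.
#' @export
integrate_pca <- function(estimates, k_reference = NULL) {
  m <- as.matrix(estimates)
  cc <- stats::complete.cases(m)
  if (sum(cc) < 3) stop("need at least 3 strains with complete estimates")
  m <- m[cc, , drop = FALSE]
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  scores <- p$x[, 1]
  flip <- FALSE
  if (!is.null(k_reference)) {
    kr <- k_reference[rownames(m)]
    ok <- is.finite(kr) & is.finite(scores)
    if (sum(ok) >= 3 && stats::sd(kr[ok]) > 0 && stats::sd(scores[ok]) > 0) {
      flip <- stats::cor(scores[ok], kr[ok]) < 0
    }
  } else {
    flip <- p$rotation[1, 1] < 0
  }
  if (flip) {
    scores <- -scores
    p$rotation[, 1] <- -p$rotation[, 1]
  }
  list(scores = scores, var_explained = ve, loadings = p$rotation,
       n_used = sum(cc))
}

#' Assemble per-strain copy-number profiles from the three assay tables
#'
#' Runs the three estimators over full assay tables, attaches the PCA
#' composite score (complete-case strains only) and the sensitivity call.
#'
#' @param reads Data frame: `strain`, `rsp_reads`, `total_mapped`; must
#'   include the reference strain's row.
#' @param blot Data frame: `strain`, `slot`, `signal_rsp`, `signal_rp49`.
#' @param qpcr Data frame: `strain`, `replicate`, `ct`.
#' @param standards Data frame: `mass_ng`, `ct` (reference serial dilution).
#' @param ref_strain Reference strain id present in each assay table.
#' @param ref_copies Reference Rsp copies (default 1100).
#' @param qpcr_input_ng DNA input mass per qPCR reaction.
#' @param k_reference Optional named k vector for PC1 sign orientation.
#' @param sensitive_method Which estimate feeds the sensitivity call:
#'   `"illumina"` (default, the computational estimate), `"blot"`,
#'   `"qpcr"`, or `"pc1_available"` is not allowed — the threshold is on
#'   copies.
#' @param threshold Sensitivity threshold in copies (default 100; fewer
#'   than this is insensitive).
#' @return Data frame: strain, est_illumina, est_blot, est_qpcr, pc1,
#'   sensitive (logical; NA when the chosen estimate is missing).
#' @export
copy_number_profiles <- function(reads, blot, qpcr, standards,
                                 ref_strain = "Iso1", ref_copies = 1100,
                                 qpcr_input_ng = 1.9, k_reference = NULL,
                                 sensitive_method = c("illumina", "blot", "qpcr"),
                                 threshold = 100) {
  sensitive_method <- match.arg(sensitive_method)
  strains <- sort(unique(c(reads$strain, blot$strain, qpcr$strain)))
  strains <- setdiff(strains, ref_strain)

  ref_row <- reads[reads$strain == ref_strain, , drop = FALSE]
  if (nrow(ref_row) != 1) stop("reference strain must appear once in `reads`")
  est_ill <- rep(NA_real_, length(strains))
  i <- match(reads$strain, strains)
  keep <- !is.na(i)
  est_ill[i[keep]] <- estimate_from_reads(reads$rsp_reads[keep],
                                          reads$total_mapped[keep],
                                          ref_row$rsp_reads,
                                          ref_row$total_mapped, ref_copies)

  ref_slots <- blot[blot$strain == ref_strain, , drop = FALSE]
  ok <- ref_slots$signal_rp49 > 0
  if (!any(ok)) stop("reference strain has no usable blot slots")
  ref_ratio <- mean(ref_slots$signal_rsp[ok] / ref_slots$signal_rp49[ok])
  est_blot <- vapply(strains, function(s) {
    b <- blot[blot$strain == s, , drop = FALSE]
    if (!nrow(b)) return(NA_real_)
    estimate_from_blot(b$signal_rsp, b$signal_rp49, ref_ratio, ref_copies)
  }, numeric(1))

  curve <- fit_standard_curve(standards$mass_ng, standards$ct)
  est_qpcr <- vapply(strains, function(s) {
    q <- qpcr[qpcr$strain == s, , drop = FALSE]
    if (!nrow(q) || !any(is.finite(q$ct) | is.infinite(q$ct))) return(NA_real_)
    mean(quantify_qpcr(q$ct, curve, qpcr_input_ng, ref_copies))
  }, numeric(1))

  est <- cbind(est_illumina = est_ill, est_blot = est_blot,
               est_qpcr = est_qpcr)
  rownames(est) <- strains
  pc1 <- rep(NA_real_, length(strains))
  if (sum(stats::complete.cases(est)) >= 3) {
    pca <- integrate_pca(est, k_reference)
    pc1[match(names(pca$scores), strains)] <- pca$scores
    attr_ve <- pca$var_explained
  } else {
    attr_ve <- NULL
  }
  chosen <- est[, switch(sensitive_method, illumina = "est_illumina",
                         blot = "est_blot", qpcr = "est_qpcr")]
  out <- data.frame(strain = strains, est, pc1 = pc1,
                    sensitive = ifelse(is.na(chosen), NA, chosen >= threshold),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "var_explained") <- attr_ve
  attr(out, "curve") <- curve
  out
}
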