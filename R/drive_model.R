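#' Expected drive strength under the sensitivity/suppression model
#'
#' Maps a target chromosome's Responder (Rsp) satellite copy number and the
#' suppressor complement of a male's genotype to his expected drive strength
#' `k`, the proportion of offspring inheriting the SD-marked chromosome.
#' Without drive `k = 0.5` (Mendelian); with complete drive `k = 1`.
#'
#' The model is a minimal monotone form: chromosomes with fewer than 100
#' repeats are insensitive to sperm killing, so `k = 0.5` regardless of
#' suppressors; above that, sensitivity saturates with copy number as
#' `copies / (copies + c50)`, and each unlinked suppressor of strength
#' `s` in \[0, 1\] independently rescues a fraction `s` of the doomed sperm:
#'
#' \deqn{k = 0.5 + 0.5 \cdot sens(copies) \cdot \prod_i (1 - s_i)}
#'
#' `k` is increasing in `copies` and decreasing in every `s_i`.
#'
#' @param copies Non-negative Rsp repeat count of the target chromosome.
#'   May be a vector.
#' @param suppressor_strengths Numeric vector of suppressor strengths, each
#'   in \[0, 1\]; 0 means absent and may simply be omitted. All act in the
#'   same male (multiplicatively).
#' @param c50 Half-saturation copy number of the sensitivity curve
#'   (copies at which sensitivity is 0.5 in the limit of no threshold).
#' @return Expected `k` in \[0.5, 1\], same length as `copies`.
#' @examples
#' drive_model(0)                 # insensitive target: 0.5
#' drive_model(1100, c50 = 50)    # strong drive, ~0.96
#' drive_model(1100, 1, c50 = 50) # fully suppressed: 0.5
#' @export
drive_model <- function(copies, suppressor_strengths = numeric(0), c50 = 50) {
  if (any(!is.finite(copies)) || any(copies < 0)) {
    stop("`copies` must be finite and non-negative")
  }
  s <- suppressor_strengths
  if (length(s) && (any(!is.finite(s)) || any(s < 0) || any(s > 1))) {
    stop("suppressor strengths must lie in [0, 1]")
  }
  if (!is.finite(c50) || c50 < 0) stop("`c50` must be finite and non-negative")
  sens <- ifelse(copies < 100, 0,
                 ifelse(copies + c50 > 0, copies / (copies + c50), 0))
  0.5 + 0.5 * sens * prod(1 - s)
}

#' Classify an Rsp allele as sensitive or insensitive to SD
#'
#' Chromosomes carrying fewer than 100 Rsp repeats escape sperm killing;
#' exactly 100 copies is classified sensitive (conservative toward
#' sensitivity given the two one-sided phrasings of the threshold).
#'
#' @param copies Non-negative copy number (vectorised); `NA` propagates.
#' @return Character vector, `"sensitive"` or `"insensitive"`.
#' @export
classify_sensitivity <- function(copies) {
  if (any(copies < 0, na.rm = TRUE)) stop("`copies` must be non-negative")
  ifelse(is.na(copies), NA_character_,
         ifelse(copies < 100, "insensitive", "sensitive"))
}
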