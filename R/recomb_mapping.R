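# Recombination mapping of a major X-linked suppressor: phenotype
# partitioning, minimum-discordance interval inference, marker segregation
# and fertility tests, and the haplotype-based candidate-SNP filter.

#' Partition recombinants into suppressed and unsuppressed
#'
#' Suppressed iff `k < k_threshold` (strict; the k distribution across
#' recombinants segregating a single major suppressor is bimodal, so the
#' threshold sits in the valley between the modes).
#'
#' @param k Per-recombinant drive strength.
#' @param k_threshold Default 0.9.
#' @return List: `suppressed` (logical vector), `fraction_suppressed`.
#' @export
partition_phenotypes <- function(k, k_threshold = 0.9) {
  if (any(!is.finite(k))) stop("k must be defined for every recombinant")
  sup <- k < k_threshold
  list(suppressed = sup, fraction_suppressed = mean(sup))
}

# Donor/recipient state of each recombinant at an arbitrary coordinate,
# read from the nearest non-missing flanking markers only: both flanks
# agreeing (or a single available flank) determine the state; disagreeing
# flanks leave it ambiguous (NA).
locus_state <- function(gmat, positions, locus) {
  at <- match(locus, positions)
  apply(gmat, 1, function(g) {
    ok <- !is.na(g)
    if (!any(ok)) return(NA_character_)
    if (!is.na(at) && ok[at]) return(g[at])  # placement exactly at a marker
    left <- which(ok & positions <= locus)
    right <- which(ok & positions > locus)
    lf <- if (length(left)) g[max(left)] else NA_character_
    rf <- if (length(right)) g[min(right)] else NA_character_
    if (is.na(lf)) return(rf)
    if (is.na(rf)) return(lf)
    if (lf == rf) lf else NA_character_
  })
}

#' Minimum-discordance localisation of the suppressor
#'
#' Scores every candidate locus placement — each marker position and each
#' inter-marker gap (plus the two terminal flanks) — by the number of
#' recombinants whose donor/recipient state there, read from the nearest
#' non-missing flanking markers, mismatches their suppression label
#' (donor-derived state is expected to suppress). Recombinants whose state
#' at a placement is ambiguous (disagreeing flanks, or no genotyped marker
#' at all) contribute nothing there. The reported interval is the span
#' between the innermost markers bounding the minimum-score placements;
#' ties across non-adjacent placements are reported as the union span and
#' flagged ambiguous.
#'
#' @param gmat Recombinants x markers character matrix of
#'   `"donor"`/`"recipient"`/`NA` (a data frame of those columns works).
#' @param marker_map Data frame with `marker`, `chrom`, `pos` (strictly
#'   increasing positions, matching `gmat` columns in order).
#' @param suppressed Logical label per recombinant
#'   (from [partition_phenotypes()]).
#' @return List: `interval` (chrom, start, end: 1-based inclusive marker
#'   bounds; terminal placements extend to the outermost marker),
#'   `score` (minimum discordance), `discordant` (row indices mismatching
#'   at the optimum), `ambiguous` (TRUE when tied placements are not
#'   contiguous), `scores` (per-placement table).
#' @export
map_interval <- function(gmat, marker_map, suppressed) {
  gmat <- as.matrix(gmat)
  if (ncol(gmat) < 1) stop("need at least one marker")
  if (!all(diff(marker_map$pos) > 0)) stop("marker positions must increase")
  if (ncol(gmat) != nrow(marker_map)) {
    stop("genotype columns must match the marker map")
  }
  all_missing <- apply(gmat, 1, function(g) all(is.na(g)))
  if (any(all_missing)) {
    message(sum(all_missing), " recombinant(s) with no genotyped marker excluded")
    gmat <- gmat[!all_missing, , drop = FALSE]
    suppressed <- suppressed[!all_missing]
  }
  pos <- marker_map$pos
  # candidate placements: at each marker, and in each gap (incl. terminal)
  cand_pos <- sort(unique(c(pos, pos - 0.5, max(pos) + 0.5)))
  score_at <- function(locus) {
    st <- locus_state(gmat, pos, locus)
    mism <- !is.na(st) & ((st == "donor") != suppressed)
    sum(mism)
  }
  scores <- vapply(cand_pos, score_at, numeric(1))
  best <- which(scores == min(scores))
  # innermost bounding markers of the minimum-score placements
  span_lo <- min(cand_pos[best])
  span_hi <- max(cand_pos[best])
  # ambiguous when tied placements straddle an interior marker (more than
  # one marker interval is optimal); the union span is then reported
  ambiguous <- length(best) > 1 &&
    sum(pos > span_lo & pos < span_hi) > 0
  left_markers <- pos[pos <= span_lo]
  right_markers <- pos[pos >= span_hi]
  start <- if (length(left_markers)) max(left_markers) else min(pos)
  end <- if (length(right_markers)) min(right_markers) else max(pos)
  opt <- cand_pos[best[1]]
  st <- locus_state(gmat, pos, opt)
  discordant <- which(!is.na(st) & ((st == "donor") != suppressed))
  list(interval = data.frame(chrom = marker_map$chrom[1], start = start,
                             end = end, stringsAsFactors = FALSE),
       score = min(scores), discordant = discordant, ambiguous = ambiguous,
       scores = data.frame(locus = cand_pos, score = scores))
}

#' Exact test of 1:1 marker segregation
#'
#' Two-sided exact binomial test of the marker-carrier count against a 1:1
#' ratio; independence of the suppressor from a visible marker at the far
#' end of the chromosome.
#'
#' @param n_with_marker,n_total Counts, `n_with_marker <= n_total`,
#'   `n_total >= 1`.
#' @return Two-sided exact p-value.
#' @export
marker_segregation_test <- function(n_with_marker, n_total) {
  if (n_total < 1 || n_with_marker < 0 || n_with_marker > n_total) {
    stop("invalid counts")
  }
  stats::binom.test(n_with_marker, n_total, p = 0.5)$p.value
}

#' Fertility comparison between suppressed and unsuppressed males
#'
#' Group means of total offspring per male and a two-sided Welch t-test;
#' a suppressor that rescues sperm raises fertility in SD-bearing males.
#'
#' @param n_offspring Per-recombinant total offspring.
#' @param suppressed Logical labels.
#' @return List: `mean_suppressed`, `mean_unsuppressed`, `ratio`, `p`
#'   (`NA` when either group has < 2 members; error when a group is empty).
#' @export
fertility_compare <- function(n_offspring, suppressed) {
  a <- n_offspring[suppressed]
  b <- n_offspring[!suppressed]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  p <- if (length(a) >= 2 && length(b) >= 2 &&
           (stats::sd(a) > 0 || stats::sd(b) > 0)) {
    stats::t.test(a, b)$p.value
  } else NA_real_
  list(mean_suppressed = mean(a), mean_unsuppressed = mean(b),
       ratio = mean(a) / mean(b), p = p)
}

#' Haplotype-based candidate SNP filter for a mapped suppressor region
#'
#' Within the mapped region, keeps sites where the focal (suppressor)
#' strain differs from the reference strain and where no suppressor-free
#' strain carries the focal allele (missing genotypes count as not
#' carrying). For each candidate, the fraction of known X-suppressor
#' strains carrying the focal allele is reported; if no candidate exceeds
#' `share_threshold`, the focal suppressor haplotype is private — other
#' distinct X-linked suppressors must exist in the panel.
#'
#' @param sites Site metadata (`site`, `chrom`, `pos`).
#' @param geno Sites x strains 0/1/NA matrix (columns named by strain).
#' @param focal_strain,reference_strain Strain ids.
#' @param suppressor_free_strains,x_sup_strains Disjoint strain id sets.
#' @param region List/data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param share_threshold Carrier-fraction threshold (default 0.5).
#' @return List: `candidates` (site, pos, focal_allele, carrier_fraction),
#'   `shared_above_threshold` (logical).
#' @export
haplotype_filter <- function(sites, geno, focal_strain, reference_strain,
                             suppressor_free_strains, x_sup_strains,
                             region, share_threshold = 0.5) {
  if (!focal_strain %in% colnames(geno)) stop("focal strain absent from table")
  if (!reference_strain %in% colnames(geno)) {
    stop("reference strain absent from table")
  }
  if (length(intersect(suppressor_free_strains, x_sup_strains))) {
    stop("suppressor-free and X-suppressor strain sets must be disjoint")
  }
  in_region <- sites$chrom == region$chrom & sites$pos >= region$start &
    sites$pos <= region$end
  idx <- which(in_region)
  foc <- geno[idx, focal_strain]
  ref <- geno[idx, reference_strain]
  differs <- !is.na(foc) & !is.na(ref) & foc != ref
  sf <- geno[idx, intersect(suppressor_free_strains, colnames(geno)),
             drop = FALSE]
  # focal allele carried by any suppressor-free strain? (missing = absent)
  carried_sf <- vapply(seq_along(idx), function(i) {
    any(sf[i, ] == foc[i], na.rm = TRUE)
  }, logical(1))
  keep <- differs & !carried_sf
  cidx <- idx[keep]
  xs <- geno[cidx, intersect(x_sup_strains, colnames(geno)), drop = FALSE]
  frac <- vapply(seq_along(cidx), function(i) {
    g <- xs[i, ]
    ok <- !is.na(g)
    if (!any(ok)) return(NA_real_)
    mean(g[ok] == geno[cidx[i], focal_strain])
  }, numeric(1))
  cands <- data.frame(site = sites$site[cidx], pos = sites$pos[cidx],
                      focal_allele = geno[cidx, focal_strain],
                      carrier_fraction = frac, stringsAsFactors = FALSE)
  list(candidates = cands,
       shared_above_threshold = any(frac > share_threshold, na.rm = TRUE))
}

#' Convert a 1-based inclusive interval to a BED row (0-based half-open)
#' @param interval Data frame with `chrom`, `start`, `end`.
#' @param label Feature name.
#' @return One-row data frame in BED column order.
#' @export
interval_to_bed <- function(interval, label = "interval") {
  data.frame(chrom = interval$chrom, start = interval$start - 1,
             end = interval$end, name = label, stringsAsFactors = FALSE)
}
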