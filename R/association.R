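# Per-SNP linear-model association scan of drive strength k with optional
# copy-number covariate and genotype x covariate interaction, plus the
# MAF/missingness site filters and Bonferroni thresholds.

#' Per-site allele-frequency and missingness statistics
#'
#' Genotypes are haploid-coded 0/1 for inbred lines, `NA` missing.
#'
#' @param geno Sites x strains integer matrix of 0/1/NA.
#' @return Data frame: `maf` (folded, in \[0, 0.5\]), `missing_rate`.
#' @export
snp_stats <- function(geno) {
  p <- rowMeans(geno == 1, na.rm = TRUE)
  p[is.nan(p)] <- NA_real_
  data.frame(maf = pmin(p, 1 - p),
             missing_rate = rowMeans(is.na(geno)))
}

#' Filter SNPs on minor-allele frequency and missingness
#'
#' Retains sites with `maf >= maf_min` and `missing_rate <= missing_max`
#' (the plink-style `--maf 0.1 --geno 0.1` behaviour; monomorphic sites
#' fall at maf 0 and are removed).
#'
#' @param sites Site metadata data frame (same row order as `geno`).
#' @param geno Sites x strains 0/1/NA matrix.
#' @param maf_min,missing_max Thresholds (defaults 0.1 / 0.1).
#' @return List with the filtered `sites` and `geno`.
#' @export
filter_sites <- function(sites, geno, maf_min = 0.1, missing_max = 0.1) {
  st <- snp_stats(geno)
  keep <- !is.na(st$maf) & st$maf >= maf_min & st$missing_rate <= missing_max
  list(sites = sites[keep, , drop = FALSE],
       geno = geno[keep, , drop = FALSE])
}

# OLS of y on design X with t-test p-values; returns NA on rank deficiency
# of the tested columns.
ols_coef_p <- function(X, y, cols) {
  qr_ <- qr(X)
  n <- length(y)
  df <- n - qr_$rank
  out <- matrix(NA_real_, length(cols), 2,
                dimnames = list(cols, c("beta", "p")))
  if (qr_$rank < ncol(X) || df <= 0) return(out)
  beta <- qr.coef(qr_, y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / df
  if (s2 == 0) {  # perfect fit / constant phenotype: no error variance to test
    out[, "beta"] <- beta[match(cols, colnames(X))]
    return(out)
  }
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(s2 * diag(XtXinv))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  idx <- match(cols, colnames(X))
  out[, "beta"] <- beta[idx]
  out[, "p"] <- p[idx]
  out
}

#' Per-SNP linear association scan of drive strength
#'
#' For each retained site, ordinary least squares of the phenotype on the
#' haploid genotype, optionally with a per-strain covariate (the Rsp
#' copy-number composite or a single-method estimate) and, under
#' `model = "interaction"`, the genotype x covariate product. Strains with
#' a missing genotype are dropped per site; p-values come from the t
#' distribution on residual degrees of freedom. Significance thresholds
#' are Bonferroni over the retained site count m: genome-wide `alpha/m`
#' and suggestive `1/m`. The genotype main-effect p is the primary
#' association; the interaction p is reported alongside.
#'
#' @param sites Site metadata (`site`, `chrom`, `pos`), filtered.
#' @param geno Filtered sites x strains 0/1/NA matrix.
#' @param phenotype Named per-strain k vector (names = strain ids).
#' @param covariate Optional named per-strain covariate vector.
#' @param model `"main"` or `"interaction"` (interaction requires a
#'   covariate).
#' @param alpha Genome-wide significance level before correction
#'   (default 0.05).
#' @param min_n Minimum complete strains per site (default 3).
#' @return Data frame: site, chrom, pos, n, beta_g, p_g, beta_int, p_int,
#'   pass_genomewide, pass_suggestive; attributes `m`,
#'   `genomewide_threshold`, `suggestive_threshold`.
#' @export
assoc_scan <- function(sites, geno, phenotype, covariate = NULL,
                       model = c("main", "interaction"), alpha = 0.05,
                       min_n = 3) {
  model <- match.arg(model)
  if (model == "interaction" && is.null(covariate)) {
    stop("interaction model requires a covariate")
  }
  strains <- colnames(geno)
  y_all <- phenotype[strains]
  cv_all <- if (!is.null(covariate)) covariate[strains] else NULL
  m <- nrow(geno)
  beta_g <- p_g <- beta_int <- p_int <- rep(NA_real_, m)
  n_used <- integer(m)
  for (j in seq_len(m)) {
    g <- geno[j, ]
    ok <- !is.na(g) & is.finite(y_all)
    if (!is.null(cv_all)) ok <- ok & is.finite(cv_all)
    n_used[j] <- sum(ok)
    if (n_used[j] < min_n) next
    g_ok <- g[ok]
    if (stats::var(g_ok) == 0) next  # monomorphic after missingness removal
    y <- y_all[ok]
    if (is.null(cv_all)) {
      X <- cbind(`(Intercept)` = 1, g = g_ok)
      cols <- "g"
    } else if (model == "main") {
      X <- cbind(`(Intercept)` = 1, g = g_ok, cv = cv_all[ok])
      cols <- "g"
    } else {
      X <- cbind(`(Intercept)` = 1, g = g_ok, cv = cv_all[ok],
                 gxc = g_ok * cv_all[ok])
      cols <- c("g", "gxc")
    }
    cp <- ols_coef_p(X, y, cols)
    beta_g[j] <- cp["g", "beta"]
    p_g[j] <- cp["g", "p"]
    if ("gxc" %in% cols) {
      beta_int[j] <- cp["gxc", "beta"]
      p_int[j] <- cp["gxc", "p"]
    }
  }
  gw <- alpha / m
  sug <- 1 / m
  out <- data.frame(site = sites$site, chrom = sites$chrom, pos = sites$pos,
                    n = n_used, beta_g = beta_g, p_g = p_g,
                    beta_int = beta_int, p_int = p_int,
                    pass_genomewide = !is.na(p_g) & p_g < gw,
                    pass_suggestive = !is.na(p_g) & p_g < sug,
                    stringsAsFactors = FALSE)
  attr(out, "m") <- m
  attr(out, "genomewide_threshold") <- gw
  attr(out, "suggestive_threshold") <- sug
  out
}

#' Plot-ready Manhattan and QQ tables
#'
#' Adds cumulative genome coordinates (chromosomes laid end to end in
#' their input order) and -log10 p per site, and builds the
#' expected-vs-observed quantile table for a QQ plot.
#'
#' @param rows [assoc_scan()] output (non-empty).
#' @return List: `manhattan` (site, chrom, pos, cum_pos, neglog10p),
#'   `qq` (expected, observed, ascending).
#' @export
export_manhattan_qq <- function(rows) {
  if (!nrow(rows)) stop("no association rows")
  chroms <- unique(rows$chrom)
  offset <- 0
  cum <- numeric(nrow(rows))
  for (ch in chroms) {
    idx <- rows$chrom == ch
    cum[idx] <- rows$pos[idx] + offset
    offset <- offset + max(rows$pos[idx])
  }
  man <- data.frame(site = rows$site, chrom = rows$chrom, pos = rows$pos,
                    cum_pos = cum, neglog10p = -log10(rows$p_g),
                    stringsAsFactors = FALSE)
  p <- sort(rows$p_g[!is.na(rows$p_g)])
  qq <- data.frame(expected = -log10(stats::ppoints(length(p))),
                   observed = -log10(p))
  qq <- qq[order(qq$expected), ]
  rownames(qq) <- NULL
  list(manhattan = man, qq = qq)
}
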