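# Umbrella pipeline: simulate -> copy number -> drive -> census -> scan ->
# recombination mapping, with a reproducibility manifest.

#' Default pipeline configuration
#'
#' Stage parameters mirror each module's defaults; override any element
#' before passing to [run_pipeline()], or supply a YAML file with the same
#' structure.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed (drives the simulation stage).
#' @return Nested list of stage parameter blocks.
#' @export
pipeline_config <- function(out_dir = "results", seed = 1L) {
  list(out_dir = out_dir,
       seed = as.integer(seed),
       sim = list(),  # overrides for sim_config()
       copynum = list(ref_strain = "Iso1", ref_copies = 1100,
                      qpcr_input_ng = 1.9, sensitive_method = "illumina",
                      threshold = 100),
       drive = list(k_threshold = 0.9, alpha = 0.05, strong_delta = 0.1,
                    min_offspring = 40, pooled_variance = FALSE),
       census = list(n_boot = 10000),
       gwas = list(maf_min = 0.1, missing_max = 0.1, model = "main",
                   covariate = "pc1", alpha = 0.05),
       mapx = list(k_threshold = 0.9))
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the [pipeline_config()] structure.
#' @return Config list (defaults filled in for absent blocks).
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipeline_config(out_dir = user$out_dir %||% "results",
                          seed = user$seed %||% 1L)
  for (blk in intersect(names(user), names(base))) {
    if (is.list(base[[blk]])) {
      for (nm in names(user[[blk]])) base[[blk]][[nm]] <- user[[blk]][[nm]]
    } else {
      base[[blk]] <- user[[blk]]
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on a synthetic panel
#'
#' Executes every stage in dependency order, writes each stage's tables
#' under `config$out_dir`, and finishes with a JSON manifest recording the
#' seed, parameters and an md5 per artifact, so a run is reproducible from
#' config + seed alone.
#'
#' @param config A [pipeline_config()] list (or path to a YAML file).
#' @param stages Character subset of
#'   `c("simulate", "copynum", "drive", "census", "gwas", "mapx")`.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "copynum", "drive", "census",
                                    "gwas", "mapx")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  res <- list()
  msg <- function(...) message("[sdsup] ", sprintf(...))

  cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  panel <- simulate_panel(cfg)
  recs <- simulate_recombinants(cfg)
  if ("simulate" %in% stages) {
    write_tsv(panel$truth, out("truth.tsv"))
    write_tsv(panel$crosses, out("crosses.tsv"))
    write_tsv(panel$reads, out("reads.tsv"))
    write_tsv(panel$blot, out("blot.tsv"))
    write_tsv(panel$qpcr, out("qpcr.tsv"))
    write_tsv(panel$standards, out("standards.tsv"))
    write_geno_tsv(panel$snp_sites, panel$snp_geno, out("snps.tsv"))
    write_snp_vcf(panel$snp_sites, panel$snp_geno, out("snps.vcf"))
    write_tsv(recs, out("recombinants.tsv"))
    write_tsv(recombinant_marker_map(cfg), out("markers.tsv"))
    msg("simulate: %d strains, %d cross replicates, %d SNPs, %d recombinants",
        cfg$n_strains, nrow(panel$crosses), nrow(panel$snp_sites), nrow(recs))
  }
  res$panel <- panel
  res$recombinants <- recs

  est <- drive_estimates(panel$crosses, config$drive$min_offspring)
  k_dg <- est$k[est$design == "DGRP-X"]
  names(k_dg) <- est$strain[est$design == "DGRP-X"]
  cn <- config$copynum
  profiles <- copy_number_profiles(panel$reads, panel$blot, panel$qpcr,
                                   panel$standards,
                                   ref_strain = cn$ref_strain,
                                   ref_copies = cn$ref_copies,
                                   qpcr_input_ng = cn$qpcr_input_ng,
                                   k_reference = k_dg,
                                   sensitive_method = cn$sensitive_method,
                                   threshold = cn$threshold)
  if ("copynum" %in% stages) {
    write_tsv(profiles, out("copy_number.tsv"))
    msg("copynum: %d strains profiled, %d complete for PCA",
        nrow(profiles), sum(stats::complete.cases(
          profiles[, c("est_illumina", "est_blot", "est_qpcr")])))
  }
  res$profiles <- profiles

  calls <- suppressor_calls(panel$crosses, profiles,
                            k_threshold = config$drive$k_threshold,
                            alpha = config$drive$alpha,
                            strong_delta = config$drive$strong_delta,
                            min_offspring = config$drive$min_offspring,
                            pooled_variance = config$drive$pooled_variance)
  if ("drive" %in% stages) {
    write_tsv(est, out("drive_estimates.tsv"))
    write_tsv(calls, out("suppressor_calls.tsv"))
    msg("drive: %d strains classified", nrow(calls))
  }
  res$estimates <- est
  res$calls <- calls

  if ("census" %in% stages) {
    cen <- summarize_census(calls)
    jsonlite::write_json(unclass(cen), out("census.json"),
                         auto_unbox = TRUE, digits = NA)
    msg("census: %d%% any suppressor, %d%% autosomal over %d tested",
        cen$pct_any_sup, cen$pct_autosomal, cen$n_tested)
    res$census <- cen
  }

  if ("gwas" %in% stages) {
    flt <- filter_sites(panel$snp_sites, panel$snp_geno,
                        config$gwas$maf_min, config$gwas$missing_max)
    covar <- switch(config$gwas$covariate %||% "none",
                    none = NULL,
                    pc1 = stats::setNames(profiles$pc1, profiles$strain),
                    illumina = stats::setNames(profiles$est_illumina,
                                               profiles$strain))
    scan <- assoc_scan(flt$sites, flt$geno, k_dg, covariate = covar,
                       model = config$gwas$model, alpha = config$gwas$alpha)
    write_tsv(scan, out("assoc.tsv"))
    msg("gwas: %d/%d sites retained, %d genome-wide hits",
        nrow(flt$sites), nrow(panel$snp_sites), sum(scan$pass_genomewide,
                                                    na.rm = TRUE))
    res$scan <- scan
  }

  if ("mapx" %in% stages) {
    mm <- recombinant_marker_map(cfg)
    part <- partition_phenotypes(recs$k[recs$n_offspring > 0],
                                 config$mapx$k_threshold)
    keep <- recs$n_offspring > 0
    gmat <- as.matrix(recs[keep, grep("^m[0-9]+$", names(recs))])
    mapres <- map_interval(gmat, mm, part$suppressed)
    write_interval(mapres, out("interval.bed"), out("interval.json"))
    fert <- fertility_compare(recs$n_offspring[keep], part$suppressed)
    write_tsv(data.frame(group = c("suppressed", "unsuppressed"),
                         mean_offspring = c(fert$mean_suppressed,
                                            fert$mean_unsuppressed),
                         p = fert$p), out("fertility.tsv"))
    msg("mapx: interval %s:%d-%d, %.0f%% suppressed",
        mapres$interval$chrom, mapres$interval$start, mapres$interval$end,
        100 * part$fraction_suppressed)
    res$mapres <- mapres
    res$fertility <- fert
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config), "out_dir")],
                   artifacts = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  res$manifest <- manifest
  invisible(res)
}
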