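# Shared readers and writers. All tabular formats are plain TSV with a
# header; genotypes travel either as a 0/1/NA TSV or as a minimal GT-only
# VCF. Every writer's output round-trips through the matching reader.

#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a haploid genotype matrix as site-metadata + 0/1/NA TSV
#' @param sites Site metadata (`site`, `chrom`, `pos`, ...).
#' @param geno Sites x strains matrix.
#' @param path Output path.
#' @export
write_geno_tsv <- function(sites, geno, path) {
  write_tsv(cbind(sites, as.data.frame(geno, check.names = FALSE)), path)
}

#' Read a genotype TSV written by [write_geno_tsv()]
#' @param path File path.
#' @param meta_cols Names of the leading metadata columns.
#' @return List with `sites` and integer `geno` matrix.
#' @export
read_geno_tsv <- function(path, meta_cols = c("site", "chrom", "pos", "class")) {
  d <- read_tsv(path)
  meta_cols <- intersect(meta_cols, names(d))
  geno <- as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE])
  mode(geno) <- "integer"
  rownames(geno) <- d$site
  list(sites = d[, meta_cols, drop = FALSE], geno = geno)
}

#' Write a minimal GT-only VCF from a haploid genotype matrix
#'
#' Sites become VCF records with placeholder ref/alt alleles and a single
#' GT FORMAT field; haploid codes 0/1 are written as such and missing as
#' `.`.
#'
#' @param sites Site metadata (`chrom`, `pos`; optional `site` for ID).
#' @param geno Sites x strains 0/1/NA matrix (columns named by strain).
#' @param path Output path (`.vcf`, uncompressed).
#' @export
write_snp_vcf <- function(sites, geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(geno)), collapse = "\t")),
             con)
  id <- if ("site" %in% names(sites)) sites$site else rep(".", nrow(sites))
  gt <- matrix(".", nrow(geno), ncol(geno))
  gt[!is.na(geno)] <- as.character(geno[!is.na(geno)])
  body <- paste(sites$chrom, sites$pos, id, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a VCF into a haploid 0/1/NA genotype matrix
#'
#' Inbred-line coding: `0`, `0/0`, `0|0` map to 0; `1`, `1/1`, `1|1` map
#' to 1; missing calls map to `NA`. Heterozygous calls are treated as
#' missing (with a warning) — inbred panel lines are expected homozygous,
#' so residual heterozygosity is unreliable.
#'
#' @param path VCF path (plain or bgzipped; anything [vcfR::read.vcfR()]
#'   accepts).
#' @return List: `sites` (site, chrom, pos) and integer `geno`
#'   (sites x strains).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  code <- function(x) {
    x[x %in% c(".", "./.", ".|.")] <- NA
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0", "0/0", "0|0")] <- 0L
    out[x %in% c("1", "1/1", "1|1")] <- 1L
    het <- !is.na(x) & x %in% c("0/1", "1/0", "0|1", "1|0")
    if (any(het)) {
      warning(sum(het), " heterozygous call(s) set to missing")
    }
    out
  }
  geno <- matrix(code(as.vector(gt)), nrow = nrow(gt),
                 dimnames = dimnames(gt))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- sprintf("%s_%d", chrom, pos)[is.na(id) | id == "."]
  sites <- data.frame(site = id, chrom = chrom, pos = pos,
                      stringsAsFactors = FALSE)
  rownames(geno) <- sites$site
  list(sites = sites, geno = geno)
}

#' Write an interval as BED (0-based half-open) and JSON (1-based)
#' @param mapres A [map_interval()] result.
#' @param bed_path,json_path Output paths (NULL skips either).
#' @param label Feature label.
#' @export
write_interval <- function(mapres, bed_path = NULL, json_path = NULL,
                           label = "SuX_interval") {
  if (!is.null(bed_path)) {
    utils::write.table(interval_to_bed(mapres$interval, label), bed_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(chrom = mapres$interval$chrom,
                              start = mapres$interval$start,
                              end = mapres$interval$end,
                              score = mapres$score,
                              ambiguous = mapres$ambiguous,
                              discordant = mapres$discordant),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(mapres)
}
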