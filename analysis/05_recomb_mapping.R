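#!/usr/bin/env Rscript
# Stage 5: recombination mapping of the major X-linked suppressor.
#
# Recombinant k values are bimodal; k < 0.9 defines suppression. The
# minimum-discordance search places the suppressor in the marker interval
# whose donor/recipient state best co-segregates with suppression, the
# exact binomial test checks 1:1 segregation with the telomeric y marker,
# fertility is compared between groups, and the haplotype filter screens
# panel SNPs in the mapped region for candidates shared by X-suppressor
# strains.

library(sdsup)

recs <- read_tsv("results/recombinants.tsv")
mm <- read_tsv("results/markers.tsv")
recs <- recs[recs$n_offspring > 0, ]

part <- partition_phenotypes(recs$k, 0.9)
message(sprintf("%d of %d recombinants suppress (k < 0.9): %.0f%%",
                sum(part$suppressed), nrow(recs),
                100 * part$fraction_suppressed))

gmat <- as.matrix(recs[, grep("^m[0-9]+$", names(recs))])
mi <- map_interval(gmat, mm, part$suppressed)
message(sprintf("mapped interval %s:%s..%s (discordance %d, %d discordant recombinants%s)",
                mi$interval$chrom, format(mi$interval$start, big.mark = ","),
                format(mi$interval$end, big.mark = ","), mi$score,
                length(mi$discordant),
                if (mi$ambiguous) ", ambiguous tie" else ""))
write_interval(mi, "results/interval.bed", "results/interval.json")

n_y <- sum(recs$y_marker)
p_seg <- marker_segregation_test(n_y, nrow(recs))
message(sprintf("y marker in %d/%d recombinants (%.0f%%), exact 1:1 test P = %.2f",
                n_y, nrow(recs), 100 * n_y / nrow(recs), p_seg))

fert <- fertility_compare(recs$n_offspring, part$suppressed)
message(sprintf("offspring per male: %.0f suppressed vs %.0f unsuppressed (ratio %.2f, P = %.2g)",
                fert$mean_suppressed, fert$mean_unsuppressed, fert$ratio,
                fert$p))
write_tsv(data.frame(group = c("suppressed", "unsuppressed"),
                     mean_offspring = c(fert$mean_suppressed,
                                        fert$mean_unsuppressed),
                     p = fert$p), "results/fertility.tsv")

# haplotype screen: candidates private to a strong X-suppressor strain
# within the mapped region, shared (or not) by the other X-sup strains
snps <- read_geno_tsv("results/snps.tsv")
calls <- read_tsv("results/suppressor_calls.tsv")
truth <- read_tsv("results/truth.tsv")
x_sup <- calls$strain[calls$x_linked & calls$x_strong]
sup_free <- calls$strain[!calls$x_linked & !calls$autosomal &
                           !calls$rsp_insensitive %in% TRUE]
focal <- x_sup[which.max(truth$sup_X[match(x_sup, truth$strain)])]
reference <- sup_free[1]
hf <- haplotype_filter(snps$sites, snps$geno, focal, reference,
                       setdiff(sup_free, reference), setdiff(x_sup, focal),
                       list(chrom = mi$interval$chrom,
                            start = mi$interval$start,
                            end = mi$interval$end))
write_tsv(hf$candidates, "results/haplotype_candidates.tsv")
message(sprintf("haplotype screen (focal %s vs %s): %d candidate SNPs, shared above 50%%: %s",
                focal, reference, nrow(hf$candidates),
                hf$shared_above_threshold))
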