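#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study panel.
#
# One run of the generator at its default study-scale conditions: 90 inbred
# strains with lognormal Rsp copy numbers, per-chromosome suppressor
# carriers (X ~52%, chr2 ~39%, chr3 ~25%), reciprocal crosses in both
# F1-male designs, three copy-number assay readouts, a SNP matrix, and 239
# recombinant X chromosomes segregating one major mid-X suppressor.
# All downstream stages read these tables from results/.

library(sdsup)

cfg <- sim_config(seed = 1L)
dir.create("results", showWarnings = FALSE)

panel <- simulate_panel(cfg)
recs <- simulate_recombinants(cfg)

write_tsv(panel$truth, "results/truth.tsv")
write_tsv(panel$crosses, "results/crosses.tsv")
write_tsv(panel$reads, "results/reads.tsv")
write_tsv(panel$blot, "results/blot.tsv")
write_tsv(panel$qpcr, "results/qpcr.tsv")
write_tsv(panel$standards, "results/standards.tsv")
write_geno_tsv(panel$snp_sites, panel$snp_geno, "results/snps.tsv")
write_snp_vcf(panel$snp_sites, panel$snp_geno, "results/snps.vcf")
write_tsv(recs, "results/recombinants.tsv")
write_tsv(recombinant_marker_map(cfg), "results/markers.tsv")

message(sprintf("panel: %d strains (%d with <100 Rsp copies), %d cross replicates",
                nrow(panel$truth), sum(panel$truth$true_copies < 100),
                nrow(panel$crosses)))
message(sprintf("SNPs: %d sites x %d strains; recombinants: %d",
                nrow(panel$snp_sites), ncol(panel$snp_geno), nrow(recs)))
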