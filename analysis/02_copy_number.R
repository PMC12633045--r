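#!/usr/bin/env Rscript
# Stage 2: Rsp copy number per strain from the three assays, fused by PCA.
#
# Each assay is normalised against the Iso1 reference allele (1100 copies):
# read counts as reads-per-million, blot signal ratios against the loading
# control, and qPCR threshold cycles through the reference standard curve.
# The composite PC1 score (sign-oriented to correlate positively with drive
# strength) summarises the three estimates; strains with fewer than 100
# copies are flagged insensitive to drive.

library(sdsup)

reads <- read_tsv("results/reads.tsv")
blot <- read_tsv("results/blot.tsv")
qpcr <- read_tsv("results/qpcr.tsv")
standards <- read_tsv("results/standards.tsv")
crosses <- read_tsv("results/crosses.tsv")

est <- drive_estimates(crosses)
dgx <- est$design == "DGRP-X"
k_dg <- setNames(est$k[dgx], est$strain[dgx])

prof <- copy_number_profiles(reads, blot, qpcr, standards, k_reference = k_dg)
write_tsv(prof, "results/copy_number.tsv")

ve <- attr(prof, "var_explained")
message(sprintf("profiled %d strains; %d insensitive (<100 copies) by the computational estimate",
                nrow(prof), sum(!prof$sensitive, na.rm = TRUE)))
message(sprintf("assay medians: illumina %.0f, blot %.0f, qPCR %.0f copies",
                median(prof$est_illumina, na.rm = TRUE),
                median(prof$est_blot, na.rm = TRUE),
                median(prof$est_qpcr, na.rm = TRUE)))
message(sprintf("PCA on %d complete strains: PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%",
                sum(!is.na(prof$pc1)), 100 * ve[1], 100 * ve[2], 100 * ve[3]))
message(sprintf("PC1 vs k (DGRP-X): r = %.2f",
                cor(prof$pc1, k_dg[prof$strain], use = "complete.obs")))
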