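#!/usr/bin/env Rscript
# Stage 3: drive strength, suppressor classification, and the census.
#
# Replicates with 40 or fewer offspring are dropped; per strain and cross
# design, k is pooled over counts. X-linked suppressors are called from the
# one-tailed reciprocal comparison (k higher in NoX males than in DGRP-X
# males), autosomal suppression from pooled k(NoX) < 0.9, and strains with
# insensitive Rsp are excluded from suppressor inference. The stage closes
# with the chromosome-level product estimator applied to the study's
# printed extraction counts as a worked example.

library(sdsup)

crosses <- read_tsv("results/crosses.tsv")
prof <- read_tsv("results/copy_number.tsv")

est <- drive_estimates(crosses)
write_tsv(est, "results/drive_estimates.tsv")

calls <- suppressor_calls(crosses, prof)
write_tsv(calls, "results/suppressor_calls.tsv")

cen <- summarize_census(calls)
print(cen)
jsonlite::write_json(unclass(cen), "results/census.json",
                     auto_unbox = TRUE, digits = NA)

# chromosome-level frequencies from the printed extraction counts:
# 51/88 strains with dominant autosomal suppressors; 6/9 extracted second
# and 3/7 extracted third chromosomes suppressed in a common background
chr2 <- chromosome_frequency(51 / 88, 6, 9, seed = 1)
chr3 <- chromosome_frequency(51 / 88, 3, 7, seed = 2)
message(sprintf("second chromosomes suppressing: %d%% (95%% CI %.0f-%.0f%%)",
                chr2$percent, 100 * chr2$ci[1], 100 * chr2$ci[2]))
message(sprintf("third chromosomes suppressing: %d%% (95%% CI %.0f-%.0f%%)",
                chr3$percent, 100 * chr3$ci[1], 100 * chr3$ci[2]))
write_tsv(data.frame(arm = c("2", "3"),
                     percent = c(chr2$percent, chr3$percent),
                     ci_lo = c(chr2$ci[1], chr3$ci[1]),
                     ci_hi = c(chr2$ci[2], chr3$ci[2])),
          "results/chromosome_frequency.tsv")
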