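---
title: "Models and methods behind the suppressor census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the suppressor census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdsup)
```

This vignette is the package's own account of its models: what is assumed,
which parameters matter, what the synthetic generator does and does not
emulate, and where the genuinely open design choices were settled.

## Drive strength and the sensitivity model

Drive strength is the proportion of a male's offspring inheriting the
SD-marked chromosome, $k = n_{SD}/(n_{SD}+n_{WT})$, with $k = 0.5$ under
Mendelian segregation. The package's generative model for $k$ is

$$k \;=\; 0.5 + 0.5\,\mathrm{sens}(c)\prod_i (1 - s_i),
\qquad
\mathrm{sens}(c) = \begin{cases} 0 & c < 100\\[2pt]
\dfrac{c}{c + c_{50}} & c \ge 100,\end{cases}$$

where $c$ is the *Rsp* repeat count of the target chromosome, $c_{50}$ the
half-saturation copy number, and $s_i \in [0,1]$ the strengths of the
unlinked suppressors carried by the male. The assumptions: chromosomes
under ~100 repeats escape killing entirely; sensitivity saturates with
copy number; suppressors act multiplicatively and independently, each
rescuing a fraction $s_i$ of the doomed sperm. This is the minimal monotone
form consistent with the known facts (a hard insensitivity threshold, a
positive copies–drive relationship, suppressors that reduce but never
reverse drive); no empirical dose–response for either axis exists, so any
"strength" recovered downstream is model-relative. The default
$c_{50} = 50$ keeps a reference-like 1100-copy target at
$k \approx 0.98$ — essentially complete drive — without suppressors.

Two consequences worth knowing. First, with $c_{50}=50$ sensitivity is
nearly saturated over most of the copy distribution, so the copies–$k$
correlation across a panel *with* segregating suppressors is weak; the
association-scan property that conditioning on copy number removes
copies-mediated signal is therefore demonstrated on suppressor-free panels,
which isolate that pathway. Second, negative distortion ($k<0.5$) is
impossible by construction, matching the assay design.

## The synthetic panel

`sim_config()` records every generative choice; `simulate_panel()` draws,
per strain: true copies $\sim\mathrm{round}(\mathrm{Lognormal}(\log 800,\,1))$,
putting a few percent of strains under the 100-copy threshold (two strains
of 90 in a typical draw); suppressor carriage on the X, second and third
chromosome with probabilities 0.52, 0.39 and 0.25 and strengths uniform on
$[0.5, 1]$. Per replicate male and cross design, total offspring is
negative binomial (mean 104, dispersion 5 — overdispersed fly fecundity)
and SD-marked offspring binomial with the male's expected $k$; males whose
sperm are rescued (expected $k<0.9$) produce 2.16-fold more offspring, the
ratio of the two fertility means the recombination stage recovers
(~225 vs ~104).

The three assay tables are generated so each quantifier inverts its
simulator in expectation: read counts are Poisson around
$c \times \mathrm{depth}$ with lognormal multiplicative noise (mean 1, CV
`noise_illumina`); blot slots carry multiplicative noise on both probe and
loading-control signals; qPCR threshold cycles follow perfect doubling
chemistry ($-1/\log_{10}2 \approx -3.32$ per 10-fold dilution) with noise
entering as a multiplicative error on template mass. The reference strain's
rows and the dilution standards are emitted *without* noise: the reference
is the calibration anchor that defines the copy-number scale, and
uncertainty in a pure scale factor is unidentifiable from panel data —
simulating it would only inject an arbitrary shared bias into every strain.
With every noise CV at 0 the inversion is exact, which the tests assert.
The default CVs (0.2 sequencing, 0.3 blot and qPCR) produce between-method
rank correlations around 0.9, tighter than real assay panels; consequently
the PC1 variance share on synthetic data (~95%) overstates what real
heterogeneous assays give, and tests assert PC1 dominance rather than any
particular percentage. Passing these tests shows the estimators and their
fusion are correct, not that real assays are this well behaved.

SNP matrices are haploid 0/1 (inbred lines), with uniform-MAF background
sites, a perfect haplotype on the X tagging X-suppressor carriers (what a
causal haplotype looks like at full linkage), and pericentric chromosome-2
sites that tag high-copy strains with a 10% flip rate — sites whose only
path to $k$ runs through copy number. Linkage disequilibrium between
background sites, population structure and relatedness are *not* emulated;
the scan's nominal type-I behaviour on this matrix says nothing about
confounding in structured panels.

## Drive assay and classification

Replicates with 40 or fewer offspring are discarded (strict inequality).
The strain-level $k$ pools counts, $\sum n_{SD} / \sum n$, rather than
averaging replicate proportions — replicates with more offspring carry more
information — while the displayed standard error is computed across
replicate-level $k$ values; both are reported. The reciprocal comparison is
a one-tailed two-sample t-test on replicate $k$ values (alternative:
$k_{NoX} > k_{DGRP\text{-}X}$), Welch form by default since nothing
guarantees equal variances; `pooled_variance = TRUE` restores the classic
equal-variance test. When both designs are degenerate (every replicate $k$
identical, e.g. complete drive throughout), the comparison falls back to
the one-sided Fisher exact test on the pooled 2×2 count table, labelled
`method = "exact"`. No multiple-testing correction enters the per-strain
calls — the assay is a census, not a discovery scan — but a
Benjamini–Hochberg column is emitted alongside for transparency.

Strains whose *Rsp* allele is insensitive are excluded from suppressor
inference: with no killing there is nothing to suppress, and their low $k$
would otherwise masquerade as suppression. Which assay feeds the
sensitivity call is configurable (default: the computational estimate).
Note one deliberate conflation inherited from the assay design: pooled
$k_{NoX} < 0.9$ cannot distinguish dominant autosomal suppressors from
intermediate-sensitivity *Rsp* alleles, so the "autosomal" class contains
both.

## Census and the product estimator

Census percentages use round-half-away-from-zero (base R's `round()` is
banker's rounding). The chromosome-level frequency multiplies the fraction
of strains with dominant autosomal suppressors by the fraction of extracted
chromosomes of one arm that suppressed: with the study-scale counts,
$(51/88)\times(6/9)=38.6\% \to 39\%$ for the second chromosome and
$(51/88)\times(3/7)=24.8\% \to 25\%$ for the third. The parametric
bootstrap CI (resampling both binomial proportions) is an extension beyond
the point estimate — nine and seven extractions are fragile denominators
and the interval makes that visible; its coverage is checked by simulation
in the test suite.

## Association scan

Per retained site (MAF $\ge$ 0.1, missingness $\le$ 0.1, haploid coding
with heterozygous VCF calls demoted to missing), ordinary least squares of
$k$ on genotype, optionally with a per-strain copy-number covariate and a
genotype × covariate interaction. Strains missing a genotype are dropped
per site; p-values come from the t distribution on residual degrees of
freedom; sites left monomorphic or rank-deficient after dropping return
missing p-values. The genotype main effect is the primary association;
the interaction p-value is reported alongside. Thresholds are Bonferroni
over the retained site count $m$: genome-wide $0.05/m$, suggestive $1/m$.
No kinship or relatedness correction is applied — a known limitation,
matching the scan's design.

## Recombination mapping

Recombinants are generated under a single-crossover model (uniform
position on the marker span, donor segment on either side with equal
probability). One generation of recombination over ~21 Mb makes double
crossovers rare enough to ignore for interval mapping, but the inference
side never *assumes* single crossovers: a recombinant's state at a
candidate locus is read from its nearest non-missing flanking markers
only, so genotyping errors that create extra switches merely add local
ambiguity.

The interval search scores every candidate placement — each marker and
each inter-marker gap, plus the terminal flanks — by the number of
recombinants whose flank-read state (donor ⇒ suppressed expected)
mismatches their $k<0.9$ label; recombinants whose flanks disagree at a
placement are ambiguous there and contribute nothing. The reported
interval spans the innermost markers bounding the minimum-score
placements; ties straddling an interior marker are unioned and flagged
ambiguous. The search is exhaustive and the tests verify it against an
independently written brute-force enumeration.

Two properties of this scorer shaped the defaults. Because ambiguous
recombinants contribute zero, masking genotypes can only *lower* the
optimal score (the monotone direction the tests assert), and — less
benignly — wider gaps absorb more crossovers into ambiguity and thereby
get discounted scores. The default marker map is therefore an even 1.5 Mb
lattice with the suppressor locus mid-gap, the layout a mapping study
would design around a candidate region; on it, the true flanking-marker
interval is recovered in ~99% of seeded simulations at 239 recombinants
and 5% phenotype noise. Recovery degrades when the locus abuts a marker
(few informative crossovers on the short side) or when gap widths vary
strongly; users supplying their own maps should prefer comparable gap
widths or interpret wide-gap optima cautiously.

The 1:1 segregation check against the telomeric marker is an exact
two-sided binomial test (only one margin of the 2×2 is available in
count form; with both margins a Fisher test is the natural extension).
Fertility is compared with a two-sided Welch t-test on offspring totals.
The haplotype filter keeps region SNPs where the focal suppressor strain
differs from the reference and no suppressor-free strain carries the focal
allele (missing genotypes count as absent), then reports each candidate's
carrier fraction among the other X-suppressor strains; on the synthetic
panel the planted haplotype is found at carrier fraction 1, whereas on
real data a below-threshold fraction is the signature of allelic
heterogeneity among X-linked suppressors.

## Numerical choices and degenerate inputs

Tie handling: exactly 100 copies classifies as sensitive (the threshold's
two one-sided phrasings disagree at the boundary; sensitivity is the
conservative call); $k$ exactly 0.9 is *not* suppressed; a replicate with
exactly 40 offspring is dropped. A single-marker map degenerates to a
point interval flagged ambiguous. Zero-variance phenotypes yield missing
scan p-values rather than zeros. All genomic coordinates are 1-based
inclusive internally; BED export converts to 0-based half-open.

Problem sizes in the test and acceptance runs — 90-strain panels, 2,000
background SNPs, 10,000 null sites for the type-I check, 200 seeded
mapping simulations, 10,000 bootstrap draws — were chosen as the smallest
sizes at which the binomial/Monte-Carlo error of each checked quantity is
comfortably below its assertion tolerance.

## Known limitations

No multi-generation population dynamics, no drive enhancers or
inversions, no temperature or age effects, no negative distortion, no
linkage disequilibrium or relatedness structure in the SNP generator, no
gene-level annotation of mapped intervals. The suppressor-strength scale
is model-relative throughout.
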