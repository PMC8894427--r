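---
title: "Models and methods in poolSeqER"
author: "poolSeqER authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in poolSeqER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolSeqER)
```

# Scope

`poolSeqER` analyses evolve-and-resequence experiments with reciprocal
transplants, in the design popularised by multigenerational selection
studies in copepods: two selection lines (ambient, AM; ocean warming and
acidification, OWA) evolved in replicate cultures for ~20 non-overlapping
generations, then each replicate split and reared for three further
generations in both environments.  Each of the 48 samples (2 lines x 2
environments x 3 generations x 4 replicates) is a pooled RNA library of 20
diploid adults, from which both gene-level counts and allele read counts
at biallelic sites are derived.

The package implements the downstream statistics only; read processing,
alignment and variant calling are out of scope, and inputs enter as
sync-style allele count tables and gene x sample count matrices.

# Variant filtering and adaptive-locus detection

The filter cascade drops, in order: (1) sites with any sample below 50
total reads (2.5 reads per diploid in a pool of 20; zero-depth "missing"
samples fall here too); (2) sites whose median depth exceeds 3x the
dataset-wide median site depth (collapsed paralogs); (3) sites with fewer
than four samples carrying a within-sample minor-allele frequency of at
least 0.025, i.e. one heterozygote among 40 chromosomes.  Minor-allele
frequencies are read-based, as appropriate for pooled data.  The cascade
order is not fully determined by its description; the implemented order is
the one above and the per-rule rejection ledger makes it auditable.

Divergence between the home lines (AM_AM vs OWA_OWA) is tested per site
and generation with the classic Cochran-Mantel-Haenszel chi-square
without continuity correction, one 2x2 table (alleles x lines, read
counts) per replicate stratum.  Strata with a zero margin are skipped
rather than 0.5-corrected; at 50x coverage and above the choice is
invisible.  Counts enter as reads, not pool-size-rescaled chromosomes;
read counts overstate the number of independent chromosomes sampled, so
p-values are anti-conservative in absolute terms, which is why detection
is gated by the severe Bonferroni threshold alpha / (n_sites x
n_generations) and by the requirement that a site be significant in *all*
tested generations.  With the study-scale inputs (322,595 sites, 3
generations, alpha = 0.05) the threshold is 5.17e-08.  `alpha >= 1` is
accepted as a degenerate everything-significant setting.

Small-table behaviour of the chi-square is checked in the test suite
against an exact conditional oracle that enumerates all tables with the
observed margins (product-hypergeometric null, mid-p of the statistic).
Agreement within 2x holds throughout the regime the filters admit (every
cell at least 2 reads); for pathological tables with empty or near-empty
cells no 1-df asymptotic test tracks the exact tail, and no claim is made
there.

# Differential expression and the plasticity partition

Counts are filtered (genes with fewer than 10 reads in more than 90% of
samples are removed), normalised by median-of-ratios size factors and,
for geometry only, transformed as log2(normalised + 1).  A heavier
variance-stabilising transform would change nothing downstream of it but
rank structure, which the transform preserves.

Each generation is analysed separately with five two-cell contrasts:
within-line plastic responses (AM_AM vs AM_OWA; OWA_OWA vs OWA_AM), the
home-line divergence (AM_AM vs OWA_OWA) and the two
transplant-vs-destination contrasts.  Per gene we fit a negative-binomial
log-linear model by IRLS with the log size factor as offset and a fixed
per-gene dispersion: a method-of-moments estimate from within-cell
residuals, floored at 1e-8, then shrunk 50% (geometrically) toward a
mean-dispersion trend fitted as alpha(mu) = a0 + a1/mu.  The trend is fit
on the natural scale because a log-log linear fit is biased low for noisy
dispersion estimates and measurably inflates false positives downstream.

The Wald statistic for the contrast is referred to a *moderated t*
distribution whose degrees of freedom are the dispersion-estimation
residual df plus an equal prior df contributed by the 50% shrinkage
(equal-weight shrinkage is exactly an equal-weight prior).  At this
design size (4 replicates per cell) a plain normal reference is
anti-conservative: in null simulations it rejects 7-8% at nominal 5%.
With the moderated reference, null simulations at the design size give
approximately uniform p-values and a BH false-discovery fraction at or
below its nominal level; planted twofold changes are detected with >90%
power at the per-test level, and stronger changes survive the BH step.
These operating characteristics are asserted in the test suite.

Plastic gene sets per line are the BH-significant genes (padj < 0.05) of
the within-line contrasts.  Genes diverged between the home lines are
partitioned per direction of adaptation: *genetic change* (GC) when the
transplanted line still differs from its destination home line, otherwise
*plasticity only* (PO) when the source line's plastic contrast is
significant.  The classes are mutually exclusive by construction and need
not cover the eligible set, since a diverged gene may be significant in
neither follow-up contrast.

The cross-line comparison of plastic responses is an ordinary
least-squares slope of one line's log2 fold changes on the other's over
genes differentially expressed in one or both lines (union).  OLS is used
because the choice of regression family is not determined by the
analysis; a major-axis variant can be obtained by fitting the returned
fold changes externally.

# Discriminant-space shifts

For each generation the two non-transplanted groups define a
discriminant axis: PCA of the centred features (log-expression, or
alternate-allele frequencies at filtered sites), then a two-group linear
discriminant on the retained PC scores, axis proportional to the pooled
within-group covariance inverse times the group-mean difference (ridge
1e-8 when singular).  Four PCs are retained for expression and three for
allele frequencies by default; a retain-to-80%-variance mode exists
because the original retention rule is data-dependent.  Transplanted
samples are projected onto the axis; projection is affine and reproduces
the home-group means.

Shifts are modelled as coordinate = intercept + line + line-specific
transplant effect with a replicate-culture random intercept (each
replicate culture was split into both environments, so replicate is
shared across cells).  The model is fitted by a Gibbs sampler with
conjugate normal/inverse-gamma priors on standardised data (vague prior
variance 100 on coefficients, IG(0.001, 0.001) on variances), 500
burn-in iterations and 2500 retained draws.  Per effect the posterior
sign-crossing p-value is 2 min(Pr(>0), Pr(<0)), floored at 1/2500 =
4e-04 when no draw crosses zero — the "< 4e-04" reporting convention.
The between-line comparison is the posterior of |effect AM| - |effect
OWA|.  Split-chain R-hat above 1.1 triggers a warning; with 16
observations and conjugate updates the sampler mixes essentially
immediately, and doubling the draws moves posterior means by less than
two Monte-Carlo standard errors (asserted in tests).

# Nucleotide diversity

Per-site diversity in a pooled sample is the unbiased read-pair
heterozygosity 2 ref alt / (C (C-1)), the probability that two reads
drawn without replacement differ; sites with fewer than two reads are
skipped.  No pool-size correction is applied by default: at pool size 20
the n/(n-1) factor is a near-constant 40/39 that cancels in the delta-pi
contrasts; a knob enables it.  Windows tile each contig in 100-bp
non-overlapping blocks (0-based half-open against 1-based site
positions); window pi divides by the full window length, with a
minimum-covered-fraction knob (default 0) for RNA-derived patchy
coverage.  Per-replicate median pi is compared across treatment x
generation cells by one-way ANOVA with Tukey HSD and a compact letter
display.  Targeted erosion is tested by flagging windows containing at
least one adaptive SNP, computing each window's change in
replicate-mean pi relative to the AM_AM F1 baseline, and comparing
adaptive against non-adaptive windows per cell with two-sided Wilcoxon
rank-sum tests, Bonferroni-corrected across cells.

# Rank-based enrichment

Functional enrichment is threshold-free: per category, a one-sided
Mann-Whitney U test of in-category gene statistics against all other
genes, midranks for ties, tie-corrected variance with continuity
correction in the normal approximation, and exact enumeration of rank
placements when both groups have at most 8 genes.  Allelic statistics
are collapsed to genes by the minimum p-value over a gene's SNPs
(reported as -log10).  Categories are tested flat: no ontology-graph
propagation or category merging is performed, which is the main
difference from graph-walking GO tools and is deliberate scope.

# Life history

Per mate pair, egg production rate is (E_u + E_h)/t and hatching success
E_h/(E_u + E_h); pairs with a dead female are excluded entirely, pairs
with a dead male keep EPR only, and zero-egg pairs have undefined
hatching success.  Day-specific survival is P_1 = 1 and P_x = l_x /
l_{x-1} on the observation grid (no interpolation).  The Leslie matrix
has these probabilities on the subdiagonal and, on all days from the
first observed adult onward (a strict-after knob exists), a first row of
EPR x HS scaled by the proportion of females among sexed adults —
"ratio of females to males" is dimensionally ambiguous, and proportion
female is the demographically standard reading (a raw-ratio knob
exists).  The net reproductive rate lambda is the dominant eigenvalue;
every eligible survivorship beaker is crossed with every eligible mate
pair of its cell (at most 4 x 12 = 48 matrices) and the cell estimate is
the mean with the normal-theory interval xbar +/- 1.960 SD / sqrt(n).
Survivorship curves are compared with the classic two-group log-rank
statistic on the decrement series.

# The synthetic-data generator

The generator exists so that every stage is testable without the
deposited sequencing data; it emulates the statistical structure the
analysis assumes, not the biology of any particular transcriptome.

*Allele frequencies*: unlinked loci, initial frequencies uniform on
[0.05, 0.95], Wright-Fisher binomial drift of 2 ne gametes per
generation.  Selected loci (default 5%) receive the deterministic update
p(1+s)/(1+ps) before drift in the OWA line during burn-in; during the
transplant phase selection continues forward in the OWA environment and
is reversed (favouring the ancestral allele, coefficient `sTransplant`,
default equal to s) for the OWA line returned to ambient, while AM_AM
stays neutral.  The culture census was ~4000; within-culture effective
size is unreported, so ne defaults to 1000 and is exposed, not asserted.
Pooled counts are sampled as pool (binomial, 40 chromosomes), then depth
(negative binomial around 174x), then reads (binomial); allele-biased
expression is off by default, mirroring the finding that it leaves no
detectable imprint, with a bias knob for sensitivity analysis.

*Expression*: negative-binomial counts around a log-linear mean with a
per-sample depth factor.  Gene classes: 15% plastic (environment
effect, 2 log2 units), 5% carrying a purely constitutive line effect
(2 log2 units), and half of the plastic genes also carrying the aligned
constitutive shift — adaptive plasticity that became assimilated.  In
the OWA line the plastic effect is multiplied by (1 - loss), with loss =
1 for a default 90% of plastic genes.  These defaults were chosen once
to reproduce the qualitative regime of the motivating system — a
strongly asymmetric plastic response (AM far exceeding OWA at F1), more
plasticity-only than genetic-change genes in the forward direction and
the reverse in the opposite direction, and a larger AM than OWA
discriminant shift at F1 — and are stated here rather than tuned per
test.  Effect sizes are large because the emulated system detects
thousands of responding genes at four replicates per cell.

*Life history*: binomial survival chains from 25 individuals (daily
survival by food level: 0.97 replete, 0.93 limited, 0.60 starved — the
last guaranteeing no survival to maturity, as observed), Poisson egg
production with a transplant penalty (strongest for OWA returned to
ambient), binomial hatching, Bernoulli sexing, and elevated female
mortality in the OWA-to-ambient food-limited cell where the emulated
assay lost the most pairs.

What passing tests on this generator do *not* show: linkage and physical
clustering of selected loci, transcriptome-wide coverage structure
(coverage here is exchangeable across sites), batch or lane effects,
transgenerational plasticity, and any coupling between allele
frequencies and expression beyond the optional bias knob.  Conclusions
about those features of real data are outside what the suite certifies.

# Reproducibility and problem sizes

All stochastic stages derive a child seed deterministically from the
top-level seed and the stage name, so runs are bit-reproducible.  The
test suite and the acceptance script run the generator at 2,000 loci and
2,000 genes (400/300 for the smoke fixtures) — sizes chosen so the full
statistical structure (48 samples, 4 replicate strata, 3 generations) is
exercised while a complete run stays interactive on a laptop; the
detection and recovery properties asserted are scale-free rates, not
absolute counts.

# Known limitations

The NB GLM is a documented simplification of empirical-Bayes DE
machinery (no per-gene dispersion likelihood, no fold-change shrinkage);
the enrichment module tests flat categories only; the CMH uses read
counts with an optional pool-rescaling knob (default off) — read-based
testing is anti-conservative in absolute p terms and is paired with the
severe multi-generation intersection rule; lambda confidence intervals
use the normal formula on a cross-product ensemble whose 48 values are
not independent (12 pairs x 4 beakers), so they understate uncertainty
— this is the published estimator, reproduced as specified.
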