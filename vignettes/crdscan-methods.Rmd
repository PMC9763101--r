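---
title: "Methods: calling cis-regulatory domains and dissecting their genetic regulation"
author: "crdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling cis-regulatory domains and dissecting their genetic regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`crdscan` analyses coordinated regulatory activity in population-scale
chromatin data. The input is a cohort of individuals with (i) chromatin peak
quantifications (e.g. H3K27ac ChIP-seq), (ii) gene expression, and (iii)
genotypes. The pipeline:

1. normalizes phenotypes (covariate regression + rank-normal transform),
2. calls **cis-regulatory domains (CRDs)** — sets of genomically contiguous
   peaks whose activity is correlated across individuals,
3. characterizes condition-specific CRDs (per-peak Mann-Whitney tests,
   per-CRD correlation shifts, annotation enrichment),
4. tests CRDs and genes for differential activity/expression between
   conditions with a negative-binomial Wald test on raw counts,
5. maps cis-QTLs for genes, peaks and CRD activity with a permutation pass
   and beta approximation, conditional signals, genotype-by-condition
   interactions, and RTC colocalization,
6. associates CRDs with genes, builds (variant, CRD, gene) triplets via PC1
   pseudo-phenotypes, and classifies each triplet as **causal**
   (variant &rarr; CRD &rarr; gene), **reactive** (variant &rarr; gene
   &rarr; CRD) or **independent** with Gaussian Bayesian networks and
   bootstrap confidence.

A synthetic-cohort generator with planted ground truth accompanies the
pipeline; every statistical component is validated against it.

## Normalization

Phenotypes are residualized on covariates (genotype PCs for ancestry,
phenotype PCs for technical structure, any declared covariates) and then
each feature is mapped to N(0, 1) by the rank-based inverse normal
transform, `qnorm((rank - 0.5) / m)`. Residualize-then-transform is the
usual QTL-mapping order and is what `normalize_phenotypes()` implements.
Ties are broken deterministically by input order; NAs keep their positions
and all downstream statistics use pairwise-complete samples. The number of
phenotype PCs can be fixed or chosen by `select_pc_count()`, which picks the
k maximizing FDR-5% QTL discoveries in a reduced-permutation pass (ties go
to the smallest k). The transform refuses all-equal inputs, whose ranks are
degenerate.

## CRD calling

**Correlation map.** Per chromosome, Pearson correlations between all peak
pairs within a 250-peak sliding window (pairwise-complete samples; pairs
with fewer than 10 complete samples are set NA and logged). 250 peaks is the
window used throughout; it bounds compute and reflects the scale at which
coordinated domains occur.

**Background.** The calling criteria compare within-domain correlation to
"twice the background". We estimate the background as the *null correlation
scale* of the chromosome: `qnorm(0.995) * median(|r|) / qnorm(0.75)` over
banded off-diagonal pairs — i.e. the magnitude below which ~99% of
uncoordinated pair correlations fall, estimated robustly so that the
minority of truly coordinated pairs cannot inflate it. Two properties drove
this choice over a plain mean of signed correlations: (i) on a chromosome
where most pairs are uncorrelated the signed mean is centred at zero, which
would make "twice the background" vacuous and admit arbitrary noise pairs
as domains; (ii) the null scale shrinks as 1/sqrt(n) with sample size, so
the criteria automatically demand more of small cohorts, where sampling
noise produces larger chance correlations. A configurable floor (0.01)
guards degenerate estimates.

**Tree.** Agglomerative clustering constrained to genomically adjacent
clusters: at each step the adjacent pair with maximal mean pairwise
correlation between members is merged (ties to the leftmost). Pairs beyond
the band, or with undefined correlation, contribute the background value.
Adjacency-constrained merging guarantees every tree node is a contiguous
genomic segment, which is what a *domain* is; unconstrained clustering could
regroup distant peaks. Internal nodes carry the statistics the criteria
need; prefix-sum arithmetic keeps tree construction O(n^2) per chromosome.

**Criteria and acceptance.** Depth-first from the root, a node is accepted
as a CRD iff:

* mean pairwise member correlation &ge; 2 x background,
* edge correlation (mean correlation between each of the two boundary peaks
  and all other members) &ge; 2 x background,
* it spans at least two non-overlapping member intervals.

Accepted nodes are not descended into, so calls are maximal, well-delimited
and mutually disjoint; nested sub-domains are not emitted. Signed
correlations are used throughout: anti-coordinated peaks do not form a
domain. The edge form averages 2(k-1) pairs rather than the single
boundary-boundary pair, reducing variance. On chromosomes small enough to
enumerate, the accepted set provably equals the maximal tree nodes passing
the three criteria recomputed from scratch (see the test suite).

**Quantification.** CRD activity per individual is the NA-aware mean of the
member peaks' normalized quantifications; for count-based differential
testing, raw member counts are summed per CRD.

## Condition-specific CRD structure

CRDs called in one condition whose member peaks belong to no CRD of the
other condition are "condition-specific". Their member peaks are tested for
differential activity with a two-sided Mann-Whitney U test on *uncorrected*
quantifications (a rank test needs no distributional assumptions and the
uncorrected scale keeps effect directions interpretable); per-CRD mean
member correlations are computed per group on *covariate-corrected*
quantifications and compared globally with an unpaired two-sided
Mann-Whitney test on the two sets of per-CRD estimates. Annotation
enrichment uses a two-sided Fisher exact test on the 2x2 of
(foreground/background) x (&ge;1 bp overlap); the reported odds ratio is
the sample OR ad/bc, with a Haldane-corrected OR alongside whenever a cell
is zero.

## Differential testing

The differential core is a negative-binomial Wald test on raw counts:
median-of-ratios size factors; per-feature NB GLM with log link, log
size-factor offset and design `~ condition (+ covariates)`; dispersion by
Cox-Reid-adjusted profile maximum likelihood, shrunk toward a log-linear
mean-dispersion trend with a prior weight of 10 pseudo-samples; two-sided
Wald test on the condition coefficient; Storey q-values at FDR 5%. The
implementation deliberately omits independent filtering, fold-change
shrinkage and outlier replacement — at the scales this package targets the
calibration of the plain Wald test is verified directly by simulation
(type-I error within [0.035, 0.065] at alpha = 0.05 under the null; power
&ge; 0.8 for 2-fold changes at n = 60 + 60, dispersion 0.1).

Covariates enter the design when `screen_covariates()` flags them: a
covariate associates with condition (Mann-Whitney) or with many features
(pi1 of per-covariate regression p-values above a configurable threshold;
0.05 by default, though small feature panels need a larger value because
the pi1 estimator's sampling noise at a few hundred features exceeds it).

**Storey machinery.** pi0 is the smoothed tail proportion
`#{p > lambda} / (m (1 - lambda))` over lambda in 0.05 ... 0.95 (cubic
smoothing spline, df = 3, evaluated at the largest lambda); q-values are
the usual step-up minima, and pi1 = 1 - pi0 measures replication/sharing.
Inputs of fewer than 20 p-values fall back to pi0 = 1, which makes the
q-values exactly Benjamini-Hochberg. At m = 5,000 the pi1 estimate carries
a sampling sd of roughly 0.03: recovery of a planted pi1 = 0.3 within
&plusmn;0.05 requires alternatives whose p-values genuinely concentrate
near zero — with heavy-tailed alternatives (e.g. Beta(0.1, 1)) part of the
alternative mass lies above lambda and is not identifiable by any
tail-based pi0 estimator, deflating pi1 by ~0.03 before noise.

## QTL mapping

**Nominal pass.** Per phenotype x variant with the variant inside the
&plusmn;1 Mb cis window: OLS slope and two-sided t-test. The window anchor
is the strand-aware TSS for genes and the feature start for peaks and CRDs.
Variants below 5% MAF are excluded.

**Permutation pass.** Per phenotype, the best nominal p over cis variants
is calibrated against 1,000 whole-phenotype permutations (sample labels
shuffled, genotypes fixed — preserving cis LD): a Beta(a, b) distribution
is fitted to the permutation minima by maximum likelihood (L-BFGS-B on the
log-parameters from a method-of-moments start) and the adjusted p is the
Beta CDF at the observed best p. Storey q-values across phenotypes give the
FDR-5% discovery set. The degrees-of-freedom refinement of the original
fast-permutation scheme is omitted; the beta approximation is instead
validated directly against deep direct permutations (adjusted p within a
factor 2 of a 100,000-permutation empirical p for effects in the estimable
range — an empirical p of order 1/n_perm or smaller is pure censoring, so
the comparison is only meaningful for true p &ge; ~1e-4).

**Conditional pass.** Phenotypes significant at FDR 5% are re-scanned with
a forward-backward scheme. The per-phenotype nominal threshold is the Beta
quantile of the genome-wide adjusted-p significance bound (boundary
midpoint between the significant and non-significant adjusted p-values;
when every phenotype is significant the bound is the FDR level itself).
Forward: iteratively add the best variant whose conditional p (partial
correlation given the already-selected dosages) passes the threshold.
Backward: re-test each selected variant conditional on all others and drop
failures. Collinear candidates are dropped with a log message; survivors
are ranked in forward order (rank 0 = primary).

**Interaction QTLs.** For QTLs discovered in the case set, the model
`phenotype ~ genotype + condition + covariates + genotype x condition` is
fitted on all samples and the interaction term tested two-sided, with
Storey FDR over the tested set. Per-group slopes are reported for
interpretation.

**RTC.** For a QTL and a GWAS variant inside one recombination-interval,
the phenotype is residualized on each of the N interval variants in turn
and the QTL association is re-assessed on every residual; corrections are
ranked by how much association they remove and RTC = (N - rank_gwas)/N.
Values near 1 mean correcting for the GWAS variant removes the QTL signal
as well as the best correction does — the two variants tag one functional
effect. The degenerate case (QTL variant = GWAS variant) yields RTC = 1 by
construction and is flagged. Hotspot intervals are supplied as a BED file;
synthetic tests use fixed-width intervals.

**Sharing.** Discovery (phenotype, variant) pairs are re-associated in a
replication set and the pi1 of the resulting p-values estimates the shared
fraction; at least 20 pairs are required for a stable pi0.

## Gene-CRD pairs, triplets and causal inference

Genes are associated with CRDs whose span overlaps the TSS &plusmn;1 Mb
window using the same permutation + beta machinery with CRD activities as
predictors. For each FDR-5% pair, standardized gene expression and CRD
activity are aggregated by PCA; PC1 (sign-aligned to correlate positively
with the gene; variance explained is exactly (1+|r|)/2) becomes a
pseudo-phenotype anchored at the gene TSS and mapped for QTLs. A
significant pseudo-phenotype QTL completes a (variant, CRD, gene) triplet.
Pairs with |r| < 0.05 are skipped: PC1 of a near-orthogonal pair does not
represent shared signal.

Each triplet is scored under three Gaussian linear networks — causal
L(C|V)L(G|C), reactive L(G|V)L(C|G), independent L(C|V)L(G|V) — by
BIC-penalized log-likelihood, normalized by softmax under a uniform model
prior. The marginal of V is identical across models and cancels; so does
the BIC penalty (all models have six parameters), but both are kept
explicit in the code. Posteriors are invariant to affine rescaling of C
and G. Model recovery on simulated chains is &ge; 90% for the causal and
independent models at n = 150, beta_vc = 0.5, beta_cg = 0.7; the reactive
model needs asymmetric effects to be equally identifiable because with
symmetric betas the reactive and causal factorizations approach score
equivalence.

Confidence comes from 100 bootstrap resamples of individuals: the accuracy
is the fraction of resamples whose top model matches the full-data call,
and triplets below 0.55 are filtered out. The 0.55 default reproduces the
fixed threshold used in the study cohort (there derived as a lower
quartile, which is data-dependent; a quantile rule can be substituted by
the caller). Mechanism changes between conditions are classified per
matched triplet as same / causal-to-different / different-to-causal /
non-causal-change, with "causal" the reference category because mediation
through the CRD is the mechanistically distinguished model.

## The synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
assumes: each planted CRD has a latent per-individual factor f ~ N(mu_g, 1)
and member peak j = loading x f + N(0, noise_sd); background peaks are
independent noise. Within-CRD correlation is therefore
loading^2/(loading^2 + noise_sd^2) in closed form — the reference settings
(loading 1, noise 1) give r = 0.5. Case/control shifts move factor means by
`diff_effect`; QTL effects add beta x centered dosage to a factor or gene;
interaction QTLs add a case-only slope; triplet CRD/gene pairs are rewired
under a chosen causal model; counts are NB with mean
exp(a + b x activity) and configurable dispersion. Genotypes are
independent biallelic variants with uniform MAF in a configurable range —
no LD structure, no ancestry admixture, no read-level noise. Peaks sit on
one synthetic chromosome at 2-kb spacing with 1-kb widths and contiguous
CRD members, matching the caller's assumption of positional ordering.

Reference conditions: 200 individuals at the 98:174 case:control proportion
of the motivating cohort (72 cases, 128 controls), 1,000 peaks, ~100
planted CRDs of 2-10 members (60% of peaks in CRDs), within-CRD r = 0.5.
Everything is a deterministic function of the config seed, so cohorts are
reproducible bit-for-bit and on-disk copies are checksum-stable.

What passing tests on this generator do **not** show: robustness to LD
(conditional signals in real data are entangled by LD; here "independent
signals" are genuinely independent), to peak-calling artifacts, to
batch structure beyond what PCs capture, or to count models other than NB.

## Numerical choices and degenerate inputs

* Correlations on pairwise-complete samples everywhere; pairs with < 10
  complete samples are treated as missing and contribute the background.
* Beta MLE is clamped to p in [1e-12, 1-1e-12] and parameters to
  [1e-3, 1e6]; failures fall back to method-of-moments.
* NB IRLS caps |linear predictor| at 30 and flags non-convergent features
  (p = NA) rather than reporting unstable estimates.
* Bootstrap resamples with constant dosage are redrawn up to 10 times, then
  counted as mismatches (conservative for the accuracy).
* Ties in the rank-normal transform break by input order; all-equal
  features are refused.
* The pipeline derives per-stage seeds from the master seed by stage name,
  so stages are independently reproducible; manifests contain no
  wall-clock fields and are byte-identical across reruns.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one core: the reference cohort
(200 x 1,000 peaks) for recovery, 20 matched noise cohorts for the null
calling rate, 500 null phenotypes x 50 variants x 1,000 permutations (plus
20 planted signals against 100,000 direct permutations) for calibration,
2,000 null and 500 powered simulations for the interaction test, 200 seeds
per generative model for BN recovery, m = 5,000 for pi1 recovery, and
2,000 features for NB calibration. Pipeline runs in the suite reduce
permutations to 100-200 per phenotype; the per-module defaults remain
1,000.

## Known limitations

* The background estimator is chromosome-local and assumes most banded
  pairs are uncoordinated; a chromosome that is one giant domain would
  inflate its own background.
* Signed-correlation criteria ignore anti-coordinated regulatory pairs.
* The BN "posterior" is a BIC-softmax approximation to a marginal
  likelihood, adequate for model ranking but not calibrated as a Bayesian
  posterior; absolute probability magnitudes should not be over-read.
* Gene-CRD association and triplet QTL mapping reuse the same cohort, as in
  the study design; estimates are conditional on discovery and carry
  winner's curse.
* No trans effects, no nested CRDs, no >3-node networks.
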