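---
title: "Methods: quantifying blood-brain methylation concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying blood-brain methylation concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epigenome-wide association studies of brain phenotypes usually measure DNA
methylation in whole blood, because brain tissue is inaccessible in living
subjects. Whether a blood measurement at a given CpG says anything about the
brain depends on two things at that CpG: whether methylation *varies*
between individuals at all, and whether that inter-individual variation is
*correlated* between blood and brain. `methcord` implements a pipeline that
quantifies both, CpG by CpG, from matched-tissue beta-value matrices
(CpG x sample methylation proportions in [0, 1]), and calls CpGs
"informative" when they clear both bars.

## The concordance model

For each brain region, the per-CpG concordance statistic is the Spearman
rank correlation of methylation across the subjects that have both tissues
(`spearman_per_cpg()`). Ranks receive average values at ties; a CpG with
zero variance in either tissue has no defined rank correlation and is
reported as missing rather than zero, so flat probes cannot dilute a
correlation distribution with spurious zeros. Because Spearman correlation
is invariant to strictly increasing transforms, beta and M-value input give
identical results; the convention of correlating M values is therefore
honoured by construction (and asserted by a test).

Variability is summarized by the *reference range*: the difference between
the 90th and 10th percentile of a CpG's betas across samples
(`reference_range()`). Compared with the full range, it measures spread in
the bulk of a small cohort while limiting the leverage of a single outlier
sample. Quantiles interpolate linearly between order statistics (the
`type = 7` convention), so the statistic is continuous in the data.

### The permutation null

To show that a positive-skewed correlation distribution reflects true
pairing rather than an artifact, `permutation_null()` recomputes all
correlations after randomly unmatching the subjects (default: 5
permutations). The default unmatching scheme is a uniform shuffle with only
the identity permutation excluded. We deliberately do **not** force a full
derangement: conditioning on "no subject keeps its own sample" makes each
brain sample slightly anti-correlated with its true partner, biasing the
null mean by about $-\bar\rho/(n-1)$ (roughly $-0.02$ at 16 subjects when
the mean paired correlation is 0.3), which is large enough to distort the
comparison the null exists for. The uniform-shuffle null is unbiased; the
occasional fixed point (one expected per shuffle) slightly fattens its
positive tail, which is conservative for the paired-versus-null contrast.
`scheme = "derangement"` is available for users who prefer the stricter
reading.

## Deriving the correlation threshold

The correlation distribution of variable CpGs is bimodal: a broad,
approximately central peak of non-concordant CpGs and a positive peak
dominated by CpGs whose variation has a subject-level cause shared across
tissues (genotype at polymorphic probes, sex on the sex chromosomes).
`fit_two_gaussian_mixture()` fits a two-component univariate Gaussian
mixture by expectation-maximization and defines the per-region informative
threshold as the mean of the higher-mean ("positively correlated")
component minus two of its standard deviations.

Numerical choices, all made for reproducibility:

* deterministic initialization at the 25th/75th data percentiles with the
  pooled SD and equal weights -- no random restarts on the happy path;
* convergence when the log-likelihood improves by less than `tol = 1e-8`
  (the trace is retained and tested to be non-decreasing);
* a component collapsing below SD `1e-4` triggers up to 10 seeded restarts
  from jittered quartiles, then an error;
* non-convergence within `max_iter = 500` returns the best fit flagged
  `converged = FALSE` with a warning -- this is the expected outcome when
  the input is genuinely unimodal and is surfaced, not hidden.

Two seed-set modes anchor the fit (`derive_seed_set()`): `snp_sex`, the
union of polymorphic and X/Y-chromosome probes, and `top_variable`, the
CpGs passing a strict blood reference-range cut (default 0.2). The package
default is `top_variable`; the strict cut is exposed as a parameter because
reasonable analyses differ on it. Probes in the `snp_sex` set guide the
thresholds but are excluded from informative calling itself, since
genotype- and sex-driven concordance is not the biological signal of
interest.

### Informative calls

`call_informative()` flags a CpG per region as `informative_positive` when
its blood reference range is at least `variability_cut` (default 0.1, in
beta units) **and** its correlation reaches the region threshold;
`informative_negative` mirrors this at `-threshold`. The variability gate
uses `>=` at the cut. The union over regions defines the overall
informative set, and per-region overlap counts are reported. Raising
either cut can only shrink the called set (tested as a monotonicity
property).

## Differential methylation

`fit_paired_tissue_model()` quantifies tissue differences per CpG with a
linear mixed model on M values -- fixed effects for tissue, sex and
centred age, and a random intercept per subject to capture the paired
design. M values are used because their variance is far more homogeneous
across the methylation range than beta variance; the effect users act on,
`delta_beta`, is reported on the beta scale as the difference of tissue
means. P-values are Wald t-tests with between-within (containment)
denominator degrees of freedom, `n_obs - n_fixed - (n_subjects - 1)`,
which on a complete balanced paired design equal the paired-t degrees of
freedom; one model structure is estimated once and refit per CpG, keeping
genome-scale scans tractable. Multiple testing uses Benjamini-Hochberg
(`bh_adjust()`, a thin wrapper around `stats::p.adjust` that preserves
missing values), and `volcano_calls()` applies the joint cutoffs
`|delta_beta| >= 0.1` and FDR < 0.001.

## Cell composition

Bulk tissues are cell mixtures, and composition differences are a major
source of apparent methylation differences. `estimate_cell_proportions()`
performs reference-based deconvolution: non-negative least squares of each
sample's betas onto sorted-cell reference profiles, renormalized to sum to
one. `adjust_cell_composition()` removes compositional variance by
residualizing each CpG on the proportion covariates (one cell type dropped
against the sum-to-one constraint) within a tissue group, re-centering on
the group mean. The default modelling scale is M; `scale = "beta"` is
available and is exact when the compositional signal is a linear mixture
of profiles on the beta scale. Two caveats are documented deliberately:
residualization on k covariates with n samples removes about `k/(n-1)` of
*every* CpG's variance in sample-specific directions, so per-CpG
correlations shift after adjustment even at composition-independent CpGs
-- an intrinsic cost of covariate adjustment at n = 16, not a bug; and
M-scale removal of a beta-linear signal is exact only up to logit
curvature (a few parts per thousand of residual variance in practice).

`cell_effect_metric()` reports, per CpG and tissue, both the R-squared of
M values on the proportion covariates (variance fraction) and the mean
absolute beta change under adjustment, so users can judge composition
sensitivity on either scale.

## Gene annotation and enrichment

`associate_cpgs()` assigns features inclusively: a probe is a *promoter*
probe within [TSS - 1500, TSS + 300] strand-aware, *intragenic* within any
transcript body, *three_prime* within 300 bp past the transcript end, and
may hold several features across several genes (transcript-level union);
only probes matching nothing are *intergenic*. Window sizes are explicit
parameters because no single convention is canonical. BED input is
converted from 0-based half-open to 1-based closed at the reader boundary.

`monte_carlo_enrichment()` compares the informative set's feature counts
with sets of the same size drawn uniformly from the probe universe
(default 10 000 iterations). The empirical p-value is one-sided in the
observed direction with an add-one correction, so it is bounded below by
`1/(n_iter + 1)` and never zero. The null matches set size only -- not CpG
density, island membership or chip chemistry -- which is a documented
limitation of this style of resampling. The universe should be the probes
that survived preprocessing minus upstream exclusions; draws never leave
it (tested).

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture: it
generates the study design the pipeline targets -- 16 subjects sampled in
whole blood and three cortical regions (BA7, BA10, BA20), 64 samples, or
63 with `missing_last_region = TRUE` -- with known per-CpG ground truth,
so every downstream stage has a parameter-recovery test.

All signals are generated on the M scale and converted to betas, keeping
additive noise well-defined near the 0/1 boundaries. Classes:

* **concordant** -- per-subject latent signal shared across tissues;
  `concordance_strength` in [0, 1] sets the shared fraction (1 gives
  cross-tissue correlation exactly 1 at zero noise);
* **discordant** -- subject draws independent in every tissue; mean levels
  drawn once for blood and once for brain, so planted mean-shift signal is
  blood-brain only and brain-brain differential calls have a ground truth
  of zero;
* **invariant** -- constant extreme methylation, noise halved, blood
  reference range below 0.05 by construction;
* **polymorphic** -- Hardy-Weinberg genotypes at `maf` (default 0.3)
  mapped to betas near 0.9/0.5/0.1 identically in all tissues, the
  genotype-driven trimodal pattern;
* **sex_linked** -- mean beta 0.75 vs 0.25 by subject sex, identical in
  all tissues;
* **cell_driven** -- betas are convex combinations of per-tissue-class
  cell-type profiles (6 blood, 2 brain cell types by default) weighted by
  each sample's Dirichlet-drawn true proportions;
  `simulate_reference_profiles()` returns the exact profiles for
  deconvolution testing.

Batch effects are additive per-chip, per-CpG M-scale shifts
(`batch_sd = 0.2`). Chips are assigned by randomized balanced allocation:
assignment schemes that block chips by tissue or by subject were rejected
because they confound batch with tissue (creating spurious differential
calls) or create cross-subject correlation blocks (biasing the permutation
null), respectively.

Defaults the source data do not determine -- noise SD 0.3 M units,
subject-level signal SD 1 M unit, class effect sizes above, Dirichlet
concentration of the proportion draws -- were chosen once as values a
methylation-array analyst would call realistic (middling signal-to-noise;
blood granulocyte-dominated around 55%, brain roughly 35/65
neuron/glia) and are not tuned thereafter. Reproducibility is per-section:
each generator stage uses a seed derived from the configuration seed, so
changing, say, the number of cell types perturbs only the stages that
depend on it.

What the generator does **not** emulate: linkage disequilibrium between
probes, Infinium type I/II chemistry differences, realistic genome-wide
correlation structure, or hydroxymethylation. Passing tests therefore
demonstrate statistical correctness of the pipeline's machinery under a
known generative model, not performance on any real cohort.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline at 20 000
CpGs x 63-64 samples (the scale at which thresholds and calls stabilize),
with smaller cohorts for focused unit checks; mixture recovery uses 10 000
draws, and enrichment oracles use exhaustive hypergeometric computations
on universes of 10-20 probes. Every stochastic step takes an explicit
seed, and identical configurations reproduce bit-identical cohorts.

On real data, the pipeline expects betas that are already normalized and
batch-corrected (e.g. BMIQ and ComBat upstream); those published methods
are deliberately not reimplemented here. `pca_association()` provides the
screening step -- principal components of the probe-centred matrix tested
against sheet variables by ANOVA (categorical) or Spearman correlation
(continuous), with PC1 hidden by default since it is dominated by tissue
identity in multi-tissue data.

## Known limitations

* Spearman correlation at n = 16 is granular and noisy; per-region
  thresholds inherit that noise, and small threshold changes move many
  CpGs in or out of the informative set.
* The enrichment null matches set size only (see above).
* The containment degrees of freedom are exact for the balanced complete
  design and an approximation under missingness.
* Deconvolution accuracy depends on reference-profile fidelity; collinear
  references are flagged but not resolved.
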