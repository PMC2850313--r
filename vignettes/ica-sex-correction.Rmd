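---
title: "Correcting the sex confound in genome-wide methylation data with infomax ICA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting the sex confound in genome-wide methylation data with infomax ICA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methylICA)
```

## The problem

Array-style methylation assays report, for each CpG site and subject, a
*beta value* in [0, 1]: the fraction of methylated signal at that locus.
Sex shapes these values genome-wide. X-inactivation leaves many X-linked
promoters more methylated in females; a smaller set of X and autosomal
sites goes the other way. When methylation is tested against any other
phenotype — age, substance use, disease — this latent sex structure is a
confound: it inflates or masks associations at every site it touches,
and simply discarding the X chromosome both loses real signal and leaves
the autosomal part of the effect in place.

methylICA treats the sex effect as a *latent factor* of the data matrix.
Rather than picking a threshold for which sites are "sex sites", it
estimates a single genome-wide pattern that carries the sex influence at
whatever strength each site expresses it, verifies that this factor is
associated with sex and with nothing else, and subtracts it.

## Model and procedure

Write `X` for the `n x m` subjects-by-sites matrix after QC and per-site
centering. Both factorizations used here decompose `X = A S` with
subject weights `A` (`n x K`) and site patterns `S` (`K x m`); source
rows are scaled to unit (population) variance, with the compensating
scale absorbed into the mixing columns, and each factor is oriented so
its largest-|loading| site is positive.

1. **Site QC** (`qc_filter_sites()`). Sites with very low mean
   methylation or very low variance carry mostly measurement error and
   are removed: in *relative* mode the cutoffs are 5% of the maximum
   attainable beta (i.e. mean < 0.05) and 1% of the maximum observed
   per-site variance; *absolute* mode takes raw cutoffs (0.01 / 0.0001
   suit low-plex cancer-panel data) and an optional mean detection-P rule
   (> 0.5 = signal below negative controls) catches failed probes. A
   site failing *any* rule is removed; the report attributes each removed
   site to a single rule (detection, then mean, then variance) so counts
   add up without double counting. Both readings of the variance rule
   are deliberately available — the observed-maximum reference is the
   default because "maximum variation" refers to the data, while the
   mean rule references the scale maximum 1.0, the only reading that
   gives a fixed cutoff.
2. **Sitewise scan** (`ttest_by_group()`, `correlate_with_phenotype()`).
   Pooled-variance two-sample t-tests against the binary phenotype
   (Welch available by flag; pooled is the conventional reading of a
   "two-sample t-test") and Pearson correlations against continuous
   phenotypes, two-sided, with 5% Bonferroni control across the retained
   sites. Missing values are handled pairwise per site.
3. **Factorization** (`pca_decompose()`, `select_components_by_variance()`,
   `infomax_ica()`). PCA on the centered (covariance, not correlation)
   matrix — beta values share a common scale, so rescaling sites would
   only amplify noise. `K` is the smallest component count whose
   cumulative explained variance reaches the target (default 99%). ICA
   then whitens to those `K` directions and fits an unmixing rotation by
   natural-gradient ascent.
4. **Factor profiling and identification** (`profile_factors()`,
   `identify_sex_factor()`). Every factor's subject weights are tested
   against every phenotype; significance is Bonferroni-corrected across
   the `K` factors *within* each phenotype (the family that makes a
   factor-level p of 1.8e-3 significant at K = 26 while 2.7e-3 is not).
   The sex factor must be sex-significant under that correction and
   *clean* of every protected phenotype at an uncorrected 0.05 — a
   deliberately conservative screen: a marginal cross-association (p of
   0.05 or 0.02, say) is enough to disqualify a factor, because removing
   it would subtract real signal of the protected phenotype. If several
   factors qualify the smallest sex-p wins with a warning; if none
   qualifies the package refuses to correct and says so — factorization
   is then not an appropriate correction for those data.
5. **Correction** (`remove_factor()`). The rank-one term
   `A[, j] %*% S[j, ]` is subtracted from the uncentered values; site
   means are untouched because the factor was fitted on the centered
   matrix. The subtraction is exact by construction
   (`corrected + rank-one term == original` to machine precision).
   Corrected values may leave [0, 1] slightly; they are preserved
   (downstream tests are scale-free) and counted, with clipping
   available by flag.
6. **Re-test and compare** (`compare_before_after()`). The sitewise scan
   is re-run on the *same* QC-retained site universe — no re-filtering,
   so before/after counts are comparable — and the significant-site sets
   are compared per phenotype (common / gained / lost).

The per-site *Z scores* of a factor are its source row standardized over
sites (population denominator — a descriptive standardization over
thousands of sites where the n/n−1 distinction is irrelevant, fixed for
determinism). The identified factor's report re-orients weights so the
female mean is positive, and counts subjects whose weight sign
contradicts their group's majority — individual-level exceptions are
reported, never "fixed".

## The infomax variant, and why it is extended

The original Bell–Sejnowski infomax ascends the entropy of a logistic
squashing of the unmixed signals with the natural-gradient update
`W <- W + lr * (I + (1 - 2*g(U)) U'/m) W`. That update is only stable
when the sources are super-Gaussian (sparse/heavy-tailed). Methylation
factor loadings are typically sparse, so the logistic rule would work on
the intended signal — but it provably cannot separate sub-Gaussian
sources (two uniform sources stall near |r| = 0.7 of the truth), and a
general-purpose decomposition should not silently depend on the kurtosis
sign of the data. The default is therefore the *extended* infomax update
(`W <- W + lr * (I - K tanh(U) U'/m - U U'/m) W`, with `K` the diagonal
of per-component kurtosis signs), the variant the standard
neuroimaging/EEG infomax implementations use; `extended = FALSE` gives
the plain logistic rule. With extended infomax the same planted
two-source uniform mixture is recovered at |r| > 0.999.

Numerical defaults: learning rate 0.05, halved whenever an update
diverges and shrunk by 10% whenever the gradient direction reverses;
convergence when the largest absolute weight update drops below 1e-6;
iteration cap 2,000. On data whose retained basis contains many
near-Gaussian noise components the weight change plateaus around 1e-4 —
rotations among isotropic components carry no information and never
settle — so the cap, not the tolerance, usually ends the run; the
`converged` flag reports this honestly, and the structured components
are locked in long before (in the full-scale synthetic run below,
single-factor concentration of the sex signal is reached by roughly
iteration 1,500). `W` is initialized as a seeded random orthonormal
matrix; the seed is a required argument of the pipeline, making every
run bit-reproducible.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the validation conditions for the whole
package: `n = 200` subjects with a female fraction of 54/197, `m = 2,000`
sites of which 100 are X-annotated; a sex factor loading on 40 X-linked
plus 20 autosomal sites with mean effect 0.15 beta units (SD 0.03,
floored at 30% of the mean), 55% of loaded sites hypermethylated in
females and the rest in males; an age factor on 40 disjoint sites with
slope 0.004 beta units/year over ages 21–55; i.i.d. Gaussian measurement
noise with SD 0.05 (the replicate-reproducibility scale of beadarray
methylation assays); and a bimodal promoter-like baseline,
`0.6 Beta(2,8) + 0.4 Beta(8,2)`, with loaded sites drawn from the
mid-methylation range 0.25–0.70 so planted offsets stay inside [0, 1].
Values are truncated to [0, 1]; a configuration clipping more than 5% of
values is rejected. Effects are additive on the beta scale (the
statistics used downstream are linear in beta) rather than logit-scale.

Two deliberate design choices about the phenotypes: ages are
decorrelated from the sex assignment in-sample, and the nuisance
phenotypes (an AUDIT-like score, a cigarettes-per-day count) are
decorrelated from both sex and age before rounding. "Independent" is a
population statement; in any single finite cohort a sampling-accident
correlation of |r| ≈ 0.1 is routine, and with it a cross-association
test at uncorrected 0.05 trips purely by chance. Enforcing the
independence the generator *means* makes tests of the method measure the
method, not the luck of one cohort draw.

What passing these tests does **not** show about real data: real
methylation covariance is not i.i.d. noise plus two sparse factors —
cell-composition, batch and broad biological gradients give a much more
structured spectrum (which is why a 99% variance target retains ~26
components on real saliva arrays but ~195 on the synthetic cohort);
effects on real arrays are not exactly additive-Gaussian; and probe
chemistry, detection-failure patterns and tissue heterogeneity are not
modeled at all (the simulator's detection-P support is a constant
column).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `mean_threshold` | 0.05 (relative) | fraction of max beta | near-zero sites carry mostly error |
| `variance_threshold` | 0.01 (relative) | fraction of max site variance | uninformative flat sites |
| `detection_threshold` | 0.5 | probability | signal below negative controls |
| `alpha` | 0.05 | FWER | 5% Bonferroni throughout |
| `variance_target` | 0.99 | fraction | retained PCA variance before ICA |
| `learning_rate` | 0.05 | — | natural-gradient step; annealed |
| `max_iter` | 2000 | iterations | cap; structured factors settle earlier |
| `tol` | 1e-6 | max |dW| | convergence rule |
| `protected_alpha` | 0.05 | uncorrected P | cross-association screen |

## Degenerate inputs and tie-breaks

Sites with zero variance in both groups get an undefined statistic,
direction `undefined`, p = 1 and a degenerate flag; correlations against
a constant vector (or with < 3 complete pairs) are flagged rather than
reported as numbers. `k` above the numerical rank of the input is an
error (for a column-centered matrix the rank is at most `subjects − 1`,
so the usual `k <= min(n − 1, m)` bound is implied). Overlap percentages
round half away from zero and always carry their exact counts. Factor
sign is fixed by the largest-|loading| site; factor order by the
variance each carries.

## Problem sizes used in the validation suite

The acceptance-style checks run the full study conditions (200 × 2,000,
60 sex-loaded sites) once end-to-end — about 90 s, dominated by the
k ≈ 195 ICA — plus a 500-replicate × 1,000-site null calibration of the
sitewise t-test (type-I error 0.05 ± Monte-Carlo error; Bonferroni
family-wise error ≤ 0.05). Unit tests use a 40 × 400 cohort with the
same structure, which keeps each pipeline run near 3 s.

## Known limitations

* ICA must be able to concentrate the confound into one component. That
  needs enough site-observations per retained dimension (in practice
  m/K of roughly 10 or more). With too few sites — or a variance target
  that drags in hundreds of pure-noise dimensions on small matrices —
  the sex signal splits across factors, many factors profile as
  sex-associated, and removing one under-corrects. The factor-profile
  table makes this visible (dozens of "significant" sex factors instead
  of one); lower `k` or `variance_target` in that case.
* The protection screen is a per-cohort hypothesis test: a genuinely
  clean factor can be disqualified by a chance cross-association (about
  a 5% risk per protected phenotype). This is the price of the
  conservative rule; the error message reports exactly which phenotype
  tripped it.
* Only single-factor removal is implemented; removing several factors is
  a documented loop over `remove_factor()`, re-profiling after each
  removal.
* If an unmeasured trait truly drives the "sex" factor, removing it
  removes that trait's signal too. The package can only check the
  phenotypes it is given; measure candidate traits and add them to the
  protected list.
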