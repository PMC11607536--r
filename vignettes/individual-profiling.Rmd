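---
title: "Methods: individual profiling from ancient DNA genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual profiling from ancient DNA genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adnaprofile)
```

This vignette documents the statistical models behind each stage of the
package, the tunable parameters and their defaults, the design choices
made where the methodology is genuinely open, and what the synthetic-data
tests do — and do not — establish about behaviour on real data.

## Genetic sexing

For a sequenced individual, reads aligning to the X and Y chromosomes are
tallied as `n_x` and `n_y`, and the sex is inferred from

$$R_Y = \frac{n_Y}{n_Y + n_X},$$

which is near 0 for an XX individual (Y hits are mismapping noise) and
near 0.09 for XY (the Y is short and repeat-rich, so it draws well under
half of the sex-chromosome alignments). Treating `n_y` as binomial in
`n = n_x + n_y` gives the normal-approximation 95% interval
$R_Y \pm 1.96\sqrt{R_Y(1-R_Y)/n}$, clipped to $[0,1]$. At the read depths
where sexing is attempted ($n \gtrsim 10^5$) the normal approximation is
excellent.

Calls use the conventional thresholds `xx_max = 0.016` and
`xy_min = 0.075`. By default the **whole interval** must clear a
threshold (XX iff the upper bound is below 0.016; XY iff the lower bound
is above 0.075), which is conservative at low depth; comparing the point
estimate instead is available via `decision = "point"`. Both satisfy the
high-depth regime where the interval is a fraction of a percent wide; they
differ only for shallow libraries, where the conservative default returns
"indeterminate" rather than over-calling.

`endogenous_rate()` is the routine library QC statistic: uniquely mapped
read pairs over total read pairs, as a percentage to one decimal.

## Marine diet and radiocarbon calibration

Bone collagen records diet: a fully terrestrial consumer in this setting
has roughly $\delta^{13}\mathrm{C} = -22$‰ and
$\delta^{15}\mathrm{N} = 10$‰, a fully marine one $-12$‰ and $23$‰. The
package places a measured individual on that continuum with the linear
two-endpoint mixing model per isotope,

$$f_i = \frac{x_i - t_i}{m_i - t_i} \in [0, 1],$$

and combines the two isotope systems by their **mean** (the default;
either single-isotope estimate is available via `combine`). The mean is
preferred because the two isotopes carry partly independent dietary
signals and neither is privileged; values outside the endpoint range are
clipped before averaging. Endpoints are configurable — they are
empirical regional quantities, not constants of nature.

Marine carbon is depleted in ^14^C (the reservoir effect), so a consumer
of marine protein appears too old against a purely atmospheric
calibration curve. The correction mixes the atmospheric and marine curves
in proportion to the marine diet fraction $\alpha$, following the
Mix_Curves convention:

$$\mu(t) = (1-\alpha)\,\mu_T(t) + \alpha\,\bigl(\mu_M(t) + \Delta R\bigr),$$
$$\sigma(t)^2 = \bigl((1-\alpha)\sigma_T(t)\bigr)^2 +
  \bigl(\alpha\,\sigma_M(t)\bigr)^2 + (\alpha\,\sigma_{\Delta R})^2 +
  \bigl(\sigma_\alpha\,(\mu_M(t) + \Delta R - \mu_T(t))\bigr)^2,$$

on the 1-year intersection grid of the two curves, each linearly
interpolated. $\Delta R$ is the local deviation from the global marine
reservoir age; its default of 0 (with zero uncertainty) reflects settings
where local paired-sample estimates are too variable to apply. The
$\sigma_\alpha$ term propagates uncertainty in the diet fraction itself
and defaults to 0.

Calibration is the standard intercept-free probability-density method: a
uniform prior over the calendar grid, Gaussian measurement error combined
in quadrature with the curve error at each year, normalised over the
grid. The highest-posterior-density region at level $p$ (default 0.954,
the two-sigma convention) is the smallest density-threshold set of grid
years with mass at least $p$; density ties at the threshold are included
as a whole, so plateaued synthetic curves have a well-defined answer.
Contiguous years merge into intervals, each reported with its mass to
0.1% in both cal BP and cal CE ($\mathrm{CE} = 1950 - \mathrm{BP}$), with
endpoints at whole calendar years. Mass piling up at the grid boundary
(more than $10^{-6}$ in an edge cell) triggers a truncation warning, or
an error under `boundary = "error"`.

The two published reference curves are not redistributed with the
package; `read_cal_curve()` parses their standard `.14c` layout from
user-supplied files, and all engine tests run on synthetic curves with
closed-form answers.

## Runs of homozygosity and the inbreeding coefficient

Long tracts where an individual's two chromosomes agree at every common
SNP indicate recent parental relatedness. Imputed genotypes from a
low-coverage genome contain scattered errors, so the scanner must
tolerate isolated heterozygous calls rather than breaking a tract at the
first one.

The scan runs per chromosome over SNPs filtered to minor-allele frequency
strictly above `maf_min = 0.03` (rare sites are uninformative — almost
everyone is homozygous at them). A candidate fragment opens at the first
homozygous call at or after the scan cursor and extends call by call. A
heterozygote is admitted unless adding it would push the fragment's
heterozygote count over `max_het_count = 60` **or** its share of
genotyped calls over `max_het_prop = 0.01`; either violation (or the
chromosome end) closes the candidate. The closed candidate is trimmed
back to its last homozygous call — a fragment should not end on a
heterozygote — and accepted iff it is strictly longer than
`min_length_cm = 1` and contains at least `min_hom_snps = 1000`
homozygous calls. After an accepted fragment the scan resumes just past
its end; after a rejected one it resumes just past the candidate's first
internal heterozygote, which guarantees that no acceptable fragment
starting inside the rejected span can be missed, at amortised linear
cost. Missing calls are spanned but counted in neither tally: imputed
panels have few, and counting them as heterozygous would bias the
estimate down. Each of these policies (trim target, restart rule,
proportion denominator, strict length inequality) is an explicit choice
where the procedure is underdetermined; all are exercised directly by an
independent literal-rules oracle in the tests.

The inbreeding coefficient is the map fraction covered:

$$F = \frac{\sum_{\text{accepted}} \text{length}_\text{cM}}{3523.4\
\text{cM}},$$

with 3523.4 cM the total autosomal genetic map the default parameters
assume; it is configurable together with every threshold
(`roh_params()`). `min_hom_snps` must be scaled to the panel's SNP
density: with the default thresholds tuned for ~3,000 SNPs/cM panels, a
synthetic panel at ~6 SNPs/cM uses proportionally smaller values (the
tests use 50).

## Ancestry projection and region assignment

The reference PCA normalises each SNP $j$ the way smartpca does: centre
by $2\hat p_j$ and scale by $\sqrt{\hat p_j(1-\hat p_j)}$, with
$\hat p_j$ the observed alternate-allele frequency and missing genotypes
set to the mean after centring. The uncorrected $\hat p$ is used rather
than the shrunk $(1+\text{count})/(2+2n)$ form — at reference-panel sizes
the difference is negligible — with the corrected form available via
`bayesian_freq = TRUE`. Monomorphic SNPs (scale zero) are dropped with a
warning. Components come from the eigendecomposition of the
samples-by-samples cross-product, so cost scales with samples rather than
SNPs, and column signs are fixed deterministically (largest-magnitude
loading positive) so runs are reproducible.

An ancient, partially missing sample is **projected by least squares**
onto the fixed loadings restricted to its observed SNPs — the lsqproject
approach. With no missingness this is the exact transform (orthonormal
loadings), so reference individuals reproduce their own scores; with
missingness it avoids the shrinkage toward the origin that zero-filling
causes, which would drag an ancient sample spuriously toward the panel
centroid.

Assignment uses the eigenvalue-weighted Euclidean distance over the first
$k = 10$ components,

$$d(a, b) = \sqrt{\sum_{j=1}^{k} \lambda_j (a_j - b_j)^2},$$

from the query to every reference individual. The weighting is applied
linearly inside the square — the natural "weighted by their eigenvalues"
reading; a squared-weight variant is available and the choice is recorded
in the result. The region with the smallest mean distance wins, and every
other region is compared to it with a Welch (unequal-variance) two-sided
t-test on the per-individual distance sets — Welch because region sample
sizes and dispersions differ in real reference panels. The p-values
quantify whether the best region is *significantly* closer, mirroring how
such assignments are reported.

## f4 statistics

For populations A, B, C, D with observed alternate-allele frequencies
$p_\cdot$ at SNP $s$, the statistic is

$$f_4 = \frac{1}{S}\sum_s (p_{A,s} - p_{B,s})(p_{C,s} - p_{D,s}),$$

over SNPs where every population has at least one observed genotype
(others are dropped, not imputed). No small-sample bias correction is
applied: the cross-population product has no within-population
$p(1-p)$ term, unlike f2. In the scan orientation — outgroup : ancient ;
anchor : test region — a positive value means excess shared drift between
the ancient individual and the test region.

Standard errors use a weighted delete-one-block jackknife over
consecutive blocks of `block_size = 500` SNPs (the Busing weighting, with
blocks weighted by SNP count), which is robust to linkage between
neighbouring SNPs. On the package's uniform synthetic map, SNP-count
blocks and cM blocks coincide; on real data with variable SNP density a
user wanting cM blocks can pre-chunk accordingly. The calibration test
checks the jackknife SE against the replicate standard deviation of the
estimator across 200 independent simulations.

## The synthetic-data generator

`simulate_panel()` emulates exactly the structure the estimators assume,
with known truth for recovery tests:

- **Region structure** by the Balding–Nichols model: ancestral frequency
  $p$ uniform over the configured minor-allele range (mirrored to
  $(0,1)$), regional frequency $\sim
  \mathrm{Beta}\bigl(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\bigr)$, so the
  between-region variance is $p(1-p)F$ — the simplest drift model that
  produces county-like PCA structure. The default $F_{st} = 0.005$ is of
  the magnitude that separates sub-national regions of a single country.
- **A uniform genetic map**: 22 chromosomes totalling 3523.4 cM at
  1 cM/Mb. Only cM spans matter to the ROH scanner, so uniformity loses
  nothing; recombination-rate variation is deliberately not modelled.
- **An ancient target** drawn from one region, with planted ROH: inside
  each planned tract one haplotype is sampled per SNP and doubled, making
  the tract perfectly homozygous. Imputation error is a separate knob
  (`het_error_rate`, default 0); missingness spares planted tracts by
  default so the planted truth is exact.
- **Sex reads** as a single binomial draw with $q = 0.089$ (XY) or a
  small mismapping floor (XX, default 0.001); **isotopes** as the exact
  inverse of the mixing model plus optional Gaussian noise.

Everything is deterministic under the configured seed.

What passing recovery tests shows: the estimators invert the generative
models they assume, at realistic sizes (20,000 SNPs, 8 regions of 100,
70% missingness in the target, $F_{st}$ 0.005). What it does not show:
robustness to linkage disequilibrium (SNPs here are independent given the
regional frequencies), to imputation error that is *spatially
correlated* rather than independent, to reference-panel ascertainment
bias, or to admixed targets between regions. Those effects are exactly
why real analyses validate against held-out reference individuals — which
the package supports via self-projection and duplicate-sample checks.

## Numerical choices and degenerate inputs

- Calibration grids are 1-year; posterior normalisation is exact by
  construction and asserted to $10^{-9}$ in tests. HPD masses are
  reported to 0.1%.
- Beta draws in the simulator are clamped away from 0 and 1 by $10^{-9}$
  to avoid degenerate binomial parameters at extreme drift.
- The PCA drops monomorphic SNPs rather than dividing by a zero scale;
  projection requires at least as many observed SNPs as components and
  errors on rank deficiency.
- A zero read total, an empty calibration curve, an empty MAF-filtered
  panel, a tract planted off the simulated map, and an all-missing
  projected sample are all errors raised before any computation.
- Problem sizes in the test suite (22,000-SNP ROH panels, 20 seeds;
  20,000-SNP assignment panels; 200 f4 replicates) were chosen as the
  smallest sizes at which the recovery claims are sharp; they complete in
  a few minutes on one core.

## Known limitations

- The ROH scanner is a threshold method, not an HMM; it has no explicit
  error model and its thresholds must be rescaled with SNP density.
- Least-squares projection assumes the query's missingness is
  uninformative; systematically missing regions (e.g. capture panels)
  can bias coordinates.
- The f4 jackknife assumes block exchangeability; strong long-range LD
  (inversions) violates it.
- The diet model is a two-source linear mixer; freshwater-fish signals
  and trophic-level effects are outside it, and endpoint choice moves the
  estimate by construction.
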