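---
title: "Methods: propensity-matched transfer of regional atrophy models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensity-matched transfer of regional atrophy models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Structural MRI studies of rare clinical subgroups - genetically defined
Parkinson's disease (PD) variants, biomarker-defined strata - face two
linked obstacles: the subgroups are small (often under 20 usable
participants after matching), and they differ systematically from the
comparison groups in age, sex, disease duration and acquisition site.
Fitting separate brain-wide models inside each small subgroup is
underpowered and unstable; comparing unmatched groups confounds the
biology of interest with demographics.

`morphoxfer` implements a two-part remedy:

1. **Balance first.** Participants from the two groups of every contrast
   are paired one-to-one by optimal assignment on propensity scores, so
   that group membership cannot be predicted from background covariates
   within the matched sample.
2. **Transfer a reference model.** Regional atrophy models are fitted once
   in the best-powered contrast (sporadic PD vs healthy controls) and then
   applied, coefficients frozen, to the matched data-poor subgroups. Each
   participant is scored by how far their measured morphometry deviates
   from what the reference atrophy model predicts for someone with their
   covariates and diagnosis.

## Propensity matching

For a contrast between groups A and B, the propensity score
$\mathrm{PS} = P(y = 1 \mid C)$ is estimated by maximum-likelihood
logistic regression of the group indicator on background covariates $C$
only - never on morphometry. Sex enters as female = 0 / male = 1; site as
one indicator per level; disease duration is included where both sides
carry it (which restricts the SAA contrast to diagnosed participants,
since duration is undefined otherwise). If the fit separates - likely when
small groups meet many site indicators - a ridge-penalized fit (penalty
$10^{-4}$, intercept unpenalized) is substituted with a warning; the
penalty is orders of magnitude below any scale that would move a
non-degenerate fit.

Matching is a minimum-cost one-to-one assignment: the cost of pairing
$i \in A$ with $j \in B$ is $|\mathrm{PS}_i - \mathrm{PS}_j|$, solved
exactly by the Hungarian algorithm in its Jonker-Volgenant
shortest-augmenting-path form ($O(n^3)$, exact; cross-checked against
exhaustive enumeration in the test suite). A caliper excludes unacceptable
pairs: the default is 0.2 times the SD of the logit of the PS, applied on
the logit scale - the standard convention in the matching literature - and
is configurable (`caliper_spec()`), with a raw-probability-scale option.
Pairs beyond the caliper receive a sentinel cost
$(n_A + n_B)(\max \text{finite gap} + 1)$, strictly larger than any
feasible total, so the solver matches as many within-caliper pairs as
possible and any pair assigned at sentinel cost is discarded. Costs are
rounded at $10^{-12}$ and participants sorted by id before solving, so the
matching is invariant to input row order.

Balance is reported as standardized mean differences (SMD),
$|\bar{x}_A - \bar{x}_B| / \sqrt{(s_A^2 + s_B^2)/2}$, with proportion
variance $p(1-p)$ for binary covariates, before and after matching.

A limitation worth stating plainly: the propensity score is a
one-dimensional summary, so two participants can share a PS while
differing in opposite directions on individual covariates, and the
maximum-cardinality rule keeps caliper-boundary pairs. In our simulations
at $n = 150$ per arm with a 4-year age shift and 2:1 site imbalance, the
median post-match age SMD is about 0.04 (from roughly 0.42 before
matching), but roughly one run in ten exceeds 0.1. An independent
reference implementation of the same procedure shows the same tail, so
this is a property of caliper-constrained 1-D propensity matching at this
sample size, not of this implementation. Balance should always be
inspected via the returned `BalanceReport`.

## The regional atrophy models

On the matched reference sample, each of the 82 regions (68
Desikan-Killiany cortical thickness parcels, mm; 14 Harvard-Oxford
subcortical volume parcels, mm^3) gets an ordinary least-squares model

$$Y = \beta_1\,\mathrm{diagnosis} + \beta_2\,\mathrm{age}
  + \beta_3\,\mathrm{sex} + \beta_4\,\mathrm{site} (+\,\beta_5\,\mathrm{TIV})$$

with an explicit intercept; total intracranial volume enters subcortical
models only, since volumes scale with head size while thickness does not.
Design choices:

* **Intercept and site coding.** The model is written without an explicit
  intercept when site is fully indicator-coded; we include an intercept
  and drop one site level (the first, alphabetically) instead. The two
  parameterizations span the same column space, so $\beta_1$ is
  identical, and an explicit intercept keeps the "mean training residual
  is zero" property testable.
* **Sex encoding.** Inside the linear models sex is male = 0 / female = 1.
  This is deliberately the reverse of the propensity-score convention;
  each is a fixed convention of its model family, and $\beta_1$ is
  unaffected by either.
* **Outcome scale.** Whether to standardize morphometry before regression
  is genuinely open; effect sizes near 0.3 are more natural in SD units
  than in millimetres, so the default z-scores each region's outcome using
  the reference sample's mean and SD, and those constants are stored in
  the model set. A native-units mode (`zscore = FALSE`) is provided; the
  z-scored $\beta_1$ is invariant to the native measurement scale.
* **Age centering.** Age is centered at the reference-sample mean for
  numerical stability; this shifts only the intercept, never $\beta_1$.

All 82 models share one design per tissue class, so the fit is a single QR
decomposition per tissue with a matrix response; coefficients agree with a
pseudo-inverse oracle to $10^{-8}$ in the test suite.

## Transfer and deviation scores

`predict_morphometry()` applies the frozen coefficients to new
participants using each participant's *observed* diagnosis status: 1 for
both sides of LRRK2 PD vs sPD, 0 for both sides of NMC vs HC, observed
for the SAA contrast. This makes the non-PD contrast a pure non-diagnosis
comparison and never re-estimates a parameter. Z-scoring at transfer time
uses the training constants stored in the model set - the transfer never
peeks at target-group statistics. Site levels unseen at training are an
error by default; the pipeline maps them to the reference level with a
warning, which biases those participants' predictions toward the
reference-site intercept and is logged for that reason.

The deviation is **measured minus predicted**, so positive values mean
the structure is better preserved than the PD atrophy model expects. (The
opposite operand order appears in some verbal descriptions of such
analyses; the figure-level convention "positive = preserved" is the one
users reason with, so it is fixed here and tagged in the map semantics.)
Deviations are averaged within subgroup to one value per region, and the
subgroup difference is tested on the 82 region-level means. The default
test family is a two-sample Welch t-test across regions, with a paired
option (regions paired across subgroups); region-level means are spatially
correlated to some degree, and the shared component of model-transfer
error is common to both subgroups, which makes the two-sample test mildly
conservative under the null - its empirical size at the matched-42 scale
sits near 0.03-0.05 in the acceptance simulations.

## Spin-permutation test

Brain-map pairs (e.g. the preservation map against the diagnosis-beta
map) are compared by Pearson correlation; significance uses a spatial
null that preserves autocorrelation: parcel centroids on each
hemisphere's registration sphere are rigidly rotated by a uniform random
rotation (quaternion-sampled), the mirrored rotation is applied to the
right hemisphere, and each parcel takes the value of the nearest rotated
centroid. Nearest-centroid reassignment is not always a bijection;
duplicate counts are logged per permutation. Subcortical parcels have no
spherical model and are excluded from the null (the uniform-permutation
alternative for them is deliberately not offered as a default because it
destroys spatial structure). The p-value is two-sided on $|r|$ with the
add-one convention $p = (1 + \#\{|r_0| \ge |r|\})/(n_\mathrm{perm}+1)$,
so its smallest attainable value is $1/(n_\mathrm{perm}+1)$. With
white-noise maps the empirical rejection rate at $\alpha = 0.05$ is
consistent with the nominal level (acceptance suite, 500 replicates at
499 rotations).

Because the package is exercised on synthetic cohorts, parcel centroids
are themselves synthetic: a Fibonacci spiral per hemisphere mirrored in
x. They reproduce the geometry's role (unit sphere, hemispheric
symmetry, distinct locations), not the anatomical adjacency of real
Desikan-Killiany parcels.

## Clinical and genetic associations

The structural quantity correlated with clinical scores is the
model-*predicted* morphometry (averaged over regions for the global
analyses), matching the "morphometry estimates" wording of the analyses
this package supports; measured values or deviations can be substituted.
UPDRS III and MoCA use plain Pearson correlations; PRS uses a partial
correlation controlling the first 10 genetic principal components
(residualize both sides on the PCs with intercept, correlate residuals,
$t$ reference with $n - 2 - k$ df). FDR control is Benjamini-Hochberg,
with the regional family defined as all regions x all three scores (246
tests) and the global family as 3 tests.

## What the synthetic cohort emulates

`cohort_config()` defaults encode the cohort structure the analyses
assume:

| parameter | default | rationale |
|---|---|---|
| group sizes | HC 139, sPD 293, LRRK2 PD 77, LRRK2 NMC 94 | the four-group cohort the design targets |
| age (yr) | group means 61.1-65.0, SD 6.9-11.7 | group-specific demographics |
| male fraction | 0.43-0.66 by group | carriers without PD skew female |
| disease duration (yr) | sPD 2.2 +- 1.9, LRRK2 PD 3.2 +- 2.2 | PD groups only; missing otherwise |
| sites | 5, group-dependent usage, offsets SD 0.3 z | site as a genuine confounder |
| diagnosis effect | Uniform(-0.4, 0) z per region | the printed range of atrophy betas |
| LRRK2 attenuation | 0.5 | milder atrophy in LRRK2 PD |
| SAA effect | 0.5 x diagnosis profile for SAA+ | extra atrophy under synucleinopathy |
| residual SD | 0.7 z | covariates explain roughly half the variance of z-scored morphometry |
| age slope | -0.03 z/yr | age as the dominant nuisance signal |
| TIV coupling | 0.4 z/z, subcortical only | volumes scale with head size |
| MoCA coupling | +3 points per z of biological deviation, noise SD 2.5 | cognition declines with atrophy |
| UPDRS III coupling | -2 points per z, noise SD 9 | weak motor-structure link |

Two numerical details matter downstream. First, effects are injected on
the z-scale relative to each region's baseline SD (native-units mode
available), and clinical scores couple to the *biological* part of a
participant's mean deviation - injected effects, age trend and regional
noise, excluding site offsets and TIV, since cognition should not track
scanner assignment. Second, the residual SD of 0.7 encodes the assumption
that age, site and sex jointly explain roughly half the variance of
z-scored regional morphometry, consistent with age being the dominant
source of structural variation in adult cohorts; it is set once here, not
per analysis.

What the generator does **not** emulate: spatial correlation of noise
across regions (regions are conditionally independent given covariates),
non-Gaussian site effects or scanner interactions, longitudinal change,
vertex-level data, and any spatially distinct LRRK2 pattern (attenuation
is uniform across regions, so a preservation map is anticorrelated with
the atrophy map by construction - the spatially-divergent-pattern case
must come from real data). Passing tests therefore demonstrate that the
machinery recovers what it injects under a faithful but simplified
generative model, not that real cohorts satisfy these assumptions.

## Determinism and problem sizes

Every stochastic step takes an explicit seed; a single top-level seed
fans out as `seed * 100 + stage` (mod $2^{31}-1$) to the cohort and spin
stages, and matching is deterministic given the data. Reruns with the
same seed produce byte-identical artifacts apart from the manifest
timestamp; the manifest embeds an MD5 hash of the generating
configuration.

The test suite exercises the pipeline at the scales of the study design
it emulates: 104 per arm for the reference fit, 19, 42 and 23 per side
for the three transfer contrasts, 100-500 simulation replicates per
property, and 499 rotations per spin test; the full default pipeline on
603 participants runs in a few seconds on one CPU.
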