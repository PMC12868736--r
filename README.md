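# morphoxfer

Propensity-matched transfer of regional brain atrophy models.

## The problem

Comparing brain structure between clinical subgroups is hard when the
subgroups are small and demographically unbalanced — the situation for
genetically defined Parkinson's disease (PD) variants (e.g. LRRK2
pathogenic-variant carriers) and biomarker-defined strata (e.g.
alpha-synuclein seed-amplification-assay status). Fitting brain-wide
models inside a 20-person subgroup is unstable; comparing unmatched
groups confounds biology with age, sex, disease duration and scanner
site.

`morphoxfer` implements the combined remedy used in modern
pattern-matching morphometry studies:

1. **Propensity matching with optimal assignment.** For each contrast,
   PS = P(y = 1 | C) is fitted by logistic regression on background
   covariates only; participants are paired one-to-one by the Hungarian
   algorithm on |ΔPS|, with a caliper (default 0.2 × SD of logit PS)
   excluding distant pairs. Covariate balance is reported as
   standardized mean differences before/after.
2. **Regional atrophy models.** On the matched reference contrast
   (sporadic PD vs healthy controls), one OLS model per region —
   68 Desikan-Killiany cortical thickness parcels plus 14 Harvard-Oxford
   subcortical volumes:
   `Y = β₁·diagnosis + β₂·age + β₃·sex + β₄·site (+ β₅·TIV)`,
   TIV in subcortical models only. The 82 diagnosis coefficients β₁ form
   the transferable atrophy map.
3. **Model transfer.** The frozen models predict morphometry for matched
   data-poor subgroups; each participant's deviation
   (measured − predicted; positive = preserved structure) is averaged
   per region, and subgroup differences are tested on the 82 region
   means (two-sample Welch by default, paired optional).
4. **Spatial and clinical context.** Brain-map pairs are compared with
   Pearson's r against a spin-permutation null (random sphere rotations
   of cortical parcel centroids, mirrored across hemispheres); predicted
   morphometry is correlated with UPDRS III, MoCA, and PRS (partial
   correlation over 10 genetic PCs), with Benjamini-Hochberg FDR
   control.

A synthetic cohort generator (`cohort_config()` / `generate_cohort()`)
reproduces the group structure these analyses assume — four groups with
realistic demographics, site confounding, per-region diagnosis effects,
attenuated atrophy in LRRK2 PD, extra atrophy under SAA positivity, and
clinical scores coupled to structural deviation — so the full pipeline
runs and is tested without access-controlled data.

## Worked example

```r
library(morphoxfer)
res <- run_all(seed = 1)
print(res)
#> <pipeline_result> 603 participants
#>   reference pairs: 139
#>   lrrk2_pd_vs_spd   69 pairs, mean dev +0.1020 vs -0.0048, p = 1.19e-06
#>   nmc_vs_hc         68 pairs, mean dev +0.0107 vs +0.0012, p = 0.573
#>   saa_pos_vs_neg    32 pairs, mean dev -0.0644 vs +0.1379, p = 4.34e-12
#>   spin: r = -0.576, p_spin = 0.0010
```

Reading this output: the reference contrast matched 139 sPD/HC pairs and
fitted the 82 atrophy models on them. Transferring those models, the
LRRK2-PD arm sits **+0.10 z above** the atrophy the PD model predicts
(milder-than-typical atrophy, p ≈ 1e-06 across regions), the
non-manifesting-carrier contrast shows no deviation (p = 0.57), and the
SAA-positive arm sits **below** its prediction (excess atrophy,
p ≈ 4e-12). The spin test compares the LRRK2 preservation map with the
atrophy beta map; in the synthetic cohort attenuation is spatially
uniform, so the two maps are strongly anticorrelated by construction
(r = −0.58 at the smallest attainable p for 999 rotations).

Pieces can be used separately:

```r
cohort <- generate_cohort(cohort_config(seed = 1))
m <- match_subgroups(
  cohort$participants[cohort$participants$group %in% c("HC", "sPD"), ],
  outcome = "pd_diagnosis", covariates = c("age", "sex", "site"))
m$balance
#>  covariate smd_before  smd_after
#>        age 0.17510399 0.09584764
#>        sex 0.08275081 0.06085806
#>        ...
```

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/morphoxfer.R simulate --seed 1 --out data/
Rscript inst/scripts/morphoxfer.R run-all --seed 1 --out results/ \
    --participants data/participants.tsv --morphometry data/morphometry.tsv
```

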