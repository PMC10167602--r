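# tauroi

Group-level and individualized regions of interest (ROIs) for measuring
longitudinal change in regional tau-PET SUVR, with a clinical-trial
power framework for comparing them.

## The problem

Tau pathology in Alzheimer disease spreads along a broadly hierarchical
cortical cascade, but *where* tau is currently accumulating differs
between individuals. Fixed group-level ROIs — data-driven stage
composites, Braak-stage sets, the temporal or whole-brain meta-ROI —
therefore mix regions that are already saturated in some participants
with regions not yet involved in others, diluting the longitudinal
signal that a trial outcome needs. `tauroi` is for neuroimaging
statisticians and trialists who want to quantify that dilution: it
implements the group-level readouts, five participant-specific ROI
definitions, and the downstream sample-size arithmetic, plus a fully
seeded synthetic cohort generator with known ground truth for validating
the whole chain.

## What it computes

For a ROI with volume-weighted mean SUVR `x` at baseline and `y` at
follow-up, `Δt` years apart, the primary outcome is the annual
percentage change `100·(y − x)/(x·Δt)`, summarized per diagnostic group
(amyloid-positive CU, MCI, AD dementia) with t-based 95% CIs and
one-sample t tests against 0. Five individualized ROI definitions are
provided:

| method | participant ROI |
|---|---|
| `q1` | quartile of regions closest (by connectivity path length) to the subject's tau epicenter, i.e. the top 10% of regions by Gaussian-mixture positivity probability |
| `probability` | regions whose positivity probability falls in the data-selected interval (12 candidates from lower starts 0.2/0.3/0.4 and uppers 0.7/0.8/0.9/1.0) |
| `overlap` | voxels above SUVR 1.40 at *both* timepoints within gray matter |
| `highest_dds` | the latest (highest-index) staged composite that is tau-positive at baseline |
| `sustain` | regions in the assigned stage band (1–10 / 11–20 / 21–30) of a fixed 4-subtype, 30-stage event-sequence model |

Trial sample size per arm, for a treatment reducing the mean annual
change by a fraction `f` at two-sided `α` and a target power, uses the
normal-approximation closed form
`n = ⌈2(z₁₋α/₂ + z_power)² σ² / (f μ)²⌉`, and ROI-to-ROI sample-size
reductions `100·(1 − n_roi/n_ref)` carry paired-bootstrap 95% CIs
(1000 replicates).

## Worked example

Simulate a realistic cohort (97 CU, 77 MCI, 41 AD, 69 amyloid-negative
controls; 200 regions in 5 stages; heterogeneous epicenters) and compare
the group-level staged ROIs with the highest-positive-stage method:

```r
library(tauroi)
cfg <- simulation_config(seed = 1)
report <- run_pipeline(sim = cfg, methods = c("group", "highest_dds"),
                       effect_fractions = 0.3, n_boot = 1000, seed = 2)
print(report)
#> tauroi_report: 284 subjects, 200 regions; methods: group, highest_dds
#>
#> Group mean annual % change (95% CI):
#>   CU   DDS_1              3.41 [  2.91,   3.90]  n=97
#>   CU   DDS_2              3.82 [  3.09,   4.55]  n=97
#>   ...
#>   CU   temporal_meta      3.41 [  3.05,   3.77]  n=97
#>   CU   highest_dds        6.76 [  6.12,   7.39]  n=97
#>   MCI  highest_dds        6.92 [  6.29,   7.54]  n=77
#>   AD   highest_dds        7.38 [  6.78,   7.99]  n=41
```

Reading each subject in its own most recently affected stage roughly
doubles the measured change relative to the best fixed composite
(e.g. CU: 6.76 vs 3.82 %/y), which translates directly into smaller
trials:

```r
subset(report$reductions,
       roi == "highest_dds" & reference_kind == "reference",
       select = c(group, n_roi, n_ref, reduction_pct, ci_low, ci_high,
                  significant))
#>    group n_roi n_ref reduction_pct    ci_low  ci_high significant
#> 7     CU    38    48      20.83333  5.405405 36.21082        TRUE
#> 21   MCI    28    45      37.77778 17.070870 56.00000        TRUE
#> 35    AD    12    44      72.72727 53.125000 84.61538        TRUE
```

so at a 30% treatment effect the highest-positive-stage outcome needs
38 CU participants per arm where the temporal meta-ROI needs 48, a
20.8% reduction with a bootstrap CI excluding zero. Setting
`epicenter_heterogeneity = 0` and point-mass stage distributions in
`simulation_config()` makes every subject's individualized ROI coincide
with a group-level set and the advantage collapses to zero — the
control experiment that the gain really comes from between-subject
heterogeneity.

The single-method building blocks are exported too
(`fit_gmm_region()`, `region_cutoff()`, `define_epicenter()`,
`quartile_q1_roi()`, `probability_interval_search()`,
`overlap_index_roi()`, `highest_positive_dds_roi()`,
`sustain_assign()`, `sample_size_per_arm()`,
`bootstrap_sample_size_reduction()`, ...), as are readers/writers for
cohort tables (wide/long TSV), connectivity matrices, region-set JSON,
voxel blocks (TSV or NIfTI) and fitted-mixture JSON.

## The methods vignette

`vignettes/individualized-tau-rois.Rmd` documents the statistical
model, the positivity mixture and its bimodality guard, each ROI
definition's tie-breaking and fallback rules, the power formula and its
simulation validation, what the synthetic generator does and does not
emulate, and known limitations.
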