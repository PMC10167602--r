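---
title: "Methods: individualized ROIs for longitudinal tau-PET change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individualized ROIs for longitudinal tau-PET change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tau accumulation in Alzheimer disease follows a broadly hierarchical
spatial cascade, but where an individual's tau emerges and where it is
currently accumulating varies substantially between people. A clinical
trial that reads out longitudinal change in a fixed, group-level region of
interest (ROI) — a data-driven stage composite, a Braak-stage set, or the
temporal meta-ROI — therefore averages over regions that have long been
saturated in some participants and not yet involved in others, diluting
the measurable signal. `tauroi` implements both the group-level readouts
and five participant-specific ROI definitions, and quantifies what the
individualization buys in trial sample size.

All analyses operate on two-timepoint regional SUVR tables (standardized
uptake value ratio: regional tracer uptake divided by volume-weighted
uptake in a reference region, typically the inferior cerebellar cortex;
`normalize_to_reference()` performs this step when raw uptake is
supplied). The package is atlas-agnostic: regions are opaque string
identifiers, and ROI composites are supplied as data (JSON region sets),
not hard-coded anatomy.

## Change metrics

For a ROI aggregated to its volume-weighted mean SUVR $x$ at baseline and
$y$ at follow-up, separated by $\Delta t$ years:

* annual percentage change: $100\,(y - x)/(x\,\Delta t)$ (%/year),
* annual change: $(y - x)/\Delta t$ (SUVR/year),
* tau extent: the fraction of ROI voxels with SUVR above a threshold
  (default 1.40), with the same annualized percentage-change formula
  applied to the extent values.

Aggregation happens first, change second; individualized ROIs are defined
once and held fixed for the change computation (only the overlap method
uses the follow-up scan in the ROI definition, by design). Group
summaries are means with t-based 95% CIs and two-sided one-sample t tests
against zero.

## Tau positivity

Per-region (or per-ROI) positivity is modelled with a two-component
Gaussian mixture over participants' baseline values: a tau-negative and a
tau-positive component. The EM fit is deterministic: the first restart
initializes component means from the lowest and highest deciles, nine
further restarts jitter that start under a seeded RNG, and the best
log-likelihood wins. By default the fit pools all subjects, including
amyloid-negative controls — the controls anchor the tau-negative
component; per-group fitting is available via the `subjects` selector.

A region is called *unimodal* (no usable tau-positive component) when any
of three conditions holds: a component weight below 0.02, component means
closer than the larger component SD, or a two-component fit that fails to
beat a single Gaussian on BIC. The first two conditions alone proved
insufficient: EM on genuinely unimodal data routinely converges to
spurious splits whose means are several (small) component SDs apart, and
the BIC comparison is the standard model-selection guard against exactly
that. Unimodal regions get cutoff $+\infty$ and positivity probability 0.

The positivity probability at SUVR $s$ is the posterior probability of
the high component by Bayes' rule (computed on log densities for
stability in the tails). The default cutoff is the posterior-0.5 root
between the component means; `low_mean_plus_2sd` is available as the
conventional alternative.

## The five individualized ROI definitions

1. **Quartile 1 (Q1).** Per-region positivity probabilities define a
   participant-specific epicenter: the top 10% of regions by probability
   (ties broken lexicographically by region id, so selection is
   deterministic). Connectivity weights are converted to path lengths
   ($1/w$ for positive weights; nonpositive weights carry no edge — path
   semantics are undefined for negative correlations) and all-pairs
   shortest paths computed by Dijkstra's algorithm. Non-epicenter regions
   are ranked by mean distance to the epicenter and split into four
   quartiles whose sizes differ by at most one (remainder to the earlier
   quartiles); Q1 is the ROI. The epicenter itself is excluded by
   default, with an inclusion option for sensitivity analyses. A single
   template connectivity matrix is used for all subjects; epicenters
   remain subject-specific.
2. **Probability interval.** Candidate intervals pair lower starts
   {0.2, 0.3, 0.4} with upper ends {0.7, 0.8, 0.9, 1.0} (12 candidates);
   a subject's ROI under $[\ell, u]$ is the set of regions whose
   positivity probability lies in the closed interval. The interval
   maximizing the group-mean annual percentage change wins; ties prefer
   the narrower interval, then the lower start. The search runs per
   diagnostic group by default (pooled optionally); subjects with an
   empty ROI under the winner are excluded and logged. The rationale for
   an upper bound below 1 is saturation: regions at their plateau no
   longer accumulate.
3. **Overlap index.** Baseline and follow-up voxel maps are binarized at
   SUVR > 1.40 within gray matter; the ROI is the intersection mask
   (voxels abnormal at both timepoints), and |intersection|/|union| is
   recorded. Subjects with disjoint masks are excluded and logged.
4. **Highest tau-positive stage.** Positivity cutoffs derived per staged
   ROI are applied to baseline stage means; the ROI is the staged set
   with the *largest* positive stage index — the most recently affected
   composite, where accumulation should be fastest. Noncontiguous
   positivity (a hierarchy violation) still uses the maximum positive
   index and is flagged. Tau-negative subjects default to the stage-1 set
   with a flag (keeping group sizes comparable across methods);
   exclusion is available.
5. **Subtype/stage assignment.** A fixed, pre-trained event-sequence
   model (4 subtypes x 30 stages by default) is applied — training such
   models is out of scope. Regional z-scores versus the amyloid-negative
   controls are scored against the expected event pattern of every
   (subtype, stage) pair under a Gaussian event model with unit noise;
   the maximum-likelihood pair wins, scanned exhaustively. The ROI is
   the union of regions in the assigned stage's band (closed bands
   1–10, 11–20, 21–30; a boundary stage uses its own band). Stage 0
   (no event passed) yields no ROI and exclusion.

## Trial power

For a two-arm trial whose outcome is the annual percentage change, a
treatment effect is a fractional reduction $f \in \{0.2, 0.3, 0.4\}$ of
the placebo-arm mean. The per-arm sample size uses the
normal-approximation closed form

$$n = \left\lceil \frac{2\,(z_{1-\alpha/2} + z_{\text{power}})^2\,
  \sigma^2}{(f\mu)^2} \right\rceil,$$

with $\alpha = 0.05$ two-sided and power 0.80 as configurable defaults.
The closed form was chosen over iterative t-based designs because
realistic $n$ far exceeds 30 and an independent simulation oracle in the
test suite bounds the approximation error (empirical power at the
closed-form $n$ stays within [0.78, 0.82] at 10,000 simulated trials
across a grid of coefficient-of-variation and effect settings). Note $n$
depends on $(\mu, \sigma)$ only through $\sigma/\mu$. Groups whose mean
change is nonpositive have no defined trial size and are reported as
such, never imputed.

Sample-size reductions between ROIs, $100\,(1 - n_{\text{roi}}/
n_{\text{ref}})$, are compared against the temporal meta-ROI and the
best-performing staged ROI of each group (recomputed per run). CIs come
from a paired bootstrap over subjects (1000 replicates): each replicate
recomputes mean, SD, $n$ and the reduction. Replicates whose resampled
mean is nonpositive — or so close to zero that the required $n$ is not
representable — are rejected, redrawn and counted.

`bootstrap_compare()` implements the two-group rule: resample each group,
form percentile 95% CIs of the statistic, and call the difference
significant when the observed statistic of the higher group exceeds the
upper CI bound of the lower group. A caveat documented deliberately: for
two *independent* samples this rule is anti-conservative (its type-I
rate is roughly $2\Phi(-1.96/\sqrt{2}) \approx 17\%$, since the
difference of two means is $\sqrt{2}$ times noisier than either mean);
it behaves far better for the paired, positively correlated ROI
comparisons it is used for in the pipeline, where the effective noise of
the difference shrinks with the correlation. The test suite measures
this rate honestly rather than hiding it.

## The synthetic cohort generator

`simulate_cohort()` generates the conditions the analysis assumes, with
full determinism under a seed:

* regions partitioned evenly into $K = 5$ ordered stages that double as
  modules of a block-modular connectivity template (within-module mean
  weight 0.6, between 0.15), so connectivity-based proximity aligns with
  the spreading pattern;
* per subject, an attained stage drawn from a group-specific
  distribution — CU weighted toward early stages, MCI intermediate, AD
  late, amyloid-negative controls fixed at stage 0 (tau-free). The
  defaults (97 CU, 77 MCI, 41 AD, 69 controls; scan interval 1.8 ± 0.3
  years) mirror a realistic longitudinal tau-PET cohort;
* baseline SUVR of 1.20 ± 0.05 in unaffected regions plus a positive
  shift of 0.60 ± 0.20 in regions at or below the attained stage —
  placing affected-region SUVR near 1.8, comfortably above the 1.40
  voxel threshold convention;
* annual accumulation fastest in the most recently attained stage
  (default 8 %/y, between-subject SD 2), decaying by a factor 0.5 per
  step back in the cascade, zero in not-yet-affected regions;
* subject-specific epicenters: each template stage-1 region is swapped
  with its strongest later-stage connectivity neighbour with probability
  0.3 (0 = a single shared epicenter; swaps preserve stage-set sizes);
  positivity is monotone in stage at generation, so hierarchy violations
  arise only from measurement noise;
* measurement noise of SD 0.03 SUVR per region and timepoint, and
  optional voxel blocks drawn i.i.d. around regional means.

What it deliberately does not emulate: spatial autocorrelation of voxel
noise, scanner point-spread and partial-volume effects, off-target
meningeal signal, atrophy, or any cognition model (diagnostic groups
differ only in stage distribution and size). Passing tests therefore
demonstrate that the *algorithms* behave as specified under the assumed
statistical structure — not that real cohorts satisfy that structure.

The generator writes the exact table formats the readers ingest, so the
pipeline has no synthetic-only code path.

## Validation strategy and problem sizes

The test suite works oracle-first: closed-form arithmetic cases,
sort/slice and set-intersection oracles, an exhaustive likelihood scan
for subtype/stage assignment (all 4 x 30 noise-free combinations
recovered exactly), an independent multi-restart EM implementation
(mclust) as cross-check for the mixture fits, and a vectorized
simulation oracle for the power formula. End-to-end runs use the
default-scale cohort (284 subjects, 200 regions, 3 seeds) and verify the
qualitative headline: under heterogeneous staging, the
highest-positive-stage method yields a higher group-mean annual
percentage change than every group-level staged ROI in every group, with
significant positive sample-size reductions versus the temporal
meta-ROI; with a shared epicenter and a degenerate (point-mass) stage
distribution the advantage collapses to zero, because every subject's
individualized ROI coincides with the group-level set. Generator
recovery checks use 100 subjects; since a t-based 95% CI misses the
configured rate in 5% of replicates by construction, the acceptance test
requires coverage in at least 2 of 3 seeded replicates.

## Known limitations

* The event-model assignment uses a point maximum-likelihood scan; no
  posterior uncertainty over (subtype, stage) is propagated.
* The probability-interval search optimizes in-sample mean change and is
  not cross-validated; its selected interval should be interpreted as
  descriptive.
* The bootstrap significance rule is the field convention it reproduces,
  with the anti-conservativeness noted above for independent samples.
* Voxel blocks model no spatial structure, so overlap-index and
  tau-extent results on synthetic data exercise logic, not image
  realism.
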