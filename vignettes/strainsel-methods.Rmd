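---
title: "Strain-curve features and multi-method feature selection for CRT response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain-curve features and multi-method feature selection for CRT response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainsel)
```

## Background

Cardiac resynchronization therapy (CRT) is offered to heart-failure
patients with conduction delay, typically left bundle branch block (LBBB),
yet roughly a third of implanted patients do not remodel favourably.
Speckle-tracking echocardiography measures longitudinal strain — percent
shortening of each myocardial segment along the long axis, negative during
contraction — in the three standard apical views (4-, 3- and 2-chamber,
six segments each). LBBB mechanics leave characteristic signatures in
these curves: the septum activates early and is then stretched by the
late-contracting lateral wall (rebound stretch), and part of the
deformation occurs after aortic valve closure (AVC), when it no longer
ejects blood and is mechanically wasted.

`strainsel` quantifies these signatures as a fixed 158-element feature
vector per patient, and provides a multi-method stage for asking which
features carry information about CRT response (defined from the
end-systolic volume change at follow-up).

## The feature scheme

All features are computed on a uniform 500 Hz grid (linear interpolation
of the exported curves) with time zero at the QRS onset, and strain values
inside the ±5 % dead zone are ignored by every contraction calculation:
small oscillations around zero reflect noise and tethering rather than
contraction.

For each segment $sg$ of view $vw$:

* $P_{vw}^{sg}$ — peak contraction magnitude, $\max(-s(t))$, clipped below
  at 0;
* $T_{vw,peak}^{sg}$ — time of the first global strain minimum, defined
  only when the excursion passes −5 % (a flat segment has no datable
  contraction event, and fabricating one would corrupt the timing
  statistics);
* $I_{vw,avc}^{sg} = \int_0^{T_{avc}} |s(t)|\,[s(t) < -5]\,dt$ — cumulative
  contraction up to AVC: the strain that ejects blood;
* $I_{vw,peak}^{sg}$ — the same integral up to $T_{vw,peak}^{sg}$: total
  contraction deployed by the segment;
* $E_{vw}^{sg} = I_{vw,peak}^{sg} - I_{vw,avc}^{sg}$ — the efficiency
  marker. Positive values mean the strain peak falls after AVC with
  qualifying contraction in between: cumulative strain wasted after the
  valve has closed.

Per view these are aggregated into means and standard deviations, the
heterogeneity and dyssynchrony spreads
$\Delta P_{vw} = \max_{sg} P - \min_{sg} P$ and
$\Delta T_{vw,peak} = \max_{sg} T - \min_{sg} T$, the two wall ("side")
sums of each integral family (septal/lateral for 4ch,
anteroseptal/posterior for 3ch, inferior/anterior for 2ch) and their
side differences, always first-listed minus second-listed wall. With the
per-view AVC time that is 52 features per view; the QRS duration and the
LVEF complete the 158-vector. Names follow the grammar
`<family>_<view>_<qualifier>` (`E_4ch_BS`, `Iavc_2ch_std`, `dP_3ch`,
`Tavc_2ch`, `Ipeak_4ch_SmL`, …), canonical order given by
`feature_names()`.

Responder status uses the strict volumetric criterion: a decrease in LV
end-systolic volume of more than 15 % at follow-up
(`classify_response()`); a decrease of exactly 15 % is a non-responder.

### Numerical choices

* **Integration rule.** The masked integral is evaluated on the
  piecewise-linear 500 Hz trace with the ±5 % boundary crossings located
  exactly by linear interpolation and crossing panels split there. The
  masked integrand jumps from 0 to 5 at a crossing, so a plain per-sample
  mask under the trapezoid rule biases each crossing by up to
  $2.5h \approx 5\times10^{-3}$ %·s at $h = 2$ ms; splitting restores
  $O(h^2)$ accuracy, and the implementation agrees with closed-form
  integrals of triangular and raised-cosine test pulses to better than
  $10^{-3}$ %·s.
* **Tie-break for $T_{peak}$**: first global minimum — deterministic, and
  the earliest mechanical event.
* **Undefined $T_{peak}$**: $I_{peak} = 0$, hence $E = -I_{avc}$; the
  segment is excluded from the timing mean/std/spread (count logged). A
  view where all six segments are undefined is flagged low quality.
* **Identities.** $E = I_{peak} - I_{avc}$ holds bit-exactly by
  construction; side sums equal their member sums and side differences are
  antisymmetric under side swap, tested on randomized views.

## Feature-importance stage

* **Out-of-bag random-forest importance** (`oob_importance()`): Breiman's
  permutation importance — the mean decrease in out-of-bag accuracy when a
  feature is permuted over each tree's out-of-bag samples, averaged over
  trees, unscaled — normalized so the top feature scores 1. The forest
  uses 700 trees, Gini splitting, 10 candidate features per split,
  unlimited depth, and inverse-class-frequency weights for the unbalanced
  classes. Permutation importance (rather than split-impurity importance)
  is used because the importance notion here is sensitivity of the
  out-of-bag decision to each feature; "Gini" names the split criterion
  only.
* **Correlation graph** (`correlation_graph()`): Pearson correlation among
  a chosen feature subset (Pearson, because the quantity of interest is
  linear redundancy between continuous markers); edges only for
  $|r| > 0.5$ strictly, drawn with thickness $10|r| - 5$, so thickness is
  in $(0, 5]$.
* **Five filter/wrapper rankers**, each returning a full permutation of
  the features: absolute point-biserial correlation with the response;
  absolute Welch $t$; univariate ANOVA $F$ (the K-Best scorer — for two
  classes the square of the pooled $t$, the most common default for this
  filter); recursive feature elimination with an L2-regularized
  least-squares linear classifier on standardized features, eliminating
  one lowest-|weight| feature per round (the estimator and step are
  exposed as configuration; a linear, deterministic estimator keeps the
  elimination order reproducible); and ReliefF with $k = 10$ neighbors on
  min-max-scaled features, all samples used.
* **CWF combination** (`cwf_combine()`): a feature is eligible when it
  appears in the top-20 of at least three of the five rankers; its score
  is its mean rank over the lists where it appears (averaging only over
  those lists — the alternative of penalizing absent lists would mix two
  scales); ascending mean rank orders the result, ties broken
  lexicographically by name.

All stochastic steps are seeded; ties everywhere are broken
lexicographically so reruns are byte-identical. Missing feature values
(timing statistics of low-quality views) are median-imputed before
ranking, with a logged count.

`reference_top20()` ships the 20-name OOB and CWF lists reported for a
published 130-patient multicenter clinical CRT cohort, transcribed into
this package's name grammar. They serve as a structural reference — their
view census (12/5/3 over 4ch/2ch/3ch for the OOB list) and their mutual
overlap (10 features) — not as values this package's synthetic runs are
expected to reproduce: importance scores on real patients depend on the
clinical data itself.

## The synthetic cohort generator

No public raw-curve dataset accompanies the feature scheme, so the
package ships a generator (`generate_cohort()`) that emulates segmental
strain curves with LBBB-like mechanics, making every downstream stage
testable end-to-end.

Each segment curve is a sum of raised-cosine lobes: a negative systolic
lobe (depth = peak strain, centred at the peak time) plus, for septal
segments, a positive rebound lobe directly after it. Raised cosines were
chosen because their extrema and masked integrals have closed forms, so
the extraction stage can be checked against independent analytic oracles.
Baseline mechanics: peak strain drawn from a truncated normal
(16 ± 2.5 %, clipped to 5–25 %), septal segments peaking early
(0.30 s) with a narrower lobe and rebound fraction 0.25, the lateral wall
last (0.33 s), others at 0.32 s; cycle length 0.8 s; per-view AVC at
0.38/0.37/0.36 s; export rate 100 Hz (a typical clinical strain-export
rate above the 60 frames/s acquisition floor, and coarse enough that the
500 Hz upsampling step does real work); additive Gaussian sample noise of
1 % strain.

Labels are assigned first — the responder count is exactly
`round(fraction * n)`, so 130 patients at 0.64 give the 83/47 split —
then curve parameters are drawn conditioned on the label. Responders
differ by three offsets applied to the 4ch septal and lateral walls (the
walls the septal/lateral opposition names):

* `septal_t_peak` (+0.12 s): displaces the septal strain minimum beyond
  AVC. This realizes post-systolic septal shortening and makes the septal
  efficiency features positive for responders (wasted septal work, the
  pattern associated with CRT benefit). With a single-lobe-plus-rebound
  curve family a pre-AVC peak can only give $E \le 0$, so the responder
  effect is expressed through the timing of the deepest septal
  deformation rather than through the rebound alone, which both groups
  share.
* `lateral_amplitude` (+4 percentage points) and `lateral_t_peak`
  (+0.08 s): a stronger, AVC-crossing lateral contraction, raising the
  lateral cumulative-strain-to-peak features.

ESV pairs are drawn conditioned on the label (responders lose 20–45 % of
baseline ESV, non-responders −8 to +12 %, both always on the correct
side of the strict 15 % boundary), so stored labels always agree with
`classify_response()`. `planted_features()` names the five features the
offsets act on (`E_4ch_BS/MS/AS`, `E_4ch_S`, `Ipeak_4ch_L`); with the
default effect sizes they separate the groups at Welch $|t| > 5$ and are
recovered into the OOB top-20 across seeds, while an all-zero effect map
yields a null cohort in which the strain features show no group
structure.

What the generator does **not** emulate: measurement drift and segment
drop-out, inter-vendor strain differences, heart-rate and cycle-length
variability, atrial fibrillation, correlated multi-segment noise, and any
image-level artifact. Passing recovery tests therefore shows that the
pipeline detects the effect structure it encodes — not that the same
features would rank first in real patients.

## Pipeline, seeds and problem sizes

`run_pipeline()` (and the `inst/scripts/strainsel-cli.R` wrapper with
subcommands `synth`, `extract`, `rank`, `report`) chains generation,
extraction and ranking. One run-level seed is fanned out to per-stage
seeds by a fixed affine map (`derive_seed()`), so stages can be re-run
independently; every output file carries the seed and the MD5 hash of the
YAML config in `# key: value` comment headers, and identical configs
produce byte-identical reports.

The shipped test suite exercises the recovery experiment at the cohort
scale the generator defaults encode (130 patients, 64 % responders, 700
trees, 20 seeds) and the method oracles at small sizes (ReliefF vs a
naive neighbor scan at $n \le 30$, $p \le 5$; CWF vs brute-force
recomputation on 100 random ranking quintuples; 100 randomized views for
the algebraic identities).

## Limitations

The extraction stage assumes single-beat, QRS-aligned exports with a
declared AVC time per view; it does not compute global longitudinal
strain, strain rate, or post-systolic indices beyond the efficiency
marker. The K-Best scorer and the RFE estimator are conventional defaults
exposed as configuration, not uniquely determined choices; ReliefF uses
the canonical multi-neighbor form. The correlation stage is linear by
design. Predictive performance of the response classifier (AUC, accuracy)
is deliberately out of scope: ranking stability, not classification
skill, is what a cohort of this size supports.
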