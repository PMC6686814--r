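---
title: "Methods: outcome analysis for the ovine annular-lesion disc degeneration model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outcome analysis for the ovine annular-lesion disc degeneration model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivdd)
```

# The experiment this package analyses

The package implements the quantitative outcome layer of a large-animal
disc degeneration experiment. In the emulated design, lumbar
intervertebral discs (IVDs) of adult sheep receive a controlled
anterolateral annular lesion; degeneration develops for 4 weeks (early and
late acute groups, EA/LA) or 12 weeks (established group, EST); the lesion
discs are then injected with mesenchymal stem cells (MSC) or PBS carrier,
and after a recovery period the outcome is measured against nonoperated
controls (NOC). One disc level per sheep feeds each modality: histology
(L1L2), gene expression (L3L4), and biomechanics plus biochemistry (L5L6);
biochemical and expression assays are zonal (outer annulus AF1, inner
annulus AF2, nucleus pulposus NP), with six sheep per analysis cell.

No raw data from such experiments are deposited; all published results are
in-text summaries. The package therefore pairs every analysis stage with a
synthetic-study generator whose presets are calibrated to those cohort
summaries, so that each estimator can be validated against known ground
truth and the whole pipeline can be exercised end to end.

# Torque-angle biomechanics

## The estimators

Functional spinal units are cycled in flexion-extension, lateral bending
or axial rotation at 5 deg/s to a torque limit of +/-5 Nm for 10 cycles,
sampled at 20 Hz; the final full cycle is analysed.

* **Range of motion (ROM)** — total angular deflection between the sample
  at maximal positive torque and the sample at minimal negative torque.
* **Smoothing** — each loading direction of the final cycle is fitted with
  a seventh-order polynomial of torque on angle by ordinary least squares
  (`fit_direction()`). The angle is centred and scaled to [-1, 1] before
  fitting for numerical conditioning; gradients are evaluated analytically
  from the fitted coefficients.
* **Neutral zone (NZ)** — per direction, the fitted gradient is evaluated
  on a 0.01 deg grid over the shared angle domain; the direction's NZ is
  the maximal contiguous interval with gradient strictly below
  0.05 Nm/deg that contains (or is nearest to) that direction's
  zero-torque crossing; the final NZ is the intersection ("common
  overlapping range") of the two per-direction intervals, and is absent
  when either direction has no sub-threshold region or the overlap is
  empty. A seventh-order polynomial can have several sub-threshold
  pockets; anchoring at the zero-torque crossing is the package's
  tie-break, and both the grid step and the threshold are arguments.
* **Initial and final stiffness** — per direction, the fitted gradient at
  the zero-torque crossing, averaged over the maximal contiguous interval
  around it where the gradient deviates from its crossing value by less
  than 0.05 Nm/deg ("change in gradient" is read as deviation from the
  neutral-position gradient, which makes the band parameter-free and
  sampling-independent); final stiffness is the arithmetic mean of the two
  directions.

Ties at the threshold are excluded (strict `<`), matching the printed
inequality. Positive torque corresponds to flexion / left bending / left
rotation.

## The synthetic hysteresis loop

`simulate_loop()` generates records from a smooth odd dual-stiffness
backbone

$$T(\theta) = k_{nz}\,\theta + (k_{el} - k_{nz})\,\frac{\theta^5}{5a^4},
\qquad
T'(\theta) = k_{nz} + (k_{el} - k_{nz})\left(\frac{\theta}{a}\right)^4,$$

plus a constant +/- hysteresis offset by direction of motion and additive
Gaussian torque noise. The quartic gradient well has a genuinely flat
neutral region of stiffness $k_{nz}$ that stiffens progressively towards
end range; the transition scale $a$ is set from the `nz_half_width`
parameter so the gradient crosses the 0.05 Nm/deg criterion at exactly
+/- `nz_half_width`. The neutral-zone width, and the per-direction
initial-stiffness estimand (the mean gradient over the 0.05-band around
each limb's zero crossing), then exist in closed form (`loop_truth()`).

Two design points deserve emphasis:

* **The backbone lies inside the degree-7 polynomial family.** During
  development we also examined saturating transitions of tanh type; a
  seventh-order least-squares fit of such backbones carries 0.1-1.6 deg of
  smoothing bias in the recovered neutral zone, which would make it
  impossible to distinguish estimator defects from model mismatch. With a
  quintic backbone the smoothing step is bias-free by construction, so the
  oracle tests isolate the estimator logic (grid scan, interval selection,
  overlap, stiffness band). The price is realism at end range: real
  torque-angle curves plateau near the torque limit, the quintic keeps
  stiffening. Passing oracle tests therefore certify the procedure, not
  its robustness to model mismatch on real loops.
* **The stiffness estimand is not $k_{nz}$.** For the quartic well, the
  mean gradient over the symmetric band where the gradient has risen by
  less than 0.05 Nm/deg equals $k_{nz} + 0.05/5$ exactly (the mean of a
  quartic over its sub-level set is one fifth of its peak), and a nonzero
  hysteresis offset moves each limb's zero crossing onto the transition
  shoulder, raising the estimand further. The generator therefore reports
  the analytic value of the estimand itself as ground truth, and recovery
  is always measured against that value, never against raw $k_{nz}$.

A practical acquisition limit: because the quintic stiffens without bound,
loops with `nz_half_width` below about 0.25 deg reach the +/-5 Nm limit
within roughly a degree of excursion, and at the rig's fixed 20 Hz /
5 deg/s acquisition such records carry fewer samples per direction than a
seventh-order fit requires (the fit demands at least nine). The oracle
sweep therefore covers half-widths from 0.75 deg upward on a factorial
grid, with the zero-half-width (linear, no neutral zone) case covered
separately. Axial-rotation presets set the neutral-region stiffness above
the criterion, reproducing the observation that axial rotation shows no
region of low stiffness; the procedure must report an absent neutral zone
there.

# Disc height index radiogrammetry

Landmarks are named coordinates on a lateral radiograph: the four corners
of the cranial and caudal vertebral bodies and anterior/middle/posterior
disc-margin pairs. All heights are measured along the local spine axis
(the unit vector joining the two vertebral-body centroids), which removes
rotation sensitivity; disc height is the mean of the three disc-space
distances, and

$$\mathrm{DHI} = \frac{2\,\mathrm{disc\ height}}
{\mathrm{VB}_{cranial} + \mathrm{VB}_{caudal}},$$

the standard radiogrammetric convention in which magnification cancels.
`percent_dhi()` expresses the endpoint DHI as a percentage of the
pre-surgery DHI of the same disc; among the four radiographic timepoints,
pre-surgery is taken as the denominator. The generator applies an
independent similarity transform (magnification 0.85-1.25, rotation
+/-12 deg, translation) to every radiograph, and the invariance of DHI
under such transforms is tested to 1e-9 relative over random transforms.

# Cumulative histopathology scoring

Six ordinal criteria are scored per disc section: toluidine-blue GAG
staining, structural characteristics of the lesion, cellular morphology,
blood vessel ingrowth, cellular infiltration, and specific
degenerative/repair features (chondroid metaplasia, cystic degeneration,
collagen denudation). The published per-criterion ranges are not
reproduced in text, so ranges are configuration (`scoring_scheme()`), with
a 0-5 default per criterion (scheme maximum 30), consistent with cohort
cumulative means up to the low twenties.

Two blinded observers score every section; no reconciliation rule is
published, so the package uses the per-criterion mean rounded half-up to
the ordinal grid, recording per-criterion absolute disagreement. The
cumulative score is the sum of the six consensus scores.

The generator draws observer 1's score as `floor(mean) + Bernoulli(frac)`
plus a symmetric integer jitter with discretised-normal weights truncated
so it cannot cross the ordinal range; the expectation is exactly the
criterion mean, while the realised dispersion is bounded above by the
requested SD (substantially so for sub-unit dispersions — a zero-mean or
at-maximum criterion is drawn deterministically). Observer 2 repeats
observer 1 but with probability 0.3 scores one step lower. The jitter is
one-sided by design: with the half-up rounded-mean consensus, a symmetric
+/-1 jitter would bias the consensus upward by the probability of an
upward step per criterion (x - 0.5 rounds to x, x + 0.5 rounds to x + 1),
breaking the calibration of cohort expectations; a downward-only step
leaves the consensus equal to observer 1 while still exercising the
disagreement bookkeeping. No published inter-observer statistics constrain
the jitter magnitude.

# Calibration of the cohort presets

`default_presets()` carries four cohorts. The cumulative-score means and
disc-height ratios are the calibration anchors; the per-criterion
allocation is a design choice (any allocation with the same sum is
equivalent for cohort means):

| preset | criterion means (a-f) | cumulative | SD | DHI ratio |
|---|---|---|---|---|
| NOC | 1,1,0,0,0,0 | 2 | 0.3/criterion | 1.00 |
| degenerate-baseline | 4,4,4,4,3,3 | 22 | 2.2/sqrt(6) | 0.85 |
| PBS-endpoint | 4,4,3,3,3,2 | 19 | 2.5/sqrt(6) | 0.80 |
| MSC-endpoint | 1,1,1,1,0,0 | 4 | 0.4/sqrt(6) | 0.935 |

The per-criterion dispersion is the cohort SD divided by sqrt(6) so that
six independent criteria compound to approximately the cohort SD. The
MSC DHI ratio 0.935 sits mid-way in the 92-95% re-attainment band of the
emulated study; the PBS ratio 0.80 sits mid-way in its 15-25% loss band.

Biochemical contents (GAG about 45/28/20 ug per mg wet weight in NP/AF2/
AF1 for controls, reduced in carrier-injected discs and restored under
treatment; hydroxyproline about 18/15/6 ug/mg, largely unchanged) and the
expression multipliers (catabolic panel MMP2/3/9/13, ADAMTS4/5, IL1RN
raised 3-6 fold in carrier discs, normalised under treatment; COL2A1/ACAN
halved in carrier discs) are not printed numerically in the source
material; they were chosen once as field-realistic values and feed only
round-trip and power tests, not calibrated recovery targets. Expression is
reported per zone but the default multipliers do not differ by zone.

# Standard-curve quantitation

Both chromogenic assays (DMMB for sulfated GAG against a chondroitin
sulfate standard; dimethylaminobenzaldehyde for hydroxyproline) are used
in their linear ranges, so calibration is an ordinary least-squares line
of signal on amount — not a four-parameter logistic — with at least three
distinct standards required. Back-calculation averages the triplicate
signals, inverts the line, corrects for the digested fraction assayed
(aliquot/digest volume bookkeeping travels in the generator config) and
divides by wet weight; whether contents are per wet or dry weight is not
specified in the source material, and wet weight is assumed. Amounts
outside the standard range are flagged `extrapolated` but still returned;
negative back-calculated amounts clamp to zero with a warning.

qPCR standard curves come from five ten-fold dilutions of pooled disc
cDNA, fitted as `Ct = intercept + slope * log10(copies)` with relative
copies anchored to the top standard = 1; the amplification efficiency
`10^(-1/slope) - 1` must fall in (0, 1.2]. Samples are normalised by
total RNA loading, not by housekeeping genes, whose expression shifts
with disc disease. Triplicates are averaged on the Ct scale before
back-transformation; replicate ranges above 1 Ct are flagged. Fold
changes against nonoperated controls are ratios of geometric means.

# Nonparametric statistics

Group comparisons use the Mann-Whitney U test with midrank ties. For
`n1 * n2 <= 100` the two-sided p-value is exact: all `choose(n1+n2, n1)`
assignments of the pooled observations are enumerated and p is the
proportion whose U deviates from the null mean `n1*n2/2` at least as far
as observed (under ties this is the permutation null conditional on the
pooled values). Larger samples fall back to the tie-corrected normal
approximation with continuity correction. Identical pooled values are
degenerate and return p = 1.

Multiplicity is handled by the Benjamini-Hochberg step-up rule: sort the
m p-values, find the largest k with `p_(k) <= k * alpha / m`, reject the k
smallest, and report `p_(k)` as the corrected significance threshold — a
data-dependent output, never a constant. Adjusted p-values use the
standard monotone BH adjustment (`stats::p.adjust`). `run_study()` pools
all MSC-vs-PBS comparisons study-wide into a single correction by
default; the published analysis does not state the pooling family, and a
per-endpoint family can be obtained by running the correction on subsets.
The mixed ordinal-logistic screening step of the original analysis is out
of scope; the Mann-Whitney layer is the implemented comparator.

# Problem sizes and numerical choices

* Gradient grids: 0.01 deg for the estimators; oracle checks use 0.001 deg
  finite differences of the noiseless backbone.
* Default acquisition: 10 cycles at 20 Hz and 5 deg/s; torque noise SD
  0.05 Nm; hysteresis offset 0.3 Nm (0 in oracle sweeps).
* The oracle and recovery sweeps use 45-50 loops; the exact-test size
  simulation uses 2000 null replicates at n = 6 vs 6; DHI invariance uses
  1000 random similarity transforms; the study-level power check runs 20
  replicate studies of the full design at n = 6. These sizes were chosen
  to estimate the checked proportions with adequate precision while
  keeping the default suite fast.
* Half-up rounding (`floor(x + 0.5)`) is used wherever ordinal consensus
  is formed.
* Zero-torque crossings are located by sign change on the grid and
  refined by root-finding on the fitted polynomial.

# Known limitations

* The quintic backbone certifies estimator logic, not robustness to
  polynomial model mismatch; real loops deviate from any degree-7 curve
  and the published procedure inherits whatever bias that brings.
* Radiographs are landmark tables and histology is score sheets: there is
  no image synthesis, no landmark placement error model beyond the
  similarity jitter, and no lesion geometry.
* Realised histopathology dispersion is bounded above by the requested SD
  because of the range-respecting discrete draw; cohorts with sub-unit SD
  are close to deterministic.
* Expression multipliers are zone-constant by default, and the melt-curve
  and RNA-quality QC of real qPCR are reduced to a replicate-range flag.
* The generator's group-level biomechanical differences are encoded in
  the per-arm presets; the default preset map does not vary loop
  parameters between EA, LA and EST beyond that.
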