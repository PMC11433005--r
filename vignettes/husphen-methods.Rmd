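---
title: "Quantitative methods for ultrasound and metabolic phenotyping of diet-induced obesity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative methods for ultrasound and metabolic phenotyping of diet-induced obesity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(husphen)
```

`husphen` implements the quantitative layer of a longitudinal mouse study in
which C57Bl/6J mice of both sexes are fed a standard diet (SD) or a
Western-type diet (WD) from 8 to 24 weeks of age and phenotyped by
high-frequency ultrasound (HFUS), blood chemistry and terminal histology.
Because such studies rarely deposit raw images and traces, the package pairs
every analysis stage with a seeded synthetic-data generator that reproduces
the statistical structure the stage assumes, so the whole pipeline is
testable end to end without animal data.

# Synthetic study inputs

## Cohort generator

`generate_cohort()` draws one record per mouse per week. Body weight follows
a per-mouse linear trend: a sex-specific baseline (defaults 22.5 g males,
18.0 g females), a sex-by-diet slope (defaults 0.35/0.70 g/week for SD/WD
males, 0.22/0.42 g/week for females), and Gaussian residual scatter
(0.5 g). WD animals receive a transient hyperphagia bump (+0.8 g/day for the
first two weeks after the diet switch) and endpoint shifts of the fasting
blood panel (glucose +60 mg/dL, cholesterol +70 mg/dL, insulin +0.8 ng/mL,
and so on); all effect sizes are mean/SD pairs in the variable's own units
and live in one editable object, `cohort_effects()`. These defaults are
chosen once to be typical of diet-induced-obesity cohorts in this strain;
they are deliberately mild enough that endpoint group separation requires
the statistics layer rather than being visually trivial. Attrition is
modeled as missing-at-random truncation: a mouse drops out after a uniformly
chosen week, exercising the incomplete-series path of the repeated-measures
ANOVA (the kind of single-animal loss — e.g. malocclusion — that such
studies report).

`cohort_effects(null = TRUE)` removes every diet effect while keeping the
variability, which is how the type-I-error calibration tests build their
null cohorts; `zero_noise = TRUE` makes the generator fully deterministic.

What the generator does *not* emulate: growth-curve plateauing (trends are
linear over the 17-week window), within-mouse autocorrelation beyond the
random slope, seasonal/litter effects, and the baseline sex-by-diet
imbalance that real randomization can produce. Tests passing on these
cohorts therefore validate formula and inference plumbing, not biological
realism.

## Speckle phantoms

`generate_phantom()` renders a B-mode-like frame from labeled rectangular
tissue blocks. The acquisition contract is an 8-bit image (256 gray levels)
over an 11 x 13 mm field; the default canvas is 550 x 650 px at
0.02 mm/px. Each region has a target mean echogenicity in arbitrary units
(a.u.) and an optional slowly varying Gaussian heterogeneity field (white
noise smoothed at 4 px and rescaled, so coarseness and amplitude decouple).
Texture is fully developed multiplicative Rayleigh speckle with the scale
chosen as sqrt(2/pi), making the multiplier unit-mean so regional expected
intensity is preserved (verified to <0.5% on 1e5-pixel regions before
quantization). A Gaussian point-spread function (default sigma 1.5 px)
blurs the speckled image; intensities are then clamped to [0, 255] and
quantized by round-half-even. Clipping at 255 is negligible after the blur
at the intensity levels used here.

The phantom is a *statistical* phantom: no wave propagation, attenuation,
shadowing or depth-dependent gain is simulated, and speckle is spatially
white before the PSF rather than governed by a physical resolution cell. It
is exactly what is needed to test ROI statistics and ratio estimators, and
no more. Heterogeneity levels for "coarsened" parenchyma grades are free
parameters, since no texture statistics are published for the visual grades.

## Doppler waveforms

`generate_waveform()` builds an intra-renal arterial velocity trace cycle by
cycle: a linear systolic upstroke from the end-diastolic velocity (EDV) to
the peak systolic velocity (PSV) over the first 15% of the cycle, a
shifted-exponential decay (shape constant k, exactly reaching its endpoint)
to a post-systolic trough over the next 65%, a half-cosine recovery to EDV,
and an end-diastolic plateau at EDV. With no mean-velocity target the
trough equals EDV, giving the classic monotone low-resistance renal
profile.

When a cycle-mean velocity `mv_target` is requested, the generator solves
for the shape numerically (bisection via `uniroot` on a dense one-cycle
grid): first the decay constant with the trough pinned at EDV; if the
target is below what any monotone decay can reach, the trough itself is
lowered below EDV (k fixed at 8). This matters because the published
pulsatility-index reference for this model (PI = (PSV - EDV)/MV = 1.18 with
PSV 30 and EDV 15 mm/s) implies MV = 12.71 mm/s, *below* EDV — impossible
for a waveform whose global minimum is EDV. The package therefore
distinguishes the end-diastolic velocity (the pre-upstroke value) from the
mid-diastolic trough, and the extraction side makes the same distinction
(below). Calibration accuracy is <0.1% relative, verified against a
trapezoidal-integration oracle. Because the systolic apex rarely falls
exactly on the sampling grid, the nearest sample of each cycle is snapped
onto PSV so the sampled trace attains its nominal peak; the effect on the
cycle mean is orders of magnitude below the calibration tolerance.

# Metabolic indices

All formulas are implemented exactly as defined for this study design:

* body-weight gain relative to the earliest record per mouse;
* food efficiency ratio, `100 x cumulative gain / cumulative intake`, in
  grams (default) or kcal mode — the two differ only by the diet's caloric
  density (3.150 kcal/g for SD, 4.2594 kcal/g for WD), and both are exposed
  because published figure legends are ambiguous about which denominator was
  used; a per-interval variant sits behind `cumulative = FALSE`;
* caloric intake, `g/day x kcal/g`;
* HOMA-IR with murine unit conversions: insulin ng/mL x 172.18 / 6 to
  uIU/mL, glucose mg/dL x 0.0555 to mmol/L, product / 22.5;
* the hyperglycemia flag at >= 250 mg/dL, defined for non-fasting samples
  only (fasting input is a contract violation, not a silent pass);
* liver-to-body-weight percentage (hepatomegaly index).

HOMA2 (%B/%S) is intentionally not computed: it comes from an external
structural-model calculator, so the package treats such values as imported
pass-through columns.

# Echocardiographic derivations

From averaged long-axis calipers (>= 3 beats), `echo_derive()` computes the
Teichholz single-diameter volume `(7.0/(2.4 + D)) D^3` (uL from mm),
ejection fraction, fractional shortening, corrected LV mass
(`1.053 ((LVIDd + LVPWd + IVSd)^3 - LVIDd^3) x 0.8`, mg), stroke volume,
cardiac output and relative wall thickness. Indices are derived from raw
calipers first; `echo_normalize()` then applies the allometric convention —
1-D measures / BW^(1/3), 3-D measures / BW — leaving EF, FS and RWT
untouched. The order does not matter for the dimensionless indices, which
the tests assert.

Two caveats are documented deliberately. First, EF from the Teichholz
formula is only *asymptotically* scale-free: the `2.4 + D` prefactor
couples it weakly to absolute chamber size (about 1% per 10% size change
near mouse geometry), so only FS and RWT are exactly invariant under
uniform geometric scaling. Second, group means of per-animal indices are
mean-of-ratios, while an index computed from group-mean calipers is a
ratio-of-means; with realistically correlated diastolic/systolic calipers
(r ~ 0.9 within a heart) the two agree within 2% for FS/EF/RWT, which is
the sense in which printed group tables can be checked against the
formulas. The absolute scale of published *normalized* caliper tables is
not reconstructible from the stated exponents alone and is not asserted.

# Parametric liver ultrasound

ROIs are circles with nominal area in mm^2; a pixel belongs to the ROI if
its center is inside the equivalent radius, the ROI must lie fully inside
the image and cover >= 30 pixels, and statistics are the arithmetic mean
and *population* SD of the covered intensities. The image origin is
top-left, rows run with depth, and depth is center row x spacing.

The hepatic-renal ratio (HR) divides the liver ROI mean by the renal-cortex
ROI mean on the liver/kidney interface view; the hepatic-portal ratio (HPV)
normalizes to the portal-vein blood pool instead (with a division guard for
an anechoic lumen). Both enforce the protocol's ROI area (0.1 +/- 0.02
mm^2, a hard error, encoding the printed tolerance) and depth matching
within 10% — the paper requires "the same distance from the probe" without
a number, so 10% of depth is this package's documented choice. Gray-level
histogram (GLH) analysis uses 1 +/- 0.02 mm^2 ROIs on three standard
planes; heterogeneity is the within-ROI SD of the right median axial plane
and anisotropy the population SD (n denominator, a documented convention
choice) of the three plane means. Portal-vein diameter is the Euclidean
distance between two caliper points times the pixel spacing.

Visual grading (echostructure pattern 1-4, echogenicity vs the renal cortex
0-2, ascites 0/1) is operator-entered ordinal data; the package validates,
stores and tabulates it but never computes it from pixels. Frequency tables
report counts and two forms of percentage: rounded to 2 decimals (columns
sum to ~100) and truncated to 2 decimals, because published tables print
truncated sevenths (85.71 / 42.85 / 14.28 for 6/7, 3/7, 1/7). One published
set of male percentages is mutually inconsistent with its own table counts
(12.5/16.6/12.5% against counts 1/8, 6/8, 1/8); the package reproduces
count arithmetic only and takes no position on the intended values.

# Renal Doppler

`detect_cycles()` finds systolic peaks as local maxima above the trace
midline separated by >= 60% of the expected beat interval, the heart rate
coming from a hint or from the dominant 2-20 Hz spectral peak; fewer than
three detected cycles is an error, per the "average of three to four
cardiac cycles" protocol. `doppler_indices()` then reports PSV, EDV, the
velocity-time integral and mean velocity (VTI/MV over one representative
cycle — the one whose peak is the median of the used peaks — or over all
used cycles behind a flag), and RI = (PSV - EDV)/PSV,
PI = (PSV - EDV)/MV.

Conventions and numerical choices:

* EDV is the *pre-upstroke* local minimum (true end-diastole), not the
  global cycle minimum; the two differ exactly when the diastolic trough
  undershoots the end-diastolic value, which the PI reference above implies.
* For clean or synthetic input the trace is its own envelope and extraction
  is exact (RI = 0.500 to machine precision on the 30/15 construction).
* For noisy input (`envelope = "smooth"`), extraction works on a folded
  beat: the used cycles are aligned at their systolic peaks and averaged
  (cycle-synchronous averaging), smoothed with a running mean whose width
  scales with the cycle length. Two corrections keep the features unbiased:
  the foot (end-diastolic) window steps back past the smoothing radius so
  upstroke samples cannot leak in, and the systolic apex — a sharp corner
  that any running mean rounds down by (|up slope| + |down slope|)/2 times
  the kernel's mean absolute offset — is de-rounded using flank slopes
  fitted away from the corner (an intersecting-tangents refinement). With
  4-cycle traces sampled at 2 kHz and noise at 5% of PSV this recovers RI
  within 0.02 in >= 95/100 seeds; a moving-maximum envelope
  (`envelope = "movmax"`) is available for spectral-style input but is
  upward-biased under noise and not used for calibration claims.
* Window fractions (15% upstroke share, foot window 8% of the cycle, flank
  offsets) are stated in cycle units so behaviour is sampling-rate
  invariant.

Cortical morphometry is thin arithmetic: CRT/BW = cortical thickness / body
weight, and cortical echogenicity change is value minus baseline per mouse.

# Histology scoring

The NAFLD activity score sums steatosis, hypertrophy and inflammation
grades (each 0-3) to 0-9. The grading system scores macro- and
microvesicular steatosis separately, but a 0-9 total implies a single
steatosis term; this package uses `max(macro, micro)` — it preserves the
printed range and grades mixed-pattern steatosis by its dominant component
— with a sum-capped-at-3 variant behind a flag. This is the one place the
scoring rules required an interpretive decision, and it is flagged
prominently here for that reason.

Glomerular grading maps the altered fraction of (target) 20 glomeruli to
0 (<30%), 1 (30% to <70%) and 2 (>= 70%); the published rule's strict
inequalities leave exactly 30% and 70% unassigned, so boundaries close
upward here. Frequency tables share the rounded/truncated percentage
convention above (one published male score-2 percentage, 48.85%, conflicts
with its own counts, 3/7 = 42.85%; counts win). Cross-modality association
uses the one-tailed Pearson correlation (t distribution, n - 2 df),
directional for positive association between histology and ultrasound
severity.

# Statistics layer

* **Mann-Whitney**: for combined n <= 16 the two-sided p comes from the
  full permutation distribution of U over all `choose(m+n, m)` group
  assignments (ties handled exactly, two-sidedness by distance from mn/2);
  larger samples use the normal approximation with tie correction and
  continuity correction. The exact branch is validated against an
  independent brute-force enumeration and against the reference
  implementation in `stats`.
* **Repeated-measures mixed-design ANOVA**: split-plot sums of squares via
  `aov` with a subject stratum; within-subject effects carry
  Greenhouse-Geisser-corrected fractional degrees of freedom, epsilon
  estimated from the pooled within-group covariance of the
  subject-by-timepoint matrix through an orthonormal contrast basis.
  Subjects with incomplete series are dropped with a message — a
  complete-case approximation to the proprietary "mixed effect" behavior of
  the original analysis software, documented as such. Degenerate designs
  are guarded: a zero effect reports F = 0, p = 1; a deterministic effect
  with zero residual reports F = Inf with p floored at 1e-15. Per-timepoint
  Welch t contrasts follow, Sidak-adjusted (`1 - (1 - p)^m`) with family
  size m = number of timepoints by default; the true post hoc family of the
  original analysis is unstated, so m is configurable.
* **Change from baseline** subtracts each subject's earliest value and
  drops baseline rows, the transform used when groups differ at baseline.
* **Sample size** uses the z-based two-sided formula
  `n = ceil(2 sd^2 (z_{1-a/2} + z_{power})^2 / delta^2)`; with the study's
  spec (reference 100 vs 70, SD 20, alpha 0.05, power 0.80) it gives 7 per
  group, 8 after 10% attrition inflation — the z form, not an iterative t
  solution, because it reproduces the planning numbers of the web
  calculator used for the design.
* **Type-I calibration**: on null cohorts the endpoint Mann-Whitney and the
  diet effect of the mixed ANOVA both reject at 0.05 +/- 0.02 over 1000
  simulations (the Mann-Whitney rate sits slightly below 0.05 because the
  exact test is conservative at discrete attainable levels).

Report assembly (`build_report()`) produces mean +/- SD group summaries,
passes score frequency tables through, and stars comparisons at the
conventional thresholds (p < 0.05/0.01/0.001/0.0001).

# Problem sizes and determinism

Every stochastic component is a pure function of (spec, seed); generators
save and restore the caller's RNG state. The shipped test suite uses: 200
seeds for slope recovery, 100 seeded phantoms per hepatic-renal target (the
full 550 x 650 px canvas), 100 seeds for noisy RI recovery, 1000
simulations for each type-I calibration, and exhaustive enumeration
(<= `choose(16, 8)` assignments) for exact Mann-Whitney checks — sizes
chosen so the whole suite runs in a few minutes on one core while keeping
Monte-Carlo standard errors well inside the asserted tolerances.

# Known limitations

* The phantom and waveform generators are statistical emulators, not
  physical simulators; agreement on them demonstrates estimator
  correctness, not imaging fidelity.
* The mixed-model path is complete-case; mice lost to attrition contribute
  nothing after dropout rather than being handled by likelihood-based
  missing-data machinery.
* Automated steatosis grading from texture is out of scope by design:
  visual and histological grades enter as operator data.
* Diastolic function and strain are not implemented (not part of the study
  design this package mirrors).
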