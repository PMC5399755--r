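---
title: "Methods: quantifying the osmotic-upshift response in the droplet assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the osmotic-upshift response in the droplet assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmodrop)
```

## The measurement problem

Adult *C. elegans* placed singly in 6 µl droplets swim with continuous
sinusoidal body thrashes, occasionally interrupted by reorienting
maneuvers — reversals and large Ω-shaped body bends, pooled here as
*turns*. An upshift in solution osmolarity (e.g. from the ~150 mOsm of
cultivation medium to 400 mOsm) gradually raises the turning rate over
about five minutes; the rate in the 5th minute is the primary
behavioral statistic. osmodrop implements the computations that turn
raw recordings into that statistic, the accompanying measurements
(thrash frequency, body-area shrinkage, solution osmolarity,
GCaMP ΔF/F), and the statistical layer used to compare groups.

No raw recordings are publicly deposited, so the package ships a
synthetic-data generator that emulates each kind of raw input with
known ground truth. Every downstream stage is tested by parameter
recovery against that truth.

## Turn detection by equivalent-ellipse eccentricity

Each video frame is thresholded (Otsu by default), the largest
8-connected component is kept, holes are filled (a self-overlapping
omega posture encloses background), and the mask's equivalent ellipse
is computed from its normalized central second moments: with
eigenvalues $\lambda_1 \ge \lambda_2$ of
$C = \frac{1}{\mu_{00}}\big(\begin{smallmatrix}\mu_{20} & \mu_{11}\\
\mu_{11} & \mu_{02}\end{smallmatrix}\big)$, the semi-axes are
$a = 2\sqrt{\lambda_1}$, $b = 2\sqrt{\lambda_2}$ and the eccentricity
$e = \sqrt{1 - \lambda_2/\lambda_1}$. This convention matches the mass
distribution of a solid ellipse: a disk has $e = 0$ and an elongated
rod $e \to 1$. An extended swimming worm sits near $e \approx 0.95$;
curled turn postures fall far below. Moments are computed on the
binary mask by default; grayscale-weighted moments are an option
(`weighted = TRUE`) since nothing in the assay's definition fixes the
choice, and on well-segmented frames the two differ negligibly.

A turn is called when $e$ drops below a threshold: maximal
sub-threshold runs lasting at least `min_duration_s` become events,
and events separated by less than `merge_gap_s` merge. Defaults, all
config-exposed, were fixed once by calibration on the simulator:

* `threshold = 0.85` — roughly midway between the swim band
  (~0.95–0.97 at default rendering) and turn postures (~0.43 omega,
  ~0.55 reversal fold). `calibrate_threshold()` re-derives it from
  annotated (or ground-truth) intervals by maximizing event-level F1
  over a 0.01-step grid, ties broken toward the higher threshold,
  mirroring how the original threshold was fixed against manually
  scored turns.
* `min_duration_s = 0.2` — two frames at the 10 Hz camera rate,
  rejecting single-frame segmentation glitches.
* `merge_gap_s = 0.1` — one frame interval. Merging exists to bridge
  gaps created by flagged (lost-worm) frames inside one turn; a larger
  gap would start fusing *distinct* turns, which at 33 turns/min
  biases counts down by ~10–15%. Raising it is appropriate for real
  data whose eccentricity is noisier than the simulator's.

Lost-worm frames are flagged, never dropped: they are excluded from
run membership but do not interrupt a run or the merge logic, so a
turn spanning a brief tracking failure is still one event. Events are
assigned to half-open minute bins $[60(m-1), 60m)$ by their start
time; minute 5 is $[240, 300)$ s.

## The swim-video generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline is validated.

The worm midline is a fixed-arclength curve with curvature
$\kappa(s,t) = A \sin(2\pi f t - k s)$ while swimming
($f$ = 2 Hz thrash frequency, 1.5 wavelengths along the body,
$A L = 9$ rad by default, chosen to produce the C-shaped posture of
swimming worms while keeping swim eccentricity well above the turn
band). During a turn episode the curvature is replaced wholesale by a
high uniform curvature: a 306° arc for `"omega"`, or a 270° fold
concentrated in the middle third for `"reversal-bend"` — both depress
eccentricity far below threshold, matching the operational definition
that pools reversals with big bends. The body is the midline dilated
to the half-width; linear dimensions scale by
$\sqrt{\texttt{area\_scale}}$ so rendered area scales by
`area_scale`. Curvature switches sharply at episode boundaries, so one
above-threshold frame suffices to separate consecutive episodes.

Turn episodes are drawn from an inhomogeneous Poisson process. Naive
merging of overlapping arrivals would bias episode counts below the
nominal rate (at rate $\lambda$ with dead time $d$ a Poisson process
yields episode starts at rate $\lambda' e^{-\lambda' d}$), so the
generator solves $x e^{-x} = \lambda(t)\,d$ pointwise (principal
branch) and thins at the inflated intensity $x/d$, with
$d = \texttt{turn\_duration\_s} + 1/\texttt{frame\_rate\_hz}$ — the
posture duration plus the one-frame camera resolution below which two
turns are indistinguishable. Logged episode counts are therefore
unbiased at `turn_rate_fn`, which the test suite verifies to
Monte-Carlo precision. Parameters where $\lambda_{\max} d \ge 1/e$
(episodes that cannot be resolved) are rejected as unphysical.

The ramp profile
$\lambda(t) = \lambda_0 + (\lambda_5 - \lambda_0)\min(t/t_{\mathrm{ramp}}, 1)$
reaches its plateau at $t_{\mathrm{ramp}} = 240$ s by default, so the
expected rate throughout the minute-5 bin equals $\lambda_5$ — the
published 5th-minute rates are bin expectations, and a ramp still
rising through the bin would undershoot them by construction.

What the generator does *not* emulate: translation of the worm within
the droplet (the worm undulates in place; shape metrics are
translation-invariant so nothing downstream changes), hydrodynamics,
photometric texture, multi-worm occlusion, and gradual postural
drift. Passing recovery tests therefore demonstrates correctness of
the measurement pipeline under the stated phenomenology, not
robustness to every imaging artifact of real videos; the
`calibrate_threshold()` path and the config knobs are the intended
adaptation route for real data.

Worm appearance (contrast, noise) is not described anywhere
authoritative; defaults (foreground 200, background 30, noise SD 8 on
an 8-bit scale) were chosen once for reliable Otsu segmentability and
are config-exposed.

## Thrash counting

The bend signal splits the mask at the centroid along the major axis
and reports the signed angle between the two halves' principal axes;
sign continuity is maintained by keeping the axis direction consistent
across frames (no head/tail identity is attempted — it is irrelevant
to counting alternations). A Schmitt trigger with a ±0.2 rad band
counts one thrash per sign alternation exceeding the band, i.e. two
per undulation cycle, one "curving toward either side" each. The band
makes the count immune to sub-band noise; counts are binned per minute
like turns. Whether thrashes were counted manually or automatically in
the original assay is unstated; the automated path operationalizes the
same definition, and a manual-annotation import is trivially the
`turns_per_minute()`-style binning of annotated crossing times.

## Dehydration measurement

Body area is the foreground pixel count of the segmented still image
times the squared pixel size. The generator renders pre/post pairs
with linear dimensions scaled by $\sqrt{\text{area ratio}}$ and
randomized pose; recovery tests require the measured post/pre ratio to
track the generating parameter within rasterization tolerance.
`blind_rename()` reproduces the anti-bias procedure: a seeded random
permutation assigns condition-agnostic names, the sealed mapping is
written separately, and `unblind()` inverts it after measurement.

## Calcium ΔF/F with bleach correction

A trace is corrected for photobleaching by fitting
$\hat F(t) = a e^{-b t}$ ($b \ge 0$) and dividing it out,
renormalized to $t = 0$:
$F_{\mathrm{corr}}(t) = F(t)\hat F(0)/\hat F(t)$. Ratiometric
correction preserves fractional responses, which is what ΔF/F
measures; subtractive correction would distort them. Then
$\Delta F/F(t) = (F_{\mathrm{corr}}(t) - F_{\mathrm{base}})/
F_{\mathrm{base}} \times 100\%$ with $F_{\mathrm{base}}$ the mean over
the first 60 s, reported over the first 120 s, and the per-animal
response summary is the mean ΔF/F over $[60, 120)$ s.

Two numerical choices deserve note. First, the decay model carries no
additive offset: over a 60–120 s window with weak bleaching the
three-parameter model $a e^{-bt} + c$ is ill-conditioned ($a$, $b$,
$c$ are nearly collinear when $bT \ll 1$) and fails outright in
standard nonlinear least squares; the two-parameter form is the
ImageJ-style exponential bleach model and is exactly the generator's
truth. Second, the decay is fitted on the *baseline window only* and
extrapolated (`fit_window = "baseline"`), because a whole-trace fit
partially absorbs a genuine step response into the decay estimate —
measured on the simulator, a 20% step survives baseline-window
correction at 20.0% but collapses to ~6% under whole-trace fitting
with the non-negativity constraint. Whole-trace fitting remains
available (`fit_window = "full"`) for traces known to contain no
response. The fit starts from the closed-form log-linear estimate and
is refined by Levenberg–Marquardt; a non-convergent fit falls back to
a linear detrend with a warning, never silently. The imaging sample
rate is nowhere stated; 10 Hz is the configurable default, and nothing
downstream depends on it beyond window membership.

Normality of response samples is checked with both a
Kolmogorov–Smirnov test against a normal with the sample's mean and SD
and the Shapiro–Wilk test; group separation uses the pooled-variance
Student's t test.

## Group statistics

Summaries are mean ± SEM (n) per genotype-by-condition cell, SEM
= SD/√n (undefined for n = 1 and reported as missing). Two-group
comparisons default to the classical pooled-variance Student's t test,
matching the named test; Welch's form is a flag. The summary-statistic
entry point reproduces a t test exactly from published mean/SEM/n
triples — e.g. the droplet-volume check (23.6 ± 0.31 vs 23.2 ± 0.35
µl, n = 8) gives p ≈ 0.41, consistent with the published p = 0.38
computed from unrounded data.

The genotype × osmolarity interaction is tested by two-way
fixed-effects ANOVA with Type II sums of squares: the published cell
sizes are unbalanced and the ANOVA flavor is unstated; Type II is the
standard choice when the interaction is the hypothesis under test, and
it coincides with the sequential decomposition on balanced data (a
property the tests check numerically, alongside an exact brute-force
cell-means oracle). Missing cells raise an error rather than being
imputed. No multiple-testing correction is applied across
candidate-gene screens, mirroring the original analysis; a
Benjamini–Hochberg adjustment can be applied to the returned p values
with `p.adjust` when reanalyzing.

Calibration of both tests (type-I error 0.05 ± 0.015 under
1000-replicate null simulations at the published cell sizes) is part
of the acceptance suite.

## Problem sizes and runtimes

The validation suite scales cohorts to what the statistics require
rather than what the hardware allows: turn-rate recovery runs the two
published control conditions at the published n = 32 with full
five-minute videos at 10 Hz on a 64 px single-droplet crop (about
2–3 ms per frame end to end); dehydration recovery uses the published
7 worms × 3 images at micrograph-like resolution (200 px canvas,
120 px worm); statistical calibration uses 1000 null replicates.
Smaller cohorts appear in unit tests where only determinism or
wiring is under test.

## Known limitations

* Readers accept multi-page TIFF and in-memory arrays; AVI must be
  converted externally.
* The simulator's reversal is rendered as a deep fold. Whether a
  straight-backing reversal (no deep bend) depresses eccentricity
  enough to be detected is an open question of the eccentricity
  definition itself; such events would be missed by any
  eccentricity-threshold detector.
* Eccentricity-based turn calling does not distinguish reversals from
  omega bends — by design, as the assay pools them.
* The mean-±-SEM statistics layer models the minute-5 snapshot only;
  minute-by-minute curves are reported but not modeled
  longitudinally.
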