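---
title: "BacFlow: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BacFlow: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

BacFlow analyzes brightfield time-lapse movies of rod-shaped bacteria
colonizing a surface under laminar flow, and ships an agent-based
simulator that produces ground-truthed synthetic movies of the same
process. This vignette explains the models behind both, the estimators,
the parameters that matter, and the choices made where the design was
genuinely open.

## 1. The scene model

`simulateTruth()` advances a per-cell state at every rendered frame.

**Arrivals.** Bacteria bind as a Poisson process
(`arrival_rate_per_min`, default 3/min) during the injection window only
(default 20 min, the study protocol's two injection phases combined);
`n_initial_cells` may seed cells at t = 0. Placement uses volume
exclusion (minimum separation 1.5× the mean initial length): a bacterium
cannot bind on top of one already there.

**Growth and division.** The population growth-rate schedule GR(t) is a
Gompertz sigmoid (default `y0 = 0.01`, `A = 0.025` µm/min, `k = 0.05`
/min, `t_i = 60` min): surface binding resets single-cell growth to a low
value, and after a lag the population transitions into biofilm-phase
growth at roughly 2–3× the initial rate. A cell elongates at GR(t) for
the first two thirds of its cycle and then accelerates in proportion to
its length — linear early, near-exponential close to division. Division
occurs at `division_length_um` (4.5 µm), splitting 0.5 ±
`division_asymmetry`. Daughters anchor at the division septum and
elongate **outward**, so siblings push apart as a microcolony chain
grows; a 0.8 µm septum cleft separates them at birth, matching the
visible constriction-and-slip seen in brightfield at division. Each
newborn daughter is washed away with probability
`daughter_detach_prob`.

**Detachment.** A cell's surface residence time is drawn at binding from
an exponential with rate ln2 / `detach_halflife_min`. We treat the
characteristic binding time T~1/2~ as a half-life (rate ln2/T~1/2~)
rather than a mean residence time — the two readings differ by ln 2 — and
use the same convention in the fitter, so simulator and estimator are
self-consistent. The event log stores the continuous times, so residence
statistics are exact rather than frame-quantized.

**Orientation.** Each cell carries a median axis angle that relaxes
exponentially from flow-aligned (≈0°) toward flow-normal (90°) at
`realign_rate_per_min` (default 0.012/min, putting most of the
realignment within a 3-h experiment), modeling progressive fimbrial
engagement. On top of that, the instantaneous axis wiggles as a
mean-reverting Ornstein–Uhlenbeck angle with stationary sd
`wiggle_amplitude_deg` (3°) and correlation time `wiggle_relax_time_s`
(5 s). The rigid-body rotation is centered on a pivot at signed position
`pivot_offset_frac` × L along the axis: 0 gives symmetric rocking about
the center (distributed fimbriae-like contacts), a negative offset gives
an upstream twisting pivot (single membrane-patch contact). The wiggle
update uses the exact OU transition, so statistics are frame-rate
independent.

**Rendering.** `renderMovie()` draws each bound cell as a projected
spherocylinder (width `cell_width_um` = 1 µm) darker than the background
(background 0.75, midline attenuation 0.45), multiplies by a quadratic
uneven-illumination field, applies Gaussian optical blur
(`blur_sigma_px`, optionally modulated over the movie to emulate focus
drift), adds Gaussian noise (`noise_sd` = 0.01 on the [0, 1] intensity
scale), and can sprinkle small (~0.5 µm) round spots at
`nanoparticle_rate_per_min` to emulate peptide-aggregate confounders.
The default pixel size is 0.2 µm/px — coarser than the 63× water-immersion
optics it emulates — chosen so that validation movies render in seconds;
all gate defaults are calibrated at this scale.

What the generator does **not** emulate: phase-contrast halos,
cell-to-cell hydrodynamic coupling, nutrient depletion, colony buckling
in the third dimension, and motile unbound cells sweeping through the
field (the frame-averaging step exists to remove those in real data, and
is exercised on synthetic data only via its arithmetic). Passing tests
therefore demonstrate correctness of the estimators under a faithful but
idealized image-formation model, not robustness to every artifact of
real footage.

## 2. Segmentation

The mask chain follows the standard brightfield recipe: illumination
correction, offset subtraction, two median-filter passes,
marker-controlled watershed, shape/size gates.

`correctIllumination()` fits a quadratic surface to the background by
iteratively reweighted least squares (pixels far darker than the surface
— the cells — are excluded and the fit repeated), divides it out and
subtracts the residual background level, leaving background ≈ 0 and
cells as positive attenuation magnitudes.

`segmentFrame()` subtracts the user-set `intensity_offset` (default
0.22, half the rendered cell amplitude, so the threshold contour tracks
the half-maximum boundary), median-filters twice (radius 1; for radius 1
a vectorized 3×3 selection-network median is used for speed), and
watersheds. The watershed **elevation is the filtered attenuation
image**, not the distance transform of the mask: two cells touching
side-by-side merge into one solid mask whose distance transform has a
single ridge, but their contact line remains measurably *less dark* than
the cell interiors, and that seam is exactly where the watershed line
falls. The h-maxima tolerance (`watershed_tolerance` = 0.08 intensity
units) is set above the interior plateau wobble and below the seam
depth. End-on contacts whose junction is as dark as the cells themselves
cannot be split by any elevation; in practice dividing cells separate
via the septum cleft before this matters.

Gates: area 1–15 µm², aspect ratio ≥ 1.4, solidity ≥ 0.85. The width
used in the aspect gate is area/length, which is insensitive to the
small axis-direction errors that inflate the minor-axis extent of short
newborn daughters; with it, 2-µm newborns measure aspect ≈ 1.9–2.0 while
round objects measure ≈ 1.3. Round nanoparticles are primarily removed
by the area gate. All gates are exposed in `segmentationParams()`.

**Length estimator.** Footprint extent along the major axis is quantized
at the pixel scale; with slow growth (0.1 µm per ±5-min window at 0.2
µm/px) most regression windows then see no change at all and the median
population GR collapses toward zero. BacFlow instead integrates the
corrected attenuation over the footprint **dilated by 2 px** — the
corrected background averages zero and blur preserves integrals, so the
sum varies smoothly with sub-pixel motion and rotation — and divides by
the plateau of the axial line-density profile (pixel mass linearly
shared between adjacent axial bins), adding the spherocylinder cap
correction W(1 − π/4) from inverting the capsule area
A = (L − W)W + πW²/4. On static synthetic rods this yields a mean
absolute length error of ≈ 0.07 µm (0.36 px) with ≤ 0.05 µm orientation
dependence, and it removes the systematic growth-rate biases that the
extent estimator produces. Orientation comes from intensity-weighted
second moments, folded to [0°, 90°] for reporting (a rod's axis is
direction-free) with the signed representative in (−90°, 90°] retained
for motion analysis.

## 3. Tracking

Frame-to-frame stitching is greedy by footprint overlap (ties broken by
overlap area, then minimal length change), accepting links whose length
changed < 25 %. At 0.1 fps effective rate, bound cells barely move, so
overlap is near-unambiguous and a global assignment would add cost
without benefit. A footprint mapping onto two unclaimed footprints whose
lengths sum to the mother's (within the same 25 %) closes the mother as
divided and opens two children carrying her id. An unmatched trajectory
is held for `gap_tolerance_min` (1 min) and resumed if an observation
reappears within one cell length with length within 15 % ("unaltered
appearance"); both thresholds are exposed. Trajectories end at division,
detachment (closed before the movie end) or censoring.

`filterForGrowth()` drops trajectories shorter than 10 min and marks the
first and last 5 min of the survivors ineligible for growth estimation
(these edges are noise-prone); the observations are retained for
counting.

## 4. Growth kinetics

Momentaneous GR is the OLS slope of length over ±5 min around each
eligible point (≥ 3 points required). Per-trajectory means are pooled in
20-min bins; bin medians and quartiles are the population boxplot data.
`fitGompertz()` fits `y0 + (A − y0) exp(−exp(−k(t − t_i)))` by
Levenberg–Marquardt from a 5 × 5 multi-start grid (t_i over the time-span
quantiles, k over a decade), keeping the lowest RSS; an explicit
baseline y0 is kept because the post-binding initial GR is distinctly
nonzero. Flat data (range below 2 % of the level) are flagged degenerate
and refuse to report a transition time. With 8–9 bins and realistic
noise, y0, A and t_i are precise (few percent) while k is intrinsically
poorly identified — only ~3 bins lie on the rising limb — so k estimates
should be read as order-of-magnitude; the transition time, which is the
quantity used downstream, does not suffer from this.

`duplicationTime()` implements T₂(t) = (2/3) · L(t_end)/GR(t) with
t_end = the last populated bin center. `summarizeReplicates()` defines
an experiment's initial (final) GR as the median of per-cell mean GRs
over bins strictly before (after) its transition time, reports
mean ± SE across experiments per condition, and compares conditions with
Welch's two-sample t-test on the per-experiment values (n = number of
experiments, not cells — the conservative unit of replication).

## 5. Binding kinetics

`buildColonizationCurve()` counts gated objects per averaged frame and
annotates the binding / plateau / exponential phases by slope changes of
the smoothed curve. `fitBindingTime()` models the post-transition count
as a net growth–release exponential,
N(t) = N₀ exp(∫ₜ₀ᵗ [ln2/T₂(s) − ln2/T~1/2~] ds), fitted on log N with
weights ∝ N (variance-stabilizing for Poisson counts). The division
contribution is supplied either as the constant end-of-experiment T₂ or
as a time-varying T₂(t) function (config flag); the residual slope is
the detachment rate. A fitted detachment rate ≤ 0 reports T~1/2~ = ∞ (no
resolvable detachment); detachment-dominated, decaying curves are fitted
by the same path. This algebraic form is a reconstruction consistent
with the constraint that the observed net time constant combines the
division rate and the release rate, with the release convention
ln2/T~1/2~ matching the simulator.

## 6. Motion analysis

`computeMotionWindow()` works on 2-min windows at the original frame
rate (≈ 240 samples at 2 fps; windows with < 50 % of the expected frames
are rejected). Axis angles are canonicalized to (−90°, 90°], the median
axis M is the median centroid plus the circular median (angle-doubled)
axis angle, and ∂θ is the signed deviation from M unwrapped modulo 180°
so small wiggles never flip sign across the ±90° seam.

`wiggleProfile()` evaluates, per frame and per position l along the
axis, the lateral separation of the point at l from M. The classical
pure-rotation expression l·sin(∂θ) is reported
(`sep_std_rot_um`), but the default profile **includes the lateral
centroid offset**: a pivot off the center manifests as correlated
translation + rotation, and only the translation-inclusive separation
(c⊥ + l·sin ∂θ ≈ (l − p)·∂θ) has its variance minimum at the pivot —
the pure-rotation form always dips at the center and cannot localize p.
The pivot estimate is the quadratically interpolated argmin over 21
positions. Classification: rocking if |p̂| ≤ 0.15 L and the two pole
amplitudes agree within 1.5×, twisting otherwise, undetermined (flagged)
when there is no measurable wiggle; these thresholds are our
calibration of a qualitative distinction. Positions l are signed from
the cell center, consistent with rocking being symmetric about the
center.

## 7. Near-wall hydrodynamics

`nearWallSpeed()` evaluates the analytic Fourier-series solution for
pressure-driven laminar flow in a square duct at a point above the
midpoint of one wall, normalized by the series-integrated volumetric
rate; terms are added until the relative change is < 10⁻⁶ (≈ 300 terms).
At the study geometry (0.8 × 0.8 mm, 100 µL/min) it gives 31.2 µm/s at
1 µm — the parallel-plate formula 6Q/(wh²)·z gives 19.5 µm/s and is a
strict lower bound there, since the square duct concentrates shear at
the wall midpoints. Linearity in Q is exact; linearity in distance holds
to < 1 % out to 5 µm.

## 8. Numerical choices and degenerate inputs

* Frame counts are floor(duration · fps + 10⁻⁹) to avoid losing frames
  to floating-point (1/30 fps × 30 s is not exactly 1).
* All randomness flows from the single config seed; the renderer draws
  from an offset stream so truth tables are identical whether or not a
  movie is rendered. Identical (config, seed) gives bit-identical truth
  tables, stacks and pipeline outputs.
* Degenerate inputs are first-class: constant frames warn and return
  zeros; empty foregrounds return empty observation tables; flat
  Gompertz data are flagged; zero wiggle flags an undetermined binding
  mode; a single replicate reports SE as missing; t-tests on essentially
  constant groups report NA rather than aborting a summary.
* Division detection needs both daughters gated in the division frame;
  a daughter that flickers out is recovered by gap bridging, at the cost
  of a parentless trajectory (counted as a link error in validation).

## 9. Problem sizes used in the tests

Validation movies are deliberately small so the whole suite runs on a
laptop: 300–400 px frames at 0.2 µm/px, 8–15 cells, 25–150 min of
simulated time, with full-rate (2 fps) rendering only for the 2-min
motion windows. The end-to-end replicate comparison runs ten 150-min
scenes (five control, five with the growth schedule scaled by 0.75),
rendering a frame every 30 s and averaging 4 frames per observation —
the study's 20:1 frame averaging at desk scale; averaging over the
angular wiggle also dithers out the last sub-pixel length ripple, which
matters when the per-window growth signal is only ~0.1 µm. These sizes
are the package's validation choices, not limits of the methods.

## 10. Known limitations

* The renderer's image-formation model is simple (multiplicative
  illumination, Gaussian blur and noise); camera shot noise,
  phase-contrast halos and debris are not modeled.
* Watershed splitting needs a brightness seam; end-on contacts as dark
  as the cells themselves are not separable.
* The tracker is greedy and local; it is not meant for motile cells or
  for dense colonies past the first few generations, where chains
  collide and occlusion begins (the simulator likewise does not model
  colony buckling).
* k from Gompertz fits of 8–9 bins is weakly identified (see §4).
* The pivot estimator assumes a rigid cell; flexible tethers would
  smear the variance minimum.
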