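# BacFlow

Label-free, single-cell analysis of bacterial surface colonization under
flow, from brightfield time-lapse microscopy.

When rod-shaped bacteria such as *E. coli* bind to the floor of a
microfluidic channel, their subsequent behavior — a post-binding lag with
reset growth, a transition into biofilm-phase growth, division, detachment,
and a slow realignment from flow-aligned to flow-normal as adhesive
fimbriae engage — can all be read from ordinary brightfield movies, with no
fluorescent labels. BacFlow implements that entire readout as a tested R
pipeline, together with an agent-based synthetic-scene generator that
renders ground-truthed brightfield movies for validation. It is intended
for groups running flow-chamber live-cell assays of early biofilm
formation or surface antimicrobial efficacy, and for method developers who
need a ground-truthed benchmark for rod-cell segmentation and tracking.

## The quantities it computes

* **Single-cell growth rate.** Cell length `L` is the per-cell metabolic
  readout; the momentaneous growth rate GR is the OLS slope of `L(t)` over
  ±5 min. Per-cell mean GRs are pooled in 20-min bins, and the population
  curves GR(t) and L(t) are fitted with the Gompertz sigmoid
  `y(t) = y0 + (A − y0) exp(−exp(−k (t − t_i)))`, whose inflection `t_i`
  is the **transition time** from the adaptation lag to biofilm growth.
* **Duplication time** `T2(t) = (2/3) · L(t_end) / GR(t)`.
* **Mean binding time** `T1/2`: after division starts at `t0 ≈ t_i`, the
  count of bound cells follows
  `N(t) = N0 · exp( ∫ [ln2/T2(s) − ln2/T1/2] ds )`;
  fitting log N (Poisson weights) and removing the known division term
  leaves the detachment rate `ln2/T1/2`.
* **Binding geometry.** Over 2-min full-frame-rate windows, the median
  binding angle `θ_M` versus the flow, its spread STD(θ), and the wiggle
  profile — the standard deviation of the instantaneous lateral separation
  `l × sin(∂θ)` at each position `l` along the cell axis — whose minimum
  localizes the adhesion pivot and classifies cells as **rocking**
  (centered pivot, distributed fimbrial contacts) or **twisting** (offset
  pivot, single contact patch).
* **Near-wall flow speed** in a square duct from the analytic laminar
  Fourier-series profile (`nearWallSpeed()`), to translate pump rates into
  the shear environment cells experience.

## Worked example

Simulate a 150-min colonization experiment (Poisson arrivals during a
10-min injection, Gompertz GR schedule rising 0.010 → 0.035 µm/min with a
transition at 60 min, division at 4.5 µm, detachment half-life 600 min),
render it as a brightfield movie, and run the full analysis chain:

```r
library(BacFlow)

cfg <- sceneConfig(duration_min = 150, frame_rate_fps = 1/30,
                   image_shape = c(300L, 300L), injection_window_min = 10,
                   arrival_rate_per_min = 0.5, n_initial_cells = 12L,
                   initial_length_um = c(2.8, 0.3),
                   gr_schedule = gompertzParams(0.01, 0.035, 0.08, 60),
                   division_length_um = 4.5, detach_halflife_min = 600,
                   daughter_detach_prob = 0.1, seed = 42)
cfg
#> SceneConfig: 150 min at 0.03333 fps, 300 x 300 px (0.2 um/px), seed 42

simulateTruth(cfg)
#> TruthTable: 64 cells, 5783 bound-cell frame records

bundle <- runPipeline(cfg,
                      seg_params = segmentationParams(averaging_block = 4))
bundle$gr_fit
#> GompertzFit: y0=0.008993, A=0.03647, k=0.07031 /min, t_i=59.84 min (rsd 0.000828)
bundle$trajectories
#> TrajectorySet: 40 trajectories (censored=15, detached=8, divided=17)
t(bundle$summary[, c("initial_gr_um_min", "final_gr_um_min",
                     "transition_min", "T2_end_min", "N_final")])
#> initial_gr_um_min  0.0089
#> final_gr_um_min    0.0353
#> transition_min    59.8428
#> T2_end_min        76.3263
#> N_final           28.0000
```

The recovered initial and final growth rates (0.0089 and 0.0353 µm/min)
and the transition time (59.8 min) match the configured schedule
(0.010 / 0.035 µm/min, 60 min); 17 divisions were linked into
mother–daughter lineages, and 28 cells remain bound in the last frame.
`renderReport(bundle, "report/")` writes the standard figure panels
(colonization curve with fit, GR/length boxplots per bin, Gompertz
overlay, orientation scatter, wiggle-profile bars).

And the near-wall speed for the imaging channel:

```r
nearWallSpeed(100, 0.8, 1)   # 100 uL/min, 0.8 mm square duct, 1 um up
#> [1] 31.2
```

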