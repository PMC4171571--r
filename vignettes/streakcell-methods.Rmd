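---
title: "Models and methods behind streakcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind streakcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streakcell)
```

# Scope

streakcell quantifies single-cell behaviour during the differentiation
of mouse embryonic stem cells towards a primitive-streak-like fate:
trajectory motility statistics, nuclear-intensity image analysis,
reporter-positive population fractions, and kinetic qPCR
quantification. Because the underlying experiments (multi-day
live-imaging movies, confocal stacks, cytometry runs) are not shipped
with the package, a first-class synthetic-data module generates data
with the same statistical structure under named condition presets; all
analysis code is exercised end-to-end against it.

This vignette records the models, their assumptions, the tunable
parameters, the numerical conventions, and the design decisions taken
where the underlying experimental description left the choice open.

# The cell-behaviour model

## Persistent random walk with an EMT switch

Each simulated cell moves with heading $\theta$ and speed $s(t)$:

$$\theta_{j+1} = \theta_j + \eta_j,\qquad \eta_j \sim
\mathcal{N}(0, \sigma_\theta^2)$$

$$s(t) = s_{\mathrm{base}} \cdot m_{\mathrm{EMT}}(t)\cdot
\bigl(1 + \beta\, g(t)/g_{\mathrm{peak}}\bigr)$$

* $s_{\mathrm{base}}$ is log-normal across cells (median 16 μm/h,
  geometric sd 1.5 by default): speeds are positive and right-skewed,
  as frame-to-frame speed distributions of adherent cells are.
* $m_{\mathrm{EMT}}$ ramps linearly from 1 to `emt_speed_mult` over
  `mult_ramp` hours after the cell's EMT onset (normal across cells),
  capturing the observation that cells accelerate only after leaving
  the epithelial colony. Under a `motility_blocked` preset (EMT
  inhibition, e.g. the cyclosporine-A condition) the ramp never starts.
* $\beta$ couples the reporter pulse to speed
  (`expr_speed_coupling`); it encodes that reporter-high cells move
  faster, and is the mechanism the association statistics are expected
  to recover.
* Headings receive wrapped-normal increments per frame
  ($\sigma_\theta = 0.6$ rad by default), giving persistent motion
  whose turning-angle distribution is strongly peaked at zero. Speed
  and heading are independent given the pulse.

Positions reflect at a circular confinement boundary whose radius
switches from `confine_radius_pre` (40 μm, the colony) to
`confine_radius_post` (65 μm) at EMT onset, and tracks are
right-censored at the first frame that leaves the square field of view
(half-width 250 μm); the out-of-view position is discarded, so every
retained sample lies inside the field, mirroring how manual tracking
stops when a cell leaves the frame.

The reporter pulse is piecewise linear — a rise over `expr_rise` (6 h),
a plateau, and a symmetric fall ending `dur` hours after onset — with a
log-normal per-cell peak. Only population-level expression waves are
observable in the data this emulates; single-cell pulse shape and
amplitude statistics are modelling choices, and the piecewise-linear
form is the simplest shape with a finite rise time. Onset times are
normal, truncated at 12 h (no expression before the epithelial state
is left); durations are normal and truncated positive, so durations
shorter than twice the rise give triangular pulses.

## Condition presets and calibration

Presets are generative parameter bundles per experimental condition
(`default_presets()`): dual stimulation `act_chi` (36% of cells
express, onset N(38, 8) h, duration N(50, 10) h, EMT N(30, 8) h,
speed-up ×3.0, β = 0.6), `chi` (30%, shorter pulse, ×2.6), `act`
(12%, late onset N(60, 10) h, ×2.2), the `lb` pluripotency control
(no expression, no EMT), `csa` and `bcat_null` (motility blocked,
rare/absent expression) and `bra_null` (EMT without the fast-motion
program: ×1.4, β = 0).

These values were calibrated once, forward from the model, so that the
full pipeline applied to preset data reproduces the headline numbers
the package's acceptance checks encode (positive-fraction plateaus of
~33/25/10%, a ~60 μm/h population velocity peak, a ~3 h MSD plateau
onset), and were then frozen. Two calibration notes:

* The expression-window parameters follow from the target fractions
  analytically: the expected positive fraction at time $t$ is
  `p_express` × P(onset < t < onset + duration) (plus a 0.1%
  gate-leak), which fixes `p_express` given the onset/duration laws.
* The post-EMT confinement radius sets the ensemble-MSD plateau. With
  speeds of ~50–60 μm/h and a ~0.9 h persistence time, a 65-μm
  reflecting disk places the intersection of the initial MSD slope
  with the fitted asymptote at ~3 h. Larger radii (100 μm and above)
  move the plateau onset past 10 h, and field-of-view censoring alone
  cannot restore it: censoring depresses the asymptote and the early
  slope together.

## What the generator does and does not emulate

Emulated: heterogeneous per-cell expression and EMT timing; the
condition ordering of expression waves; speed/expression coupling;
persistence; confinement; censoring by the field of view; replicate
structure and viability flags in event tables; correlated
reporter/protein channels in images; triplicate qPCR noise.

Not emulated: cell division and lineage, cell–cell adhesion and
collisions, 3-D motion, colony geometry (confinement is a disk),
photobleaching, background gradients and uneven illumination, and
plateau-phase qPCR chemistry. Tests passing on synthetic data
therefore validate the statistics and their implementation — not the
biological fidelity of any of these excluded features; on real data,
segmentation and gating choices would need to be re-examined against
controls.

# Motility statistics

* **Instant velocity** is the frame-to-frame displacement divided by
  Δt (1/6 h). Timestamps are pair midpoints, and binning windows are
  half-open `[lo, hi)`, so abutting bins partition samples exactly.
  Tracks with gaps are split into contiguous segments first; no
  velocity, MSD pair or turning angle ever spans a gap.
* **MSD** is time-averaged with overlapping pairs. The experimental
  description leaves open whether time- or ensemble-averaging was
  used; overlapping time-averaging is the standard single-particle
  choice, and a brute-force all-pairs oracle in the test suite pins
  the exact semantics. The ensemble curve averages per-cell MSDs with
  equal weight per cell (the per-cell curves are the primary object;
  weighting by pair counts would let long tracks dominate), dropping a
  cell at any lag where it contributes fewer than 6 pairs.
* **Effective diffusivity** is slope/4 of an OLS line (free intercept)
  over the default window (0, 2] h — inside the initial regime where
  the MSD grows linearly before confinement bends it — with the slope
  standard error reported. The window is configurable; 10-h windows
  partition experiment time for the diffusivity timecourse, and empty
  windows yield missing values rather than errors.
* **Turning angles** are signed (counter-clockwise positive, x-right /
  y-up), in (−π, π], with exact reversals mapped to +π by convention.
  Steps shorter than `min_step` (default 1 μm, about the localization
  jitter of a nucleus centroid between frames) are skipped and the
  chain restarts, so near-stationary jitter does not flood the angle
  distribution. Isotropy is tested by a one-sample KS test against
  Uniform(−π, π], pooled per condition (whether the published test
  pooled cells or tested per cell is unstated; pooling is the more
  powerful default and the per-track function remains available).
* **MSD plateau onset** fits $\mathrm{MSD}(\tau) = L(1 -
  e^{-\tau/\tau_c})$ by Levenberg–Marquardt (initialized at the
  empirical 63% crossing) and intersects the initial-slope line
  (OLS over lags ≤ 0.5 h) with the asymptote $L$.

# Image analysis

Segmentation is Gaussian smoothing (σ = 2 px), a global Otsu threshold,
8-connected component labeling, and removal of components below 50 px²
— chosen because the synthetic nuclei (and the well-separated nuclei
this emulates) do not touch; no watershed splitting is attempted, and
touching-nuclei separation is out of scope. A constant image produces
zero labels with a warning (Otsu is undefined), not an error. Setting
σ = 0 disables smoothing, which makes segmentation and extraction
pixel-exact on noiseless fixtures — the test suite uses this to verify
exactness of counts, centroids and means.

Pixel coordinates are 0-based with origin top-left and y increasing
downwards; centroids and ROI geometry follow this convention. No
background subtraction or flat-field correction is applied.

Per-nucleus means feed distribution timecourses (50 bins on a shared
per-channel range so histograms are comparable across timepoints) and
pairwise Pearson correlation timecourses with an optional baseline
condition; zero-variance channels are flagged as undefined rather than
erroring. The concordance channel model generates reporter = protein +
noise with a noise-to-signal sd ratio of 0.822, so the designed
correlation is $1/\sqrt{1 + 0.822^2} \approx 0.773$; the end-to-end
imaging pipeline is expected to recover slightly less due to pixel
noise and mask dilution at nucleus boundaries.

The track-ROI readout averages pixels whose centres lie within a 10-μm
radius of the track position, flags edge-clipped ROIs, and returns a
missing value when the ROI lies fully outside the image.

# Population fractions

Events flagged non-viable are removed first. The positivity gate is
the 99.9th percentile (empirical type-7 quantile) of a negative
control: the gate rule of the emulated experiment is unpublished, so a
declared quantile convention is used and exposed as a parameter;
re-gating the control against its own threshold leaves ~0.1%
positives by construction. Fractions are reported in percent, per
replicate, then summarized as mean ± SD across replicates (three by
default). Condition testing is a per-timepoint one-way ANOVA followed
by Tukey HSD against the time-matched control with flags at 0.05 and
0.01; no across-time multiplicity correction is applied, mirroring the
per-timepoint design.

# Kinetic qPCR

The MAK2 recurrence $D_n = D_{n-1} + k\ln(1 + D_{n-1}/k)$ doubles the
product in early cycles and decelerates smoothly; fluorescence is
$F_n = F_b + s D_n$. Because $(cD_0, ck, s/c)$ produce identical
curves, $s$ is held fixed (default 1) and $D_0$ is reported in
fluorescence-equivalent units. The adaptation of MAK2 used in the
emulated experiments is unpublished; this module implements the
published recurrence with declared fitting conventions:

* fit window: cycles up to the last one before fluorescence exceeds
  baseline + 85% of the total rise (the plateau phase is not modelled
  by MAK2), with the baseline estimated from the first five cycles;
* optimization: Levenberg–Marquardt on $(\log D_0, \log k, F_b)$ with
  a multi-start over seven log-spaced $D_0$ initializations spanning
  $10^{-8}$–$10^{-2}$ of the curve rise; the best residual wins, ties
  break towards the smaller $D_0$;
* degenerate inputs: a curve whose rise is below five times the
  baseline noise raises a no-amplification error; fewer than eight
  cycles is an error.

Replicates are averaged (mean ± sd/√n, a flagged undefined SE for
singletons) after fitting, then normalized to the reference gene with
first-order error propagation
$\mathrm{SE}_{\mathrm{ratio}} = r\sqrt{(\mathrm{SE}_t/\mu_t)^2 +
(\mathrm{SE}_r/\mu_r)^2}$. The declared order is fit → average →
normalize.

# Reproducibility and problem sizes

Every simulation consumes a master seed from which per-cell and
per-replicate sub-seeds are derived by a fixed counter scheme, so the
first $k$ cells of a large run reproduce a $k$-cell run exactly and
identical inputs give bit-identical outputs. `run_pipeline()` rereads
its own written tables between stages, so a cached single-stage rerun
is byte-identical to the full run, and its manifest (config hash,
seed, versions, row counts) suffices to reproduce any number.

The shipped reproduction sizes (`reproduce_targets()`): event tables
of 10,000 events × 3 replicates per condition; 100–200 tracks of
60–96 h at 6 frames/h; 500 nuclei across five image tiles; these sizes
put the Monte-Carlo error of each recovered quantity well inside its
check tolerance while keeping a full run around ten seconds on one
core. Test-suite simulations use smaller sizes chosen the same way
(e.g. 500 Brownian tracks for 10% diffusivity recovery, 400 replicates
for test-calibration checks).

# Known limitations

* The simulator omits division, adhesion, collisions and colony
  geometry; recovered motility parameters describe the model, and
  agreement with any particular experiment depends on features the
  model excludes.
* Ensemble MSD mixes pre- and post-EMT epochs of each track; the
  plateau-onset time is therefore a population summary, not a per-cell
  confinement scale.
* Segmentation assumes well-separated nuclei; touching nuclei merge.
* MAK2 parameters $D_0$ and $k$ are strongly correlated in the fit;
  $D_0$ is well determined only when early exponential cycles carry
  signal above the noise floor, which is why the no-amplification
  guard exists.
* The KS test treats angles as linear data on (−π, π]; it is used as
  an isotropy screen, not as a circular-statistics inference.
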