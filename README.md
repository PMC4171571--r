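# streakcell

Quantitative analysis of single-cell behaviour during the
differentiation of mouse embryonic stem cells (mESCs) towards a
primitive-streak-like fate. When mESCs are exposed to activin A (Act, a
nodal agonist) and/or CHIR99021 (Chi, a GSK3 inhibitor that mimics
Wnt/β-catenin signalling), a transient wave of brachyury (Bra)
expression sweeps the population; cells undergo an
epithelial-to-mesenchymal transition (EMT), accelerate, and move as
persistent random walkers. This package provides the statistics used to
quantify that behaviour, together with a synthetic-data generator that
reproduces the statistical structure of each data modality so every
stage is testable without any microscope or cytometer.

It is aimed at quantitative cell biologists analysing live-imaging
track tables, imaging-cytometry stacks, flow-cytometry-like event
tables and kinetic qPCR curves.

## What it computes

**Trajectory motility** (`instant_velocities`, `bin_velocities_by_start`,
`cumulative_distance`, `msd_curve`, `ensemble_msd`,
`fit_effective_diffusivity`, `diffusivity_timecourse`, `turning_angles`,
`ks_uniformity_test`, `expression_motility_association`,
`msd_plateau_onset`):

- instant velocity `v_i = |r_{i+1} − r_i| / Δt` (μm/h) at the 10-min
  frame interval (Δt = 1/6 h);
- time-averaged mean-squared displacement with overlapping pairs,
  `MSD(kΔt) = ⟨|r(t_i + kΔt) − r(t_i)|²⟩_i`, per cell and averaged over
  cells with equal weight;
- effective diffusivity `D_eff = slope/4` from an ordinary
  least-squares line fitted to the 2-D MSD over its initial linear
  window, including over consecutive 10-h intervals;
- signed turning angles between consecutive displacement vectors and a
  one-sample Kolmogorov–Smirnov test against Uniform(−π, π] — a
  distribution peaked at 0 means persistent motion;
- the association between reporter level and motion (Pearson r of g vs
  v; distance ratio for cells above vs below the mean peak reporter
  level, with a bootstrap CI).

**Quantitative image analysis** (`segment_nuclei`,
`extract_nuclear_intensities`, `quantify_scene`,
`intensity_distribution_timecourse`, `pairwise_correlation_timecourse`,
`track_roi_intensity`): nuclei are segmented on the Hoechst channel
(Gaussian smoothing, Otsu threshold, 8-connected components,
small-object removal), per-nucleus mean intensities are extracted per
channel, and distribution/correlation timecourses are assembled; a
10-μm circular ROI readout follows a track through a time-lapse stack.

**Population fractions** (`gate_events`, `threshold_from_control`,
`fraction_positive_timecourse`, `compare_to_control`): viability
gating, a negative-control quantile gate (default 99.9th percentile),
percent-positive timecourses with replicate mean ± SD, and per-timepoint
one-way ANOVA with Tukey HSD versus the time-matched control.

**Kinetic qPCR** (`mak2_params`, `mak2_forward`, `fit_mak2`,
`average_replicates`, `normalize_to_reference`, `quantify_qpcr`): the
MAK2 mechanistic amplification model
`D_n = D_{n−1} + k·ln(1 + D_{n−1}/k)`, `F_n = Fb + s·D_n`, fitted per
reaction by Levenberg–Marquardt with multi-start initialization to
estimate the initial target amount `D0`, followed by technical-replicate
averaging and reference-gene (GAPDH) normalization with propagated
standard errors.

**Synthetic data** (`condition_preset`, `default_presets`,
`simulate_trajectories`, `simulate_event_population`,
`synthesize_image_series`, `simulate_qpcr_replicates`): confined
persistent random walks with EMT-dependent speed-up, reporter pulses
coupled to speed, field-of-view censoring; cytometry-like event tables;
multi-channel nuclear image stacks with a correlated-channel
"concordance" model; noisy MAK2 amplification curves. Named presets
(`act_chi`, `chi`, `act`, `lb`, `csa`, `bcat_null`, `bra_null`) encode
the conditions of the study the package models.

## Worked example

```r
library(streakcell)
preset <- get_preset("act_chi")
tracks <- simulate_trajectories(preset, n_cells = 100, duration = 96, seed = 1)

v    <- instant_velocities(tracks)
bins <- bin_velocities_by_start(v, bin_edges = seq(0, 96, 2))
max(bins$summary$mean_v, na.rm = TRUE)   # 60.7 um/h

fit_effective_diffusivity(ensemble_msd(tracks, max_lag = 12),
                          fit_window = c(0, 2))
#> Effective diffusivity (interval all): D_eff = 383.5 um^2/h
#>   slope 1534 +/- 45.1 um^2/h over (0, 2] h (12 points)

ks_uniformity_test(turning_angles(tracks))
#> KS test vs Uniform(-pi, pi]: D = 0.2696, p = 0 (n = 57181 angles)

expression_motility_association(tracks, seed = 1)
#> Reporter/motility association over 100 cells (57600 samples)
#>   Pearson r(g, v)          : 0.341
#>   distance ratio (hi/lo g) : 1.34 [1.13, 1.58]

ev   <- simulate_event_population(preset, c(24, 48, 72, 96), 10000, 3, seed = 1)
ctl  <- simulate_event_population(get_preset("lb"), c(24, 48, 72, 96), 10000, 3, seed = 1)
gate <- threshold_from_control(gate_events(ctl)$intensity_afu)
fraction_positive_timecourse(gate_events(ev), gate)
#> Reporter-positive fractions (gate 302.4 AFU)
#>   condition timepoint_h n_replicates mean_pct  sd_pct
#> 1   act_chi          24            3     1.40 0.12802
#> 2   act_chi          48            3    31.50 0.37198
#> 3   act_chi          72            3    31.70 0.00911
#> 4   act_chi          96            3     9.39 0.19125
```

Reading the output: under dual stimulation the population-average
instant velocity peaks near 60 μm/h; the MSD is initially linear with
an effective diffusivity of a few hundred μm²/h; turning angles are
decisively non-uniform (persistent motion); reporter level and speed
are positively coupled, and cells with above-average reporter cover
~1.3× more ground; the reporter-positive fraction rises to a sustained
~32% plateau across 48–72 h before falling.

A thin CLI over the same functions is installed at
`inst/cli/streakcell` with subcommands `simulate`, `motility`, `qia`,
`population`, `qpcr`, `run` and `reproduce-targets`.

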