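---
title: "Classifying mRNA particle motion from single-particle trajectories"
author: "motrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying mRNA particle motion from single-particle trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motrack)
```

## The problem

Single mRNA molecules tagged with MS2 stem-loops and a fluorescent coat
protein can be followed in live neurites, giving per-particle trajectories
$(x(t), y(t))$ sampled at a fixed frame interval (here 0.6 s for 90 s, i.e.
up to 151 frames per track). The biological question is how transport is
partitioned between active, motor-driven runs, free diffusion and confinement
— and how that partition changes between genotypes. `motrack` implements the
track-level analysis: time-averaged mean squared displacement (MSD), an
anomalous-diffusion fit, exponent-based motion classes, displacement-based
directionality classes, and replicate-level aggregation with Welch's t test
between groups. A simulator with known ground truth stands in for the raw
movies, which are not part of the package's scope (particle detection and
linking are assumed done by the tracking software).

## The model

For one uniformly sampled track the time-averaged MSD at lag $\tau = k\,
\Delta t$ is

$$\mathrm{MSD}(\tau) \;=\; \big\langle\, [x(t+\tau)-x(t)]^2 +
[y(t+\tau)-y(t)]^2 \,\big\rangle_t,$$

the average running over all overlapping origins $t$ (a sliding origin is the
standard estimator in single-particle tracking and maximizes the number of
pairs on ~150-frame tracks; the alternative of independent, non-overlapping
pairs discards most of the data). Lags are restricted to the first 25% of the
trajectory duration, $k \le \lfloor 0.25\,(N-1) \rfloor$, where long-lag
averages become too noisy to use; at least the first lag is always kept so
very short tracks still produce a curve.

The curve is then fitted with the anomalous diffusion model

$$\mathrm{MSD}(\tau) = A\,\tau^{\alpha} + B,$$

where $A$ reflects the particle's mobility, $B$ is the residual MSD (the
offset produced by, e.g., localization error), and the exponent $\alpha$
indicates the motion type: $\alpha \approx 2$ for ballistic, motor-driven
transport, $\alpha \approx 1$ for free diffusion, $\alpha \ll 1$ for
confinement. Tracks are classified with strict inequalities:
**active** if $\alpha > 1.5$, **diffusive** if $0.9 < \alpha < 1.1$,
**confined** if $\alpha < 0.5$. Exponents in the gaps $[0.5, 0.9]$ and
$[1.1, 1.5]$, exact boundary values, and non-converged fits are reported as
**ambiguous** — they are counted as their own fraction rather than
redistributed or silently dropped, because dropping them would bias the class
fractions.

Independently, two displacement features are computed from the axial
coordinate only: the net displacement $ND = |x_{\mathrm{last}} -
x_{\mathrm{first}}|$ and the lateral maximal displacement
$LMD = \max_t |x(t) - x_{\mathrm{first}}|$. Tracks are **directed** if
$ND > 5\ \mu m$, **stationary** if $ND < 5\ \mu m$ and $LMD < 1\ \mu m$, and
**oscillatory** otherwise. Magnitudes are used rather than signed
differences: a 6-µm retrograde run is as directed as an anterograde one, and
the tracks carry no soma-orientation information that would make signs
meaningful. Exact boundary values ($ND = 5$, $LMD = 1$) are undefined by the
strict inequalities and fall to the oscillatory branch by evaluation order.

Only tracks with strictly more than 20 frames enter the analysis.

## Numerical choices in the fit

The fit is unweighted nonlinear least squares in linear space with bounds
$A \ge 0$, $0 \le \alpha \le 3$, $B \ge 0$ (the upper bound keeps the
ballistic $\alpha = 2$ interior). Weighted or log-log fitting would be
defensible alternatives; linear-space unweighted is the simplest reading of
"fitted with an anomalous diffusion model" and is what the tests freeze.

Optimization uses bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) from
two starting points: the canonical start $\alpha = 1$,
$A = \mathrm{MSD}(\tau_1)/\tau_1$, $B = 0$, and a second start taken from a
log–log regression of MSD on lag. The second start matters: for strongly
superdiffusive curves the canonical start can converge to a local minimum
pinned at the $\alpha = 3$ bound, while the log–log start lands near the
global solution; the lower-residual fit wins. Curves with fewer than three
lags or an essentially flat profile (range below $10^{-12}$ of scale) are
flagged non-converged, because $A$ and $\alpha$ are jointly non-identifiable
when $A \approx 0$ — a flat curve is equally well fit by any exponent.
Non-converged tracks are classified ambiguous.

## What the simulator emulates

`simulate_track()` reproduces the acquisition geometry — frames every 0.6 s
for 90 s, hence $\lfloor 90/0.6 \rfloor + 1 = 151$ frames — and adds i.i.d.
Gaussian localization noise (default $\sigma = 0.02\ \mu m$ per coordinate, a
typical sub-pixel localization error for this kind of imaging) *after* the
physical path. Three ground-truth regimes are available:

* **ballistic** — constant velocity along the axial (x) axis; default test
  velocity 0.3 µm/s gives a 27 µm run over 90 s, comfortably directed;
* **brownian** — independent Gaussian increments of variance $2 D \Delta t$
  per coordinate; $D = 0.1\ \mu m^2/s$ is a typical mRNP diffusivity;
* **confined** — the same increments inside a reflecting disc. Reflection is
  implemented as radial folding ($r \to 2R - r$, repeated until inside),
  which preserves the angle and is adequate while steps are not much larger
  than the corral. A 0.2 µm corral with $D = 0.1\ \mu m^2/s$ mixes within a
  single frame, producing the flat, plateaued MSD the confined class
  describes.

Randomness is reproducible per track: each track's stream is seeded from a
hash of (run seed, track id), so simulating a subset or reordering tracks
never changes any individual trajectory.

The simulator deliberately omits several features of real data: no
photobleaching or blinking, no tracking gaps or mislinkages, no z-dimension
(the acquisition maximum-projects three z-slices), no heterogeneity within a
track (no switching between motion states), and no drift. Passing the
recovery tests therefore shows that the estimator chain is correct for clean
realizations of the three idealized regimes — not that real, state-switching
mRNP tracks are classified with the same accuracy.

## Aggregation and statistics

The statistical unit is the culture replicate, never the pooled track: class
fractions (motion family: active/diffusive/confined/ambiguous;
directionality family: directed/stationary/oscillatory) are computed within
each (group, replicate) cell, then summarised per group as mean ± SD across
replicates, mirroring a "means ± SD of three to five cultures" design.
Two groups are compared per class with Welch's unequal-variance two-sided
t test on the per-replicate fractions; with fewer than two replicates in a
group the comparison is skipped with a warning. No multiple-testing
correction is applied by default (tests are reported per panel); `holm =
TRUE` applies a Holm adjustment within each classifier family.

## Worked example

```{r example}
acq <- acq_config(seed = 7)           # 0.6 s interval, 90 s, sigma 0.02 um
tracks <- c(
  simulate_tracks(motion_spec("ballistic", velocity = 0.3), acq, 20),
  simulate_tracks(motion_spec("brownian", D = 0.1), acq, 20),
  simulate_tracks(motion_spec("confined", D = 0.1, corral_radius = 0.2),
                  acq, 20, id_prefix = "confined"))
meta <- data.frame(track_id = names(tracks),
                   replicate_id = rep(c("r1", "r2"), 30),
                   group = "sim")
run <- run_pipeline(tracks_to_table(tracks), metadata = meta)
run
table(run$records$true_mode, run$records$motion_class)
```

A single fit can be inspected directly:

```{r single-fit, fig.width = 5, fig.height = 4}
fit <- fit_anomalous(compute_msd(tracks[["ballistic_1"]]))
summary(fit)
plot(fit)
```

## Problem sizes used in the checks

The package's recovery checks use 200 tracks per diffusive regime at the
acquisition's native 151 frames — enough that the ensemble mean exponent is
stable to a few hundredths — and 100 random tracks of up to 50 frames for the
exact brute-force MSD comparison. The end-to-end mixture uses 40 tracks per
mode per replicate across two replicates.

## Known limitations

* Classification operates per track on the whole track; particles that
  switch motion state mid-track get a single, blended label.
* Single-track exponent estimates are noisy ($\mathrm{sd}(\hat\alpha)
  \approx 0.2$–0.3 for Brownian tracks at this length), so many genuinely
  diffusive tracks land in the ambiguous gaps; ensemble means are the
  reliable readout.
* The directionality features use the axial coordinate as given; for raw
  tracks whose frame is not aligned with the neurite, apply
  `project_axial()` first.
* Welch's t test on 3–5 replicate fractions has limited power; the p-values
  are descriptive, as in the original design.
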