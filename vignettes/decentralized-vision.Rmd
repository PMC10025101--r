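---
title: "Modeling decentralized vision and object taxis in sea urchins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling decentralized vision and object taxis in sea urchins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific problem

Sea urchins detect and approach visual objects without eyes or a brain.
The working hypothesis implemented here is that shielded photoreceptor
cells (PRCs) at the bases of the tube feet, arranged along the five
ambulacra, act together as a very coarse compound eye, and that the
animal's internal nervous system — five radial nerves (RNs) joined by the
oral nerve ring (ONR) around the mouth — integrates their signals into a
directional decision. `echinovision` implements this processing chain as a
firing-rate network and couples it to a probabilistic movement model, so
that simulated arena experiments can be compared with behavioral data and
used to design new stimuli.

The pipeline is: stimulus profile on the arena wall → animal-centred
projection → PRC activation → RN inhibition → eONR disinhibition →
population-vector readout → (static or step-by-step) taxis → cohort-level
circular statistics.

## Stimuli and their reconstruction

Stimuli are one-dimensional angular ink profiles on the unit-radius arena
wall, vertically homogeneous by assumption; intensity is `1 - ink`. Six
families are provided (`make_stimulus()`): a uniform control, a black bar,
a difference of Gaussians (DoG), a flanked bar, and Haar, Morlet and first
Hermitian wavelet profiles. `phi_stim` is the angular width of the target
region. For the DoG, `phi_stim` is interpreted as the span of the dark
region bounded by the two flanking white intensity maxima (equivalently
their peak-to-peak separation). This reading makes the detection mechanism
geometrically transparent: the two white maxima of a 69° DoG are ~69°
apart, nearly the 72° ambulacral spacing, so both can strike ambulacra
simultaneously, whereas a 29° DoG can illuminate only one.

Every non-control pattern is *isoluminant*: its circular mean intensity
equals the background grey (the control's level), enforced exactly by
construction — the bar's surround level is solved analytically, the DoG
uses a surround/centre width ratio of 2 with relative surround amplitude
1/2 (zero integral), and the other families are mean-centred numerically on
a fine grid. Detection therefore requires resolving spatial structure, not
comparing radiance.

The exact amplitudes of the original printed patterns are not part of the
published model description, so the stimulus forms here are a
reconstruction under the stated constraints (dark target, flanking lighter
maxima, isoluminance). The one genuinely free scalar is the background
grey. It matters because the RN sigmoid (location parameter `x_c = -0.6`
on the normalized input) gives the network a limited dynamic range in mean
light level: far below it the RNs saturate near their spontaneous rate and
transmit almost nothing. The default `background_grey = 0.464` is the
calibration of this dial: it is fixed once at the level at which the model
reproduces the published behavioral detection pattern — the 69° DoG
detected (`v_max > theta_p`) while the 40° bar, 29° DoG and control are
not, with cohort statistics of the published magnitude. All stimulus
constructors expose the background level, so the sensitivity of any result
to this calibration can be examined directly.

## Photoreceptor layer

Each of the five ambulacra carries `n_prc = 100` PRC groups spread
uniformly over `center ± delta` (`delta = 15°`). A group's angular
sensitivity is a rectified cosine,
`f = [(cos(phi - center) - a)/(1 - a)]+` with `a = 2cos(delta_rho/2) - 1`,
a tail-free approximation of a truncated Gaussian tuning curve whose FWHM
is exactly the acceptance angle `delta_rho` (30° by default). The response
to an extended stimulus is the sensitivity-weighted mean of the perceived
intensity (midpoint quadrature on a 0.5° grid; the integration error is
orders of magnitude below the solver tolerance, verified against a 0.01°
oracle in the tests). The pointwise maximum over one ambulacrum's curves
has FWHM `delta_rho + 2 delta = 60°`, the effective acceptance angle that
behavioral estimates constrain. A supplementary-style variant draws
per-cell acceptance angles from a configurable uniform range
(`delta_rho_range`), seeded for reproducibility; uniform is the minimal
assumption since the original distribution is unspecified.

From off-centre positions the wall pattern is projected by exact ray
casting (`perceived_profile()`): the target region widens as the animal
approaches it, which is what lets the dynamic model change course near the
wall. There is no distance attenuation and no occlusion by the animal's
own body, since only angular structure is modeled.

## Network and solver

RN and eONR groups are sigmoidal rate units
`S(x) = 1/(1 + exp(-2 beta (x - x_c)))`, with the input normalized by the
magnitude of the unit's maximal feedforward drive, so that full
photoreceptor activation corresponds to `x = -1`. The sign structure is
double inhibition: light excites PRCs, PRCs inhibit RNs (which otherwise
sit near their spontaneous rate `S(0) ≈ 0.973`), RNs effectively inhibit
eONR cells (via implicit inhibitory interneurons folded into negative
weights), and eONR cells excite their ring neighbours. Light therefore
*disinhibits* the eONR groups facing it.

Connectivity is local and configurable: each RN group receives its three
index-aligned PRC groups (truncated at ambulacrum edges) plus adjacent RN
neighbours; each of the 500 eONR groups receives the three angularly
nearest RN groups of its nearest ambulacrum plus its two ring neighbours.
Afferent weights are scaled by the inverse square root of the per-unit
fan-in (an `inverse_linear` option exists; because of the input
normalization only the lateral-to-feedforward ratio is observable).
Ambulacrum assignment and nearest-neighbour selection are computed in
ambulacrum-relative coordinates with rounded distances so that the wiring
is exactly five-fold symmetric — without this, floating-point tie-breaking
at the inter-ambulacral midpoints breaks the rotation equivariance of the
readout at the 1e-2 level.

The steady state is found by synchronous iteration from zero activity
(`solve_steady_state()`), stopping when the maximum per-unit rate change
falls below 1e-5, with a cap of 600 iterations; at the default operating
point convergence takes ~10-15 iterations and the fixed point is
independent of initialization (checked from both zero and saturated
starts). Batched inputs (all 360 orientations at once) share the solver;
converged columns are frozen so batched and single solves agree exactly.

## Readout and movement

Preferred directions are measured operationally: a 2° white bar on black is
presented at every integer probe direction and each eONR group is assigned
the circular argmax of its response (`compute_preferred_directions()`).
Preferences track angular position within ambulacra and accrue a mismatch
of up to ~21° in the gaps, resetting at the next ambulacrum — an emergent
consequence of nearest-ambulacrum wiring. The population vector is the
rate-weighted sum of preferred-direction unit vectors; lengths above
`theta_p = 5` signal detection.

The static movement model draws a final wall bearing per subject: uniform
if the centre-of-arena population vector is at or below threshold,
otherwise wrapped-Gaussian around the vector's bearing with s.d.
`min(1/(|v| - theta_p), 1)` radians (read in radians, the printed
constraint being "≤ 1"). The dynamic model takes steps of `0.1` arena
radii until radius `0.75`, re-solving the network at each position with
the orientation fixed; each heading is drawn from a mixture: with
probability `q = 1/(1 + exp(-10(|v| - theta_p)))` a wrapped Gaussian
around the vector bearing with s.d. `max(10°/(|v| - theta_p), 1e-5°)`
(values above 360° give a uniform draw), otherwise a wrapped Gaussian of
s.d. 10° around the previous heading. The first step's "previous heading"
is uniform, and the mixture applies from the first step. For subthreshold
vectors the raw `sigma_1` is negative and the floor applies, which is
inconsequential since `q` is then essentially zero.

Cohorts (`run_cohort()`) use one master seed expanded into per-replicate
streams (`seed + 1000003 * replicate`, mod 2^31 - 1), so replicates are
independent and restartable and all outputs are bit-reproducible. Static
cohorts sample initial orientations from the 360 integer degrees of the
precomputed population-vector table. Replicate experiments are summarised
by the circular mean vector and by Rayleigh and V tests, implemented from
the standard series and normal approximations and cross-checked against
Monte-Carlo uniform nulls in the test suite.

## Parameter sweeps

`vmax_heatmap()` maps the maximal population-vector length across
orientations over the `(delta_rho, delta)` plane (defaults 16 × 16 over
15-90° × 5-20°), rebuilding the photoreceptor layer *and* re-probing
preferred directions at every grid point, since the map depends on both
parameters; `delta ≥ 36°` cells (overlapping ambulacra) are masked.
`detection_contours()` extracts the `v_max = theta_p` and `v_max = 4`
level sets and the `delta_rho + 2 delta = 60°` reference line.
`randomized_acceptance_sweep()` repeats the analysis with per-cell
acceptance angles drawn uniformly around each scanned value; a zero-width
range reduces exactly to the fixed sweep. Qualitatively, bar detection
improves with larger acceptance angles while DoG and Morlet detection
improve with smaller ones, asserted in the tests as endpoint trends along
the default `delta` row.

## What the simulations do and do not show

The synthetic cohorts emulate the arena protocol: subjects start at the
centre with uniformly random orientations, and the model measures the
concentration of final wall positions toward the stimulus. They do not
emulate several features of real experiments: animals that rotate while
moving, variable speed, spine shadowing, vertical light gradients, or
luminance calibration of printed patterns — all outside the model's scope.
Passing tests therefore show that the implemented network reproduces the
published detection pattern and cohort statistics under the reconstructed
stimulus dialect, not that the biological parameters are uniquely
identified; the sweep module exists precisely to show how conclusions move
with the optics parameters.

## Numerical choices and problem sizes

Angular grids use 0.5° for wall and perceived profiles (720 points; the 2°
probe bar spans 4 samples) and 1° for probe and orientation scans. The
solver tolerance (1e-5) and iteration cap (600) follow the reference
description; convergence failures are flagged, and the dynamic model
proceeds with the last iterate under a logged warning rather than
aborting. Exact ties in the probe argmax are resolved by the circular mean
of the tied set. The test suite runs the full-size model (5 × 100 PRC/RN
groups, 500 eONR groups) for all deterministic checks; stochastic
cross-checks (static-versus-dynamic cohort agreement, Monte-Carlo nulls)
use scaled cohorts of 20-30 subjects and a few replicates, sizes at which
the comparisons are already well powered, while the acceptance script runs
the full 100-replicate × 100-subject protocol.

## Known limitations

The stimulus dialect is a reconstruction; only its constraints, not its
exact coefficients, are published (the background-grey calibration above
is the visible consequence). The analytic route to preferred directions is
not implemented — the probe procedure is normative here. Inhibitory ONR
interneurons are not explicit units. Gaussian PRC placement, latitudinal
structure, looming responses, and surgical-lesion simulations are out of
scope.
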