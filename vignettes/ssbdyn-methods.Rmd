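---
title: "Models and methods behind ssbdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssbdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbdyn)
```

`ssbdyn` analyses single-molecule and bulk measurements of single-stranded
DNA-binding proteins (SSBs) on ssDNA. SSB tetramers occupy ssDNA in two
interconverting modes — a *binding* mode occluding roughly 30 nt per
tetramer and a *wrapping* mode occluding roughly 60 nt, in which the DNA
bends around the tetramer — and the balance between the modes governs how
strongly the protein compacts the DNA, how it dissociates when the salt
concentration changes, and how much of a long template it covers. The
package implements the quantitative models for each assay in that workflow
and, alongside them, synthetic-data generators so that every fitting stage
can be exercised and validated end to end without instrument data.

## Polymer mechanics: the eFJC model

Force spectroscopy on surface-tethered ssDNA yields force–distance curves.
These are described by the extensible freely jointed chain (eFJC),

$$L(F) = L_c\left[\coth\!\left(\frac{2 F L_p}{k_B T}\right)
      - \frac{k_B T}{2 F L_p}\right]\left(1 + \frac{F}{S}\right),$$

with contour length $L_c$ (µm), persistence length $L_p$ (nm), stretch
modulus $S$ (pN; fixed at the standard ssDNA value 800 pN) and thermal
energy $k_BT$ = 4.11 pN·nm at 25 °C. Protein binding shortens $L_c$
(compaction) and raises $L_p$ (stiffening), so the two fitted parameters
summarise the mechanical consequence of coating.

Design choices worth knowing:

* **Residuals live in distance.** Force is the controlled variable in an
  acoustic force ramp, so the fit minimises deviations of predicted
  extension from measured distance (`fit_efjc()`), with bounded
  Levenberg–Marquardt (`minpack.lm`), bounds $L_c \in (0, 100]$ µm,
  $L_p \in (0, 100]$ nm, and starting values $L_c$ = max observed distance,
  $L_p$ = 1 nm. The bounds keep the Langevin argument well conditioned.
* **Force windows are clipped, never extrapolated.** Bare ssDNA is fitted
  over 0.1–15 pN; coated ssDNA only over 0.1–2 pN, where the curve deviates
  from the bare one. If the requested window extends beyond the data the
  effective window is reported (`window_clipped`).
* **Retraction curves are the default input** for parameter estimation,
  because molecules can stick non-specifically to the surface at very low
  force during extension.
* The Langevin bracket $\coth x - 1/x$ switches to its series
  $x/3 - x^3/45$ below $x = 10^{-4}$; the model is evaluated accurately
  from the $F \to 0$ limit to the rigid-backbone limit.

Energies come from trapezoid integration of the force difference between
two curves interpolated onto the union of their distance grids restricted
to the overlap (`curve_energy()`): coated-versus-bare retraction curves
give the work stored by protein binding, extension-versus-retraction of one
ramp gives the hysteresis (non-equilibrium unbinding work), and the
difference between two successive ramps' hysteresis (`ddE()`) measures the
protein lost between ramps. Energies are reported in pN·nm and in $k_BT$
($k_B$ = 1.380649×10⁻² pN·nm/K, so 4.1 pN·nm ≈ 1 $k_BT$ at 25 °C). The
trapezoid scheme agrees with adaptive quadrature to better than 0.5% on
smooth curves with ≥ 200 samples (regression-tested).

## Compaction kinetics

In TIRF movies of flow-stretched, protein-coated ssDNA, adding salt
triggers compaction. Per molecule, the apparent length is normalised by its
pre-salt baseline $L_0$ (mean of the first three frames) and shifted to
salt-aligned time $t^* = t - t_0^*$; the ensemble mean is fitted with

$$L(t^*)/L_0 = \beta\, e^{-k_c t^*} + L_f/L_0,$$

where $\beta$ is the compaction amplitude, $k_c$ the compaction rate, and
$L_f$ the final length; at $t^* = 0$ the model passes through 1, so
$\beta + L_f/L_0 \approx 1$.

The onset time $t_0^*$ is detected per molecule with a threshold rule: the
first frame at which the centred 3-frame rolling mean of $L/L_0$ — and the
raw series, which stops a single noise outlier from depressing three
consecutive rolling means on its own — drops below $1 - \delta$ (default
$\delta = 0.05$) and stays below for three frames. Two refinements matter
quantitatively:

* the decay curve still passes through full length at the *true* onset, so
  the trigger frame is systematically one frame late; `detect_salt_onset()`
  therefore returns the preceding frame and then refines it by fitting an
  exponential to the post-onset decay and solving for its $L/L_0 = 1$
  crossing. Without this refinement the one-frame misalignment propagates
  into an amplitude underestimate of about $\beta(1 - e^{-k_c \Delta t})$
  (≈ 0.06 under the defaults), which is larger than the amplitude's own
  statistical error;
* the common $t^*$ grid (spacing = the movies' frame interval) is anchored
  so that $t^* = 0$ is an exact grid point, making "the ensemble starts at
  1" a measurable statement.

This rule is a parameterised stand-in: criteria for locating salt arrival
are acquisition-specific, and $\delta$ and the persistence
length of the test should be tuned to the noise of real movies. The
ensemble fit is performed on the mean curve, unweighted; per-point molecule
counts are reported so a weighted variant can be assessed. Percent
compaction compares $L_0$ against an uncoated flow-stretched reference
(`percent_compaction()`).

## Two-state dissociation kinetics

Intensity traces of coated molecules after a salt jump show a fast decay
followed by a slow one — not a single exponential. The model is the
irreversible chain wrapped → bound → free,

$$\frac{dw}{dt} = -k_{-w} w, \qquad
  \frac{db}{dt} = k_{-w} w - k_{-b} b,$$

with dissociation only from the bound state. `two_state_solution()` is the
closed form; the degenerate case $k_{-w} = k_{-b}$ is reached continuously
through an `expm1` formulation (validated against an independent RK4
integration to 10⁻⁸ relative error, including the diagonal). Intensities
convert to monomer counts by dividing by the single-fluorophore intensity
(counts stay real-valued).

Fitting (`fit_two_state()`) uses bounded least squares from multiple
starting points: the total count is a biexponential whose least-squares
surface develops degenerate local minima when the two rates are within a
factor of ~3 of each other, and a single start can converge to a swapped
ridge solution. When a converged fit has $k_{-w} > k_{-b}$ it is
re-expressed through the equivalent biexponential with $k_{-b} > k_{-w}$
(the convention that matches the observed fast-then-slow phenomenology)
whenever both initial pools remain non-negative. Fits whose rate ratio lies
in [0.5, 2] carry an identifiability note, and a single-exponential
sub-model is always fitted for AIC comparison.

Photobleaching multiplies the visible count by $e^{-k_\text{bleach} t}$,
which shifts *both* apparent rates up by exactly $k_\text{bleach}$ — the
synthetic generator reproduces this confound (bleached-but-attached
tetramers stay attached and invisible), and `correct_photobleaching()`
subtracts the independently measured bleaching rate from both rates,
flooring at zero. The generator is a continuous-time Gillespie simulation
(exponential waiting times are exact for the Markov chain; sampling at the
camera interval mimics integration), with four independently bleaching
fluorophores per tetramer and optional incomplete labelling.

Coverage arithmetic (`coverage_model()`, `coverage_fraction()`) turns
monomer counts and mode fractions into occluded nucleotides via the 30 and
60 nt per-tetramer footprints, capped at 1 with an over-saturation warning.

## Two-color competition

With two spectrally separated labels, each ssDNA molecule is classed by
per-channel detection thresholds (default 3× the channel's background SD)
as visible in one channel, both, or neither; molecules dark in both
channels cannot be counted from fluorescence and are excluded from the
percentage base (the exclusion count is reported). Channel cross-talk is
assumed zero. On co-coated molecules, per-channel monomer counts give the
channel-A composition fraction, which is invariant to a common rescaling of
the two single-fluorophore calibrations. Real-time exchange runs are
summarised as per-channel ensemble means with the sign of a fitted linear
slope as the trend statistic.

## Bulk assays

Biolayer-interferometry sensorgrams follow the 1:1 Langmuir model:
association $R(t) = R_\text{eq}(1 - e^{-(k_\text{on} C + k_\text{off})t})$
with $R_\text{eq} = R_\text{max} C/(C + K_d)$, dissociation decaying at
$k_\text{off}$ from the association end point, $K_d =
k_\text{off}/k_\text{on}$. `fit_bli_global()` fits all concentrations and
both phases simultaneously with one shared parameter triple (association
and dissociation share $k_\text{off}$); a single-concentration input is
accepted with an identifiability warning. Baseline drift is not modelled.

Mass-photometry event lists are fitted histogram-free: the single-Gaussian
MLE is the sample mean and SD; for a user-chosen number of components ≥ 2
a Gaussian mixture is fitted by EM (via `mclust`). The component count is
never auto-selected. A zero-variance sample returns the value with the SD
floored at the histogram resolution limit ($\text{bin}/\sqrt{12}$).

## TIRF quantification

`segment_frame()`/`link_frames()` are a deliberately minimal measurement
stand-in, validated only on synthetic images: per-frame background =
median + MAD, threshold at median + 3×MAD, 8-connected components, length =
axis-aligned extent along the flow (column) axis × pixel size (filaments
are flow-straightened, so no skeletonisation), intensity =
background-subtracted pixel sum, anchor = upstream-most pixel. Tethered
molecules have stationary anchors, so tracks link by nearest anchor within
3 px. A frame whose bulk sits far above its darkest pixels (median − 1st
percentile > 10× MAD) defeats the median background estimate and is
refused rather than mis-measured.

## What the generators emulate — and what they do not

Every generator takes an explicit seed (bit-identical reruns are
regression-tested) and emits a ground-truth sidecar; all recovery tests
compare fit output only against that sidecar. The default parameters are
the study conditions of the assays they emulate: eFJC regimes (4.8 µm/1.9
nm bare, 1.3 µm/9.3 nm and 2.5 µm/3.3 nm coated), compaction amplitudes
0.63 and 0.80 with 60-molecule ensembles, 5-s frames and 0.05 normalised
length noise, WT-like (w₀ ≈ 2b₀ ≈ 300 monomers) and mutant-like (b₀ ≈ w₀ ≈
1100) dissociation presets with k₋w three times faster for the mutant,
bleaching at 5.9×10⁻³ s⁻¹, the (0.24, 0.76, 0) equimolar competition mix,
the 0.625–5 nM BLI panel with 300 s/600 s phases, and 67 ± 2 / 60 ± 2 kDa
mass distributions. The compaction rate default (k_c = 0.03 s⁻¹, decay over
one to two minutes of 5-s frames) is a realistic movie timescale chosen
once; the rate criteria are formulated as ratios and relative recovery and
do not depend on its absolute value.

The generators are deliberately idealised: Gaussian/lognormal noise instead
of camera-specific statistics, no stage drift or illumination gradients, no
flow fluctuations, zero channel cross-talk, no optical PSF by default, and
no rebinding or cooperativity in the kinetic scheme. Passing recovery tests
therefore demonstrates the *estimators* are correct and calibrated under
the stated statistical structure — not that real instrument data meet that
structure. Stochastic recovery checks are asserted on the median over a
fixed seed sequence, because single-realisation errors at the stated
ensemble sizes (e.g. ~13% SD for the mutant-preset k₋b from 50 molecules)
exceed the bias being tested.

## Worked example

```{r example, eval = FALSE}
# simulate a WT-like dissociation experiment and recover the rates
sim <- gen_dissociation_gillespie(w0_monomers = 300, b0_monomers = 150,
                                  k_unwrap = 0.004, k_unbind = 0.03,
                                  k_bleach = 5.9e-3, n_molecules = 50,
                                  seed = 1)
fit <- fit_two_state(average_dissoc_traces(sim$traces))
correct_photobleaching(fit, 5.9e-3)

# how much of the template does that protein load occlude?
coverage_fraction(coverage_model(tet_binding = 25, tet_wrapping = 70,
                                 template_nt = 48502))
```

## Known limitations

* The salt-onset criterion is an invented, parameterised stand-in.
* The two-state fit reports — but cannot resolve — near-degenerate rate
  pairs; a global (shared-rate) multi-molecule fit mode is not implemented,
  only per-trace fits with ensemble summaries.
* TIRF segmentation assumes flow-straightened filaments and a flat
  background; it is not a general filament tracer.
* BLI fitting has no drift or mass-transport terms.
* Heterotetramers (mixed-subunit species) are outside the competition
  model.
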