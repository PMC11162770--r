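# ssbdyn

Quantitative analysis of single-stranded DNA-binding protein (SSB)
dynamics on ssDNA, from single-molecule force spectroscopy and TIRF
imaging to bulk binding assays.

SSB tetramers occupy ssDNA in two interconverting modes — a *binding* mode
with a footprint of ~30 nt per tetramer and a *wrapping* mode of ~60 nt in
which the DNA bends around the tetramer. The balance between these modes
determines how strongly a protein variant compacts ssDNA, how fast it
dissociates after a salt jump, and how much of a long template it covers.
`ssbdyn` implements the complete analysis pipeline for experiments that
probe this balance, for researchers analysing (or simulating) such data:

* **Polymer mechanics** — extensible freely jointed chain (eFJC) fitting of
  force–distance curves,
  `L(F) = Lc [coth(2·F·Lp/kBT) − kBT/(2·F·Lp)] (1 + F/S)`, with bounded
  least squares, windowed fits, and energy integration between curves
  (protein-binding work, force-ramp hysteresis, ramp-to-ramp differences).
* **Compaction kinetics** — per-molecule salt-onset detection, L/L0
  normalisation and ensemble alignment on t* = t − t0*, and fitting of
  `L/L0 = β·exp(−kc·t*) + Lf/L0`.
* **Dissociation kinetics** — the two-state wrapped → bound → free scheme
  `dw/dt = −k₋w·w`, `db/dt = k₋w·w − k₋b·b` (dissociation only from the
  bound state), in closed form, with multi-start fitting, photobleaching
  correction by rate subtraction, and footprint-based coverage arithmetic.
* **Two-color competition** — classification of molecules by channel
  (one-channel / co-coated), per-molecule composition from
  single-fluorophore calibration, and real-time exchange summaries.
* **Bulk assays** — global multi-concentration 1:1 Langmuir fits of
  biolayer-interferometry sensorgrams (k_on, k_off, K_d) and Gaussian fits
  of mass-photometry event distributions.
* **TIRF quantification** — minimal segmentation and frame linking of
  flow-stretched filaments (length, background-subtracted intensity).
* **Synthetic data** — seeded generators for every assay, each emitting a
  ground-truth sidecar, so the full pipeline is testable with no external
  data.

## Worked example

Simulate a wild-type-like dissociation experiment (300 wrapped + 150 bound
monomers per molecule, unwrapping at 0.004 /s, unbinding at 0.03 /s,
photobleaching at 0.0059 /s), fit the two-state model to the 50-molecule
ensemble mean, and correct the rates for bleaching:

```r
library(ssbdyn)
sim <- gen_dissociation_gillespie(w0_monomers = 300, b0_monomers = 150,
                                  k_unwrap = 0.004, k_unbind = 0.03,
                                  k_bleach = 5.9e-3, n_molecules = 50,
                                  seed = 1)
fit <- fit_two_state(average_dissoc_traces(sim$traces))
correct_photobleaching(fit, 5.9e-3)
#> Two-state W->B->0 fit: w0 = 257.7, b0 = 191.8, k-w = 0.004083 /s,
#>   k-b = 0.03125 /s (bleach-corrected, k_bleach = 0.0059 /s)
```

Both corrected rates land within a few percent of the generating values.
The fitted pool sizes and the mode footprints then give the fraction of a
48,502-nt template the protein occludes:

```r
coverage_fraction(coverage_model(tet_binding = 25, tet_wrapping = 70,
                                 template_nt = 48502))
#> [1] 0.1020576
```

i.e. ~10% coverage — 25 binding-mode tetramers × 30 nt plus 70
wrapping-mode tetramers × 60 nt over 48,502 nt. A noiseless eFJC
self-consistency check:

```r
p <- efjc_params(Lc = 4.8, Lp = 1.9)         # bare-ssDNA regime
f <- seq(0.1, 15, length.out = 150)
cur <- force_extension_curve(rev(efjc_extension(f, p)), rev(f),
                             phase = "retraction")
fit_efjc(cur)
#> eFJC fit over force window [0.1,15] pN
#> eFJC parameters: Lc = 4.8 um, Lp = 1.9 nm, S = 800 pN, kBT = 4.11 pN nm
#> residual norm: 1.057e-14 um over 150 points
```

End-to-end simulate-then-fit runs for any assay, with JSON/CSV artifacts
and a run log, go through `run_pipeline()` (or the thin CLI at
`inst/cli/ssbdyn.R`):

```r
run_pipeline(list(assay = "bli", seed = 1, out_dir = "runs/bli"))
```

The methods vignette (`vignettes/ssbdyn-methods.Rmd`) documents the models,
their assumptions, the numerical choices, and what the synthetic-data
generators do and do not emulate.

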