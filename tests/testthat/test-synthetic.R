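test_that("all generators are reproducible under a fixed seed", {
  p <- efjc_params(1.3, 9.3)
  bare <- efjc_params(4.8, 1.9)
  runs <- lapply(1:2, function(i) list(
    efjc = gen_efjc_curve(p, noise_sd = 0.02, unbind_fraction = 0.2,
                          params_bare = bare, seed = 42),
    comp = gen_compaction_ensemble(n_molecules = 5, seed = 42),
    diss = gen_dissociation_gillespie(n_molecules = 3, T_total = 200,
                                      k_bleach = 0.006, seed = 42),
    tc = gen_two_color_table(n_molecules = 20, seed = 42),
    bli = gen_bli_traces(noise_sd = 0.01, seed = 42),
    mp = gen_mass_events(n = 100, seed = 42),
    tirf = gen_tirf_movie(data.frame(anchor_row = 5, anchor_col = 3,
                                     length_px = 10, intensity_per_px = 30),
                          n_frames = 2, seed = 42)))
  expect_identical(runs[[1]], runs[[2]])
  # a different seed changes the noise realisation
  alt <- gen_mass_events(n = 100, seed = 43)
  expect_false(identical(alt$masses, runs[[1]]$mp$masses))
})

test_that("generators emit ground-truth sidecars", {
  sim <- gen_compaction_ensemble(n_molecules = 4, seed = 1)
  expect_named(sim, c("traces", "truth"))
  expect_true(all(c("beta", "kc", "L0", "t_onset") %in% names(sim$truth)))
  expect_length(sim$truth$L0, 4)
})

test_that("degenerate generator settings produce the expected limits", {
  # all rates zero: constant dissociation trace
  g0 <- gen_dissociation_gillespie(w0_monomers = 100, b0_monomers = 60,
                                   k_unwrap = 0, k_unbind = 0, k_bleach = 0,
                                   T_total = 100, seed = 1)
  expect_true(all(g0$traces[[1]]$count == 160))
  # bleach-only run decays at k_bleach
  gb <- gen_dissociation_gillespie(w0_monomers = 2000, b0_monomers = 2000,
                                   k_unwrap = 0, k_unbind = 0,
                                   k_bleach = 0.0059, T_total = 600,
                                   n_molecules = 20, seed = 2)
  k_est <- estimate_bleach_rate(average_dissoc_traces(gb$traces))
  expect_lt(abs(k_est / 0.0059 - 1), 0.05)
  # plateau-only compaction (kc = 0) stays flat up to noise
  gc <- gen_compaction_ensemble(n_molecules = 3, beta = 0, kc = 0,
                                Lf_frac = 1, noise_sd = 0, seed = 3)
  for (tr in gc$traces)
    expect_equal(stats::sd(tr$length_um), 0)
  # zero-noise single molecule reproduces the decay law exactly
  g1 <- gen_compaction_ensemble(n_molecules = 1, noise_sd = 0,
                                onset_jitter_frames = 0, seed = 4)
  tr <- g1$traces[[1]]
  ts <- pmax(tr$time_s - g1$truth$t_onset, 0)
  expect_equal(tr$length_um / g1$truth$L0,
               ifelse(tr$time_s <= g1$truth$t_onset, 1,
                      0.8 * exp(-0.03 * ts) + 0.2),
               tolerance = 1e-12)
})

test_that("Gillespie ensemble means converge to the ODE solution", {
  check_within_3se <- function(n_mol, seed) {
    sim <- gen_dissociation_gillespie(
      w0_monomers = 300, b0_monomers = 150, k_unwrap = 0.004,
      k_unbind = 0.03, n_molecules = n_mol, T_total = 600, seed = seed)
    mat <- vapply(sim$traces, `[[`, numeric(121), "count")
    m <- rowMeans(mat)
    se <- apply(mat, 1, stats::sd) / sqrt(n_mol)
    t <- sim$traces[[1]]$time_s
    expected <- two_state_solution(t, sim$truth$w0_monomers,
                                   sim$truth$b0_monomers, 0.004, 0.03)
    list(z_max = max(abs(m - expected) / pmax(se, 1e-9)),
         rmse = sqrt(mean((m - expected)^2)))
  }
  big <- check_within_3se(1000, seed = 17)
  expect_lt(big$z_max, 3)
  # ~1/sqrt(n) convergence: RMSE shrinks substantially from n=100 to n=1000
  small <- check_within_3se(100, seed = 17)
  expect_lt(big$rmse, small$rmse)
})

test_that("two-color generator respects degenerate class probabilities", {
  sim <- gen_two_color_table(n_molecules = 30, class_probs = c(1, 0, 0),
                             seed = 6)
  expect_true(all(sim$records$true_class == "A_only"))
  expect_true(all(sim$records$I_B_au < 3 * sim$truth$background_sd + 60))
})

test_that("flat BLI and zero-variance mass generators behave", {
  sim <- gen_bli_traces(concentrations = 0, noise_sd = 0)
  expect_true(all(sim$traces$response_nm == 0))
  mp <- gen_mass_events(mean_kDa = 67, sd_kDa = 0, n = 50, seed = 2)
  expect_true(all(mp$masses == 67))
})
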