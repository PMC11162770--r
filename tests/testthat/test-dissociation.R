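test_that("intensity converts to real-valued monomer counts", {
  expect_equal(intensity_to_count(5000, 10), 500)
  expect_equal(intensity_to_count(0, 10), 0)
  expect_equal(intensity_to_count(900, 10, labeling_efficiency = 0.9), 100)
  expect_equal(intensity_to_count(5, 10), 0.5)  # not rounded
  expect_error(intensity_to_count(100, 0), "I_single")
  expect_error(intensity_to_count(100, 10, labeling_efficiency = 1.2),
               "labeling_efficiency")
})

test_that("closed-form two-state solution matches RK4 integration", {
  t <- seq(0, 30, by = 0.5)
  rates <- rbind(c(0.004, 0.03), c(0.03, 0.004), c(0.1, 0.1),
                 c(0.1, 0.1 + 1e-10), c(0.2, 0.05), c(0, 0.05))
  for (i in seq_len(nrow(rates))) {
    kw <- rates[i, 1]; kb <- rates[i, 2]
    closed <- two_state_solution(t, 300, 150, kw, kb)
    oracle <- rk4_two_state(t, 300, 150, kw, kb, dt = 0.01)
    expect_lt(max(abs(closed - oracle) / pmax(oracle, 1e-12)), 1e-8)
  }
  # continuity across the degenerate diagonal
  near <- two_state_solution(t, 100, 50, 0.1, 0.1 * (1 + 1e-12))
  at <- two_state_solution(t, 100, 50, 0.1, 0.1)
  expect_lt(max(abs(near - at)), 1e-9)
})

test_that("two-state limits: t = 0, frozen wrapped pool, long-time decay", {
  expect_equal(two_state_solution(0, 300, 150, 0.004, 0.03), 450)
  # frozen wrapped pool when k_unwrap = 0
  t <- seq(0, 100, 5)
  expect_equal(two_state_solution(t, 300, 150, 0, 0.02),
               300 + 150 * exp(-0.02 * t))
  # frozen spot value: equal rates 0.1/s at t = 10 s
  comp <- two_state_solution(10, 100, 0, 0.1, 0.1, components = TRUE)
  expect_equal(comp$w, 36.78794, tolerance = 1e-6)
  expect_equal(comp$b, 36.78794, tolerance = 1e-6)
  expect_equal(comp$n, 73.57589, tolerance = 1e-6)
  # n(t) non-increasing, n -> 0 when k_unbind > 0
  n <- two_state_solution(seq(0, 5000, 10), 300, 150, 0.004, 0.03)
  expect_true(all(diff(n) <= 0))
  expect_lt(n[length(n)], 1e-3)
})

test_that("noiseless two-state fits recover parameters to 0.5%", {
  t <- seq(0, 900, 5)
  for (p in list(c(300, 150, 0.004, 0.03), c(1100, 1100, 0.012, 0.03))) {
    tr <- dissoc_trace("m", t, two_state_solution(t, p[1], p[2], p[3], p[4]))
    fit <- fit_two_state(tr)
    expect_lt(abs(fit$w0 / p[1] - 1), 0.005)
    expect_lt(abs(fit$b0 / p[2] - 1), 0.005)
    expect_lt(abs(fit$k_unwrap / p[3] - 1), 0.005)
    expect_lt(abs(fit$k_unbind / p[4] - 1), 0.005)
    expect_gt(fit$k_unbind, fit$k_unwrap)  # label convention
  }
})

test_that("rate recovery bias from 50-molecule Gillespie ensembles is below 10%", {
  presets <- list(wt = list(w0 = 300, b0 = 150, kw = 0.004, kb = 0.03),
                  mut = list(w0 = 1100, b0 = 1100, kw = 0.012, kb = 0.03))
  for (nm in names(presets)) {
    p <- presets[[nm]]
    est <- t(vapply(1:15, function(s) {
      sim <- gen_dissociation_gillespie(
        w0_monomers = p$w0, b0_monomers = p$b0, k_unwrap = p$kw,
        k_unbind = p$kb, n_molecules = 50, T_total = 900, seed = s)
      fit <- fit_two_state(average_dissoc_traces(sim$traces))
      c(fit$k_unwrap, fit$k_unbind)
    }, numeric(2)))
    expect_lt(abs(stats::median(est[, 1]) / p$kw - 1), 0.10)
    expect_lt(abs(stats::median(est[, 2]) / p$kb - 1), 0.10)
  }
})

test_that("fits refuse non-decaying traces and flag near-degenerate rates", {
  t <- seq(0, 100, 5)
  flat <- dissoc_trace("f", t, rep(100, length(t)))
  expect_error(fit_two_state(flat), "does not decay")
  short <- dissoc_trace("s", 0:8, 9:1)
  expect_error(fit_two_state(short), ">= 10")
  # near-equal rates produce an identifiability note
  tr <- dissoc_trace("d", seq(0, 600, 5),
                     two_state_solution(seq(0, 600, 5), 200, 100, 0.02, 0.03))
  fit <- fit_two_state(tr)
  expect_false(is.null(fit$identifiability_note))
  expect_true(is.finite(fit$aic_single_exp))
})

test_that("photobleaching correction subtracts the bleach rate with a floor", {
  t <- seq(0, 900, 5)
  tr <- dissoc_trace("m", t, two_state_solution(t, 300, 150, 0.004, 0.03))
  fit <- fit_two_state(tr)
  # k_unwrap = 0.004 < k_bleach, so this correction also floors and warns
  expect_warning(corr <- correct_photobleaching(fit, 0.0059), "floored")
  expect_equal(corr$k_unbind, 0.03 - 0.0059, tolerance = 1e-3)
  expect_true(corr$corrected)
  # double correction refused
  expect_error(correct_photobleaching(corr, 0.0059), "already")
  # zero bleach is identity
  id <- correct_photobleaching(fit, 0)
  expect_equal(id$k_unwrap, fit$k_unwrap)
  # flooring: k_unwrap = 0.004 < k_bleach = 0.0059
  expect_warning(fl <- correct_photobleaching(fit, 0.0059 + fit$k_unwrap),
                 "floored")
  expect_equal(fl$k_unwrap, 0)
})

test_that("bleach-corrected rates from bleached simulations are unbiased within 5%", {
  kb_bleach <- 0.0059
  est <- t(vapply(1:5, function(s) {
    sim <- gen_dissociation_gillespie(
      w0_monomers = 300, b0_monomers = 150, k_unwrap = 0.004, k_unbind = 0.03,
      k_bleach = kb_bleach, n_molecules = 100, T_total = 900, seed = s)
    fit <- fit_two_state(average_dissoc_traces(sim$traces))
    corr <- correct_photobleaching(fit, kb_bleach)
    c(corr$k_unwrap, corr$k_unbind)
  }, numeric(2)))
  expect_lt(abs(stats::median(est[, 1]) / 0.004 - 1), 0.05)
  expect_lt(abs(stats::median(est[, 2]) / 0.03 - 1), 0.05)
})

test_that("bleach-rate estimation recovers a synthetic control", {
  t <- seq(0, 900, 5)
  ctrl <- dissoc_trace("c", t, 450 * exp(-0.0059 * t))
  expect_lt(abs(estimate_bleach_rate(ctrl) / 0.0059 - 1), 0.02)
  expect_equal(estimate_bleach_rate(dissoc_trace("f", t, rep(450, length(t)))), 0)
  expect_error(estimate_bleach_rate(dissoc_trace("r", t, 450 * exp(0.001 * t))),
               "rises")
  two_regime <- dissoc_trace("t", t,
                             two_state_solution(t, 400, 200, 0.002, 0.05))
  expect_warning(estimate_bleach_rate(two_regime), "two decay regimes")
})

test_that("footprint coverage reproduces the printed tetramer arithmetic", {
  # WT: 25 binding-mode + 70 wrapping-mode tetramers on 48,502 nt -> ~10%
  wt <- coverage_model(tet_binding = 25, tet_wrapping = 70, template_nt = 48502)
  expect_equal(100 * coverage_fraction(wt), 10.2, tolerance = 0.01)
  # mutant: 2200 monomers, modes split evenly -> ~50%
  mut <- coverage_model(n_monomers = 2200, frac_binding = 0.5,
                        template_nt = 48502)
  expect_equal(100 * coverage_fraction(mut), 51.0, tolerance = 0.01)
  # empty and saturated templates
  expect_equal(coverage_fraction(coverage_model(0, 0.5, 48502)), 0)
  expect_warning(
    full <- coverage_fraction(coverage_model(1e5, 0, 48502)), "capped")
  expect_equal(full, 1)
  expect_error(coverage_model(100, 0.5, template_nt = 0), "> 0")
})

test_that("coverage is linear in the monomer count below saturation", {
  covs <- vapply(c(100, 200, 400), function(n)
    coverage_fraction(coverage_model(n, 0.26, 48502)), numeric(1))
  expect_equal(covs[2] / covs[1], 2, tolerance = 1e-12)
  expect_equal(covs[3] / covs[1], 4, tolerance = 1e-12)
  expect_equal(monomers_to_tetramers(2200), 550)
})
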