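test_that("eFJC extension matches direct numeric evaluation of the model", {
  p <- efjc_params(Lc = 4.8, Lp = 1.9, S = 800, kBT = 4.11)
  # independent evaluation: x = 2 F Lp / kBT, L = Lc (coth x - 1/x)(1 + F/S)
  f <- c(0.1, 0.5, 1, 2, 5, 10, 15)
  x <- 2 * f * p$Lp / p$kBT
  expected <- p$Lc * (cosh(x) / sinh(x) - 1 / x) * (1 + f / p$S)
  expect_equal(efjc_extension(f, p), expected, tolerance = 1e-10)
  # frozen spot value at 10 pN (x = 9.2457, bracket = 0.89184, x1.0125)
  expect_equal(efjc_extension(10, p), 4.334353, tolerance = 1e-6)
})

test_that("eFJC limits behave physically", {
  p <- efjc_params(Lc = 4.8, Lp = 1.9)
  # F -> 0: extension -> 0 like Lc * x/3
  f_small <- 1e-8
  x <- 2 * f_small * p$Lp / p$kBT
  expect_equal(efjc_extension(f_small, p), p$Lc * x / 3, tolerance = 1e-6)
  # rigid backbone, high force: L -> Lc
  p_stiff <- efjc_params(Lc = 4.8, Lp = 1.9, S = 1e15)
  expect_equal(efjc_extension(1e7, p_stiff), p_stiff$Lc, tolerance = 1e-6)
  # F <= 0 rejected
  expect_error(efjc_extension(0, p), "force must be > 0")
  expect_error(efjc_extension(-1, p), "force must be > 0")
})

test_that("eFJC extension is monotone in force, Lc and Lp", {
  f <- seq(0.05, 20, length.out = 400)
  p <- efjc_params(2, 5)
  expect_true(all(diff(efjc_extension(f, p)) > 0))
  for (f0 in c(0.1, 1, 10)) {
    l_by_Lc <- vapply(c(1, 2, 4), function(Lc)
      efjc_extension(f0, efjc_params(Lc, 5)), numeric(1))
    expect_true(all(diff(l_by_Lc) > 0))
    l_by_Lp <- vapply(c(1, 3, 9), function(Lp)
      efjc_extension(f0, efjc_params(2, Lp)), numeric(1))
    expect_true(all(diff(l_by_Lp) > 0))  # smaller Lp -> smaller extension
  }
})

test_that("noiseless eFJC fits recover generating parameters to 0.1%", {
  regimes <- list(bare = c(4.8, 1.9), coated_wt = c(1.3, 9.3),
                  coated_mut = c(2.5, 3.3))
  for (nm in names(regimes)) {
    p <- efjc_params(regimes[[nm]][1], regimes[[nm]][2])
    win <- if (nm == "bare") c(0.1, 15) else c(0.1, 2)
    cur <- make_efjc_curve(p, f = seq(win[1], win[2], length.out = 120))
    fit <- fit_efjc(cur, force_window = win)
    expect_lt(abs(fit$params$Lc / p$Lc - 1), 1e-3)
    expect_lt(abs(fit$params$Lp / p$Lp - 1), 1e-3)
    expect_equal(fit$params$S, 800)  # stays fixed
  }
})

test_that("noisy eFJC fits recover coated-regime parameters within 5% (median over seeds)", {
  p <- efjc_params(1.3, 9.3)
  rel_err <- t(vapply(1:20, function(s) {
    sim <- gen_efjc_curve(p, F_grid = seq(0.1, 2, length.out = 100),
                          noise_sd = 0.02, seed = s)
    fit <- fit_efjc(sim$retraction, force_window = c(0.1, 2))
    c(abs(fit$params$Lc / p$Lc - 1), abs(fit$params$Lp / p$Lp - 1))
  }, numeric(2)))
  expect_lt(stats::median(rel_err[, 1]), 0.05)
  expect_lt(stats::median(rel_err[, 2]), 0.05)
})

test_that("force window is clipped to the data support and reported", {
  p <- efjc_params(4.8, 1.9)
  cur <- make_efjc_curve(p, f = seq(0.5, 10, length.out = 80))
  fit <- fit_efjc(cur, force_window = c(0.1, 2))
  expect_true(fit$window_clipped)
  expect_equal(fit$window, c(0.5, 2))
  # too few in-window samples
  cur2 <- make_efjc_curve(p, f = seq(5, 15, length.out = 50))
  expect_error(fit_efjc(cur2, force_window = c(0.1, 2)), "overlap|insufficient")
  cur3 <- make_efjc_curve(p, f = c(0.5, 1, 1.5, 2, 3, 4, 5, 8, 12))
  expect_error(fit_efjc(cur3, force_window = c(0.1, 1.6)), "insufficient")
})

test_that("curve energy reproduces analytic and quadrature references", {
  d <- seq(0, 1, length.out = 101)
  a <- force_extension_curve(d, rep(2, 101))
  b <- force_extension_curve(d, rep(1, 101))
  # identity
  expect_equal(curve_energy(a, a)$delta_E_pNnm, 0)
  # constant 1 pN over 1 um: 1000 pN nm ~ 243 kBT
  e <- curve_energy(a, b)
  expect_equal(e$delta_E_pNnm, 1000, tolerance = 1e-9)
  expect_equal(e$delta_E_kBT, 1000 / 4.1164, tolerance = 1e-3)
  # antisymmetry
  expect_equal(curve_energy(b, a)$delta_E_pNnm, -1000, tolerance = 1e-9)
  # additivity over adjacent distance intervals
  d1 <- seq(0, 0.5, length.out = 51); d2 <- seq(0.5, 1, length.out = 51)
  e1 <- curve_energy(force_extension_curve(d1, rep(2, 51)),
                     force_extension_curve(d1, rep(1, 51)))$delta_E_pNnm
  e2 <- curve_energy(force_extension_curve(d2, rep(2, 51)),
                     force_extension_curve(d2, rep(1, 51)))$delta_E_pNnm
  expect_equal(e1 + e2, e$delta_E_pNnm, tolerance = 1e-9)
})

test_that("trapezoid energy agrees with adaptive quadrature on eFJC curves", {
  pa <- efjc_params(1.3, 9.3)   # coated: shorter, stiffer -> higher force
  pb <- efjc_params(4.8, 1.9)   # bare
  f <- seq(0.1, 15, length.out = 250)
  ca <- make_efjc_curve(pa, f)
  cb <- make_efjc_curve(pb, f)
  e <- curve_energy(ca, cb)
  d_rng <- e$integration_range
  oracle <- quad_energy_pNnm(pa, pb, d_rng[1], d_rng[2])
  expect_gt(e$delta_E_pNnm, 0)  # coated curve lies above bare
  expect_lt(abs(e$delta_E_pNnm / oracle - 1), 0.005)
})

test_that("curves without overlapping distance support are rejected", {
  a <- force_extension_curve(c(0, 1), c(1, 2))
  b <- force_extension_curve(c(2, 3), c(1, 2))
  expect_error(curve_energy(a, b), "no overlapping distance support")
})

test_that("hysteresis energy and ddE follow the generator's ordering", {
  p <- efjc_params(1.3, 9.3)
  bare <- efjc_params(4.8, 1.9)
  # extension == retraction -> zero hysteresis
  ext <- make_efjc_curve(p, phase = "extension")
  ret <- make_efjc_curve(p, phase = "retraction")
  expect_equal(hysteresis_energy(ext, ret)$delta_E_pNnm, 0, tolerance = 1e-9)
  # protein loss between phases -> positive hysteresis
  sim <- gen_efjc_curve(p, unbind_fraction = 0.3, params_bare = bare, seed = 2)
  h1 <- hysteresis_energy(sim$extension, sim$retraction)
  expect_gt(h1$delta_E_pNnm, 0)
  # identical ramps -> ddE = 0; R2 with fewer bound proteins -> ddE > 0
  expect_equal(as.numeric(ddE(h1, h1)), 0)
  sim2 <- gen_efjc_curve(p, unbind_fraction = 0.3 * 0.7, params_bare = bare,
                         ramp_id = "R2", seed = 2)
  h2 <- hysteresis_energy(sim2$extension, sim2$retraction)
  expect_gt(ddE(h1, h2), 0)
  # mismatched ramp labels warn but compute
  expect_warning(hysteresis_energy(sim$extension, sim2$retraction),
                 "different ramps")
})

test_that("pN nm <-> kBT conversion is linear and self-inverse", {
  expect_equal(pNnm_to_kBT(4.1), 1, tolerance = 0.01)
  expect_equal(pNnm_to_kBT(0), 0)
  expect_equal(pNnm_to_kBT(41), 10 * pNnm_to_kBT(4.1))
  E <- c(0.1, 1, 250, 1e4)
  expect_equal(kBT_to_pNnm(pNnm_to_kBT(E)), E)
  expect_equal(pNnm_to_kBT(2 * E), 2 * pNnm_to_kBT(E))
  expect_error(pNnm_to_kBT(1, T_celsius = -10), "0-100")
})

test_that("theoretical contour length is multiplicative with the nt rise", {
  expect_equal(theoretical_contour_length(48502), 16.0, tolerance = 1e-3)
  expect_equal(theoretical_contour_length(1), 0.33 / 1000)
  expect_equal(theoretical_contour_length(9000), 2.97)
  expect_error(theoretical_contour_length(0), "> 0")
})
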