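test_that("initial length and intensity are the 3-frame means", {
  tr <- molecule_trace("m1", time = 0:4 * 5,
                       length = c(2.5, 2.6, 2.58, 1.9, 1.5),
                       intensity = c(400, 410, 420, 300, 200))
  expect_equal(initial_length(tr), 2.56)
  expect_equal(initial_intensity(tr), 410)
  flat <- molecule_trace("m2", 0:9, rep(4.14, 10))
  expect_equal(initial_length(flat), 4.14)
  short <- molecule_trace("m3", 0:1, c(1, 1))
  expect_error(initial_length(short), "insufficient")
})

test_that("salt onset is found within one frame on noiseless traces", {
  dt <- 5
  for (onset_frame in c(6, 8, 11, 15, 20)) {
    sim <- gen_compaction_ensemble(n_molecules = 1, noise_sd = 0,
                                   onset_frame = onset_frame,
                                   onset_jitter_frames = 0, seed = 1)
    t0 <- suppressWarnings(detect_salt_onset(sim$traces[[1]]))
    expect_lt(abs(t0 - sim$truth$t_onset[1]), dt + 1e-9)
  }
})

test_that("onset edge cases: constant trace, immediate decay", {
  flat <- molecule_trace("f", 0:19 * 5, rep(3, 20))
  expect_true(is.na(detect_salt_onset(flat)))
  t <- 0:19 * 5
  falling <- molecule_trace("d", t, 3 * (0.3 * exp(-0.05 * t) + 0.7))
  expect_warning(t0 <- detect_salt_onset(falling), "plateau is short")
  expect_lte(attr(t0, "frame"), 5)
})

test_that("normalized ensembles align and average correctly", {
  # single trace: ensemble equals its own normalised series
  sim <- gen_compaction_ensemble(n_molecules = 1, noise_sd = 0,
                                 onset_jitter_frames = 0, seed = 3)
  tr <- sim$traces[[1]]
  ens <- normalize_and_align(sim$traces, t0 = sim$truth$t_onset)
  merged <- stats::approx(tr$time_s - sim$truth$t_onset[1],
                          tr$length_um / initial_length(tr),
                          xout = ens$t_star)$y
  expect_equal(ens$mean, merged, tolerance = 1e-12)
  expect_true(all(ens$sd[ens$n > 1] == 0 | is.na(ens$sd)))

  # two identical traces shifted in onset: zero SD after alignment
  t <- 0:49 * 5
  mk <- function(onset_t) {
    ts <- pmax(t - onset_t, 0)
    molecule_trace(paste0("m", onset_t), t,
                   2.5 * ifelse(t <= onset_t, 1, 0.8 * exp(-0.03 * ts) + 0.2))
  }
  ens2 <- normalize_and_align(list(mk(50), mk(75)), t0 = c(50, 75))
  expect_true(all(ens2$sd[ens2$n == 2] < 1e-12))
})

test_that("the ensemble mean tracks the generating decay within 3 SE", {
  sim <- gen_compaction_ensemble(n_molecules = 40, seed = 11)
  ens <- suppressWarnings(normalize_and_align(sim$traces))
  post <- ens[ens$t_star >= 0 & ens$n >= 10, ]
  expected <- with(sim$truth, beta * exp(-kc * post$t_star) + Lf_frac)
  se <- post$sd / sqrt(post$n)
  expect_gt(mean(abs(post$mean - expected) <= 3 * pmax(se, 1e-6)), 0.95)
  # starts at full length: first grid point within 2 SE of 1
  first <- post[1, ]
  expect_lt(abs(first$mean - 1), 2 * first$sd / sqrt(first$n) + 0.02)
})

test_that("noiseless compaction decay is recovered exactly", {
  t_star <- seq(0, 300, by = 5)
  ens <- data.frame(t_star = t_star,
                    mean = 0.8 * exp(-0.02 * t_star) + 0.2)
  fit <- fit_compaction_decay(ens)
  expect_equal(fit$beta, 0.8, tolerance = 1e-6)
  expect_equal(fit$kc, 0.02, tolerance = 1e-6)
  expect_equal(fit$Lf_over_L0, 0.2, tolerance = 1e-6)
  expect_equal(fit$beta + fit$Lf_over_L0, 1, tolerance = 1e-6)
})

test_that("compaction amplitude is recovered within 0.05 in both salt regimes", {
  for (b in c(0.63, 0.80)) {
    sim <- gen_compaction_ensemble(n_molecules = 60, beta = b, seed = 21)
    ens <- suppressWarnings(normalize_and_align(sim$traces))
    fit <- fit_compaction_decay(ens)
    expect_lt(abs(fit$beta - b), 0.05)
  }
})

test_that("a factor-2 rate difference is recovered within 15% (median over seeds)", {
  ratios <- vapply(1:20, function(s) {
    f1 <- fit_compaction_decay(suppressWarnings(normalize_and_align(
      gen_compaction_ensemble(kc = 0.04, seed = s)$traces)))
    f2 <- fit_compaction_decay(suppressWarnings(normalize_and_align(
      gen_compaction_ensemble(kc = 0.02, seed = s + 500)$traces)))
    f1$kc / f2$kc
  }, numeric(1))
  expect_lt(abs(stats::median(ratios) / 2 - 1), 0.15)
})

test_that("fit bias shrinks with ensemble size", {
  err_n <- vapply(c(10, 100), function(n) {
    errs <- vapply(1:5, function(s) {
      sim <- gen_compaction_ensemble(n_molecules = n, seed = 40 + s)
      fit <- fit_compaction_decay(suppressWarnings(normalize_and_align(sim$traces)))
      fit$beta - sim$truth$beta
    }, numeric(1))
    abs(mean(errs))
  }, numeric(1))
  expect_lt(err_n[2], err_n[1] + 0.01)
})

test_that("non-decaying ensembles are refused", {
  flat <- data.frame(t_star = 0:50, mean = rep(1, 51))
  expect_error(fit_compaction_decay(flat), "does not decay")
})

test_that("percent compaction reproduces the worked arithmetic", {
  expect_equal(percent_compaction(2.56, 8.5), 69.88, tolerance = 1e-3)
  expect_equal(percent_compaction(4.14, 8.5), 51.29, tolerance = 1e-3)
  expect_equal(percent_compaction(8.5, 8.5), 0)
  expect_warning(out <- percent_compaction(9, 8.5), "beyond reference")
  expect_lt(out, 0)
  expect_error(percent_compaction(1, 0), "> 0")
  # strictly increasing as L0 decreases
  expect_true(all(diff(percent_compaction(c(6, 4, 2), 8.5)) > 0))
})
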