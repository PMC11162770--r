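# Synthetic-data generators. Each generator emulates the statistical
# structure of one assay, takes an explicit seed, and returns the generated
# data together with a machine-readable ground-truth list so recovery tests
# can compare fit output against the generating parameters only.

# exponential waiting time that tolerates rate 0 (never fires)
.rexp0 <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else stats::rexp(n, rate)
}

#' Generate an eFJC force-extension / retraction curve pair
#'
#' Samples the eFJC forward model on a force grid for the extension phase
#' and, optionally, a retraction phase in which a fraction of the bound
#' protein has unbound at high force: the retraction parameters are linear
#' interpolations between the coated and bare parameter sets, which creates
#' positive hysteresis by construction. Noise is multiplicative Gaussian on
#' the distances.
#'
#' Parameter presets mirror the three measured regimes: bare ssDNA
#' (Lc = 4.8 um, Lp = 1.9 nm), WT-coated (1.3 um, 9.3 nm) and mutant-coated
#' (2.5 um, 3.3 nm), all at S = 800 pN.
#'
#' @param params An [efjc_params()] object (the coated, or only, state).
#' @param F_grid Positive, sorted force grid in pN. Default
#'   `seq(0.1, 15, length.out = 150)`.
#' @param noise_sd Multiplicative distance noise SD (e.g. 0.02 for 2%).
#'   Default 0.
#' @param unbind_fraction Fraction of protein lost between extension and
#'   retraction, in `[0, 1]`. Requires `params_bare` when > 0. Default 0.
#' @param params_bare Bare-ssDNA [efjc_params()] towards which retraction
#'   parameters are interpolated.
#' @param ramp_id,condition Labels stored on the curves.
#' @param seed Integer seed.
#' @return List with `extension` and `retraction`
#'   ([force_extension_curve()] objects) and `truth` (generating
#'   parameters).
#' @export
gen_efjc_curve <- function(params, F_grid = seq(0.1, 15, length.out = 150),
                           noise_sd = 0, unbind_fraction = 0,
                           params_bare = NULL, ramp_id = "R1",
                           condition = "protein", seed = 1) {
  stopifnot(inherits(params, "efjc_params"))
  if (any(F_grid <= 0) || is.unsorted(F_grid))
    stop("F_grid must be positive and sorted", call. = FALSE)
  if (unbind_fraction < 0 || unbind_fraction > 1)
    stop("unbind_fraction must be in [0, 1]", call. = FALSE)
  if (unbind_fraction > 0 && is.null(params_bare))
    stop("params_bare is required when unbind_fraction > 0", call. = FALSE)
  withr::with_seed(seed, {
    u <- unbind_fraction
    p_ret <- if (u > 0)
      efjc_params(params$Lc + u * (params_bare$Lc - params$Lc),
                  params$Lp + u * (params_bare$Lp - params$Lp),
                  params$S, params$kBT)
    else params
    d_ext <- efjc_extension(F_grid, params)
    d_ret <- efjc_extension(rev(F_grid), p_ret)
    if (noise_sd > 0) {
      d_ext <- d_ext * (1 + stats::rnorm(length(d_ext), 0, noise_sd))
      d_ret <- d_ret * (1 + stats::rnorm(length(d_ret), 0, noise_sd))
    }
    list(
      extension = force_extension_curve(d_ext, F_grid, "extension",
                                        ramp_id, condition),
      retraction = force_extension_curve(d_ret, rev(F_grid), "retraction",
                                         ramp_id, condition),
      truth = list(params = params, params_retraction = p_ret,
                   unbind_fraction = u, noise_sd = noise_sd, seed = seed)
    )
  })
}

#' Generate a salt-induced compaction trace ensemble
#'
#' Per-molecule apparent-length traces with a pre-salt plateau at L0 (drawn
#' from a lognormal across molecules), then an exponential decay
#' L(t*)/L0 = beta exp(-kc t*) + (1 - beta) starting at `onset_frame`, with
#' additive Gaussian noise on the normalised length. Defaults reflect the
#' high-salt regime: beta = 0.8, kc = 0.03/s, 60 molecules, 5-s frames.
#'
#' @param n_molecules Number of molecules. Default 60.
#' @param beta Compaction amplitude (fraction of L0). Default 0.8.
#' @param kc Compaction rate in 1/s. Default 0.03.
#' @param Lf_frac Final normalised length. Default `1 - beta` (so traces
#'   start at 1).
#' @param L0_mean,L0_cv Mean (um) and coefficient of variation of the
#'   lognormal L0 distribution. Defaults 2.56 um and 0.25.
#' @param onset_frame Last plateau frame; decay starts on the next frame.
#'   Default 10. A small per-molecule jitter of +/- `onset_jitter_frames`
#'   frames is applied.
#' @param onset_jitter_frames Integer jitter half-width. Default 2.
#' @param n_frames Total frames per movie. Default 60.
#' @param dt Frame interval in s. Default 5.
#' @param noise_sd Additive noise SD on L/L0. Default 0.05.
#' @param seed Integer seed.
#' @return List with `traces` (list of [molecule_trace()]) and `truth`
#'   (generating parameters incl. per-molecule `L0` and onset times).
#' @export
gen_compaction_ensemble <- function(n_molecules = 60, beta = 0.8, kc = 0.03,
                                    Lf_frac = 1 - beta, L0_mean = 2.56,
                                    L0_cv = 0.25, onset_frame = 10,
                                    onset_jitter_frames = 2, n_frames = 60,
                                    dt = 5, noise_sd = 0.05, seed = 1) {
  stopifnot(beta >= 0, beta <= 1, kc >= 0, Lf_frac >= 0, Lf_frac <= 1)
  withr::with_seed(seed, {
    sdlog <- sqrt(log(1 + L0_cv^2))
    L0 <- stats::rlnorm(n_molecules, log(L0_mean) - sdlog^2 / 2, sdlog)
    jit <- if (onset_jitter_frames > 0)
      sample(-onset_jitter_frames:onset_jitter_frames, n_molecules, TRUE)
    else rep(0L, n_molecules)
    onset <- pmax(onset_frame + jit, 6L)
    t <- (seq_len(n_frames) - 1) * dt
    traces <- lapply(seq_len(n_molecules), function(i) {
      t_on <- (onset[i] - 1) * dt
      ts <- pmax(t - t_on, 0)
      rel <- ifelse(t <= t_on, 1, beta * exp(-kc * ts) + Lf_frac)
      rel <- rel + stats::rnorm(n_frames, 0, noise_sd)
      molecule_trace(paste0("mol", i), t, pmax(rel, 0) * L0[i])
    })
    list(traces = traces,
         truth = list(beta = beta, kc = kc, Lf_frac = Lf_frac, L0 = L0,
                      onset_frame = onset, t_onset = (onset - 1) * dt,
                      dt = dt, noise_sd = noise_sd, seed = seed))
  })
}

#' Gillespie simulation of two-state dissociation with photobleaching
#'
#' Continuous-time Markov simulation of the W -> B -> detached scheme per
#' tetramer: a wrapped tetramer waits Exp(k_unwrap) before entering the
#' bound state, a bound tetramer waits Exp(k_unbind) before detaching
#' (exponential waiting times are exact for the scheme; sampling at the
#' camera interval then mimics integration). Each of the 4 subunits carries
#' a fluorophore with probability `labeling_efficiency` and bleaches
#' independently at `k_bleach`; bleached-but-attached tetramers stay
#' attached and invisible, reproducing the confound that rate subtraction
#' corrects. The recorded trace is the number of visible (attached,
#' unbleached) fluorophores, i.e. an apparent monomer count.
#'
#' Presets mirror the measured regimes: WT-like w0 ~ 300, b0 ~ 150 monomers
#' with slow unwrapping; mutant-like b0 ~ w0 ~ 1100 monomers with ~3x
#' faster unwrapping.
#'
#' @param w0_monomers,b0_monomers Initial monomers in the wrapped and bound
#'   states (converted to tetramers as n/4). Defaults 300 and 150.
#' @param k_unwrap,k_unbind Rates in 1/s. Defaults 0.004 and 0.03.
#' @param k_bleach Per-fluorophore bleaching rate in 1/s. Default 0.
#' @param labeling_efficiency Fraction of labeled subunits. Default 1.
#' @param dt Sampling interval in s. Default 5.
#' @param T_total Trace duration in s. Default 900.
#' @param n_molecules Number of independent ssDNA molecules (traces).
#'   Default 1.
#' @param seed Integer seed.
#' @return List with `traces` (list of [dissoc_trace()]) and `truth`.
#' @export
gen_dissociation_gillespie <- function(w0_monomers = 300, b0_monomers = 150,
                                       k_unwrap = 0.004, k_unbind = 0.03,
                                       k_bleach = 0, labeling_efficiency = 1,
                                       dt = 5, T_total = 900,
                                       n_molecules = 1, seed = 1) {
  stopifnot(w0_monomers >= 0, b0_monomers >= 0, k_unwrap >= 0, k_unbind >= 0,
            k_bleach >= 0, labeling_efficiency > 0, labeling_efficiency <= 1)
  n_w <- round(w0_monomers / 4)
  n_b <- round(b0_monomers / 4)
  t_sample <- seq(0, T_total, by = dt)
  withr::with_seed(seed, {
    traces <- lapply(seq_len(n_molecules), function(m) {
      # detach time per tetramer
      t_det_w <- .rexp0(n_w, k_unwrap) + .rexp0(n_w, k_unbind)
      t_det_b <- .rexp0(n_b, k_unbind)
      t_det <- c(t_det_w, t_det_b)
      n_tet <- length(t_det)
      # per-fluorophore disappearance = min(bleach, tetramer detach)
      labeled <- stats::runif(4 * n_tet) < labeling_efficiency
      t_bleach <- .rexp0(4 * n_tet, k_bleach)
      t_gone <- pmin(t_bleach, rep(t_det, each = 4))
      t_gone <- t_gone[labeled]
      sorted <- sort(t_gone[is.finite(t_gone)])
      visible <- length(t_gone) - findInterval(t_sample, sorted,
                                               left.open = TRUE)
      dissoc_trace(paste0("mol", m), t_sample, visible)
    })
    list(traces = traces,
         truth = list(w0_monomers = 4 * n_w, b0_monomers = 4 * n_b,
                      k_unwrap = k_unwrap, k_unbind = k_unbind,
                      k_bleach = k_bleach,
                      labeling_efficiency = labeling_efficiency,
                      dt = dt, T_total = T_total, seed = seed))
  })
}

#' Average a list of dissociation traces sharing a time base
#'
#' @param traces List of [dissoc_trace()] objects on identical time grids.
#' @return One [dissoc_trace()] holding the ensemble mean count.
#' @export
average_dissoc_traces <- function(traces) {
  stopifnot(length(traces) >= 1)
  t0 <- traces[[1]]$time_s
  mat <- vapply(traces, function(tr) {
    stopifnot(isTRUE(all.equal(tr$time_s, t0)))
    tr$count
  }, numeric(length(t0)))
  dissoc_trace("ensemble_mean", t0, rowMeans(matrix(mat, nrow = length(t0))))
}

#' Generate a two-color molecule table with known class labels
#'
#' Multinomial class assignment (`A_only`, `both`, `B_only`) followed by
#' per-class lognormal monomer counts converted to intensities; the silent
#' channel of single-color classes carries only background noise. The
#' `"1:1"` regime preset uses class probabilities (0.24, 0.76, 0), the
#' composition observed at equimolar mixing.
#'
#' @param n_molecules Number of molecules. Default 300.
#' @param class_probs Probabilities for (A_only, both, B_only); must sum
#'   to 1. Default `c(0.24, 0.76, 0)`.
#' @param mean_counts Named list of mean monomer counts: `A` (on A-only and
#'   the A channel of co-coated), `B` likewise. Default list(A = 400,
#'   B = 150).
#' @param count_cv Lognormal coefficient of variation of counts.
#'   Default 0.3.
#' @param I_single_A,I_single_B Single-fluorophore intensities. Default 10.
#' @param background_sd Background intensity SD per channel. Default 20.
#' @param ratio_condition Condition label. Default `"1:1"`.
#' @param seed Integer seed.
#' @return List with `records` (data.frame `molecule_id`, `I_A_au`,
#'   `I_B_au`, `ratio_condition`, `true_class`) and `truth`.
#' @export
gen_two_color_table <- function(n_molecules = 300,
                                class_probs = c(0.24, 0.76, 0),
                                mean_counts = list(A = 400, B = 150),
                                count_cv = 0.3, I_single_A = 10,
                                I_single_B = 10, background_sd = 20,
                                ratio_condition = "1:1", seed = 1) {
  stopifnot(length(class_probs) == 3, abs(sum(class_probs) - 1) < 1e-9)
  withr::with_seed(seed, {
    cls <- sample(c("A_only", "both", "B_only"), n_molecules, TRUE,
                  prob = class_probs)
    sdlog <- sqrt(log(1 + count_cv^2))
    rcount <- function(n, mu)
      stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
    nA <- ifelse(cls %in% c("A_only", "both"),
                 rcount(n_molecules, mean_counts$A), 0)
    nB <- ifelse(cls %in% c("B_only", "both"),
                 rcount(n_molecules, mean_counts$B), 0)
    I_A <- pmax(nA * I_single_A + stats::rnorm(n_molecules, 0, background_sd), 0)
    I_B <- pmax(nB * I_single_B + stats::rnorm(n_molecules, 0, background_sd), 0)
    list(records = data.frame(
           molecule_id = paste0("mol", seq_len(n_molecules)),
           I_A_au = I_A, I_B_au = I_B,
           ratio_condition = ratio_condition, true_class = cls),
         truth = list(class_probs = class_probs, mean_counts = mean_counts,
                      I_single_A = I_single_A, I_single_B = I_single_B,
                      background_sd = background_sd, seed = seed))
  })
}

#' Generate a multi-concentration BLI sensorgram set
#'
#' Samples [bli_1to1_model()] over a 300-s association and 600-s
#' dissociation phase at each concentration of the panel (default 0.625,
#' 1.5, 2.5 and 5 nM), with additive Gaussian response noise.
#'
#' @param k_on Association rate, 1/(M s). Default 1e6.
#' @param k_off Dissociation rate, 1/s. Default 1.17e-3 (so K_d = 1.17 nM
#'   at the default k_on).
#' @param R_max Saturation response, nm. Default 1.
#' @param concentrations Analyte concentrations in M.
#'   Default `c(0.625, 1.5, 2.5, 5) * 1e-9`.
#' @param t_assoc,t_dissoc Phase durations in s. Defaults 300 and 600.
#' @param dt Sampling interval in s. Default 2.
#' @param noise_sd Additive response noise SD in nm. Default 0.
#' @param seed Integer seed.
#' @return List with `traces` (a [bli_traces()] data.frame) and `truth`.
#' @export
gen_bli_traces <- function(k_on = 1e6, k_off = 1.17e-3, R_max = 1,
                           concentrations = c(0.625, 1.5, 2.5, 5) * 1e-9,
                           t_assoc = 300, t_dissoc = 600, dt = 2,
                           noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    t <- seq(0, t_assoc + t_dissoc, by = dt)
    per <- lapply(concentrations, function(C) {
      r <- bli_1to1_model(t, C, k_on, k_off, R_max, t_assoc)
      if (noise_sd > 0) r <- r + stats::rnorm(length(t), 0, noise_sd)
      data.frame(time_s = t, response_nm = r, conc_M = C,
                 phase = ifelse(t <= t_assoc, "association", "dissociation"))
    })
    df <- do.call(rbind, per)
    list(traces = bli_traces(df$time_s, df$response_nm, df$conc_M, df$phase),
         truth = list(k_on = k_on, k_off = k_off,
                      K_d_nM = k_off / k_on * 1e9, R_max = R_max,
                      concentrations = concentrations, t_assoc = t_assoc,
                      noise_sd = noise_sd, seed = seed))
  })
}

#' Generate mass-photometry events
#'
#' Gaussian per-event masses; a two-component mixture when `mean_kDa` has
#' length > 1 (weights in `weights`). The WT and mutant tetramer operating
#' points are 67 +/- 2 and 60 +/- 2 kDa.
#'
#' @param mean_kDa Component mean(s) in kDa. Default 67.
#' @param sd_kDa Component SD(s) in kDa (recycled). Default 2.
#' @param n Number of events. Default 5000.
#' @param weights Mixing weights (recycled, normalised). Default equal.
#' @param seed Integer seed.
#' @return List with `masses` (numeric vector) and `truth`.
#' @export
gen_mass_events <- function(mean_kDa = 67, sd_kDa = 2, n = 5000,
                            weights = NULL, seed = 1) {
  k <- length(mean_kDa)
  sd_kDa <- rep_len(sd_kDa, k)
  w <- rep_len(weights %||% 1, k); w <- w / sum(w)
  withr::with_seed(seed, {
    comp <- sample.int(k, n, TRUE, prob = w)
    masses <- stats::rnorm(n, mean_kDa[comp], sd_kDa[comp])
    list(masses = masses,
         truth = list(mean_kDa = mean_kDa, sd_kDa = sd_kDa, weights = w,
                      n = n, seed = seed))
  })
}

#' Generate a synthetic TIRF movie of flow-stretched filaments
#'
#' Renders horizontal filaments (anchored at a pixel, extending downstream
#' along the column axis) onto a constant background with additive Gaussian
#' noise. Filament lengths may change over frames (e.g. a compaction
#' preset); intensity is deposited uniformly along the filament. No optical
#' PSF is applied by default, so edges are crisp and segmentation accuracy
#' can be checked at the pixel level.
#'
#' @param filaments Data.frame with columns `anchor_row`, `anchor_col`,
#'   `length_px` (starting length), `intensity_per_px`; optional
#'   `length_end_px` for linear shrink across the movie.
#' @param n_frames Number of frames. Default 10.
#' @param shape Frame dimensions c(rows, cols). Default c(64, 128).
#' @param background Constant background level. Default 100.
#' @param noise_sd Additive Gaussian noise SD. Default 2.
#' @param pixel_size um/pixel. Default 0.1.
#' @param frame_interval s/frame. Default 5.
#' @param anchor_jitter_px Integer jitter half-width on the anchor per
#'   frame. Default 0.
#' @param seed Integer seed.
#' @return List with `stack` ([frame_stack()]) and `truth` (per-filament,
#'   per-frame lengths and photon sums).
#' @export
gen_tirf_movie <- function(filaments, n_frames = 10, shape = c(64, 128),
                           background = 100, noise_sd = 2, pixel_size = 0.1,
                           frame_interval = 5, anchor_jitter_px = 0,
                           seed = 1) {
  stopifnot(is.data.frame(filaments),
            all(c("anchor_row", "anchor_col", "length_px",
                  "intensity_per_px") %in% names(filaments)))
  withr::with_seed(seed, {
    truth_rows <- list()
    frames <- lapply(seq_len(n_frames), function(f) {
      fr <- matrix(background, shape[1], shape[2])
      if (noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(prod(shape), 0, noise_sd),
                          shape[1], shape[2])
      for (i in seq_len(nrow(filaments))) {
        fil <- filaments[i, ]
        L_end <- if ("length_end_px" %in% names(filaments) &&
                     !is.na(fil$length_end_px)) fil$length_end_px
                 else fil$length_px
        frac <- if (n_frames > 1) (f - 1) / (n_frames - 1) else 0
        L <- max(round(fil$length_px + frac * (L_end - fil$length_px)), 1)
        jr <- if (anchor_jitter_px > 0)
          sample(-anchor_jitter_px:anchor_jitter_px, 1) else 0
        r <- min(max(fil$anchor_row + jr, 1), shape[1])
        c0 <- fil$anchor_col
        cols <- c0:min(c0 + L - 1, shape[2])
        fr[r, cols] <- fr[r, cols] + fil$intensity_per_px
        truth_rows[[length(truth_rows) + 1]] <<- data.frame(
          filament = i, frame = f, row = r, anchor_col = c0,
          length_px = length(cols), length_um = length(cols) * pixel_size,
          photons = fil$intensity_per_px * length(cols))
      }
      fr
    })
    list(stack = frame_stack(frames, pixel_size, frame_interval),
         truth = do.call(rbind, truth_rows))
  })
}
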