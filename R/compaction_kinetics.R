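# Salt-induced ssDNA compaction kinetics from per-molecule TIRF length
# traces: initial length, salt-onset detection, ensemble normalisation and
# alignment, exponential-decay fitting, percent-compaction arithmetic.

#' Construct a per-molecule TIRF trace
#'
#' Time series of apparent length (the visible extent of a flow-stretched
#' ssDNA molecule) and integrated fluorescence intensity for one molecule.
#'
#' @param molecule_id Molecule label.
#' @param time Time in s, strictly increasing.
#' @param length Apparent length in um, all >= 0.
#' @param intensity Integrated intensity in a.u. (optional; defaults to NA).
#' @param salt_mM Salt concentration condition (mM).
#' @param protein Protein label (e.g. `"WT"`, `"R107Q"`).
#' @param channel Imaging channel label.
#' @return A `molecule_trace` data.frame with one row per frame and
#'   attributes `molecule_id`, `salt_mM`, `protein`, `channel`.
#' @export
molecule_trace <- function(molecule_id, time, length, intensity = NA_real_,
                           salt_mM = NA_real_, protein = NA_character_,
                           channel = NA_character_) {
  stopifnot(is.numeric(time), is.numeric(length))
  if (length(time) != length(length))
    stop("time and length must have equal length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (any(length < 0))
    stop("lengths must be >= 0", call. = FALSE)
  intensity <- rep_len(intensity, length(time))
  structure(
    data.frame(time_s = time, length_um = length, intensity_au = intensity),
    molecule_id = molecule_id, salt_mM = salt_mM, protein = protein,
    channel = channel,
    class = c("molecule_trace", "data.frame")
  )
}

#' Initial length and intensity of a trace
#'
#' Mean over the first three frames of the movie, the convention used to
#' define the pre-salt baseline L0 (and I0) of each molecule.
#'
#' @param trace A [molecule_trace()].
#' @return `initial_length`: L0 in um. `initial_intensity`: I0 in a.u.
#' @export
initial_length <- function(trace) {
  stopifnot(inherits(trace, "molecule_trace"))
  if (nrow(trace) < 3)
    stop("insufficient data: need >= 3 frames to define L0", call. = FALSE)
  mean(trace$length_um[1:3])
}

#' @rdname initial_length
#' @export
initial_intensity <- function(trace) {
  stopifnot(inherits(trace, "molecule_trace"))
  if (nrow(trace) < 3)
    stop("insufficient data: need >= 3 frames to define I0", call. = FALSE)
  mean(trace$intensity_au[1:3])
}

# refine a trigger-frame onset by fitting L/L0 = A exp(-k t) + Lf to the
# post-onset decay and solving for the time where the curve crosses 1
# (the decay passes through full length at the true onset). Falls back to
# the coarse estimate when the fit fails or the refinement leaves a window
# of 3 frames before / 1 frame after the trigger.
.refine_onset <- function(time, rel, frame, coarse_t0) {
  idx <- max(frame - 1L, 1L):length(rel)
  if (length(idx) < 5) return(coarse_t0)
  t <- time[idx]; y <- rel[idx]
  Lf0 <- min(max(mean(utils::tail(y, max(3, length(y) %/% 10))), 0), 0.99)
  k0 <- 1 / max(t[length(t)] - t[1], 1e-6) * 3
  fit <- tryCatch(minpack.lm::nls.lm(
    par = c(A = (1 - Lf0) * exp(k0 * t[1]), k = k0, Lf = Lf0),
    lower = c(1e-12, 1e-9, 0), upper = c(Inf, Inf, 1),
    fn = function(p) y - (p[1] * exp(-p[2] * t) + p[3]),
    control = minpack.lm::nls.lm.control(maxiter = 100)
  ), error = function(e) NULL)
  if (is.null(fit)) return(coarse_t0)
  A <- fit$par[1]; k <- fit$par[2]; Lf <- fit$par[3]
  if (Lf >= 1 || A <= 0 || k <= 0) return(coarse_t0)
  t0 <- log(A / (1 - Lf)) / k
  dt <- stats::median(diff(time))
  if (!is.finite(t0) || t0 < time[frame] - 3 * dt || t0 > time[frame] + dt)
    return(coarse_t0)
  t0
}

# centered 3-frame rolling mean with shrunken edges
.roll3 <- function(x) {
  n <- length(x)
  out <- x
  if (n >= 3) out[2:(n - 1)] <- (x[1:(n - 2)] + x[2:(n - 1)] + x[3:n]) / 3
  if (n >= 2) {
    out[1] <- mean(x[1:2])
    out[n] <- mean(x[(n - 1):n])
  }
  out
}

#' Detect the salt-onset time of a compaction trace
#'
#' The time t0* at which added salt starts to shorten the molecule. The
#' trigger: the first frame at which the centred 3-frame rolling mean of
#' L/L0 drops below `1 - delta` and stays below for `persistence`
#' consecutive frames. Because the decay curve still passes through the
#' full length at the true onset, the returned t0* is the frame *before*
#' the trigger (the last full-length frame); the trigger frame itself is
#' reported in the `frame` attribute. The exact criterion used with real
#' movies is an acquisition-specific choice; this rule is a parameterised
#' stand-in and `delta` should be tuned to the noise level of the data.
#'
#' @param trace A [molecule_trace()] with a pre-salt plateau of at least 5
#'   frames (a shorter plateau triggers a warning).
#' @param delta Fractional drop threshold. Default 0.05.
#' @param persistence Number of consecutive sub-threshold frames required.
#'   Default 3.
#' @param refine If `TRUE` (default), refine the frame-resolution trigger
#'   by fitting an exponential to the post-onset decay and solving for the
#'   time at which the fitted curve crosses full length, which removes the
#'   frame-quantisation and noise bias of the threshold rule.
#' @return t0* in seconds (time of the last pre-effect frame), or `NA` if
#'   no onset is found. The returned value carries attribute `frame`
#'   (1-based index of the trigger frame).
#' @export
detect_salt_onset <- function(trace, delta = 0.05, persistence = 3,
                              refine = TRUE) {
  stopifnot(inherits(trace, "molecule_trace"))
  if (nrow(trace) < persistence + 2)
    stop("trace too short for onset detection", call. = FALSE)
  L0 <- initial_length(trace)
  if (L0 <= 0) stop("non-positive L0; onset undetectable", call. = FALSE)
  rel <- trace$length_um / L0
  r <- .roll3(rel)
  # requiring the raw series below threshold as well keeps a single noise
  # outlier (which depresses three consecutive rolling means on its own)
  # from triggering a false onset
  below <- r < 1 - delta & rel < 1 - delta
  runs <- rle(below)
  idx <- cumsum(runs$lengths) - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= persistence)
  if (!length(hit)) return(structure(NA_real_, frame = NA_integer_))
  frame <- idx[hit[1]]
  if (frame <= 5)
    warning("onset detected within the first 5 frames; pre-salt plateau is short",
            call. = FALSE)
  t0 <- trace$time_s[max(frame - 1L, 1L)]
  if (refine)
    t0 <- .refine_onset(trace$time_s, trace$length_um / L0, frame, t0)
  structure(t0, frame = frame)
}

#' Normalize and align compaction traces into an ensemble
#'
#' Each molecule's length series is normalised by its own L0 and shifted to
#' salt-aligned time t* = t - t0*. All molecules are then interpolated
#' linearly onto a common t* grid (spacing = the median frame interval) and
#' averaged. No extrapolation: grid points outside a molecule's observed
#' span do not contribute, and the per-point molecule count `n` is reported.
#'
#' @param traces List of [molecule_trace()] objects.
#' @param delta,persistence Passed to [detect_salt_onset()].
#' @param t0 Optional numeric vector of onset times (s), one per trace,
#'   overriding detection.
#' @return A `compaction_ensemble` data.frame with columns `t_star`, `mean`,
#'   `sd`, `n`; the per-molecule normalised series is kept in attribute
#'   `molecules` (long data.frame).
#' @export
normalize_and_align <- function(traces, delta = 0.05, persistence = 3, t0 = NULL) {
  if (!length(traces)) stop("empty trace list", call. = FALSE)
  stopifnot(all(vapply(traces, inherits, TRUE, "molecule_trace")))
  if (!is.null(t0) && length(t0) != length(traces))
    stop("t0 must have one onset per trace", call. = FALSE)
  per <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    L0 <- initial_length(tr)
    t0i <- if (is.null(t0)) as.numeric(detect_salt_onset(tr, delta, persistence))
           else t0[i]
    if (is.na(t0i))
      stop("no salt onset found for molecule ",
           attr(tr, "molecule_id") %||% i, call. = FALSE)
    data.frame(molecule_id = as.character(attr(tr, "molecule_id") %||% i),
               t_star = tr$time_s - t0i,
               L_norm = tr$length_um / L0)
  })
  long <- do.call(rbind, per)
  dt <- stats::median(unlist(lapply(traces, function(tr) diff(tr$time_s))))
  # anchor the grid so that t* = 0 (the salt onset) is an exact grid point
  lo <- -dt * ceiling(max(-min(long$t_star), 0) / dt)
  grid <- seq(lo, max(long$t_star), by = dt)
  interp <- lapply(per, function(df) {
    y <- stats::approx(df$t_star, df$L_norm, xout = grid, rule = 1, ties = mean)$y
    y
  })
  mat <- do.call(cbind, interp)
  n <- rowSums(!is.na(mat))
  keep <- n > 0
  structure(
    data.frame(
      t_star = grid[keep],
      mean = rowMeans(mat, na.rm = TRUE)[keep],
      sd = apply(mat, 1, stats::sd, na.rm = TRUE)[keep],
      n = n[keep]
    ),
    molecules = long,
    class = c("compaction_ensemble", "data.frame")
  )
}

#' Fit the exponential compaction decay to an ensemble
#'
#' Fits L/L0 = beta * exp(-kc * t*) + Lf/L0 to the ensemble mean curve for
#' t* >= 0 by bounded nonlinear least squares, unweighted (per-point
#' molecule counts are reported but not used as weights). `beta` is the
#' amplitude of the salt-dependent compaction (fraction of L0), `kc` its
#' rate, and `Lf/L0` the final normalised length; at t* = 0 the model
#' satisfies beta + Lf/L0 ~ 1.
#'
#' @param ensemble A `compaction_ensemble` from [normalize_and_align()], or
#'   any data.frame with columns `t_star` and `mean`.
#' @return A `compaction_fit`: list with `beta`, `kc`, `Lf_over_L0`, their
#'   `se` and 95% confidence intervals (`ci95`, from the fit covariance),
#'   `residual_norm`, and `n_points`.
#' @export
fit_compaction_decay <- function(ensemble) {
  stopifnot(is.data.frame(ensemble), all(c("t_star", "mean") %in% names(ensemble)))
  df <- ensemble[ensemble$t_star >= 0 & is.finite(ensemble$mean), ]
  if (nrow(df) < 5) stop("too few post-onset points to fit", call. = FALSE)
  tail_mean <- mean(utils::tail(df$mean, max(3, ceiling(nrow(df) * 0.1))))
  head_val <- df$mean[1]
  if (head_val - tail_mean < 0.02)
    stop("ensemble does not decay; compaction fit refused", call. = FALSE)
  start <- c(beta = max(min(head_val - tail_mean, 1), 1e-3),
             kc = 1 / max(df$t_star[which(df$mean <= (head_val + tail_mean) / 2)[1]], 1e-6),
             Lf = max(min(tail_mean, 1), 0))
  if (is.na(start["kc"])) start["kc"] <- 1 / max(df$t_star)
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = c(0, 0, 0), upper = c(1, Inf, 1),
    fn = function(p) df$mean - (p[1] * exp(-p[2] * df$t_star) + p[3]),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (fit$info %in% c(0, 9))
    stop("compaction fit did not converge: ", fit$message, call. = FALSE)
  est <- fit$par
  se <- tryCatch(sqrt(diag(.nls_lm_vcov(fit))), error = function(e) rep(NA_real_, 3))
  ci <- cbind(est - 1.96 * se, est + 1.96 * se)
  dimnames(ci) <- list(c("beta", "kc", "Lf_over_L0"), c("lo", "hi"))
  structure(list(
    beta = unname(est[1]), kc = unname(est[2]), Lf_over_L0 = unname(est[3]),
    se = stats::setNames(se, c("beta", "kc", "Lf_over_L0")),
    ci95 = ci,
    residual_norm = sqrt(sum(fit$fvec^2)),
    n_points = nrow(df)
  ), class = "compaction_fit")
}

#' @export
print.compaction_fit <- function(x, ...) {
  cat(sprintf("Compaction decay fit: beta = %.3f, kc = %.4g /s, Lf/L0 = %.3f (%d points)\n",
              x$beta, x$kc, x$Lf_over_L0, x$n_points))
  invisible(x)
}

#' Percent compaction relative to a reference length
#'
#' 100 * (1 - L0 / L_reference). With the flow-stretched SYBR-stained bare
#' ssDNA reference of 8.5 um, a WT-coated L0 of 2.56 um gives ~70%
#' compaction and an R107Q-coated L0 of 4.14 um gives ~50%.
#'
#' @param L0 Observed initial length (um).
#' @param L_reference Reference length (um), > 0.
#' @return Percent compaction; negative (with a warning) if `L0` exceeds
#'   the reference.
#' @examples
#' percent_compaction(2.56, 8.5)  # ~69.9
#' @export
percent_compaction <- function(L0, L_reference) {
  if (any(L_reference <= 0)) stop("L_reference must be > 0", call. = FALSE)
  out <- 100 * (1 - L0 / L_reference)
  if (any(out < 0))
    warning("L0 exceeds the reference length; molecule stretched beyond reference",
            call. = FALSE)
  out
}
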