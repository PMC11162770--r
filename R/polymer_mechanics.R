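# Polymer mechanics: eFJC model evaluation and fitting for force-distance
# curves from acoustic force spectroscopy (AFS), energy integration between
# curves, and related unit arithmetic.

#' Boltzmann constant in pN nm / K
#' @keywords internal
.kB_pNnm_per_K <- 1.380649e-2

#' eFJC model parameters
#'
#' Container for the extensible freely jointed chain (eFJC) parameters used
#' to model ssDNA force-extension behaviour: contour length `Lc` (maximum
#' end-to-end length, um), persistence length `Lp` (bending stiffness scale,
#' nm), stretch modulus `S` (enthalpic backbone stiffness, pN) and thermal
#' energy `kBT` (pN nm).
#'
#' Defaults follow standard ssDNA practice: `S = 800` pN and
#' `kBT = 4.11` pN nm (25 C).
#'
#' @param Lc Contour length in um (> 0).
#' @param Lp Persistence length in nm (> 0).
#' @param S Stretch modulus in pN (> 0). Default 800.
#' @param kBT Thermal energy in pN nm (> 0). Default 4.11.
#' @return An object of class `efjc_params`.
#' @examples
#' efjc_params(Lc = 4.8, Lp = 1.9)
#' @export
efjc_params <- function(Lc, Lp, S = 800, kBT = 4.11) {
  stopifnot(is.numeric(Lc), is.numeric(Lp), is.numeric(S), is.numeric(kBT))
  if (Lc <= 0 || Lp <= 0 || S <= 0 || kBT <= 0)
    stop("all eFJC parameters (Lc, Lp, S, kBT) must be positive", call. = FALSE)
  structure(list(Lc = Lc, Lp = Lp, S = S, kBT = kBT), class = "efjc_params")
}

#' @export
print.efjc_params <- function(x, ...) {
  cat(sprintf("eFJC parameters: Lc = %.4g um, Lp = %.4g nm, S = %.4g pN, kBT = %.4g pN nm\n",
              x$Lc, x$Lp, x$S, x$kBT))
  invisible(x)
}

# Langevin bracket coth(x) - 1/x, numerically stable near 0 and for large x.
.langevin <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-4
  # series: x/3 - x^3/45 + 2x^5/945
  xs <- x[small]
  out[small] <- xs / 3 - xs^3 / 45
  xl <- x[!small]
  out[!small] <- 1 / tanh(xl) - 1 / xl
  out
}

#' Evaluate the eFJC extension at a given force
#'
#' Predicted tether extension under the extensible freely jointed chain
#' model,
#' \deqn{L(F) = L_c\left[\coth\left(\frac{2 F L_p}{k_B T}\right) -
#'   \frac{k_B T}{2 F L_p}\right]\left(1 + \frac{F}{S}\right),}
#' the standard polymer model for ssDNA stretching. The Langevin bracket is
#' undefined at F = 0; the physical F -> 0 limit of the extension is 0, and
#' callers needing that limit should supply it themselves.
#'
#' @param force Applied force in pN; all values must be > 0.
#' @param params An [efjc_params()] object.
#' @return Extension in um, same length as `force`. Strictly increasing in
#'   force and in `Lc`; approaches `Lc * (1 + F/S)` at high force.
#' @examples
#' p <- efjc_params(Lc = 4.8, Lp = 1.9)
#' efjc_extension(10, p)  # ~4.33 um
#' @export
efjc_extension <- function(force, params) {
  stopifnot(inherits(params, "efjc_params"))
  if (!is.numeric(force) || any(!is.finite(force)))
    stop("force must be finite numeric", call. = FALSE)
  if (any(force <= 0))
    stop("force must be > 0 (the Langevin bracket is undefined at 0; the F->0 limit of the extension is 0)",
         call. = FALSE)
  x <- 2 * force * params$Lp / params$kBT
  params$Lc * .langevin(x) * (1 + force / params$S)
}

#' Construct a force-extension curve
#'
#' One phase of an AFS force ramp: paired bead-surface distances and applied
#' forces, with ramp and phase labels. Within a phase the force is expected
#' to be monotone (non-decreasing for extension ramps, non-increasing for
#' retraction); because measurement noise produces local violations, the
#' monotonicity check runs on a 5-sample running-median-filtered series.
#'
#' @param distance Bead-surface distance series in um (length >= 2).
#' @param force Applied force series in pN (same length, all >= 0).
#' @param phase `"extension"` or `"retraction"`.
#' @param ramp_id Ramp label (e.g. `"R1"`).
#' @param condition Free-text condition label (`"bare"` or a protein name).
#' @return An object of class `force_extension_curve` (a data.frame with
#'   attributes `phase`, `ramp_id`, `condition`).
#' @export
force_extension_curve <- function(distance, force, phase = c("extension", "retraction"),
                                  ramp_id = "R1", condition = "bare") {
  phase <- match.arg(phase)
  stopifnot(is.numeric(distance), is.numeric(force))
  if (length(distance) != length(force))
    stop("distance and force must have equal length", call. = FALSE)
  if (length(force) < 2)
    stop("a curve needs at least 2 samples", call. = FALSE)
  if (any(force < 0))
    stop("forces must be >= 0", call. = FALSE)
  f_med <- if (length(force) >= 5) stats::runmed(force, 5) else force
  d <- diff(f_med)
  ok <- if (phase == "extension") all(d >= -1e-12) else all(d <= 1e-12)
  if (!ok)
    warning("force series is not monotone for phase '", phase,
            "' even after median filtering", call. = FALSE)
  structure(
    data.frame(distance_um = distance, force_pN = force),
    phase = phase, ramp_id = ramp_id, condition = condition,
    class = c("force_extension_curve", "data.frame")
  )
}

#' Fit the eFJC model to a force-distance curve
#'
#' Bounded nonlinear least squares of the eFJC model against one curve,
#' with residuals defined in distance (the model predicts L from F, matching
#' force-clamped AFS ramps). The stretch modulus is held fixed by default
#' (`S = 800` pN, the usual ssDNA value); free parameters are `Lc` and `Lp`.
#'
#' The requested force window is clipped to the data support; the effective
#' window is reported in the result. Retraction curves are the recommended
#' input for Lc/Lp estimation since ssDNA can stick non-specifically to the
#' flow-cell at very low force during extension.
#'
#' @param curve A [force_extension_curve()].
#' @param force_window Numeric length-2, fitting window in pN. Default
#'   `c(0.1, 15)` (use `c(0.1, 2)` for protein-coated ssDNA, where only the
#'   initial part of the curve deviates from bare DNA).
#' @param fixed Named list of parameters to hold fixed; any of `Lc`, `Lp`,
#'   `S`, `kBT`. Default fixes `S = 800` and `kBT = 4.11`.
#' @param start Optional named list of starting values for free parameters.
#' @return An object of class `efjc_fit`: list with `params`
#'   ([efjc_params()]), `se` (1-sigma uncertainties of free parameters),
#'   `residual_norm`, `window` (effective, after clipping), `window_clipped`
#'   flag, `n_points`, and the underlying `fit` object.
#' @examples
#' p <- efjc_params(4.8, 1.9)
#' f <- seq(0.1, 15, length.out = 100)
#' cur <- force_extension_curve(efjc_extension(f, p), f)
#' fit_efjc(cur)$params
#' @export
fit_efjc <- function(curve, force_window = c(0.1, 15),
                     fixed = list(S = 800, kBT = 4.11), start = NULL) {
  stopifnot(inherits(curve, "force_extension_curve"))
  if (length(force_window) != 2 || force_window[1] >= force_window[2])
    stop("force_window must be c(Fmin, Fmax) with Fmin < Fmax", call. = FALSE)
  f <- curve$force_pN
  d <- curve$distance_um
  pos <- f > 0
  f <- f[pos]; d <- d[pos]
  support <- range(f)
  eff <- c(max(force_window[1], support[1]), min(force_window[2], support[2]))
  clipped <- !isTRUE(all.equal(eff, force_window, tolerance = 1e-12))
  if (eff[1] >= eff[2])
    stop("force window does not overlap the data support [",
         signif(support[1], 3), ", ", signif(support[2], 3), "] pN", call. = FALSE)
  inw <- f >= eff[1] & f <= eff[2]
  if (sum(inw) < 5)
    stop("insufficient data: only ", sum(inw),
         " samples inside the force window (need >= 5)", call. = FALSE)
  f <- f[inw]; d <- d[inw]

  defaults <- list(Lc = NA_real_, Lp = NA_real_, S = 800, kBT = 4.11)
  fixed <- fixed[names(fixed) %in% names(defaults)]
  free_names <- setdiff(names(defaults), names(fixed))
  if (!all(c("S", "kBT") %in% names(fixed)) && !("Lc" %in% free_names))
    stop("at least Lc or Lp should be free", call. = FALSE)
  start_def <- list(Lc = max(d), Lp = 1, S = 800, kBT = 4.11)
  start <- utils::modifyList(start_def[free_names], as.list(start %||% list()))
  lower <- c(Lc = 1e-4, Lp = 1e-3, S = 1, kBT = 0.1)[free_names]
  upper <- c(Lc = 100, Lp = 100, S = 1e5, kBT = 100)[free_names]

  model_fun <- function(pars) {
    p <- utils::modifyList(as.list(fixed), as.list(pars))
    efjc_extension(f, efjc_params(p$Lc, p$Lp, p$S, p$kBT))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = unlist(start),
      lower = unlist(lower), upper = unlist(upper),
      fn = function(par) d - model_fun(as.list(par)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("eFJC fit failed: ", conditionMessage(e), call. = FALSE)
  )
  if (fit$info %in% c(0, 9))
    stop("eFJC fit did not converge (info = ", fit$info, "): ", fit$message,
         call. = FALSE)
  est <- as.list(fit$par)
  p_all <- utils::modifyList(as.list(fixed), est)
  se <- tryCatch(sqrt(diag(.nls_lm_vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  structure(list(
    params = efjc_params(p_all$Lc, p_all$Lp, p_all$S, p_all$kBT),
    se = se,
    residual_norm = sqrt(sum(fit$fvec^2)),
    window = eff,
    window_clipped = clipped,
    n_points = length(f),
    fit = fit
  ), class = "efjc_fit")
}

# covariance of an nls.lm fit (parameter space)
.nls_lm_vcov <- function(object, ...) {
  npar <- length(object$par)
  dof <- max(length(object$fvec) - npar, 1)
  s2 <- sum(object$fvec^2) / dof
  s2 * solve(object$hessian / 2)
}

#' @export
print.efjc_fit <- function(x, ...) {
  cat("eFJC fit over force window [", signif(x$window[1], 3), ",",
      signif(x$window[2], 3), "] pN",
      if (x$window_clipped) " (clipped to data support)", "\n", sep = "")
  print(x$params)
  if (length(x$se))
    cat("1-sigma uncertainties:",
        paste(names(x$se), signif(x$se, 3), sep = " = ", collapse = ", "), "\n")
  cat(sprintf("residual norm: %.4g um over %d points\n", x$residual_norm, x$n_points))
  invisible(x)
}

#' Convert energy from pN nm to units of kBT
#'
#' Linear conversion E / (kB * T) with kB = 1.380649e-2 pN nm / K. At 25 C,
#' kBT is about 4.1 pN nm, so 4.1 pN nm converts to ~1 kBT.
#'
#' @param E Energy in pN nm (vectorised).
#' @param T_celsius Temperature in Celsius, within 0-100. Default 25.
#' @return Energy in kBT units.
#' @export
pNnm_to_kBT <- function(E, T_celsius = 25) {
  if (T_celsius < 0 || T_celsius > 100)
    stop("T_celsius must be within 0-100", call. = FALSE)
  E / (.kB_pNnm_per_K * (T_celsius + 273.15))
}

#' @rdname pNnm_to_kBT
#' @param E_kBT Energy in kBT units.
#' @export
kBT_to_pNnm <- function(E_kBT, T_celsius = 25) {
  if (T_celsius < 0 || T_celsius > 100)
    stop("T_celsius must be within 0-100", call. = FALSE)
  E_kBT * (.kB_pNnm_per_K * (T_celsius + 273.15))
}

#' Theoretical contour length of ssDNA
#'
#' Nucleotide count times the inter-nucleotide rise. With the default rise
#' of 0.33 nm/nt, the 48,502-nt lambda-phage ssDNA comes out at 16 um.
#'
#' @param n_nt Number of nucleotides (> 0).
#' @param rise_per_nt Rise per nucleotide in nm. Default 0.33.
#' @return Contour length in um.
#' @examples
#' theoretical_contour_length(48502)  # 16.0 um
#' @export
theoretical_contour_length <- function(n_nt, rise_per_nt = 0.33) {
  stopifnot(is.numeric(n_nt), is.numeric(rise_per_nt))
  if (any(n_nt <= 0)) stop("n_nt must be > 0", call. = FALSE)
  n_nt * rise_per_nt / 1000
}

# Interpolate both curves on the union distance grid restricted to overlap
# and return the trapezoid integral of (F_a - F_b) dd in pN um.
.between_curve_integral <- function(curve_a, curve_b) {
  ra <- range(curve_a$distance_um)
  rb <- range(curve_b$distance_um)
  lo <- max(ra[1], rb[1]); hi <- min(ra[2], rb[2])
  if (lo >= hi)
    stop("curves have no overlapping distance support", call. = FALSE)
  grid <- sort(unique(c(curve_a$distance_um, curve_b$distance_um)))
  grid <- grid[grid >= lo & grid <= hi]
  if (!lo %in% grid) grid <- c(lo, grid)
  if (!hi %in% grid) grid <- c(grid, hi)
  fa <- stats::approx(curve_a$distance_um, curve_a$force_pN, xout = grid, ties = mean)$y
  fb <- stats::approx(curve_b$distance_um, curve_b$force_pN, xout = grid, ties = mean)$y
  dif <- fa - fb
  area <- sum(diff(grid) * (utils::head(dif, -1) + utils::tail(dif, -1)) / 2)
  list(area_pNum = area, range = c(lo, hi))
}

#' Energy between two force-distance curves
#'
#' Integrates the force difference between two curves over their overlapping
#' distance support, Delta E = integral (F_a - F_b) dd, by the trapezoid
#' rule after linear interpolation of both curves onto the union distance
#' grid restricted to the overlap. Used to quantify the work stored in a
#' protein-coated tether relative to bare ssDNA (retraction vs retraction),
#' or, via [hysteresis_energy()], the non-equilibrium work within one ramp.
#'
#' Antisymmetric: `curve_energy(a, b)` equals `-curve_energy(b, a)`.
#'
#' @param curve_a,curve_b [force_extension_curve()] objects sharing part of
#'   their distance support.
#' @param T_celsius Temperature for the kBT conversion. Default 25.
#' @return An `energy_result`: list with `delta_E_pNnm`, `delta_E_kBT`, and
#'   `integration_range` (um).
#' @export
curve_energy <- function(curve_a, curve_b, T_celsius = 25) {
  stopifnot(inherits(curve_a, "force_extension_curve"),
            inherits(curve_b, "force_extension_curve"))
  res <- .between_curve_integral(curve_a, curve_b)
  E_pNnm <- res$area_pNum * 1000  # pN um -> pN nm
  structure(list(
    delta_E_pNnm = E_pNnm,
    delta_E_kBT = pNnm_to_kBT(E_pNnm, T_celsius),
    integration_range = res$range
  ), class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("Delta E = %.4g pN nm = %.4g kBT over distance [%.3g, %.3g] um\n",
              x$delta_E_pNnm, x$delta_E_kBT,
              x$integration_range[1], x$integration_range[2]))
  invisible(x)
}

#' Hysteresis energy of one force ramp
#'
#' Area between the extension and retraction curves of the same ramp,
#' reflecting non-equilibrium protein unbinding during the stretch. For
#' physically generated data the result is >= 0 up to numerical tolerance.
#' Mismatched ramp labels trigger a warning but the computation proceeds.
#'
#' @param extension Extension-phase [force_extension_curve()].
#' @param retraction Retraction-phase curve of the same ramp.
#' @inheritParams curve_energy
#' @return An `energy_result` (see [curve_energy()]).
#' @export
hysteresis_energy <- function(extension, retraction, T_celsius = 25) {
  if (!identical(attr(extension, "ramp_id"), attr(retraction, "ramp_id")))
    warning("extension and retraction come from different ramps (",
            attr(extension, "ramp_id"), " vs ", attr(retraction, "ramp_id"),
            "); computing anyway", call. = FALSE)
  curve_energy(extension, retraction, T_celsius)
}

#' Difference between the hysteresis energies of two successive ramps
#'
#' Delta-Delta-E = Delta E(ramp 1) - Delta E(ramp 2). A positive value means
#' the second ramp dissipated less energy, i.e. protein was lost between the
#' ramps.
#'
#' @param ramp1,ramp2 `energy_result` objects from [hysteresis_energy()].
#' @return Energy difference in pN nm, with attribute `kBT`.
#' @export
ddE <- function(ramp1, ramp2) {
  stopifnot(inherits(ramp1, "energy_result"), inherits(ramp2, "energy_result"))
  out <- ramp1$delta_E_pNnm - ramp2$delta_E_pNnm
  attr(out, "kBT") <- ramp1$delta_E_kBT - ramp2$delta_E_kBT
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
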