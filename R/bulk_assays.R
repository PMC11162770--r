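# Bulk assays: 1:1 Langmuir kinetics for biolayer-interferometry (BLI)
# sensorgrams with a global multi-concentration fit, and Gaussian fitting
# of mass-photometry event distributions.

#' 1:1 Langmuir binding model for a BLI sensorgram
#'
#' Standard pseudo-first-order kinetics for analyte at concentration C
#' binding immobilised ligand. During association,
#' R(t) = R_eq (1 - exp(-(k_on C + k_off) t)) with
#' R_eq = R_max C / (C + K_d) and K_d = k_off / k_on; during dissociation
#' the response decays from its association end point as
#' R(t) = R_end exp(-k_off (t - t_assoc)).
#'
#' @param time Time in s from the start of association (vectorised).
#' @param conc Analyte concentration in M (>= 0).
#' @param k_on Association rate in 1/(M s).
#' @param k_off Dissociation rate in 1/s.
#' @param R_max Saturation response in nm.
#' @param t_assoc Association-phase duration in s; times beyond it are in
#'   the dissociation phase. Default 300.
#' @return Model response in nm.
#' @export
bli_1to1_model <- function(time, conc, k_on, k_off, R_max, t_assoc = 300) {
  stopifnot(conc >= 0, k_on > 0, k_off >= 0, R_max > 0)
  Kd <- k_off / k_on
  Req <- R_max * conc / (conc + Kd)
  kobs <- k_on * conc + k_off
  R_end <- Req * (1 - exp(-kobs * t_assoc))
  ifelse(time <= t_assoc,
         Req * (1 - exp(-kobs * time)),
         R_end * exp(-k_off * (time - t_assoc)))
}

#' Generate or validate a BLI sensorgram table
#'
#' @param time Time in s (global, increasing within a concentration).
#' @param response Response in nm.
#' @param conc_M Analyte concentration in M.
#' @param phase `"association"` or `"dissociation"` per row.
#' @return A `bli_traces` data.frame.
#' @export
bli_traces <- function(time, response, conc_M, phase) {
  stopifnot(length(time) == length(response),
            length(time) == length(conc_M),
            length(time) == length(phase))
  if (!all(phase %in% c("association", "dissociation")))
    stop("phase must be 'association' or 'dissociation'", call. = FALSE)
  structure(
    data.frame(time_s = time, response_nm = response, conc_M = conc_M,
               phase = phase),
    class = c("bli_traces", "data.frame")
  )
}

#' Global 1:1 fit of multi-concentration BLI sensorgrams
#'
#' Simultaneous bounded least squares of [bli_1to1_model()] across all
#' concentrations and both phases, sharing one (k_on, k_off, R_max) triple —
#' association and dissociation are fitted jointly with a common k_off. The
#' association duration is taken per concentration as the largest
#' association-phase time. A single-concentration input is accepted with a
#' warning about the k_on / K_d identifiability limit.
#'
#' @param traces A `bli_traces` data.frame (see [bli_traces()]).
#' @param start Optional named list of starting values (`k_on`, `k_off`,
#'   `R_max`).
#' @return A `binding_fit_1to1`: list with `k_on` (1/(M s)), `k_off` (1/s),
#'   `K_d_nM` (= k_off/k_on in nM), `R_max` (nm), `se`, `residual_norm`.
#' @export
fit_bli_global <- function(traces, start = NULL) {
  stopifnot(inherits(traces, "data.frame"),
            all(c("time_s", "response_nm", "conc_M", "phase") %in% names(traces)))
  concs <- sort(unique(traces$conc_M[traces$conc_M > 0]))
  if (length(concs) < 2)
    warning("single analyte concentration: k_on and K_d are only weakly identifiable",
            call. = FALSE)
  t_assoc <- vapply(split(traces, traces$conc_M), function(df) {
    a <- df$time_s[df$phase == "association"]
    if (length(a)) max(a) else 0
  }, numeric(1))
  ta_of <- function(conc) t_assoc[as.character(conc)]
  st <- utils::modifyList(
    list(k_on = 1e6, k_off = 1e-3, R_max = max(traces$response_nm) * 1.2),
    as.list(start %||% list()))
  resid_fun <- function(p) {
    pred <- bli_1to1_model(traces$time_s, traces$conc_M, p[1], p[2], p[3],
                           t_assoc = unname(ta_of(traces$conc_M)))
    traces$response_nm - pred
  }
  fit <- minpack.lm::nls.lm(
    par = c(k_on = st$k_on, k_off = st$k_off, R_max = st$R_max),
    lower = c(1, 1e-8, 1e-6), upper = c(1e12, 10, 1e4),
    fn = resid_fun, control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (fit$info %in% c(0, 9))
    stop("global BLI fit did not converge: ", fit$message, call. = FALSE)
  p <- fit$par
  se <- tryCatch(sqrt(diag(.nls_lm_vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(list(
    k_on = unname(p["k_on"]), k_off = unname(p["k_off"]),
    K_d_nM = unname(p["k_off"] / p["k_on"]) * 1e9,
    R_max = unname(p["R_max"]),
    se = stats::setNames(se, c("k_on", "k_off", "R_max")),
    residual_norm = sqrt(sum(fit$fvec^2))
  ), class = "binding_fit_1to1")
}

#' @export
print.binding_fit_1to1 <- function(x, ...) {
  cat(sprintf(
    "1:1 binding fit: k_on = %.3g /(M s), k_off = %.3g /s, K_d = %.3g nM, R_max = %.3g nm\n",
    x$k_on, x$k_off, x$K_d_nM, x$R_max))
  invisible(x)
}

#' Gaussian fit of a mass-photometry event distribution
#'
#' Histogram-free maximum likelihood. With one component the MLE is the
#' sample mean and SD; with more components a Gaussian mixture
#' (unequal variances) is fitted by EM via \pkg{mclust}. The component
#' count is user-chosen, not auto-selected. A degenerate sample (all events
#' identical) returns the value with the SD floored at the histogram
#' bin-width resolution limit, with a warning.
#'
#' @param masses Numeric vector of per-event masses in kDa (>= 30 events).
#' @param n_components Number of Gaussian components. Default 1.
#' @param bin_kDa Nominal histogram bin width used only as the degenerate
#'   SD floor (`bin_kDa / sqrt(12)`). Default 2.
#' @return A `gaussian_fit`: list with `mean`, `sd`, `amplitude` (each of
#'   length `n_components`; amplitudes are mixing proportions) and `n`.
#' @examples
#' fit_mass_gaussian(rnorm(1000, 67, 2))
#' @export
fit_mass_gaussian <- function(masses, n_components = 1, bin_kDa = 2) {
  stopifnot(is.numeric(masses))
  masses <- masses[is.finite(masses)]
  if (length(masses) < 30)
    stop("insufficient data: need >= 30 events for a stable fit", call. = FALSE)
  if (stats::sd(masses) == 0) {
    warning("all events identical; SD floored at the bin resolution limit",
            call. = FALSE)
    return(structure(list(mean = masses[1], sd = bin_kDa / sqrt(12),
                          amplitude = 1, n = length(masses)),
                     class = "gaussian_fit"))
  }
  if (n_components == 1) {
    out <- list(mean = mean(masses), sd = stats::sd(masses), amplitude = 1,
                n = length(masses))
  } else {
    mc <- mclust::Mclust(masses, G = n_components, modelNames = "V",
                         verbose = FALSE)
    if (is.null(mc)) stop("mixture fit failed", call. = FALSE)
    ord <- order(mc$parameters$mean)
    out <- list(mean = unname(mc$parameters$mean[ord]),
                sd = sqrt(unname(mc$parameters$variance$sigmasq[ord])),
                amplitude = unname(mc$parameters$pro[ord]),
                n = length(masses))
  }
  structure(out, class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  for (i in seq_along(x$mean))
    cat(sprintf("component %d: mean = %.2f kDa, sd = %.2f kDa, weight = %.2f\n",
                i, x$mean[i], x$sd[i], x$amplitude[i]))
  invisible(x)
}

#' Mass of an oligomer from its subunit mass
#'
#' @param monomer_kDa Subunit mass in kDa.
#' @param n_subunits Number of subunits (>= 1).
#' @return `monomer_kDa * n_subunits` in kDa.
#' @examples
#' oligomer_mass(16.25, 4)  # 65 kDa tetramer
#' @export
oligomer_mass <- function(monomer_kDa, n_subunits) {
  if (any(n_subunits < 1)) stop("n_subunits must be >= 1", call. = FALSE)
  monomer_kDa * n_subunits
}
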