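# Independent numerical oracles used by the tests. These deliberately do
# not call the package's solution paths: the ODE oracle integrates the
# kinetic scheme with a hand-written fixed-step RK4, and the energy oracle
# uses adaptive quadrature on the model force field.

# RK4 integration of dw/dt = -kw w, db/dt = kw w - kb b.
# Returns n(t) = w(t) + b(t) at the requested times (which must lie on the
# step grid implied by dt).
rk4_two_state <- function(times, w0, b0, kw, kb, dt = 0.005) {
  deriv <- function(s) c(-kw * s[1], kw * s[1] - kb * s[2])
  t_end <- max(times)
  n_steps <- ceiling(t_end / dt + 1e-9)
  s <- c(w0, b0)
  out_t <- 0
  out_n <- sum(s)
  for (i in seq_len(n_steps)) {
    k1 <- deriv(s)
    k2 <- deriv(s + dt / 2 * k1)
    k3 <- deriv(s + dt / 2 * k2)
    k4 <- deriv(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out_t <- c(out_t, i * dt)
    out_n <- c(out_n, sum(s))
  }
  stats::approx(out_t, out_n, xout = times)$y
}

# adaptive-quadrature energy between two eFJC force fields expressed as
# F(d): inverts L(F) numerically per distance and integrates the force
# difference with integrate().
quad_energy_pNnm <- function(params_a, params_b, d_lo, d_hi) {
  force_at <- function(params) {
    function(d) {
      vapply(d, function(di)
        stats::uniroot(function(f) efjc_extension(f, params) - di,
                       lower = 1e-8, upper = 500, tol = 1e-12)$root,
        numeric(1))
    }
  }
  fa <- force_at(params_a)
  fb <- force_at(params_b)
  1000 * stats::integrate(function(d) fa(d) - fb(d), d_lo, d_hi,
                          rel.tol = 1e-9)$value
}

# convenience: eFJC curve pair over a force grid without noise
make_efjc_curve <- function(params, f = seq(0.1, 15, length.out = 200),
                            phase = "extension", ...) {
  d <- efjc_extension(f, params)
  if (phase == "retraction") {
    f <- rev(f)
    d <- rev(d)
  }
  force_extension_curve(d, f, phase = phase, ...)
}
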