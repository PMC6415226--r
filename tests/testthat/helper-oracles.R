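# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: finite differences instead of analytic derivatives,
# closed forms instead of quadrature, Maxwell equal-area instead of the
# P/mu root solver, grid scans instead of Newton iterations.

central_diff <- function(fn, x, h = abs(x) * 1e-6 + 1e-12) {
  (fn(x + h) - fn(x - h)) / (2 * h)
}

# Square-well B2 closed form: V = Inf (r < sigma), -eps (sigma <= r < lambda
# sigma), 0 beyond. B2 = (2 pi / 3) sigma^3 [1 - (lambda^3 - 1)(e^eps - 1)].
square_well_B2 <- function(sigma, lambda, eps) {
  (2 * pi / 3) * sigma^3 * (1 - (lambda^3 - 1) * (exp(eps) - 1))
}

# van der Waals closed-form critical point (kB = 1).
vdw_critical <- function(a, b) list(rho_c = 1 / (3 * b), Tc = 8 * a / (27 * b))

# Maxwell equal-area construction for van der Waals coexistence at T < Tc.
# Works in volume per particle v = 1/rho with P(v) = T/(v - b) - a/v^2 and
# the exact antiderivative  int P dv = T log(v - b) + a / v.
vdw_maxwell <- function(a, b, T_K, tol = 1e-12) {
  P_of_v <- function(v) T_K / (v - b) - a / v^2
  dP_of_v <- function(v) -T_K / (v - b)^2 + 2 * a / v^3
  vc <- 3 * b
  v_min <- uniroot(dP_of_v, c(b * (1 + 1e-9), vc), tol = tol)$root
  v_max <- uniroot(dP_of_v, c(vc, 1e6 * b), tol = tol)$root
  P_lo <- max(P_of_v(v_min), 1e-12 * P_of_v(v_max))
  P_hi <- P_of_v(v_max)
  area_mismatch <- function(P) {
    vl <- uniroot(function(v) P_of_v(v) - P, c(b * (1 + 1e-12), v_min),
                  tol = tol)$root
    vg <- uniroot(function(v) P_of_v(v) - P, c(v_max, 10 * T_K / P + v_max),
                  tol = tol)$root
    T_K * log((vg - b) / (vl - b)) + a / vg - a / vl - P * (vg - vl)
  }
  P_coex <- uniroot(area_mismatch, c(P_lo * (1 + 1e-9), P_hi * (1 - 1e-9)),
                    tol = tol)$root
  vl <- uniroot(function(v) P_of_v(v) - P_coex, c(b * (1 + 1e-12), v_min),
                tol = tol)$root
  vg <- uniroot(function(v) P_of_v(v) - P_coex, c(v_max, 10 * T_K / P_coex + v_max),
                tol = tol)$root
  list(rho_gas = 1 / vg, rho_liq = 1 / vl, P = P_coex)
}

# Brute-force critical-temperature bracket: the highest T at which the
# isotherm betaP(rho) is non-monotone on a fine log-spaced grid, refined by
# bisection. Returns c(lo, hi) bracketing Tc to `resolution`.
grid_critical_bracket <- function(model, T_range, resolution = 0.02,
                                  n_rho = 4000) {
  rho <- exp(seq(log(model$rho_range[1] * 1.01), log(model$rho_range[2] * 0.99),
                 length.out = n_rho))
  nonmono <- function(T_K) any(diff(pressure(model, T_K, rho)) < 0)
  lo <- T_range[1]; hi <- T_range[2]
  if (!nonmono(lo)) stop("grid oracle: no loop at lower temperature bound")
  if (nonmono(hi)) stop("grid oracle: loop persists at upper temperature bound")
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (nonmono(mid)) lo <- mid else hi <- mid
  }
  c(lo, hi)
}

# Default tetramer demonstration model at a tabulated salt.
demo_model <- function(S = 0.5, valence = 4L, reference = "virial2",
                       tail = tail_correction(), order3 = FALSE) {
  dft <- synthetic_virial_defaults(S)
  free_energy_model(reference, B2 = dft$B2,
                    B3 = if (reference == "virial3") dft$B3 else 0,
                    salt = S, valence = valence, tail = tail)
}
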