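#' Reference-fluid equation-of-state table
#'
#' A tibble of pressure-density state points for the non-bonding reference
#' fluid (nanostars with scrambled sticky ends) at fixed temperature, salt and
#' valence. Pressures are beta-scaled (`beta P`, units nm^-3) so that the
#' ideal-gas law reads `betaP = rho`.
#'
#' @param rho Number densities, nm^-3; strictly increasing, all > 0.
#' @param betaP Beta-scaled pressures, nm^-3; all > 0.
#' @param sigma_betaP Optional 1-sigma uncertainties on `betaP`, nm^-3.
#' @param T_K Temperature, Kelvin.
#' @param S Molar salt concentration, mol/L.
#' @param f Valence.
#' @return A tibble with class `eos_table` and columns `rho_per_nm3`,
#'   `betaP_per_nm3` and (if given) `sigma_betaP`; metadata stored as
#'   attributes `T_K`, `S`, `f`.
#' @examples
#' eos_table(c(1e-5, 1e-4, 1e-3), c(1.05e-5, 1.4e-4, 4e-3), T_K = 293.15, S = 0.5, f = 4)
#' @export
eos_table <- function(rho, betaP, sigma_betaP = NULL,
                      T_K = NA_real_, S = NA_real_, f = NA_integer_) {
  check_positive(rho, "rho")
  check_positive(betaP, "betaP")
  if (length(rho) != length(betaP) || length(rho) < 3) {
    abort("`rho` and `betaP` must have equal length >= 3.",
          class = "nanostarphase_usage_error")
  }
  if (any(diff(rho) <= 0)) {
    abort("`rho` must be strictly increasing.", class = "nanostarphase_usage_error")
  }
  tbl <- tibble::tibble(rho_per_nm3 = rho, betaP_per_nm3 = betaP)
  if (!is.null(sigma_betaP)) {
    check_positive(sigma_betaP, "sigma_betaP")
    tbl$sigma_betaP <- sigma_betaP
  }
  structure(tbl, T_K = T_K, S = S, f = f,
            class = c("eos_table", class(tbl)))
}

#' @export
print.eos_table <- function(x, ...) {
  cat(sprintf("<eos_table>  T = %s K, S = %s M, f = %s\n",
              format(attr(x, "T_K")), format(attr(x, "S")), format(attr(x, "f"))))
  NextMethod()
}

#' Second virial coefficient by quadrature
#'
#' `B2 = -1/2 * integral 4 pi r^2 (exp(-V(r)) - 1) dr` for an effective pair
#' potential `V(r)` given in kB*T units, via adaptive quadrature
#' ([stats::integrate()]). `V` may return `Inf` inside a hard core. Supply
#' `breaks` at discontinuities (e.g. a hard-core diameter) so the integrator
#' never brackets a jump.
#'
#' @param pair_potential Function of distance r (nm) returning energy in kB*T.
#' @param r_max Upper integration limit, nm; the potential must have decayed
#'   so that the neglected tail is below `tail_tol` of the running integral.
#' @param breaks Optional sorted interior breakpoints (nm) at potential
#'   discontinuities.
#' @param abs_tol Absolute quadrature tolerance in nm^3; defaults to
#'   `1e-10 * r_max^3`.
#' @param tail_tol Relative tolerance for the neglected tail beyond `r_max`.
#' @return B2 in nm^3.
#' @examples
#' # hard spheres of diameter 1 nm: B2 = 2*pi/3
#' hs <- function(r) ifelse(r < 1, Inf, 0)
#' second_virial(hs, r_max = 3, breaks = 1)
#' @export
second_virial <- function(pair_potential, r_max, breaks = NULL,
                          abs_tol = 1e-10 * r_max^3, tail_tol = 1e-10) {
  check_positive(r_max, "r_max")
  integrand <- function(r) {
    v <- pair_potential(r)
    em1 <- ifelse(is.infinite(v) & v > 0, -1, expm1(-v))
    4 * pi * r^2 * em1
  }
  lims <- unique(sort(c(0, breaks, r_max)))
  if (any(lims < 0) || any(lims > r_max)) {
    abort("`breaks` must lie inside (0, r_max).", class = "nanostarphase_usage_error")
  }
  pieces <- vapply(seq_len(length(lims) - 1L), function(i) {
    out <- tryCatch(
      integrate(integrand, lims[i], lims[i + 1L],
                abs.tol = abs_tol / (length(lims) - 1L), rel.tol = 1e-10,
                subdivisions = 500L),
      error = function(e) abort(
        sprintf("Quadrature failed on [%g, %g]: %s", lims[i], lims[i + 1L],
                conditionMessage(e)),
        class = "nanostarphase_numerical_error")
    )
    out$value
  }, numeric(1))
  total <- sum(pieces)
  # tail check: integrand just inside r_max must be negligible
  tail_probe <- abs(integrand(r_max * (1 - 1e-6))) * r_max
  if (is.finite(tail_probe) && abs(total) > 0 && tail_probe > tail_tol * abs(total)) {
    warn(sprintf("Integrand tail at r_max (%.3g) exceeds %.1e of the integral; increase r_max.",
                 tail_probe, tail_tol))
  }
  -0.5 * total
}

#' Fit the third virial coefficient to an EOS table
#'
#' Least-squares fit of `betaP = rho + B2 rho^2 + B3 rho^3` with `B2` held
#' fixed, so B3 is the only free parameter. Weighted by `1/sigma^2` when the
#' table carries uncertainties, unweighted otherwise.
#'
#' @param table An [eos_table()].
#' @param B2 Second virial coefficient, nm^3 (held fixed).
#' @return An object of class `b3_fit` with elements `B3`, `std_error`, `B2`,
#'   the underlying [stats::lm] fit, and the table. Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' tb <- eos_table(c(1e-5, 1e-4, 5e-4), 1e-5 * c(1, 10, 50) * (1 + 2e3 * c(1e-5, 1e-4, 5e-4)))
#' fit_B3(tb, B2 = 2e3)
#' @export
fit_B3 <- function(table, B2) {
  if (!inherits(table, "eos_table")) {
    abort("`table` must be an eos_table.", class = "nanostarphase_usage_error")
  }
  if (nrow(table) < 3) {
    abort("At least 3 state points are required to fit B3.",
          class = "nanostarphase_insufficient_data_error")
  }
  rho <- table$rho_per_nm3
  y <- table$betaP_per_nm3 - rho - B2 * rho^2
  w <- if ("sigma_betaP" %in% names(table)) 1 / table$sigma_betaP^2 else NULL
  dat <- data.frame(y = y, x3 = rho^3)
  fit <- if (is.null(w)) lm(y ~ 0 + x3, data = dat) else {
    dat$w <- w
    lm(y ~ 0 + x3, data = dat, weights = w)
  }
  # noiseless tables fit exactly; lm's "perfect fit" warning is expected there
  sm <- suppressWarnings(summary(fit)$coefficients)
  structure(
    list(B3 = unname(sm[1, 1]), std_error = unname(sm[1, 2]),
         B2 = B2, fit = fit, table = table),
    class = "b3_fit"
  )
}

#' @export
print.b3_fit <- function(x, ...) {
  cat(sprintf("<b3_fit>  B3 = %.6g +/- %.3g nm^6  (B2 fixed at %.6g nm^3, %d points)\n",
              x$B3, x$std_error, x$B2, nrow(x$table)))
  invisible(x)
}

#' Excess free energy from the virial expansion
#'
#' `beta fex = B2 rho` (order 2) or `B2 rho + B3 rho^2 / 2` (order 3), per
#' particle in kB*T units.
#'
#' @param rho Number density, nm^-3 (>= 0). Vectorized.
#' @param B2 Second virial coefficient, nm^3.
#' @param B3 Third virial coefficient, nm^6 (ignored at order 2).
#' @param order Truncation order, 2 or 3.
#' @return Excess free energy per particle (dimensionless).
#' @examples
#' fex_virial(5e-4, B2 = 2000, B3 = 1e6, order = 3)
#' @export
fex_virial <- function(rho, B2, B3 = 0, order = 3L) {
  check_nonnegative(rho, "rho")
  order <- as.integer(order)
  if (!order %in% c(2L, 3L)) {
    abort("`order` must be 2 or 3.", class = "nanostarphase_usage_error")
  }
  if (order == 2L) B2 * rho else B2 * rho + B3 * rho^2 / 2
}

#' Interpolant of an EOS table for thermodynamic integration
#'
#' Fits the excess compressibility `betaP/rho - 1` with a polynomial
#' `B2 rho + c2 rho^2 + ... + ck rho^k` whose linear coefficient is pinned to
#' the supplied B2, so the `rho -> 0` limit of the TI integrand is exact and
#' the integral is available in closed form. A monotone Hyman spline through
#' the integrand values is available as an alternative (`method = "spline"`),
#' integrated by adaptive quadrature.
#'
#' @param table An [eos_table()].
#' @param B2 Second virial coefficient pinning the dilute limit, nm^3.
#' @param order Polynomial order k in the excess channel (default 3).
#' @param method `"poly"` (default, closed-form integral) or `"spline"`.
#' @return An object of class `ti_interpolant`.
#' @export
ti_interpolant <- function(table, B2, order = 3L, method = c("poly", "spline")) {
  method <- match.arg(method)
  if (!inherits(table, "eos_table")) {
    abort("`table` must be an eos_table.", class = "nanostarphase_usage_error")
  }
  rho <- table$rho_per_nm3
  y <- table$betaP_per_nm3 / rho - 1 # excess compressibility
  if (method == "poly") {
    order <- as.integer(order)
    if (order < 1L) abort("`order` must be >= 1.", class = "nanostarphase_usage_error")
    resid <- y - B2 * rho
    coefs <- numeric(order) # coefs[k] multiplies rho^k; coefs[1] = B2
    coefs[1] <- B2
    if (order >= 2L) {
      X <- outer(rho, 2:order, `^`)
      colnames(X) <- paste0("p", 2:order)
      fit <- lm.fit(X, resid)
      coefs[2:order] <- fit$coefficients
    }
    structure(list(method = "poly", coefs = coefs, B2 = B2,
                   rho_max = max(rho)),
              class = "ti_interpolant")
  } else {
    # integrand h(rho) = (betaP - rho)/rho^2 = y/rho, finite limit B2 at 0
    h <- y / rho
    sf <- splinefun(c(0, rho), c(B2, h), method = "hyman")
    structure(list(method = "spline", spline = sf, B2 = B2,
                   rho_max = max(rho)),
              class = "ti_interpolant")
  }
}

#' Excess free energy by thermodynamic integration
#'
#' `beta fex(rho) = integral_0^rho (betaP(r) - r) / r^2 dr`, with the
#' `r -> 0` limit of the integrand pinned to B2. For the default polynomial
#' interpolant the integral is evaluated term by term in closed form:
#' if `betaP/rho - 1 = sum_k c_k rho^k` then
#' `beta fex = sum_k c_k rho^k / k`.
#'
#' @param table An [eos_table()] or a prebuilt [ti_interpolant()].
#' @param rho Densities at which to evaluate, nm^-3; must lie within
#'   `[0, max(table rho)]`.
#' @param B2 Second virial coefficient (ignored if `table` is already an
#'   interpolant).
#' @param ... Passed to [ti_interpolant()] (e.g. `order`, `method`).
#' @return Excess free energy per particle (dimensionless), one per `rho`.
#' @examples
#' rho <- 10^seq(-6, -3.5, length.out = 8)
#' tb <- eos_table(rho, rho + 2000 * rho^2 + 1e6 * rho^3)
#' fex_TI(tb, rho = 1e-4, B2 = 2000)
#' @export
fex_TI <- function(table, rho, B2 = NULL, ...) {
  interp <- if (inherits(table, "ti_interpolant")) table else {
    if (is.null(B2)) {
      abort("`B2` is required when `table` is an eos_table.",
            class = "nanostarphase_usage_error")
    }
    ti_interpolant(table, B2, ...)
  }
  check_nonnegative(rho, "rho")
  if (any(rho > interp$rho_max * (1 + 1e-12))) {
    abort(sprintf("TI requested beyond the table range (max rho = %g nm^-3).",
                  interp$rho_max),
          class = "nanostarphase_range_error")
  }
  if (interp$method == "poly") {
    k <- seq_along(interp$coefs)
    vapply(rho, function(r) sum(interp$coefs * r^k / k), numeric(1))
  } else {
    vapply(rho, function(r) {
      if (r == 0) return(0)
      integrate(interp$spline, 0, r, rel.tol = 1e-10,
                abs.tol = 1e-12 * max(1, interp$B2 * r))$value
    }, numeric(1))
  }
}

#' Ideal-gas free energy per particle
#'
#' `beta fid = log(v0 rho) - 1`. The reference volume `v0` only shifts the
#' free energy by a density-independent amount times log(v0); it cancels in
#' the pressure and in all coexistence conditions.
#'
#' @param rho Number density, nm^-3 (> 0). Vectorized.
#' @param v0 Reference volume, nm^3 (> 0).
#' @return Ideal free energy per particle (dimensionless).
#' @export
f_ideal <- function(rho, v0 = 1) {
  check_positive(rho, "rho")
  check_positive(v0, "v0")
  log(v0 * rho) - 1
}

#' Overlap density of a star polymer
#'
#' `rho* = 3 / (4 pi L_arm^3)`, the density at which nanostars of arm length
#' `L_arm` begin to interpenetrate; it marks the onset of the semi-dilute
#' regime and sets the validity ceiling of virial-based references.
#'
#' @param L_arm Arm length, nm (> 0). Vectorized.
#' @return Overlap density in nm^-3.
#' @examples
#' overlap_density(8.72) # ~3.6e-4 nm^-3
#' @export
overlap_density <- function(L_arm) {
  check_positive(L_arm, "L_arm")
  3 / (4 * pi * L_arm^3)
}
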