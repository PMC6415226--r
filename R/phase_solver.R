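#' Construct a free-energy model from explicit derivative functions
#'
#' Low-level constructor for a composable Helmholtz free energy per particle
#' `beta f(T, rho)` with analytic density derivatives up to third order,
#' declared valid over a (T, rho) box. The phase solvers need third
#' derivatives of the free energy (second derivatives of the pressure), so
#' purely numerical differentiation is too noisy; models supply analytic
#' derivatives and the contract is verified against central finite
#' differences at construction time.
#'
#' @param f_fun Function `(T_K, rho) -> beta f` (kB*T units per particle),
#'   vectorized in `rho`.
#' @param d_fun Function `(T_K, rho, order) -> d^order (beta f) / d rho^order`
#'   for order 1, 2, 3; vectorized in `rho`.
#' @param T_range Validity range in Kelvin, length 2.
#' @param rho_range Validity range in nm^-3, length 2 with `rho_range[1] > 0`.
#' @param label Short description used in printing.
#' @param check Verify the derivative contract by finite differences
#'   (default TRUE).
#' @return An object of class `fe_model`.
#' @export
fe_model <- function(f_fun, d_fun, T_range, rho_range, label = "custom",
                     check = TRUE) {
  check_positive(rho_range, "rho_range")
  check_positive(T_range, "T_range")
  m <- structure(
    list(f = f_fun, d = d_fun,
         T_range = sort(T_range), rho_range = sort(rho_range), label = label),
    class = "fe_model"
  )
  if (check) check_derivative_contract(m)
  m
}

check_derivative_contract <- function(m, rtol = 1e-4) {
  T_mid <- mean(m$T_range)
  rhos <- exp(seq(log(m$rho_range[1] * 2), log(m$rho_range[2] / 2), length.out = 3))
  for (r in rhos) {
    h <- r * 1e-5
    fd1 <- (m$f(T_mid, r + h) - m$f(T_mid, r - h)) / (2 * h)
    fd2 <- (m$d(T_mid, r + h, 1L) - m$d(T_mid, r - h, 1L)) / (2 * h)
    fd3 <- (m$d(T_mid, r + h, 2L) - m$d(T_mid, r - h, 2L)) / (2 * h)
    an <- c(m$d(T_mid, r, 1L), m$d(T_mid, r, 2L), m$d(T_mid, r, 3L))
    fd <- c(fd1, fd2, fd3)
    scale <- pmax(abs(an), abs(fd), 1e-8 / h^2)
    if (any(abs(an - fd) / scale > rtol)) {
      abort(sprintf(
        "Analytic derivatives disagree with finite differences at rho = %g (max rel dev %.2e).",
        r, max(abs(an - fd) / scale)),
        class = "nanostarphase_contract_error")
    }
  }
  invisible(m)
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model: %s>  T in [%g, %g] K, rho in [%g, %g] nm^-3\n",
              x$label, x$T_range[1], x$T_range[2],
              x$rho_range[1], x$rho_range[2]))
  invisible(x)
}

## polynomial reference in the excess-compressibility channel:
## betaP/rho - 1 = sum_k c_k rho^k  =>  beta fex = sum_k c_k rho^k / k
poly_fex_derivs <- function(coefs) {
  k <- seq_along(coefs)
  list(
    f = function(rho) vapply(rho, function(r) sum(coefs * r^k / k), numeric(1)),
    d = function(rho, order) {
      switch(order,
        vapply(rho, function(r) sum(coefs * r^(k - 1)), numeric(1)),
        vapply(rho, function(r) sum(coefs * (k - 1) * r^(k - 2)), numeric(1)),
        vapply(rho, function(r) sum(coefs * (k - 1) * (k - 2) * pmax(r, 0)^(k - 3)), numeric(1))
      )
    }
  )
}

#' Assemble a nanostar free-energy model
#'
#' Builds the total Wertheim free energy per particle
#' `beta f(T, rho) = beta fid + beta fex + beta fb`: ideal gas plus a
#' non-bonding reference excess (virial order 2 or 3, or a thermodynamic
#' integration polynomial fitted to an EOS table) plus the bonding term driven
#' by the sticky-end bond strength `Delta(T, S)`.
#'
#' The default density ceiling is `1.5 rho*` when the salt concentration is
#' one with a tabulated arm length ([nanostar_constants()]), since virial
#' references lose validity around the overlap density.
#'
#' @param reference `"virial2"`, `"virial3"` or `"ti"`.
#' @param B2 Second virial coefficient, nm^3 (all references).
#' @param B3 Third virial coefficient, nm^6 (`"virial3"` only).
#' @param table An [eos_table()] for `reference = "ti"`; interpolated with
#'   the polynomial scheme of [ti_interpolant()] (spline interpolants have no
#'   analytic derivatives and are not usable here).
#' @param ti_order Polynomial order for the TI reference.
#' @param params A [sticky_end_params()].
#' @param salt A [salt_condition()] or bare molarity.
#' @param tail A [tail_correction()].
#' @param valence Number of sticky ends per star (3 or 4).
#' @param v0 Ideal-gas reference volume, nm^3 (cancels in all observables
#'   derived from density derivatives).
#' @param T_range Validity range, K.
#' @param rho_max Density ceiling, nm^-3; defaults to `1.5 * rho*(S)` when
#'   known.
#' @param rho_min Density floor, nm^-3.
#' @return An `fe_model`.
#' @examples
#' m <- free_energy_model("virial2", B2 = 4000, salt = 0.5, valence = 4)
#' pressure(m, 300, 1e-4)
#' @export
free_energy_model <- function(reference = c("virial2", "virial3", "ti"),
                              B2, B3 = 0, table = NULL, ti_order = 3L,
                              params = sticky_end_params(),
                              salt, tail = tail_correction(),
                              valence = 4L, v0 = 1,
                              T_range = c(260, 380),
                              rho_max = NULL, rho_min = 1e-8) {
  reference <- match.arg(reference)
  salt <- as_salt(salt)
  if (B2 <= 0) warn("`B2` <= 0: the reference fluid is expected to be repulsive.")
  ref <- switch(reference,
    virial2 = poly_fex_derivs(B2),
    virial3 = poly_fex_derivs(c(B2, B3)),
    ti = {
      if (is.null(table)) {
        abort("`table` is required for the TI reference.",
              class = "nanostarphase_usage_error")
      }
      interp <- ti_interpolant(table, B2, order = ti_order, method = "poly")
      poly_fex_derivs(interp$coefs)
    })
  if (is.null(rho_max)) {
    consts <- nanostar_constants()
    key <- format(salt$S)
    rho_max <- if (key %in% names(consts$L_arm_nm)) {
      1.5 * overlap_density(consts$L_arm_nm[[key]])
    } else {
      abort("No tabulated arm length for this salt concentration; supply `rho_max`.",
            class = "nanostarphase_usage_error")
    }
  }
  delta_of_T <- function(T_K) bond_strength(T_K, salt, params, tail)
  f_fun <- function(T_K, rho) {
    a <- delta_of_T(T_K) * valence
    f_ideal(rho, v0) + ref$f(rho) +
      bonding_free_energy(bond_fraction(a * rho), valence)
  }
  d_fun <- function(T_K, rho, order) {
    a <- delta_of_T(T_K) * valence
    id <- switch(order, 1 / rho, -1 / rho^2, 2 / rho^3)
    id + ref$d(rho, order) + a^order * bonding_dx(a * rho, valence, order)
  }
  label <- sprintf("%s + Wertheim f=%d, S=%g M%s", reference, valence, salt$S,
                   if (tail$enabled) " (tail on)" else "")
  m <- fe_model(f_fun, d_fun, T_range, c(rho_min, rho_max), label)
  m$meta <- list(reference = reference, B2 = B2, B3 = B3, valence = valence,
                 salt = salt, params = params, tail = tail, v0 = v0)
  m
}

#' Van der Waals free-energy model
#'
#' `beta f = log(rho / (1 - b rho)) - 1 - a rho / T` with kB = 1, whose
#' critical point has the closed form `rho_c = 1/(3b)`, `T_c = 8a/(27b)`.
#' Used as an analytically solvable test bed for the phase solvers.
#'
#' @param a Attraction parameter (energy * volume, kB = 1).
#' @param b Excluded volume per particle.
#' @param T_range,rho_range Validity box; defaults bracket the critical point.
#' @return An `fe_model`.
#' @export
fe_model_vdw <- function(a, b, T_range = NULL, rho_range = NULL) {
  check_positive(a, "a")
  check_positive(b, "b")
  Tc <- 8 * a / (27 * b)
  rc <- 1 / (3 * b)
  if (is.null(T_range)) T_range <- c(0.3 * Tc, 1.5 * Tc)
  if (is.null(rho_range)) rho_range <- c(1e-4 * rc, 2.9 * rc)
  fe_model(
    f_fun = function(T_K, rho) log(rho / (1 - b * rho)) - 1 - a * rho / T_K,
    d_fun = function(T_K, rho, order) {
      switch(order,
        1 / rho + b / (1 - b * rho) - a / T_K,
        -1 / rho^2 + b^2 / (1 - b * rho)^2,
        2 / rho^3 + 2 * b^3 / (1 - b * rho)^3
      )
    },
    T_range = T_range, rho_range = rho_range,
    label = sprintf("van der Waals (a=%g, b=%g)", a, b)
  )
}

in_box <- function(m, T_K, rho, slack = 1e-9) {
  T_K >= m$T_range[1] * (1 - slack) & T_K <= m$T_range[2] * (1 + slack) &
    rho >= m$rho_range[1] * (1 - slack) & rho <= m$rho_range[2] * (1 + slack)
}

require_in_box <- function(m, T_K, rho) {
  if (!all(in_box(m, T_K, rho))) {
    abort(sprintf(
      "Evaluation outside the model validity box (T in [%g, %g] K, rho in [%g, %g] nm^-3).",
      m$T_range[1], m$T_range[2], m$rho_range[1], m$rho_range[2]),
      class = "nanostarphase_range_error")
  }
}

#' Pressure of a free-energy model
#'
#' `beta P = rho^2 d(beta f)/d(rho)` in nm^-3, from the model's analytic
#' derivative.
#'
#' @param model An `fe_model`.
#' @param T_K Temperature, K.
#' @param rho Number density, nm^-3. Vectorized.
#' @return `beta P` in nm^-3.
#' @export
pressure <- function(model, T_K, rho) {
  require_in_box(model, T_K, rho)
  rho^2 * model$d(T_K, rho, 1L)
}

#' Chemical potential of a free-energy model
#'
#' `beta mu = beta f + beta P / rho` (the Gibbs free energy per particle of a
#' one-component phase).
#'
#' @inheritParams pressure
#' @return `beta mu` (dimensionless).
#' @export
chemical_potential <- function(model, T_K, rho) {
  require_in_box(model, T_K, rho)
  model$f(T_K, rho) + rho * model$d(T_K, rho, 1L)
}

## dimensionless residuals of the critical conditions:
## d(betaP)/drho = 2 rho f' + rho^2 f''           (O(1))
## rho * d2(betaP)/drho2 = rho (2 f' + 4 rho f'' + rho^2 f''')
dbetaP_drho <- function(m, T_K, rho) {
  2 * rho * m$d(T_K, rho, 1L) + rho^2 * m$d(T_K, rho, 2L)
}
d2betaP_drho2 <- function(m, T_K, rho) {
  2 * m$d(T_K, rho, 1L) + 4 * rho * m$d(T_K, rho, 2L) + rho^2 * m$d(T_K, rho, 3L)
}

#' Locate the gas-liquid critical point
#'
#' Solves the pair of conditions `dP/drho = 0`, `d2P/drho2 = 0` by
#' multi-start root finding (quasi-Newton via [pracma::fsolve()]) on a grid
#' of initial conditions in the (log rho, T) plane, as densities span several
#' decades. Converged roots are deduplicated and the physical root inside the
#' search ranges with the smallest residual norm (ties broken by smaller
#' rho_c) is returned.
#'
#' @param model An `fe_model`.
#' @param T_range Search range in K (defaults to the model box).
#' @param rho_range Search range in nm^-3 (defaults to the model box).
#' @param n_starts Starts per axis of the initial-condition grid.
#' @param resid_tol Acceptance tolerance on the dimensionless residual pair.
#' @return An object of class `critical_point` with fields `Tc`, `rho_c`,
#'   `betaP_c`, `mu_c`, `residuals` and a tibble `roots` of all distinct
#'   converged roots. Has [tidy()] and [glance()] methods.
#' @examples
#' m <- fe_model_vdw(a = 3, b = 0.1)
#' find_critical_point(m)
#' @export
find_critical_point <- function(model, T_range = model$T_range,
                                rho_range = model$rho_range,
                                n_starts = 12L, resid_tol = 1e-8) {
  T_range <- sort(T_range); rho_range <- sort(rho_range)
  resid <- function(z) {
    rho <- exp(z[1]); T_K <- z[2]
    if (!is.finite(rho) || rho <= 0 || T_K <= 0) return(c(1e6, 1e6))
    r <- c(dbetaP_drho(model, T_K, rho),
           rho * d2betaP_drho2(model, T_K, rho))
    r[!is.finite(r)] <- 1e6
    r
  }
  lr <- seq(log(rho_range[1]), log(rho_range[2]), length.out = n_starts + 2L)[-c(1L, n_starts + 2L)]
  Ts <- seq(T_range[1], T_range[2], length.out = n_starts + 2L)[-c(1L, n_starts + 2L)]
  roots <- list()
  best_resid <- Inf
  for (t0 in Ts) {
    for (l0 in lr) {
      sol <- tryCatch(
        suppressWarnings(pracma::fsolve(resid, c(l0, t0), maxiter = 200, tol = 1e-12)),
        error = function(e) NULL)
      if (is.null(sol)) next
      rn <- max(abs(resid(sol$x)))
      best_resid <- min(best_resid, rn)
      rho_c <- exp(sol$x[1]); Tc <- sol$x[2]
      ok <- rn < resid_tol &&
        Tc >= T_range[1] - 1e-9 && Tc <= T_range[2] + 1e-9 &&
        rho_c >= rho_range[1] * (1 - 1e-9) && rho_c <= rho_range[2] * (1 + 1e-9)
      if (ok) roots[[length(roots) + 1L]] <- c(Tc = Tc, rho_c = rho_c, resid = rn)
    }
  }
  if (length(roots) == 0) {
    abort(sprintf("No critical point found in the search box (best residual %.3e).",
                  best_resid),
          class = "nanostarphase_notfound_error")
  }
  tb <- tibble::as_tibble(do.call(rbind, roots))
  # deduplicate within relative tolerance
  tb <- dplyr::arrange(tb, .data$resid, .data$rho_c)
  keep <- rep(TRUE, nrow(tb))
  for (i in seq_len(nrow(tb))) {
    if (!keep[i]) next
    if (i < nrow(tb)) {
      j <- (i + 1L):nrow(tb)
      dup <- abs(tb$Tc[j] - tb$Tc[i]) < 1e-6 * abs(tb$Tc[i]) + 1e-9 &
        abs(tb$rho_c[j] - tb$rho_c[i]) < 1e-6 * abs(tb$rho_c[i]) + 1e-15
      keep[j][dup] <- FALSE
    }
  }
  tb <- tb[keep, , drop = FALSE]
  Tc <- tb$Tc[1]; rho_c <- tb$rho_c[1]
  structure(
    list(Tc = Tc, rho_c = rho_c,
         betaP_c = rho_c^2 * model$d(Tc, rho_c, 1L),
         mu_c = model$f(Tc, rho_c) + rho_c * model$d(Tc, rho_c, 1L),
         residuals = c(dP = dbetaP_drho(model, Tc, rho_c),
                       d2P = d2betaP_drho2(model, Tc, rho_c)),
         roots = tb, model_label = model$label),
    class = "critical_point"
  )
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("<critical_point>  Tc = %.4f K (%.2f C), rho_c = %.6g nm^-3, betaP_c = %.6g nm^-3\n",
              x$Tc, kelvin_to_celsius(x$Tc), x$rho_c, x$betaP_c))
  if (nrow(x$roots) > 1) {
    cat(sprintf("  (%d distinct converged roots; smallest-residual root reported)\n",
                nrow(x$roots)))
  }
  invisible(x)
}

#' Trace the gas-liquid coexistence curve
#'
#' For each temperature below the critical point, solves the common-tangent
#' conditions `P(rho_gas) = P(rho_liq)` and `mu(rho_gas) = mu(rho_liq)` for
#' the coexisting densities, rejecting the trivial equal-density root. The
#' solution at each temperature seeds the next lower one (continuation), with
#' a grid of initial pairs straddling `rho_c` as fallback.
#'
#' @param model An `fe_model`.
#' @param T_list Temperatures in K, all strictly below `Tc`.
#' @param critical Optional precomputed [find_critical_point()] result.
#' @param resid_tol Acceptance tolerance on the scaled residual pair.
#' @param min_sep Minimum relative separation `(rho_liq - rho_gas) / rho_c`
#'   below which a root is considered trivial.
#' @return A tibble of class `binodal` with columns `T_K`, `T_C`,
#'   `rho_gas_per_nm3`, `rho_liq_per_nm3`, `betaP_per_nm3`, `mu`; temperatures
#'   with no nontrivial root are dropped with a warning. The critical point is
#'   attached as attribute `critical`.
#' @examples
#' m <- fe_model_vdw(a = 3, b = 0.1)
#' cp <- find_critical_point(m)
#' coexistence_curve(m, T_list = cp$Tc * c(0.98, 0.95, 0.9), critical = cp)
#' @export
coexistence_curve <- function(model, T_list, critical = NULL,
                              resid_tol = 1e-8, min_sep = 1e-3) {
  if (is.null(critical)) critical <- find_critical_point(model)
  Tc <- critical$Tc; rho_c <- critical$rho_c
  if (any(T_list >= Tc)) {
    abort(sprintf("All temperatures must be below Tc = %.4f K.", Tc),
          class = "nanostarphase_domain_error")
  }
  Pscale <- max(abs(critical$betaP_c), rho_c, 1e-300)
  ord <- order(T_list, decreasing = TRUE)
  T_sorted <- T_list[ord]
  resid <- function(z, T_K) {
    rg <- exp(z[1]); rl <- exp(z[2])
    if (!is.finite(rg) || !is.finite(rl) || rg <= 0 || rl <= 0 ||
        rl >= model$rho_range[2] * 1.5) return(c(1e6, 1e6))
    d1g <- model$d(T_K, rg, 1L); d1l <- model$d(T_K, rl, 1L)
    r <- c((rg^2 * d1g - rl^2 * d1l) / Pscale,
           (model$f(T_K, rg) + rg * d1g) - (model$f(T_K, rl) + rl * d1l))
    r[!is.finite(r)] <- 1e6
    r
  }
  prev <- NULL
  rows <- list()
  for (T_K in T_sorted) {
    starts <- list()
    if (!is.null(prev)) starts[[1]] <- prev
    # mean-field closure: branches open as ~2 sqrt(1 - T/Tc) around rho_c
    amp <- max(2 * sqrt(max(1 - T_K / Tc, 0)), 4 * min_sep)
    starts[[length(starts) + 1L]] <- log(rho_c * c(1 - amp / (1 + amp), 1 + amp))
    # straddling grid: gas below rho_c, liquid above, widening with quench depth
    for (k in c(1.1, 1.3, 1.8, 2.8, 5, 10, 30)) {
      starts[[length(starts) + 1L]] <- c(log(rho_c / k), log(min(rho_c * k, model$rho_range[2] * 0.95)))
    }
    found <- NULL
    for (z0 in starts) {
      sol <- tryCatch(
        suppressWarnings(pracma::fsolve(function(z) resid(z, T_K), z0,
                                        maxiter = 300, tol = 1e-13)),
        error = function(e) NULL)
      if (is.null(sol)) next
      rg <- exp(min(sol$x)); rl <- exp(max(sol$x))
      rn <- max(abs(resid(log(c(rg, rl)), T_K)))
      # genuine coexistence straddles rho_c; near-degenerate pairs on a
      # spinodal (where P' = mu' = 0) also zero the residuals and must be
      # rejected along with the trivial equal-density root
      if (rn < resid_tol && rg < rho_c && rl > rho_c &&
          (rl - rg) / rho_c > min_sep) {
        found <- c(rg, rl); break
      }
    }
    if (is.null(found)) {
      warn(sprintf("No nontrivial coexistence root found at T = %.4f K.", T_K))
      next
    }
    prev <- log(found)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      T_K = T_K, T_C = kelvin_to_celsius(T_K),
      rho_gas_per_nm3 = found[1], rho_liq_per_nm3 = found[2],
      betaP_per_nm3 = found[1]^2 * model$d(T_K, found[1], 1L),
      mu = model$f(T_K, found[1]) + found[1] * model$d(T_K, found[1], 1L)
    )
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    T_K = numeric(), T_C = numeric(), rho_gas_per_nm3 = numeric(),
    rho_liq_per_nm3 = numeric(), betaP_per_nm3 = numeric(), mu = numeric())
  out <- dplyr::arrange(out, .data$T_K)
  structure(out, critical = critical,
            class = c("binodal", class(out)))
}
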