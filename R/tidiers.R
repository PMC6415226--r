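#' Tidy a B3 fit
#'
#' @param x A `b3_fit` from [fit_B3()].
#' @param ... Unused.
#' @return One-row tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.b3_fit <- function(x, ...) {
  tibble::tibble(term = "B3", estimate = x$B3, std.error = x$std_error)
}

#' @rdname tidy.b3_fit
#' @export
glance.b3_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(
    B2_fixed = x$B2, B3 = x$B3, std.error = x$std_error,
    sigma = sm$sigma, df.residual = x$fit$df.residual,
    nobs = nrow(x$table)
  )
}

#' Tidy a critical point
#'
#' @param x A `critical_point` from [find_critical_point()].
#' @param ... Unused.
#' @return A tibble of all distinct converged roots (first row = reported
#'   root) with columns `Tc_K`, `Tc_C`, `rho_c_per_nm3`, `residual`.
#' @export
tidy.critical_point <- function(x, ...) {
  tibble::tibble(
    Tc_K = x$roots$Tc, Tc_C = kelvin_to_celsius(x$roots$Tc),
    rho_c_per_nm3 = x$roots$rho_c, residual = x$roots$resid
  )
}

#' @rdname tidy.critical_point
#' @export
glance.critical_point <- function(x, ...) {
  tibble::tibble(
    Tc_K = x$Tc, Tc_C = kelvin_to_celsius(x$Tc), rho_c_per_nm3 = x$rho_c,
    betaP_c_per_nm3 = x$betaP_c, mu_c = x$mu_c,
    resid_dP = unname(x$residuals["dP"]),
    resid_d2P = unname(x$residuals["d2P"]),
    n_roots = nrow(x$roots)
  )
}

#' Plot an EOS table
#'
#' Reduced pressure `betaP / rho` against density on a log axis, optionally
#' overlaying a fitted virial curve.
#'
#' @param object An [eos_table()].
#' @param fit Optional `b3_fit` whose curve to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eos_table <- function(object, fit = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$rho_per_nm3,
                                        .data$betaP_per_nm3 / .data$rho_per_nm3)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(rho ~ (nm^-3)),
                  y = expression(beta * P / rho),
                  title = "Reference-fluid equation of state")
  if ("sigma_betaP" %in% names(df)) {
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(
      ymin = (.data$betaP_per_nm3 - .data$sigma_betaP) / .data$rho_per_nm3,
      ymax = (.data$betaP_per_nm3 + .data$sigma_betaP) / .data$rho_per_nm3),
      width = 0)
  }
  if (!is.null(fit)) {
    grid <- tibble::tibble(
      rho_per_nm3 = exp(seq(log(min(df$rho_per_nm3)), log(max(df$rho_per_nm3)),
                            length.out = 200)))
    grid$y <- 1 + fit$B2 * grid$rho_per_nm3 + fit$B3 * grid$rho_per_nm3^2
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(.data$rho_per_nm3, .data$y),
                                linetype = "dashed")
  }
  p
}

#' Plot a binodal
#'
#' Temperature-density coexistence curve with gas and liquid branches and
#' the critical point.
#'
#' @param object A `binodal` tibble from [coexistence_curve()].
#' @param celsius Plot temperature in Celsius (default) or Kelvin.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binodal <- function(object, celsius = TRUE, ...) {
  df <- tibble::as_tibble(object)
  tcol <- if (celsius) "T_C" else "T_K"
  long <- dplyr::bind_rows(
    tibble::tibble(T = df[[tcol]], rho = df$rho_gas_per_nm3, branch = "gas"),
    tibble::tibble(T = df[[tcol]], rho = df$rho_liq_per_nm3, branch = "liquid")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$rho, .data$T, colour = .data$branch)) +
    ggplot2::geom_path() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(rho ~ (nm^-3)),
                  y = if (celsius) "T (°C)" else "T (K)",
                  title = "Gas-liquid coexistence")
  cp <- attr(object, "critical")
  if (!is.null(cp)) {
    cpt <- tibble::tibble(rho = cp$rho_c,
                          T = if (celsius) kelvin_to_celsius(cp$Tc) else cp$Tc)
    p <- p + ggplot2::geom_point(data = cpt, ggplot2::aes(.data$rho, .data$T),
                                 inherit.aes = FALSE, shape = 8, size = 3)
  }
  p
}

#' Pressure isotherms of a free-energy model
#'
#' `betaP(rho)` at one or more temperatures; sub-critical isotherms display
#' the van der Waals loop.
#'
#' @param model An `fe_model`.
#' @param T_K Temperatures, K.
#' @param n Number of densities per isotherm.
#' @return A ggplot.
#' @export
plot_isotherms <- function(model, T_K, n = 300) {
  rho <- exp(seq(log(model$rho_range[1]), log(model$rho_range[2]), length.out = n))
  df <- purrr::map_dfr(T_K, function(tt) tibble::tibble(
    T_K = tt, rho = rho, betaP = pressure(model, tt, rho)))
  ggplot2::ggplot(df, ggplot2::aes(.data$rho, .data$betaP,
                                   colour = factor(.data$T_K))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(rho ~ (nm^-3)), y = expression(beta * P ~ (nm^-3)),
                  colour = "T (K)")
}
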