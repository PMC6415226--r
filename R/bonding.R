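#' Fraction of formed bonds from the mass-action law
#'
#' For f identical sticky ends per star the law of mass action gives the bond
#' probability `pb` as the physical root of `pb = x (1 - pb)^2` with
#' `x = Delta * f * rho`. The naive closed form is 0/0 at x = 0; the
#' cancellation-free rearrangement `pb = 4x / (1 + sqrt(1 + 4x))^2`
#' (equivalently `1 - pb = 2 / (1 + sqrt(1 + 4x))`) keeps full relative
#' precision from the dilute limit up to saturation.
#'
#' @param x Dimensionless bonding strength `Delta * f * rho` (>= 0). Vectorized.
#' @param complement Return `1 - pb` instead of `pb`; the complement is the
#'   accurate quantity near saturation (`pb -> 1`).
#' @return Bond fraction in `[0, 1)` (or its complement in `(0, 1]`).
#' @examples
#' bond_fraction(c(0, 2, 6)) # 0, 1/2, 2/3
#' @export
bond_fraction <- function(x, complement = FALSE) {
  check_nonnegative(x, "x")
  s1 <- 1 + sqrt(1 + 4 * x)
  if (complement) 2 / s1 else 4 * x / s1^2
}

#' Wertheim bonding free energy per particle
#'
#' `beta fb = f * (log(1 - pb) + pb / 2)` for f identical bonding sites, in
#' units of kB*T per particle. Non-positive on `[0, 1)` and vanishing as
#' `pb -> 0`.
#'
#' @param pb Bond fraction in `[0, 1)`. Vectorized.
#' @param f Valence (number of arms, typically 3 or 4).
#' @return Bonding free energy per particle in kB*T units.
#' @examples
#' bonding_free_energy(0.5, f = 4)
#' @export
bonding_free_energy <- function(pb, f) {
  check_nonnegative(pb, "pb")
  if (any(pb >= 1)) {
    abort("`pb` must be < 1.", class = "nanostarphase_domain_error")
  }
  f * (log1p(-pb) + pb / 2)
}

## Derivatives of beta*fb with respect to x = Delta*f*rho, obtained by
## implicit differentiation of pb = x (1 - pb)^2. With s = sqrt(1 + 4x):
##   d(bfb)/dx   = -f (1 - pb)^2 / 2 = -2 f / (1 + s)^2
##   d2(bfb)/dx2 =  8 f / (s (1 + s)^3)
##   d3(bfb)/dx3 = -16 f (1 + 4 s) / (s^3 (1 + s)^4)
bonding_dx <- function(x, f, order = 1L) {
  s <- sqrt(1 + 4 * x)
  switch(order,
    -2 * f / (1 + s)^2,
    8 * f / (s * (1 + s)^3),
    -16 * f * (1 + 4 * s) / (s^3 * (1 + s)^4)
  )
}

#' Density derivative of the bonding free energy
#'
#' Analytic `d(beta fb)/d(rho)` obtained by implicit differentiation of the
#' mass-action law; needed because the pressure is `rho^2 d(beta f)/d(rho)`.
#' In the dilute limit it tends to `-f^2 Delta / 2` (each of the f ends gains
#' half a bond's worth of free energy per partner at density `rho`).
#'
#' @param delta Bond strength in nm^3 (>= 0).
#' @param f Valence.
#' @param rho Number density in nm^-3 (>= 0). Vectorized.
#' @param order Derivative order in rho: 1, 2 or 3.
#' @return Derivative in nm^3 (order 1), nm^6 (order 2) or nm^9 (order 3).
#' @examples
#' bonding_free_energy_drho(1e5, 4, 1e-4)
#' @export
bonding_free_energy_drho <- function(delta, f, rho, order = 1L) {
  check_nonnegative(delta, "delta")
  check_nonnegative(rho, "rho")
  order <- as.integer(order)
  if (!order %in% 1:3) {
    abort("`order` must be 1, 2 or 3.", class = "nanostarphase_usage_error")
  }
  a <- delta * f
  a^order * bonding_dx(a * rho, f, order)
}
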