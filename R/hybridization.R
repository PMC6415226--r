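#' Sticky-end thermochemical parameters
#'
#' Bundles the pre-summed nearest-neighbor hybridization thermochemistry of a
#' sticky-end sequence together with the reference volume used to convert the
#' hybridization free energy into a bond-strength volume. The defaults are the
#' values for a 6-nt self-complementary sticky end flanked by unpaired
#' nucleotides, the sequence used throughout the package examples.
#'
#' @param delta_H Hybridization enthalpy, cal/mol. Negative for a binding
#'   sequence.
#' @param delta_S_nosalt Salt-independent hybridization entropy, cal/(mol K).
#'   Negative for a binding sequence.
#' @param L_DNA Number of nucleotides entering the salt-entropy rule
#'   (integer, >= 1).
#' @param v_b Reference volume of the non-bonded single strands, nm^3.
#' @return An object of class `sticky_end_params`.
#' @examples
#' sticky_end_params()
#' @export
sticky_end_params <- function(delta_H = -54000,
                              delta_S_nosalt = -151.99,
                              L_DNA = 6L,
                              v_b = 1.6606) {
  check_positive(v_b, "v_b")
  L_DNA <- as.integer(L_DNA)
  if (is.na(L_DNA) || L_DNA < 1L) {
    abort("`L_DNA` must be an integer >= 1.", class = "nanostarphase_domain_error")
  }
  if (delta_H >= 0 || delta_S_nosalt >= 0) {
    warn("`delta_H` and `delta_S_nosalt` are expected to be negative for a binding sequence.")
  }
  structure(
    list(delta_H = delta_H, delta_S_nosalt = delta_S_nosalt,
         L_DNA = L_DNA, v_b = v_b),
    class = "sticky_end_params"
  )
}

#' @export
print.sticky_end_params <- function(x, ...) {
  cat("<sticky_end_params>\n")
  cat(sprintf("  delta_H        %10.1f cal/mol\n", x$delta_H))
  cat(sprintf("  delta_S_nosalt %10.2f cal/(mol K)\n", x$delta_S_nosalt))
  cat(sprintf("  L_DNA          %10d nt\n", x$L_DNA))
  cat(sprintf("  v_b            %10.4f nm^3\n", x$v_b))
  invisible(x)
}

#' Monovalent salt condition
#'
#' @param S Molar salt concentration, mol/L. Must be positive; multivalent
#'   salts are not supported by the underlying entropy rule.
#' @return An object of class `salt_condition`.
#' @export
salt_condition <- function(S) {
  check_positive(S, "S")
  structure(list(S = S), class = "salt_condition")
}

#' Electrostatic tail correction to the hybridization free energy
#'
#' Sticky ends attached to a charged nanostar body feel an extra electrostatic
#' repulsion from the flanking arms, which weakens hybridization most at low
#' salt. The correction is parameterized as an enthalpy shift plus a
#' salt-dependent entropy shift `ddS(S) = ddS_a + ddS_b * log(S)`, mirroring
#' the functional form of the salt-entropy rule. Disabled by default and then
#' contributes exactly zero.
#'
#' @param enabled Logical flag; when `FALSE` the correction is exactly zero.
#' @param ddH Enthalpy shift, cal/mol (positive = extra repulsion).
#' @param ddS_a,ddS_b Coefficients of the entropy shift in cal/(mol K):
#'   `ddS(S) = ddS_a + ddS_b * log(S)`.
#' @return An object of class `tail_correction`.
#' @export
tail_correction <- function(enabled = FALSE, ddH = 0, ddS_a = 0, ddS_b = 0) {
  structure(
    list(enabled = isTRUE(enabled), ddH = ddH, ddS_a = ddS_a, ddS_b = ddS_b),
    class = "tail_correction"
  )
}

as_salt <- function(salt) {
  if (inherits(salt, "salt_condition")) return(salt)
  salt_condition(salt)
}

#' Salt-dependent hybridization entropy
#'
#' The SantaLucia monovalent-salt entropy correction
#' `0.368 * (L_DNA - 1) * log(S)` in cal/(mol K). Zero at 1 M, negative below.
#'
#' @param S Molar salt concentration, mol/L (> 0).
#' @param L_DNA Number of nucleotides in the salt rule (integer >= 1).
#' @return Entropy correction in cal/(mol K).
#' @examples
#' salt_entropy(0.05, 6) # -5.51 cal/(mol K)
#' @export
salt_entropy <- function(S, L_DNA) {
  check_positive(S, "S")
  0.368 * (L_DNA - 1) * log(S)
}

tail_terms <- function(tail, S) {
  if (!inherits(tail, "tail_correction")) {
    abort("`tail` must be a tail_correction object.", class = "nanostarphase_usage_error")
  }
  if (!tail$enabled) return(list(ddH = 0, ddS = 0))
  list(ddH = tail$ddH, ddS = tail$ddS_a + tail$ddS_b * log(S))
}

#' Sticky-end hybridization free energy
#'
#' `dG(T, S) = dH - T * (dS_nosalt + dS_salt(S))` in cal/mol, with optional
#' electrostatic tail corrections added to the enthalpy and entropy when
#' enabled.
#'
#' @param T_K Temperature in Kelvin (> 0). Vectorized.
#' @param salt A [salt_condition()] or a bare molar concentration.
#' @param params A [sticky_end_params()].
#' @param tail A [tail_correction()]; default disabled.
#' @return Free energy in cal/mol (negative favours bonding).
#' @examples
#' hybridization_dG(300, salt_condition(1), sticky_end_params())
#' @export
hybridization_dG <- function(T_K, salt, params = sticky_end_params(),
                             tail = tail_correction()) {
  check_positive(T_K, "T_K")
  salt <- as_salt(salt)
  tc <- tail_terms(tail, salt$S)
  dH <- params$delta_H + tc$ddH
  dS <- params$delta_S_nosalt + salt_entropy(salt$S, params$L_DNA) + tc$ddS
  dH - T_K * dS
}

#' Bond-strength volume
#'
#' The mass-action bond strength `Delta = v_b * exp(-dG / (R T))` in nm^3,
#' the single quantity through which temperature, salt and sequence enter the
#' bonding free energy. Evaluated in log space with a clamped exponent so that
#' deeply bonded (low-temperature) states do not overflow.
#'
#' @inheritParams hybridization_dG
#' @return Bond strength in nm^3 (strictly positive).
#' @examples
#' bond_strength(300, salt_condition(0.5))
#' @export
bond_strength <- function(T_K, salt, params = sticky_end_params(),
                          tail = tail_correction()) {
  dG <- hybridization_dG(T_K, salt, params, tail)
  log_delta <- log(params$v_b) - dG / (R_CAL * T_K)
  # ~1e300 ceiling: beyond this the bond fraction is 1 to machine precision
  exp(pmin(log_delta, 690))
}

#' Melting temperature of the sticky end
#'
#' The temperature at which the hybridization free energy vanishes,
#' `Tm = dH / (dS_nosalt + dS_salt)` (tail corrections included when enabled).
#'
#' @inheritParams hybridization_dG
#' @return Melting temperature in Kelvin.
#' @examples
#' melting_temperature(salt_condition(1)) # 355.3 K for the default sticky end
#' @export
melting_temperature <- function(salt, params = sticky_end_params(),
                                tail = tail_correction()) {
  salt <- as_salt(salt)
  tc <- tail_terms(tail, salt$S)
  dS <- params$delta_S_nosalt + salt_entropy(salt$S, params$L_DNA) + tc$ddS
  if (abs(dS) < .Machine$double.eps * abs(params$delta_S_nosalt + 1)) {
    abort("Total entropy change is zero; melting temperature is singular.",
          class = "nanostarphase_singular_error")
  }
  (params$delta_H + tc$ddH) / dS
}
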