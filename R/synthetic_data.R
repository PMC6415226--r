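#' Specification of a synthetic reference-fluid EOS
#'
#' Defines the ground truth and noise model of a synthetic pressure-density
#' table standing in for bulk simulations of the non-bonding reference fluid.
#' The default grid is 8 log-spaced densities spanning three decades below
#' the overlap density, matching how few state points suffice when the
#' reference pressure is a convex, virial-like function of density.
#'
#' @param B2_true Ground-truth second virial coefficient, nm^3.
#' @param B3_true Ground-truth third virial coefficient, nm^6.
#' @param B4_true Optional quartic coefficient (nm^9) for model-mismatch
#'   studies; default 0.
#' @param rho_grid Density grid, nm^-3; default 8 log-spaced points over
#'   three decades up to `rho_max`.
#' @param rho_max Upper end of the default grid, nm^-3.
#' @param noise_rel Relative (multiplicative) noise on `betaP`; simulation
#'   pressure uncertainty scales with its magnitude across the density
#'   decades. Set `additive = TRUE` for absolute noise of the same nominal
#'   size instead.
#' @param additive Use additive instead of multiplicative noise.
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `synthetic_eos_spec`.
#' @export
synthetic_eos_spec <- function(B2_true, B3_true, B4_true = 0,
                               rho_grid = NULL, rho_max = 4e-4,
                               noise_rel = 0.01, additive = FALSE,
                               seed = 1L) {
  if (is.null(rho_grid)) {
    rho_grid <- 10^seq(log10(rho_max) - 3, log10(rho_max), length.out = 8)
  }
  check_positive(rho_grid, "rho_grid")
  if (any(diff(rho_grid) <= 0)) {
    abort("`rho_grid` must be strictly increasing.", class = "nanostarphase_usage_error")
  }
  check_nonnegative(noise_rel, "noise_rel")
  structure(
    list(B2_true = B2_true, B3_true = B3_true, B4_true = B4_true,
         rho_grid = rho_grid, noise_rel = noise_rel,
         additive = isTRUE(additive), seed = as.integer(seed)),
    class = "synthetic_eos_spec"
  )
}

#' Generate a synthetic EOS table
#'
#' Evaluates `betaP = rho + B2 rho^2 + B3 rho^3 (+ B4 rho^4)` on the spec's
#' density grid and perturbs each point with seeded multiplicative Gaussian
#' noise `(1 + noise_rel * z)`. The `sigma_betaP` column records the nominal
#' 1-sigma uncertainty `noise_rel * betaP`.
#'
#' @param spec A [synthetic_eos_spec()].
#' @param T_K Temperature metadata, K.
#' @param S Salt concentration metadata, mol/L.
#' @param f Valence metadata.
#' @return An [eos_table()].
#' @examples
#' spec <- synthetic_eos_spec(B2_true = 4000, B3_true = 2e6, noise_rel = 0)
#' generate_eos_table(spec, T_K = 293.15, S = 0.5)
#' @export
generate_eos_table <- function(spec, T_K = NA_real_, S = NA_real_, f = 4L) {
  if (!inherits(spec, "synthetic_eos_spec")) {
    abort("`spec` must be a synthetic_eos_spec.", class = "nanostarphase_usage_error")
  }
  rho <- spec$rho_grid
  betaP <- rho + spec$B2_true * rho^2 + spec$B3_true * rho^3 + spec$B4_true * rho^4
  sigma <- NULL
  if (spec$noise_rel > 0) {
    z <- withr::with_seed(spec$seed, rnorm(length(rho)))
    if (spec$additive) {
      # constant absolute noise sized from the smallest pressure, so the
      # dilute points (3 decades below the densest) are not swamped
      sigma <- rep(spec$noise_rel * min(betaP), length(rho))
      betaP <- betaP + sigma * z
    } else {
      sigma <- spec$noise_rel * betaP
      betaP <- betaP * (1 + spec$noise_rel * z)
    }
    if (any(betaP <= 0)) {
      abort("Noise drove a pressure non-positive; reduce `noise_rel`.",
            class = "nanostarphase_numerical_error")
    }
  }
  eos_table(rho, betaP, sigma_betaP = sigma, T_K = T_K, S = S, f = f)
}

#' Nucleotide bookkeeping for a nanostar system
#'
#' Total nucleotide count of `n_stars` stars of valence `f` built from one
#' strand per arm of `strand_length` nucleotides:
#' `n_stars * f * strand_length`.
#'
#' @param f Valence (strands per star).
#' @param n_stars Number of stars.
#' @param strand_length Nucleotides per strand.
#' @return Integer nucleotide count.
#' @examples
#' total_nucleotides(f = 4, n_stars = 250, strand_length = 49) # 49000
#' @export
total_nucleotides <- function(f, n_stars, strand_length) {
  check_positive(f, "f"); check_positive(n_stars, "n_stars")
  check_positive(strand_length, "strand_length")
  as.integer(n_stars) * as.integer(f) * as.integer(strand_length)
}

#' Physical constants of the reference nanostar system
#'
#' Immutable registry of the measured constants used throughout the package:
#' salt-dependent arm lengths of the tetravalent/trivalent nanostar (nm),
#' the default sticky-end thermochemistry, and the supported valences.
#' Modifying the returned object raises an error.
#'
#' @return A locked list of class `nanostar_constants` with elements
#'   `L_arm_nm` (named by molar salt), `sticky_end`, `valences`.
#' @examples
#' nanostar_constants()$L_arm_nm[["0.2"]] # 8.93 nm
#' @export
nanostar_constants <- function() {
  structure(
    list(
      L_arm_nm = c("0.05" = 9.70, "0.2" = 8.93, "0.5" = 8.72),
      sticky_end = sticky_end_params(),
      valences = c(3L, 4L)
    ),
    class = "nanostar_constants"
  )
}

#' @export
`$<-.nanostar_constants` <- function(x, name, value) {
  abort("nanostar_constants is an immutable registry.",
        class = "nanostarphase_immutable_error")
}

#' @export
`[[<-.nanostar_constants` <- function(x, i, value) {
  abort("nanostar_constants is an immutable registry.",
        class = "nanostarphase_immutable_error")
}

#' @export
`[<-.nanostar_constants` <- function(x, i, value) {
  abort("nanostarphase constants are an immutable registry.",
        class = "nanostarphase_immutable_error")
}

#' Synthetic per-salt virial coefficients
#'
#' Plausible stand-in virial coefficients for demonstration workflows,
#' scaled from the overlap volume at each tabulated salt concentration:
#' `B2 = 1.5 / rho*(S)` and `B3 = 0.3 / rho*(S)^2`. These are synthetic
#' defaults — the reference-fluid virial coefficients of a real system are
#' inputs to be measured or supplied — but they have the right magnitude and
#' salt ordering (larger stars at lower salt are more repulsive).
#'
#' @param S Molar salt concentration; must be one of 0.05, 0.2, 0.5.
#' @return A list with `B2` (nm^3) and `B3` (nm^6).
#' @examples
#' synthetic_virial_defaults(0.5)
#' @export
synthetic_virial_defaults <- function(S) {
  consts <- nanostar_constants()
  key <- format(S)
  if (!key %in% names(consts$L_arm_nm)) {
    abort("No synthetic defaults for this salt; supply B2/B3 explicitly.",
          class = "nanostarphase_usage_error")
  }
  rs <- overlap_density(consts$L_arm_nm[[key]])
  list(B2 = 1.5 / rs, B3 = 0.3 / rs^2)
}
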