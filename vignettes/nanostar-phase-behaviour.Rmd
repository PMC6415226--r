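---
title: "Predicting the phase behaviour of DNA nanostar fluids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the phase behaviour of DNA nanostar fluids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanostarphase)
```

## The model

DNA nanostars are branched constructs of `f` single strands (here `f = 3` or
`4`) that self-assemble into `f` stiff double-stranded arms, each tipped with
a short self-complementary single-stranded *sticky end*. Sticky-end
hybridization bonds stars to each other, and at low enough temperature the
solution separates into a dilute gas of stars and a bonded liquid network.

The package predicts this gas–liquid transition with Wertheim thermodynamic
perturbation theory (TPT). The Helmholtz free energy per particle splits into
a non-bonding reference part and a bonding part:

$$\beta \bar f(T, \rho) = \underbrace{\ln(v_0\rho) - 1}_{\text{ideal}}
  + \beta f_\mathrm{ex}(T,\rho) + \beta f_b(T,\rho),$$

where the reference fluid is the same construct with scrambled sticky ends
(purely repulsive), and the bonding term for `f` identical sites is

$$\beta f_b = f\left[\ln(1 - p_b) + \tfrac{p_b}{2}\right],$$

with the bond fraction `p_b` given by the law of mass action
$p_b = x (1-p_b)^2$, $x = \Delta f \rho$. A note on this form: one sometimes
sees the $\tfrac12 p_b$ term written outside the factor `f`; the form with
`f` multiplying both terms is the standard first-order TPT result for `f`
identical sites and is the one that reduces correctly in the dilute and
single-site limits, so it is what `bonding_free_energy()` implements.

All of the chemistry enters through the bond-strength volume

$$\Delta = v_b\, e^{-\beta\Delta G},\qquad
  \Delta G = \Delta H - T\left[\Delta S_\mathrm{nosalt}
  + 0.368\,(L_\mathrm{DNA}-1)\ln S\right],$$

the nearest-neighbor (SantaLucia-style) hybridization free energy of the
sticky end with the monovalent-salt entropy correction. The packaged defaults
(`sticky_end_params()`) are the pre-summed values for a 6-nt
self-complementary sticky end: $\Delta H = -54{,}000$ cal/mol,
$\Delta S_\mathrm{nosalt} = -151.99$ cal/(mol·K), $L_\mathrm{DNA} = 6$,
$v_b = 1.6606\ \mathrm{nm}^3$. We treat these as molar quantities and use
$R = 1.98720$ cal/(mol·K) in $\beta$, which is the convention under which
these magnitudes are tabulated. Per-sequence nearest-neighbor summation is
out of scope: the aggregate $(\Delta H, \Delta S)$ is an input.

An optional *tail correction* (`tail_correction()`) models the extra
electrostatic repulsion that the charged nanostar body exerts on the sticky
ends, which weakens hybridization mostly at low salt. It is parameterized as
an enthalpy shift plus an entropy shift $a + b\ln S$, mirroring the salt
rule; it defaults to off, and precise coefficient values are left to the
user because they depend on construct geometry and are not settled
quantities. Multivalent salts are unsupported throughout.

## The reference free energy

Three interchangeable references are offered (`free_energy_model()`):

* **virial-order-2**: $\beta f_\mathrm{ex} = B_2\rho$. `B2` is an input —
  either measured, computed from an effective pair potential with
  `second_virial()`, or taken from the synthetic defaults below.
* **virial-order-3**: $\beta f_\mathrm{ex} = B_2\rho + \tfrac12 B_3\rho^2$,
  with `B3` typically obtained by `fit_B3()`: a least-squares fit of
  $\beta P = \rho + B_2\rho^2 + B_3\rho^3$ to a pressure–density table with
  `B2` held fixed, weighted by $1/\sigma^2$ when uncertainties are present.
* **TI**: thermodynamic integration of a tabulated equation of state,
  $\beta f_\mathrm{ex}(\rho) = \int_0^\rho [\beta P(\rho') - \rho']/\rho'^2\,
  d\rho'$. The additive integration constant of this route is set to zero:
  it is independent of density, so it cannot affect pressures,
  chemical-potential differences, or phase boundaries.

For TI the table is interpolated in the *excess-compressibility channel*:
$\beta P/\rho - 1$ is fitted by a polynomial $\sum_k c_k \rho^k$ whose linear
coefficient is pinned to `B2`. This makes the $\rho \to 0$ limit of the
integrand exact (it is `B2`) and gives the integral in closed form,
$\beta f_\mathrm{ex} = \sum_k c_k\rho^k/k$. The default order is 3. A
monotone Hyman-spline interpolant is available behind
`ti_interpolant(..., method = "spline")` for tables a low-order polynomial
cannot follow; its integral is evaluated by adaptive quadrature, and because
splines do not provide trustworthy third derivatives the spline route is for
free-energy evaluation only, not for building phase-solver models.

Virial-based references are trusted only up to about the overlap density
$\rho^* = 3/(4\pi L_\mathrm{arm}^3)$, where stars begin to interpenetrate
and an effective pair description degrades; the model's validity ceiling
defaults to $1.5\rho^*$ at the three tabulated salt conditions
($L_\mathrm{arm} = 9.70, 8.93, 8.72$ nm at $S = 0.05, 0.2, 0.5$ M;
`nanostar_constants()`). Critical points land well below $\rho^*$, which is
why the simple virial routes work at all.

## Phase solvers

Pressure and chemical potential follow from the analytic density
derivatives: $\beta P = \rho^2\,\partial_\rho(\beta\bar f)$ and
$\beta\mu = \beta\bar f + \beta P/\rho$. The critical point solves
$\partial_\rho P = \partial^2_\rho P = 0$, which involves *third*
derivatives of $\bar f$ — the reason every term carries analytic
derivatives (the bonding ones via implicit differentiation of the
mass-action law) and finite differences appear only as test oracles. Every
model verifies its derivative contract against central finite differences at
construction.

`find_critical_point()` runs a quasi-Newton root search from a grid of
starts (default 12×12) in the $(\ln\rho, T)$ plane — logarithmic density
because candidate densities span decades. Converged roots are deduplicated
at $10^{-6}$ relative; the in-range root with the smallest residual norm
wins, ties broken toward smaller $\rho_c$, and all distinct roots are kept
in the result (`tidy()` shows them). Acceptance requires the dimensionless
residual pair $(\partial_\rho\beta P,\ \rho\,\partial^2_\rho\beta P)$ below
$10^{-8}$.

`coexistence_curve()` solves $P_1 = P_2$, $\mu_1 = \mu_2$ in
$(\ln\rho_\mathrm{gas}, \ln\rho_\mathrm{liq})$ at each temperature below
$T_c$, seeding each temperature with the previous solution (descending
continuation stabilizes deep quenches). Fresh starts combine a mean-field
closure estimate — branches open as $\sim 2\sqrt{1 - T/T_c}$ around
$\rho_c$ — with a widening straddle grid. The trivial equal-density root is
rejected when the branch separation falls below $10^{-3}\rho_c$. Pressure
equality is scaled by $\beta P_c$ so both residuals are order one.

The ideal-gas reference volume `v0` shifts $\beta\mu$ by a constant and
cancels from every phase-boundary condition; a test asserts the critical
point is identical for `v0 = 1` and `v0 = 1.6606`.

## Numerical choices

* **Bond fraction.** The textbook closed form for `p_b` is 0/0 at $x = 0$
  and loses all relative precision for small $x$ if written as
  $1 - 2/(1+\sqrt{1+4x})$. `bond_fraction()` uses the rearrangement
  $p_b = 4x/(1+\sqrt{1+4x})^2$, exact in relative terms over the whole
  range, and exposes the complement $1-p_b = 2/(1+\sqrt{1+4x})$, the
  accurate quantity near saturation. With these two forms the mass-action
  identity holds to a few $10^{-16}$ relative over twenty decades of $x$.
* **Bond strength.** $\Delta$ is evaluated as the exponential of a clamped
  log-space argument so that deep cooling cannot overflow.
* **Quadrature.** `second_virial()` uses adaptive quadrature with an
  absolute tolerance defaulting to $10^{-10} r_\mathrm{max}^3$, accepts
  breakpoints at potential discontinuities (hard cores, well edges), and
  warns when the integrand has not decayed at `r_max`.
* **Degenerate inputs** raise classed conditions
  (`nanostarphase_domain_error`, `_range_error`, `_usage_error`,
  `_notfound_error`, ...) so callers can react programmatically.

## The synthetic EOS generator

`generate_eos_table()` stands in for the expensive bulk simulations that
would normally measure the reference pressure. It emulates their data
*structure*: because the scrambled-sticky-end fluid is purely repulsive, its
$\beta P(\rho)$ is convex and virial-like, so eight log-spaced state points
spanning three density decades characterize it. Ground truth is
$\beta P = \rho + B_2\rho^2 + B_3\rho^3$ (optionally a $B_4$ term for
model-mismatch studies), and each point gets seeded multiplicative Gaussian
noise $(1 + \epsilon z)$ with $\sigma$ recorded — multiplicative because
simulation pressure uncertainty scales with the pressure across decades. An
additive mode exists behind a flag, with constant $\sigma$ sized from the
smallest pressure so dilute points are not swamped.

What the generator does **not** emulate: correlated sampling errors,
finite-size effects, the breakdown of pair additivity in the semi-dilute
regime, or any temperature/salt dependence of the true virial coefficients.
Tests that pass on synthetic tables therefore validate the *estimators and
solvers*, not the fidelity of any particular simulation data set.

The demonstration virial coefficients (`synthetic_virial_defaults()`) are
likewise synthetic: scaled once from the overlap volume as
$B_2 = 1.5/\rho^*(S)$ and $B_3 = 0.3/\rho^{*2}(S)$. The prefactors were
chosen as physically plausible for soft, star-like repulsive particles
(excluded volume of order the overlap volume; $B_3/B_2^2 \approx 0.13$,
softer than hard spheres) and give critical points in the tens-of-°C range
with the default thermochemistry. Real applications should supply measured
or fitted coefficients.

## Problem sizes and runtimes

The shipped tests exercise: a $10^6$-point mass-action sweep; 100-seed B3
recovery at 1% noise on 8-point tables; critical points on van der Waals
(closed form) and on the demonstration tetramer, cross-checked by a
brute-force bisection oracle that detects loss of isotherm monotonicity on a
4000-point density grid to 0.02 K; and binodals of a handful of temperatures
per model, cross-checked against a Maxwell equal-area construction evaluated
from the exact van der Waals antiderivative. The full suite runs in well
under a minute.

## Known limitations

* Wertheim TPT at this order systematically underestimates critical
  densities for low-valence patchy particles; trends in $T_c$ and the
  topology of the phase diagram are more trustworthy than $\rho_c$ itself.
* No bond loops, intra-star bonding, spinodals, interfacial tensions, or
  finite-size corrections.
* The salt-entropy rule and the tail-correction form are monovalent-salt
  extrapolations; behaviour outside roughly 0.05–1 M is untested.
* Quantities above the validity ceiling ($1.5\rho^*$ by default) are
  refused rather than extrapolated.

## A worked example

```{r example, eval = FALSE}
library(nanostarphase)

# synthetic "measured" EOS at 20 C, 0.5 M, tetramers
dft <- synthetic_virial_defaults(0.5)
spec <- synthetic_eos_spec(dft$B2, dft$B3, noise_rel = 0.01, seed = 7)
tbl <- generate_eos_table(spec, T_K = celsius_to_kelvin(20), S = 0.5, f = 4)

# recover B3 with B2 held fixed, then build the order-3 model
fit <- fit_B3(tbl, B2 = dft$B2)
model <- free_energy_model("virial3", B2 = dft$B2, B3 = fit$B3,
                           salt = 0.5, valence = 4)

cp <- find_critical_point(model)
binodal <- coexistence_curve(model, T_list = seq(cp$Tc - 0.5, cp$Tc - 8, by = -0.5),
                             critical = cp)
autoplot(binodal)
```
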