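test_that("second virial quadrature matches hard-sphere and square-well closed forms", {
  sigma <- 1
  hs <- function(r) ifelse(r < sigma, Inf, 0)
  expect_equal(second_virial(hs, r_max = 4, breaks = sigma),
               2 * pi / 3 * sigma^3, tolerance = 1e-8)
  expect_equal(second_virial(function(r) 0 * r, r_max = 4), 0, tolerance = 1e-12)
  # square well, attractive: B2 can go negative for deep wells
  sw <- function(sig, lam, eps) function(r) {
    ifelse(r < sig, Inf, ifelse(r < lam * sig, -eps, 0))
  }
  cases <- expand.grid(sig = c(0.8, 1.2), lam = c(1.3, 1.8), eps = c(0.3, 1.5))
  for (i in seq_len(nrow(cases))) {
    sg <- cases$sig[i]; lm <- cases$lam[i]; ep <- cases$eps[i]
    expect_equal(
      second_virial(sw(sg, lm, ep), r_max = 5, breaks = c(sg, lm * sg)),
      square_well_B2(sg, lm, ep), tolerance = 1e-8)
  }
})

test_that("second virial is invariant under r_max once the tail has decayed", {
  lj_rep <- function(r) (0.5 / r)^18 # steep repulsion, fast decay
  b1 <- second_virial(lj_rep, r_max = 5)
  b2 <- second_virial(lj_rep, r_max = 10)
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("B3 fit is exact on noiseless tables and errors on short input", {
  B2 <- 4000; B3 <- 2.3e6
  rho <- 10^seq(-7, -3.4, length.out = 8)
  tb <- eos_table(rho, rho + B2 * rho^2 + B3 * rho^3)
  fit <- fit_B3(tb, B2)
  expect_equal(fit$B3, B3, tolerance = 1e-10)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$estimate, fit$B3)
  expect_error(fit_B3(structure(tb[1:2, ], class = class(tb)), B2),
               class = "nanostarphase_insufficient_data_error")
})

test_that("B3 recovery from noisy tables is unbiased and calibrated", {
  B2 <- 4000; B3_true <- 2.3e6
  ests <- numeric(100); ses <- numeric(100)
  for (s in 1:100) {
    spec <- synthetic_eos_spec(B2, B3_true, noise_rel = 0.01, seed = s)
    fit <- fit_B3(generate_eos_table(spec), B2)
    ests[s] <- fit$B3; ses[s] <- fit$std_error
  }
  # mean recovered B3 within 2 standard errors (of the mean) of truth
  expect_lt(abs(mean(ests) - B3_true), 2 * sd(ests) / sqrt(100))
  # with B3_true = 0 the fit should not pretend significance
  hits <- 0
  for (s in 1:100) {
    spec <- synthetic_eos_spec(B2, 0, noise_rel = 0.01, seed = 1000 + s)
    fit <- fit_B3(generate_eos_table(spec), B2)
    if (abs(fit$B3) < fit$std_error) hits <- hits + 1
  }
  expect_gte(hits, 60) # |t| < 1 expected ~68% of the time
})

test_that("virial excess free energy evaluates its truncations", {
  expect_identical(fex_virial(0, 1, 2), 0)
  expect_equal(fex_virial(0.5, B2 = 1, B3 = 2, order = 3), 0.75)
  rho <- c(1e-5, 1e-4)
  expect_equal(fex_virial(rho, 3000, 0, order = 3),
               fex_virial(rho, 3000, 0, order = 2))
  expect_error(fex_virial(0.1, 1, 1, order = 4), class = "nanostarphase_usage_error")
})

test_that("TI of an exact virial table reproduces the virial excess free energy", {
  B2 <- 4000; B3 <- 2.3e6
  rho <- 10^seq(-7, -3.4, length.out = 8)
  tb <- eos_table(rho, rho + B2 * rho^2 + B3 * rho^3)
  expect_equal(fex_TI(tb, rho, B2 = B2),
               fex_virial(rho, B2, B3, order = 3), tolerance = 1e-8)
  # ideal-gas table integrates to zero
  tb_id <- eos_table(rho, rho * (1 + 1e-14)) # betaP = rho (positivity-safe)
  expect_equal(fex_TI(tb_id, rho, B2 = 0), rep(0, length(rho)), tolerance = 1e-10)
  expect_error(fex_TI(tb, max(rho) * 2, B2 = B2),
               class = "nanostarphase_range_error")
})

test_that("TI is zero at the origin, increasing, and exceeds the order-2 virial", {
  B2 <- 4000; B3 <- 2.3e6
  rho <- 10^seq(-7, -3.4, length.out = 8)
  tb <- eos_table(rho, rho + B2 * rho^2 + B3 * rho^3)
  expect_identical(fex_TI(tb, 0, B2 = B2), 0)
  vals <- fex_TI(tb, rho, B2 = B2)
  expect_true(all(diff(vals) > 0))
  # the third virial term raises the excess free energy above order 2
  expect_true(all(vals > fex_virial(rho, B2, order = 2)))
})

test_that("TI through the monotone spline agrees with the polynomial route on smooth tables", {
  B2 <- 4000; B3 <- 2.3e6
  rho <- 10^seq(-7, -3.4, length.out = 10)
  tb <- eos_table(rho, rho + B2 * rho^2 + B3 * rho^3)
  interp <- ti_interpolant(tb, B2, method = "spline")
  probe <- c(1e-5, 1e-4, 3e-4)
  expect_equal(fex_TI(interp, probe), fex_virial(probe, B2, B3, order = 3),
               tolerance = 1e-3)
})

test_that("ideal free energy and overlap density follow their closed forms", {
  expect_equal(f_ideal(1, v0 = 1), -1)
  expect_equal(f_ideal(exp(1), v0 = 1), 0, tolerance = 1e-14)
  expect_error(f_ideal(0), class = "nanostarphase_domain_error")
  expect_equal(overlap_density(9.70), 2.61e-4, tolerance = 3e-3)
  expect_equal(overlap_density(8.93), 3.35e-4, tolerance = 3e-3)
  expect_equal(overlap_density(8.72), 3.60e-4, tolerance = 3e-3)
})

test_that("eos_table enforces its invariants", {
  expect_error(eos_table(c(1e-4, 1e-5, 1e-3), rep(1e-4, 3)),
               class = "nanostarphase_usage_error")
  expect_error(eos_table(c(1e-5, 1e-4), c(1e-5, 1e-4)),
               class = "nanostarphase_usage_error")
  expect_error(eos_table(c(1e-5, 1e-4, 1e-3), c(1e-5, -1, 1e-3)),
               class = "nanostarphase_domain_error")
})
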