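test_that("pressure reduces to known forms and matches a finite-difference oracle", {
  # ideal reference with bonding off: betaP = rho
  p_off <- suppressWarnings(sticky_end_params(delta_H = 1e6, delta_S_nosalt = -1,
                                              L_DNA = 1)) # dG huge => Delta ~ 0
  m_id <- free_energy_model("virial2", B2 = 1e-30, salt = 0.5, valence = 4,
                            params = p_off)
  rho <- c(1e-6, 1e-5, 1e-4)
  expect_equal(pressure(m_id, 300, rho), rho, tolerance = 1e-9)
  # virial-3 reference with bonding off: betaP = rho + B2 rho^2 + B3 rho^3
  B2 <- 4000; B3 <- 2.3e6
  m_v3 <- free_energy_model("virial3", B2 = B2, B3 = B3, salt = 0.5,
                            valence = 4, params = p_off)
  expect_equal(pressure(m_v3, 300, rho), rho + B2 * rho^2 + B3 * rho^3,
               tolerance = 1e-9)
  # full model vs central differences of beta f
  m <- demo_model()
  for (r in c(1e-5, 1e-4, 3e-4)) {
    fd <- r^2 * central_diff(function(rr) m$f(300, rr), r)
    expect_equal(pressure(m, 300, r), fd, tolerance = 1e-7)
  }
  expect_error(pressure(m, 300, 1), class = "nanostarphase_range_error")
})

test_that("chemical potential obeys Gibbs-Duhem and shifts trivially with f", {
  m <- demo_model()
  rho <- 10^seq(-6, -3.6, length.out = 25)
  dmu <- vapply(rho, function(r) central_diff(function(x) chemical_potential(m, 300, x), r),
                numeric(1))
  dbp <- vapply(rho, function(r) central_diff(function(x) pressure(m, 300, x), r),
                numeric(1))
  expect_equal(dmu, dbp / rho, tolerance = 1e-6)
  # ideal gas: beta mu = log(v0 rho)
  p_off <- suppressWarnings(sticky_end_params(delta_H = 1e6, delta_S_nosalt = -1,
                                              L_DNA = 1))
  m_id <- free_energy_model("virial2", B2 = 1e-30, salt = 0.5, valence = 4,
                            params = p_off, v0 = 1.7)
  expect_equal(chemical_potential(m_id, 300, rho), log(1.7 * rho),
               tolerance = 1e-9)
})

test_that("the ideal-gas reference volume cancels in the critical point", {
  dft <- synthetic_virial_defaults(0.2)
  cps <- lapply(c(1, 1.6606), function(v0) {
    m <- free_energy_model("virial2", B2 = dft$B2, salt = 0.2, valence = 4,
                           v0 = v0)
    find_critical_point(m, n_starts = 6L)
  })
  expect_equal(cps[[1]]$Tc, cps[[2]]$Tc, tolerance = 1e-9)
  expect_equal(cps[[1]]$rho_c, cps[[2]]$rho_c, tolerance = 1e-9)
})

test_that("critical-point solver reproduces the van der Waals closed form", {
  for (ab in list(c(3, 0.1), c(1.2, 0.02))) {
    m <- fe_model_vdw(ab[1], ab[2])
    cp <- find_critical_point(m, n_starts = 8L)
    ref <- vdw_critical(ab[1], ab[2])
    expect_equal(cp$Tc, ref$Tc, tolerance = 1e-6)
    expect_equal(cp$rho_c, ref$rho_c, tolerance = 1e-6)
    expect_lt(max(abs(cp$residuals)), 1e-8)
  }
})

test_that("critical point brackets the onset of the van der Waals loop", {
  m <- demo_model()
  cp <- find_critical_point(m, n_starts = 8L)
  rho <- exp(seq(log(m$rho_range[1] * 1.05), log(m$rho_range[2] * 0.95),
                 length.out = 2500))
  above <- pressure(m, cp$Tc + 0.5, rho)
  below <- pressure(m, cp$Tc - 0.5, rho)
  expect_true(all(diff(above) > 0))
  expect_true(any(diff(below) < 0))
})

test_that("critical point agrees with the brute-force monotonicity-loss oracle", {
  m <- demo_model()
  cp <- find_critical_point(m, n_starts = 8L)
  bracket <- grid_critical_bracket(m, c(cp$Tc - 3, cp$Tc + 3), resolution = 0.02)
  expect_gte(cp$Tc, bracket[1] - 0.02)
  expect_lte(cp$Tc, bracket[2] + 0.02)
})

test_that("critical outputs are stable under more starts and tighter tolerances", {
  m <- demo_model()
  cp1 <- find_critical_point(m, n_starts = 6L, resid_tol = 1e-8)
  cp2 <- find_critical_point(m, n_starts = 12L, resid_tol = 5e-9)
  expect_equal(cp1$Tc, cp2$Tc, tolerance = 1e-6)
  expect_equal(cp1$rho_c, cp2$rho_c, tolerance = 1e-6)
})

test_that("no critical point exists when bonding is switched off", {
  p_off <- suppressWarnings(sticky_end_params(delta_H = 1e6, delta_S_nosalt = -1,
                                              L_DNA = 1))
  m <- free_energy_model("virial2", B2 = 4000, salt = 0.5, valence = 4,
                         params = p_off)
  expect_error(find_critical_point(m, n_starts = 6L),
               class = "nanostarphase_notfound_error")
})

test_that("coexistence matches the Maxwell equal-area oracle on van der Waals", {
  a <- 3; b <- 0.1
  m <- fe_model_vdw(a, b)
  cp <- find_critical_point(m, n_starts = 8L)
  T9 <- 0.9 * cp$Tc
  bin <- coexistence_curve(m, T_list = T9, critical = cp)
  oracle <- vdw_maxwell(a, b, T9)
  expect_equal(bin$rho_gas_per_nm3, oracle$rho_gas, tolerance = 1e-6)
  expect_equal(bin$rho_liq_per_nm3, oracle$rho_liq, tolerance = 1e-6)
  expect_equal(bin$betaP_per_nm3, oracle$P / T9, tolerance = 1e-6)
})

test_that("both binodal branches close onto the critical point as T -> Tc", {
  m <- demo_model()
  cp <- find_critical_point(m, n_starts = 8L)
  Ts <- cp$Tc - c(2, 1, 0.5, 0.25)
  bin <- coexistence_curve(m, Ts, critical = cp)
  expect_equal(nrow(bin), 4L)
  gas_gap <- abs(bin$rho_gas_per_nm3 - cp$rho_c)
  liq_gap <- abs(bin$rho_liq_per_nm3 - cp$rho_c)
  expect_true(all(diff(gas_gap) < 0)) # rows ordered by increasing T
  expect_true(all(diff(liq_gap) < 0))
  expect_error(coexistence_curve(m, cp$Tc + 1, critical = cp),
               class = "nanostarphase_domain_error")
})

test_that("pressure and chemical potential balance along the binodal, rechecked independently", {
  m <- demo_model()
  cp <- find_critical_point(m, n_starts = 8L)
  bin <- coexistence_curve(m, cp$Tc - c(1, 3, 5), critical = cp)
  for (i in seq_len(nrow(bin))) {
    Tk <- bin$T_K[i]; rg <- bin$rho_gas_per_nm3[i]; rl <- bin$rho_liq_per_nm3[i]
    expect_equal(pressure(m, Tk, rg), pressure(m, Tk, rl),
                 tolerance = 1e-6)
    expect_equal(chemical_potential(m, Tk, rg), chemical_potential(m, Tk, rl),
                 tolerance = 1e-6)
    expect_lt(rg, rl)
  }
})

test_that("adding a constant to the free energy shifts mu, leaves P unchanged", {
  m <- demo_model()
  shift <- 2.5
  m2 <- fe_model(function(T_K, rho) m$f(T_K, rho) + shift, m$d,
                 m$T_range, m$rho_range, check = FALSE)
  expect_equal(pressure(m2, 300, 1e-4), pressure(m, 300, 1e-4))
  expect_equal(chemical_potential(m2, 300, 1e-4),
               chemical_potential(m, 300, 1e-4) + shift)
})

test_that("the derivative contract rejects inconsistent models", {
  expect_error(
    fe_model(function(T_K, rho) rho^2,
             function(T_K, rho, order) switch(order, 5 * rho, 2, 0),
             T_range = c(1, 2), rho_range = c(0.1, 1)),
    class = "nanostarphase_contract_error")
})
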