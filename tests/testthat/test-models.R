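test_that("coupling constants assemble from microscopic parameters", {
  pc <- physical_constants()
  # dipolar: closed form recomputed independently here
  r <- 1.5e-10
  expected <- (1e-7)^2 * pc$gamma_H^4 * pc$hbar^2 / 5 * r^-6 * 0.5 * 1.5
  cc <- coupling_constant("dipolar_homonuclear",
                          gyromagnetic_ratio = pc$gamma_H,
                          internuclear_distance = r,
                          spin_quantum_number = 0.5)
  expect_equal(cc$const_value, expected, tolerance = 1e-12)
  # quadrupolar
  eqQ <- 2 * pi * 220e3
  cq <- coupling_constant("quadrupolar", quadrupole_coupling = eqQ,
                          asymmetry = 0.1)
  expect_equal(cq$const_value, 3 / 80 * eqQ^2 * (1 + 0.01 / 3),
               tolerance = 1e-12)
  # agreement check between explicit value and micro-parameters
  expect_silent(coupling_constant("dipolar_homonuclear",
                                  const_value = expected,
                                  gyromagnetic_ratio = pc$gamma_H,
                                  internuclear_distance = r))
  expect_error(
    coupling_constant("dipolar_homonuclear", const_value = expected * 1.01,
                      gyromagnetic_ratio = pc$gamma_H,
                      internuclear_distance = r),
    "disagrees"
  )
  expect_error(coupling_constant("dipolar_homonuclear", const_value = -1),
               "positive")
  expect_error(coupling_constant("quadrupolar"), "required")
})

test_that("rmtd model validates its parameters", {
  expect_error(rmtd_model(0), "chi")
  expect_error(rmtd_model(1.2), "chi")
  expect_error(rmtd_model(0.5, k_low = 10, k_high = 1), "k_low")
  expect_error(rmtd_model(0.5, transport_coefficient = -1), "transport")
  expect_equal(dispersion_exponent(rmtd_model(0.5, "gaussian")), 0.75)
  expect_equal(dispersion_exponent(rmtd_model(0.27, "cauchy")), 0.27)
})

test_that("rmtd spectral density matches a dense quadrature oracle", {
  for (stat in c("gaussian", "cauchy")) {
    m <- rmtd_model(0.4, stat)
    fl <- rmtd_cutoff_frequencies(m)$f_low_MHz
    omega <- 2 * pi * 1e6 * c(0, 10 * fl, 100 * fl, 1000 * fl)
    expect_equal(rmtd_spectral_density(m, omega), riemann_rmtd(m, omega),
                 tolerance = 1e-5)
  }
})

test_that("rmtd mid-band slope follows the exponent relations", {
  slope_at <- function(m, f_MHz) {
    w <- 2 * pi * f_MHz * 1e6
    h <- 1.05
    log(rmtd_spectral_density(m, w * h) / rmtd_spectral_density(m, w)) /
      log(h)
  }
  for (stat in c("gaussian", "cauchy")) {
    for (chi in seq(0.1, 0.9, by = 0.2)) {
      m <- wide_rmtd(chi, stat)
      f_mid <- 100 * rmtd_cutoff_frequencies(m)$f_low_MHz
      expected <- if (stat == "gaussian") -(1 + chi) / 2 else -chi
      expect_lt(abs(slope_at(m, f_mid) - expected), 0.02,
                label = sprintf("%s chi=%.1f slope deviation", stat, chi))
    }
  }
})

test_that("spectral density at zero frequency is a finite plateau", {
  m <- rmtd_model(0.5, "gaussian")
  I0 <- rmtd_spectral_density(m, 0)
  expect_true(is.finite(I0) && I0 > 0)
  # non-increasing in omega
  omegas <- 10^seq(2, 9, by = 0.5)
  vals <- rmtd_spectral_density(m, omegas)
  expect_true(all(diff(vals) < 0))
  expect_error(rmtd_spectral_density(m, -1), "omega")
  expect_error(rmtd_spectral_density(m, NaN), "omega")
})

test_that("relaxation rates obey the extreme narrowing and 10/3 limits", {
  Iw <- white_spectral_density(1e-9)
  cc <- 1e9
  # white spectrum: R1 = R2 = R1rho = 5 const I0
  expect_equal(r1_dipolar(Iw, cc, 1e6), 5 * cc * 1e-9)
  expect_equal(r2_dipolar(Iw, cc, 1e6), r1_dipolar(Iw, cc, 1e6))
  expect_equal(r1rho(Iw, cc, 1e4, 1e6), r1_dipolar(Iw, cc, 1e6))
  # zero spectrum
  I0f <- white_spectral_density(0)
  expect_equal(r1_dipolar(I0f, cc, 1e6), 0)
  expect_equal(r2_dipolar(I0f, cc, 1e6), 0)
  # Lorentzian in extreme narrowing: R1 = R2
  Il <- lorentzian_spectral_density(1e-12)
  expect_equal(r1_dipolar(Il, cc, 1e6), r2_dipolar(Il, cc, 1e6),
               tolerance = 1e-6)
  # slow-motion spectrum: I(omega), I(2 omega) << I(0)
  # => T2(omega)/T1(0) = (5 const I0)/(1.5 const I0) = 10/3
  Islow <- as_spectral_density(function(w) ifelse(w == 0, 1e-6, 1e-14))
  ratio <- r1_dipolar(Islow, cc, 0) / r2_dipolar(Islow, cc, 1e8)
  expect_equal(ratio, 10 / 3, tolerance = 1e-3)
  # r1rho with zero lock field coincides with r2
  Il2 <- lorentzian_spectral_density(1e-6)
  expect_equal(r1rho(Il2, cc, 0, 1e6), r2_dipolar(Il2, cc, 1e6))
  # dominant I(omega_L): R1rho -> 1.5 const I(omega_L)
  Idom <- as_spectral_density(function(w) ifelse(w < 1e3, 1e-6, 1e-15))
  expect_equal(r1rho(Idom, cc, 10, 1e8), 1.5 * cc * 1e-6, tolerance = 1e-6)
  expect_error(r1_dipolar(Iw, -5, 1e6), "const")
  expect_error(r1_dipolar(as_spectral_density(function(w) -w), 1, 1),
               "non-negative")
})

test_that("fast exchange rate is the population-weighted average", {
  expect_equal(fast_exchange_rate(fast_exchange_model(0, 0.1, 2)), 1 / 2)
  expect_equal(fast_exchange_rate(fast_exchange_model(1, 0.1, 2)), 1 / 0.1)
  expect_equal(fast_exchange_rate(fast_exchange_model(0.5, 0.1, 2)), 5.25)
  # linear in p_a
  p <- seq(0, 1, by = 0.1)
  rates <- vapply(p, function(pa) {
    fast_exchange_rate(fast_exchange_model(pa, 0.05, 2))
  }, numeric(1))
  expect_equal(diff(rates), rep(diff(rates)[1], 10), tolerance = 1e-12)
  expect_error(fast_exchange_model(1.5, 0.1, 2), "p_a")
  expect_error(fast_exchange_model(0.5, -1, 2), "times")
})

test_that("dead-time loss reproduces the benchtop probe estimates", {
  expect_equal(round(deadtime_loss(15, 20), 2), 0.43)
  expect_equal(round(deadtime_loss(15, 30), 2), 0.22)
  expect_equal(deadtime_loss(0, 20), 0)
  # strictly increasing in t_dead, strictly decreasing in T2
  td <- seq(0, 40, by = 2)
  expect_true(all(diff(deadtime_loss(td, 25)) > 0))
  T2s <- seq(10, 100, by = 5)
  expect_true(all(diff(deadtime_loss(15, T2s)) < 0))
  expect_error(deadtime_loss(15, -1), "T2")
  expect_error(deadtime_loss(-1, 20), "t_dead")
})

test_that("H/D isotope factors come out near 42 and 6.5", {
  fac <- hdo_isotope_factors()
  expect_equal(fac$rate, 42.4, tolerance = 0.1 / 42.4)
  expect_equal(fac$frequency, 6.51, tolerance = 0.01 / 6.51)
  expect_equal(hdo_intramolecular_factor(), fac$rate)
  expect_equal(hdo_isotope_factors(1, 1)$rate, 1)
  expect_error(hdo_isotope_factors(-1, 1), "gyromagnetic")
})

test_that("signal fraction converts to macromolecular weight fraction", {
  # closed-form solution w = f d_w / (f d_w + (1-f) d_pg), evaluated
  # independently for the quoted 14% case
  f <- 0.14
  w_expected <- f * (2 / 18) / (f * (2 / 18) + (1 - f) * (40 / 640))
  expect_equal(pg_weight_fraction(0.14), w_expected, tolerance = 1e-12)
  expect_equal(pg_weight_fraction(0.14), 0.2245, tolerance = 1e-3)
  expect_equal(pg_weight_fraction(0), 0)
  expect_equal(pg_weight_fraction(1), 1)
  fs <- seq(0, 1, by = 0.05)
  expect_true(all(diff(pg_weight_fraction(fs)) > 0))
  expect_error(pg_weight_fraction(1.2), "signal_fraction")
  expect_error(pg_weight_fraction(0.5, proton_density_pg = 0), "densities")
})
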