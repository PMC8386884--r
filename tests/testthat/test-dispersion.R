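test_that("monoexponential recovery fits return the generating T1", {
  cv <- simulate_recovery_curve(200)
  fit <- fit_monoexp_recovery(cv$t_ms, cv$M)
  expect_equal(fit$T1_ms, 200, tolerance = 1e-6)
  # 1% noise: recovered within 2%
  cvn <- simulate_recovery_curve(200, noise_sigma = 0.01, seed = 11)
  expect_equal(fit_monoexp_recovery(cvn$t_ms, cvn$M)$T1_ms, 200,
               tolerance = 0.02)
  # inversion mode
  ci <- simulate_recovery_curve(150, mode = "inversion")
  expect_equal(fit_monoexp_recovery(ci$t_ms, ci$M, mode = "inversion")$T1_ms,
               150, tolerance = 1e-6)
  expect_error(fit_monoexp_recovery(c(1, 2, 3), c(1, 2, 3)), "at least 4")
  expect_error(fit_monoexp_recovery(c(10, 20, 30, 40), rep(1, 4)), "decade")
  expect_error(fit_monoexp_recovery(log_spaced(1, 1000, 8), rep(0, 8)),
               "flat|converge|zero")
})

test_that("power-law fits recover dispersion exponents", {
  m <- wide_rmtd(0.27, "cauchy")
  prof <- simulate_dispersion(m, 1, freqs = rmtd_fit_freqs(m))
  expect_equal(fit_powerlaw(prof, band = rmtd_fit_band(m))$gamma, 0.27,
               tolerance = 0.01 / 0.27)
  mg <- wide_rmtd(0.5, "gaussian")
  pg <- simulate_dispersion(mg, 1, freqs = rmtd_fit_freqs(mg))
  expect_equal(fit_powerlaw(pg, band = rmtd_fit_band(mg))$gamma, 0.75,
               tolerance = 0.02 / 0.75)
  # frequency-independent profile: gamma = 0
  flat <- dispersion_profile(log_spaced(0.03, 1, 12), rep(5, 12))
  expect_equal(fit_powerlaw(flat, band = c(0.03, 1))$gamma, 0,
               tolerance = 1e-10)
  expect_error(fit_powerlaw(flat, band = c(0.5, 0.6)), "at least 5")
})

test_that("exponent recovery holds across the chi grid at 2% noise", {
  # accuracy of the estimator against its own quoted standard error,
  # assessed on the mean of independent replicate profiles
  for (stat in c("gaussian", "cauchy")) {
    for (chi in c(0.2, 0.45, 0.7)) {
      m <- wide_rmtd(chi, stat)
      freqs <- rmtd_fit_freqs(m)
      gam <- dispersion_exponent(m)
      fits <- lapply(1:8, function(r) {
        seed <- 2000 + 300 * match(stat, c("gaussian", "cauchy")) +
          round(100 * chi) + r
        prof <- simulate_dispersion(m, 1, freqs = freqs, noise_rel = 0.02,
                                    seed = seed)
        fit_powerlaw(prof, band = rmtd_fit_band(m))
      })
      mean_gamma <- mean(vapply(fits, `[[`, numeric(1), "gamma"))
      se_single <- stats::median(vapply(fits, `[[`, numeric(1), "gamma_err"))
      expect_lt(abs(mean_gamma - gam), se_single,
                label = sprintf("%s chi=%.2f deviation", stat, chi))
    }
  }
})

disp_with_dips <- function(amps, widths = rep(0.01, 3), bulk = 0,
                           noise_rel = 0, seed = NULL) {
  m <- wide_rmtd(0.27, "cauchy")
  coup <- 10 / (rmtd_spectral_density(m, 2 * pi * 0.1e6) +
                  4 * rmtd_spectral_density(m, 4 * pi * 0.1e6))
  freqs <- sort(unique(c(log_spaced(0.2, 5, 30),
                         seq(0.45, 0.80, by = 0.002),
                         seq(2.0, 3.2, by = 0.002))))
  dips <- if (is.null(amps)) NULL else dip_model(amplitudes = amps,
                                                 widths = widths)
  simulate_dispersion(m, coup, dips = dips, bulk_rate = bulk, freqs = freqs,
                      noise_rel = noise_rel, seed = seed)
}

test_that("baseline subtraction isolates the injected dips", {
  prof <- disp_with_dips(c(2, 1.2, 1))
  dt <- isolate_dips(prof)
  # residual outside the windows is consistent with zero
  outside <- dt[is.na(dt$window), ]
  expect_lt(max(abs(outside$R1_dip)) / max(prof$R1_per_s), 0.01)
  # residual peaks at the injected centres
  for (ctr in c(0.6, 2.3, 2.9)) {
    win <- dt[!is.na(dt$window) & abs(dt$freq_MHz - ctr) < 0.2, ]
    expect_lt(abs(win$freq_MHz[which.max(win$R1_dip)] - ctr), 0.02)
  }
  # a dip-free profile leaves a near-zero dip table
  base <- disp_with_dips(NULL)
  dt0 <- isolate_dips(base)
  expect_lt(max(abs(dt0$R1_dip)) / max(base$R1_per_s), 0.01)
  expect_error(isolate_dips(base, dip_windows = list(c(50, 60))),
               "outside")
})

test_that("dip areas match the Lorentzian closed form and scale linearly", {
  amps <- c(2, 1.2, 1)
  widths <- rep(0.01, 3)
  prof <- disp_with_dips(amps, widths)
  ar <- dip_area(isolate_dips(prof))
  expected <- pi * amps * widths
  expect_equal(unname(ar$areas), expected, tolerance = 0.05)
  # doubling the amplitudes doubles the total area
  ar2 <- dip_area(isolate_dips(disp_with_dips(2 * amps, widths)))
  expect_equal(ar2$total / ar$total, 2, tolerance = 0.02)
  # dip-free profile integrates to about zero
  ar0 <- dip_area(isolate_dips(disp_with_dips(NULL)))
  expect_lt(abs(ar0$total) / ar$total, 0.05)
  expect_error(dip_area(data.frame()), "dip_table")
})

test_that("drier synthetic states give larger dip areas and exponents", {
  chis <- c(0.27, 0.35, 0.45)
  scales <- c(1, 3, 10)
  areas <- numeric(3)
  gammas <- numeric(3)
  base_freqs <- sort(unique(c(log_spaced(0.02, 5, 40),
                              seq(0.45, 0.80, by = 0.002),
                              seq(2.0, 3.2, by = 0.002))))
  for (i in 1:3) {
    m <- wide_rmtd(chis[i], "cauchy")
    coup <- (10 + 5 * i) /
      (rmtd_spectral_density(m, 2 * pi * 0.1e6) +
         4 * rmtd_spectral_density(m, 4 * pi * 0.1e6))
    prof <- simulate_dispersion(
      m, coup,
      dips = dip_model(amplitudes = scales[i] * c(2, 1.2, 1),
                       widths = rep(0.01, 3)),
      freqs = base_freqs
    )
    areas[i] <- dip_area(isolate_dips(prof))$total
    gammas[i] <- fit_powerlaw(prof, band = c(0.02, 0.4),
                              exclude_dips = TRUE)$gamma
  }
  expect_true(all(diff(areas) > 0))
  expect_true(all(diff(gammas) > 0))
})

test_that("1H and 2H exponents are compared with a joint error", {
  m <- wide_rmtd(0.27, "cauchy")
  f <- rmtd_fit_freqs(m, n = 30)
  p1 <- simulate_dispersion(m, 1, freqs = f)
  p2 <- simulate_dispersion(m, 1, freqs = f, nucleus = "2H")
  cmp <- compare_nuclei(p1, p2, rmtd_fit_band(m))
  expect_equal(cmp$delta_gamma, 0, tolerance = 1e-8)
  expect_true(cmp$consistent)
  m2 <- wide_rmtd(0.10, "cauchy")
  p3 <- simulate_dispersion(m2, 1, freqs = f, noise_rel = 0.01, seed = 3,
                            nucleus = "2H")
  cmp2 <- compare_nuclei(p1, p3, rmtd_fit_band(m))
  expect_equal(cmp2$delta_gamma, 0.17, tolerance = 0.1)
  expect_error(compare_nuclei(p1, p2, c(1e6, 2e6)), "overlap")
})
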