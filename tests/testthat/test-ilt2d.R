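test_that("kernels take their analytic values at characteristic points", {
  sc <- acquisition_scheme(recovery_times = c(1, 100, 1e6), n_echoes = 400)
  g <- inversion_grid(T1 = c(10, 100, 1000),
                      T2 = c(0.02, 80), gaussian_boundary = 1)
  k <- build_kernels(sc, g)
  # fully recovered inversion column approaches 1
  expect_equal(k$K1[3, ], rep(1, 3), tolerance = 1e-10)
  # Gaussian kernel at t = T2 (20 us, below the boundary)
  n20 <- which(acquisition_times(sc) == 20)
  expect_equal(k$K2[n20, 1], exp(-1), tolerance = 1e-12)
  # exponential kernel at t = T2 (80 ms, above the boundary)
  n80 <- which(acquisition_times(sc) == 80 * 1000)
  expect_equal(k$K2[n80, 2], exp(-1), tolerance = 1e-12)
  expect_true(all(k$K1 >= -1 & k$K1 <= 1))
  # entries in [0, 1]: the Gaussian kernel underflows to exactly zero far
  # beyond the decay time
  expect_true(all(k$K2 >= 0 & k$K2 <= 1))
  # acquisition times below the dead time are rejected
  sc_bad <- sc
  sc_bad$dead_time <- 50
  expect_error(build_kernels(sc_bad, g), "dead time")
})

test_that("a noiseless single component is recovered as a sharp peak", {
  sc <- small_scheme()
  ds <- simulate_ir_fidcpmg(relaxation_component(100, 10, 1), sc)
  g <- inversion_grid(T1 = log_spaced(1, 1e4, 32),
                      T2 = log_spaced(5e-3, 1e3, 32))
  map <- invert(ds, g)
  peak <- which(map$amplitude == max(map$amplitude), arr.ind = TRUE)
  cell_ratio_T1 <- (1e4 / 1) ^ (1 / 31)
  cell_ratio_T2 <- (1e3 / 5e-3) ^ (1 / 31)
  expect_lt(abs(log(g$T1[peak[1]] / 100)), 1.5 * log(cell_ratio_T1))
  expect_lt(abs(log(g$T2[peak[2]] / 10)), 1.5 * log(cell_ratio_T2))
  # at least 90% of the mass within the 3x3 neighbourhood of the peak
  ii <- pmax(1, peak[1] - 1):pmin(32, peak[1] + 1)
  jj <- pmax(1, peak[2] - 1):pmin(32, peak[2] + 1)
  expect_gt(sum(map$amplitude[ii, jj]) / sum(map$amplitude), 0.9)
  expect_true(all(map$amplitude >= 0))
})

test_that("well-separated components give the generating fractions", {
  # the echo train must cover the longest T2: 400 echoes reach 100 ms
  sc <- small_scheme(n_echoes = 400)
  comps <- list(relaxation_component(400, 50, 8),
                relaxation_component(250, 1.5, 2))
  ds <- simulate_ir_fidcpmg(comps, sc)
  g <- inversion_grid(T1 = log_spaced(1, 1e4, 32),
                      T2 = log_spaced(5e-3, 1e3, 32))
  map <- invert(ds, g)
  pk <- segment_peaks(map, rel_threshold = 0.01)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$fraction[1], 0.8, tolerance = 0.02 / 0.8)
  expect_equal(pk$fraction[2], 0.2, tolerance = 0.02 / 0.2)
  expect_equal(pk$T2_ms[1], 50, tolerance = 0.15)
  expect_equal(pk$T2_ms[2], 1.5, tolerance = 0.15)
})

test_that("Tikhonov trade-off is monotone in alpha", {
  sc <- small_scheme(noise_sigma = 2, seed = 99)
  ds <- simulate_ir_fidcpmg(cartilage_components(), sc)
  g <- inversion_grid(T1 = log_spaced(1, 1e4, 16),
                      T2 = log_spaced(5e-3, 1e3, 16))
  maps <- lapply(10^seq(-2, 2), function(a) {
    invert(ds, g, alpha_method = "fixed", alpha = a)
  })
  res <- vapply(maps, `[[`, numeric(1), "residual_norm")
  sol <- vapply(maps, `[[`, numeric(1), "solution_norm")
  expect_true(all(diff(res) >= -1e-8))
  expect_true(all(diff(sol) <= 1e-8))
})

test_that("compressed solver equals brute-force non-negative least squares", {
  g <- inversion_grid(T1 = log_spaced(1, 1e4, 16),
                      T2 = log_spaced(5e-3, 1e3, 16))
  for (case in list(list(noise = 0, alpha = 1),
                    list(noise = 2, alpha = 1),
                    list(noise = 2, alpha = 10))) {
    sc <- small_scheme(noise_sigma = case$noise, seed = 99)
    ds <- simulate_ir_fidcpmg(cartilage_components(), sc)
    # svd_rank above all dimensions: compression is lossless, so the
    # compressed active-set solution must match the dense oracle
    map <- invert(ds, g, alpha_method = "fixed", alpha = case$alpha,
                  svd_rank = 64)
    k <- build_kernels(sc, g)
    A <- kronecker(k$K2, k$K1)
    Aaug <- rbind(A, sqrt(case$alpha) * diag(ncol(A)))
    baug <- c(as.vector(ds$signal), rep(0, ncol(A)))
    oracle <- pracma::lsqnonneg(Aaug, baug)$x
    x <- as.vector(map$amplitude)
    expect_lt(sqrt(sum((x - oracle)^2)) / sqrt(sum(oracle^2)), 1e-6)
  }
})

test_that("map intensity is conserved against the generating amplitudes", {
  # total map intensity matches the extrapolated fully-recovered signal
  # within 5% at signal-to-noise of about 100
  sc <- small_scheme(noise_sigma = 10, seed = 5)
  ds <- simulate_ir_fidcpmg(cartilage_components(), sc)
  g <- inversion_grid(T1 = log_spaced(1, 1e4, 48),
                      T2 = log_spaced(5e-3, 1e3, 48))
  map <- invert(ds, g)
  expect_equal(map$total_intensity, 1062, tolerance = 0.05)
})

test_that("degenerate inversion inputs raise explicit errors", {
  sc <- small_scheme()
  ds <- simulate_ir_fidcpmg(relaxation_component(100, 10, 1), sc)
  ds$signal[] <- 0
  expect_error(invert(ds, inversion_grid()), "all-zero")
  ds2 <- simulate_ir_fidcpmg(relaxation_component(100, 10, 1), sc)
  expect_error(invert(ds2, inversion_grid(), alpha_method = "fixed"),
               "alpha")
})

test_that("1D inversion localizes exponential components", {
  t <- seq(16, 250000, by = 250)
  g1 <- log_spaced(0.1, 1000, 48)
  # single exponential: single sharp peak at the true value
  f1 <- invert_1d(t, exp(-t / 5000), "T2", values = g1)
  expect_equal(f1$values[which.max(f1$amplitude)], 5, tolerance = 0.15)
  # two components a decade apart at high SNR: two separated clusters
  y2 <- exp(-t / 5000) + 0.5 * exp(-t / 50000)
  f2 <- invert_1d(t, y2, "T2", values = g1, alpha_method = "fixed",
                  alpha = 1e-7)
  support <- f2$values[f2$amplitude > 0.02 * max(f2$amplitude)]
  gaps <- diff(log10(support))
  expect_equal(sum(gaps > 0.5) + 1, 2) # two clusters
  expect_error(invert_1d(t, rep(0, length(t)), "T2"), "all-zero")
  # T1 recovery kind
  tr <- log_spaced(1, 5000, 24)
  yr <- 1 - 2 * exp(-tr / 300)
  fr <- invert_1d(tr, yr, "T1", values = log_spaced(1, 1e4, 48))
  expect_equal(fr$values[which.max(fr$amplitude)], 300, tolerance = 0.15)
})
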