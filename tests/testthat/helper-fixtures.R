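# compact acquisition scheme: keeps the structure of the benchtop protocol
# (log-spaced recovery, FID + echo train, 15 us dead time) at a size suited
# to unit tests
small_scheme <- function(n_echoes = 40, ...) {
  acquisition_scheme(
    recovery_times = log_spaced(1, 5000, 20),
    fid_times = seq(16, 240, by = 8),
    n_echoes = n_echoes,
    ...
  )
}

# wide-cutoff RMTD model: the mode integral converges slowly towards the
# upper cutoff, so exponent-relation checks need well-separated cutoffs to
# expose the asymptotic power law
wide_rmtd <- function(chi, statistics) {
  tc <- if (statistics == "gaussian") 1.15e-9 else 0.1
  rmtd_model(chi, statistics, k_low = 1e3, k_high = 1e15,
             transport_coefficient = tc)
}

# frequency grid and fit band in the clean power-law regime of a model
rmtd_fit_freqs <- function(model, n = 25) {
  fl <- rmtd_cutoff_frequencies(model)$f_low_MHz
  log_spaced(20 * fl, 1000 * fl, n)
}

rmtd_fit_band <- function(model) {
  fl <- rmtd_cutoff_frequencies(model)$f_low_MHz
  c(50 * fl, 500 * fl)
}

# independent dense-quadrature oracle for the RMTD mode integral:
# trapezoidal sum over a fine log-k grid, written directly from the
# definition of the integral
riemann_rmtd <- function(model, omega, n = 20001) {
  x <- seq(log(model$k_low), log(model$k_high), length.out = n)
  k <- exp(x)
  tau <- if (model$statistics == "gaussian") {
    1 / (model$transport_coefficient * k^2)
  } else {
    1 / (model$transport_coefficient * k)
  }
  vapply(omega, function(w) {
    y <- model$amplitude * k^(-model$chi) * tau / (1 + w^2 * tau^2) * k
    sum((y[-1] + y[-n]) / 2 * diff(x))
  }, numeric(1))
}
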