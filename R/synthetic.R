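#' Relaxation component
#'
#' One spin pool with longitudinal time T1, transverse time T2, amplitude
#' (extrapolated signal at zero acquisition time under full recovery) and a
#' decay shape: `"exponential"` for liquid-like pools,
#' `"gaussian"` (S(t) = A exp(-(t/T2)^2)) for solid-like, strongly
#' dipolar-coupled pools with T2 of tens of microseconds.
#'
#' @param T1 Longitudinal relaxation time, ms.
#' @param T2 Transverse relaxation time, ms.
#' @param amplitude Signal amplitude, arbitrary units.
#' @param decay_shape `"exponential"` or `"gaussian"`.
#' @return An object of class `relax_component`.
#' @examples
#' relaxation_component(T1 = 635, T2 = 80.8, amplitude = 928)
#' @export
relaxation_component <- function(T1, T2, amplitude,
                                 decay_shape = c("exponential", "gaussian")) {
  decay_shape <- match.arg(decay_shape)
  if (!all(is.finite(c(T1, T2, amplitude))) || T1 <= 0 || T2 <= 0 ||
      amplitude <= 0) {
    stop_param("T1, T2 and amplitude must be positive and finite")
  }
  structure(list(T1 = T1, T2 = T2, amplitude = amplitude,
                 decay_shape = decay_shape),
            class = "relax_component")
}

#' The two-component composition of a fully hydrated cartilage sample
#'
#' Convenience constructor for the archetypal composition observed in fresh
#' bovine cartilage: a dominant liquid-like (bulk-like water) pool with
#' exponential T2 of tens of ms and a minor solid-like pool (macromolecular
#' protons plus strongly bound water) with Gaussian T2 of tens of us, both
#' with similar T1 in the hundreds of ms.
#'
#' @param T1_main,T2_main,A_main Main (liquid-like) pool parameters (ms, ms,
#'   signal units).
#' @param T1_sec,T2_sec,A_sec Secondary (solid-like) pool parameters.
#' @return A list of two [relaxation_component()]s.
#' @examples
#' comps <- cartilage_components()
#' sum(vapply(comps, function(cp) cp$amplitude, numeric(1))) # 1062
#' @export
cartilage_components <- function(T1_main = 635, T2_main = 80.8, A_main = 928,
                                 T1_sec = 666, T2_sec = 0.03, A_sec = 134) {
  list(
    relaxation_component(T1_main, T2_main, A_main, "exponential"),
    relaxation_component(T1_sec, T2_sec, A_sec, "gaussian")
  )
}

#' Acquisition scheme for an FID-CPMG recovery experiment
#'
#' Describes the combined experiment: a recovery period (inversion or
#' saturation) followed by acquisition of the free induction decay on a
#' uniform microsecond grid and then one point per echo top of a CPMG train.
#' The FID section captures transverse decays far below the echo time and
#' thereby extends the accessible T2 range by more than an order of
#' magnitude. Defaults mirror the benchtop protocol for fully hydrated
#' samples: 32 recovery times log-spaced from 1 to 5000 ms, 250 us echo time,
#' 2000 echoes, 15 us receiver dead time, 1 us FID sampling.
#'
#' @param recovery_times Recovery delays, ms, strictly increasing.
#' @param recovery_mode `"inversion"` or `"saturation"`.
#' @param inversion_efficiency f_inv in (0, 1]; 1 is a perfect inversion.
#' @param fid_times FID sample times, us; must lie strictly between the dead
#'   time and the first echo. Default: a 1 us grid from just after the dead
#'   time to just before the first echo.
#' @param echo_time Echo spacing, us.
#' @param n_echoes Number of echoes; one sample is taken per echo top.
#' @param dead_time Receiver dead time, us; samples before it do not exist.
#' @param noise_sigma Standard deviation of the additive Gaussian noise, in
#'   signal units (single-channel, phased data).
#' @param seed Integer seed for the noise stream, or NULL.
#' @return An object of class `acq_scheme`.
#' @examples
#' sc <- acquisition_scheme()
#' length(acquisition_times(sc)) # FID samples plus one per echo
#' @export
acquisition_scheme <- function(recovery_times = log_spaced(1, 5000, 32),
                               recovery_mode = c("inversion", "saturation"),
                               inversion_efficiency = 1,
                               fid_times = NULL,
                               echo_time = 250,
                               n_echoes = 2000,
                               dead_time = 15,
                               noise_sigma = 0,
                               seed = NULL) {
  recovery_mode <- match.arg(recovery_mode)
  if (any(diff(recovery_times) <= 0) || any(recovery_times <= 0)) {
    stop_param("recovery_times must be positive and strictly increasing")
  }
  if (inversion_efficiency <= 0 || inversion_efficiency > 1) {
    stop_param("inversion_efficiency must lie in (0, 1]")
  }
  if (echo_time <= 0) stop_param("echo_time must be > 0")
  if (n_echoes < 1) stop_param("need at least one echo")
  if (dead_time < 0) stop_param("dead_time must be >= 0")
  if (noise_sigma < 0) stop_param("noise_sigma must be >= 0")
  if (is.null(fid_times)) {
    fid_times <- seq(dead_time + 1, echo_time - 1, by = 1)
  }
  if (length(fid_times)) {
    if (any(diff(fid_times) <= 0)) stop_param("fid_times must be strictly increasing")
    if (fid_times[1] <= dead_time) {
      stop_param("first FID sample (%.3g us) must come after the dead time (%.3g us)",
                 fid_times[1], dead_time)
    }
    if (fid_times[length(fid_times)] >= echo_time) {
      stop_param("FID samples must precede the first echo")
    }
  }
  structure(
    list(
      recovery_times = as.numeric(recovery_times),
      recovery_mode = recovery_mode,
      inversion_efficiency = inversion_efficiency,
      fid_times = as.numeric(fid_times),
      echo_time = echo_time, n_echoes = as.integer(n_echoes),
      dead_time = dead_time, noise_sigma = noise_sigma,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "acq_scheme"
  )
}

#' Acquisition time grid of a scheme
#'
#' Concatenated FID sample times and echo-top times, in us, strictly
#' increasing.
#'
#' @param scheme An [acquisition_scheme()].
#' @return Numeric vector of times in us.
#' @export
acquisition_times <- function(scheme) {
  stopifnot(inherits(scheme, "acq_scheme"))
  c(scheme$fid_times, scheme$echo_time * seq_len(scheme$n_echoes))
}

# internal: longitudinal recovery factor for a recovery delay t_rec (ms)
recovery_factor <- function(t_rec_ms, T1_ms, mode, f_inv) {
  if (mode == "inversion") {
    1 - 2 * f_inv * exp(-t_rec_ms / T1_ms)
  } else {
    1 - exp(-t_rec_ms / T1_ms)
  }
}

# internal: transverse decay factor for acquisition times t_acq (us), T2 (ms)
decay_factor <- function(t_acq_us, T2_ms, shape) {
  x <- t_acq_us / (1000 * T2_ms)
  if (shape == "gaussian") exp(-x^2) else exp(-x)
}

#' Simulate an FID-CPMG inversion/saturation-recovery dataset
#'
#' Builds the two-dimensional signal matrix
#' \deqn{S(t_{rec}, t_{acq}) = \sum_j A_j\, rec_j(t_{rec})\, dec_j(t_{acq})
#'   + \epsilon,}
#' with inversion recovery \eqn{rec_j = 1 - 2 f_{inv} e^{-t_{rec}/T_{1,j}}}
#' (or saturation recovery \eqn{1 - e^{-t_{rec}/T_{1,j}}}) and exponential or
#' Gaussian transverse decay per component. Samples before the dead time are
#' never generated; noise is i.i.d. additive Gaussian and reproducible under
#' the scheme's seed.
#'
#' @param components List of [relaxation_component()]s (at least one).
#' @param scheme An [acquisition_scheme()].
#' @return An object of class `decay_dataset`: list with `scheme`, `signal`
#'   (matrix, recovery x acquisition), `acq_times` (us) and `channel`.
#' @examples
#' ds <- simulate_ir_fidcpmg(
#'   cartilage_components(),
#'   acquisition_scheme(n_echoes = 100)
#' )
#' dim(ds$signal)
#' @export
simulate_ir_fidcpmg <- function(components, scheme) {
  stopifnot(inherits(scheme, "acq_scheme"))
  if (inherits(components, "relax_component")) components <- list(components)
  if (!length(components)) stop_param("need at least one relaxation component")
  lapply(components, function(cp) {
    if (!inherits(cp, "relax_component")) {
      stop_param("components must be relaxation_component objects")
    }
  })
  t_acq <- acquisition_times(scheme)
  t_rec <- scheme$recovery_times
  signal <- matrix(0, nrow = length(t_rec), ncol = length(t_acq))
  for (cp in components) {
    rec <- recovery_factor(t_rec, cp$T1, scheme$recovery_mode,
                           scheme$inversion_efficiency)
    dec <- decay_factor(t_acq, cp$T2, cp$decay_shape)
    signal <- signal + cp$amplitude * outer(rec, dec)
  }
  if (scheme$noise_sigma > 0) {
    signal <- signal + with_seed(
      scheme$seed,
      matrix(stats::rnorm(length(signal), sd = scheme$noise_sigma),
             nrow = nrow(signal))
    )
  }
  structure(
    list(scheme = scheme, signal = signal, acq_times = t_acq,
         channel = "1H"),
    class = "decay_dataset"
  )
}

#' @export
print.decay_dataset <- function(x, ...) {
  cat(sprintf(
    "<decay_dataset> %d recovery times x %d acquisition points (%s recovery)\n",
    nrow(x$signal), ncol(x$signal), x$scheme$recovery_mode
  ))
  invisible(x)
}

#' Quadrupolar-dip model
#'
#' Localized enhancements of the proton R1 where the proton Zeeman splitting
#' crosses the quadrupolar levels of immobilized 14N nuclei, at about 0.6,
#' 2.3 and 2.9 MHz. Modelled phenomenologically as Lorentzians added to the
#' relaxation rate: \eqn{\Delta R_1(f) = a\, w^2 / ((f - f_0)^2 + w^2)} per
#' dip, with peak height a (s^-1) and half width at half maximum w (MHz).
#'
#' @param centers Dip centre frequencies, MHz.
#' @param widths Half widths at half maximum, MHz.
#' @param amplitudes Peak heights added to R1, s^-1.
#' @return An object of class `dip_model`.
#' @examples
#' dip_model(amplitudes = c(2, 1.2, 1))
#' @export
dip_model <- function(centers = c(0.6, 2.3, 2.9),
                      widths = rep(0.01, length(centers)),
                      amplitudes = rep(1, length(centers))) {
  if (length(centers) != length(widths) ||
      length(centers) != length(amplitudes)) {
    stop_param("centers, widths and amplitudes must have equal length")
  }
  if (any(centers <= 0) || any(widths <= 0) || any(amplitudes <= 0)) {
    stop_param("centers, widths and amplitudes must be positive")
  }
  structure(list(centers = centers, widths = widths, amplitudes = amplitudes),
            class = "dip_model")
}

# internal: summed Lorentzian dip contribution at frequency f (MHz)
dip_contribution <- function(dips, freq_MHz) {
  if (is.null(dips)) return(rep(0, length(freq_MHz)))
  stopifnot(inherits(dips, "dip_model"))
  out <- rep(0, length(freq_MHz))
  for (i in seq_along(dips$centers)) {
    out <- out + dips$amplitudes[i] * dips$widths[i]^2 /
      ((freq_MHz - dips$centers[i])^2 + dips$widths[i]^2)
  }
  out
}

#' Simulate a field-cycling T1 dispersion profile
#'
#' R1 as a function of Larmor frequency assembled from an RMTD power-law
#' dispersion, a frequency-independent bulk rate, and phenomenological
#' quadrupolar dips:
#' \deqn{R_1(f) = const\,[I(2\pi f) + 4 I(4\pi f)] + R_{1,bulk}
#'   + \sum_d \Delta R_d(f),}
#' optionally degraded by multiplicative Gaussian noise of relative size
#' `noise_rel`, reproducible under `seed`.
#'
#' @param rmtd An [rmtd_model()], or NULL for no dispersive term.
#' @param coupling A [coupling_constant()] or positive number scaling the
#'   RMTD term.
#' @param dips A [dip_model()], or NULL for no dips.
#' @param bulk_rate Frequency-independent rate offset, s^-1.
#' @param freqs Larmor frequencies, MHz, positive and strictly increasing.
#' @param noise_rel Relative noise level (>= 0).
#' @param seed Integer seed or NULL.
#' @param nucleus `"1H"` or `"2H"` label.
#' @return A [dispersion_profile()] data frame with columns `freq_MHz`,
#'   `R1_per_s`, `R1_err`.
#' @examples
#' prof <- simulate_dispersion(
#'   rmtd = rmtd_model(0.27, "cauchy"), coupling = 1e9,
#'   dips = NULL, bulk_rate = 0.3,
#'   freqs = log_spaced(0.01, 20, 25)
#' )
#' head(prof)
#' @export
simulate_dispersion <- function(rmtd, coupling, dips = NULL, bulk_rate = 0,
                                freqs, noise_rel = 0, seed = NULL,
                                nucleus = "1H") {
  if (any(freqs <= 0) || any(diff(freqs) <= 0)) {
    stop_param("freqs must be positive and strictly increasing (MHz)")
  }
  if (noise_rel < 0) stop_param("noise_rel must be >= 0")
  if (bulk_rate < 0) stop_param("bulk_rate must be >= 0")
  omega <- 2 * pi * freqs * 1e6
  r1 <- rep(bulk_rate, length(freqs))
  if (!is.null(rmtd)) {
    I_rmtd <- spectral_density_rmtd(rmtd)
    r1 <- r1 + r1_dipolar(I_rmtd, coupling, omega)
  }
  r1 <- r1 + dip_contribution(dips, freqs)
  if (all(r1 <= 0)) stop_param("simulated profile has no positive rates; supply an RMTD term, dips or a bulk rate")
  err <- noise_rel * r1
  if (noise_rel > 0) {
    r1 <- r1 * (1 + with_seed(seed, stats::rnorm(length(r1), sd = noise_rel)))
  }
  dispersion_profile(freqs, r1, err, nucleus = nucleus)
}

#' Simulate a single recovery curve
#'
#' Longitudinal magnetization recovery at one relaxation field, for testing
#' monoexponential recovery fitting end to end.
#'
#' @param T1 Longitudinal relaxation time, ms.
#' @param times Recovery delays, ms (default 20 log-spaced points to 5 T1).
#' @param mode `"saturation"` or `"inversion"`.
#' @param M0 Equilibrium magnetization.
#' @param f_inv Inversion efficiency (inversion mode).
#' @param noise_sigma Additive noise standard deviation, signal units.
#' @param seed Integer seed or NULL.
#' @return A data frame with columns `t_ms` and `M`.
#' @examples
#' simulate_recovery_curve(200, times = c(50, 100, 200, 400, 1000))
#' @export
simulate_recovery_curve <- function(T1, times = log_spaced(1, 5 * T1, 20),
                                    mode = c("saturation", "inversion"),
                                    M0 = 1, f_inv = 1,
                                    noise_sigma = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (T1 <= 0) stop_param("T1 must be > 0")
  M <- M0 * recovery_factor(times, T1, mode, f_inv)
  if (noise_sigma > 0) {
    M <- M + with_seed(seed, stats::rnorm(length(M), sd = noise_sigma))
  }
  data.frame(t_ms = times, M = M)
}

#' Simulate a single-sided depth scan of a drying sample
#'
#' Emulates profiling with a single-sided scanner: at each observation time a
#' saturation-recovery curve is generated for every depth slice, with the
#' per-slice T1 given by a user map and the sample height shrinking as the
#' tissue dries (e.g. from 1.2 to 0.6 mm). Slices outside the sample return
#' noise only.
#'
#' @param T1_map Function `(depth_mm, time_index) -> T1 ms`, or a matrix with
#'   one row per depth and one column per time step.
#' @param heights Sample height (mm) at each time step.
#' @param depths Depth grid, mm, strictly increasing, measured from the
#'   sample bottom.
#' @param times Recovery delays, ms.
#' @param amplitude Signal amplitude of slices inside the sample.
#' @param noise_sigma Additive noise standard deviation.
#' @param seed Integer seed or NULL.
#' @return A long data frame with columns `time_index`, `depth_mm`, `t_ms`,
#'   `M`, and a logical `in_sample`.
#' @examples
#' prof <- simulate_depth_profile(
#'   T1_map = function(d, i) 230 - 20 * (i - 1),
#'   heights = c(1.2, 1.2, 0.9),
#'   depths = seq(0.05, 1.2, by = 0.1)
#' )
#' @export
simulate_depth_profile <- function(T1_map, heights,
                                   depths = seq(0.05, 1.2, by = 0.1),
                                   times = log_spaced(1, 2000, 20),
                                   amplitude = 1,
                                   noise_sigma = 0, seed = NULL) {
  if (!length(depths) || !length(heights)) stop_param("empty depth or time grid")
  if (any(diff(depths) <= 0)) stop_param("depths must be strictly increasing")
  lookup <- if (is.function(T1_map)) {
    T1_map
  } else {
    T1m <- as.matrix(T1_map)
    if (nrow(T1m) != length(depths) || ncol(T1m) != length(heights)) {
      stop_param("T1_map matrix must be |depths| x |heights|")
    }
    function(d, i) T1m[match(d, depths), i]
  }
  rows <- list()
  with_seed(seed, {
    for (i in seq_along(heights)) {
      for (j in seq_along(depths)) {
        inside <- depths[j] <= heights[i]
        M <- if (inside) {
          T1 <- lookup(depths[j], i)
          if (!is.finite(T1) || T1 <= 0) stop_param("T1_map must return positive T1")
          amplitude * recovery_factor(times, T1, "saturation", 1)
        } else {
          rep(0, length(times))
        }
        if (noise_sigma > 0) M <- M + stats::rnorm(length(M), sd = noise_sigma)
        rows[[length(rows) + 1L]] <- data.frame(
          time_index = i, depth_mm = depths[j], t_ms = times, M = M,
          in_sample = inside
        )
      }
    }
  })
  do.call(rbind, rows)
}
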