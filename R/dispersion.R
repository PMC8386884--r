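#' Relaxation dispersion profile
#'
#' A table of longitudinal relaxation rates versus Larmor frequency, as
#' produced by a fast field-cycling experiment or by
#' [simulate_dispersion()].
#'
#' @param freq_MHz Larmor frequencies, MHz, positive and strictly increasing.
#' @param R1_per_s Longitudinal rates, s^-1, positive.
#' @param R1_err Rate uncertainties, s^-1 (0 when unknown).
#' @param nucleus `"1H"` or `"2H"`.
#' @return A data frame of class `dispersion_profile` with attribute
#'   `nucleus`.
#' @export
dispersion_profile <- function(freq_MHz, R1_per_s,
                               R1_err = rep(0, length(freq_MHz)),
                               nucleus = c("1H", "2H")) {
  nucleus <- match.arg(nucleus)
  if (any(freq_MHz <= 0) || any(diff(freq_MHz) <= 0)) {
    stop_param("frequencies must be positive and strictly increasing")
  }
  if (any(R1_per_s <= 0)) stop_param("R1 must be positive")
  if (length(R1_per_s) != length(freq_MHz) ||
      length(R1_err) != length(freq_MHz)) {
    stop_param("freq_MHz, R1_per_s and R1_err must have equal length")
  }
  structure(
    data.frame(freq_MHz = freq_MHz, R1_per_s = R1_per_s, R1_err = R1_err),
    nucleus = nucleus,
    class = c("dispersion_profile", "data.frame")
  )
}

#' Default quadrupolar-dip windows
#'
#' Frequency intervals (MHz) bracketing the three proton-(14)N level
#' crossings near 0.6, 2.3 and 2.9 MHz.
#'
#' @return A list of length-2 numeric vectors.
#' @export
default_dip_windows <- function() {
  list(c(0.45, 0.80), c(2.0, 2.6), c(2.6, 3.2))
}

#' Fit a monoexponential recovery curve
#'
#' Least-squares fit of \eqn{M(t) = M_0 (1 - e^{-t/T_1})} (saturation) or
#' \eqn{M_0 (1 - 2 f_{inv} e^{-t/T_1})} (inversion) to a recovery curve,
#' rendering the average T1 at one relaxation field. Requires at least four
#' points spanning at least one decade of recovery time.
#'
#' @param t Recovery delays, ms.
#' @param M Magnetization values.
#' @param mode `"saturation"` or `"inversion"`.
#' @param f_inv Inversion efficiency.
#' @return List with `T1_ms`, `T1_err_ms`, `M0`.
#' @examples
#' cv <- simulate_recovery_curve(200)
#' fit_monoexp_recovery(cv$t_ms, cv$M)$T1_ms
#' @export
fit_monoexp_recovery <- function(t, M, mode = c("saturation", "inversion"),
                                 f_inv = 1) {
  mode <- match.arg(mode)
  if (length(t) < 4) stop_param("need at least 4 recovery points")
  if (max(t) / min(t) < 10) {
    stop_param("recovery times must span at least one decade")
  }
  M0_0 <- max(abs(M))
  if (M0_0 == 0) stop_param("flat zero curve cannot be fitted")
  # crossing of the 1 - 1/e level gives the T1 starting value
  frac <- M / M0_0
  lvl <- if (mode == "saturation") 1 - exp(-1) else 1 - 2 * f_inv * exp(-1)
  T1_0 <- if (any(frac >= lvl)) t[which(frac >= lvl)[1]] else max(t) / 3
  T1_0 <- max(T1_0, min(t))
  form <- if (mode == "saturation") {
    M ~ M0 * (1 - exp(-t / T1))
  } else {
    M ~ M0 * (1 - 2 * f_inv * exp(-t / T1))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = list(M0 = M0_0, T1 = T1_0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop_param("monoexponential recovery fit failed: %s", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  if (!is.finite(cf["T1"]) || cf["T1"] <= 0) {
    stop_param("recovery fit produced a non-positive T1")
  }
  se <- tryCatch(summary(fit)$coefficients["T1", "Std. Error"],
                 error = function(e) NA_real_)
  list(T1_ms = unname(cf["T1"]), T1_err_ms = unname(se), M0 = unname(cf["M0"]))
}

# internal: rows of a profile inside any of the given windows
in_windows <- function(freq, windows) {
  hit <- rep(FALSE, length(freq))
  for (w in windows) hit <- hit | (freq >= w[1] & freq <= w[2])
  hit
}

#' Fit a power law to a T1 dispersion
#'
#' Linear regression of log T1 on log frequency over a band,
#' \eqn{T_1(\omega) \sim \omega^{\gamma}}, optionally excluding the
#' quadrupolar dip windows. The exponent gamma characterises the
#' surface-mode spectrum sampled by water diffusing along the matrix.
#'
#' @param profile A [dispersion_profile()].
#' @param band Length-2 frequency interval, MHz (default: the low-frequency
#'   region below the dips, 0.03-1.0 MHz).
#' @param exclude_dips Drop points inside `dip_windows` before fitting.
#' @param dip_windows List of dip windows, MHz.
#' @return An object of class `powerlaw_fit`: list with `gamma`,
#'   `gamma_err`, `amplitude` (T1 in s at 1 MHz), `band`, `n_points`.
#' @examples
#' prof <- simulate_dispersion(rmtd_model(0.27, "cauchy"), 1e9,
#'                             freqs = log_spaced(0.02, 2, 30))
#' fit_powerlaw(prof, band = c(0.03, 1))$gamma # about 0.27
#' @export
fit_powerlaw <- function(profile, band = c(0.03, 1.0), exclude_dips = FALSE,
                         dip_windows = default_dip_windows()) {
  stopifnot(inherits(profile, "dispersion_profile"))
  sel <- profile$freq_MHz >= band[1] & profile$freq_MHz <= band[2]
  if (exclude_dips) sel <- sel & !in_windows(profile$freq_MHz, dip_windows)
  if (sum(sel) < 5) stop_param("need at least 5 points in the fit band")
  lf <- log(profile$freq_MHz[sel])
  lt <- log(1 / profile$R1_per_s[sel])
  fit <- stats::lm(lt ~ lf)
  sm <- suppressWarnings(summary(fit))
  structure(
    list(
      gamma = unname(stats::coef(fit)[2]),
      gamma_err = sm$coefficients[2, "Std. Error"],
      amplitude = exp(unname(stats::coef(fit)[1])),
      band = band, n_points = sum(sel)
    ),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> gamma = %.3f +/- %.3f over %.3g-%.3g MHz (%d points)\n",
    x$gamma, x$gamma_err, x$band[1], x$band[2], x$n_points
  ))
  invisible(x)
}

#' Isolate quadrupolar dips from a dispersion profile
#'
#' Fits the background dipolar relaxation on all points outside the dip
#' windows — as a power law in log-log coordinates (default) or a smoothing
#' spline for curved baselines — and subtracts it, leaving the (14)N
#' contribution.
#'
#' @param profile A [dispersion_profile()].
#' @param dip_windows List of length-2 MHz intervals; each must lie inside
#'   the profile range with at least 3 baseline points on each side.
#' @param baseline `"powerlaw"` or `"spline"`.
#' @return Data frame with columns `freq_MHz`, `R1_dip` (baseline-subtracted
#'   rate), `baseline`, and `window` (index of the containing dip window, NA
#'   outside).
#' @examples
#' prof <- simulate_dispersion(rmtd_model(0.27, "cauchy"), 1e9,
#'                             dips = dip_model(),
#'                             freqs = log_spaced(0.05, 10, 200))
#' dips <- isolate_dips(prof)
#' @export
isolate_dips <- function(profile, dip_windows = default_dip_windows(),
                         baseline = c("powerlaw", "spline")) {
  stopifnot(inherits(profile, "dispersion_profile"))
  baseline <- match.arg(baseline)
  f <- profile$freq_MHz
  for (w in dip_windows) {
    if (w[1] >= w[2]) stop_param("dip window limits must be increasing")
    if (w[1] < min(f) || w[2] > max(f)) {
      stop_param("dip window [%.3g, %.3g] MHz lies outside the profile range",
                 w[1], w[2])
    }
    if (sum(f < w[1]) < 3 || sum(f > w[2]) < 3) {
      stop_param("need at least 3 baseline points on each side of window [%.3g, %.3g]",
                 w[1], w[2])
    }
  }
  inside <- in_windows(f, dip_windows)
  base <- if (baseline == "powerlaw") {
    fit <- stats::lm(log(R1_per_s) ~ log(freq_MHz),
                     data = profile[!inside, ])
    exp(stats::predict(fit, newdata = data.frame(freq_MHz = f)))
  } else {
    fit <- stats::smooth.spline(log(f[!inside]),
                                log(profile$R1_per_s[!inside]))
    exp(stats::predict(fit, log(f))$y)
  }
  window <- rep(NA_integer_, length(f))
  for (i in seq_along(dip_windows)) {
    w <- dip_windows[[i]]
    window[f >= w[1] & f <= w[2]] <- i
  }
  data.frame(freq_MHz = f, R1_dip = profile$R1_per_s - base,
             baseline = base, window = window)
}

#' Integrated quadrupolar-dip areas
#'
#' Trapezoidal integral of the baseline-subtracted rate over frequency,
#' per dip window and in total. For a Lorentzian dip of height h and half
#' width w the full-line area is pi h w; the integral over a finite window
#' approaches it as the window widens relative to w. Areas are linear in the
#' dip amplitudes and invariant to the baseline level. Only relative
#' comparisons (ratios between hydration states) are meaningful as results
#' of record.
#'
#' @param dip_table Output of [isolate_dips()].
#' @return List with `areas` (s^-1 MHz per window) and `total`.
#' @examples
#' prof <- simulate_dispersion(rmtd_model(0.27, "cauchy"), 1e9,
#'                             dips = dip_model(),
#'                             freqs = log_spaced(0.05, 10, 400))
#' dip_area(isolate_dips(prof))$total
#' @export
dip_area <- function(dip_table) {
  if (!is.data.frame(dip_table) ||
      !all(c("freq_MHz", "R1_dip", "window") %in% names(dip_table)) ||
      !nrow(dip_table)) {
    stop_param("dip_table must be a non-empty result of isolate_dips()")
  }
  windows <- sort(unique(dip_table$window[!is.na(dip_table$window)]))
  areas <- vapply(windows, function(wi) {
    rows <- dip_table[!is.na(dip_table$window) & dip_table$window == wi, ]
    if (nrow(rows) < 2) return(0)
    pracma::trapz(rows$freq_MHz, rows$R1_dip)
  }, numeric(1))
  list(areas = stats::setNames(areas, paste0("window", windows)),
       total = sum(areas))
}

#' Compare 1H and 2H dispersion exponents in an overlap band
#'
#' Fits power laws to both profiles over the same frequency band and reports
#' the exponent difference with its combined standard error. Agreement of
#' the two dispersions is the signature of intramolecular (rotational)
#' relaxation dominating over intermolecular contributions.
#'
#' @param profile_1H,profile_2H [dispersion_profile()]s.
#' @param overlap_band Length-2 MHz interval; must intersect both profiles.
#' @param conf_level Confidence level for the interval on the difference.
#' @return List with `gamma_1H`, `gamma_2H`, `delta_gamma`, `se`,
#'   `conf_int`, and logical `consistent` (|difference| below the combined
#'   error).
#' @export
compare_nuclei <- function(profile_1H, profile_2H, overlap_band,
                           conf_level = 0.95) {
  rng1 <- range(profile_1H$freq_MHz)
  rng2 <- range(profile_2H$freq_MHz)
  if (overlap_band[1] >= overlap_band[2] ||
      overlap_band[2] < max(rng1[1], rng2[1]) ||
      overlap_band[1] > min(rng1[2], rng2[2])) {
    stop_param("overlap_band does not intersect both profiles")
  }
  f1 <- fit_powerlaw(profile_1H, band = overlap_band)
  f2 <- fit_powerlaw(profile_2H, band = overlap_band)
  delta <- f1$gamma - f2$gamma
  se <- sqrt(f1$gamma_err^2 + f2$gamma_err^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(
    gamma_1H = f1$gamma, gamma_2H = f2$gamma,
    delta_gamma = delta, se = se,
    conf_int = delta + c(-1, 1) * z * se,
    consistent = abs(delta) < se
  )
}
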