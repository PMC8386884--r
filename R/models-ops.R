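#' RMTD spectral density by quadrature over surface modes
#'
#' Evaluates the spectral density of orientational fluctuations produced by
#' translational diffusion along a corrugated surface,
#' \deqn{I(\omega) = \int_{k_{low}}^{k_{high}} S(k)
#'   \frac{\tau(k)}{1 + \omega^2 \tau(k)^2} \, dk,}
#' with the power-law mode spectrum \eqn{S(k) = A k^{-\chi}} and mode
#' correlation times \eqn{\tau(k) = 1/(D k^2)} (gaussian propagator) or
#' \eqn{\tau(k) = 1/(c k)} (Cauchy statistics). In the mid-band, well inside
#' the cutoff frequencies, the local log-log slope of I(omega) is
#' \eqn{-(1+\chi)/2} for gaussian and \eqn{-\chi} for cauchy statistics. The
#' integral is evaluated by adaptive quadrature on log k.
#'
#' @param model An [rmtd_model()].
#' @param omega Angular frequency, rad s^-1; vectorised, all values >= 0.
#' @return I(omega) in seconds (same length as `omega`).
#' @examples
#' m <- rmtd_model(chi = 0.5, statistics = "gaussian")
#' rmtd_spectral_density(m, c(0, 1e5, 1e6))
#' @export
rmtd_spectral_density <- function(model, omega) {
  stopifnot(inherits(model, "rmtd_model"))
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop_param("omega must be finite and >= 0")
  }
  tau_of_k <- if (model$statistics == "gaussian") {
    function(k) 1 / (model$transport_coefficient * k^2)
  } else {
    function(k) 1 / (model$transport_coefficient * k)
  }
  one <- function(w) {
    # substitute k = exp(x): dk = k dx, so the integrand gains a factor k
    integrand <- function(x) {
      k <- exp(x)
      tau <- tau_of_k(k)
      model$amplitude * k^(1 - model$chi) * tau / (1 + w^2 * tau^2)
    }
    stats::integrate(integrand, log(model$k_low), log(model$k_high),
                     rel.tol = 1e-9, subdivisions = 500L)$value
  }
  vapply(omega, one, numeric(1))
}

#' Dipolar/quadrupolar relaxation rates from a spectral density
#'
#' Standard second-order perturbation expressions for the longitudinal rate,
#' \deqn{1/T_1(\omega) = const\,[I(\omega) + 4 I(2\omega)],}
#' the transverse rate,
#' \deqn{1/T_2(\omega) = const/2\,[3 I(0) + 5 I(\omega) + 2 I(2\omega)],}
#' and the rotating-frame rate at lock frequency omega_L,
#' \deqn{1/T_{1\rho}(\omega_L) = const/2\,[3 I(\omega_L) + 5 I(\omega)
#'   + 2 I(2\omega)].}
#' For a white (constant) spectrum all three coincide (extreme narrowing,
#' T1 = T2); when I(omega) and I(2 omega) are negligible against I(0) the
#' transverse rate reduces to `1.5 const I(0)`, giving the familiar
#' T2(omega) = (10/3) T1(0) limit relative to the zero-field longitudinal
#' rate.
#'
#' @param I A [spectral_density] object or a plain function of omega.
#' @param const A [coupling_constant()] or a positive number (s^-2).
#' @param omega Larmor angular frequency, rad s^-1, >= 0; vectorised.
#' @param omega_lock Spin-lock angular frequency, rad s^-1, >= 0.
#' @return Relaxation rate(s) in s^-1.
#' @examples
#' Iw <- white_spectral_density(1e-9)
#' r1_dipolar(Iw, 1e9, 1e6) # equals r2_dipolar for a white spectrum
#' @export
r1_dipolar <- function(I, const, omega) {
  const <- const_value_of(const)
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop_param("omega must be finite and >= 0")
  }
  const * (eval_spectral_density(I, omega) +
             4 * eval_spectral_density(I, 2 * omega))
}

#' @rdname r1_dipolar
#' @export
r2_dipolar <- function(I, const, omega) {
  const <- const_value_of(const)
  if (any(!is.finite(omega)) || any(omega < 0)) {
    stop_param("omega must be finite and >= 0")
  }
  const / 2 * (3 * eval_spectral_density(I, rep(0, length(omega))) +
                 5 * eval_spectral_density(I, omega) +
                 2 * eval_spectral_density(I, 2 * omega))
}

#' @rdname r1_dipolar
#' @export
r1rho <- function(I, const, omega_lock, omega) {
  const <- const_value_of(const)
  if (any(!is.finite(omega)) || any(omega < 0) ||
      any(!is.finite(omega_lock)) || any(omega_lock < 0)) {
    stop_param("omega and omega_lock must be finite and >= 0")
  }
  const / 2 * (3 * eval_spectral_density(I, omega_lock) +
                 5 * eval_spectral_density(I, omega) +
                 2 * eval_spectral_density(I, 2 * omega))
}

const_value_of <- function(const) {
  if (inherits(const, "coupling_constant")) return(const$const_value)
  if (is.numeric(const) && length(const) == 1L && is.finite(const) &&
      const > 0) {
    return(const)
  }
  stop_param("const must be a coupling_constant or a positive number")
}

#' Observed relaxation rate under two-site fast exchange
#'
#' \deqn{1/T_i = p_a/T_{i,surf} + (1-p_a)/T_{i,bulk}.}
#' The rate is linear in the adsorbed fraction `p_a`.
#'
#' @param model A [fast_exchange_model()].
#' @return Rate in s^-1.
#' @examples
#' fast_exchange_rate(fast_exchange_model(0.5, T_surf = 0.1, T_bulk = 2))
#' # 0.5/0.1 + 0.5/2 = 5.25
#' @export
fast_exchange_rate <- function(model) {
  stopifnot(inherits(model, "fast_exchange_model"))
  model$p_a / model$T_surf + (1 - model$p_a) / model$T_bulk
}

#' Fraction of a Gaussian-decaying signal lost within the receiver dead time
#'
#' Solid-like proton pools decay as \eqn{S(t) = S_0 \exp(-(t/T_2)^2)} (the
#' Gaussian shape typical of strongly dipolar-coupled spins). The fraction of
#' the signal that has decayed before acquisition can start is
#' \deqn{1 - \exp(-(t_{dead}/T_2)^2).}
#' With the 15 us dead time typical of benchtop probes, components with
#' T2 = 20 us and 30 us lose 43\% and 22\% of their amplitude. The loss is
#' strictly increasing in the dead time and strictly decreasing in T2.
#'
#' @param t_dead Receiver dead time, us; >= 0. Vectorised.
#' @param T2_gauss Gaussian transverse decay time, us; > 0.
#' @return Fraction lost, in [0, 1).
#' @examples
#' deadtime_loss(15, c(20, 30)) # about 0.43 and 0.22
#' @export
deadtime_loss <- function(t_dead, T2_gauss) {
  if (any(!is.finite(t_dead)) || any(t_dead < 0)) {
    stop_param("t_dead must be finite and >= 0")
  }
  if (any(!is.finite(T2_gauss)) || any(T2_gauss <= 0)) {
    stop_param("T2_gauss must be > 0")
  }
  1 - exp(-(t_dead / T2_gauss)^2)
}

#' Isotope factors for H -> D substitution in water
#'
#' Replacing a proton by a deuteron in HDO reduces the intramolecular dipolar
#' relaxation rate by the square of the gyromagnetic-ratio quotient,
#' `(gamma_H/gamma_D)^2` (about 42), and shifts the Larmor frequency at fixed
#' field by `gamma_H/gamma_D` (about 6.5). The rate factor deliberately keeps
#' only the gyromagnetic-ratio dependence; spin-quantum-number bookkeeping of
#' the heteronuclear coupling is a smaller correction that is not included.
#'
#' @param gamma_H,gamma_D Gyromagnetic ratios in rad s^-1 T^-1; defaults from
#'   [physical_constants()].
#' @return `hdo_isotope_factors` returns a list with `rate` and `frequency`;
#'   `hdo_intramolecular_factor` returns the rate factor alone.
#' @examples
#' hdo_isotope_factors() # rate about 42.4, frequency about 6.51
#' @export
hdo_isotope_factors <- function(gamma_H = physical_constants()$gamma_H,
                                gamma_D = physical_constants()$gamma_D) {
  if (gamma_H <= 0 || gamma_D <= 0) stop_param("gyromagnetic ratios must be > 0")
  list(rate = (gamma_H / gamma_D)^2, frequency = gamma_H / gamma_D)
}

#' @rdname hdo_isotope_factors
#' @export
hdo_intramolecular_factor <- function(gamma_H = physical_constants()$gamma_H,
                                      gamma_D = physical_constants()$gamma_D) {
  hdo_isotope_factors(gamma_H, gamma_D)$rate
}

#' Convert a proton-signal fraction to a macromolecular weight fraction
#'
#' A signal fraction f contributed by a pool with proton mass density d_pg
#' (protons per molecular weight; default 40/640, the heparin-sulfate value
#' used for proteoglycan) against water with d_w = 2/18 corresponds to the
#' weight fraction w solving
#' \deqn{f = \frac{w\,d_{pg}}{w\,d_{pg} + (1-w)\,d_w},}
#' i.e. \eqn{w = f d_w / (f d_w + (1-f) d_{pg})}. A 14\% signal fraction maps
#' to roughly 23 wt-\% of proteoglycan. Strictly increasing in f.
#'
#' @param signal_fraction Signal fraction f in [0, 1]; vectorised.
#' @param proton_density_pg Proton mass density of the macromolecular pool.
#' @param proton_density_water Proton mass density of water.
#' @return Weight fraction w in [0, 1].
#' @examples
#' pg_weight_fraction(0.14) # about 0.224
#' @export
pg_weight_fraction <- function(signal_fraction,
                               proton_density_pg = 40 / 640,
                               proton_density_water = 2 / 18) {
  if (any(!is.finite(signal_fraction)) ||
      any(signal_fraction < 0) || any(signal_fraction > 1)) {
    stop_param("signal_fraction must lie in [0, 1]")
  }
  if (!is.finite(proton_density_pg) || proton_density_pg <= 0 ||
      !is.finite(proton_density_water) || proton_density_water <= 0) {
    stop_param("proton densities must be positive and finite")
  }
  f <- signal_fraction
  f * proton_density_water /
    (f * proton_density_water + (1 - f) * proton_density_pg)
}
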