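#' Coupling constant for dipolar or quadrupolar relaxation
#'
#' The rate prefactor `const` that multiplies the spectral-density combinations
#' in the longitudinal and transverse relaxation-rate expressions. It can be
#' given directly as an opaque number (in s^-2), or assembled from microscopic
#' parameters:
#' for homonuclear dipolar coupling
#' \deqn{const = (\mu_0/4\pi)^2 \gamma^4 \hbar^2 / 5 \; r^{-6} I(I+1)}
#' and for quadrupolar coupling
#' \deqn{const = \frac{3}{80} (e^2 qQ/\hbar)^2 (1 + \eta^2/3).}
#' When both the value and the microscopic parameters are supplied they must
#' agree to a relative tolerance of 1e-10.
#'
#' @param kind `"dipolar_homonuclear"` or `"quadrupolar"`.
#' @param const_value Rate prefactor in s^-2. May be omitted when the
#'   microscopic parameters are given.
#' @param gyromagnetic_ratio gamma in rad s^-1 T^-1 (dipolar).
#' @param internuclear_distance r in m (dipolar).
#' @param spin_quantum_number I (dipolar); 1/2 for protons.
#' @param quadrupole_coupling e^2 qQ / hbar in rad s^-1 (quadrupolar).
#' @param asymmetry Electric-field-gradient asymmetry eta in [0, 1]
#'   (quadrupolar).
#' @param mu0_over_4pi,hbar Physical constants, overridable; defaults from
#'   [physical_constants()].
#' @return An object of class `coupling_constant` with elements `kind` and
#'   `const_value` (plus the microscopic parameters when supplied).
#' @examples
#' coupling_constant("dipolar_homonuclear", const_value = 1e9)
#' # water proton pair at 1.5 Angstrom separation
#' coupling_constant("dipolar_homonuclear",
#'   gyromagnetic_ratio = physical_constants()$gamma_H,
#'   internuclear_distance = 1.5e-10, spin_quantum_number = 0.5
#' )
#' @export
coupling_constant <- function(kind = c("dipolar_homonuclear", "quadrupolar"),
                              const_value = NULL,
                              gyromagnetic_ratio = NULL,
                              internuclear_distance = NULL,
                              spin_quantum_number = 0.5,
                              quadrupole_coupling = NULL,
                              asymmetry = 0,
                              mu0_over_4pi = physical_constants()$mu0_over_4pi,
                              hbar = physical_constants()$hbar) {
  kind <- match.arg(kind)
  micro <- NULL
  if (kind == "dipolar_homonuclear" &&
      !is.null(gyromagnetic_ratio) && !is.null(internuclear_distance)) {
    if (gyromagnetic_ratio <= 0 || internuclear_distance <= 0 ||
        spin_quantum_number <= 0) {
      stop_param("dipolar micro-parameters must be positive")
    }
    micro <- mu0_over_4pi^2 * gyromagnetic_ratio^4 * hbar^2 / 5 *
      internuclear_distance^-6 *
      spin_quantum_number * (spin_quantum_number + 1)
  }
  if (kind == "quadrupolar" && !is.null(quadrupole_coupling)) {
    if (quadrupole_coupling <= 0 || asymmetry < 0 || asymmetry > 1) {
      stop_param("need quadrupole_coupling > 0 and asymmetry in [0, 1]")
    }
    micro <- 3 / 80 * quadrupole_coupling^2 * (1 + asymmetry^2 / 3)
  }
  if (is.null(const_value)) {
    if (is.null(micro)) {
      stop_param("either const_value or the full set of micro-parameters for '%s' is required", kind)
    }
    const_value <- micro
  } else if (!is.null(micro) &&
             abs(const_value - micro) > 1e-10 * abs(micro)) {
    stop_param(
      "const_value (%.6g) disagrees with the micro-parameter value (%.6g)",
      const_value, micro
    )
  }
  if (!is.finite(const_value) || const_value <= 0) {
    stop_param("const_value must be a positive finite number")
  }
  structure(
    list(
      kind = kind, const_value = const_value,
      gyromagnetic_ratio = gyromagnetic_ratio,
      internuclear_distance = internuclear_distance,
      spin_quantum_number = spin_quantum_number,
      quadrupole_coupling = quadrupole_coupling,
      asymmetry = asymmetry
    ),
    class = "coupling_constant"
  )
}

#' Surface-mode model for relaxation by reorientations mediated by
#' translational displacements (RMTD)
#'
#' Water diffusing along a macromolecular surface reorients whenever the
#' surface orientation changes; the orientational correlation then decays
#' through a spectrum of surface modes with wavenumber k. A power-law mode
#' distribution \eqn{S(k) \sim k^{-\chi}} between two cutoffs produces a
#' power-law T1 dispersion \eqn{T_1(\omega) \sim \omega^{\gamma}} with
#' \eqn{\gamma = (1+\chi)/2} for normal (Gaussian-propagator) surface
#' diffusion and \eqn{\gamma = \chi} for Cauchy (Levy-walk) statistics.
#'
#' @param chi Mode-distribution exponent, 0 < chi < 1.
#' @param statistics `"gaussian"` (mode correlation time 1/(D k^2)) or
#'   `"cauchy"` (1/(c k)).
#' @param k_low,k_high Mode wavenumber cutoffs in m^-1, `k_low < k_high`. The
#'   defaults span four decades so the mid-band power law extends over at
#'   least two decades of frequency.
#' @param transport_coefficient D in m^2 s^-1 for gaussian statistics
#'   (default: half the bulk-water self-diffusion coefficient, the value
#'   measured in hydrated cartilage) or c in m s^-1 for cauchy statistics.
#' @param amplitude Normalisation of S(k); arbitrary units.
#' @return An object of class `rmtd_model`.
#' @examples
#' rmtd_model(chi = 0.27, statistics = "cauchy")
#' @seealso [rmtd_spectral_density()], [dispersion_exponent()]
#' @export
rmtd_model <- function(chi,
                       statistics = c("gaussian", "cauchy"),
                       k_low = 1e5, k_high = 1e9,
                       transport_coefficient = NULL,
                       amplitude = 1) {
  statistics <- match.arg(statistics)
  if (is.null(transport_coefficient)) {
    transport_coefficient <- if (statistics == "gaussian") 1.15e-9 else 0.1
  }
  if (!is.finite(chi) || chi <= 0 || chi >= 1) {
    stop_param("chi must lie strictly between 0 and 1, got %s", format(chi))
  }
  if (!(k_low > 0 && k_high > k_low)) stop_param("need 0 < k_low < k_high")
  if (transport_coefficient <= 0) stop_param("transport_coefficient must be > 0")
  if (amplitude <= 0) stop_param("amplitude must be > 0")
  structure(
    list(
      chi = chi, statistics = statistics,
      k_low = k_low, k_high = k_high,
      transport_coefficient = transport_coefficient,
      amplitude = amplitude
    ),
    class = "rmtd_model"
  )
}

#' Predicted dispersion exponent of an RMTD model
#'
#' Exponent gamma of the resulting power law \eqn{T_1(\omega) \sim
#' \omega^{\gamma}}: `(1 + chi) / 2` for gaussian statistics, `chi` for
#' cauchy statistics.
#'
#' @param model An [rmtd_model()].
#' @return The exponent gamma.
#' @export
dispersion_exponent <- function(model) {
  stopifnot(inherits(model, "rmtd_model"))
  if (model$statistics == "gaussian") (1 + model$chi) / 2 else model$chi
}

#' Cutoff frequencies of an RMTD model
#'
#' The mode cutoffs k_low and k_high translate into angular-frequency
#' cutoffs 1/tau(k): `D k^2` for gaussian statistics, `c k` for cauchy.
#' Between them (with margin on both sides) the spectral density follows its
#' power law; outside, it flattens to a plateau (below) or falls off as
#' omega^-2 (above). Because the mode integral converges slowly towards the
#' upper cutoff for small chi, the clean power-law regime starts roughly two
#' decades above `f_low` and may require widely separated cutoffs.
#'
#' @param model An [rmtd_model()].
#' @return List with `f_low_MHz` and `f_high_MHz`.
#' @export
rmtd_cutoff_frequencies <- function(model) {
  stopifnot(inherits(model, "rmtd_model"))
  pw <- if (model$statistics == "gaussian") 2 else 1
  list(
    f_low_MHz = model$transport_coefficient * model$k_low^pw / (2 * pi * 1e6),
    f_high_MHz = model$transport_coefficient * model$k_high^pw / (2 * pi * 1e6)
  )
}

#' Two-site fast-exchange relaxation model
#'
#' In the fast-exchange (Brownstein-Tarr) limit the observed relaxation rate
#' of a fluid in a porous matrix is the population-weighted average of a
#' surface-phase and a bulk-phase rate,
#' \deqn{1/T_i = p_a/T_{i,surf} + (1-p_a)/T_{i,bulk},}
#' where the surface term is proportional to the surface-to-volume ratio
#' times the surface relaxivity.
#'
#' @param p_a Adsorbed (surface) fraction, in [0, 1].
#' @param T_surf Surface-phase relaxation time, s.
#' @param T_bulk Bulk relaxation time, s; about 2 s for the saline water phase
#'   in cartilage.
#' @param surface_to_volume Optional S/V in um^-1.
#' @param surface_relaxivity Optional rho_i in um s^-1. When S/V and rho are
#'   both given they stand for the surface term p_a/T_surf.
#' @return An object of class `fast_exchange_model`.
#' @examples
#' fast_exchange_model(p_a = 0.02, T_surf = 0.005, T_bulk = 2)
#' @seealso [fast_exchange_rate()]
#' @export
fast_exchange_model <- function(p_a, T_surf, T_bulk = 2,
                                surface_to_volume = NULL,
                                surface_relaxivity = NULL) {
  if (!is.finite(p_a) || p_a < 0 || p_a > 1) {
    stop_param("p_a must lie in [0, 1], got %s", format(p_a))
  }
  if (T_surf <= 0 || T_bulk <= 0) stop_param("relaxation times must be > 0")
  if (xor(is.null(surface_to_volume), is.null(surface_relaxivity))) {
    stop_param("surface_to_volume and surface_relaxivity must be given together")
  }
  structure(
    list(
      p_a = p_a, T_surf = T_surf, T_bulk = T_bulk,
      surface_to_volume = surface_to_volume,
      surface_relaxivity = surface_relaxivity
    ),
    class = "fast_exchange_model"
  )
}

#' Spectral density functions
#'
#' A `spectral_density` wraps an evaluator mapping angular frequency omega
#' (rad s^-1) to the spectral density I(omega) (s), together with its
#' provenance. Constructors are provided for the RMTD mode integral, a
#' Lorentzian (single correlation time), a white (frequency-independent)
#' spectrum, and an arbitrary tabulated/closed-form evaluator.
#'
#' The Lorentzian is \eqn{I(\omega) = 2\tau/(1 + \omega^2\tau^2)}.
#'
#' @param model An [rmtd_model()].
#' @param tau Correlation time in s (Lorentzian).
#' @param I0 Constant level in s (white spectrum).
#' @param f Function of omega returning I(omega) >= 0 (tabulated).
#' @param provenance Provenance label for `as_spectral_density`.
#' @return An object of class `spectral_density`: a list with elements
#'   `evaluator` (a vectorised function of omega) and `provenance`.
#' @examples
#' I <- lorentzian_spectral_density(tau = 1e-9)
#' I$evaluator(0) # 2 tau
#' @name spectral_density
NULL

new_spectral_density <- function(evaluator, provenance) {
  structure(list(evaluator = evaluator, provenance = provenance),
            class = "spectral_density")
}

#' @rdname spectral_density
#' @export
spectral_density_rmtd <- function(model) {
  stopifnot(inherits(model, "rmtd_model"))
  force(model)
  new_spectral_density(function(omega) rmtd_spectral_density(model, omega),
                       "rmtd")
}

#' @rdname spectral_density
#' @export
lorentzian_spectral_density <- function(tau) {
  if (tau <= 0) stop_param("tau must be > 0")
  new_spectral_density(function(omega) 2 * tau / (1 + omega^2 * tau^2),
                       "lorentzian")
}

#' @rdname spectral_density
#' @export
white_spectral_density <- function(I0) {
  if (I0 < 0) stop_param("I0 must be >= 0")
  new_spectral_density(function(omega) rep(I0, length(omega)), "white")
}

#' @rdname spectral_density
#' @export
as_spectral_density <- function(f, provenance = "tabulated") {
  if (inherits(f, "spectral_density")) return(f)
  stopifnot(is.function(f))
  new_spectral_density(f, provenance)
}

eval_spectral_density <- function(I, omega) {
  I <- as_spectral_density(I)
  vals <- I$evaluator(omega)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_param("spectral density must be finite and non-negative")
  }
  vals
}

#' @export
print.coupling_constant <- function(x, ...) {
  cat(sprintf("<coupling_constant> %s, const = %.6g s^-2\n",
              x$kind, x$const_value))
  invisible(x)
}

#' @export
print.rmtd_model <- function(x, ...) {
  cat(sprintf(
    "<rmtd_model> chi = %.3g (%s statistics, predicted gamma = %.3g)\n  k in [%.3g, %.3g] m^-1, transport coefficient %.3g\n",
    x$chi, x$statistics, dispersion_exponent(x),
    x$k_low, x$k_high, x$transport_coefficient
  ))
  invisible(x)
}

#' @export
print.fast_exchange_model <- function(x, ...) {
  cat(sprintf(
    "<fast_exchange_model> p_a = %.3g, T_surf = %.3g s, T_bulk = %.3g s\n",
    x$p_a, x$T_surf, x$T_bulk
  ))
  invisible(x)
}
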