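#' Hydration series of relaxation observables
#'
#' Per-stage sample weights and relaxation times along a drying (or
#' rehydration) trajectory, as in a drying experiment where a slice is
#' weighed and measured repeatedly.
#'
#' @param labels Stage labels.
#' @param sample_weight Sample weights, g, positive.
#' @param T1,T2 Relaxation times of the observable pool, ms.
#' @param water_fraction Optional water weight fraction.
#' @return A data frame of class `hydration_series`.
#' @examples
#' hydration_series(c("D1", "D2", "D3"), c(0.075, 0.055, 0.045),
#'                  T1 = c(635, 515, 441), T2 = c(80.8, 46.9, 30.9))
#' @export
hydration_series <- function(labels, sample_weight, T1, T2,
                             water_fraction = NULL) {
  n <- length(labels)
  if (length(sample_weight) != n || length(T1) != n || length(T2) != n) {
    stop_param("all columns must have the same length")
  }
  if (any(sample_weight <= 0)) stop_param("weights must be > 0")
  if (n < 3) stop_param("a hydration series needs at least 3 stages for fitting")
  out <- data.frame(label = labels, sample_weight = sample_weight,
                    T1 = T1, T2 = T2)
  if (!is.null(water_fraction)) out$water_fraction <- water_fraction
  class(out) <- c("hydration_series", "data.frame")
  out
}

#' Linear dependence of relaxation times on sample weight
#'
#' Ordinary least squares of T1 or T2 against sample weight — the empirical
#' parameterization in which drying trajectories are usually displayed. The
#' fast-exchange model predicts the *rate* to be linear in inverse free
#' water, so an exactly linear time-versus-weight dependence is an
#' approximation; the R^2 quantifies how well it holds.
#'
#' @param series A [hydration_series()].
#' @param which `"T1"` or `"T2"`.
#' @return List with `slope` (ms/g), `intercept` (ms), `r_squared`, and the
#'   underlying `lm` fit.
#' @examples
#' s <- hydration_series(paste0("D", 1:5),
#'                       c(0.075, 0.055, 0.045, 0.035, 0.022),
#'                       T1 = c(635, 515, 441, 354, 126),
#'                       T2 = c(80.8, 46.9, 30.9, 17.6, 2.4))
#' fit_linear_weight(s, "T2")$r_squared
#' @export
fit_linear_weight <- function(series, which = c("T1", "T2")) {
  which <- match.arg(which)
  stopifnot(inherits(series, "hydration_series"))
  if (length(unique(series$sample_weight)) < 2) {
    stop_param("sample weights are degenerate; cannot fit a line")
  }
  y <- series[[which]]
  fit <- stats::lm(y ~ sample_weight, data = series)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit))$r.squared,
    fit = fit
  )
}

#' Fast-exchange fit of rates against inverse free water
#'
#' Under two-site fast exchange the observed rate is
#' \eqn{1/T_i = (S/V)\rho_i + 1/T_{i,bulk}} with the surface-to-volume ratio
#' inversely proportional to the free-water content. This fits
#' \eqn{1/T_i - 1/T_{i,bulk}} against the inverse free-water measure
#' (sample weight minus dry weight); the slope is the surface term
#' (the product of S/V scale and surface relaxivity, in s^-1 g).
#'
#' @param series A [hydration_series()] with `T1`/`T2` in ms.
#' @param which `"T1"` or `"T2"`.
#' @param bulk_time Bulk relaxation time, s (default 2 s, the bulk value of
#'   the saline water phase).
#' @param dry_weight Dry weight, g; all sample weights must exceed it.
#' @return List with `surface_term` (s^-1 g), `intercept` (s^-1, ideally 0),
#'   `r_squared`, and the `lm` fit.
#' @examples
#' w <- c(0.075, 0.055, 0.045, 0.035)
#' rate <- 0.5 + 0.002 / (w - 0.02) # exact fast-exchange data
#' s <- hydration_series(paste0("D", 1:4), w,
#'                       T1 = 1000 / rate, T2 = 1000 / rate)
#' fit_fast_exchange(s, "T1", bulk_time = 2, dry_weight = 0.02)$surface_term
#' @export
fit_fast_exchange <- function(series, which = c("T1", "T2"),
                              bulk_time = 2, dry_weight = 0) {
  which <- match.arg(which)
  stopifnot(inherits(series, "hydration_series"))
  if (bulk_time <= 0) stop_param("bulk_time must be > 0")
  free_water <- series$sample_weight - dry_weight
  if (any(free_water <= 0)) {
    stop_param("non-positive free-water measure: all sample weights must exceed the dry weight")
  }
  x <- 1 / free_water
  if (length(unique(x)) < 2) stop_param("degenerate weights; cannot fit")
  y <- 1000 / series[[which]] - 1 / bulk_time # rates in s^-1 (T in ms)
  fit <- stats::lm(y ~ x)
  list(
    surface_term = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit))$r.squared,
    fit = fit
  )
}

#' Trend summary of a drying trajectory
#'
#' Classifies how peak positions and fractions evolve across drying stages
#' ordered by decreasing sample weight. Each observable gets a flag:
#' `"decreasing"` / `"increasing"` for strictly monotone series, `"flat"`
#' when the total relative variation stays within `flat_tol`, otherwise
#' `"mixed"`. In drying cartilage the main-peak T1 and T2 fall with weight
#' loss while the secondary-peak T2 stays flat at about 20 us.
#'
#' @param stages Data frame with columns `sample`, `weight` and at least two
#'   numeric observable columns (e.g. `T1_main`, `T2_main`, `I_main`,
#'   `T1_sec`, `T2_sec`, `I_sec`).
#' @param flat_tol Relative range (range/median) below which a series is
#'   flagged flat.
#' @return List with `stages` (input augmented with `fraction_main` /
#'   `fraction_sec` when both intensities are present) and `trends` (named
#'   character vector of flags, one per observable).
#' @export
drying_summary <- function(stages, flat_tol = 0.5) {
  if (!is.data.frame(stages) || !all(c("sample", "weight") %in% names(stages))) {
    stop_param("stages must contain 'sample' and 'weight' columns")
  }
  if (nrow(stages) < 2) stop_param("need at least 2 drying stages")
  obs_cols <- setdiff(names(stages), c("sample", "weight"))
  num <- obs_cols[vapply(stages[obs_cols], is.numeric, logical(1))]
  if (!length(num)) stop_param("no numeric observable columns found")
  stages <- stages[order(-stages$weight), , drop = FALSE]
  if (all(c("I_main", "I_sec") %in% num)) {
    tot <- stages$I_main + stages$I_sec
    stages$fraction_main <- stages$I_main / tot
    stages$fraction_sec <- stages$I_sec / tot
    num <- c(num, "fraction_main", "fraction_sec")
  }
  classify <- function(v) {
    d <- diff(v)
    if (all(d < 0)) return("decreasing")
    if (all(d > 0)) return("increasing")
    rel <- (max(v) - min(v)) / max(abs(stats::median(v)), .Machine$double.eps)
    if (rel <= flat_tol) "flat" else "mixed"
  }
  trends <- vapply(stages[num], classify, character(1))
  list(stages = stages, trends = trends)
}
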