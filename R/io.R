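#' Read and write decay datasets as CSV plus a JSON sidecar
#'
#' The signal matrix is stored in long format with columns `recovery_ms`,
#' `acq_us`, `signal`, with full decimal precision so that a write/read
#' round trip reproduces the values exactly; the acquisition scheme travels
#' in a JSON sidecar (`<path>.json`).
#'
#' @param dataset A `decay_dataset`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_decay_csv` returns `path` invisibly; `read_decay_csv`
#'   returns a `decay_dataset`.
#' @examples
#' ds <- simulate_ir_fidcpmg(
#'   relaxation_component(100, 10, 1),
#'   acquisition_scheme(recovery_times = c(1, 10, 100, 1000), n_echoes = 5)
#' )
#' p <- tempfile(fileext = ".csv")
#' write_decay_csv(ds, p)
#' ds2 <- read_decay_csv(p)
#' identical(ds$signal, ds2$signal)
#' @export
write_decay_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "decay_dataset"))
  long <- data.frame(
    recovery_ms = rep(dataset$scheme$recovery_times,
                      times = ncol(dataset$signal)),
    acq_us = rep(dataset$acq_times, each = nrow(dataset$signal)),
    signal = as.vector(dataset$signal)
  )
  txt <- data.frame(
    recovery_ms = sprintf("%.17g", long$recovery_ms),
    acq_us = sprintf("%.17g", long$acq_us),
    signal = sprintf("%.17g", long$signal)
  )
  utils::write.csv(txt, path, row.names = FALSE, quote = FALSE)
  sc <- dataset$scheme
  meta <- list(
    recovery_times = sc$recovery_times, recovery_mode = sc$recovery_mode,
    inversion_efficiency = sc$inversion_efficiency, fid_times = sc$fid_times,
    echo_time = sc$echo_time, n_echoes = sc$n_echoes,
    dead_time = sc$dead_time, noise_sigma = sc$noise_sigma, seed = sc$seed,
    channel = dataset$channel
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  long <- utils::read.csv(path, colClasses = "numeric")
  needed <- c("recovery_ms", "acq_us", "signal")
  missing_cols <- setdiff(needed, names(long))
  if (length(missing_cols)) {
    stop_param("decay CSV is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  if (!nrow(long)) stop_param("decay CSV is empty")
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop_param("missing scheme sidecar: %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  scheme <- acquisition_scheme(
    recovery_times = meta$recovery_times,
    recovery_mode = meta$recovery_mode,
    inversion_efficiency = meta$inversion_efficiency,
    fid_times = meta$fid_times,
    echo_time = meta$echo_time, n_echoes = meta$n_echoes,
    dead_time = meta$dead_time, noise_sigma = meta$noise_sigma,
    seed = meta$seed
  )
  t_acq <- acquisition_times(scheme)
  n_rec <- length(scheme$recovery_times)
  if (nrow(long) != n_rec * length(t_acq)) {
    stop_param("decay CSV has %d rows; scheme implies %d x %d = %d",
               nrow(long), n_rec, length(t_acq), n_rec * length(t_acq))
  }
  # recovery and acquisition grids are strictly increasing, so a numeric
  # sort restores the (recovery x acquisition) layout
  ord <- order(long$acq_us, long$recovery_ms)
  signal <- matrix(long$signal[ord], nrow = n_rec)
  structure(
    list(scheme = scheme, signal = signal, acq_times = t_acq,
         channel = if (is.null(meta$channel)) "1H" else meta$channel),
    class = "decay_dataset"
  )
}

#' Read and write dispersion profiles as CSV
#'
#' Columns `freq_MHz`, `R1_per_s`, `err`, `nucleus`.
#'
#' @param profile A [dispersion_profile()].
#' @param path CSV file path.
#' @return `write_dispersion_csv` returns `path` invisibly;
#'   `read_dispersion_csv` returns a [dispersion_profile()].
#' @export
write_dispersion_csv <- function(profile, path) {
  stopifnot(inherits(profile, "dispersion_profile"))
  out <- data.frame(
    freq_MHz = sprintf("%.17g", profile$freq_MHz),
    R1_per_s = sprintf("%.17g", profile$R1_per_s),
    err = sprintf("%.17g", profile$R1_err),
    nucleus = attr(profile, "nucleus")
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dispersion_csv
#' @export
read_dispersion_csv <- function(path) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  df <- utils::read.csv(path)
  needed <- c("freq_MHz", "R1_per_s", "err")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_param("dispersion CSV is missing column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  nucleus <- if ("nucleus" %in% names(df)) df$nucleus[1] else "1H"
  dispersion_profile(df$freq_MHz, df$R1_per_s, df$err, nucleus = nucleus)
}

#' Read and write relaxation maps as a CSV/JSON file set
#'
#' Writes `<stem>_T1axis.csv`, `<stem>_T2axis.csv`, `<stem>_amplitude.csv`
#' and `<stem>_meta.json` (regularization weight, norms, kernel boundary).
#'
#' @param map A `relaxation_map`.
#' @param stem Path stem without extension.
#' @return `write_relaxation_map` returns `stem` invisibly;
#'   `read_relaxation_map` returns a `relaxation_map`.
#' @export
write_relaxation_map <- function(map, stem) {
  stopifnot(inherits(map, "relaxation_map"))
  utils::write.csv(data.frame(T1_ms = sprintf("%.17g", map$grid$T1)),
                   paste0(stem, "_T1axis.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(T2_ms = sprintf("%.17g", map$grid$T2)),
                   paste0(stem, "_T2axis.csv"), row.names = FALSE, quote = FALSE)
  amp <- apply(map$amplitude, 2, function(col) sprintf("%.17g", col))
  utils::write.table(amp, paste0(stem, "_amplitude.csv"),
                     row.names = FALSE, col.names = FALSE, sep = ",",
                     quote = FALSE)
  jsonlite::write_json(
    list(alpha = map$alpha, alpha_method = map$alpha_method,
         gaussian_boundary = map$grid$gaussian_boundary,
         residual_norm = map$residual_norm,
         solution_norm = map$solution_norm,
         total_intensity = map$total_intensity),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(stem)
}

#' @rdname write_relaxation_map
#' @export
read_relaxation_map <- function(stem) {
  paths <- paste0(stem, c("_T1axis.csv", "_T2axis.csv", "_amplitude.csv",
                          "_meta.json"))
  for (p in paths) if (!file.exists(p)) stop_param("missing map file: %s", p)
  T1 <- utils::read.csv(paths[1])$T1_ms
  T2 <- utils::read.csv(paths[2])$T2_ms
  amp <- as.matrix(utils::read.table(paths[3], sep = ","))
  dimnames(amp) <- NULL
  meta <- jsonlite::read_json(paths[4], simplifyVector = TRUE)
  if (nrow(amp) != length(T1) || ncol(amp) != length(T2)) {
    stop_param("amplitude matrix is %d x %d but axes have %d and %d values",
               nrow(amp), ncol(amp), length(T1), length(T2))
  }
  structure(
    list(
      grid = inversion_grid(T1, T2, meta$gaussian_boundary),
      amplitude = amp, alpha = meta$alpha, alpha_method = meta$alpha_method,
      residual_norm = meta$residual_norm, solution_norm = meta$solution_norm,
      total_intensity = meta$total_intensity
    ),
    class = "relaxation_map"
  )
}

#' Read and write run configurations
#'
#' A run configuration is a plain named list (seed, grids, scheme options,
#' inversion and dispersion options, output paths) serialised to JSON. The
#' round trip write/read is lossless for numeric, character and logical
#' fields.
#'
#' @param config Named list.
#' @param path JSON file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_param("no such file: %s", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
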