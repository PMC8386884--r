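#' Physical constants used in relaxation calculations
#'
#' Returns the CODATA 2018 values used throughout the package. All of them can
#' be overridden in the functions that consume them, so alternative conventions
#' (e.g. older gyromagnetic-ratio tabulations) can be swapped in without
#' touching the code.
#'
#' @return A named list with elements
#'   \describe{
#'     \item{gamma_H}{proton gyromagnetic ratio, rad s^-1 T^-1}
#'     \item{gamma_D}{deuteron gyromagnetic ratio, rad s^-1 T^-1}
#'     \item{mu0_over_4pi}{magnetic constant divided by 4 pi, T m A^-1}
#'     \item{hbar}{reduced Planck constant, J s}
#'   }
#' @examples
#' physical_constants()$gamma_H / physical_constants()$gamma_D # about 6.51
#' @export
physical_constants <- function() {
  list(
    gamma_H = 2.6752218744e8,
    gamma_D = 4.10662791e7,
    mu0_over_4pi = 1e-7,
    hbar = 1.054571817e-34
  )
}

# internal: deterministic RNG scope that restores the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Logarithmically spaced grid
#'
#' Convenience generator for the log-spaced timing and frequency grids used
#' throughout recovery experiments and inversion grids.
#'
#' @param from,to Positive endpoints, `from < to`.
#' @param n Number of points (>= 2).
#' @return Numeric vector of `n` log-spaced values including both endpoints.
#' @examples
#' log_spaced(1, 5000, 32)
#' @export
log_spaced <- function(from, to, n) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)
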