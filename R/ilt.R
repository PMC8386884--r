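#' Log-spaced inversion grid for T1-T2 maps
#'
#' Relaxation-time grids on which the inverse Laplace transform is computed.
#' T2 values below `gaussian_boundary` use a Gaussian decay kernel (the
#' solid-like regime of tens of microseconds); values above it use an
#' exponential kernel (the liquid-like regime of milliseconds to seconds).
#' The defaults span the values encountered in hydrated and dried cartilage:
#' T1 from 1 ms to 10 s and T2 from 5 us to 1 s, 64 points each.
#'
#' @param T1 T1 grid values, ms, strictly increasing.
#' @param T2 T2 grid values, ms, strictly increasing.
#' @param gaussian_boundary Boundary in ms between Gaussian and exponential
#'   T2 kernels; must lie within the T2 range.
#' @return An object of class `inversion_grid`.
#' @examples
#' g <- inversion_grid()
#' range(g$T2)
#' @export
inversion_grid <- function(T1 = log_spaced(1, 1e4, 64),
                           T2 = log_spaced(5e-3, 1e3, 64),
                           gaussian_boundary = 1) {
  if (any(diff(T1) <= 0) || any(diff(T2) <= 0) ||
      any(T1 <= 0) || any(T2 <= 0)) {
    stop_param("T1 and T2 grids must be positive and strictly increasing")
  }
  if (gaussian_boundary < min(T2) || gaussian_boundary > max(T2)) {
    stop_param("gaussian_boundary must lie within the T2 range")
  }
  structure(list(T1 = as.numeric(T1), T2 = as.numeric(T2),
                 gaussian_boundary = gaussian_boundary),
            class = "inversion_grid")
}

#' Discretized recovery and decay kernels
#'
#' K1 maps a T1 distribution to recovery amplitudes:
#' `K1[m, i] = 1 - 2 f_inv exp(-t_rec[m]/T1[i])` for inversion recovery, or
#' `1 - exp(-t_rec[m]/T1[i])` for saturation recovery. K2 maps a T2
#' distribution to the acquisition decay with the mixed kernel:
#' `exp(-(t_acq[n]/T2[j])^2)` for grid T2 below the Gaussian boundary and
#' `exp(-t_acq[n]/T2[j])` above it.
#'
#' @param scheme An [acquisition_scheme()].
#' @param grid An [inversion_grid()].
#' @return List with matrices `K1` (recovery x T1) and `K2`
#'   (acquisition x T2).
#' @examples
#' k <- build_kernels(acquisition_scheme(n_echoes = 10), inversion_grid())
#' dim(k$K1); dim(k$K2)
#' @export
build_kernels <- function(scheme, grid) {
  stopifnot(inherits(scheme, "acq_scheme"), inherits(grid, "inversion_grid"))
  t_acq <- acquisition_times(scheme)
  if (any(t_acq < scheme$dead_time)) {
    stop_param("acquisition times below the dead time are not observable")
  }
  K1 <- vapply(grid$T1, function(T1) {
    recovery_factor(scheme$recovery_times, T1, scheme$recovery_mode,
                    scheme$inversion_efficiency)
  }, numeric(length(scheme$recovery_times)))
  K2 <- vapply(seq_along(grid$T2), function(j) {
    shape <- if (grid$T2[j] < grid$gaussian_boundary) "gaussian" else "exponential"
    decay_factor(t_acq, grid$T2[j], shape)
  }, numeric(length(t_acq)))
  list(K1 = K1, K2 = K2)
}

# Lawson-Hanson active-set NNLS on the normal equations:
# minimise ||A x - b||^2 s.t. x >= 0, given AtA = A'A and Atb = A'b.
# Used on the SVD-compressed Tikhonov system, where AtA is positive definite.
fnnls <- function(AtA, Atb, tol = 1e-10, max_iter = NULL) {
  n <- length(Atb)
  if (is.null(max_iter)) max_iter <- max(200L, min(5L * n, 1500L))
  scale <- max(abs(Atb), .Machine$double.eps)
  gtol <- tol * scale
  x <- numeric(n)
  P <- logical(n)
  w <- Atb
  iter <- 0L
  while (any(!P) && max(w[!P]) > gtol) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop_param("non-negative least squares did not converge (gradient norm %.3g after %d iterations)",
                 max(w[!P]), max_iter)
    }
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      idx <- which(P)
      s <- numeric(n)
      sol <- tryCatch(
        solve(AtA[idx, idx, drop = FALSE], Atb[idx]),
        error = function(e) {
          qr.coef(qr(AtA[idx, idx, drop = FALSE]), Atb[idx])
        }
      )
      sol[is.na(sol)] <- 0
      s[idx] <- sol
      if (all(s[idx] > 0)) {
        x <- s
        break
      }
      bad <- idx[s[idx] <= 0]
      alpha <- min(x[bad] / (x[bad] - s[bad]))
      x <- x + alpha * (s - x)
      x[x < 0] <- 0
      P <- P & (x > 0)
      if (!any(P)) break
    }
    w <- Atb - drop(AtA %*% x)
  }
  x
}

# GCV score for Tikhonov regularization in the (compressed) singular basis:
# sigma are the singular values of the compressed kernel, beta the data
# coefficients in the corresponding left singular basis.
gcv_score <- function(alpha, sigma2, beta) {
  filt <- alpha / (sigma2 + alpha)
  sum((filt * beta)^2) / sum(filt)^2
}

select_alpha_gcv <- function(sigma2, beta) {
  smax <- max(sigma2)
  grid <- smax * 10^seq(-9, 1, by = 0.25)
  scores <- vapply(grid, gcv_score, numeric(1), sigma2 = sigma2, beta = beta)
  best <- which.min(scores)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(length(grid), best + 1L)]
  opt <- stats::optimize(function(la) gcv_score(exp(la), sigma2, beta),
                         lower = log(lo), upper = log(hi))
  exp(opt$minimum)
}

# Butler-Reed-Dawson fixed point: at the optimum the dual vector is
# c = residual / alpha, and alpha is chosen so that ||c|| matches the noise
# level, alpha = sqrt(N) sigma_noise / ||c||.
select_alpha_brd <- function(solve_for_alpha, n_data, sigma_noise,
                             alpha0, max_iter = 30, rtol = 1e-3) {
  alpha <- alpha0
  for (i in seq_len(max_iter)) {
    res_norm <- solve_for_alpha(alpha)
    c_norm <- res_norm / alpha
    alpha_new <- sqrt(n_data) * sigma_noise / max(c_norm, .Machine$double.eps)
    if (abs(log(alpha_new / alpha)) < rtol) return(alpha_new)
    alpha <- alpha_new
  }
  alpha
}

#' Two-dimensional inverse Laplace transform of an FID-CPMG dataset
#'
#' Solves
#' \deqn{\hat F = \arg\min_{F \ge 0} \|K_1 F K_2^T - M\|_F^2
#'   + \alpha \|F\|_F^2}
#' after compressing both kernels to `svd_rank` singular components
#' (the standard projection approach for two-dimensional Fredholm
#' inversions). The non-negative solution on the compressed problem is found
#' by active-set non-negative least squares on the normal equations, which
#' inherit the Kronecker structure of the compressed kernels. The
#' regularization weight is chosen by generalized cross-validation
#' (`"gcv"`, default), by the Butler-Reed-Dawson fixed point (`"brd"`), or
#' fixed by the caller (`"fixed"`).
#'
#' @param dataset A `decay_dataset` from [simulate_ir_fidcpmg()] or
#'   [read_decay_csv()].
#' @param grid An [inversion_grid()].
#' @param alpha_method `"gcv"`, `"brd"` or `"fixed"`.
#' @param alpha Regularization weight for `alpha_method = "fixed"` (also the
#'   starting value for `"brd"`).
#' @param svd_rank Number of singular components retained per dimension
#'   (default 16); effective ranks are capped by the data and grid sizes.
#' @param noise_sigma Noise level for `"brd"`; when NULL it is estimated
#'   from the part of the data orthogonal to the compressed kernel space.
#' @return An object of class `relaxation_map`: list with `grid`,
#'   `amplitude` (|T1| x |T2| non-negative matrix), `alpha`, `alpha_method`,
#'   `residual_norm`, `solution_norm` and `total_intensity`.
#' @examples
#' sc <- acquisition_scheme(
#'   recovery_times = log_spaced(1, 5000, 16),
#'   n_echoes = 50
#' )
#' ds <- simulate_ir_fidcpmg(
#'   relaxation_component(100, 10, 1),
#'   sc
#' )
#' g <- inversion_grid(
#'   T1 = log_spaced(10, 1000, 24),
#'   T2 = log_spaced(1, 100, 24),
#'   gaussian_boundary = 1
#' )
#' m <- invert(ds, g, alpha_method = "fixed", alpha = 1e-8)
#' @export
invert <- function(dataset, grid = inversion_grid(),
                   alpha_method = c("gcv", "brd", "fixed"),
                   alpha = NULL, svd_rank = 16, noise_sigma = NULL) {
  alpha_method <- match.arg(alpha_method)
  stopifnot(inherits(dataset, "decay_dataset"), inherits(grid, "inversion_grid"))
  M <- dataset$signal
  if (all(M == 0)) stop_param("all-zero dataset cannot be inverted")
  if (alpha_method == "fixed" && (is.null(alpha) || alpha < 0)) {
    stop_param("alpha_method = 'fixed' requires a non-negative alpha")
  }
  kern <- build_kernels(dataset$scheme, grid)
  r1 <- min(svd_rank, dim(kern$K1))
  r2 <- min(svd_rank, dim(kern$K2))
  if (r1 < 1 || r2 < 1) stop_param("svd_rank must be >= 1")
  s1 <- svd(kern$K1, nu = r1, nv = r1)
  s2 <- svd(kern$K2, nu = r2, nv = r2)
  d1 <- s1$d[seq_len(r1)]
  d2 <- s2$d[seq_len(r2)]
  # compressed kernels K~ = diag(d) V', data projected onto the retained
  # left singular vectors
  K1c <- d1 * t(s1$v)
  K2c <- d2 * t(s2$v)
  Mt <- crossprod(s1$u, M) %*% s2$u                     # r1 x r2
  sigma2 <- as.vector(outer(d1^2, d2^2))                # singular values^2 of kron
  beta <- as.vector(Mt)
  G1 <- crossprod(K1c)                                  # N1 x N1
  G2 <- crossprod(K2c)
  Atb <- as.vector(crossprod(K1c, Mt) %*% K2c)          # vec(K1c' Mt K2c)
  AtA0 <- kronecker(G2, G1)
  n1 <- length(grid$T1); n2 <- length(grid$T2)
  solve_nnls <- function(alpha) {
    AtA <- AtA0
    diag(AtA) <- diag(AtA) + alpha
    fnnls(AtA, Atb)
  }
  if (alpha_method == "gcv") {
    alpha <- select_alpha_gcv(sigma2, beta)
  } else if (alpha_method == "brd") {
    if (is.null(noise_sigma)) {
      # noise estimate from the data outside the compressed kernel space
      resid_proj <- M - s1$u %*% Mt %*% t(s2$u)
      dof <- length(M) - length(Mt)
      noise_sigma <- sqrt(sum(resid_proj^2) / max(dof, 1))
      if (noise_sigma <= 0) noise_sigma <- 1e-8 * max(abs(M))
    }
    alpha0 <- if (is.null(alpha)) 1e-4 * max(sigma2) else alpha
    alpha <- select_alpha_brd(function(a) {
      f <- solve_nnls(a)
      sqrt(sum((beta - sigma_apply(K1c, K2c, f, n1, n2))^2))
    }, n_data = length(beta), sigma_noise = noise_sigma, alpha0 = alpha0)
  }
  x <- solve_nnls(alpha)
  F <- matrix(x, nrow = n1, ncol = n2)
  fitted <- kern$K1 %*% F %*% t(kern$K2)
  structure(
    list(
      grid = grid, amplitude = F, alpha = alpha, alpha_method = alpha_method,
      svd_rank = c(r1, r2),
      residual_norm = sqrt(sum((fitted - M)^2)),
      solution_norm = sqrt(sum(F^2)),
      total_intensity = sum(F)
    ),
    class = "relaxation_map"
  )
}

# compressed forward map vec(K1c F K2c')
sigma_apply <- function(K1c, K2c, x, n1, n2) {
  F <- matrix(x, n1, n2)
  as.vector(K1c %*% F %*% t(K2c))
}

#' @export
print.relaxation_map <- function(x, ...) {
  cat(sprintf(
    "<relaxation_map> %d x %d grid, alpha = %.3g (%s), total intensity %.4g\n  residual norm %.4g, solution norm %.4g\n",
    nrow(x$amplitude), ncol(x$amplitude), x$alpha, x$alpha_method,
    x$total_intensity, x$residual_norm, x$solution_norm
  ))
  invisible(x)
}

#' One-dimensional regularized inversion of a single decay or recovery curve
#'
#' The 1D analogue of [invert()]: fits a non-negative distribution of
#' relaxation times to a single curve, with Tikhonov regularization. For
#' `kind = "T2"` the mixed Gaussian/exponential kernel is used on
#' acquisition times in us; for `kind = "T1"` the recovery kernel is used on
#' recovery times in ms.
#'
#' @param t Time axis: us for `kind = "T2"`, ms for `kind = "T1"`.
#' @param y Signal values.
#' @param kind `"T1"` or `"T2"`.
#' @param values Relaxation-time grid, ms, strictly increasing.
#' @param gaussian_boundary Gaussian/exponential boundary, ms (`kind = "T2"`).
#' @param recovery_mode,f_inv Recovery kernel parameters (`kind = "T1"`).
#' @param alpha_method,alpha,svd_rank As in [invert()].
#' @return List with `values` (the grid), `amplitude` (non-negative),
#'   `alpha`, `residual_norm`, `solution_norm`.
#' @examples
#' t <- seq(16, 20000, by = 50)
#' y <- exp(-t / 5000)
#' fit <- invert_1d(t, y, "T2", values = log_spaced(0.1, 100, 40),
#'                  alpha_method = "fixed", alpha = 1e-8)
#' fit$values[which.max(fit$amplitude)] # near 5 ms
#' @export
invert_1d <- function(t, y, kind = c("T2", "T1"),
                      values = NULL, gaussian_boundary = 1,
                      recovery_mode = "inversion", f_inv = 1,
                      alpha_method = c("gcv", "fixed"), alpha = NULL,
                      svd_rank = 16) {
  kind <- match.arg(kind)
  alpha_method <- match.arg(alpha_method)
  if (length(t) != length(y)) stop_param("t and y must have equal length")
  if (all(y == 0)) stop_param("all-zero curve cannot be inverted")
  if (is.null(values)) {
    values <- if (kind == "T2") log_spaced(5e-3, 1e3, 64) else log_spaced(1, 1e4, 64)
  }
  K <- if (kind == "T2") {
    vapply(seq_along(values), function(j) {
      shape <- if (values[j] < gaussian_boundary) "gaussian" else "exponential"
      decay_factor(t, values[j], shape)
    }, numeric(length(t)))
  } else {
    vapply(values, function(T1) recovery_factor(t, T1, recovery_mode, f_inv),
           numeric(length(t)))
  }
  r <- min(svd_rank, dim(K))
  sv <- svd(K, nu = r, nv = r)
  d <- sv$d[seq_len(r)]
  Kc <- d * t(sv$v)
  b <- drop(crossprod(sv$u, y))
  if (alpha_method == "gcv") {
    alpha <- select_alpha_gcv(d^2, b)
  } else if (is.null(alpha) || alpha < 0) {
    stop_param("alpha_method = 'fixed' requires a non-negative alpha")
  }
  AtA <- crossprod(Kc)
  diag(AtA) <- diag(AtA) + alpha
  x <- fnnls(AtA, drop(crossprod(Kc, b)))
  fitted <- drop(K %*% x)
  list(values = values, amplitude = x, alpha = alpha,
       residual_norm = sqrt(sum((fitted - y)^2)),
       solution_norm = sqrt(sum(x^2)))
}

#' Display a T1-T2 correlation map
#'
#' Filled image of the amplitude distribution on log axes.
#'
#' @param x A `relaxation_map`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.relaxation_map <- function(x, main = "T1-T2 correlation map", ...) {
  graphics::image(
    log10(x$grid$T2), log10(x$grid$T1), t(x$amplitude),
    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
    xlab = "log10 T2 (ms)", ylab = "log10 T1 (ms)", main = main, ...
  )
  invisible(x)
}
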