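#' Configuration for constrained spherical deconvolution
#'
#' @param l_max even SH order (default 8; auto-capped by
#'   [csd_fit_volume()] so the coefficient count never exceeds the number
#'   of measurements — no super-resolution).
#' @param lambda regularization weight of the non-negativity term
#'   (default 4). The useful scale of `lambda` is tied to the package's
#'   FOD amplitude convention; the default suppresses negative lobes to
#'   ~1% of constraint directions while keeping noiseless crossings free
#'   of constraint-induced ringing (see the methods vignette).
#' @param tau threshold factor: the amplitude threshold of an iterate is
#'   `tau` times its mean amplitude on the constraint sampling
#'   (default 0.1).
#' @param i_max iteration cap (default 50; convergence is typically reached
#'   after 5 to 10 iterations).
#' @param constraint_frequency icosphere frequency of the constraint
#'   sampling (default 5, 252 directions).
#' @param constraint_sampling optional explicit `sphere_sampling` override.
#' @return object of class `csd_config`.
#' @export
csd_config <- function(l_max = 8L, lambda = 4.0, tau = 0.1, i_max = 50L,
                       constraint_frequency = 5L, constraint_sampling = NULL) {
  if (i_max < 1L) stop("'i_max' must be >= 1")
  if (!(tau > 0)) stop("'tau' must be > 0")
  if (lambda < 0) stop("'lambda' must be >= 0")
  structure(list(l_max = as.integer(l_max), lambda = lambda, tau = tau,
                 i_max = as.integer(i_max),
                 constraint_frequency = as.integer(constraint_frequency),
                 constraint_sampling = constraint_sampling),
            class = "csd_config")
}

# Precomputed per-acquisition CSD design matrices.
csd_design <- function(gradients, response, config) {
  basis <- sh_basis(config$l_max)
  fac <- zonal_factors(response, basis$l)
  Bg <- sh_basis_matrix(basis, gradients)
  Cs <- if (is.null(config$constraint_sampling)) {
    make_icosphere(config$constraint_frequency)
  } else config$constraint_sampling
  hemi <- hemisphere_index(Cs)
  Bc <- sh_basis_matrix(basis, Cs$directions[hemi, , drop = FALSE])
  list(basis = basis, fwd = sweep(Bg, 2L, fac, "*"), Bc = Bc)
}

#' Constrained spherical deconvolution of one voxel
#'
#' Iteratively solves the regularized deconvolution: minimize
#' `||K *_{S2} g - S||^2 + lambda^2 ||L_{f_i}(g)||^2` where `L_h` keeps the
#' amplitudes of `g` at constraint directions where the previous iterate
#' `h` falls below `tau` times its mean (Heaviside selection) and ignores
#' the rest, driving negative lobes to zero. The initial iterate is the
#' data-driven (unconstrained, lightly damped) solution; iteration stops
#' when the sub-threshold constraint set is unchanged (with a coefficient
#' delta below 1e-6 as numerical guard) or at `i_max`.
#'
#' @param signal per-gradient attenuation values.
#' @param gradients N x 3 unit vectors.
#' @param response single-fiber [zonal_kernel()] (z-aligned).
#' @param config a [csd_config()].
#' @param design optional precomputed design from repeated calls.
#' @return SH coefficient vector of the FOD, with attributes `"iterations"`
#'   and `"converged"`.
#' @export
csd_fit_voxel <- function(signal, gradients, response, config = csd_config(),
                          design = NULL) {
  if (is.null(design)) design <- csd_design(gradients, response, config)
  fwd <- design$fwd; Bc <- design$Bc
  K <- ncol(fwd)
  if (length(signal) < K) {
    stop("fewer measurements than coefficients (super-resolution disabled)")
  }
  ridge <- 1e-8 * sum(fwd^2) / K
  A0 <- crossprod(fwd) + ridge * diag(K)
  b0 <- crossprod(fwd, signal)
  f <- tryCatch(solve(A0, b0), error = function(e)
    stop("conditioning error: ", conditionMessage(e)))
  if (config$lambda == 0) {
    f <- drop(f)
    attr(f, "iterations") <- 0L
    attr(f, "converged") <- TRUE
    return(f)
  }
  lam2 <- config$lambda^2
  prev_set <- NULL
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    amp <- drop(Bc %*% f)
    thr <- config$tau * mean(amp)
    set <- amp < thr
    if (!is.null(prev_set) && identical(set, prev_set)) {
      converged <- TRUE
      break
    }
    prev_set <- set
    if (any(set)) {
      Bn <- Bc[set, , drop = FALSE]
      A <- A0 + lam2 * crossprod(Bn)
    } else {
      A <- A0
    }
    f_new <- solve(A, b0)
    if (max(abs(f_new - f)) < 1e-6) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
    if (it >= config$i_max) break
  }
  f <- drop(f)
  attr(f, "iterations") <- it
  attr(f, "converged") <- converged
  f
}

#' Constrained spherical deconvolution of a volume
#'
#' Voxelwise [csd_fit_voxel()] over a diffusion-weighted volume; masked-out
#' voxels get zero coefficients. `l_max` is auto-capped so that the
#' coefficient count does not exceed the number of gradient directions
#' (e.g. 32 directions force `l_max = 6`, 28 coefficients).
#'
#' @param dw a `dw_signal` volume (see [dw_signal()]).
#' @param response single-fiber [zonal_kernel()].
#' @param config a [csd_config()].
#' @param mask optional logical vector (voxels) or array; default all TRUE.
#' @return an [sh_field()] with attribute `"iterations"` (per-voxel count).
#' @export
csd_fit_volume <- function(dw, response, config = csd_config(), mask = NULL) {
  N_o <- nrow(dw$gradients)
  l_max <- config$l_max
  while ((l_max + 1) * (l_max + 2) / 2 > N_o && l_max > 0) l_max <- l_max - 2L
  if (l_max != config$l_max) {
    config$l_max <- l_max
    message(sprintf("csd_fit_volume: l_max capped to %d for %d directions",
                    l_max, N_o))
  }
  design <- csd_design(dw$gradients, response, config)
  V <- nrow(dw$values)
  if (is.null(mask)) mask <- rep(TRUE, V)
  mask <- as.logical(mask)
  coef <- matrix(0, V, design$basis$n_coef)
  iters <- integer(V)
  for (v in which(mask)) {
    f <- csd_fit_voxel(dw$values[v, ], dw$gradients, response, config,
                       design = design)
    coef[v, ] <- f
    iters[v] <- attr(f, "iterations")
  }
  out <- sh_field(coef, config$l_max, dw$grid_shape, dw$voxel_size)
  attr(out, "iterations") <- iters
  out
}

#' Diffusion-weighted signal volume
#'
#' Attenuations relative to unit b = 0 intensity on a voxel grid.
#'
#' @param values voxels x gradients matrix of nonnegative attenuations.
#' @param gradients N x 3 unit vectors (normalized if slightly off).
#' @param b_value diffusion weighting in s/mm^2.
#' @param grid_shape integer 3-vector.
#' @param voxel_size mm.
#' @return object of class `dw_signal`.
#' @export
dw_signal <- function(values, gradients, b_value, grid_shape, voxel_size = 1) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(is.matrix(values), nrow(values) == prod(grid_shape),
            ncol(values) == nrow(gradients), all(is.finite(values)),
            all(values >= 0))
  nrm <- sqrt(rowSums(gradients^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    warning("non-unit gradient vectors normalized")
  }
  gradients <- gradients / nrm
  structure(list(values = values, gradients = gradients, b_value = b_value,
                 grid_shape = grid_shape,
                 voxel_size = rep(voxel_size, length.out = 3L)),
            class = "dw_signal")
}

#' @export
print.dw_signal <- function(x, ...) {
  cat(sprintf("dw_signal: %s grid, %d gradients, b = %g s/mm^2\n",
              paste(x$grid_shape, collapse = "x"), nrow(x$gradients),
              x$b_value))
  invisible(x)
}

#' Estimate a single-fiber response function from selected voxels
#'
#' For each supplied voxel the signal is aligned to the z-axis by the
#' principal eigenvector of a tensor fit, refit in the SH basis, and the
#' axially symmetric (`m = 0`) part retained; the per-order coefficients
#' are averaged across voxels.
#'
#' @param dw a [dw_signal()] volume.
#' @param single_fiber_voxels integer vector of voxel (linear) indices.
#' @param l_max even order of the response (default 8, capped as in CSD).
#' @return a [zonal_kernel()].
#' @export
estimate_response <- function(dw, single_fiber_voxels, l_max = 8L) {
  if (length(single_fiber_voxels) < 1L) {
    stop("need at least one single-fiber voxel")
  }
  N_o <- nrow(dw$gradients)
  while ((l_max + 1) * (l_max + 2) / 2 > N_o && l_max > 0) l_max <- l_max - 2L
  basis <- sh_basis(l_max)
  tens <- dti_fit(subset_dw(dw, single_fiber_voxels))
  acc <- numeric(l_max / 2 + 1)
  for (k in seq_along(single_fiber_voxels)) {
    v <- single_fiber_voxels[k]
    D <- tens$tensors[[k]]
    e <- eigen(D, symmetric = TRUE)
    R <- cbind(e$vectors[, 2L], e$vectors[, 3L], e$vectors[, 1L])
    if (det(R) < 0) R[, 1L] <- -R[, 1L]
    g_rot <- dw$gradients %*% R            # principal axis -> e_z
    cf <- sh_fit(dw$values[v, ], basis, g_rot)
    m0 <- cf[basis$m == 0L]
    acc <- acc + m0
  }
  zonal_kernel(l_max, acc / length(single_fiber_voxels))
}

subset_dw <- function(dw, voxels) {
  structure(list(values = dw$values[voxels, , drop = FALSE],
                 gradients = dw$gradients, b_value = dw$b_value,
                 grid_shape = c(length(voxels), 1L, 1L),
                 voxel_size = dw$voxel_size),
            class = "dw_signal")
}
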