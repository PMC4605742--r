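#' Contour-enhancement diffusion parameters
#'
#' Parameters of the hypo-elliptic contour-enhancement diffusion on the
#' coupled space of positions and orientations: spatial diffusion acts only
#' along the current orientation with diffusivity `D33` (voxel-length
#' squared per unit time), angular diffusion is isotropic on the sphere with
#' diffusivity `D44` (squared radians per unit time), and `t` is the
#' diffusion time. A smooth kernel exists iff both diffusivities are
#' strictly positive (the Hoermander condition); `t = 0` is the identity.
#'
#' @param D33 spatial diffusivity, > 0.
#' @param D44 angular diffusivity, > 0.
#' @param t diffusion time, >= 0.
#' @param voxel_scale optional scale (voxels per spatial unit) applied to
#'   spatial arguments; defaults to 1 (spatial coordinates in voxel units).
#' @return object of class `enhancement_params`.
#' @export
enhancement_params <- function(D33 = 1.0, D44 = 0.02, t = 1.0,
                               voxel_scale = 1.0) {
  if (!(D33 > 0) || !(D44 > 0)) {
    stop("Hoermander condition: D33 and D44 must both be > 0")
  }
  if (t < 0) stop("'t' must be nonnegative")
  structure(list(D33 = D33, D44 = D44, t = t, voxel_scale = voxel_scale),
            class = "enhancement_params")
}

#' @export
print.enhancement_params <- function(x, ...) {
  cat(sprintf("enhancement_params: D33 = %g, D44 = %g, t = %g\n",
              x$D33, x$D44, x$t))
  invisible(x)
}

#' Stabilized half-angle cotangent factor
#'
#' The factor `theta / (2 tan(theta / 2))` appearing in the logarithmic
#' coordinates of the planar roto-translation group. For `|theta| < pi/10`
#' it is evaluated by its Taylor series
#' `1 - theta^2/12 - theta^4/720 - theta^6/30240 - theta^8/1209600` to
#' avoid cancellation; it is continuous at 0 with value 1.
#'
#' @param theta angle(s) in radians, `|theta| < pi`.
#' @return numeric vector.
#' @export
stab_factor <- function(theta) {
  if (any(abs(theta) >= pi)) stop("|theta| must be < pi")
  out <- numeric(length(theta))
  small <- abs(theta) < pi / 10
  th <- theta[small]
  out[small] <- 1 - th^2 / 12 - th^4 / 720 - th^6 / 30240 - th^8 / 1209600
  th <- theta[!small]
  out[!small] <- th / (2 * tan(th / 2))
  out
}

# Wrap angles to [-pi, pi).
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out
}

#' Sub-Riemannian exponent modulus of the planar enhancement kernel
#'
#' The weighted modulus `EN(x, y, theta)` of the logarithmic coordinates
#' `c1 = stab * x + theta * y / 2`, `c2 = -theta * x / 2 + stab * y`,
#' `c3 = theta` (with `stab = theta / (2 tan(theta/2))`):
#' `EN = sqrt((c3^2/D44 + c1^2/D33)^2 + c2^2 / (D33 D44))`.
#' It vanishes only at the origin and is invariant under
#' `(x, y) -> (-x, -y)`.
#'
#' @param x,y planar offsets (voxel lengths); `x` is the coordinate along
#'   the reference orientation.
#' @param theta orientation offset in radians, `|theta| < pi`.
#' @param params an [enhancement_params()].
#' @return nonnegative numeric vector.
#' @export
en_distance <- function(x, y, theta, params) {
  st <- stab_factor(theta)
  c1 <- st * x + theta * y / 2
  c2 <- -theta * x / 2 + st * y
  sqrt((theta^2 / params$D44 + c1^2 / params$D33)^2 +
         c2^2 / (params$D33 * params$D44))
}

#' Planar contour-enhancement kernel
#'
#' Analytic approximation of the Green's function of the contour-enhancement
#' diffusion on positions and orientations in the plane:
#' `p ~ exp(-EN(x, y, theta) / (4 t))` with a constant prefactor. Only the
#' normalized shape matters downstream (discrete tables are renormalized to
#' unit mass), so the prefactor is nominal.
#'
#' @inheritParams en_distance
#' @return nonnegative kernel values.
#' @export
kernel_2d <- function(x, y, theta, params) {
  if (!(params$t > 0)) stop("'t' must be > 0 (t = 0 is a delta)")
  theta <- wrap_angle(theta)
  # keep strictly inside (-pi, pi); the kernel is vanishingly small there
  theta <- pmin(pi - 1e-9, pmax(-pi + 1e-9, theta))
  pref <- 1 / (32 * pi * params$t^2 * sqrt(params$D33 * params$D44))
  pref * exp(-en_distance(x, y, theta, params) / (4 * params$t))
}

#' Spatial-orientation contour-enhancement kernel
#'
#' Approximate Green's function on 3D positions x orientations, written as a
#' product of two planar kernels in the angular coordinates `(beta, gamma)`
#' of the target orientation:
#' `p_t(y, n) ~ kernel_2d(z/2, x, beta) * kernel_2d(z/2, -y, gamma)`.
#' The kernel is maximal at the origin `(0, e_z)`, decays with the
#' sub-Riemannian cost of reaching `(y, n)` from there, and is (to good
#' approximation) symmetric under simultaneous rotation of `y` and `n`
#' about the z-axis. At the parametrization singularity `n = +-e_x` the
#' degenerate `gamma = 0` is used; kernel values there are negligible for
#' relevant diffusion times.
#'
#' @param y numeric 3-vector of spatial offsets (voxel units), or an N x 3
#'   matrix.
#' @param n unit orientation 3-vector, or N x 3 matrix matched row-wise with
#'   `y`.
#' @param params an [enhancement_params()].
#' @return nonnegative kernel values.
#' @export
kernel_3d <- function(y, n, params) {
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 3L)
  N <- sampling_directions(n)
  if (nrow(N) == 1L && nrow(Y) > 1L) N <- N[rep(1L, nrow(Y)), , drop = FALSE]
  stopifnot(nrow(Y) == nrow(N))
  Y <- Y * params$voxel_scale
  bg <- to_beta_gamma(N)
  kernel_2d(Y[, 3L] / 2, Y[, 1L], bg$beta, params) *
    kernel_2d(Y[, 3L] / 2, -Y[, 2L], bg$gamma, params)
}

#' Default spatial window half-width for a kernel table
#'
#' Chosen from the along-fiber spatial standard deviation of the analytic
#' kernel, `2 sqrt(D33 t)`, so that the clipped tail mass stays below
#' roughly `1e-3`.
#' @param params an [enhancement_params()].
#' @return integer half-width in voxels (>= 1).
#' @export
default_half_width <- function(params) {
  max(1L, as.integer(ceiling(3.3 * 2 * sqrt(params$D33 * params$t))))
}

#' Discretized, normalized shift-twist enhancement kernel
#'
#' Builds the lookup table `lut[offset, target orientation, source
#' orientation]` with `p_t(R_n'^T (y - y'), R_n'^T n)` evaluated
#' analytically for every source orientation `n'` of the sampling (the
#' canonical z-aligned kernel transported by the package rotation convention
#' [rotation_to()]), on the cubic offset window `{-h..h}^3`. Each source
#' slice is normalized to unit mass under the sampling's quadrature weights;
#' optionally the table is then balanced (alternate source/target
#' renormalization) so that the discrete shift-twist convolution both
#' conserves total mass and preserves constants to near machine precision.
#'
#' @param params an [enhancement_params()] with `t > 0`.
#' @param sampling a `sphere_sampling` with at least 42 directions.
#' @param half_width window half-width in voxels (default
#'   [default_half_width()]).
#' @param mass_tolerance maximal tolerated clipped tail-mass fraction; the
#'   canonical slice is probed on an extended window and an error naming the
#'   required half-width is raised when exceeded.
#' @param balance logical; apply the double (source/target) normalization.
#' @return object of class `kernel_lut` with fields `table` (3D array:
#'   offsets x targets x sources), `offsets` (matrix of integer offsets),
#'   `params`, `sampling`, `half_width`, `clipped_mass`.
#' @export
build_kernel_lut <- function(params, sampling, half_width = NULL,
                             mass_tolerance = 1e-3, balance = TRUE) {
  if (!(params$t > 0)) stop("'t' must be > 0")
  M <- nrow(sampling$directions)
  if (M < 42L) stop("sampling must have at least 42 directions")
  if (is.null(half_width)) half_width <- default_half_width(params)
  half_width <- as.integer(half_width)
  if (half_width < 1L) stop("'half_width' must be >= 1")

  off <- as.matrix(expand.grid(x = -half_width:half_width,
                               y = -half_width:half_width,
                               z = -half_width:half_width))
  storage.mode(off) <- "integer"
  D <- nrow(off)
  w <- sampling$weights
  dirs <- sampling$directions

  # Clipped-mass probe on the canonical (e_z) slice with an extended window.
  hx <- half_width + 2L
  offx <- as.matrix(expand.grid(-hx:hx, -hx:hx, -hx:hx))
  vx <- slice_values(offx, dirs, diag(3L), params)
  mass_in <- sum(vx[rowSums(abs(offx) <= half_width) == 3L, ] %*% w)
  mass_ext <- sum(vx %*% w)
  clipped <- 1 - mass_in / mass_ext
  if (clipped >= mass_tolerance) {
    need <- half_width
    repeat {
      need <- need + 1L
      inside <- rowSums(abs(offx) <= min(need, hx)) == 3L
      if (1 - sum(vx[inside, ] %*% w) / mass_ext < mass_tolerance ||
          need >= hx) break
    }
    stop(sprintf(paste0("window too small: clipped tail mass %.2g >= %g; ",
                        "increase half_width to at least %d"),
                 clipped, mass_tolerance, need))
  }

  tab <- array(0, dim = c(D, M, M))
  for (j in seq_len(M)) {
    R <- rotation_to(dirs[j, ])
    tab[, , j] <- slice_values(off, dirs, R, params)
  }
  # source-slice normalization: unit mass per source orientation
  for (j in seq_len(M)) {
    tab[, , j] <- tab[, , j] / sum(tab[, , j] %*% w)
  }
  if (balance) {
    # Alternate scaling (Sinkhorn style): the source-mass constraint makes
    # the convolution conserve total mass, the target-marginal constraint
    # makes it preserve constants; both hold to ~1e-13 after convergence.
    for (it in seq_len(500L)) {
      TM <- colSums(tab)                    # targets x sources
      tgt <- drop(TM %*% w)                 # sum_j w_j sum_d tab[d, n, j]
      if (max(abs(tgt - 1)) < 1e-13) break
      tab <- tab / rep(tgt, each = D)       # divide target marginals out
      m <- drop(crossprod(colSums(tab), w)) # per-source mass after scaling
      tab <- tab / rep(m, each = D * M)     # renormalize source slices
    }
  }
  structure(list(table = tab, offsets = off, params = params,
                 sampling = sampling, half_width = half_width,
                 clipped_mass = clipped),
            class = "kernel_lut")
}

# Kernel values p_t(R^T d, R^T n) on an offset x orientation grid for one
# source rotation R; returns matrix offsets x orientations.
slice_values <- function(off, dirs, R, params) {
  D <- nrow(off); M <- nrow(dirs)
  dr <- off %*% R                     # rows: R^T d
  nr <- dirs %*% R                    # rows: R^T n
  Y <- dr[rep(seq_len(D), each = M), , drop = FALSE]
  N <- nr[rep(seq_len(M), times = D), , drop = FALSE]
  matrix(kernel_3d(Y, N, params), nrow = D, ncol = M, byrow = TRUE)
}

#' @export
print.kernel_lut <- function(x, ...) {
  cat(sprintf(
    "kernel_lut: D33 = %g, D44 = %g, t = %g, half_width = %d, %d dirs\n",
    x$params$D33, x$params$D44, x$params$t, x$half_width,
    nrow(x$sampling$directions)))
  cat(sprintf("  clipped tail mass (canonical slice): %.3g\n", x$clipped_mass))
  invisible(x)
}
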