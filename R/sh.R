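#' Real symmetric spherical-harmonic basis
#'
#' The basis convention used throughout the package: real, orthonormal under
#' the uniform sphere measure, even orders only (FODs are antipodally
#' symmetric), ordered lexicographically by `(l, m)` with `m = -l..l`.
#' Coefficient count is `(l_max + 1) * (l_max + 2) / 2`; 45 for `l_max = 8`
#' and 28 for `l_max = 6`.
#'
#' @param l_max even nonnegative integer, maximal harmonic order.
#' @return an object of class `sh_basis` with fields `l_max`, `l`, `m`
#'   (per-coefficient order/degree) and `n_coef`.
#' @export
sh_basis <- function(l_max) {
  if (length(l_max) != 1L || is.na(l_max) || l_max < 0 || l_max %% 2 != 0) {
    stop("'l_max' must be an even nonnegative integer")
  }
  l <- integer(0); m <- integer(0)
  for (ll in seq(0L, l_max, by = 2L)) {
    l <- c(l, rep(ll, 2L * ll + 1L))
    m <- c(m, seq(-ll, ll))
  }
  structure(list(l_max = as.integer(l_max), l = l, m = m,
                 n_coef = length(l)), class = "sh_basis")
}

#' @export
print.sh_basis <- function(x, ...) {
  cat(sprintf("sh_basis: real symmetric, l_max = %d, %d coefficients\n",
              x$l_max, x$n_coef))
  invisible(x)
}

# Normalized associated Legendre N_l^m P_l^m(x) for m >= 0, with
# N_l^m = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) and Condon-Shortley phase.
# Returns a matrix length(x) x number of (l, m >= 0) pairs for l = 0..l_max.
assoc_legendre_norm <- function(x, l_max) {
  nx <- length(x)
  P <- vector("list", l_max + 1L)       # P[[l+1]] = matrix nx x (l+1), m=0..l
  sx <- sqrt(pmax(0, 1 - x^2))
  for (ll in 0:l_max) P[[ll + 1L]] <- matrix(0, nx, ll + 1L)
  P[[1L]][, 1L] <- 1
  if (l_max >= 1L) {
    P[[2L]][, 1L] <- x
    P[[2L]][, 2L] <- -sx              # P_1^1
  }
  for (ll in 2:max(2L, l_max)) {
    if (ll > l_max) break
    # P_l^l and P_l^{l-1}
    P[[ll + 1L]][, ll + 1L] <- -(2 * ll - 1) * sx * P[[ll]][, ll]
    P[[ll + 1L]][, ll] <- (2 * ll - 1) * x * P[[ll]][, ll]
    if (ll >= 2L) {
      for (mm in 0:(ll - 2L)) {
        P[[ll + 1L]][, mm + 1L] <-
          ((2 * ll - 1) * x * P[[ll]][, mm + 1L] -
             (ll + mm - 1) * P[[ll - 1L]][, mm + 1L]) / (ll - mm)
      }
    }
  }
  for (ll in 0:l_max) {
    mm <- 0:ll
    norm <- exp(0.5 * (log(2 * ll + 1) - log(4 * pi) +
                         lgamma(ll - mm + 1) - lgamma(ll + mm + 1)))
    P[[ll + 1L]] <- sweep(P[[ll + 1L]], 2L, norm, "*")
  }
  P
}

#' Basis matrix of a spherical-harmonic basis on a set of directions
#'
#' @param basis an [sh_basis()].
#' @param sampling a `sphere_sampling`, or an M x 3 matrix of unit vectors.
#' @return M x n_coef matrix of basis values.
#' @export
sh_basis_matrix <- function(basis, sampling) {
  dirs <- sampling_directions(sampling)
  ct <- pmin(1, pmax(-1, dirs[, 3L]))
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  P <- assoc_legendre_norm(ct, basis$l_max)
  B <- matrix(0, nrow(dirs), basis$n_coef)
  s2 <- sqrt(2)
  for (k in seq_len(basis$n_coef)) {
    ll <- basis$l[k]; mm <- basis$m[k]
    if (mm == 0L) {
      B[, k] <- P[[ll + 1L]][, 1L]
    } else if (mm > 0L) {
      B[, k] <- s2 * P[[ll + 1L]][, mm + 1L] * cos(mm * phi)
    } else {
      B[, k] <- s2 * P[[ll + 1L]][, -mm + 1L] * sin(-mm * phi)
    }
  }
  B
}

sampling_directions <- function(sampling) {
  if (inherits(sampling, "sphere_sampling")) return(sampling$directions)
  if (is.numeric(sampling) && is.null(dim(sampling)) && length(sampling) == 3L)
    return(matrix(sampling, 1L, 3L))
  stopifnot(is.matrix(sampling), ncol(sampling) == 3L)
  sampling
}

#' Least-squares spherical-harmonic fit
#'
#' Projects values sampled on the sphere onto an even-order real SH basis by
#' (optionally Laplace-Beltrami regularized) weighted least squares. The fit
#' is exact for band-limited inputs when `lambda = 0`.
#'
#' @param values numeric vector (one value per direction) or matrix
#'   (directions x fields) of function samples.
#' @param basis an [sh_basis()].
#' @param sampling `sphere_sampling` or directions matrix; when a
#'   `sphere_sampling` is given its quadrature weights are used.
#' @param lambda nonnegative Laplace-Beltrami penalty weight.
#' @param design optional precomputed basis matrix for `sampling`.
#' @return coefficient vector, or matrix (n_coef x fields).
#' @export
sh_fit <- function(values, basis, sampling, lambda = 0, design = NULL) {
  B <- if (is.null(design)) sh_basis_matrix(basis, sampling) else design
  if (nrow(B) < basis$n_coef) {
    stop("conditioning error: fewer directions than coefficients")
  }
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  stopifnot(nrow(v) == nrow(B))
  w <- if (inherits(sampling, "sphere_sampling")) sampling$weights
       else rep(1, nrow(B))
  BtW <- t(B * w)
  A <- BtW %*% B
  if (lambda > 0) {
    lb <- (basis$l * (basis$l + 1))^2
    A <- A + lambda * diag(lb, basis$n_coef)
  }
  cf <- tryCatch(solve(A, BtW %*% v),
                 error = function(e) stop("conditioning error: ",
                                          conditionMessage(e)))
  if (is.matrix(values)) cf else drop(cf)
}

#' Evaluate spherical-harmonic coefficients on directions
#'
#' @param coefficients coefficient vector (or n_coef x fields matrix).
#' @param basis an [sh_basis()].
#' @param directions `sphere_sampling` or matrix of unit vectors.
#' @param design optional precomputed basis matrix.
#' @return values per direction (vector or directions x fields matrix).
#' @export
sh_eval <- function(coefficients, basis, directions, design = NULL) {
  B <- if (is.null(design)) sh_basis_matrix(basis, directions) else design
  cf <- if (is.matrix(coefficients)) coefficients
        else matrix(coefficients, ncol = 1L)
  if (nrow(cf) != basis$n_coef) stop("coefficient length does not match basis")
  out <- B %*% cf
  if (is.matrix(coefficients)) out else drop(out)
}

#' Zonal (axially symmetric) spherical kernel
#'
#' One real SH coefficient per even order (`m = 0` only), describing a kernel
#' aligned with and symmetric around the z-axis, e.g. the single-fiber
#' response function of spherical deconvolution.
#'
#' @param l_max even integer.
#' @param coefficients numeric vector of length `l_max / 2 + 1`: the `m = 0`
#'   SH coefficients for orders `0, 2, ..., l_max`.
#' @return an object of class `zonal_kernel`.
#' @export
zonal_kernel <- function(l_max, coefficients) {
  if (l_max %% 2 != 0) stop("'l_max' must be even")
  if (length(coefficients) != l_max / 2 + 1)
    stop("need one coefficient per even order")
  structure(list(l_max = as.integer(l_max),
                 coefficients = as.numeric(coefficients)),
            class = "zonal_kernel")
}

#' @export
print.zonal_kernel <- function(x, ...) {
  cat(sprintf("zonal_kernel: l_max = %d\n", x$l_max))
  cat("  m=0 coefficients:", signif(x$coefficients, 4), "\n")
  invisible(x)
}

# Per-order Funk-Hecke convolution factor of a zonal kernel:
# (K * f)_lm = sqrt(4 pi / (2l+1)) k_l f_lm.
zonal_factors <- function(zonal, l) {
  k <- zonal$coefficients[match(l, seq(0L, zonal$l_max, by = 2L))]
  if (anyNA(k)) stop("zonal kernel lacks a coefficient for some input order")
  sqrt(4 * pi / (2 * l + 1)) * k
}

#' Zonal spherical convolution and deconvolution in the SH domain
#'
#' Applies the Funk-Hecke theorem: convolving with a zonal kernel scales each
#' order-`l` coefficient by `sqrt(4 pi / (2l + 1)) k_l`. With `inverse =
#' TRUE` the coefficients are divided instead, realizing both the forward
#' signal model of spherical deconvolution and a sharpening deconvolution
#' transform; factors smaller in magnitude than `floor` are clipped (with a
#' warning) to keep the inverse bounded.
#'
#' @param coefficients SH coefficient vector or matrix (n_coef x fields).
#' @param basis the [sh_basis()] the coefficients live in.
#' @param zonal a [zonal_kernel()] providing every order present in `basis`.
#' @param inverse logical; divide instead of multiply.
#' @param floor positive lower bound on `|factor|` in inverse mode.
#' @return coefficients of the (de)convolved function.
#' @export
zonal_convolve <- function(coefficients, basis, zonal, inverse = FALSE,
                           floor = 1e-8) {
  fac <- zonal_factors(zonal, basis$l)
  if (inverse) {
    small <- abs(fac) < floor
    if (any(small)) {
      warning(sprintf("%d zonal factor(s) below floor %g clipped",
                      sum(small), floor))
      fac[small] <- sign(fac[small] + (fac[small] == 0)) * floor
    }
    fac <- 1 / fac
  }
  if (is.matrix(coefficients)) coefficients * fac else coefficients * fac
}

#' Angular coordinates of a unit vector
#'
#' Decomposes `n = R_{e_x, gamma} R_{e_y, beta} e_z = (sin(beta),
#' -cos(beta) sin(gamma), cos(beta) cos(gamma))`. `beta` lies in
#' `[-pi, pi)` and `gamma` in `(-pi/2, pi/2]`. At `n = +-e_x` (`cos(beta) =
#' 0`) `gamma` is undefined; it is returned as 0 with `degenerate = TRUE`.
#'
#' @param n unit 3-vector or matrix of row unit vectors.
#' @return list with numeric `beta`, `gamma` and logical `degenerate`
#'   (vectors when `n` is a matrix).
#' @export
to_beta_gamma <- function(n) {
  nm <- sampling_directions(n)
  nx <- pmin(1, pmax(-1, nm[, 1L])); ny <- nm[, 2L]; nz <- nm[, 3L]
  r <- sqrt(ny^2 + nz^2)
  degenerate <- r < 1e-12
  beta0 <- asin(nx)
  beta <- ifelse(nz >= 0, beta0, pi - beta0)
  beta <- ifelse(beta >= pi, beta - 2 * pi, beta)
  gamma <- ifelse(degenerate, 0,
                  ifelse(nz >= 0, atan2(-ny, nz), atan2(ny, -nz)))
  list(beta = beta, gamma = gamma, degenerate = degenerate)
}

# Reconstruct n from (beta, gamma); inverse of to_beta_gamma.
from_beta_gamma <- function(beta, gamma) {
  cbind(sin(beta), -cos(beta) * sin(gamma), cos(beta) * cos(gamma))
}

#' Rotation mapping the north pole onto a direction
#'
#' The minimal (geodesic) rotation `R_n` with `R_n e_z = n`, via Rodrigues'
#' formula about the axis `e_z x n`. For `n` close to `-e_z` a half-turn
#' about `e_x` is used. Any rotation with `R_n e_z = n` is admissible for the
#' shift-twist kernel because the canonical kernel is (approximately) axially
#' symmetric; this choice is the package-wide convention.
#'
#' @param n unit 3-vector.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_to <- function(n) {
  n <- as.numeric(n)
  ez <- c(0, 0, 1)
  c_ <- n[3L]
  if (c_ < -1 + 1e-12) {
    return(diag(c(1, -1, -1)))
  }
  v <- c(ez[2L] * n[3L] - ez[3L] * n[2L],
         ez[3L] * n[1L] - ez[1L] * n[3L],
         ez[1L] * n[2L] - ez[2L] * n[1L])
  K <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3L) + K + K %*% K / (1 + c_)
}
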