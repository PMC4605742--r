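#' Log-linear diffusion tensor fit
#'
#' Per-voxel least-squares fit of `log S = -b g^T D g` (unit b = 0
#' intensity). Eigenvalues are clipped to a small positive floor so every
#' returned tensor is symmetric positive definite; clipped voxels are
#' flagged.
#'
#' @param dw a [dw_signal()] with at least 6 non-collinear gradients.
#' @param eps eigenvalue floor in mm^2/s (default 1e-6).
#' @return object of class `tensor_field`: list with `tensors` (list of
#'   3 x 3 SPD matrices), `clipped` (logical), `residuals` (per-voxel RMS
#'   of log-signal residuals), `grid_shape`, `voxel_size`.
#' @export
dti_fit <- function(dw, eps = 1e-6) {
  g <- dw$gradients
  if (nrow(g) < 6L) stop("need at least 6 gradient directions")
  X <- -dw$b_value * cbind(g[, 1L]^2, g[, 2L]^2, g[, 3L]^2,
                           2 * g[, 1L] * g[, 2L], 2 * g[, 1L] * g[, 3L],
                           2 * g[, 2L] * g[, 3L])
  qrX <- qr(X)
  if (qrX$rank < 6L) stop("need at least 6 non-collinear gradient directions")
  V <- nrow(dw$values)
  tensors <- vector("list", V)
  clipped <- logical(V)
  resid <- numeric(V)
  for (v in seq_len(V)) {
    y <- log(pmax(dw$values[v, ], 1e-12))
    d6 <- qr.coef(qrX, y)
    resid[v] <- sqrt(mean((X %*% d6 - y)^2))
    D <- matrix(c(d6[1L], d6[4L], d6[5L],
                  d6[4L], d6[2L], d6[6L],
                  d6[5L], d6[6L], d6[3L]), 3L, 3L)
    e <- eigen(D, symmetric = TRUE)
    if (any(e$values < eps)) {
      clipped[v] <- TRUE
      ev <- pmax(e$values, eps)
      D <- e$vectors %*% diag(ev) %*% t(e$vectors)
    }
    tensors[[v]] <- D
  }
  structure(list(tensors = tensors, clipped = clipped, residuals = resid,
                 grid_shape = dw$grid_shape, voxel_size = dw$voxel_size),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("tensor_field: %d voxels, %d clipped\n",
              length(x$tensors), sum(x$clipped)))
  invisible(x)
}

#' DTI-based fiber orientation distribution
#'
#' The baseline FOD derived from a tensor field:
#' `U_DTI(y, n) = (n^T D(y)^{-1} n)^{-3/2} / (4 pi * I)` with the global
#' normalization `I = integral over the domain of sqrt(det D)` computed as
#' a voxel-volume-weighted sum over the mask.
#'
#' @param tensors a [dti_fit()] result.
#' @param sampling a `sphere_sampling`.
#' @param domain_mask logical vector over voxels (the domain Omega);
#'   default all voxels.
#' @return a [fod_field()]; masked-out voxels are zero.
#' @export
dti_fod <- function(tensors, sampling, domain_mask = NULL) {
  V <- length(tensors$tensors)
  if (is.null(domain_mask)) domain_mask <- rep(TRUE, V)
  domain_mask <- as.logical(domain_mask)
  dirs <- sampling$directions
  M <- nrow(dirs)
  vol <- prod(tensors$voxel_size)
  dets <- vapply(tensors$tensors, det, numeric(1L))
  if (any(dets[domain_mask] <= 0)) {
    stop(sprintf("singular tensor at voxel %d",
                 which(domain_mask & dets <= 0)[1L]))
  }
  I <- sum(sqrt(dets[domain_mask])) * vol
  vals <- matrix(0, V, M)
  for (v in which(domain_mask)) {
    Dinv <- solve(tensors$tensors[[v]])
    q <- rowSums((dirs %*% Dinv) * dirs)
    vals[v, ] <- q^(-1.5) / (4 * pi * I)
  }
  fod_field(vals, tensors$grid_shape, sampling,
            voxel_size = tensors$voxel_size, symmetrize = FALSE)
}
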