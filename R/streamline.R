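#' Fiber bundle container
#'
#' A set of streamlines with per-point unit tangents. Antipodal doubling
#' (every oriented point counted with both `+n` and `-n`) is handled in the
#' coherence computations by summing over both source orientations, not by
#' duplicating storage; `n_total` reports the doubled count
#' `2 * sum(N_i)`.
#'
#' @param fibers list of numeric matrices (points x 3, mm, world
#'   coordinates), each with at least 2 points.
#' @param step nominal arclength spacing in mm (informational).
#' @return object of class `fiber_bundle` with `fibers`, `tangents`
#'   (matched list of unit tangent matrices) and `n_total`.
#' @export
fiber_bundle <- function(fibers, step = NA_real_) {
  stopifnot(is.list(fibers), length(fibers) >= 1L)
  tang <- lapply(fibers, compute_tangents)
  structure(list(fibers = fibers, tangents = tang,
                 n_total = 2L * sum(vapply(fibers, nrow, integer(1L))),
                 step = step),
            class = "fiber_bundle")
}

#' @export
print.fiber_bundle <- function(x, ...) {
  np <- vapply(x$fibers, nrow, integer(1L))
  cat(sprintf("fiber_bundle: %d fibers, %d points (median %d per fiber)\n",
              length(x$fibers), sum(np), as.integer(stats::median(np))))
  invisible(x)
}

#' Unit tangents of a sampled streamline
#'
#' Central differences at interior points, one-sided at the ends,
#' normalized to unit length.
#'
#' @param points numeric matrix (>= 2 points x 3).
#' @return matrix of unit tangents, same shape.
#' @export
compute_tangents <- function(points) {
  stopifnot(is.matrix(points), nrow(points) >= 2L, ncol(points) == 3L)
  n <- nrow(points)
  d <- points[-1L, , drop = FALSE] - points[-n, , drop = FALSE]
  seg <- sqrt(rowSums(d^2))
  if (any(seg < 1e-12)) {
    stop(sprintf("duplicate consecutive points at index %d",
                 which(seg < 1e-12)[1L]))
  }
  tg <- matrix(0, n, 3L)
  tg[1L, ] <- d[1L, ]
  tg[n, ] <- d[n - 1L, ]
  if (n > 2L) {
    tg[2:(n - 1L), ] <- points[3:n, , drop = FALSE] -
      points[1:(n - 2L), , drop = FALSE]
  }
  tg / sqrt(rowSums(tg^2))
}

#' Resample a streamline at uniform arclength spacing
#'
#' Linear interpolation along the polyline at spacing `step_mm`; the first
#' and last points are retained.
#'
#' @param points matrix (points x 3).
#' @param step_mm target spacing in mm, smaller than the curve length.
#' @return resampled matrix.
#' @export
resample_streamline <- function(points, step_mm) {
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (step_mm >= L) stop("'step_mm' must be smaller than the curve length")
  si <- seq(0, L, by = step_mm)
  if (L - si[length(si)] > step_mm / 2) si <- c(si, L) else si[length(si)] <- L
  out <- matrix(0, length(si), 3L)
  for (k in 1:3) out[, k] <- stats::approx(s, points[, k], xout = si)$y
  out
}

# Streamline length in mm.
streamline_length <- function(points) {
  sum(sqrt(rowSums((points[-1L, , drop = FALSE] -
                      points[-nrow(points), , drop = FALSE])^2)))
}
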