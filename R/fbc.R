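#' Local fiber-to-bundle coherence
#'
#' Treats every oriented streamline point (with both forward and backward
#' tangent, antipodal doubling) as a delta distribution on positions x
#' orientations, diffuses this density with the analytic contour-enhancement
#' kernel, and evaluates the diffused density back at the fiber points:
#' `LFBC(p_i) = 1/N_tot * sum over sigma, fibers j, points q of
#' p_t(R^T_{(-1)^sigma n_jq} (y_i - y_jq), R^T_{(-1)^sigma n_jq} n_i)`.
#' The self term is included. Points that lie in isolated or poorly aligned
#' fibers receive low density. Pairs farther apart than `spatial_cutoff`
#' (where the kernel is below ~1e-6 of its maximum) are skipped; the skip
#' fraction is recorded.
#'
#' @param bundle a [fiber_bundle()].
#' @param params an [enhancement_params()] (default kernel for coherence
#'   scoring: `D33 = 1`, `D44 = 0.04`, `t = 1.4`).
#' @param spatial_cutoff pairwise distance cutoff in mm; `Inf` for the
#'   exact O(N^2) sum. The default `10.5 sqrt(D33 t)` is the along-fiber
#'   distance at which the kernel falls below ~1e-6 of its maximum.
#' @return object of class `lfbc_profile`: list `values` (per fiber, per
#'   point), `params`, `skip_fraction`, `bundle_sizes`.
#' @export
compute_lfbc <- function(bundle, params = enhancement_params(1, 0.04, 1.4),
                         spatial_cutoff = NULL) {
  if (length(bundle$fibers) == 0L) stop("empty bundle")
  if (is.null(spatial_cutoff)) {
    spatial_cutoff <- 10.5 * sqrt(params$D33 * params$t)
  }
  Y <- do.call(rbind, bundle$fibers)
  Tg <- do.call(rbind, bundle$tangents)
  np <- vapply(bundle$fibers, nrow, integer(1L))
  n_pts <- nrow(Y)
  N_tot <- 2 * n_pts
  acc <- numeric(n_pts)
  skipped <- 0
  for (j in seq_len(n_pts)) {
    dy <- Y - matrix(Y[j, ], n_pts, 3L, byrow = TRUE)
    if (is.finite(spatial_cutoff)) {
      near <- which(rowSums(dy * dy) <= spatial_cutoff^2)
      skipped <- skipped + (n_pts - length(near))
    } else {
      near <- seq_len(n_pts)
    }
    if (length(near) == 0L) next
    for (sgn in c(1, -1)) {
      R <- rotation_to(sgn * Tg[j, ])
      yr <- (-dy[near, , drop = FALSE]) %*% R      # R^T (y_i - y_j)
      nr <- Tg[near, , drop = FALSE] %*% R         # R^T n_i
      acc[near] <- acc[near] + kernel_3d(yr, nr, params)
    }
  }
  vals <- split(acc / N_tot, rep(seq_along(np), np))
  structure(list(values = unname(vals), params = params,
                 skip_fraction = skipped / (n_pts^2),
                 bundle_sizes = np),
            class = "lfbc_profile")
}

#' @export
print.lfbc_profile <- function(x, ...) {
  cat(sprintf("lfbc_profile: %d fibers, skip fraction %.3f\n",
              length(x$values), x$skip_fraction))
  invisible(x)
}

#' Fiber-to-bundle coherence of one fiber
#'
#' The mean of the local coherence along the fiber (discrete form of the
#' arclength integral at uniform sampling).
#'
#' @param profile an [compute_lfbc()] result.
#' @param fiber_index fiber number.
#' @return scalar FBC.
#' @export
fbc_full <- function(profile, fiber_index) {
  mean(profile$values[[fiber_index]])
}

#' Windowed-minimum fiber-to-bundle coherence
#'
#' The minimum over all index windows of length `alpha_points` of the
#' window-mean local coherence: low values flag fibers whose least coherent
#' section of that length departs from the bundle.
#'
#' @param profile an [compute_lfbc()] result.
#' @param fiber_index fiber number.
#' @param alpha_points window length in points, `1 <= alpha <= N_i`.
#' @return scalar FBC^alpha.
#' @export
fbc_alpha <- function(profile, fiber_index, alpha_points) {
  v <- profile$values[[fiber_index]]
  n <- length(v)
  a <- as.integer(alpha_points)
  if (a < 1L || a > n) stop("'alpha_points' must be in 1..N_i")
  cs <- c(0, cumsum(v))
  min((cs[(a + 1L):(n + 1L)] - cs[1:(n - a + 1L)]) / a)
}

#' Average fiber-to-bundle coherence of a bundle
#'
#' Mean over fibers of the full-fiber coherence [fbc_full()].
#'
#' @param profile an [compute_lfbc()] result.
#' @return scalar AFBC.
#' @export
afbc <- function(profile) {
  mean(vapply(seq_along(profile$values), function(i) fbc_full(profile, i),
              numeric(1L)))
}

#' Relative fiber-to-bundle coherence scores
#'
#' `RFBC(i) = FBC^alpha(i) / AFBC`: how coherent the least coherent
#' alpha-section of each fiber is, relative to the average coherence of the
#' bundle. Scores are nonnegative; clearly spurious fibers score near 0.
#'
#' @param bundle a [fiber_bundle()].
#' @param params an [enhancement_params()] for the coherence kernel.
#' @param alpha_points window length in points; alternatively give
#'   `alpha_mm` and the bundle's step is used to convert.
#' @param alpha_mm window length in mm (used when `alpha_points` is NULL).
#' @param profile optional precomputed [compute_lfbc()].
#' @param spatial_cutoff passed to [compute_lfbc()].
#' @return numeric vector of per-fiber scores with attribute `"afbc"`.
#' @export
rfbc <- function(bundle, params = enhancement_params(1, 0.04, 1.4),
                 alpha_points = NULL, alpha_mm = 4,
                 profile = NULL, spatial_cutoff = NULL) {
  if (is.null(profile)) {
    profile <- compute_lfbc(bundle, params, spatial_cutoff = spatial_cutoff)
  }
  if (is.null(alpha_points)) {
    if (is.na(bundle$step)) stop("bundle has no step; give alpha_points")
    alpha_points <- max(1L, round(alpha_mm / bundle$step))
  }
  A <- afbc(profile)
  if (A <= 0) stop("invalid state: AFBC is zero (degenerate empty density)")
  out <- vapply(seq_along(profile$values), function(i) {
    a <- min(alpha_points, length(profile$values[[i]]))
    fbc_alpha(profile, i, a) / A
  }, numeric(1L))
  attr(out, "afbc") <- A
  out
}

#' Filter a bundle by relative coherence
#'
#' Retains fibers with `RFBC >= epsilon_fraction * max(RFBC)`; the most
#' coherent fiber always survives, so the filtered set is nonempty.
#'
#' @param bundle a [fiber_bundle()].
#' @param scores per-fiber RFBC scores (from [rfbc()]).
#' @param epsilon_fraction threshold as a fraction of the maximal score,
#'   in `[0, 1]`.
#' @return filtered [fiber_bundle()] with attribute `"kept"` (indices).
#' @export
filter_bundle <- function(bundle, scores, epsilon_fraction) {
  if (epsilon_fraction < 0 || epsilon_fraction > 1) {
    stop("'epsilon_fraction' must be in [0, 1]")
  }
  eps <- epsilon_fraction * max(scores)
  keep <- which(scores >= eps)
  out <- fiber_bundle(bundle$fibers[keep], step = bundle$step)
  attr(out, "kept") <- keep
  out
}

#' Minimal distance from a fiber bundle to a target point
#'
#' The minimum over all fiber points of the Euclidean distance to the
#' target (e.g. the Meyer's loop to temporal pole distance when the bundle
#' is a filtered optic-radiation tractogram and the target the temporal
#' pole).
#'
#' @param bundle a nonempty [fiber_bundle()].
#' @param target_point 3-vector in mm.
#' @return distance in mm.
#' @export
ml_tp_distance <- function(bundle, target_point) {
  if (length(bundle$fibers) == 0L) stop("empty bundle")
  target_point <- as.numeric(target_point)
  best <- Inf
  for (f in bundle$fibers) {
    d2 <- rowSums((f - matrix(target_point, nrow(f), 3L, byrow = TRUE))^2)
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Order fibers by an anatomical coordinate and keep the most extreme
#'
#' Helper for selecting e.g. the most anterior fibers of a tractogram
#' before coherence scoring; each fiber is keyed by the minimum (or
#' maximum) of one coordinate over its points.
#'
#' @param bundle a [fiber_bundle()].
#' @param n_keep number of fibers to keep.
#' @param axis coordinate axis (1, 2 or 3).
#' @param decreasing direction of extremeness (default FALSE: smallest
#'   minima first).
#' @return subsetted [fiber_bundle()].
#' @export
select_extreme_fibers <- function(bundle, n_keep, axis = 2L,
                                  decreasing = FALSE) {
  key <- vapply(bundle$fibers, function(f) min(f[, axis]), numeric(1L))
  o <- order(key, decreasing = decreasing)
  keep <- o[seq_len(min(n_keep, length(o)))]
  fiber_bundle(bundle$fibers[keep], step = bundle$step)
}
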