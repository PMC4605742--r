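#' Find FOD peaks on a tessellation
#'
#' A direction is a peak when its amplitude strictly exceeds all tessellation
#' neighbors and exceeds the threshold: `relative_threshold` times the
#' voxel's maximal amplitude (default mode), or an absolute amplitude in
#' absolute mode. One representative per antipodal pair is returned.
#'
#' @param values amplitudes on the sampling (antipodally symmetric).
#' @param sampling a `sphere_sampling`.
#' @param relative_threshold fraction of the maximum (default 0.1).
#' @param absolute_threshold if not `NULL`, use this amplitude instead.
#' @return list with `directions` (P x 3), `amplitudes`, `index` (vertex
#'   indices); all empty for all-zero input.
#' @export
find_peaks <- function(values, sampling, relative_threshold = 0.1,
                       absolute_threshold = NULL) {
  M <- nrow(sampling$directions)
  stopifnot(length(values) == M)
  vmax <- max(values)
  empty <- list(directions = matrix(0, 0L, 3L), amplitudes = numeric(0),
                index = integer(0))
  if (vmax <= 0) return(empty)
  thr <- if (is.null(absolute_threshold)) relative_threshold * vmax
         else absolute_threshold
  nb <- sampling$neighbors
  nbmax <- rep(-Inf, M)
  for (k in seq_len(ncol(nb))) {
    ok <- !is.na(nb[, k])
    nbmax[ok] <- pmax(nbmax[ok], values[nb[ok, k]])
  }
  is_peak <- values > nbmax & values > thr &
    seq_len(M) < sampling$antipodal_index
  idx <- which(is_peak)
  if (length(idx) == 0L) return(empty)
  o <- order(values[idx], decreasing = TRUE)
  idx <- idx[o]
  list(directions = sampling$directions[idx, , drop = FALSE],
       amplitudes = values[idx], index = idx)
}

#' Tractography configuration
#'
#' Streamline parameters: step size as a fraction of the voxel size
#' (default 1/10), termination cutoff at 10% of the maximal angular
#' response of the FOD field, initial-direction cutoff 0.9 (the first step
#' must start near the strongest peak), and for probabilistic tracking a
#' minimal radius of curvature of 1 mm, which bounds the turning angle per
#' step by `2 asin(step / (2 min_radius))`.
#'
#' @param step_fraction step size / voxel size.
#' @param cutoff relative termination threshold.
#' @param init_cutoff relative threshold for the initial direction.
#' @param min_radius minimal curvature radius in mm (probabilistic).
#' @param min_length minimal streamline length in mm.
#' @param max_steps per-direction step cap.
#' @param rng_seed integer seed; every per-seed-point substream is derived
#'   from it and from the seed position, so results do not depend on seed
#'   ordering.
#' @return object of class `tracking_config`.
#' @export
tracking_config <- function(step_fraction = 0.1, cutoff = 0.1,
                            init_cutoff = 0.9, min_radius = 1,
                            min_length = 0, max_steps = 2000L,
                            rng_seed = 1L) {
  if (!(cutoff > 0) || cutoff > init_cutoff || init_cutoff > 1) {
    stop("need 0 < cutoff <= init_cutoff <= 1")
  }
  structure(list(step_fraction = step_fraction, cutoff = cutoff,
                 init_cutoff = init_cutoff, min_radius = min_radius,
                 min_length = min_length, max_steps = as.integer(max_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_config")
}

# Trilinear interpolation of SH coefficients at world position p (mm).
# Returns NULL outside the grid. Voxel centers sit at (index - 0.5) * size.
interp_coef <- function(field, p) {
  gs <- field$grid_shape; vs <- field$voxel_size
  fx <- p[1L] / vs[1L] - 0.5; fy <- p[2L] / vs[2L] - 0.5
  fz <- p[3L] / vs[3L] - 0.5
  x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  acc <- NULL
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    w <- (if (cx) tx else 1 - tx) * (if (cy) ty else 1 - ty) *
      (if (cz) tz else 1 - tz)
    if (w < 1e-12) next
    jx <- x0 + cx + 1; jy <- y0 + cy + 1; jz <- z0 + cz + 1
    if (jx < 1 || jx > gs[1L] || jy < 1 || jy > gs[2L] ||
        jz < 1 || jz > gs[3L]) next
    v <- jx + (jy - 1) * gs[1L] + (jz - 1) * gs[1L] * gs[2L]
    cf <- w * field$coef[v, ]
    acc <- if (is.null(acc)) cf else acc + cf
  }
  acc
}

in_grid <- function(field, p) {
  gs <- field$grid_shape; vs <- field$voxel_size
  all(p >= 0) && p[1L] <= gs[1L] * vs[1L] && p[2L] <= gs[2L] * vs[2L] &&
    p[3L] <= gs[3L] * vs[3L]
}

# Maximal FOD amplitude over the field, used for the absolute cutoff
# ("10% of the maximal angular response").
field_max_amplitude <- function(field, design, nonzero = NULL) {
  if (is.null(nonzero)) nonzero <- which(rowSums(field$coef^2) > 0)
  if (length(nonzero) == 0L) return(0)
  amps <- field$coef[nonzero, , drop = FALSE] %*% t(design)
  max(amps)
}

# Refine a peak direction by the amplitude-weighted mean of directions
# within a small cone, reducing tessellation quantization.
refine_peak <- function(dir, amps, sampling, cone_deg = 6) {
  ct <- sampling$directions %*% dir
  sel <- which(abs(ct) > cos(cone_deg * pi / 180))
  if (length(sel) < 2L) return(dir)
  d <- sampling$directions[sel, , drop = FALSE]
  d <- d * sign(ct[sel])
  w <- pmax(0, amps[sel])
  if (sum(w) <= 0) return(dir)
  m <- colSums(d * w)
  m / sqrt(sum(m^2))
}

# Deterministic substream seed from master seed and a seed position.
seed_stream <- function(rng_seed, p) {
  h <- sum(round(p * 1024) * c(73856093, 19349663, 83492791))
  as.integer(abs((rng_seed * 2654435761 + h) %% 2147483629))
}

track_one <- function(field, design, sampling, seed_p, cfg, thr_abs,
                      probabilistic) {
  step <- cfg$step_fraction * min(field$voxel_size)
  cf <- interp_coef(field, seed_p)
  if (is.null(cf)) return(NULL)
  amps <- drop(design %*% cf)
  pk <- find_peaks(amps, sampling, absolute_threshold = 0)
  if (length(pk$index) == 0L) return(NULL)
  qual <- which(pk$amplitudes >= cfg$init_cutoff * max(pk$amplitudes))
  pick <- if (length(qual) > 1L) sample(qual, 1L) else qual[1L]
  d0 <- refine_peak(pk$directions[pick, ], amps, sampling)
  if (max(pk$amplitudes) < thr_abs) return(NULL)
  halves <- list()
  max_turn <- 2 * asin(min(1, step / (2 * cfg$min_radius)))
  cos_cone <- cos(max_turn)
  for (sgn in c(1, -1)) {
    p <- seed_p
    d <- sgn * d0
    pts <- matrix(p, 1L, 3L)
    for (k in seq_len(cfg$max_steps)) {
      p_new <- p + step * d
      if (!in_grid(field, p_new)) break
      cf <- interp_coef(field, p_new)
      if (is.null(cf)) break
      amps <- drop(design %*% cf)
      if (probabilistic) {
        ct <- drop(sampling$directions %*% d)
        sel <- which(abs(ct) >= cos_cone)
        if (length(sel) == 0L) break
        w <- pmax(0, amps[sel]) * sampling$weights[sel]
        if (max(pmax(0, amps[sel])) < thr_abs || sum(w) <= 0) break
        j <- sel[sample.int(length(sel), 1L, prob = w)]
        d_new <- sampling$directions[j, ] * sign(ct[j])
      } else {
        pk <- find_peaks(amps, sampling, absolute_threshold = 0)
        if (length(pk$index) == 0L) break
        al <- abs(pk$directions %*% d)
        jb <- which.max(al)
        if (pk$amplitudes[jb] < thr_abs) break
        d_new <- refine_peak(pk$directions[jb, ], amps, sampling)
        d_new <- d_new * sign(sum(d_new * d))
      }
      p <- p_new
      d <- d_new
      pts <- rbind(pts, p)
    }
    halves[[length(halves) + 1L]] <- pts
  }
  fwd <- halves[[1L]]; bwd <- halves[[2L]]
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))[-1L]), , drop = FALSE], fwd)
  if (nrow(pts) < 2L) return(NULL)
  if ((nrow(pts) - 1L) * step < cfg$min_length) return(NULL)
  pts
}

track_impl <- function(field, seeds, config, frequency, probabilistic) {
  sampling <- make_icosphere(frequency)
  design <- sh_basis_matrix(field$basis, sampling)
  thr_abs <- config$cutoff * field_max_amplitude(field, design)
  fibers <- list()
  dropped <- 0L
  for (i in seq_len(nrow(seeds))) {
    sp <- seeds[i, ]
    if (!in_grid(field, sp)) {
      dropped <- dropped + 1L
      next
    }
    set.seed(seed_stream(config$rng_seed, sp))
    pts <- track_one(field, design, sampling, sp, config, thr_abs,
                     probabilistic)
    if (!is.null(pts)) fibers[[length(fibers) + 1L]] <- unname(pts)
  }
  if (dropped > 0L) {
    message(sprintf("%d seed(s) outside the volume skipped", dropped))
  }
  if (length(fibers) == 0L) {
    return(structure(list(fibers = list(), tangents = list(), n_total = 0L,
                          step = config$step_fraction * min(field$voxel_size)),
                     class = "fiber_bundle"))
  }
  fiber_bundle(fibers, step = config$step_fraction * min(field$voxel_size))
}

#' Deterministic streamline tractography on an SH FOD field
#'
#' From each seed, the initial direction is drawn among peaks within
#' `init_cutoff` of the strongest; each subsequent step follows the FOD
#' peak most aligned with the incoming direction (sign-resolved forward),
#' terminating when the best peak falls below `cutoff` times the field's
#' maximal angular response or the track leaves the volume. Tracks proceed
#' in both directions from the seed; tracks shorter than `min_length` are
#' discarded. SH coefficients are interpolated trilinearly.
#'
#' @param field an [sh_field()].
#' @param seeds matrix of seed positions (mm, world).
#' @param config a [tracking_config()].
#' @param frequency icosphere frequency of the direction tessellation
#'   (default 8, 642 directions).
#' @return a [fiber_bundle()].
#' @export
track_deterministic <- function(field, seeds, config = tracking_config(),
                                frequency = 8L) {
  track_impl(field, seeds, config, frequency, probabilistic = FALSE)
}

#' Probabilistic streamline tractography on an SH FOD field
#'
#' Each step samples a direction among tessellation directions inside the
#' curvature cone (turning angle at most `2 asin(step / (2 min_radius))`),
#' with probability proportional to the positive FOD amplitude (quadrature
#' weighted); the track terminates when the positive mass in the cone falls
#' below `cutoff` times the voxel maximum or the field amplitude falls
#' below the absolute cutoff.
#'
#' @inheritParams track_deterministic
#' @return a [fiber_bundle()].
#' @export
track_probabilistic <- function(field, seeds, config = tracking_config(),
                                frequency = 8L) {
  track_impl(field, seeds, config, frequency, probabilistic = TRUE)
}

#' Random seed positions inside a voxel mask
#'
#' @param mask logical vector over voxels (or array).
#' @param grid_shape,voxel_size grid geometry.
#' @param n number of seeds.
#' @param rng_seed integer seed.
#' @return n x 3 matrix of world positions uniform within mask voxels.
#' @export
seed_mask <- function(mask, grid_shape, voxel_size = 1, n = 100L,
                      rng_seed = 1L) {
  voxel_size <- rep(voxel_size, length.out = 3L)
  idx <- which(as.logical(mask))
  set.seed(rng_seed)
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  nx <- grid_shape[1L]; ny <- grid_shape[2L]
  ix <- (pick - 1L) %% nx
  iy <- ((pick - 1L) %/% nx) %% ny
  iz <- (pick - 1L) %/% (nx * ny)
  cbind((ix + stats::runif(n)) * voxel_size[1L],
        (iy + stats::runif(n)) * voxel_size[2L],
        (iz + stats::runif(n)) * voxel_size[3L])
}
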