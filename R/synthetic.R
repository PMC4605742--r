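#' Synthetic fiber-bundle geometry
#'
#' Parametric centerline of a simulated white-matter bundle: a straight
#' segment, a circular arc, or a cubic spline through control points, with
#' a tube radius and a relative volume weight.
#'
#' @param type `"straight"`, `"arc"`, or `"spline"`.
#' @param from,to endpoints in mm (straight).
#' @param center,axis,radius_mm,angle_deg arc parameters: circle center,
#'   unit normal of the arc plane, curve radius (mm) and swept angle; the
#'   arc starts at the projection of `start_dir` onto the plane.
#' @param start_dir unit vector selecting the arc start point
#'   (`center + radius_mm * start_dir`).
#' @param control control-point matrix (spline).
#' @param radius tube radius in mm, > 0.
#' @param weight relative volume fraction (default 1).
#' @return object of class `bundle_geometry`.
#' @export
bundle_geometry <- function(type = c("straight", "arc", "spline"),
                            from = NULL, to = NULL,
                            center = NULL, axis = c(0, 0, 1),
                            radius_mm = NULL, angle_deg = NULL,
                            start_dir = NULL, control = NULL,
                            radius = 1, weight = 1) {
  type <- match.arg(type)
  if (!(radius > 0)) stop("tube 'radius' must be > 0")
  g <- list(type = type, radius = radius, weight = weight)
  if (type == "straight") {
    stopifnot(!is.null(from), !is.null(to))
    g$from <- as.numeric(from); g$to <- as.numeric(to)
  } else if (type == "arc") {
    stopifnot(!is.null(center), !is.null(radius_mm), !is.null(angle_deg),
              !is.null(start_dir))
    axis <- axis / sqrt(sum(axis^2))
    sd <- start_dir - sum(start_dir * axis) * axis
    g$center <- as.numeric(center); g$axis <- axis
    g$radius_mm <- radius_mm; g$angle_deg <- angle_deg
    g$start_dir <- sd / sqrt(sum(sd^2))
  } else {
    stopifnot(is.matrix(control), nrow(control) >= 3L)
    g$control <- control
  }
  class(g) <- "bundle_geometry"
  g
}

#' Sample a bundle centerline
#'
#' @param geom a [bundle_geometry()].
#' @param ds sampling step in mm.
#' @return list with `points`, unit `tangents`, arclengths `s`, total
#'   length `length`.
#' @export
curve_points <- function(geom, ds = 0.25) {
  if (geom$type == "straight") {
    d <- geom$to - geom$from
    L <- sqrt(sum(d^2))
    si <- seq(0, L, length.out = max(2L, ceiling(L / ds) + 1L))
    pts <- outer(si / L, d) + matrix(geom$from, length(si), 3L, byrow = TRUE)
    tg <- matrix(d / L, length(si), 3L, byrow = TRUE)
  } else if (geom$type == "arc") {
    e1 <- geom$start_dir
    e2 <- c(geom$axis[2L] * e1[3L] - geom$axis[3L] * e1[2L],
            geom$axis[3L] * e1[1L] - geom$axis[1L] * e1[3L],
            geom$axis[1L] * e1[2L] - geom$axis[2L] * e1[1L])
    ang <- geom$angle_deg * pi / 180
    L <- geom$radius_mm * ang
    si <- seq(0, L, length.out = max(2L, ceiling(L / ds) + 1L))
    th <- si / geom$radius_mm
    pts <- matrix(geom$center, length(si), 3L, byrow = TRUE) +
      geom$radius_mm * (outer(cos(th), e1) + outer(sin(th), e2))
    tg <- -outer(sin(th), e1) + outer(cos(th), e2)
  } else {
    u <- seq(0, 1, length.out = 200L)
    cp <- apply(geom$control, 2L, function(col) {
      stats::spline(seq(0, 1, length.out = length(col)), col, xout = u)$y
    })
    cp <- resample_streamline(cp, ds)
    pts <- cp
    tg <- compute_tangents(cp)
    seg <- sqrt(rowSums((pts[-1L, ] - pts[-nrow(pts), ])^2))
    si <- c(0, cumsum(seg))
    L <- si[length(si)]
  }
  list(points = pts, tangents = tg, s = si, length = L)
}

#' Build a digital phantom ground truth
#'
#' Rasterizes tube-shaped bundles onto a voxel grid. A voxel belongs to a
#' bundle when its center lies within the tube radius of the centerline;
#' its truth peak is the centerline tangent at the nearest curve point.
#' Truth peaks of overlapping bundles are merged when within 5 degrees.
#' Endpoint regions of interest (ROIs) are the tube voxels whose nearest
#' arclength lies within `roi_depth` of either curve end; endpoint ROIs of
#' different bundles must not overlap.
#'
#' @param geometries list of [bundle_geometry()].
#' @param grid_shape integer 3-vector.
#' @param voxel_size mm per axis (scalar or 3-vector).
#' @param roi_depth ROI depth along the curve in mm (default 2 voxels).
#' @return object of class `phantom_truth`: per-voxel truth peak list
#'   (`peaks`, unit rows; `weights` per peak), `mask` (logical), `bundles`
#'   (each with `centerline`, `tangents`, `radius`, `roi_a`, `roi_b`,
#'   `mask` as linear voxel indices, `weight`), `grid_shape`, `voxel_size`.
#' @export
make_phantom <- function(geometries, grid_shape, voxel_size = 1,
                         roi_depth = NULL) {
  grid_shape <- as.integer(grid_shape)
  voxel_size <- rep(voxel_size, length.out = 3L)
  if (is.null(roi_depth)) roi_depth <- 2 * min(voxel_size)
  V <- prod(grid_shape)
  ctr <- voxel_centers(grid_shape, voxel_size)
  peaks <- vector("list", V)
  wts <- vector("list", V)
  bundles <- vector("list", length(geometries))
  for (b in seq_along(geometries)) {
    geom <- geometries[[b]]
    cv <- curve_points(geom, ds = min(voxel_size) / 4)
    nc <- nrow(cv$points)
    # nearest curve sample per voxel center (chunked distance computation)
    d2min <- rep(Inf, V); imin <- rep(1L, V)
    chunk <- 200L
    for (a in seq(1L, nc, by = chunk)) {
      idx <- a:min(nc, a + chunk - 1L)
      D2 <- outer(rowSums(ctr^2), rep(1, length(idx))) -
        2 * ctr %*% t(cv$points[idx, , drop = FALSE]) +
        outer(rep(1, V), rowSums(cv$points[idx, , drop = FALSE]^2))
      loc <- max.col(-D2, ties.method = "first")
      dloc <- D2[cbind(seq_len(V), loc)]
      upd <- dloc < d2min
      d2min[upd] <- dloc[upd]; imin[upd] <- idx[loc[upd]]
    }
    inside <- d2min <= geom$radius^2
    svox <- cv$s[imin]
    roi_a <- which(inside & svox <= roi_depth)
    roi_b <- which(inside & svox >= cv$length - roi_depth)
    for (v in which(inside)) {
      tgt <- cv$tangents[imin[v], ]
      merged <- FALSE
      if (!is.null(peaks[[v]])) {
        ang <- acos(pmin(1, abs(peaks[[v]] %*% tgt))) * 180 / pi
        hit <- which(ang < 5)
        if (length(hit) > 0L) {
          k <- hit[1L]
          pk <- peaks[[v]][k, ]
          if (sum(pk * tgt) < 0) tgt <- -tgt
          newp <- pk * wts[[v]][k] + tgt * geom$weight
          peaks[[v]][k, ] <- newp / sqrt(sum(newp^2))
          wts[[v]][k] <- wts[[v]][k] + geom$weight
          merged <- TRUE
        }
      }
      if (!merged) {
        peaks[[v]] <- rbind(peaks[[v]], tgt)
        wts[[v]] <- c(wts[[v]], geom$weight)
      }
    }
    bundles[[b]] <- list(centerline = cv$points, tangents = cv$tangents,
                         s = cv$s, length = cv$length, radius = geom$radius,
                         roi_a = roi_a, roi_b = roi_b,
                         mask = which(inside), weight = geom$weight)
  }
  all_rois <- lapply(bundles, function(bb) list(bb$roi_a, bb$roi_b))
  flat <- unlist(all_rois, recursive = FALSE)
  if (length(flat) > 2L) {
    for (i in seq_along(flat)) for (j in seq_along(flat)) {
      same_bundle <- (ceiling(i / 2) == ceiling(j / 2))
      if (i < j && !same_bundle && length(intersect(flat[[i]], flat[[j]])) > 0L) {
        stop("endpoint ROIs of different bundles overlap")
      }
    }
  }
  mask <- !vapply(peaks, is.null, logical(1L))
  structure(list(peaks = peaks, peak_weights = wts, mask = mask,
                 bundles = bundles, grid_shape = grid_shape,
                 voxel_size = voxel_size),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s grid, %d bundles, %d mask voxels\n",
              paste(x$grid_shape, collapse = "x"), length(x$bundles),
              sum(x$mask)))
  invisible(x)
}

voxel_centers <- function(grid_shape, voxel_size) {
  nx <- grid_shape[1L]; ny <- grid_shape[2L]; nz <- grid_shape[3L]
  cbind((rep(seq_len(nx), times = ny * nz) - 0.5) * voxel_size[1L],
        (rep(rep(seq_len(ny), each = nx), times = nz) - 0.5) * voxel_size[2L],
        (rep(seq_len(nz), each = nx * ny) - 0.5) * voxel_size[3L])
}

#' Rician noise model
#'
#' The magnitude-MRI noise convention: with unit b = 0 intensity, the
#' standard deviation of the underlying complex Gaussian noise is
#' `1 / snr`; `snr = Inf` means noiseless.
#'
#' @param snr positive signal-to-noise ratio (w.r.t. the b = 0 image).
#' @param rng_seed integer seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(snr = Inf, rng_seed = 1L) {
  if (!(snr > 0)) stop("'snr' must be > 0")
  structure(list(snr = snr, rng_seed = as.integer(rng_seed)),
            class = "noise_model")
}

#' Simulate a diffusion-weighted volume from phantom truth
#'
#' Forward model: the noiseless signal of a voxel is the weight-normalized
#' sum over its truth peaks of the single-fiber response rotated to each
#' peak, evaluated at the gradient directions (spherical convolution of a
#' sum of delta-peaks with the zonal response). Voxels outside the mask get
#' an isotropic background `exp(-b * md_background)`. Rician noise:
#' `S_noisy = sqrt((S + sigma X)^2 + (sigma Y)^2)` with standard normal
#' `X, Y` and `sigma = 1 / snr`.
#'
#' @param truth a [make_phantom()] result.
#' @param response a [zonal_kernel()] single-fiber response.
#' @param gradients N x 3 unit vectors.
#' @param b_value s/mm^2 (informational; the response is already at b).
#' @param noise a [noise_model()].
#' @param md_background mean diffusivity of the isotropic background in
#'   mm^2/s (default 0.7e-3).
#' @return a [dw_signal()] volume.
#' @export
simulate_dwi <- function(truth, response, gradients, b_value,
                         noise = noise_model(), md_background = 0.7e-3) {
  gradients <- gradients / sqrt(rowSums(gradients^2))
  V <- prod(truth$grid_shape)
  N <- nrow(gradients)
  S <- matrix(exp(-b_value * md_background), V, N)
  for (v in which(truth$mask)) {
    pk <- truth$peaks[[v]]; wk <- truth$peak_weights[[v]]
    ct <- gradients %*% t(pk)            # cos(angle to each peak)
    prof <- matrix(zonal_eval(response, c(ct)), N, nrow(pk))
    S[v, ] <- drop(prof %*% wk) / sum(wk)
  }
  if (is.finite(noise$snr)) {
    sigma <- 1 / noise$snr
    set.seed(noise$rng_seed)
    X <- matrix(stats::rnorm(V * N), V, N)
    Y <- matrix(stats::rnorm(V * N), V, N)
    S <- sqrt((S + sigma * X)^2 + (sigma * Y)^2)
  }
  dw_signal(S, gradients, b_value, truth$grid_shape, truth$voxel_size)
}

# Evaluate a zonal kernel profile at cosines of the polar angle.
zonal_eval <- function(zonal, costheta) {
  lseq <- seq(0L, zonal$l_max, by = 2L)
  P <- assoc_legendre_norm(pmin(1, pmax(-1, costheta)), zonal$l_max)
  out <- 0
  for (k in seq_along(lseq)) {
    out <- out + zonal$coefficients[k] * P[[lseq[k] + 1L]][, 1L]
  }
  out
}

#' Default synthetic single-fiber response
#'
#' Zonal SH fit of the axially symmetric tensor signal
#' `exp(-b n^T diag(1.7, 0.2, 0.2) 1e-3 n)` at the configured b-value.
#'
#' @param b_value s/mm^2.
#' @param l_max even order (default 8).
#' @param lambdas eigenvalues in mm^2/s.
#' @return a [zonal_kernel()].
#' @export
default_response <- function(b_value, l_max = 8L,
                             lambdas = c(1.7e-3, 0.2e-3, 0.2e-3)) {
  s <- make_icosphere(8L)
  d <- s$directions
  sig <- exp(-b_value * (lambdas[1L] * d[, 3L]^2 + lambdas[2L] * d[, 1L]^2 +
                           lambdas[3L] * d[, 2L]^2))
  basis <- sh_basis(l_max)
  cf <- sh_fit(sig, basis, s)
  zonal_kernel(l_max, cf[basis$m == 0L])
}

#' Approximately uniform gradient directions
#'
#' Fibonacci-spiral points on the hemisphere, a standard stand-in for an
#' electrostatically optimized gradient table.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors (z >= 0 hemisphere).
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(1 - z^2)
  unname(cbind(r * cos(phi), r * sin(phi), z))
}

#' Ground-truth FOD field of a phantom
#'
#' Sharp antipodally symmetric Watson-type lobes
#' `exp(kappa ((n . p)^2 - 1))` around each truth peak, weighted by the
#' peak weights; useful as a noise-free FOD input.
#'
#' @param truth a [make_phantom()] result.
#' @param sampling a `sphere_sampling`.
#' @param kappa lobe concentration (default 12).
#' @return a [fod_field()].
#' @export
truth_fod <- function(truth, sampling, kappa = 12) {
  V <- prod(truth$grid_shape)
  M <- nrow(sampling$directions)
  vals <- matrix(0, V, M)
  for (v in which(truth$mask)) {
    pk <- truth$peaks[[v]]; wk <- truth$peak_weights[[v]]
    ct2 <- (sampling$directions %*% t(pk))^2
    vals[v, ] <- drop(exp(kappa * (ct2 - 1)) %*% wk) / sum(wk)
  }
  fod_field(vals, truth$grid_shape, sampling, voxel_size = truth$voxel_size,
            symmetrize = FALSE)
}

#' Sample ground-truth fibers from a bundle tube
#'
#' Copies of the centerline offset by a random in-disc perpendicular
#' displacement (within the tube radius), resampled at uniform arclength,
#' with optional Gaussian positional jitter.
#'
#' @param truth a [make_phantom()] result.
#' @param n_fibers number of fibers.
#' @param step_mm resampling step (must be below the curve length).
#' @param jitter_mm standard deviation of i.i.d. positional jitter.
#' @param rng_seed integer seed.
#' @param bundle bundle index (default 1).
#' @return a [fiber_bundle()].
#' @export
sample_truth_fibers <- function(truth, n_fibers, step_mm, jitter_mm = 0,
                                rng_seed = 1L, bundle = 1L) {
  bb <- truth$bundles[[bundle]]
  if (step_mm >= bb$length) stop("'step_mm' must be below the curve length")
  set.seed(rng_seed)
  fibers <- vector("list", n_fibers)
  for (i in seq_len(n_fibers)) {
    if (i == 1L && jitter_mm == 0) {
      off_r <- 0; off_phi <- 0
    } else {
      off_r <- bb$radius * sqrt(stats::runif(1))
      off_phi <- stats::runif(1, 0, 2 * pi)
    }
    pts <- offset_curve(bb$centerline, bb$tangents, off_r, off_phi)
    pts <- resample_streamline(pts, step_mm)
    if (jitter_mm > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter_mm),
                          nrow(pts), 3L)
    }
    fibers[[i]] <- pts
  }
  fiber_bundle(fibers, step = step_mm)
}

# Offset a centerline perpendicular to its tangent with a consistent frame.
offset_curve <- function(points, tangents, off_r, off_phi) {
  ref <- c(0.31287, -0.52173, 0.79371)   # fixed non-axis reference
  n <- nrow(points)
  out <- points
  for (k in seq_len(n)) {
    tg <- tangents[k, ]
    e1 <- ref - sum(ref * tg) * tg
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(tg[2L] * e1[3L] - tg[3L] * e1[2L],
            tg[3L] * e1[1L] - tg[1L] * e1[3L],
            tg[1L] * e1[2L] - tg[2L] * e1[1L])
    out[k, ] <- points[k, ] + off_r * (cos(off_phi) * e1 + sin(off_phi) * e2)
  }
  out
}

#' Inject spurious fibers into a bundle
#'
#' Appends `k` copies of existing bundle fibers that depart from the bundle
#' over their middle third: a smooth lateral bump of amplitude
#' `lateral_offset_mm` in a random perpendicular direction, combined with a
#' rotation of the displaced section by `angle_deg`. With zero offset and
#' angle the injected fibers are plain duplicates. The returned bundle
#' records the injected indices in its `"outlier_index"` attribute.
#'
#' @param bundle a [fiber_bundle()].
#' @param k number of spurious fibers, >= 0.
#' @param lateral_offset_mm bump amplitude in mm.
#' @param angle_deg tilt of the departing section in degrees.
#' @param rng_seed integer seed.
#' @return a [fiber_bundle()] with `k` extra fibers.
#' @export
inject_spurious <- function(bundle, k, lateral_offset_mm, angle_deg,
                            rng_seed = 1L) {
  if (k < 0) stop("'k' must be >= 0")
  if (k == 0L) {
    attr(bundle, "outlier_index") <- integer(0)
    return(bundle)
  }
  set.seed(rng_seed)
  nf <- length(bundle$fibers)
  fibers <- bundle$fibers
  for (i in seq_len(k)) {
    base <- bundle$fibers[[(i - 1L) %% nf + 1L]]
    n <- nrow(base)
    a <- max(2L, floor(n / 3)); b <- min(n - 1L, ceiling(2 * n / 3))
    tg <- compute_tangents(base)
    mid_t <- colMeans(tg[a:b, , drop = FALSE])
    mid_t <- mid_t / sqrt(sum(mid_t^2))
    az <- stats::runif(1, 0, 2 * pi)
    ref <- c(cos(az), sin(az), stats::runif(1, -0.3, 0.3))
    perp <- ref - sum(ref * mid_t) * mid_t
    perp <- perp / sqrt(sum(perp^2))
    pts <- base
    tau <- (seq(a, b) - a) / max(1L, b - a)
    bump <- lateral_offset_mm * sin(pi * tau)^2
    pts[a:b, ] <- pts[a:b, ] + outer(bump, perp)
    if (angle_deg != 0) {
      mid <- floor((a + b) / 2)
      ax <- c(mid_t[2L] * perp[3L] - mid_t[3L] * perp[2L],
              mid_t[3L] * perp[1L] - mid_t[1L] * perp[3L],
              mid_t[1L] * perp[2L] - mid_t[2L] * perp[1L])
      R <- rodrigues(ax, angle_deg * pi / 180)
      seg <- a:b
      ctr <- pts[mid, ]
      pts[seg, ] <- sweep(sweep(pts[seg, , drop = FALSE], 2L, ctr) %*% t(R),
                          2L, ctr, "+")
    }
    fibers[[nf + i]] <- pts
  }
  out <- fiber_bundle(fibers, step = bundle$step)
  attr(out, "outlier_index") <- nf + seq_len(k)
  out
}

rodrigues <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
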