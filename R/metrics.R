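#' Average angular error of FOD peaks against phantom truth
#'
#' For every truth peak in every mask voxel, the angular distance (with
#' antipodal identification) to the nearest estimated peak is accumulated;
#' the average over all truth peaks is reported in degrees. Estimated
#' peaks are found with [find_peaks()] on the dense tessellation with the
#' standard relative threshold 0.1. Voxels with an empty estimated peak set
#' contribute the worst case of 90 degrees per truth peak (configurable
#' convention).
#'
#' @param est an [sh_field()] (or a precomputed list of per-voxel peak
#'   direction matrices over the mask voxels, in mask order).
#' @param truth a [make_phantom()] result.
#' @param sampling dense `sphere_sampling` for peak extraction (e.g.
#'   frequency 61 for sub-degree resolution).
#' @param threshold relative peak threshold (default 0.1).
#' @param empty_penalty_deg contribution of an empty estimate (default 90).
#' @param design optional precomputed basis matrix on `sampling`.
#' @return average angular error in degrees.
#' @export
angular_error <- function(est, truth, sampling, threshold = 0.1,
                          empty_penalty_deg = 90, design = NULL) {
  vox <- which(truth$mask)
  if (length(vox) == 0L) stop("empty mask")
  precomputed <- !inherits(est, "sh_field")
  if (!precomputed && is.null(design)) {
    design <- sh_basis_matrix(est$basis, sampling)
  }
  total <- 0; count <- 0L
  for (k in seq_along(vox)) {
    v <- vox[k]
    pk_true <- truth$peaks[[v]]
    if (precomputed) {
      dirs <- est[[k]]
    } else {
      amps <- drop(design %*% est$coef[v, ])
      dirs <- find_peaks(amps, sampling, relative_threshold = threshold)$directions
    }
    nv <- nrow(pk_true)
    if (is.null(dirs) || nrow(dirs) == 0L) {
      total <- total + nv * empty_penalty_deg
    } else {
      ct <- abs(pk_true %*% t(dirs))
      best <- apply(ct, 1L, max)
      total <- total + sum(acos(pmin(1, best)) * 180 / pi)
    }
    count <- count + nv
  }
  total / count
}

#' Classify streamline connections against phantom truth
#'
#' A streamline is a valid connection (VC) when its two endpoints lie in
#' the two distinct endpoint ROIs of a single bundle; an invalid connection
#' (IC) when both endpoints lie in endpoint ROIs that do not form a truth
#' pair; no connection (NC) otherwise. Percentages are over all
#' streamlines; zero-point streamlines count as NC.
#'
#' @param bundle a [fiber_bundle()].
#' @param truth a [make_phantom()] result.
#' @return object of class `connection_stats` with `VC`, `IC`, `NC`
#'   percentages, per-streamline class labels, and for VC streamlines the
#'   matched bundle index.
#' @export
classify_connections <- function(bundle, truth) {
  nb <- length(truth$bundles)
  roi_sets <- lapply(truth$bundles, function(bb) list(a = bb$roi_a, b = bb$roi_b))
  n <- length(bundle$fibers)
  lab <- character(n)
  vc_bundle <- integer(n)
  for (i in seq_len(n)) {
    pts <- bundle$fibers[[i]]
    if (is.null(pts) || nrow(pts) == 0L) {
      lab[i] <- "NC"
      next
    }
    e1 <- point_voxel(pts[1L, ], truth)
    e2 <- point_voxel(pts[nrow(pts), ], truth)
    r1 <- roi_membership(e1, roi_sets)
    r2 <- roi_membership(e2, roi_sets)
    if (is.null(r1) || is.null(r2)) {
      lab[i] <- "NC"
    } else {
      match_pair <- r1$bundle == r2$bundle & r1$end != r2$end
      if (any(match_pair)) {
        lab[i] <- "VC"
        vc_bundle[i] <- r1$bundle[which(match_pair)[1L]]
      } else {
        lab[i] <- "IC"
      }
    }
  }
  structure(list(VC = 100 * mean(lab == "VC"),
                 IC = 100 * mean(lab == "IC"),
                 NC = 100 * mean(lab == "NC"),
                 labels = lab, vc_bundle = vc_bundle),
            class = "connection_stats")
}

#' @export
print.connection_stats <- function(x, ...) {
  cat(sprintf("connections: VC %.1f%%, IC %.1f%%, NC %.1f%%\n",
              x$VC, x$IC, x$NC))
  if (!is.null(x$ABC)) {
    cat(sprintf("ABC %.1f%%, CSR %.1f%%, VCCR %.1f%%\n",
                x$ABC, x$CSR, x$VCCR))
  }
  invisible(x)
}

# Linear voxel index of a world point (half-open voxel ownership,
# world = index * spacing with 0-based indices), NA outside.
point_voxel <- function(p, truth) {
  gs <- truth$grid_shape; vs <- truth$voxel_size
  ix <- floor(p[1L] / vs[1L]); iy <- floor(p[2L] / vs[2L])
  iz <- floor(p[3L] / vs[3L])
  if (ix < 0 || ix >= gs[1L] || iy < 0 || iy >= gs[2L] ||
      iz < 0 || iz >= gs[3L]) return(NA_integer_)
  as.integer(ix + iy * gs[1L] + iz * gs[1L] * gs[2L] + 1L)
}

# Which endpoint ROIs (bundle, end) contain a voxel.
roi_membership <- function(vox, roi_sets) {
  if (is.na(vox)) return(NULL)
  bu <- integer(0); en <- character(0)
  for (b in seq_along(roi_sets)) {
    if (vox %in% roi_sets[[b]]$a) { bu <- c(bu, b); en <- c(en, "a") }
    if (vox %in% roi_sets[[b]]$b) { bu <- c(bu, b); en <- c(en, "b") }
  }
  if (length(bu) == 0L) return(NULL)
  list(bundle = bu, end = en)
}

#' Global tractography metrics
#'
#' Completes connection statistics with the derived Tractometer-style
#' metrics: connection-to-seed ratio `CSR = 100 - NC`, valid connection to
#' connection ratio `VCCR = 100 * VC / (VC + IC)` (NaN with a flag when
#' no track connects), and average bundle coverage `ABC`: the percentage
#' of bundle-mask voxels crossed by at least one valid streamline of that
#' bundle, averaged over bundles. Streamline-voxel intersection samples
#' each segment at half-voxel spacing.
#'
#' @param stats a [classify_connections()] result.
#' @param bundle the same [fiber_bundle()].
#' @param truth a [make_phantom()] result.
#' @return `connection_stats` with `ABC`, `CSR`, `VCCR` added.
#' @export
global_metrics <- function(stats, bundle, truth) {
  stats$CSR <- 100 - stats$NC
  if (stats$VC + stats$IC > 0) {
    stats$VCCR <- 100 * stats$VC / (stats$VC + stats$IC)
    stats$vccr_defined <- TRUE
  } else {
    stats$VCCR <- NaN
    stats$vccr_defined <- FALSE
  }
  nb <- length(truth$bundles)
  cov <- numeric(nb)
  for (b in seq_len(nb)) {
    fb <- which(stats$labels == "VC" & stats$vc_bundle == b)
    hit <- integer(0)
    for (i in fb) {
      hit <- c(hit, streamline_voxels(bundle$fibers[[i]], truth))
    }
    cov[b] <- 100 * length(intersect(unique(hit), truth$bundles[[b]]$mask)) /
      length(truth$bundles[[b]]$mask)
  }
  stats$ABC <- mean(cov)
  stats$bundle_coverage <- cov
  stats
}

# Voxels traversed by a streamline (dense point sampling at <= half-voxel
# spacing along each segment).
streamline_voxels <- function(pts, truth) {
  vs <- min(truth$voxel_size)
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  if (max(seg) > vs / 2) {
    pts <- resample_streamline(pts, vs / 2)
    n <- nrow(pts)
  }
  vox <- vapply(seq_len(n), function(k) point_voxel(pts[k, ], truth),
                integer(1L))
  unique(vox[!is.na(vox)])
}
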