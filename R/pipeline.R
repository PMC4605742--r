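#' Pipeline configuration
#'
#' Validated stage-by-stage configuration of the end-to-end pipeline
#' simulate -> csd -> enhance -> track -> fbc -> metrics. Unknown keys are
#' rejected; every stage is optional (skipped when its entry is `NULL`).
#' A single master `seed` deterministically offsets every stage seed.
#'
#' @param simulate list: `geometries` (list of [bundle_geometry()]),
#'   `grid_shape`, `voxel_size`, `n_gradients`, `b_value`, `snr`.
#' @param csd list: `l_max`, `lambda`, `tau`, `i_max`.
#' @param enhance list: `D33`, `D44`, `t`, `frequency`, `half_width`,
#'   `sharpen`.
#' @param track list: `algo` ("deterministic"/"probabilistic"),
#'   `n_seeds`, `min_length`, plus [tracking_config()] fields.
#' @param fbc list: `D33`, `D44`, `t`, `alpha_mm`, `epsilon`,
#'   `resample_mm`.
#' @param metrics list: `target_point` (optional, for the ML-TP distance).
#' @param seed master integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, csd = NULL, enhance = NULL,
                            track = NULL, fbc = NULL, metrics = NULL,
                            seed = 1L) {
  allowed <- list(
    simulate = c("geometries", "grid_shape", "voxel_size", "n_gradients",
                 "b_value", "snr"),
    csd = c("l_max", "lambda", "tau", "i_max"),
    enhance = c("D33", "D44", "t", "frequency", "half_width", "sharpen"),
    track = c("algo", "n_seeds", "min_length", "step_fraction", "cutoff",
              "init_cutoff", "min_radius", "frequency"),
    fbc = c("D33", "D44", "t", "alpha_mm", "epsilon", "resample_mm"),
    metrics = c("target_point"))
  stages <- list(simulate = simulate, csd = csd, enhance = enhance,
                 track = track, fbc = fbc, metrics = metrics)
  for (nm in names(stages)) {
    st <- stages[[nm]]
    if (is.null(st)) next
    bad <- setdiff(names(st), allowed[[nm]])
    if (length(bad) > 0L) {
      stop(sprintf("unknown key(s) in stage '%s': %s", nm,
                   paste(bad, collapse = ", ")))
    }
  }
  structure(c(stages, list(seed = as.integer(seed))),
            class = "pipeline_config")
}

#' Run the configured pipeline
#'
#' Executes the configured stages in order on in-memory objects and
#' returns a report of per-stage parameters, seeds and results (counts,
#' metrics, timings). Randomness flows entirely from the master seed.
#'
#' @param config a [pipeline_config()].
#' @return list report; intermediate objects under `$objects`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(seed = config$seed, stages = list())
  obj <- list()
  seed0 <- config$seed

  if (!is.null(config$simulate)) {
    st <- config$simulate
    tr <- make_phantom(st$geometries, st$grid_shape,
                       st$voxel_size %||% 1)
    resp <- default_response(st$b_value)
    grad <- fibonacci_directions(st$n_gradients %||% 64L)
    dw <- simulate_dwi(tr, resp, grad, st$b_value,
                       noise_model(st$snr %||% Inf, rng_seed = seed0 + 11L))
    obj$truth <- tr; obj$response <- resp; obj$dwi <- dw
    report$stages$simulate <- list(
      n_mask = sum(tr$mask), snr = st$snr %||% Inf, b_value = st$b_value,
      seed = seed0 + 11L)
  }
  if (!is.null(config$csd)) {
    st <- config$csd
    cfg <- csd_config(l_max = st$l_max %||% 8L, lambda = st$lambda %||% 1,
                      tau = st$tau %||% 0.1, i_max = st$i_max %||% 50L)
    fod <- csd_fit_volume(obj$dwi, obj$response, cfg, mask = obj$truth$mask)
    obj$fod <- fod
    it <- attr(fod, "iterations")
    report$stages$csd <- list(l_max = cfg$l_max, lambda = cfg$lambda,
                              tau = cfg$tau,
                              mean_iterations = mean(it[it > 0]))
  }
  if (!is.null(config$enhance)) {
    st <- config$enhance
    par <- enhancement_params(st$D33 %||% 1, st$D44 %||% 0.02, st$t %||% 2)
    fe <- enhance_fod(obj$fod, par, frequency = st$frequency %||% 4L,
                      half_width = st$half_width,
                      sharpen = isTRUE(st$sharpen))
    obj$fod_enhanced <- fe
    report$stages$enhance <- c(unclass(par)[c("D33", "D44", "t")],
                               list(mass = as.list(attr(fe, "mass"))))
  }
  if (!is.null(config$track)) {
    st <- config$track
    fld <- obj$fod_enhanced %||% obj$fod
    tc <- tracking_config(
      step_fraction = st$step_fraction %||% 0.1,
      cutoff = st$cutoff %||% 0.1,
      init_cutoff = st$init_cutoff %||% 0.9,
      min_radius = st$min_radius %||% 1,
      min_length = st$min_length %||% 0,
      rng_seed = seed0 + 31L)
    mask <- obj$truth$bundles[[1L]]$roi_a
    seeds <- seed_mask(seq_len(prod(obj$truth$grid_shape)) %in% mask,
                       obj$truth$grid_shape, obj$truth$voxel_size,
                       n = st$n_seeds %||% 100L, rng_seed = seed0 + 37L)
    algo <- st$algo %||% "deterministic"
    bu <- if (algo == "probabilistic") {
      track_probabilistic(fld, seeds, tc, frequency = st$frequency %||% 8L)
    } else {
      track_deterministic(fld, seeds, tc, frequency = st$frequency %||% 8L)
    }
    obj$tracks <- bu
    report$stages$track <- list(algo = algo, n_tracks = length(bu$fibers),
                                seed = tc$rng_seed)
  }
  if (!is.null(config$fbc)) {
    st <- config$fbc
    bu <- obj$tracks
    if (!is.null(st$resample_mm)) {
      bu <- fiber_bundle(lapply(bu$fibers, resample_streamline,
                                step_mm = st$resample_mm),
                         step = st$resample_mm)
    }
    par <- enhancement_params(st$D33 %||% 1, st$D44 %||% 0.04,
                              st$t %||% 1.4)
    sc <- rfbc(bu, par, alpha_mm = st$alpha_mm %||% 4)
    fl <- filter_bundle(bu, sc, st$epsilon %||% 0.1)
    obj$tracks_filtered <- fl
    report$stages$fbc <- list(
      epsilon = st$epsilon %||% 0.1, n_before = length(bu$fibers),
      n_after = length(fl$fibers),
      removed_fraction = 1 - length(fl$fibers) / length(bu$fibers))
  }
  if (!is.null(config$metrics)) {
    st <- config$metrics
    bu <- obj$tracks_filtered %||% obj$tracks
    cs <- classify_connections(bu, obj$truth)
    cs <- global_metrics(cs, bu, obj$truth)
    rep_m <- list(VC = cs$VC, IC = cs$IC, NC = cs$NC, ABC = cs$ABC,
                  CSR = cs$CSR, VCCR = cs$VCCR)
    if (!is.null(obj$fod)) {
      s_dense <- make_icosphere(16L)
      rep_m$theta_deg <- angular_error(obj$fod, obj$truth, s_dense)
    }
    if (!is.null(st$target_point)) {
      rep_m$ml_tp <- ml_tp_distance(bu, st$target_point)
    }
    report$stages$metrics <- rep_m
  }
  report$objects <- obj
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
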