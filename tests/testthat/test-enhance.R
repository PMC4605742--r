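make_crossing_field <- function(s, gs = c(8, 8, 8), kappa = 8) {
  nx <- gs[1L]
  ix <- rep(seq_len(nx), times = prod(gs[2:3]))
  iy <- rep(rep(seq_len(gs[2L]), each = nx), times = gs[3L])
  iz <- rep(seq_len(gs[3L]), each = prod(gs[1:2]))
  c0 <- (nx + 1) / 2
  ampz <- exp(-((ix - c0)^2 + (iy - c0)^2) / 2)
  ampx <- exp(-((iy - c0)^2 + (iz - c0)^2) / 2)
  lobz <- exp(kappa * (s$directions[, 3L]^2 - 1))
  lobx <- exp(kappa * (s$directions[, 1L]^2 - 1))
  fod_field(outer(ampz, lobz) + outer(ampx, lobx), gs, s,
            symmetrize = FALSE)
}

test_that("shift-twist convolution conserves mass, constants, and linearity", {
  s <- icosphere_cached(3)
  p <- enhancement_params(1, 0.02, 1)
  lut <- build_kernel_lut(p, s, half_width = 3, mass_tolerance = Inf)
  gs <- c(8, 8, 8); V <- prod(gs); M <- nrow(s$directions)
  w <- s$weights
  # constants are fixed points (periodic boundary)
  Uc <- fod_field(matrix(2.5, V, M), gs, s)
  expect_lt(max(abs(shift_twist_convolve(Uc, lut, "periodic")$values - 2.5)),
            1e-9)
  set.seed(1)
  A <- fod_field(matrix(runif(V * M), V, M), gs, s)
  B <- fod_field(matrix(runif(V * M), V, M), gs, s)
  WA <- shift_twist_convolve(A, lut, "periodic")
  WB <- shift_twist_convolve(B, lut, "periodic")
  expect_lt(abs(sum(WA$values %*% w) - sum(A$values %*% w)), 1e-9)
  AB <- fod_field(2 * A$values - 3 * B$values, gs, s, symmetrize = FALSE)
  WAB <- shift_twist_convolve(AB, lut, "periodic")
  expect_lt(max(abs(WAB$values - (2 * WA$values - 3 * WB$values))), 1e-9)
  # sampling mismatch is rejected
  s2 <- icosphere_cached(2)
  U2 <- fod_field(matrix(1, V, nrow(s2$directions)), gs, s2)
  expect_error(shift_twist_convolve(U2, lut), "mismatch")
})

test_that("a delta input reproduces the kernel table slice", {
  s <- icosphere_cached(3)
  p <- enhancement_params(1, 0.02, 1)
  lut <- build_kernel_lut(p, s, half_width = 3, mass_tolerance = Inf)
  gs <- c(8, 8, 8); V <- prod(gs); M <- nrow(s$directions)
  jz <- which.max(s$directions[, 3L])
  v0 <- 4 + 3 * 8 + 3 * 64 + 1
  U0 <- matrix(0, V, M); U0[v0, jz] <- 1
  Wd <- shift_twist_convolve(fod_field(U0, gs, s, symmetrize = FALSE),
                             lut, "periodic")
  # W(v0 + d, n) = w_jz * slice[d, n]; v0 is voxel (5, 4, 4)
  for (r in sample(nrow(lut$offsets), 25L)) {
    d <- lut$offsets[r, ]
    idx <- cbind((5 + d[1L] - 1) %% 8 + 1, (4 + d[2L] - 1) %% 8 + 1,
                 (4 + d[3L] - 1) %% 8 + 1)
    lin <- idx[1L] + (idx[2L] - 1) * 8 + (idx[3L] - 1) * 64
    expect_equal(Wd$values[lin, ], s$weights[jz] * lut$table[r, , jz],
                 tolerance = 1e-12)
  }
})

test_that("finite-difference evolver realizes the degenerate limits", {
  s <- icosphere_cached(3)
  gs <- c(6, 6, 6); V <- prod(gs); M <- nrow(s$directions)
  set.seed(2)
  U <- fod_field(matrix(runif(V * M), V, M), gs, s)
  p <- enhancement_params(1, 0.02, 1)
  # full bypass: identity
  W0 <- fd_evolve(U, p, n_steps = 5, zero_D33 = TRUE, zero_D44 = TRUE)
  expect_equal(W0$values, U$values)
  # pure angular diffusion from a sphere delta: flows toward uniform
  U1 <- matrix(0, V, M); U1[, which.max(s$directions[, 3L])] <- 1
  Ud <- fod_field(U1, gs, s, symmetrize = FALSE)
  vars <- numeric(4L)
  Wk <- Ud
  for (k in 1:4) {
    Wk <- fd_evolve(Wk, enhancement_params(1, 0.5, 0.5), n_steps = 20,
                    zero_D33 = TRUE, boundary = "periodic")
    vars[k] <- stats::var(Wk$values[1L, ])
  }
  expect_true(all(diff(vars) < 0))
  # weighted angular mass conserved
  expect_lt(abs(sum(Wk$values[1L, ] * s$weights) -
                  sum(Ud$values[1L, ] * s$weights)), 1e-6)
  # unstable step is refused with the maximal stable step named
  expect_error(fd_evolve(U, enhancement_params(1, 0.02, 10), n_steps = 2),
               "maximal stable step")
})

test_that("the two realizations of the diffusion agree on bundle fields", {
  s <- icosphere_cached(4)
  p <- enhancement_params(1, 0.02, 1)
  U <- make_crossing_field(s)
  lut <- build_kernel_lut(p, s, half_width = 3, mass_tolerance = Inf)
  Wk <- shift_twist_convolve(U, lut, "periodic")
  Wf <- fd_evolve(U, p, n_steps = 40, boundary = "periodic")
  expect_gt(stats::cor(c(Wk$values), c(Wf$values)), 0.95)
  # mass conservation of the FD path
  expect_lt(abs(sum(Wf$values %*% s$weights) - sum(U$values %*% s$weights)),
            1e-6)
})

test_that("the FD evolution is approximately a semigroup", {
  s <- icosphere_cached(3)
  gs <- c(6, 6, 6)
  U <- make_crossing_field(s, gs)
  half <- enhancement_params(1, 0.02, 0.5)
  full <- enhancement_params(1, 0.02, 1)
  W2 <- fd_evolve(fd_evolve(U, half, 20, "periodic"), half, 20, "periodic")
  W1 <- fd_evolve(U, full, 40, "periodic")
  expect_lt(max(abs(W2$values - W1$values)) / max(W1$values), 1e-3)
})

test_that("enhancement at t = 0 reduces to the SH round trip", {
  fx <- straight_field()
  p0 <- enhancement_params(1, 0.02, 0)
  fe <- enhance_fod(fx$field, p0, frequency = 4)
  expect_lt(max(abs(fe$coef - fx$field$coef)), 1e-6)
})

test_that("angular diffusion reorients peaks along a curved bundle", {
  # curved (arc) bundle whose FOD peaks all point along the chord: with
  # D44 ~ 0 the peaks stay misaligned; with D44 > 0 they turn toward the
  # local tangent
  g <- bundle_geometry("arc", center = c(10, 10, 4), axis = c(0, 0, 1),
                       radius_mm = 7, angle_deg = 90,
                       start_dir = c(-1, 0, 0), radius = 1.2)
  tr <- make_phantom(list(g), c(14, 14, 8), 1)
  s <- icosphere_cached(3)
  # misaligned input: single fixed lobe along the chord direction
  chord <- c(1, -1, 0) / sqrt(2)
  V <- prod(tr$grid_shape); M <- nrow(s$directions)
  lob <- exp(10 * ((s$directions %*% chord)^2 - 1))
  vals <- matrix(0, V, M)
  vals[tr$mask, ] <- matrix(lob, sum(tr$mask), M, byrow = TRUE)
  U <- fod_field(vals, tr$grid_shape, s, symmetrize = FALSE)
  peak_angle <- function(W) {
    errs <- c()
    for (v in which(tr$mask)) {
      pk <- find_peaks(W$values[v, ], s, relative_threshold = 0.5)
      tgt <- tr$peaks[[v]][1L, ]
      errs <- c(errs, acos(min(1, abs(sum(pk$directions[1L, ] * tgt)))))
    }
    mean(errs) * 180 / pi
  }
  p <- enhancement_params(1, 0.04, 2)
  W_no_ang <- fd_evolve(U, p, 60, "periodic", zero_D44 = TRUE)
  W_ang <- fd_evolve(U, p, 60, "periodic")
  expect_lt(peak_angle(W_ang), peak_angle(W_no_ang))
})

test_that("enhancement preserves a 90-degree crossing", {
  s <- icosphere_cached(4)
  U <- make_crossing_field(s, gs = c(8, 8, 8), kappa = 10)
  p <- enhancement_params(1, 0.02, 4)
  lut <- build_kernel_lut(p, s, half_width = 3, mass_tolerance = Inf)
  W <- shift_twist_convolve(U, lut, "periodic")
  center <- 4 + 3 * 8 + 3 * 64 + 1
  s16 <- icosphere_cached(16)
  cf <- sh_fit(W$values[center, ], sh_basis(8), s)
  pk <- find_peaks(sh_eval(cf, sh_basis(8), s16), s16)
  expect_gte(nrow(pk$directions), 2L)
  a1 <- acos(min(1, abs(pk$directions[1L, 3L])))
  a2 <- acos(min(1, abs(pk$directions[2L, 1L])))
  expect_lt(sort(c(a1, a2))[1L] * 180 / pi, 5)
  expect_lt(sort(c(a1, a2))[2L] * 180 / pi, 5)
})

test_that("grid rotation by a half turn commutes with enhancement", {
  # the icosphere maps to itself under a 180-degree rotation about z, so
  # equivariance holds up to the kernel's approximate axial symmetry
  s <- icosphere_cached(3)
  gs <- c(8, 8, 8)
  U <- make_crossing_field(s, gs)
  p <- enhancement_params(1, 0.02, 1)
  lut <- build_kernel_lut(p, s, half_width = 3, mass_tolerance = Inf)
  rot_vox <- function(vals) {
    arr <- array(vals, c(gs, ncol(vals)))
    arr <- arr[gs[1L]:1, gs[2L]:1, , , drop = FALSE]
    matrix(arr, prod(gs), ncol(vals))
  }
  # direction map under (x,y,z) -> (-x,-y,z)
  dmap <- vapply(seq_len(nrow(s$directions)), function(j) {
    tgt <- s$directions[j, ] * c(-1, -1, 1)
    which.min(colSums((t(s$directions) - tgt)^2))
  }, integer(1L))
  expect_lt(max(abs(s$directions[dmap, ] -
                      sweep(s$directions, 2L, c(-1, -1, 1), "*"))), 1e-12)
  U_rot <- fod_field(rot_vox(U$values)[, dmap], gs, s, symmetrize = FALSE)
  W1 <- shift_twist_convolve(U_rot, lut, "periodic")$values
  W2 <- rot_vox(shift_twist_convolve(U, lut, "periodic")$values)[, dmap]
  expect_lt(max(abs(W1 - W2)) / max(abs(W2)), 0.05)
})

test_that("sharpening deconvolution undoes a zonal blur", {
  fx <- straight_field()
  lseq <- seq(0L, 8L, by = 2L)
  blur <- exp(-0.05 * lseq * (lseq + 1))
  zk <- zonal_kernel(8, blur * sqrt((2 * lseq + 1) / (4 * pi)))
  blurred <- sh_field(t(zonal_convolve(t(fx$field$coef), fx$field$basis, zk)),
                      8, fx$field$grid_shape, fx$field$voxel_size)
  restored <- sharpen_fod(blurred, zk)
  expect_lt(max(abs(restored$coef - fx$field$coef)), 1e-8)
})
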