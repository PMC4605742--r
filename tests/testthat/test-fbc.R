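test_that("tangent computation matches analytic curves", {
  # straight line
  pts <- cbind(seq(0, 10, by = 0.5), 0, 0)
  tg <- compute_tangents(pts)
  expect_lt(max(abs(tg - matrix(c(1, 0, 0), nrow(pts), 3L, byrow = TRUE))),
            1e-12)
  # planar circle at 1 degree sampling: tangent perpendicular to radius
  th <- seq(0, pi / 2, by = pi / 180)
  circ <- cbind(10 * cos(th), 10 * sin(th), 0)
  tgc <- compute_tangents(circ)
  inner <- 2:(length(th) - 1L)
  expect_lt(max(abs(rowSums(tgc[inner, ] * circ[inner, ]) / 10)), 1e-4)
  # helix: second-order accuracy of central differences
  hel <- function(h) {
    s <- seq(0, 4 * pi, by = h)
    pts <- cbind(cos(s), sin(s), 0.5 * s)
    tan_true <- cbind(-sin(s), cos(s), 0.5) / sqrt(1.25)
    inner <- 2:(length(s) - 1L)
    max(abs(compute_tangents(pts)[inner, ] - tan_true[inner, ]))
  }
  e1 <- hel(0.1); e2 <- hel(0.05)
  expect_gt(e1 / e2, 3)   # ~ O(h^2)
  expect_error(compute_tangents(rbind(c(0, 0, 0), c(0, 0, 0))),
               "duplicate consecutive points at index 1")
})

test_that("LFBC is invariant to duplication and rigid translation", {
  bu <- outlier_bundle()
  pr <- compute_lfbc(bu, fbc_params(), spatial_cutoff = Inf)
  # duplicating every fiber leaves LFBC unchanged (1/N_tot normalization)
  bu2 <- fiber_bundle(c(bu$fibers, bu$fibers), step = bu$step)
  pr2 <- compute_lfbc(bu2, fbc_params(), spatial_cutoff = Inf)
  n <- length(bu$fibers)
  expect_lt(max(abs(unlist(pr$values) - unlist(pr2$values[seq_len(n)]))),
            1e-12)
  # rigid translation
  bu3 <- fiber_bundle(lapply(bu$fibers, function(f)
    sweep(f, 2L, c(3.2, -1.5, 0.4), "+")), step = bu$step)
  pr3 <- compute_lfbc(bu3, fbc_params(), spatial_cutoff = Inf)
  expect_lt(max(abs(unlist(pr$values) - unlist(pr3$values))), 1e-9)
  expect_error(compute_lfbc(structure(list(fibers = list()),
                                      class = "fiber_bundle")), "empty")
})

test_that("the spatial cutoff changes LFBC negligibly while skipping pairs", {
  bu <- outlier_bundle()
  exact <- compute_lfbc(bu, fbc_params(), spatial_cutoff = Inf)
  cut <- compute_lfbc(bu, fbc_params())
  expect_gt(cut$skip_fraction, 0)
  rel <- max(abs(unlist(exact$values) - unlist(cut$values))) /
    max(unlist(exact$values))
  expect_lt(rel, 1e-4)
})

test_that("an offset outlier has the minimal coherence along the bundle", {
  bu <- outlier_bundle()
  out_idx <- attr(bu, "outlier_index")
  pr <- compute_lfbc(bu, fbc_params())
  means <- vapply(seq_along(pr$values), function(i) mean(pr$values[[i]]),
                  numeric(1L))
  expect_equal(which.min(means), out_idx[which.min(means[out_idx])])
  expect_lt(max(means[out_idx]), min(means[-out_idx]))
})

test_that("windowed coherence minima match brute-force enumeration", {
  prof <- structure(list(values = list(c(1, 1, 0, 1))), class = "lfbc_profile")
  expect_equal(fbc_alpha(prof, 1L, 1L), 0)
  expect_equal(fbc_alpha(prof, 1L, 4L), fbc_full(prof, 1L))
  expect_error(fbc_alpha(prof, 1L, 5L), "1..N_i")
  set.seed(2)
  for (rep in 1:5) {
    v <- runif(17)
    prof <- structure(list(values = list(v)), class = "lfbc_profile")
    for (a in c(1L, 3L, 8L, 17L)) {
      brute <- min(vapply(0:(17L - a), function(st) mean(v[(st + 1):(st + a)]),
                          numeric(1L)))
      expect_equal(fbc_alpha(prof, 1L, a), brute, tolerance = 1e-12)
    }
  }
})

test_that("relative coherence scores behave as normalized quantities", {
  # one fiber with alpha = N: RFBC = 1 exactly
  single <- fiber_bundle(list(cbind(seq(0, 10), 0, 0)), step = 1)
  sc1 <- rfbc(single, fbc_params(), alpha_points = 11L)
  expect_equal(as.numeric(sc1), 1, tolerance = 1e-12)
  # duplication leaves scores unchanged
  bu <- outlier_bundle()
  sc <- rfbc(bu, fbc_params(), alpha_mm = 4, spatial_cutoff = Inf)
  bu2 <- fiber_bundle(c(bu$fibers, bu$fibers), step = bu$step)
  sc2 <- rfbc(bu2, fbc_params(), alpha_mm = 4, spatial_cutoff = Inf)
  n <- length(bu$fibers)
  expect_lt(max(abs(as.numeric(sc) - as.numeric(sc2)[seq_len(n)])), 1e-9)
  expect_true(all(sc >= 0))
  # permutation invariance of the score ordering
  perm <- sample(length(bu$fibers))
  bup <- fiber_bundle(bu$fibers[perm], step = bu$step)
  scp <- rfbc(bup, fbc_params(), alpha_mm = 4, spatial_cutoff = Inf)
  expect_lt(max(abs(as.numeric(scp) - as.numeric(sc)[perm])), 1e-9)
})

test_that("coherence filtering removes offset outliers and keeps the bundle", {
  bu <- outlier_bundle()
  out_idx <- attr(bu, "outlier_index")
  sc <- rfbc(bu, fbc_params(), alpha_mm = 4)
  expect_setequal(order(sc)[seq_along(out_idx)], out_idx)
  fl <- filter_bundle(bu, sc, 0.1)
  kept <- attr(fl, "kept")
  expect_false(any(out_idx %in% kept))
  expect_gte(sum(setdiff(seq_len(20L), out_idx) %in% kept), 19L)
  # epsilon extremes
  expect_equal(length(filter_bundle(bu, sc, 0)$fibers), length(bu$fibers))
  top <- filter_bundle(bu, sc, 1)
  expect_equal(attr(top, "kept"), which(sc == max(sc)))
  expect_error(filter_bundle(bu, sc, 1.5), "0, 1")
})

test_that("coherence is invariant under rigid motions up to kernel tolerance", {
  bu <- outlier_bundle()
  sc <- rfbc(bu, fbc_params(), alpha_mm = 4, spatial_cutoff = Inf)
  R <- fodflow:::rodrigues(c(1, 2, 0.5), 0.8)
  bur <- fiber_bundle(lapply(bu$fibers, function(f)
    sweep(f %*% t(R), 2L, c(4, -2, 1), "+")), step = bu$step)
  scr <- rfbc(bur, fbc_params(), alpha_mm = 4, spatial_cutoff = Inf)
  # the R_n-convention makes the kernel only approximately rotation
  # invariant; scores agree to a few percent and the ranking of outliers
  # vs bundle fibers is preserved exactly
  expect_lt(max(abs(as.numeric(scr) - as.numeric(sc))), 0.05)
  expect_setequal(order(scr)[1:5], attr(bu, "outlier_index"))
  expect_equal(attr(filter_bundle(bur, scr, 0.1), "kept"),
               attr(filter_bundle(bu, sc, 0.1), "kept"))
})

test_that("the bundle-to-target distance is an exact point minimum", {
  through <- fiber_bundle(list(cbind(seq(-5, 5), 0, 0)), step = 1)
  expect_equal(ml_tp_distance(through, c(0, 0, 0)), 0)
  expect_equal(ml_tp_distance(through, c(0, 3, 4)), 5)
  set.seed(3)
  bu <- fiber_bundle(lapply(1:4, function(i) matrix(rnorm(30), 10L, 3L) +
                              cbind(seq(0, 9), 0, 0)), step = NA_real_)
  tgt <- c(2, -1, 3)
  brute <- sqrt(min(vapply(bu$fibers, function(f)
    min(rowSums(sweep(f, 2L, tgt)^2)), numeric(1L))))
  expect_equal(ml_tp_distance(bu, tgt), brute, tolerance = 1e-12)
  expect_error(ml_tp_distance(structure(list(fibers = list()),
                                        class = "fiber_bundle"), tgt),
               "empty")
})

test_that("duplicate injected fibers are indistinguishable in coherence", {
  g <- bundle_geometry("straight", from = c(5, 10, 10), to = c(35, 10, 10),
                       radius = 1)
  tr <- make_phantom(list(g), c(40, 20, 20), 1)
  bu <- sample_truth_fibers(tr, 15, step_mm = 1, jitter_mm = 0.1,
                            rng_seed = 9)
  dup <- inject_spurious(bu, 3, lateral_offset_mm = 0, angle_deg = 0,
                         rng_seed = 10)
  sc <- rfbc(dup, fbc_params(), alpha_mm = 4)
  oi <- attr(dup, "outlier_index")
  ratio <- mean(sc[oi]) / mean(sc[-oi])
  expect_lt(abs(ratio - 1), 0.1)
})
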