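# Shared, lazily built fixtures (cached across test files within a run).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

icosphere_cached <- function(frequency) {
  fixture(paste0("ico", frequency), function() make_icosphere(frequency))
}

# 45-degree two-bundle crossing phantom on a 16x16x10 1mm grid with 2mm
# tubes: the recurring parameter-recovery scenario.
crossing45_phantom <- function() {
  fixture("crossing45", function() {
    g1 <- bundle_geometry("straight", from = c(0, 8, 5), to = c(16, 8, 5),
                          radius = 2)
    c45 <- cos(pi / 4) * 8
    g2 <- bundle_geometry("straight",
                          from = c(8 - c45, 8 - c45, 5),
                          to = c(8 + c45, 8 + c45, 5), radius = 2)
    make_phantom(list(g1, g2), c(16, 16, 10), 1)
  })
}

crossing45_response <- function() {
  fixture("resp3000", function() default_response(3000))
}

crossing45_gradients <- function() fibonacci_directions(64)

# Straight-bundle test bed for tracking.
straight_field <- function() {
  fixture("straight_field", function() {
    g <- bundle_geometry("straight", from = c(0, 6, 6), to = c(24, 6, 6),
                         radius = 1.5)
    tr <- make_phantom(list(g), c(24, 12, 12), 1)
    s4 <- icosphere_cached(4)
    U <- truth_fod(tr, s4)
    cf <- sh_fit(t(U$values), sh_basis(8), s4)
    list(truth = tr, field = sh_field(t(cf), 8, tr$grid_shape, 1))
  })
}

# Parallel bundle of 20 fibers plus 5 strongly offset spurious fibers.
outlier_bundle <- function() {
  fixture("outlier_bundle", function() {
    g <- bundle_geometry("straight", from = c(5, 10, 10), to = c(35, 10, 10),
                         radius = 1)
    tr <- make_phantom(list(g), c(40, 20, 20), 1)
    bu <- sample_truth_fibers(tr, 20, step_mm = 1, jitter_mm = 0.1,
                              rng_seed = 7)
    inject_spurious(bu, 5, lateral_offset_mm = 8, angle_deg = 30,
                    rng_seed = 8)
  })
}

fbc_params <- function() enhancement_params(1, 0.04, 1.4)

expect_unit_rows <- function(m, tol = 1e-9) {
  expect_true(all(abs(sqrt(rowSums(m^2)) - 1) < tol))
}
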