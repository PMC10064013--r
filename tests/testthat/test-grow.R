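test_that("dt = 0 leaves the system bitwise unchanged", {
  sys <- new_root_system(small_stochastic_calib(), seed = 1)
  sys <- grow(sys, dt = 3)
  expect_identical(grow(sys, dt = 0), sys)
})

test_that("a single primary follows min(r*t, lmax) and grows straight down", {
  calib <- det_calib(list(list(r = 1, lmax = 10, la = 1, lb = 1, ln = 2)))
  sys <- grow(new_root_system(calib, seed = 1), dt = 5)
  expect_equal(sys$axes[[1]]$length, 5, tolerance = 1e-12)
  sys <- grow(sys, dt = 15)   # t = 20 > lmax/r
  expect_equal(sys$axes[[1]]$length, 10, tolerance = 1e-12)
  pts <- sys$axes[[1]]$points
  # theta = 0 and no tropism noise: pure vertical descent from the origin
  expect_equal(pts[nrow(pts), ], sys$origin + c(0, 0, 10), tolerance = 1e-9)
})

test_that("branch sites activate when parent length reaches site + lb", {
  specs <- list(list(r = 1, lmax = 10, la = 1, lb = 1, ln = 2),
                list(r = 0.5, lmax = 2, la = 0.4, lb = 0.3, ln = 0.5))
  calib <- det_calib(specs)
  sys <- grow(new_root_system(calib, seed = 1), dt = 8)
  # sites {1,3,5,7} have site + lb <= 8; site 9 needs full length 10
  expect_identical(sum(vapply(sys$axes, `[[`, integer(1), "bn") == 1L), 4L)
  sys <- grow(sys, dt = 4)
  expect_identical(sum(vapply(sys$axes, `[[`, integer(1), "bn") == 1L), 5L)
  ins <- sort(vapply(sys$axes[-1], `[[`, numeric(1), "insertion_arclength"))
  expect_equal(ins, c(1, 3, 5, 7, 9), tolerance = 1e-9)
})

test_that("unbranched zones leave no admissible site until lmax allows one", {
  # boundary case la + lb = lmax with ln > lmax: a single site exactly at the
  # basal-zone boundary, activating only when the root is at full length
  calib <- det_calib(list(list(r = 1, lmax = 10, la = 6, lb = 4, ln = 20),
                          list(r = 1, lmax = 1, la = 0.2, lb = 0.2, ln = 1)))
  sys <- grow(new_root_system(calib, seed = 1), dt = 9.99)
  expect_identical(length(sys$axes), 1L)
  sys <- grow(sys, dt = 1)
  expect_identical(length(sys$axes), 2L)
  # parents whose realized lmax falls below la + lb never branch
  gp0 <- growth_params(0, "z", r_mean = 2, r_sd = 0, lmax_mean = 10,
                       lmax_sd = 2, la = 5, lb = 5, ln_mean = 20, ln_sd = 0,
                       theta_mean = 10, theta_sd = 5, maxB = 30,
                       tropism_sigma = 5, max_order = 1)
  gp1 <- growth_params(1, "z", r_mean = 1, r_sd = 0, lmax_mean = 1,
                       lmax_sd = 0, la = 0.2, lb = 0.2, ln_mean = 1,
                       ln_sd = 0, theta_mean = 50, theta_sd = 5,
                       tropism_sigma = 5, max_order = 1)
  sys2 <- simulate_root_system(calibration(gp0, gp1), 40, seed = 9)
  parents <- Filter(function(a) a$bn == 0L, sys2$axes)
  kids <- vapply(Filter(function(a) a$bn == 1L, sys2$axes),
                 `[[`, integer(1), "parent_id")
  for (p in parents) {
    expect_identical(p$id %in% kids, p$lmax >= 10)
  }
  # parent still shorter than la: no admissible site either
  calib2 <- det_calib(list(list(r = 1, lmax = 10, la = 5, lb = 1, ln = 1),
                           list(r = 1, lmax = 1, la = 0.2, lb = 0.2, ln = 1)))
  sys3 <- grow(new_root_system(calib2, seed = 1), dt = 3)
  expect_identical(length(sys3$axes), 1L)
})

test_that("deterministic limit matches the enumeration oracle to 1e-6", {
  specs <- list(list(r = 1, lmax = 10, la = 1, lb = 1, ln = 2, theta = 30),
                list(r = 0.5, lmax = 2, la = 0.4, lb = 0.3, ln = 0.5,
                     theta = 50),
                list(r = 0.25, lmax = 0.8, la = 0.2, lb = 0.2, ln = 0.3,
                     theta = 60))
  calib <- det_calib(specs, maxB = 3)
  for (t in c(4, 9, 15, 30)) {
    sys <- grow(new_root_system(calib, seed = 1), dt = t)
    got <- root_totals(sys)
    want <- oracle_totals(calib, t)
    expect_equal(got$axes, want$axes)
    expect_equal(got$length_cm, want$length_cm, tolerance = 1e-6)
  }
})

test_that("primaries-only ensemble gives maxB * r * t total length", {
  calib <- det_calib(list(list(r = 1, lmax = 100, la = 1, lb = 1, ln = 2)),
                     maxB = 5)
  ens <- simulate_ensemble(calib, duration = 10, n_replicates = 1, seed = 3)
  expect_equal(ens$summary$mean_length_cm, 50, tolerance = 1e-9)
})

test_that("heading noise preserves arc length exactly", {
  # tropism perturbs direction, never speed: each replicate's primary length
  # is exactly r * t, and the reported length equals the polyline arc length
  calib <- calibration(growth_params(0, "c", r_mean = 1, r_sd = 0,
                                     lmax_mean = 50, lmax_sd = 0, la = 1,
                                     lb = 1, ln_mean = 2, ln_sd = 0,
                                     theta_mean = 20, theta_sd = 10,
                                     maxB = 1, tropism_sigma = 20,
                                     max_order = 0))
  set.seed(42)
  for (i in 1:10) {
    sys <- grow(new_root_system(calib), dt = 5)
    ax <- sys$axes[[1]]
    expect_equal(ax$length, 5, tolerance = 1e-9)
    arc <- sum(sqrt(rowSums((ax$points[-1, , drop = FALSE] -
                               ax$points[-nrow(ax$points), , drop = FALSE])^2)))
    expect_equal(arc, ax$length, tolerance = 1e-6)
  }
})

test_that("axis lengths are monotone in time and capped at realized lmax", {
  sys <- new_root_system(small_stochastic_calib(), seed = 11)
  prev <- numeric(0)
  for (step in 1:8) {
    sys <- grow(sys, dt = 1.5)
    len <- vapply(sys$axes, `[[`, numeric(1), "length")
    lmax <- vapply(sys$axes, `[[`, numeric(1), "lmax")
    expect_true(all(len <= lmax + 1e-9))
    if (length(prev)) expect_true(all(len[seq_along(prev)] >= prev - 1e-12))
    prev <- len
  }
})

test_that("every polyline stays inside the box and off the barrier", {
  cal <- packaged_calibrations()
  sys <- simulate_root_system(cal$water, 18, seed = 5, origin = c(-1, 0, 0))
  box <- sys$box
  for (ax in sys$axes) {
    p <- ax$points
    expect_true(all(p[, 1] >= -box[1] / 2 - 1e-9 & p[, 1] <= box[1] / 2 + 1e-9))
    expect_true(all(p[, 2] >= -box[2] / 2 - 1e-9 & p[, 2] <= box[2] / 2 + 1e-9))
    expect_true(all(p[, 3] >= -1e-9 & p[, 3] <= box[3] + 1e-9))
    if (nrow(p) > 1) {
      crossings <- sign(p[-1, 1]) != sign(p[-nrow(p), 1]) &
        pmax(p[-1, 3], p[-nrow(p), 3]) >= sys$barrier_gap
      expect_false(any(crossings))
    }
  }
})

test_that("identical seeds reproduce identical systems", {
  calib <- small_stochastic_calib()
  s1 <- simulate_root_system(calib, 6, seed = 99)
  s2 <- simulate_root_system(calib, 6, seed = 99)
  expect_identical(s1, s2)
  e1 <- simulate_ensemble(calib, 6, 3, seed = 7)
  e2 <- simulate_ensemble(calib, 6, 3, seed = 7)
  expect_identical(e1, e2)
})

test_that("lengths and branch counts are step-size invariant (deterministic)", {
  specs <- list(list(r = 1, lmax = 10, la = 1, lb = 1, ln = 2),
                list(r = 0.5, lmax = 2, la = 0.4, lb = 0.3, ln = 0.5))
  calib <- det_calib(specs)
  one <- grow(new_root_system(calib, seed = 1), dt = 12)
  many <- new_root_system(calib, seed = 1)
  for (i in 1:24) many <- grow(many, dt = 0.5)
  key <- function(s) {
    bn <- vapply(s$axes, `[[`, integer(1), "bn")
    len <- vapply(s$axes, `[[`, numeric(1), "length")
    lapply(split(round(len, 9), bn), sort)
  }
  expect_identical(key(one), key(many))
})
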