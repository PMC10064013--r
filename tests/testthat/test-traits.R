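mk_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(replicate = r$rep %||% 1L, compartment = r$comp %||% "A",
               branching_number = r$bn, length_cm = r$len,
               surface_area_cm2 = r$sa %||% 0, tips = r$tips,
               axes = r$axes %||% r$tips, biomass_g = r$mass %||% 0,
               mean_angle_deg = r$ang %||% NA_real_)
  }))
}

test_that("branching intensity/density/ratio follow their definitions", {
  tab <- mk_table(list(bn = 0, len = 2, tips = 1),
                  list(bn = 1, len = 3.5, tips = 10))
  expect_equal(branching_intensity(tab, 0), 0.5)
  expect_equal(branching_intensity(mk_table(
    list(bn = 1, len = 3.5, tips = 7)), 1), 2)
  expect_equal(branching_density(tab, 1), 5)
  expect_true(is.na(branching_density(tab, 0)))
  expect_true(is.na(branching_ratio(tab, 0)))
  tab2 <- mk_table(list(bn = 0, len = 10, tips = 1, axes = 1),
                   list(bn = 1, len = 20, tips = 45, axes = 45))
  expect_equal(branching_ratio(tab2, 1), 45)
})

test_that("zero denominators signal undefined values, not silent zeros", {
  tab <- mk_table(list(bn = 0, len = 0, tips = 0),
                  list(bn = 1, len = 1, tips = 2))
  expect_warning(v <- branching_intensity(tab, 0), "zero root length")
  expect_true(is.na(v))
  expect_warning(v <- branching_density(tab, 1), "zero root length")
  expect_true(is.na(v))
  expect_warning(v <- srl(mk_table(list(bn = 0, len = 5, tips = 1))),
                 "zero root biomass")
  expect_true(is.na(v))
})

test_that("BR(bn) = BD(bn) x mean parent length on simulated systems", {
  sys <- simulate_root_system(small_stochastic_calib(), 8, seed = 21)
  tab <- trait_table(sys)
  meanlen0 <- tab$length_cm[tab$branching_number == 0] /
    tab$axes[tab$branching_number == 0]
  expect_equal(branching_ratio(tab, 1),
               branching_density(tab, 1) * meanlen0, tolerance = 1e-12)
})

test_that("branching density approaches 1/ln for long unzoned roots", {
  # deterministic long-root limit: la = lb = 0 so BD = (floor(L/ln)+1)/L
  calib <- det_calib(list(list(r = 4, lmax = 40, la = 0, lb = 0, ln = 0.25),
                          list(r = 0.1, lmax = 0.15, la = 0.05, lb = 0.05,
                               ln = 1)))
  sys <- grow(new_root_system(calib, seed = 2), dt = 20)
  tab <- trait_table(sys)
  expect_equal(branching_density(tab, 1), (floor(40 / 0.25) + 1) / 40,
               tolerance = 1e-9)
  expect_lt(abs(branching_density(tab, 1) - 1 / 0.25), 0.05)
})

test_that("allocation proportions are symmetric and sum to one", {
  a <- mk_table(list(bn = 0, len = 63, tips = 5, sa = 10, comp = "A"))
  b <- mk_table(list(bn = 0, len = 37, tips = 5, sa = 10, comp = "B"))
  expect_equal(allocation_proportions(a, b, 0, "length"), 0.63)
  expect_equal(allocation_proportions(a, b, 0, "tips"), 0.5)
  set.seed(5)
  for (i in 1:20) {
    x <- mk_table(list(bn = 1, len = runif(1), tips = sample(10, 1),
                       sa = runif(1)))
    y <- mk_table(list(bn = 1, len = runif(1), tips = sample(10, 1),
                       sa = runif(1)))
    for (m in c("length", "surface_area", "tips")) {
      expect_equal(allocation_proportions(x, y, 1, m) +
                     allocation_proportions(y, x, 1, m), 1, tolerance = 1e-12)
    }
  }
  expect_warning(
    v <- allocation_proportions(mk_table(list(bn = 2, len = 0, tips = 0)),
                                mk_table(list(bn = 2, len = 0, tips = 0)),
                                2, "length"), "both compartments")
  expect_true(is.na(v))
})

test_that("SRL and mass fractions follow their definitions", {
  tab <- mk_table(list(bn = 0, len = 100, tips = 1, mass = 0.05, comp = "A"),
                  list(bn = 0, len = 40, tips = 1, mass = 0.6, comp = "B"),
                  list(bn = 1, len = 10, tips = 5, mass = 0.6, comp = "B"))
  expect_equal(srl(tab, "A"), 2000)
  expect_equal(mass_fraction(tab, "B"), 1.2 / 1.25)
  set.seed(6)
  for (i in 1:10) {
    t2 <- mk_table(list(bn = 0, len = 1, tips = 1, mass = runif(1), comp = "A"),
                   list(bn = 0, len = 1, tips = 1, mass = runif(1), comp = "B"))
    expect_equal(mass_fraction(t2, "A") + mass_fraction(t2, "B"), 1,
                 tolerance = 1e-12)
  }
})

test_that("traits agree between the architecture and its exported table", {
  sys <- simulate_root_system(small_stochastic_calib(), 8, seed = 33)
  tab <- trait_table(sys)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  back <- trait_table(utils::read.csv(csv))
  for (b in 0:1) {
    expect_equal(branching_intensity(back, b), branching_intensity(tab, b),
                 tolerance = 1e-9)
  }
  expect_equal(branching_density(back, 1), branching_density(tab, 1),
               tolerance = 1e-9)
  expect_equal(branching_ratio(back, 1), branching_ratio(tab, 1),
               tolerance = 1e-9)
  expect_equal(srl(back), srl(tab), tolerance = 1e-9)
})

test_that("trait_summary reports one row per replicate/compartment/order", {
  sys <- simulate_root_system(small_stochastic_calib(), 8, seed = 34)
  ts <- trait_summary(trait_table(sys))
  expect_identical(nrow(ts), 2L)
  expect_true(is.na(ts$BD[ts$branching_number == 0]))
  expect_false(is.na(ts$BD[ts$branching_number == 1]))
})
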