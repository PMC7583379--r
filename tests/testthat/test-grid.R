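test_that("hypsograph construction validates morphometry", {
  h <- hypsograph(c(0, 1.3, 2.6), c(0, 4.5e5, 9.1e5))
  expect_s3_class(h, "hypsograph")
  expect_error(hypsograph(c(0, 1, 1), c(0, 1, 2)), "strictly increasing")
  expect_error(hypsograph(c(0.5, 1), c(1, 2)), "first level")
  expect_error(hypsograph(c(0, 1), c(2, 1)), "non-decreasing")
  expect_error(hypsograph(0, 1), "at least 2")
})

test_that("lake volume is the exact trapezoid integral", {
  # cone: A(z) = a * z, V = a * zmax^2 / 2 exactly (piecewise linear)
  z <- seq(0, 2, length.out = 11)
  h <- hypsograph(z, 1e5 * z)
  expect_equal(lake_volume(h), 1e5 * 2^2 / 2, tolerance = 1e-12)
})

test_that("default 16-layer bottom-zoomed grid over 2.6 m has 10-21 cm layers", {
  g <- build_grid(fx$hyp, n_layers = 16)
  expect_length(g$heights, 16)
  expect_true(all(g$heights >= 0.10 & g$heights <= 0.21))
  # bottom refinement: thinnest at the bottom
  expect_true(all(diff(g$heights) > 0))
})

test_that("one-layer zoom-0 grid is the fully mixed box configuration", {
  g <- build_grid(fx$hyp, n_layers = 1, zoom = 0)
  expect_equal(g$heights, 2.6)
  expect_equal(g$benthic_areas, g$surface_area)
  expect_equal(sum(g$volumes), lake_volume(fx$hyp))
})

test_that("conical hypsograph yields analytic frustum volumes", {
  # cone with apex at z=0: A(z) = pi * (r z / zmax)^2 is NOT piecewise linear,
  # so tabulate a linear-area basin instead: A(z) = c z gives exact frusta
  zmax <- 2; cc <- 3e4
  h <- hypsograph(seq(0, zmax, length.out = 41), cc * seq(0, zmax, length.out = 41))
  g <- build_grid(h, n_layers = 4, zoom = 0)
  iface <- g$interfaces
  expected <- cc * (iface[-1]^2 - iface[-5]^2) / 2   # integral of c*z
  expect_equal(g$volumes, expected, tolerance = 1e-10)
})

test_that("grid conserves volume and benthic area for random hypsographs", {
  set.seed(11)
  for (i in 1:10) {
    z <- sort(c(0, runif(6, 0.1, 3), 3.2))
    a <- cumsum(c(runif(1, 0, 1e4), runif(7, 0, 2e5)))
    h <- hypsograph(z, a)
    g <- build_grid(h, n_layers = sample(2:20, 1), zoom = runif(1, 0, 0.1))
    expect_lt(abs(sum(g$volumes) - lake_volume(h)) / lake_volume(h), 1e-10)
    expect_equal(sum(g$benthic_areas), g$surface_area)
    expect_true(all(g$heights > 0))
  }
})

test_that("grid construction rejects bad input", {
  expect_error(build_grid(fx$hyp, 0), "positive integer")
  expect_error(build_grid(fx$hyp, 4, -1), "zoom")
})

test_that("hypsograph files round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hypsograph(fx$hyp, path)
  h2 <- read_hypsograph(path)
  expect_equal(h2$level_m, fx$hyp$level_m)
  expect_equal(h2$area_m2, fx$hyp$area_m2)
})
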