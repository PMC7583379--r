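test_that("depth-matched extraction pools the right layers", {
  nd <- 10
  run <- fake_run(tibble::tibble(day = 1:nd), grid = fx$grid4)
  run$layers$chl <- matrix(rep(c(10, 10, 20, 20), each = nd), nd, 4)
  # uniform column: any sampling depth returns the uniform value
  run2 <- fake_run(tibble::tibble(day = 1:nd), grid = fx$grid4)
  run2$layers$chl <- matrix(7, nd, 4)
  obs_u <- tibble::tibble(variable = "chl", day = 3, sample_depth_m = 0.8,
                          value = 1, error_fraction = 0.2)
  expect_equal(depth_matched_extract(run2, obs_u)$sim, 7)
  # full-depth sample equals the volume-weighted column mean
  obs_f <- obs_u; obs_f$sample_depth_m <- fx$grid4$max_depth
  g <- fx$grid4
  expect_equal(depth_matched_extract(run, obs_f)$sim,
               sum(c(10, 10, 20, 20) * g$volumes) / sum(g$volumes))
  # sample spanning the top two layers only (two-layer hand calculation)
  top2_depth <- g$max_depth - g$interfaces[3]
  obs_2 <- obs_u; obs_2$sample_depth_m <- top2_depth
  hand <- sum(c(20, 20) * g$volumes[3:4]) / sum(g$volumes[3:4])
  expect_equal(depth_matched_extract(run, obs_2)$sim, hand)
  # observations outside the run are skipped and counted
  obs_out <- dplyr::bind_rows(obs_u, dplyr::mutate(obs_u, day = 99))
  m <- depth_matched_extract(run2, obs_out)
  expect_equal(nrow(m), 1)
  expect_equal(attr(m, "n_skipped"), 1)
})

test_that("fit metrics satisfy their identities", {
  o <- c(2, 5, 9, 4, 7)
  perfect <- fit_metrics(o, o)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mare, 0)
  expect_equal(perfect$re, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$bias, 0)
  # uniform 10% overestimate
  sc <- fit_metrics(1.1 * o, o)
  expect_equal(sc$bias, 10)
  expect_equal(sc$re, 0.1)
  expect_equal(sc$mare, 0.1)
  # pair order invariance
  i <- c(3, 1, 5, 2, 4)
  expect_equal(fit_metrics(1.1 * o, o), fit_metrics(1.1 * o[i], o[i]))
  # rescaling both: rmse scales, the relative metrics do not
  s <- c(2.5, 4.2, 8.1, 4.4, 7.9)
  m1 <- fit_metrics(s, o); m2 <- fit_metrics(10 * s, 10 * o)
  expect_equal(m2$rmse, 10 * m1$rmse)
  expect_equal(m2$re, m1$re)
  expect_equal(m2$mare, m1$mare)
  expect_equal(m2$r2, m1$r2)
  expect_equal(m2$bias, m1$bias)
})

test_that("near-zero observations inflate MARE but not RE", {
  # the seasonal-depletion pattern: a few near-zero observed values with
  # modest absolute errors make MARE >> RE
  o <- c(4, 3.5, 0.02, 0.01, 2.8, 0.03, 3.9)
  s <- c(3.6, 3.9, 0.50, 0.40, 2.4, 0.45, 3.5)
  m <- fit_metrics(s, o)
  expect_gt(m$mare, 5 * m$re)
  expect_lt(m$re, 0.5)
})

test_that("the profiled likelihood responds to residual scale, not offsets", {
  set.seed(5)
  d <- tibble::tibble(variable = "x", value = rnorm(20, 10),
                      sim = rnorm(20, 10))
  ll1 <- log_likelihood(d)
  d2 <- d; d2$sim <- d$value + 2 * (d$sim - d$value)
  expect_equal(log_likelihood(d2), ll1 - 20 * log(2), tolerance = 1e-10)
  # adding an unrelated variable shifts the objective by a constant
  extra <- tibble::tibble(variable = "y", value = 1:10 + 0.5, sim = 1:10 * 1.0)
  shift <- log_likelihood(dplyr::bind_rows(d, extra)) - ll1
  shift2 <- log_likelihood(dplyr::bind_rows(d2, extra)) - log_likelihood(d2)
  expect_equal(shift, shift2)
  # perfect fit is capped, not infinite
  exact <- tibble::tibble(variable = "x", value = 1:5 * 1.0, sim = 1:5 * 1.0)
  expect_equal(log_likelihood(exact, cap = 100), 100)
})

test_that("differential evolution solves the sphere benchmark deterministically", {
  sphere <- function(x) -sum(x^2)
  de <- differential_evolution(sphere, rep(-5, 5), rep(5, 5), pop_size = 50,
                               generations = 200, seed = 99)
  expect_lt(sum(de$par^2), 1e-2)
  expect_true(all(diff(de$trace) >= 0))
  de2 <- differential_evolution(sphere, rep(-5, 5), rep(5, 5), pop_size = 50,
                                generations = 200, seed = 99)
  expect_identical(de$par, de2$par)
  expect_identical(de$trace, de2$trace)
})

test_that("DE respects bounds at every evaluation and finds boundary optima", {
  seen <- new.env(); seen$bad <- 0
  fn <- function(x) {
    if (any(x < 1) || any(x > 3)) seen$bad <- seen$bad + 1
    -(x[1] - 10)^2          # optimum far beyond the upper bound
  }
  de <- differential_evolution(fn, 1, 3, pop_size = 12, generations = 40,
                               seed = 3)
  expect_equal(seen$bad, 0)
  expect_equal(de$par, 3, tolerance = 1e-6)
})

test_that("range narrowing selects the top fraction and stays inside old bounds", {
  set.seed(8)
  pop <- matrix(runif(40, 0, 10), 20, 2)
  obj <- -rowSums((pop - 5)^2)
  nr <- narrow_ranges(pop, obj, lower = c(0, 0), upper = c(10, 10),
                      keep_frac = 0.1, expand_frac = 0.1)
  top <- pop[order(obj, decreasing = TRUE)[1:2], , drop = FALSE]
  span <- apply(top, 2, max) - apply(top, 2, min)
  expect_equal(nr$lower, pmax(apply(top, 2, min) - 0.1 * span, 0))
  expect_equal(nr$upper, pmin(apply(top, 2, max) + 0.1 * span, 10))
  expect_true(all(nr$lower >= 0) && all(nr$upper <= 10))
  # keep everything + huge expansion: clipping returns the old bounds
  nr_all <- narrow_ranges(pop, obj, c(0, 0), c(10, 10), keep_frac = 1,
                          expand_frac = 100)
  expect_equal(nr_all$lower, c(0, 0))
  expect_equal(nr_all$upper, c(10, 10))
  # degenerate population: point range expanded by the old span
  pop1 <- matrix(2, 6, 1)
  nr_d <- narrow_ranges(pop1, rep(0, 6), 0, 10, expand_frac = 0.1)
  expect_equal(nr_d$lower, 1)
  expect_equal(nr_d$upper, 3)
})

test_that("stepwise calibration narrows ranges and carries values forward", {
  # cheap analytic "model": runner returns a run whose single variable is a
  # parabola of two parameters; truth at (3, 7)
  grid1 <- fx$grid0d
  days <- 1:30
  runner <- function(params) {
    v <- param_values(params)
    sim <- v[["tau_temp"]] + v[["z_tau"]] * (days / 30)
    run <- fake_run(tibble::tibble(day = days), grid = grid1)
    run$layers$temp <- matrix(sim, 30, 1)
    run
  }
  truth <- runner(param_update(fx$params, tau_temp = 3, z_tau = 7))
  obs <- tibble::tibble(variable = "temp", day = days, sample_depth_m = 0.5,
                        value = truth$layers$temp[, 1],
                        error_fraction = 0.05)
  steps <- list(calibration_step("fit", "temp", c("tau_temp", "z_tau"),
                                 pop_size = 12, generations = 25))
  res <- stepwise_calibrate(runner, steps, obs, fx$params, seed = 4)
  v <- param_values(res$params)
  expect_equal(unname(v[["tau_temp"]]), 3, tolerance = 0.05)
  expect_equal(unname(v[["z_tau"]]), 7, tolerance = 0.05)
  i <- match(c("tau_temp", "z_tau"), res$params$name)
  expect_true(all(res$params$upper[i] - res$params$lower[i] <
                    fx$params$upper[i] - fx$params$lower[i]))
  # unknown parameters are rejected before any run
  bad <- list(calibration_step("x", "temp", "not_a_parameter"))
  expect_error(stepwise_calibrate(runner, bad, obs, fx$params),
               "unknown parameter")
})
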