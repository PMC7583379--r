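test_that("the default multiplier grid is the canonical 75-scenario set", {
  m <- multiplier_grid()
  expect_length(m, 75)
  expect_equal(m[1], 0.02)
  expect_equal(m[75], 1.50)
  expect_equal(multiplier_grid(0, 0, 2), 1)
  expect_equal(multiplier_grid(-4, 4, 2), c(0.96, 0.98, 1.00, 1.02, 1.04))
  expect_error(multiplier_grid(-5, 4, 2), "divisible")
  expect_error(multiplier_grid(4, -4, 2), "<=")
})

test_that("looping a baseline window repeats it exactly", {
  frc <- fx$forcing
  out <- loop_baseline(frc, c(366, 730), reps = 3)
  expect_equal(nrow(out), 3 * 365)
  expect_equal(out$day, 1:(3 * 365))
  block <- frc[frc$day >= 366 & frc$day <= 730, ]
  for (k in 0:2) {
    expect_equal(out$air_temp[k * 365 + 1:365], block$air_temp)
    expect_equal(out$q_in[k * 365 + 1:365], block$q_in)
  }
  expect_equal(sum(out$q_in), 3 * sum(block$q_in))
  # reps = 1 is the identity on the window
  one <- loop_baseline(frc, c(366, 730), 1)
  expect_equal(one$c_po4, block$c_po4)
  expect_error(loop_baseline(frc, c(366, 1460), 2), "not covered")
})

test_that("the P multiplier scales the external load exactly linearly", {
  frc <- fx$forcing
  expect_equal(apply_p_multiplier(frc, 1), frc)
  load_of <- function(f) sum(f$q_in * (f$c_po4 + f$c_orgp))
  base <- load_of(frc)
  expect_equal(load_of(apply_p_multiplier(frc, 0.5)) / base, 0.5,
               tolerance = 1e-12)
  expect_equal(load_of(apply_p_multiplier(frc, 0.02)) / base, 0.02,
               tolerance = 1e-12)
  # nitrogen and discharge untouched
  half <- apply_p_multiplier(frc, 0.5)
  expect_equal(half$c_no3, frc$c_no3)
  expect_equal(half$q_in, frc$q_in)
})

test_that("branch forcing assembles history, establishment and scenario", {
  sp_t <- scenario_spec("turbid", 1, c(366, 730), reps = 12)
  f_t <- build_branch_forcing(fx$forcing, sp_t)
  expect_equal(nrow(f_t), 730 + 12 * 365)
  # baseline multiplier 1: scenario equals 12 exact copies of the baseline
  block <- fx$forcing[fx$forcing$day >= 366 & fx$forcing$day <= 730, ]
  expect_equal(f_t$c_po4[731:(730 + 365)], block$c_po4)
  sp_c <- scenario_spec("clear", 1, c(366, 730), reps = 12,
                        establishment_years = 20)
  f_c <- build_branch_forcing(fx$forcing, sp_c)
  expect_equal(nrow(f_c) - nrow(f_t), 20 * 365)
  # establishment segment runs at the -98% multiplier
  est <- f_c$c_po4[731:(730 + 365)]
  expect_equal(est, block$c_po4 * 0.02)
  expect_error(scenario_spec("turbid", 1, c(1, 365), establishment_years = 5),
               "establishment")
})

test_that("summer means and depth limit are extracted from the final window", {
  nd <- 6 * 365
  doy <- doy365(1:nd)
  daily <- tibble::tibble(day = 1:nd, doy = doy)
  for (v in c("chl", "tp", "tn", "po4", "no3", "nh4", "o2_surf", "dia", "cya",
              "oth", "zoo", "fish_jv", "fish_ad", "fish_pi", "benthos",
              "veg_gm2", "cover", "secchi")) daily[[v]] <- 0
  daily$load_p_mg_m2 <- 7
  daily$chl <- 3                                   # constant diagnostic
  daily$tp <- ifelse(doy < 121 | doy > 273, 9, 0)  # winter-only diagnostic
  cov_layers <- matrix(0, nd, 4)
  cov_layers[, 3:4] <- 5                           # vegetated top two layers
  run <- fake_run(daily, cov_layers, fx$grid4)
  pt <- run_and_extract(run, scenario_spec("turbid", 1, c(1, 365), 1))
  expect_equal(pt$chl, 3)
  expect_equal(pt$tp, 0)                           # summer window excludes it
  expect_equal(pt$load_p_mg_m2_d, 7)
  # depth limit = bottom of layer 3 on the 4-layer grid
  expect_equal(pt$depth_limit_aug_m,
               fx$grid4$max_depth - fx$grid4$interfaces[3])
  # hand-built series: summer mean equals the hand average
  daily2 <- daily
  daily2$chl <- ifelse(doy <= 182, 10, 20)
  s_days <- doy >= 121 & doy <= 273 & daily2$day > nd - 5 * 365
  expect_equal(run_and_extract(fake_run(daily2, cov_layers, fx$grid4))$chl,
               mean(daily2$chl[s_days]))
  expect_error(run_and_extract(fake_run(daily[1:400, ], cov_layers[1:400, ],
                                        fx$grid4)),
               "shorter")
})

test_that("load-response points are ranked by load within branch", {
  set.seed(3)
  pts <- tibble::tibble(branch = rep(c("turbid", "clear"), each = 5),
                        multiplier = rep(c(0.1, 0.4, 0.7, 1.0, 1.3), 2),
                        load_p_mg_m2_d = rep(c(1, 4, 7, 10, 13), 2),
                        chl = c(5, 20, 60, 90, 120, 5, 10, 20, 80, 120))
  shuffled <- pts[sample(nrow(pts)), ]
  curves <- load_response(shuffled)
  for (b in c("turbid", "clear")) {
    sub <- curves[curves$branch == b, ]
    expect_true(all(diff(sub$load_p_mg_m2_d) >= 0))
  }
})

test_that("hysteresis detection finds the disagreement interval", {
  mk <- function(chl_a, chl_b) {
    tibble::tibble(branch = rep(c("turbid", "clear"), each = 7),
                   multiplier = rep(seq(0.2, 1.4, by = 0.2), 2),
                   load_p_mg_m2_d = rep(1:7, 2),
                   chl = c(chl_a, chl_b))
  }
  same <- mk(c(1, 2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6, 7))
  expect_equal(nrow(hysteresis_range(same, "chl", 0.2)), 0)
  # branches disagree only at loads 3-5
  diff3 <- mk(c(1, 2, 9, 12, 15, 6, 7), c(1, 2, 3, 4, 5, 6, 7))
  h <- hysteresis_range(diff3, "chl", 0.2)
  expect_equal(h$load_low, 3)
  expect_equal(h$load_high, 5)
  # widening the tolerance shrinks or preserves the interval
  h_wide <- hysteresis_range(diff3, "chl", 1.5)
  if (nrow(h_wide) == 1) {
    expect_gte(h_wide$load_low, h$load_low)
    expect_lte(h_wide$load_high, h$load_high)
  } else {
    succeed()
  }
  expect_error(hysteresis_range(mk(1:7, 1:7)[1:7, ]), "two branches")
})
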