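test_that("generated hypsograph matches the target morphometry", {
  h <- gen_hypsograph(fx$spec)
  expect_equal(max(h$area_m2), 0.91e6)
  expect_equal(max(h$level_m), 2.6)
  expect_equal(h$area_m2[1], 0)
  expect_equal(lake_volume(h) / max(h$area_m2), 1.2, tolerance = 1e-8)
})

test_that("noise-free meteorology hits the seasonal temperature targets exactly", {
  met <- gen_meteorology(fx$spec, years = 1, noise_sd = 0)
  met$diu <- met$air_temp  # includes the diurnal cycle, which averages out
  daily <- tapply(met$air_temp, floor(met$day - 1e-9), mean)
  doy <- as.numeric(names(daily))
  summer <- doy >= 121 & doy <= 273
  expect_equal(mean(daily[summer]), 14.5, tolerance = 0.02)
  expect_equal(mean(daily[!summer]), 3.7, tolerance = 0.02)
  expect_true(all(met$cloud >= 0 & met$cloud <= 1))
})

test_that("noisy meteorology keeps seasonal means within 0.3 degC over 10 years", {
  for (seed in c(42, 99)) {
    met <- gen_meteorology(fx$spec, years = 10, seed = seed)
    summer <- met$doy >= 121 & met$doy <= 273
    expect_equal(mean(met$air_temp[summer]), 14.5, tolerance = 0.3)
    expect_equal(mean(met$air_temp[!summer]), 3.7, tolerance = 0.3)
  }
  # different seeds give different series
  m1 <- gen_meteorology(fx$spec, years = 1, seed = 1)
  m2 <- gen_meteorology(fx$spec, years = 1, seed = 2)
  expect_gt(max(abs(m1$air_temp - m2$air_temp)), 0.5)
})

test_that("inflow partitions organic fractions per the monitoring convention", {
  inf <- gen_inflow(fx$spec, years = 1, noise_cv = 0)
  tp <- inf$po4 + inf$orgp
  tn <- inf$nh4 + inf$no3 + inf$orgn
  expect_equal(inf$orgp / tp, rep(0.75, nrow(inf)))
  expect_equal(inf$orgn / tn, rep(0.90, nrow(inf)))
  # the worked example: TP 0.2 mg/L splits 0.15 organic / 0.05 inorganic
  frac <- 0.2 * inf$orgp[1] / tp[1]
  expect_equal(frac, 0.15)
})

test_that("annual loads land within 10% of the configured targets", {
  inf <- gen_inflow(fx$spec, years = 3)
  loads <- inflow_loads(inf, fx$spec$surface_area_m2)
  expect_lt(abs(loads$tp_load_mg_yr - 3.0) / 3.0, 0.10)
  expect_lt(abs(loads$tn_load_mg_yr - 120) / 120, 0.10)
  # a zero-discharge month contributes zero load
  inf0 <- inf
  inf0$discharge_m3s[inf0$month == 2] <- 0
  l2 <- inflow_loads(inf0[inf0$month == 2, ], fx$spec$surface_area_m2)
  expect_equal(l2$load_p_mg_m2_d, 0)
})

test_that("discharge seasonality reflects the residence-time targets", {
  inf <- gen_inflow(fx$spec, years = 1, noise_cv = 0)
  q_m <- tapply(inf$discharge_m3s, inf$month, sum)   # total over inlets
  expect_gt(mean(q_m[c(1, 2, 11, 12)]), mean(q_m[6:8]))
  vol <- fx$spec$surface_area_m2 * fx$spec$mean_depth_m
  res_winter <- vol / (mean(q_m[c(1, 2, 12)]) * 86400)
  expect_equal(res_winter, 16, tolerance = 0.35 * 16)
})

test_that("generated observations follow the monitoring schedule", {
  run <- simulate_lake(fx$grid4, fx$params, fx$forcing, init = "turbid",
                       n_days = 730,
                       keep_layers = c("temp", "chl", "po4"))
  obs <- gen_observations(run, variables = c("chl", "po4"), noise = FALSE,
                          first_day = 366, last_day = 730)
  chl <- obs[obs$variable == "chl", ]
  month <- findInterval(doy365(chl$day), cumsum(c(1, 31, 28, 31, 30, 31, 30,
                                                  31, 31, 30, 31, 30)))
  counts <- table(month)
  # two samplings per summer month, at most one per winter month (ice skips)
  expect_true(all(counts[names(counts) %in% 5:9] == 2))
  expect_true(all(counts[!names(counts) %in% 5:9] <= 1))
  # pooled depth stays in the typical band
  expect_true(all(obs$sample_depth_m >= 0.2 & obs$sample_depth_m <= 1.0))
  # error fractions: 20% chl, 15% nutrients
  expect_equal(unique(obs$error_fraction[obs$variable == "chl"]), 0.20)
  expect_equal(unique(obs$error_fraction[obs$variable == "po4"]), 0.15)
})

test_that("observation noise matches the analytical error fraction", {
  run <- simulate_lake(fx$grid4, fx$params, fx$forcing, init = "turbid",
                       n_days = 730, keep_layers = c("temp", "chl"))
  exact <- gen_observations(run, variables = "chl", noise = FALSE)
  # noise-free observations equal the depth-matched truth
  matched <- depth_matched_extract(run, exact)
  expect_equal(matched$sim, matched$value)
  # Monte Carlo: the empirical CV of the multiplicative noise ~ 0.20
  ratios <- unlist(lapply(1:25, function(s) {
    noisy <- gen_observations(run, variables = "chl", seed = s)
    noisy$value / exact$value
  }))
  expect_gt(length(ratios), 500)
  expect_equal(stats::sd(ratios) / mean(ratios), 0.20, tolerance = 0.04)
})

test_that("generators are pure functions of spec and seed", {
  expect_identical(gen_meteorology(fx$spec, 1, seed = 5),
                   gen_meteorology(fx$spec, 1, seed = 5))
  expect_identical(gen_inflow(fx$spec, 1, seed = 5),
                   gen_inflow(fx$spec, 1, seed = 5))
})

test_that("the twin fixture is deterministic with genuinely perturbed start", {
  tw1 <- make_twin_fixture(n_layers = 2, n_days = 200)
  tw2 <- make_twin_fixture(n_layers = 2, n_days = 200)
  expect_identical(tw1$obs, tw2$obs)
  expect_identical(param_values(tw1$start_params),
                   param_values(tw2$start_params))
  i <- match(tw1$perturb, tw1$truth_params$name)
  expect_true(all(tw1$start_params$value[i] != tw1$truth_params$value[i]))
  # the truth parameters score at least as well as the perturbed start
  run_t <- tw1$runner(tw1$truth_params)
  run_s <- tw1$runner(tw1$start_params)
  ll_t <- log_likelihood(depth_matched_extract(run_t, tw1$obs))
  ll_s <- log_likelihood(depth_matched_extract(run_s, tw1$obs))
  expect_gte(ll_t, ll_s)
})
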