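test_that("light is uniform in a transparent column", {
  lp <- light_profile(100, fx$grid16, k_bg = 0)
  expect_equal(lp$par_mean, rep(100, 16))
  expect_equal(lp$par_bottom, rep(100, 16))
})

test_that("optical thickness ln 2 halves the light", {
  g1 <- build_grid(fx$hyp, 1, 0)               # 2.6 m column
  kd <- log(2) / 2.6
  lp <- light_profile(80, g1, k_bg = kd)
  expect_equal(lp$par_bottom, 40, tolerance = 1e-12)
})

test_that("layered attenuation matches fine-step quadrature", {
  g3 <- build_grid(fx$hyp, 3, 0.2)
  pom <- c(8, 4, 1); im <- c(6, 2, 0.5); phy <- c(0.5, 2, 5)
  lp <- light_profile(120, g3, phyto_dm = phy, pom = pom, im = im,
                      k_bg = 0.4, k_phyto = 0.11, k_pom = 0.04, k_im = 0.06)
  # oracle: integrate exp(-int K dz) on a 1000-step grid from the surface
  kd <- 0.4 + 0.11 * phy + 0.04 * pom + 0.06 * im  # per layer, bottom first
  nstep <- 1000
  dz <- g3$max_depth / nstep
  zmid <- seq(dz / 2, g3$max_depth, by = dz)           # depth below surface
  hab <- g3$max_depth - zmid                           # height above bottom
  layer_of <- pmin(pmax(findInterval(hab, g3$interfaces), 1), 3)
  kz <- kd[layer_of]
  cum <- cumsum(kz * dz)
  par_z <- 120 * exp(-cum)
  for (k in 1:3) {
    inlayer <- layer_of == k
    expect_equal(lp$par_mean[k], mean(par_z[inlayer]), tolerance = 5e-3)
  }
  expect_true(all(diff(lp$par_bottom) >= 0))   # deeper layers darker
})

test_that("light profile rejects negative concentrations", {
  expect_error(light_profile(10, fx$grid4, pom = -1), "non-negative")
})

test_that("water temperature relaxes to a constant equilibrium", {
  g <- fx$grid4
  temp <- rep(5, 4)
  for (i in 1:200) temp <- water_temperature_step(temp, 20, 0, g, 1, c_swr = 0)
  expect_equal(temp, rep(20, 4), tolerance = 1e-3)
})

test_that("step response is a monotone exponential with the stated time constant", {
  g <- build_grid(fx$hyp, 1, 0)
  tau0 <- 4; depth <- g$depths
  tau_eff <- tau0 * (1 + depth / 4)
  t0 <- 10
  traj <- numeric(30); temp <- t0
  for (i in 1:30) {
    temp <- water_temperature_step(temp, 15, 0, g, 1, tau0 = tau0, z_tau = 4,
                                   c_swr = 0)
    traj[i] <- temp
  }
  expected <- 15 + (t0 - 15) * exp(-(1:30) / tau_eff)
  expect_equal(traj, expected, tolerance = 1e-10)
  expect_true(all(diff(traj) > 0))
})

test_that("simulated water temperature spans the observed 0-25 degC annual range", {
  met <- gen_meteorology(fx$spec, years = 3)
  inf <- gen_inflow(fx$spec, years = 3)
  frc <- prepare_forcing(met, inf, n_days = 3 * 365)
  run <- simulate_lake(fx$grid4, fx$params, frc, init = "turbid",
                       n_days = 3 * 365)
  d <- run$daily[run$daily$day > 365, ]
  # monthly means span roughly the 0-25 degC observed annual range; sunny
  # summers overshoot the top of that range by a few degrees (a known bias
  # of the relaxation physics)
  monthly <- tapply(d$temp_surf, ceiling(d$day / 30.42), mean)
  expect_lt(min(monthly), 3)
  expect_gt(max(monthly), 20)
  expect_lt(max(monthly), 30)
  expect_true(all(d$temp_surf >= 0))
})

test_that("vertical mixing conserves mass and contracts gradients", {
  g <- fx$grid16
  set.seed(42)
  for (i in 1:5) {
    conc <- runif(16, 0, 50)
    mixed <- vertical_mixing(conc, g, wind_speed = runif(1, 0, 12), dt = 1)
    expect_lt(abs(sum(mixed * g$volumes) - sum(conc * g$volumes)) /
                sum(conc * g$volumes), 1e-12)
    expect_lte(max(mixed) - min(mixed), max(conc) - min(conc))
  }
})

test_that("mixing leaves a uniform column unchanged and mixes fully at high D*dt", {
  g <- fx$grid4
  expect_equal(vertical_mixing(rep(3, 4), g, 5, 1), rep(3, 4))
  conc <- c(10, 0, 0, 0)
  mixed <- vertical_mixing(conc, g, 0, dt = 1, d0 = 1e6, c_w = 0)
  expect_equal(mixed, rep(sum(conc * g$volumes) / sum(g$volumes), 4),
               tolerance = 1e-4)
})

test_that("bottom shear scales as wind squared and decays with depth", {
  expect_equal(bottom_shear(0, 1000, 1), 0)
  expect_equal(bottom_shear(8, 1000, 1) / bottom_shear(4, 1000, 1), 4)
  expect_lt(bottom_shear(5, 1000, 50), 1e-10)
  expect_gt(bottom_shear(5, 2000, 1), bottom_shear(5, 1000, 1))
})

test_that("reaeration drives oxygen towards saturation", {
  t <- 12
  expect_equal(reaeration_flux(o2_saturation(t), t, 5), 0, tolerance = 1e-12)
  # reference temperature: multiplier exactly 1 at 20 degC
  expect_equal(reaeration_flux(0, 20, 0, k0 = 1, k_wind = 0),
               o2_saturation(20))
  # supersaturated water outgasses
  expect_lt(reaeration_flux(o2_saturation(25) + 5, 25, 3), 0)
})
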