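test_that("a closed lake conserves phosphorus and stays positive", {
  run <- simulate_lake(fx$grid4, fx$params, fx$closed_forcing, init = "turbid",
                       n_days = 400)
  res <- budget_residual(run)
  expect_lt(abs(res$residual_p), 1e-9)
  expect_true(all(run$state$water >= 0))
  expect_true(all(run$state$sed >= 0))
  expect_true(all(as.matrix(run$daily[-1]) >= 0, na.rm = TRUE))
})

test_that("nitrogen leaves only through the tracked denitrification ledger", {
  run <- simulate_lake(fx$grid4, fx$params, fx$closed_forcing, init = "turbid",
                       n_days = 400)
  b0 <- run$init_budget; b1 <- run$final_budget
  # closed lake: no in/outflow, so dN = -(denitrified N2) - burial
  dn <- b1$total_n_g - b0$total_n_g
  expect_lt(abs(dn + b1$n2_g + b1$buried_n_g) / b0$total_n_g, 1e-9)
  expect_gt(b1$n2_g, 0)
})

test_that("positivity holds under random admissible parameter draws", {
  set.seed(13)
  for (rep in 1:3) {
    p <- fx$params
    i <- sample(nrow(p), 12)
    p$value[i] <- runif(12, p$lower[i], p$upper[i])
    run <- simulate_lake(fx$grid4, p, fx$forcing, init = "clear", n_days = 120)
    expect_true(all(run$state$water >= 0))
    expect_true(all(run$state$sed >= 0))
  }
})

test_that("the one-layer configuration behaves as a fully mixed box", {
  g <- fx$grid0d
  expect_equal(g$benthic_areas, g$surface_area)
  run <- simulate_lake(g, fx$params, fx$forcing, init = "turbid", n_days = 60,
                       keep_layers = "chl")
  # a single layer cannot have vertical structure
  expect_equal(ncol(run$layers$chl), 1)
  expect_lt(abs(budget_residual(run)$residual_p), 1e-9)
})

test_that("winter fish kill moves the whole fish stock to sediment POM and conserves P", {
  p <- param_update(fx$params, winter_kill = 1, winter_kill_day = 15)
  run <- simulate_lake(fx$grid4, p, fx$closed_forcing, init = "turbid",
                       n_days = 30)
  fish_after <- sum(run$daily[run$daily$doy == 16,
                              c("fish_jv", "fish_ad", "fish_pi")])
  expect_lt(fish_after, 1e-3)
  expect_lt(abs(budget_residual(run)$residual_p), 1e-9)
})

test_that("denser water column weakly shallows the macrophyte depth limit", {
  # increasing background extinction cannot deepen the vegetated zone
  dl <- vapply(c(0.4, 1.0, 2.0), function(kbg) {
    p <- param_update(fx$params, k_bg = kbg)
    run <- simulate_lake(fx$grid16, p, fx$forcing, init = "clear",
                         n_days = 500, keep_layers = "cover")
    prof <- colMeans(run$layers$cover[400:500, ])
    ok <- which(prof >= 0.1)
    if (length(ok)) fx$grid16$max_depth - fx$grid16$interfaces[min(ok)] else 0
  }, numeric(1))
  expect_true(all(diff(dl) <= 1e-9))
})

test_that("oxygen tends to saturation without biology at the surface", {
  # strip the water column of biota and organics: reaeration dominates
  st <- initial_state(fx$grid4, fx$params, "turbid")
  st$water[, ] <- 1e-6
  st$water["O2", ] <- 1
  st$sed[c("POMD", "POMN", "POMP", "HumD", "HumN", "HumP", "BenD", "BenN",
           "BenP", "VegD", "VegN", "VegP"), ] <- 1e-6
  run <- simulate_lake(fx$grid4, fx$params, fx$closed_forcing, init = st,
                       n_days = 60)
  t_surf <- utils::tail(run$daily$temp_surf, 1)
  expect_gt(utils::tail(run$daily$o2_surf, 1), 0.8 * o2_saturation(t_surf))
})
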