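test_that("abiotic temperature multiplier is exponential around 20 degC", {
  expect_equal(temp_factor_abiotic(20, 1.07), 1)
  expect_equal(temp_factor_abiotic(5, 1), 1)
  expect_equal(temp_factor_abiotic(30, 1.07), 1.07^10)
  expect_error(temp_factor_abiotic(10, 0), "positive")
})

test_that("biotic temperature multiplier is a symmetric Gaussian", {
  expect_equal(temp_factor_biotic(18, 18, 5), 1)
  expect_equal(temp_factor_biotic(23, 18, 5), exp(-0.5))
  expect_equal(temp_factor_biotic(13, 18, 5), temp_factor_biotic(23, 18, 5))
  # area under the curve matches the Gaussian closed form (quadrature)
  f <- function(t) temp_factor_biotic(t, 18, 5)
  area <- stats::integrate(f, -200, 200)$value
  expect_equal(area, sqrt(2 * pi) * 5, tolerance = 1e-6)
})

test_that("Droop growth is zero at the minimum quota and saturates at the maximum", {
  mu <- droop_growth(dm = 2, n = 2 * 0.02, p = 2 * 0.008, f_light = 1,
                     f_temp = 1, mu_max = 1.5, 0.02, 0.07, 0.002, 0.012)
  expect_equal(mu, 0)
  mu_full <- droop_growth(2, 2 * 0.07, 2 * 0.012, 1, 1, 1.5,
                          0.02, 0.07, 0.002, 0.012)
  expect_equal(mu_full, 1.5 * (1 - 0.02 / 0.07) * 2)
  # the minimum law picks the more limiting nutrient elementwise
  qn <- seq(0.02, 0.07, length.out = 11)
  qp <- rev(seq(0.002, 0.012, length.out = 11))
  mu_v <- droop_growth(rep(1, 11), qn, qp, 1, 1, 1, 0.02, 0.07, 0.002, 0.012)
  brute <- pmin(1 - 0.02 / qn, 1 - 0.002 / qp)
  expect_equal(mu_v, brute)
  expect_error(droop_growth(0, 1, 0, 1, 1, 1, 0.02, 0.07, 0.002, 0.012),
               "bookkeeping")
})

test_that("Droop growth is non-decreasing in the quota", {
  qn <- seq(0.02, 0.07, length.out = 50)
  mu <- droop_growth(rep(1, 50), qn, rep(0.012, 50), 1, 1, 1,
                     0.02, 0.07, 0.002, 0.012)
  expect_true(all(diff(mu) >= 0))
})

test_that("quota-regulated uptake shuts off when stores are full", {
  expect_equal(nutrient_uptake(1, q = 0.07, conc = 10, v_max = 0.1,
                               q_min = 0.02, q_max = 0.07, k = 0.1), 0)
  # saturation limit
  v_inf <- nutrient_uptake(2, 0.02, 1e9, 0.1, 0.02, 0.07, 0.1)
  expect_equal(v_inf, 0.1 * 2, tolerance = 1e-6)
  # half-saturation at empty stores: V = V_max * DM / 2
  v_half <- nutrient_uptake(3, 0.02, 0.1, 0.1, 0.02, 0.07, 0.1)
  expect_equal(v_half, 0.1 * 3 / 2)
})

test_that("chl-a ratio moves between its bounds with light limitation", {
  out_hi <- chla(dm = 4, f_light = 1, chl_min = 5, chl_max = 20)
  expect_equal(out_hi$total, 4 * 5)
  out_lo <- chla(4, 0, 5, 20)
  expect_equal(out_lo$total, 4 * 20)
  out0 <- chla(rbind(0, 0, 0), c(0.5, 0.5, 0.5), c(5, 3, 5), c(20, 12, 15))
  expect_equal(out0$total, 0)
})

test_that("zooplankton filtering saturates and respects the preference ranking", {
  prefs <- c(dia = 1, oth = 0.8, cya = 0.4, pom = 0.2)
  none <- zoo_grazing(matrix(0, 4, 1), prefs, zoo_dm = 1, f_temp = 1,
                      f_max = 0.6, h_food = 2)
  expect_equal(as.numeric(none), rep(0, 4))
  # total intake saturates hyperbolically as food grows
  tot <- vapply(c(1, 10, 100, 1000), function(f) {
    sum(zoo_grazing(matrix(f, 4, 1), prefs, 1, 1, 0.6, 2))
  }, numeric(1))
  expect_true(all(diff(tot) > 0))
  expect_lt(tot[4], 0.6 * 2 * 1.01)          # below the F_max * h asymptote
  # equal concentrations: flux share follows the preference order
  fl <- zoo_grazing(matrix(5, 4, 1), prefs, 1, 1, 0.6, 2)
  expect_true(all(diff(as.numeric(fl)) < 0))
})

test_that("macrophyte net growth has an interior temperature optimum", {
  expect_equal(as.numeric(macrophyte_net_growth(15, 50, 0)), 0)
  expect_lt(as.numeric(macrophyte_net_growth(15, 0, 100)), 0)
  tt <- seq(0, 40, by = 0.1)
  net <- as.numeric(macrophyte_net_growth(tt, 60, 100, p_max = 0.3,
                                          c_prod = 0.03, r_resp = 0.05,
                                          c_resp = 0.12, h_par = 20,
                                          b_max = 600))
  t_star <- tt[which.max(net)]
  # analytic stationary point of B*(a e^{cp(T-20)} - b e^{cr(T-20)})
  a <- 0.3 * 60 / (60 + 20) * (1 - 100 / 600)
  t_analytic <- 20 + log(a * 0.03 / (0.05 * 0.12)) / (0.12 - 0.03)
  expect_equal(t_star, t_analytic, tolerance = 0.1)
  expect_gt(t_star, 0); expect_lt(t_star, 40)
})

test_that("coverage and depth limit follow the benthic-area weighting", {
  g <- fx$grid16
  out0 <- coverage_and_depth_limit(rep(0, 16), g)
  expect_equal(out0$lake_coverage, 0)
  expect_equal(out0$depth_limit_m, 0)
  # biomass only in the shallowest layer
  b <- c(rep(0, 15), 300)
  out1 <- coverage_and_depth_limit(b, g, b_cov = 150)
  cov_top <- 100 * (1 - exp(-300 / 150))
  expect_equal(out1$lake_coverage,
               cov_top * g$benthic_areas[16] / sum(g$benthic_areas))
  # uniform biomass passes the threshold everywhere: depth limit = max depth
  out2 <- coverage_and_depth_limit(rep(50, 16), g, threshold = 0.1)
  expect_equal(out2$depth_limit_m, g$max_depth)
  expect_error(coverage_and_depth_limit(rep(1, 16), g, threshold = 0),
               "threshold")
})
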