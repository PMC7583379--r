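#' Temperature multipliers for process rates
#'
#' Abiotic processes (mineralisation, nitrification, denitrification,
#' diffusion, reaeration) are modified by an exponential curve around a
#' reference temperature of 20 degC, `theta^(T - 20)`. Biotic growth rates
#' are modified by a Gaussian curve around the group's temperature optimum.
#'
#' @param temperature Water temperature (degC).
#' @param theta Exponential base (> 0).
#' @return Dimensionless multiplier.
#' @export
temp_factor_abiotic <- function(temperature, theta) {
  assert_that(all(theta > 0), "theta must be positive")
  theta^(temperature - 20)
}

#' @param t_opt Temperature optimum (degC).
#' @param t_sigma Niche width (degC, > 0).
#' @rdname temp_factor_abiotic
#' @export
temp_factor_biotic <- function(temperature, t_opt, t_sigma) {
  assert_that(all(t_sigma > 0), "t_sigma must be positive")
  exp(-0.5 * ((temperature - t_opt) / t_sigma)^2)
}

#' Droop (cell-quota) gross production
#'
#' Growth rate depends on the internal nutrient stores (quotas
#' `q = N/DM`, `P/DM`) rather than on ambient concentrations:
#' `mu = mu_max * f_T * f_I * min_nutrients(1 - q_min/q)`, zero when the
#' limiting quota is at its minimum. Quotas are clipped into
#' `[q_min, q_max]` before evaluation.
#'
#' @param dm,n,p Biomass dry mass (g/m^3) and internal N and P (g/m^3).
#' @param f_light,f_temp Light and temperature factors in `[0, 1]`.
#' @param mu_max Maximum growth rate (1/d).
#' @param q_min_n,q_max_n,q_min_p,q_max_p Quota bounds (g nutrient / g DM).
#' @return Gross production rate (g DM m^-3 d^-1), elementwise.
#' @export
droop_growth <- function(dm, n, p, f_light, f_temp, mu_max,
                         q_min_n, q_max_n, q_min_p, q_max_p) {
  if (any(dm == 0 & (n > 0 | p > 0)))
    stop_bad("internal nutrient stores without biomass: bookkeeping error")
  qn <- clamp(ifelse(dm > 0, n / dm, q_min_n), q_min_n, q_max_n)
  qp <- clamp(ifelse(dm > 0, p / dm, q_min_p), q_min_p, q_max_p)
  lim <- pmin(1 - q_min_n / qn, 1 - q_min_p / qp)
  mu_max * f_temp * f_light * lim * dm
}

#' Quota-regulated Michaelis-Menten nutrient uptake
#'
#' `V = V_max * (q_max - q)/(q_max - q_min) * S/(S + K) * DM`; uptake
#' stops when stores are full. Dissolved inorganic N uptake is split
#' between NH4 and NO3 with a preference weight on NH4.
#'
#' @param dm Biomass (g/m^3).
#' @param q Current quota (g/g).
#' @param conc Ambient substrate concentration (g/m^3).
#' @param v_max Maximum specific uptake (g per g DM per d).
#' @param q_min,q_max Quota bounds.
#' @param k Half-saturation (g/m^3).
#' @return Uptake rate (g m^-3 d^-1).
#' @export
nutrient_uptake <- function(dm, q, conc, v_max, q_min, q_max, k) {
  assert_that(all(conc >= 0), "concentrations must be non-negative")
  qq <- clamp(q, q_min, q_max)
  v_max * (q_max - qq) / (q_max - q_min) * conc / (conc + k) * dm
}

# split of dissolved inorganic N uptake between NH4 and NO3
nh4_share <- function(nh4, no3, pref = 3) {
  tot <- pref * nh4 + no3
  ifelse(tot > 0, pref * nh4 / tot, 0.5)
}

#' Chlorophyll a from dry mass with a light-dependent ratio
#'
#' The chl-a : dry-mass ratio of each group moves between its minimum (no
#' light limitation) and maximum (full light limitation):
#' `ratio = chl_max - (chl_max - chl_min) * f_light`. Total chl a is the
#' sum over groups.
#'
#' @param dm Matrix (groups x layers) or vector of phytoplankton dry mass
#'   (g/m^3).
#' @param f_light Light factor(s) in `[0, 1]` (recycled per group).
#' @param chl_min,chl_max Ratio bounds (mg chl / g DM), per group.
#' @return List with `per_group` (matrix, ug/L) and `total` (vector, ug/L).
#' @export
chla <- function(dm, f_light, chl_min, chl_max) {
  assert_that(all(f_light >= 0 & f_light <= 1), "f_light must be in [0,1]")
  dm <- rbind(dm)
  ratio <- chl_max - (chl_max - chl_min) * f_light   # may recycle over layers
  per <- dm * ratio
  list(per_group = per, total = colSums(per))
}

#' Zooplankton grazing with hyperbolically declining filtering
#'
#' The community filters at `F_max * f_T / (1 + F/h_food)` (volume swept
#' per g zooplankton per day), where `F = sum_i p_i C_i` is
#' preference-weighted food availability, so total intake saturates at
#' high food. Per-food fluxes are `filtering * p_i * C_i * DM_zoo`. The
#' default preference ranking is diatoms > other algae > cyanobacteria >
#' POM.
#'
#' @param food Named vector or matrix (foods x layers) of food
#'   concentrations (g DM/m^3).
#' @param prefs Preferences in `[0, 1]`, one per food.
#' @param zoo_dm Zooplankton dry mass (g/m^3).
#' @param f_temp Temperature factor.
#' @param f_max Maximum filtering rate (m^3 per g DM per d).
#' @param h_food Food half-saturation (g/m^3).
#' @return Matrix (foods x layers) of grazing fluxes (g m^-3 d^-1).
#' @export
zoo_grazing <- function(food, prefs, zoo_dm, f_temp, f_max, h_food) {
  food <- rbind(food)
  assert_that(all(prefs >= 0 & prefs <= 1), "preferences must be in [0,1]")
  f_eff <- colSums(food * prefs)
  filt <- f_max * f_temp / (1 + f_eff / h_food)
  sweep(food * prefs, 2, filt * zoo_dm, "*")
}

#' Macrophyte net growth rate
#'
#' Production and maintenance respiration are two exponential functions of
#' temperature; with the respiration exponent larger than the production
#' exponent, the net rate has an interior temperature optimum. Production
#' saturates with bottom-of-layer PAR and is limited logistically by
#' biomass; net rates can be negative (die-back in the dark or at high
#' temperature).
#'
#' @param temperature Water temperature at the bed (degC).
#' @param par_bottom PAR reaching the sediment surface (W/m^2).
#' @param biomass Macrophyte dry mass (g/m^2).
#' @param p_max,c_prod Production base rate (1/d at 20 degC) and exponent.
#' @param r_resp,c_resp Respiration base rate and exponent (`c_resp > c_prod`).
#' @param h_par Light half-saturation (W/m^2).
#' @param b_max Carrying capacity (g/m^2).
#' @param f_nutrient Optional nutrient limitation factor in `[0, 1]`.
#' @return Net growth rate (g DM m^-2 d^-1); components as attributes
#'   `production` and `respiration`.
#' @export
macrophyte_net_growth <- function(temperature, par_bottom, biomass,
                                  p_max = 0.22, c_prod = 0.035,
                                  r_resp = 0.025, c_resp = 0.07,
                                  h_par = 14, b_max = 600, f_nutrient = 1) {
  assert_that(all(biomass >= 0), "biomass must be non-negative")
  prod <- biomass * p_max * exp(c_prod * (temperature - 20)) *
    par_bottom / (par_bottom + h_par) * pmax(0, 1 - biomass / b_max) * f_nutrient
  resp <- biomass * r_resp * exp(c_resp * (temperature - 20))
  out <- prod - resp
  attr(out, "production") <- prod
  attr(out, "respiration") <- resp
  out
}

#' Macrophyte coverage and depth limit
#'
#' Per-layer coverage is a saturating function of areal biomass,
#' `100 * (1 - exp(-biomass / b_cov))` percent; whole-lake coverage is the
#' benthic-area-weighted mean; the depth limit is the depth of the deepest
#' layer whose coverage reaches the threshold (0 when no layer does).
#'
#' @param biomass Per-layer macrophyte dry mass (g/m^2), layer 1 = bottom.
#' @param grid A `lake_grid`.
#' @param threshold Coverage threshold in percent (default 0.1).
#' @param b_cov Biomass scale of the coverage curve (g/m^2).
#' @return List: `per_layer` (%), `lake_coverage` (%), `depth_limit_m`.
#' @export
coverage_and_depth_limit <- function(biomass, grid, threshold = 0.1,
                                     b_cov = 150) {
  assert_that(threshold > 0 && threshold < 100, "threshold must be in (0,100)")
  cov <- 100 * (1 - exp(-biomass / b_cov))
  lake <- sum(cov * grid$benthic_areas) / sum(grid$benthic_areas)
  ok <- which(cov >= threshold)
  depth_limit <- if (length(ok)) {
    # depth of the bottom interface of the deepest vegetated layer
    deepest <- min(ok)
    min(grid$max_depth - grid$interfaces[deepest], grid$max_depth)
  } else 0
  list(per_layer = cov, lake_coverage = lake, depth_limit_m = depth_limit)
}
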