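#' Model parameter set
#'
#' A parameter set is a tibble with one row per named parameter carrying
#' its value, lower and upper bound (the calibration search space), unit
#' and description. [default_parameters()] returns the packaged default
#' parameterisation of the synthetic shallow lake; bounds are plausible
#' ranges for a temperate eutrophic lake, not authoritative values.
#'
#' @param name,value,lower,upper,unit,description Parallel vectors.
#' @return A tibble of class `param_set`.
#' @export
param_set <- function(name, value, lower, upper, unit = "", description = "") {
  assert_that(!anyDuplicated(name), "parameter names must be unique")
  assert_that(all(lower <= value & value <= upper),
              "each parameter must satisfy lower <= value <= upper")
  out <- tibble::tibble(name = name, value = as.numeric(value),
                        lower = as.numeric(lower), upper = as.numeric(upper),
                        unit = rep_len(unit, length(name)),
                        description = rep_len(description, length(name)))
  class(out) <- c("param_set", class(out))
  out
}

#' @describeIn param_set Named numeric vector of current values.
#' @param params A `param_set`.
#' @export
param_values <- function(params) {
  stats::setNames(params$value, params$name)
}

#' @describeIn param_set Return a copy with the named values replaced
#'   (clipped into their bounds).
#' @param ... Named scalar replacements, or a single named vector.
#' @export
param_update <- function(params, ...) {
  upd <- list(...)
  if (length(upd) == 1 && is.null(names(upd)) && !is.null(names(upd[[1]])))
    upd <- as.list(upd[[1]])
  if (length(upd) == 1 && is.numeric(upd[[1]]) && length(upd[[1]]) > 1 &&
      !is.null(names(upd[[1]])))
    upd <- as.list(upd[[1]])
  bad <- setdiff(names(upd), params$name)
  assert_that(length(bad) == 0,
              paste("unknown parameter(s):", paste(bad, collapse = ", ")))
  i <- match(names(upd), params$name)
  v <- unlist(upd)
  params$value[i] <- clamp(v, params$lower[i], params$upper[i])
  params
}

p_row <- function(name, value, lower, upper, unit, description) {
  list(name = name, value = value, lower = lower, upper = upper,
       unit = unit, description = description)
}

#' Default parameterisation of the synthetic shallow lake
#'
#' @return A `param_set` covering physics, the three phytoplankton groups
#'   (diatoms, cyanobacteria, other edible algae), zooplankton, three fish
#'   groups, zoobenthos, macrophytes, water-column and sediment
#'   biogeochemistry, and forcing routing.
#' @export
default_parameters <- function() {
  r <- list(
    # --- physics -----------------------------------------------------------
    p_row("tau_temp",     4,     1,    10,   "d",        "surface temperature relaxation time"),
    p_row("z_tau",        4,     1,    20,   "m",        "depth scale slowing temperature relaxation"),
    p_row("c_swr",        0.045, 0.01, 0.09, "degC m2/W","radiative warming of equilibrium temperature"),
    p_row("mix_d0",       0.5,   0.05, 5,    "m2/d",     "background vertical diffusivity"),
    p_row("mix_cw",       0.5,   0.05, 5,    "m2/d/(m/s)^3", "wind-cubed diffusivity coefficient"),
    p_row("latitude",     56,    40,   70,   "deg",      "latitude for solar geometry"),
    p_row("z_wave",       0.35,  0.1,  5,    "m",        "depth decay scale of wave shear"),
    p_row("rea_k0",       0.4,   0.1,  1,    "m/d",      "still-air reaeration piston velocity"),
    p_row("rea_kwind",    0.06,  0.01, 0.2,  "m/d/(m/s)^2", "wind-squared reaeration coefficient"),
    p_row("theta_rea",    1.024, 1.0,  1.1,  "-",        "reaeration temperature base"),
    # --- light -------------------------------------------------------------
    p_row("k_bg",         0.5,   0.1,  2,    "1/m",      "background light extinction"),
    p_row("k_pom",        0.05,  0.01, 0.2,  "m2/g",     "specific extinction of POM"),
    p_row("k_im",         0.05,  0.01, 0.2,  "m2/g",     "specific extinction of inorganic matter"),
    p_row("k_veg",        0.008, 0.001,0.05, "m2/g",     "specific extinction of macrophyte biomass"),
    # --- phytoplankton: diatoms / cyanobacteria / other --------------------
    p_row("mu_max_dia",   2.5,   0.5,  4,    "1/d",      "diatom maximum growth rate"),
    p_row("mu_max_cya",   0.75,  0.2,  2.5,  "1/d",      "cyanobacteria maximum growth rate"),
    p_row("mu_max_oth",   1.5,   0.4,  3,    "1/d",      "other-algae maximum growth rate"),
    p_row("t_opt_dia",    14,    5,    25,   "degC",     "diatom temperature optimum"),
    p_row("t_opt_cya",    25,    18,   32,   "degC",     "cyanobacteria temperature optimum"),
    p_row("t_opt_oth",    20,    10,   28,   "degC",     "other-algae temperature optimum"),
    p_row("t_sig_dia",    10,    3,    20,   "degC",     "diatom temperature niche width"),
    p_row("t_sig_cya",    12,    3,    20,   "degC",     "cyanobacteria temperature niche width"),
    p_row("t_sig_oth",    12,    3,    20,   "degC",     "other-algae temperature niche width"),
    p_row("h_par_dia",    10,    4,    60,   "W/m2",     "diatom light half-saturation (PAR)"),
    p_row("h_par_cya",    12,    5,    60,   "W/m2",     "cyanobacteria light half-saturation"),
    p_row("h_par_oth",    22,    5,    60,   "W/m2",     "other-algae light half-saturation"),
    p_row("q_min_n",      0.02,  0.01, 0.04, "gN/gDM",   "minimum N quota (all groups)"),
    p_row("q_max_n",      0.07,  0.04, 0.12, "gN/gDM",   "maximum N quota"),
    p_row("q_min_p",      0.002, 0.001,0.004,"gP/gDM",   "minimum P quota"),
    p_row("q_max_p",      0.012, 0.005,0.025,"gP/gDM",   "maximum P quota"),
    p_row("v_max_n",      0.07,  0.02, 0.2,  "gN/gDM/d", "maximum N uptake rate"),
    p_row("v_max_p_dia",  0.015, 0.003,0.04, "gP/gDM/d", "diatom maximum P uptake rate"),
    p_row("v_max_p_cya",  0.006, 0.002,0.03, "gP/gDM/d", "cyanobacteria maximum P uptake rate"),
    p_row("v_max_p_oth",  0.012, 0.003,0.04, "gP/gDM/d", "other-algae maximum P uptake rate"),
    p_row("k_n_upt",      0.15,  0.02, 0.5,  "gN/m3",    "N uptake half-saturation"),
    p_row("k_p_upt_dia",  0.012, 0.002,0.05, "gP/m3",    "diatom P uptake half-saturation"),
    p_row("k_p_upt_cya",  0.003, 0.001,0.02, "gP/m3",    "cyanobacteria P half-saturation (high affinity)"),
    p_row("k_p_upt_oth",  0.008, 0.002,0.04, "gP/m3",    "other-algae P uptake half-saturation"),
    p_row("pref_nh4",     3,     1,    10,   "-",        "NH4 over NO3 uptake preference weight"),
    p_row("chl_dm_min_dia", 5,   2,    15,   "mg/g",     "diatom minimum chl-a:DM ratio"),
    p_row("chl_dm_max_dia", 18,  8,    30,   "mg/g",     "diatom maximum chl-a:DM ratio"),
    p_row("chl_dm_min_cya", 3,   1,    10,   "mg/g",     "cyanobacteria minimum chl-a:DM"),
    p_row("chl_dm_max_cya", 12,  5,    25,   "mg/g",     "cyanobacteria maximum chl-a:DM"),
    p_row("chl_dm_min_oth", 5,   2,    15,   "mg/g",     "other-algae minimum chl-a:DM"),
    p_row("chl_dm_max_oth", 15,  8,    30,   "mg/g",     "other-algae maximum chl-a:DM"),
    p_row("settle_dia",   0.10,  0.02, 0.5,    "m/d",      "diatom settling velocity"),
    p_row("settle_cya",   0.01,  0.0,  0.1,  "m/d",      "cyanobacteria settling velocity"),
    p_row("settle_oth",   0.06,  0.01, 0.3,  "m/d",      "other-algae settling velocity"),
    p_row("settle_pom",   0.25,  0.05, 1,    "m/d",      "POM settling velocity"),
    p_row("settle_im",    0.8,   0.1,  3,    "m/d",      "inorganic matter settling velocity"),
    p_row("k_ext_phy",    0.12,  0.05, 0.3,  "m2/g",     "specific extinction of phytoplankton DM"),
    p_row("k_resp_phy",   0.03,  0.01, 0.15, "1/d",      "phytoplankton respiration at 20 degC"),
    p_row("k_mort_phy",   0.02,  0.005,0.15, "1/d",      "phytoplankton mortality"),
    p_row("f_diss_mort",  0.3,   0.1,  0.7,  "-",        "dissolved fraction of mortality N/P"),
    # --- zooplankton -------------------------------------------------------
    p_row("zoo_fmax",     0.6,   0.1,  3,    "m3/gDM/d", "maximum filtering rate"),
    p_row("zoo_hfood",    2.0,   0.3,  5,    "g/m3",     "food half-saturation of filtering"),
    p_row("pref_zoo_dia", 1.0,   0.5,  1,    "-",        "zooplankton preference: diatoms"),
    p_row("pref_zoo_oth", 0.8,   0.3,  1,    "-",        "zooplankton preference: other algae"),
    p_row("pref_zoo_cya", 0.4,   0.05, 1,    "-",        "zooplankton preference: cyanobacteria"),
    p_row("pref_zoo_pom", 0.2,   0.02, 1,    "-",        "zooplankton preference: POM"),
    p_row("zoo_assim",    0.32,  0.15, 0.7,  "-",        "assimilation efficiency of grazing"),
    p_row("zoo_topt",     18,    10,   28,   "degC",     "zooplankton temperature optimum"),
    p_row("zoo_tsig",     9,     3,    20,   "degC",     "zooplankton temperature niche width"),
    p_row("zoo_resp",     0.08,  0.02, 0.2,  "1/d",      "zooplankton respiration"),
    p_row("zoo_mort",     0.02,  0.005,0.15, "1/d",      "zooplankton background mortality"),
    # --- fish --------------------------------------------------------------
    p_row("fjv_upt",      0.20,  0.02, 0.6,  "g/gDM/d",  "juvenile fish max zooplankton uptake"),
    p_row("fjv_hzoo",     0.5,   0.1,  2,    "g/m3",     "juvenile fish zooplankton half-saturation"),
    p_row("fad_upt",      0.08,  0.01, 0.3,  "g/gDM/d",  "adult fish max zoobenthos uptake"),
    p_row("fad_hben",     5,     1,    20,   "g/m2",     "adult fish zoobenthos half-saturation"),
    p_row("fpi_upt",      0.20,  0.01, 0.5,  "g/gDM/d",  "piscivore max fish uptake"),
    p_row("fpi_hprey",    1,     0.2,  8,    "g/m3",     "piscivore prey half-saturation"),
    p_row("c_cov_veg_min",0.25,  0.05, 0.8,  "-",        "piscivory multiplier at zero coverage"),
    p_row("h_d_veg_pisc", 15,    2,    50,   "% cover",  "coverage half-saturation of piscivory"),
    p_row("zoo_refuge",   0.8,   0,    1,    "-",        "max planktivory reduction at full coverage"),
    p_row("fish_assim",   0.4,   0.2,  0.7,  "-",        "fish assimilation efficiency"),
    p_row("fish_topt",    22,    12,   30,   "degC",     "fish temperature optimum"),
    p_row("fish_tsig",    9,     3,    20,   "degC",     "fish temperature niche width"),
    p_row("fish_resp",    0.008, 0.002,0.03, "1/d",      "fish respiration"),
    p_row("fish_mort",    0.003, 0.001,0.02, "1/d",      "fish background mortality"),
    p_row("age_frac",     0.5,   0.1,  0.9,  "-",        "juvenile->adult transfer on 1 January"),
    p_row("fish_repro",   0.15,  0.02, 0.5,  "-",        "adult biomass fraction spawned to juveniles on 1 January"),
    p_row("winter_kill",  0,     0,    1,    "-",        "optional winter fish-kill fraction"),
    p_row("winter_kill_day", 15, 1,    90,   "doy",      "day of year of the winter kill"),
    # --- zoobenthos --------------------------------------------------------
    p_row("ben_upt",      0.06,  0.01, 0.2,  "g/gDM/d",  "zoobenthos max sediment-POM uptake"),
    p_row("ben_hpom",     800,   100,  3000, "g/m2",     "zoobenthos food half-saturation"),
    p_row("ben_assim",    0.3,   0.1,  0.6,  "-",        "zoobenthos assimilation efficiency"),
    p_row("ben_topt",     16,    8,    25,   "degC",     "zoobenthos temperature optimum"),
    p_row("ben_tsig",     10,    3,    20,   "degC",     "zoobenthos temperature niche width"),
    p_row("ben_resp",     0.01,  0.002,0.05, "1/d",      "zoobenthos respiration"),
    p_row("ben_mort",     0.01,  0.002,0.05, "1/d",      "zoobenthos background mortality"),
    # --- macrophytes -------------------------------------------------------
    p_row("veg_pmax",     0.28,  0.05, 0.6,  "1/d",      "macrophyte production rate base (20 degC)"),
    p_row("veg_cprod",    0.035, 0.01, 0.08, "1/degC",   "production temperature exponent"),
    p_row("veg_resp",     0.018, 0.003,0.08, "1/d",      "maintenance respiration base (20 degC)"),
    p_row("veg_cresp",    0.07,  0.03, 0.12, "1/degC",   "respiration temperature exponent"),
    p_row("veg_hpar",     35,    4,    120,   "W/m2",     "macrophyte light half-saturation at the bed"),
    p_row("veg_bmax",     600,   100,  2000, "gDM/m2",   "macrophyte carrying capacity"),
    p_row("veg_mort",     0.005, 0.001,0.03, "1/d",      "macrophyte mortality"),
    p_row("veg_wave_mort",0.4,   0,    1.0,  "1/d",      "extra macrophyte loss per unit wave shear"),
    p_row("veg_qn",       0.025, 0.01, 0.05, "gN/gDM",   "macrophyte N content"),
    p_row("veg_qp",       0.0025,0.001,0.006,"gP/gDM",   "macrophyte P content"),
    p_row("veg_hn",       0.01,  0.002,2,    "gN/m3",    "porewater N half-saturation of growth"),
    p_row("veg_hp",       0.001, 2e-4, 0.3,  "gP/m3",    "porewater P half-saturation of growth"),
    p_row("b_cov",        300,   30,   800,  "gDM/m2",   "biomass scale of the coverage curve"),
    p_row("veg_seed_b",   0.2,   0,    5,    "gDM/m2",   "effective propagule-bank biomass"),
    p_row("veg_shoot_frac",0.38, 0,    1,    "-",        "share of macrophyte nutrient uptake taken from the water column"),
    # --- water-column biogeochemistry --------------------------------------
    p_row("k_hyd_pom",    0.03,  0.005,0.15, "1/d",      "POM hydrolysis to DOM at 20 degC"),
    p_row("k_min_dom",    0.010, 0.002,0.15, "1/d",      "DOM mineralisation at 20 degC"),
    p_row("theta_min",    1.07,  1.02, 1.12, "-",        "mineralisation temperature base"),
    p_row("k_nit_w",      0.12,  0.01, 0.6,  "1/d",      "water-column nitrification at 20 degC"),
    p_row("theta_nit",    1.08,  1.02, 1.12, "-",        "nitrification temperature base"),
    p_row("h_nit_o2",     2,     0.5,  6,    "g/m3",     "O2 half-saturation of nitrification"),
    p_row("k_den_w",      0.05,  0.005,0.3,  "1/d",      "water-column denitrification at 20 degC"),
    p_row("theta_den",    1.07,  1.02, 1.12, "-",        "denitrification temperature base"),
    p_row("h_anox",       0.5,   0.1,  2,    "g/m3",     "O2 inhibition scale of denitrification"),
    p_row("y_o2_dm",      1.07,  0.8,  1.5,  "gO2/gDM",  "O2 yield of production / cost of mineralisation"),
    p_row("y_o2_nit",     4.57,  4.57, 4.57, "gO2/gN",   "O2 cost of nitrification"),
    p_row("dm_per_n",     12,    5,    50,   "gDM/gN",   "dry mass mineralised per g DOM-N (O2 cost basis)"),
    # --- sediment ----------------------------------------------------------
    p_row("h_sed",        0.10,  0.10, 0.10, "m",        "sediment layer height"),
    p_row("porosity",     0.8,   0.6,  0.95, "-",        "sediment porosity"),
    p_row("k_min_sed",    0.002, 0.0005,0.02,"1/d",      "sediment POM mineralisation at 20 degC"),
    p_row("k_hum",        0.001, 1e-4, 0.01, "1/d",      "POM humification rate"),
    p_row("k_min_hum",    1e-4,  1e-5, 1e-3, "1/d",      "humus mineralisation at 20 degC"),
    p_row("k_nit_sed",    0.15,  0.01, 0.6,  "1/d",      "sediment nitrification at 20 degC"),
    p_row("k_den_sed",    0.15,  0.01, 0.6,  "1/d",      "sediment denitrification at 20 degC"),
    p_row("k_dif",        0.015, 0.002,0.08, "m/d",      "porewater-water diffusive piston velocity"),
    p_row("theta_dif",    1.02,  1.0,  1.08, "-",        "diffusion temperature base"),
    p_row("fe_frac",      0.10,  0.02, 0.3,  "gFe/gIM",  "iron fraction of sediment inorganic matter"),
    p_row("q_ads_max",    0.007, 0.001,0.03, "gP/gFe",   "maximum P sorption per g Fe"),
    p_row("k_lang",       3,     0.5,  10,   "m3/gP",    "Langmuir affinity of P sorption"),
    p_row("k_sorp",       0.05,  0.005,0.3,  "1/d",      "sorption relaxation rate"),
    p_row("h_oxic",       1,     0.2,  4,    "g/m3",     "O2 half-saturation of oxic sorption"),
    p_row("k_resus",      5e-4,  1e-5, 0.01, "1/d",      "resuspension rate per unit excess shear"),
    p_row("tau_crit",     0.5,   0.05, 2,    "-",        "critical shear proxy for resuspension"),
    p_row("f_veg_res",    0.85,  0,    1,    "-",        "max fractional damping of resuspension by full coverage"),
    p_row("k_bury",       1e-5,  1e-6, 1e-4, "1/d",      "burial rate to the deep-sediment sink"),
    # --- forcing routing and stoichiometry ---------------------------------
    p_row("f_org_in_dom", 0.9,   0,    1,    "-",        "share of inflow organic N/P routed to DOM"),
    p_row("n_per_dm_pom", 0.06,  0.02, 0.10, "gN/gDM",   "N content of inflow/settled POM dry mass"),
    p_row("phyto_seed_in",0.02,  0,    0.2,  "gDM/m3",   "phytoplankton inoculum in inflow (per group)"),
    p_row("zoo_seed_in",  0.005, 0,    0.05, "gDM/m3",   "zooplankton inoculum in inflow"),
    p_row("fetch",        954,   100,  5000, "m",        "effective wind fetch")
  )
  d <- purrr::transpose(r)
  param_set(unlist(d$name), unlist(d$value), unlist(d$lower),
            unlist(d$upper), unlist(d$unit), unlist(d$description))
}
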