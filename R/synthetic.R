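# deterministic generators for every input the pipeline needs -----------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of the synthetic shallow lake
#'
#' Defaults emulate a small, shallow, eutrophic temperate lake: 0.91 km^2
#' surface area, 1.2 m mean and 2.6 m maximum depth, winter (Oct-Apr) and
#' summer (May-Sep) mean air temperatures of 3.7 and 14.5 degC, three
#' inlets delivering roughly 120 Mg N and 3 Mg P per year with hydraulic
#' residence times near 16 d in winter and 32 d in summer.
#'
#' @param surface_area_m2,max_depth_m,mean_depth_m Morphometry.
#' @param winter_air_c,summer_air_c Seasonal air-temperature targets (degC).
#' @param wind_mean_ms Mean wind speed (m/s).
#' @param tn_load_mg_yr,tp_load_mg_yr Annual nutrient load targets (Mg/yr).
#' @param res_winter_d,res_summer_d Hydraulic residence targets (d).
#' @param frac_org_p,frac_org_n Organic fractions of inlet TP and TN.
#' @param seed Base random seed for all generators.
#' @return A list of class `synthetic_lake_spec`.
#' @export
synthetic_lake_spec <- function(surface_area_m2 = 0.91e6, max_depth_m = 2.6,
                                mean_depth_m = 1.2, winter_air_c = 3.7,
                                summer_air_c = 14.5, wind_mean_ms = 4,
                                tn_load_mg_yr = 120, tp_load_mg_yr = 3.0,
                                res_winter_d = 16, res_summer_d = 32,
                                frac_org_p = 0.75, frac_org_n = 0.90,
                                seed = 42) {
  assert_that(mean_depth_m < max_depth_m, "mean depth must be below max depth")
  structure(as.list(environment()), class = "synthetic_lake_spec")
}

SUMMER_DOY <- function(doy) doy >= 121 & doy <= 273   # 1 May - 30 Sep

#' Generate a hypsograph for the synthetic lake
#'
#' Power-law morphometry `A(z) = A_surface * (z / z_max)^p` with the
#' exponent solved numerically so the tabulated (trapezoid-integrated)
#' mean depth `V / A_surface` matches the specification.
#'
#' @param spec A [synthetic_lake_spec()].
#' @param n_levels Number of tabulated levels.
#' @return A [hypsograph()].
#' @export
gen_hypsograph <- function(spec, n_levels = 21) {
  z <- seq(0, spec$max_depth_m, length.out = n_levels)
  mean_depth_of <- function(p) {
    h <- hypsograph(z, spec$surface_area_m2 * (z / spec$max_depth_m)^p)
    lake_volume(h) / spec$surface_area_m2
  }
  f <- function(p) mean_depth_of(p) - spec$mean_depth_m
  p <- stats::uniroot(f, c(0.05, 20), tol = 1e-10)$root
  hypsograph(z, spec$surface_area_m2 * (z / spec$max_depth_m)^p)
}

# seasonal sinusoid with winter/summer window means solved exactly
seasonal_coefs <- function(winter_target, summer_target, peak_doy = 205) {
  doy <- 1:365
  cosv <- cos(2 * pi * (doy - peak_doy) / 365)
  cw <- mean(cosv[!SUMMER_DOY(doy)])
  cs <- mean(cosv[SUMMER_DOY(doy)])
  amp <- (summer_target - winter_target) / (cs - cw)
  list(mean = winter_target - amp * cw, amp = amp, peak_doy = peak_doy)
}

#' Generate 3-hourly meteorology
#'
#' Seasonal sinusoid (calibrated so the Oct-Apr and May-Sep means equal
#' the specification's winter and summer targets exactly in the noise-free
#' limit) plus a diurnal cycle and AR(1) noise for air temperature; AR(1)
#' wind components around a configurable mean speed; bounded cloud cover;
#' pressure and dew point carried for completeness.
#'
#' @param spec A [synthetic_lake_spec()].
#' @param years Number of 365-day years.
#' @param seed Seed (defaults to the spec's).
#' @param noise_sd Marginal standard deviation of the temperature noise
#'   (degC); 0 gives the exact sinusoid.
#' @return Tibble with `day` (fractional), `doy`, `air_temp`, `pressure`,
#'   `dewpoint`, `cloud`, `wind_u`, `wind_v`.
#' @export
gen_meteorology <- function(spec, years = 1, seed = spec$seed, noise_sd = 2.5) {
  n <- years * 365 * 8
  day <- 1 + (seq_len(n) - 1) / 8
  doy <- doy365(day)
  hour <- ((seq_len(n) - 1) %% 8) * 3
  sc <- seasonal_coefs(spec$winter_air_c, spec$summer_air_c)
  base <- sc$mean + sc$amp * cos(2 * pi * (doy - sc$peak_doy) / 365)
  diurnal <- 2.0 * cos(2 * pi * (hour - 15) / 24)
  with_seed(seed, {
    phi <- 0.97                     # 3-hourly AR(1)
    innov_sd <- noise_sd * sqrt(1 - phi^2)
    noise <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                      method = "recursive"))
    cloud <- clamp(0.6 - 0.15 * cos(2 * pi * (doy - sc$peak_doy) / 365) +
                     as.numeric(stats::filter(stats::rnorm(n, 0, 0.08), 0.95,
                                              method = "recursive")), 0, 1)
    wu <- spec$wind_mean_ms * 0.65 +
      as.numeric(stats::filter(stats::rnorm(n, 0, 0.6), 0.95, method = "recursive"))
    wv <- spec$wind_mean_ms * 0.55 +
      as.numeric(stats::filter(stats::rnorm(n, 0, 0.6), 0.95, method = "recursive"))
  })
  air <- base + diurnal + noise
  tibble::tibble(day = day, doy = doy, air_temp = air,
                 pressure = 1013 + 5 * cos(2 * pi * (doy - 20) / 365),
                 dewpoint = air - 2, cloud = cloud,
                 wind_u = wu, wind_v = wv)
}

#' Generate monthly inflow forcing for three inlets
#'
#' Winter-high seasonal discharge calibrated so hydraulic residence time
#' matches the winter and summer targets at the spec's lake volume, split
#' over three inlets with lognormal month-to-month variability. Total N
#' and P concentrations are set so the noise-free annual loads equal the
#' configured targets, then partitioned using the organic fractions
#' (default 75% of TP and 90% of TN organic; the inorganic N remainder is
#' split 4:1 between NO3 and NH4).
#'
#' @param spec A [synthetic_lake_spec()].
#' @param years Number of 365-day years.
#' @param seed Seed.
#' @param noise_cv Lognormal coefficient of variation of monthly discharge
#'   and concentrations (0 = deterministic).
#' @return Tibble: `day` (first day of month), `month`, `inlet`,
#'   `discharge_m3s`, `nh4`, `no3`, `po4`, `orgn`, `orgp` (g/m^3).
#' @export
gen_inflow <- function(spec, years = 1, seed = spec$seed + 1, noise_cv = 0.15) {
  volume <- spec$surface_area_m2 * spec$mean_depth_m
  sc <- seasonal_coefs(volume / (spec$res_winter_d * 86400),
                       volume / (spec$res_summer_d * 86400), peak_doy = 20)
  month_start <- cumsum(c(0, c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30)))
  mdays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  months <- seq_len(years * 12)
  day0 <- (rep(0:(years - 1), each = 12)) * 365 + month_start[(months - 1) %% 12 + 1] + 1
  mid_doy <- month_start[(months - 1) %% 12 + 1] + mdays[(months - 1) %% 12 + 1] / 2
  q_m <- pmax(0.02, sc$mean + sc$amp * cos(2 * pi * (mid_doy - sc$peak_doy) / 365))
  # seasonal concentration shape (winter flush), normalised to unit load later
  cshape <- 1 + 0.2 * cos(2 * pi * (mid_doy - 20) / 365)
  mdays_rep <- mdays[(months - 1) %% 12 + 1]
  # noise-free annual loads with unit concentration, for exact scaling
  base_load <- sum((q_m * 86400 * mdays_rep * cshape)[seq_len(12)])
  c_tn <- spec$tn_load_mg_yr * 1e6 / base_load
  c_tp <- spec$tp_load_mg_yr * 1e6 / base_load
  share <- c(0.5, 0.3, 0.2)
  with_seed(seed, {
    out <- purrr::map_dfr(1:3, function(i) {
      jq <- if (noise_cv > 0)
        stats::rlnorm(length(months), -noise_cv^2 / 2, noise_cv) else 1
      jc <- if (noise_cv > 0)
        stats::rlnorm(length(months), -noise_cv^2 / 2, noise_cv) else 1
      tn <- c_tn * cshape * jc
      tp <- c_tp * cshape * jc
      inorg_n <- (1 - spec$frac_org_n) * tn
      tibble::tibble(
        day = day0, month = months, inlet = i,
        discharge_m3s = q_m * share[i] * jq,
        nh4 = 0.2 * inorg_n, no3 = 0.8 * inorg_n,
        po4 = (1 - spec$frac_org_p) * tp,
        orgn = spec$frac_org_n * tn,
        orgp = spec$frac_org_p * tp)
    })
    out
  })
}

#' Areal external nutrient loads of an inflow series
#'
#' Direct recomputation `sum(Q * C * dt) / lake area` in
#' mg m^-2 d^-1, the load axis of the load-response curves.
#'
#' @param inflow Tibble from [gen_inflow()].
#' @param surface_area_m2 Lake surface area.
#' @return Tibble with `load_p_mg_m2_d`, `load_n_mg_m2_d`,
#'   `tp_load_mg_yr`, `tn_load_mg_yr`.
#' @export
inflow_loads <- function(inflow, surface_area_m2) {
  mdays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  d <- inflow |>
    dplyr::mutate(nd = mdays[(.data$month - 1) %% 12 + 1],
                  q_m3 = .data$discharge_m3s * 86400 * .data$nd,
                  p_g = .data$q_m3 * (.data$po4 + .data$orgp),
                  n_g = .data$q_m3 * (.data$nh4 + .data$no3 + .data$orgn))
  ndays <- sum(mdays) * length(unique((d$month - 1) %/% 12))
  tibble::tibble(
    load_p_mg_m2_d = sum(d$p_g) * 1000 / surface_area_m2 / ndays,
    load_n_mg_m2_d = sum(d$n_g) * 1000 / surface_area_m2 / ndays,
    tp_load_mg_yr = sum(d$p_g) / 1e6 / (ndays / 365),
    tn_load_mg_yr = sum(d$n_g) / 1e6 / (ndays / 365))
}

#' Generate sparse depth-pooled observations from a truth run
#'
#' Emulates the monitoring programme: one sampling per winter month
#' (skipped under the ice proxy, surface water at or below 0.1 degC) and
#' two per summer month; samples are pooled from the surface down to twice
#' the Secchi-depth proxy (clipped to the typical 0.2-1.0 m band and to
#' the lake depth); multiplicative lognormal noise with sigma equal to the
#' analytical error fraction (0.15 for nutrients, 0.20 for chlorophyll).
#'
#' @param run A `lake_run` made with
#'   `keep_layers = c("temp","o2","chl","no3","nh4","po4","tn","tp","pom","zoo")`.
#' @param variables Which variables to observe.
#' @param seed Seed.
#' @param noise Logical; FALSE returns exact depth-pooled truth.
#' @param first_day,last_day Observation window within the run (days).
#' @return Tibble of class `observation_set`: `variable`, `day`,
#'   `sample_depth_m`, `value`, `error_fraction`.
#' @export
gen_observations <- function(run, variables = c("temp", "o2", "chl", "no3",
                                                "nh4", "po4", "tn", "tp",
                                                "pom", "zoo"),
                             seed = 7, noise = TRUE,
                             first_day = 1, last_day = nrow(run$daily)) {
  missing_v <- setdiff(variables, names(run$layers))
  assert_that(length(missing_v) == 0,
              paste("run lacks per-layer series for:",
                    paste(missing_v, collapse = ", ")))
  err <- function(v) if (v == "chl") 0.20 else if (v == "temp") 0.02 else 0.15
  # sampling schedule on the canonical year
  month_start <- cumsum(c(1, c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30)))
  sched <- unlist(lapply(1:12, function(m) {
    if (m >= 5 && m <= 9) month_start[m] + c(7, 21) else month_start[m] + 14
  }))
  days <- as.vector(outer(sched, 365 * (0:floor((last_day - 1) / 365)), "+"))
  days <- sort(days[days >= first_day & days <= last_day])
  # ice proxy: skip sampling when surface water <= 0.1 degC
  t_surf <- run$daily$temp_surf[days]
  days <- days[t_surf > 0.1]
  secchi <- run$daily$secchi[days]
  depth <- clamp(pmin(2 * secchi, run$grid$max_depth), 0.2, 1.0)
  truth <- lapply(variables, function(v)
    vapply(seq_along(days), function(i)
      pooled_layer_mean(run$layers[[v]][days[i], ], run$grid, depth[i]),
      numeric(1)))
  names(truth) <- variables
  out <- purrr::map_dfr(variables, function(v) {
    tibble::tibble(variable = v, day = days, sample_depth_m = depth,
                   value = truth[[v]], error_fraction = err(v))
  })
  if (noise) {
    out$value <- with_seed(seed, {
      s <- out$error_fraction
      out$value * stats::rlnorm(nrow(out), -s^2 / 2, s)
    })
  }
  class(out) <- c("observation_set", class(out))
  out
}

# volume-weighted mean over the layers intersecting [surface, depth]
pooled_layer_mean <- function(values, grid, sample_depth) {
  n <- grid$n_layers
  top <- grid$max_depth - grid$interfaces   # depth below surface of interfaces
  # layer k spans depths [top[k+1], top[k]] ... expressed per layer:
  upper <- grid$max_depth - grid$interfaces[2:(n + 1)]  # depth of layer top
  lower <- grid$max_depth - grid$interfaces[1:n]        # depth of layer bottom
  frac <- clamp((sample_depth - upper) / (lower - upper), 0, 1)
  wgt <- frac * grid$volumes
  if (sum(wgt) <= 0) return(values[n])
  sum(values * wgt) / sum(wgt)
}

#' Build a deterministic twin-experiment fixture
#'
#' A twin experiment synthesises observations from a model run with known
#' ("truth") parameters and then asks the calibration machinery to
#' recover those parameters from a perturbed starting point. The fixture
#' bundles everything the recovery test needs: the grid, forcing, truth
#' parameter set, noisy depth-pooled observations, a perturbed parameter
#' set (the 8 target parameters drawn uniformly from their bounds), and
#' the run protocol.
#'
#' @param spec A [synthetic_lake_spec()].
#' @param n_layers Layers of the twin grid (small for speed).
#' @param n_days Run length (the truth run and every calibration run).
#' @param obs_start First observation day.
#' @param perturb Names of the parameters to perturb and recover.
#' @param seed Seed controlling forcing noise, observation noise and the
#'   perturbation draw.
#' @return List of class `twin_fixture`: `grid`, `forcing`,
#'   `truth_params`, `start_params`, `obs`, `perturb`, `n_days`,
#'   `variables`, `runner` (function `params -> lake_run`).
#' @export
make_twin_fixture <- function(spec = synthetic_lake_spec(),
                              n_layers = 4, n_days = 550, obs_start = 120,
                              perturb = c("tau_temp", "c_swr", "k_min_dom",
                                          "k_dif", "mu_max_dia", "zoo_fmax",
                                          "zoo_resp", "settle_dia"),
                              seed = spec$seed) {
  hyp <- gen_hypsograph(spec)
  grid <- build_grid(hyp, n_layers, if (n_layers == 1) 0 else 0.03)
  years <- ceiling(n_days / 365)
  met <- gen_meteorology(spec, years = years, seed = seed)
  inf <- gen_inflow(spec, years = years, seed = seed + 1)
  forcing <- prepare_forcing(met, inf, n_days = n_days)
  truth <- default_parameters()
  variables <- c("temp", "o2", "chl", "no3", "nh4", "po4", "tn", "tp",
                 "pom", "zoo")
  runner <- function(params) {
    simulate_lake(grid, params, forcing, init = "turbid", n_days = n_days,
                  keep_layers = variables)
  }
  truth_run <- runner(truth)
  obs <- gen_observations(truth_run, variables = variables, seed = seed + 2,
                          first_day = obs_start, last_day = n_days)
  i <- match(perturb, truth$name)
  assert_that(!anyNA(i), "unknown parameter in perturb")
  start <- truth
  start$value[i] <- with_seed(seed + 3, {
    stats::runif(length(i), truth$lower[i], truth$upper[i])
  })
  structure(list(grid = grid, forcing = forcing, truth_params = truth,
                 start_params = start, obs = obs, perturb = perturb,
                 n_days = n_days, variables = variables, runner = runner),
            class = "twin_fixture")
}
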