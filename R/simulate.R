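# run driver: canonical daily forcing + day loop ------------------------------

#' Prepare canonical daily forcing from meteorology and inflow series
#'
#' Aggregates 3-hourly meteorology to daily means (air temperature, cloud,
#' wind speed from its components), derives daily shortwave from solar
#' geometry and cloud, and expands the monthly per-inlet inflow series to
#' stepwise-constant daily totals with flow-weighted mixed concentrations.
#' All series live on the package's canonical 365-day calendar (`day` 1 =
#' 1 January of the first simulated year).
#'
#' @param meteo Tibble with `day` (fractional), `air_temp`, `cloud`,
#'   `wind_u`, `wind_v` (pressure and dew point are carried but unused by
#'   the default physics).
#' @param inflow Tibble with `day` (start of each month), `inlet`,
#'   `discharge_m3s`, `nh4`, `no3`, `po4`, `orgn`, `orgp` (g/m^3).
#' @param n_days Number of days to cover; forcing is recycled over whole
#'   years if the series are shorter.
#' @param latitude Latitude for the solar geometry (deg).
#' @return Daily forcing tibble with columns `day`, `doy`, `air_temp`,
#'   `swr`, `cloud`, `wind`, `q_in` (m^3/d), `c_nh4` ... `c_orgp` (g/m^3).
#' @export
prepare_forcing <- function(meteo, inflow, n_days = NULL, latitude = 56) {
  md <- meteo |>
    dplyr::mutate(whole_day = floor(.data$day - 1e-9) + 1,
                  wind = sqrt(.data$wind_u^2 + .data$wind_v^2)) |>
    dplyr::group_by(.data$whole_day) |>
    dplyr::summarise(air_temp = mean(.data$air_temp),
                     cloud = mean(.data$cloud),
                     wind = mean(.data$wind), .groups = "drop") |>
    dplyr::rename(day = "whole_day")
  inf <- inflow |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      q_in = sum(.data$discharge_m3s) * 86400,
      c_nh4 = stats::weighted.mean(.data$nh4, .data$discharge_m3s),
      c_no3 = stats::weighted.mean(.data$no3, .data$discharge_m3s),
      c_po4 = stats::weighted.mean(.data$po4, .data$discharge_m3s),
      c_orgn = stats::weighted.mean(.data$orgn, .data$discharge_m3s),
      c_orgp = stats::weighted.mean(.data$orgp, .data$discharge_m3s),
      .groups = "drop")
  n_days <- n_days %||% max(md$day)
  day <- seq_len(n_days)
  # recycle whole years if needed
  met_n <- 365 * (max(md$day) %/% 365)
  assert_that(met_n >= 365, "meteorology must cover at least one whole year")
  mi <- match((day - 1) %% met_n + 1, md$day)
  assert_that(!anyNA(mi), "gaps in daily meteorology after aggregation")
  inf_n <- 365 * (max(inf$day + 30) %/% 365)
  inf_day <- (day - 1) %% max(inf_n, 365) + 1
  ii <- findInterval(inf_day, inf$day)
  ii[ii == 0] <- 1
  out <- tibble::tibble(
    day = day, doy = doy365(day),
    air_temp = md$air_temp[mi], cloud = md$cloud[mi], wind = md$wind[mi],
    q_in = inf$q_in[ii],
    c_nh4 = inf$c_nh4[ii], c_no3 = inf$c_no3[ii], c_po4 = inf$c_po4[ii],
    c_orgn = inf$c_orgn[ii], c_orgp = inf$c_orgp[ii])
  out$swr <- surface_par(out$doy, out$cloud, latitude = latitude)$swr_wm2
  out
}

LAYER_DIAG_VARS <- c("temp", "o2", "chl", "no3", "nh4", "po4", "tn", "tp",
                     "pom", "zoo", "phyto", "cover", "par_bottom")

#' Run the lake model
#'
#' Integrates the full ecosystem over `n_days` of daily forcing: physics
#' (temperature relaxation, light), biogeochemical and food-web rates,
#' the positivity-preserving Modified Patankar source/sink update, then
#' transport (inflow and outflow through the surface layer, implicit
#' settling with benthic deposition, implicit vertical mixing). Daily
#' diagnostics and, optionally, per-layer series are recorded.
#'
#' @param grid A `lake_grid`.
#' @param params A `param_set`.
#' @param forcing Daily forcing from [prepare_forcing()].
#' @param init A `lake_state`, or `"turbid"` / `"clear"` to build one.
#' @param n_days Days to simulate (defaults to the forcing length).
#' @param dt Internal time step in days (must divide 1).
#' @param keep_layers Character vector of per-layer series to keep:
#'   any of `"temp"`, `"o2"`, `"chl"`, `"no3"`, `"nh4"`, `"po4"`, `"tn"`,
#'   `"tp"`, `"pom"`, `"zoo"`, `"phyto"`, `"cover"`, `"par_bottom"`
#'   (empty keeps none).
#' @param start_day Offset into the forcing (days; default 0).
#' @return A `lake_run`: list with `daily` diagnostics tibble, `layers`
#'   (list of day x layer matrices), `state` (final), `init_budget` /
#'   `final_budget` ([total_np()] rows), `grid`, `params`.
#' @export
simulate_lake <- function(grid, params, forcing, init = "turbid",
                          n_days = NULL, dt = 1, keep_layers = character(),
                          start_day = 0) {
  if (is.character(init)) init <- initial_state(grid, params, init)
  assert_that(inherits(init, "lake_state"), "init must be a lake_state")
  assert_that(dt > 0 && dt <= 1 && abs(1 / dt - round(1 / dt)) < 1e-9,
              "dt must be a divisor of one day")
  if (length(keep_layers)) {
    bad <- setdiff(keep_layers, LAYER_DIAG_VARS)
    assert_that(length(bad) == 0,
                paste("unknown layer diagnostics:", paste(bad, collapse = ", ")))
  }
  n_days <- n_days %||% (nrow(forcing) - start_day)
  assert_that(nrow(forcing) >= start_day + n_days,
              "forcing does not cover the simulation window")
  pv <- param_values(params)
  n <- grid$n_layers
  vol <- grid$volumes; vtot <- sum(vol)
  ben <- grid$benthic_areas; atot <- sum(ben)

  init_budget <- total_np(init, grid)
  state <- init
  nsub <- round(1 / dt)

  diag_names <- c("day", "doy", "temp_surf", "o2_surf", "chl", "tn", "tp",
                  "no3", "nh4", "po4", "pom", "zoo", "dia", "cya", "oth",
                  "fish_jv", "fish_ad", "fish_pi", "benthos", "veg_gm2",
                  "cover", "depth_limit", "load_p_mg_m2", "load_n_mg_m2",
                  "secchi")
  out <- matrix(NA_real_, n_days, length(diag_names),
                dimnames = list(NULL, diag_names))
  layers <- lapply(stats::setNames(keep_layers, keep_layers),
                   function(v) matrix(NA_real_, n_days, n))

  fl <- as.list(forcing)                 # plain vectors for fast row access
  cache <- new.env(parent = emptyenv())
  for (d in seq_len(n_days)) {
    i <- start_day + d
    frc <- list(day = fl$day[i], doy = fl$doy[i], air_temp = fl$air_temp[i],
                swr = fl$swr[i], cloud = fl$cloud[i], wind = fl$wind[i],
                q_in = fl$q_in[i], c_nh4 = fl$c_nh4[i], c_no3 = fl$c_no3[i],
                c_po4 = fl$c_po4[i], c_orgn = fl$c_orgn[i],
                c_orgp = fl$c_orgp[i])
    load_p <- load_n <- 0
    for (ss in seq_len(nsub)) {
      stp <- model_step(state, frc, grid, pv, dt, cache)
      state <- stp$state
      load_p <- load_p + stp$diag$load_p
      load_n <- load_n + stp$diag$load_n
    }
    dg <- stp$diag
    w <- state$water
    wm <- function(x) sum(x * vol) / vtot
    tn_l <- colSums(w[c("NH4", "NO3", "DON", "POMN", "DiaN", "CyaN", "OthN",
                        "ZooN"), , drop = FALSE])
    tp_l <- colSums(w[c("PO4", "DOP", "POMP", "DiaP", "CyaP", "OthP",
                        "ZooP"), , drop = FALSE])
    out[d, ] <- c(
      frc$day, frc$doy, state$temp[n], w["O2", n], wm(dg$chl_total),
      wm(tn_l), wm(tp_l), wm(w["NO3", ]), wm(w["NH4", ]), wm(w["PO4", ]),
      wm(w["POMD", ]), wm(w["ZooD", ]),
      wm(w["DiaD", ]), wm(w["CyaD", ]), wm(w["OthD", ]),
      wm(w["FJvD", ]), wm(w["FAdD", ]), wm(w["FPiD", ]),
      sum(state$sed["BenD", ] * ben) / atot,
      sum(state$sed["VegD", ] * ben) / atot,
      dg$lake_cover, dg$depth_limit,
      load_p / grid$surface_area * 1000, load_n / grid$surface_area * 1000,
      min(1.7 / wm(dg$kd), grid$max_depth))
    for (v in keep_layers) {
      layers[[v]][d, ] <- switch(
        v,
        temp = state$temp, o2 = w["O2", ], chl = dg$chl_total,
        no3 = w["NO3", ], nh4 = w["NH4", ], po4 = w["PO4", ],
        tn = tn_l, tp = tp_l, pom = w["POMD", ], zoo = w["ZooD", ],
        phyto = colSums(w[c("DiaD", "CyaD", "OthD"), , drop = FALSE]),
        cover = dg$cover, par_bottom = dg$par_bottom)
    }
    if (anyNA(state$water) || anyNA(state$sed))
      stop_bad(sprintf("integrator failure (NaN state) at day %d", d))
  }
  structure(list(daily = tibble::as_tibble(as.data.frame(out)),
                 layers = layers, state = state,
                 init_budget = init_budget,
                 final_budget = total_np(state, grid),
                 grid = grid, params = params),
            class = "lake_run")
}

#' @export
print.lake_run <- function(x, ...) {
  cat(sprintf("<lake_run> %d days, %d layers; final chl %.1f ug/L, coverage %.1f%%\n",
              nrow(x$daily), x$grid$n_layers,
              utils::tail(x$daily$chl, 1), utils::tail(x$daily$cover, 1)))
  invisible(x)
}

#' Mass-budget residuals of a run
#'
#' Recomputes closure of the N and P budgets: the change in total internal
#' stock plus everything that left through tracked boundary fluxes
#' (outflow, denitrified N2, deep burial) minus everything that entered
#' (inflow), relative to the initial stock. Zero (to round-off) means the
#' cycles are closed.
#'
#' @param run A `lake_run`.
#' @return Tibble with `residual_n`, `residual_p` (relative).
#' @export
budget_residual <- function(run) {
  b0 <- run$init_budget; b1 <- run$final_budget
  tibble::tibble(
    residual_n = (b1$closed_n_g - b0$closed_n_g) / b0$total_n_g,
    residual_p = (b1$closed_p_g - b0$closed_p_g) / b0$total_p_g)
}

#' @describeIn simulate_lake Daily diagnostics in long tidy form.
#' @param x A `lake_run`.
#' @param ... Unused.
#' @export
tidy.lake_run <- function(x, ...) {
  tidyr::pivot_longer(x$daily, -c("day", "doy"),
                      names_to = "variable", values_to = "value")
}

#' @describeIn simulate_lake One-row run summary.
#' @export
glance.lake_run <- function(x, ...) {
  res <- budget_residual(x)
  tibble::tibble(
    n_days = nrow(x$daily), n_layers = x$grid$n_layers,
    mean_chl = mean(x$daily$chl), final_cover = utils::tail(x$daily$cover, 1),
    residual_n = res$residual_n, residual_p = res$residual_p)
}
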