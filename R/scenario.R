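# bifurcation machinery: multiplier grids, looped forcing, branch runs,
# load-response curves, hysteresis detection --------------------------------

#' External P-load multiplier grid
#'
#' Multipliers `1 + pct/100` for `pct` from `low_pct` to `high_pct` in
#' steps of `step_pct`. The defaults (-98% to +50% in 2% increments) give
#' the canonical 75-scenario grid.
#'
#' @param low_pct,high_pct,step_pct Percent change bounds and step.
#' @return Ordered numeric vector of multipliers.
#' @examples
#' length(multiplier_grid())   # 75
#' @export
multiplier_grid <- function(low_pct = -98, high_pct = 50, step_pct = 2) {
  assert_that(step_pct > 0, "step_pct must be positive")
  assert_that(low_pct <= high_pct, "low_pct must be <= high_pct")
  k <- (high_pct - low_pct) / step_pct
  assert_that(abs(k - round(k)) < 1e-9,
              "(high_pct - low_pct) must be divisible by step_pct")
  1 + seq(low_pct, high_pct, by = step_pct) / 100
}

#' Loop a baseline window of daily forcing
#'
#' Repeats the forcing of `window` (inclusive day range on the canonical
#' 365-day calendar; its length must be a whole number of years) `reps`
#' times, renumbering days so the output continues monotonically.
#'
#' @param forcing Daily forcing tibble (from [prepare_forcing()]).
#' @param window Length-2 integer vector `c(first_day, last_day)`.
#' @param reps Number of repetitions (>= 1).
#' @param start_day First day number of the output (default 1).
#' @return Forcing tibble of `reps * length(window)` days.
#' @export
loop_baseline <- function(forcing, window, reps, start_day = 1) {
  assert_that(reps >= 1, "reps must be >= 1")
  assert_that(window[1] >= 1 && window[2] <= max(forcing$day),
              "window not covered by forcing")
  len <- window[2] - window[1] + 1
  assert_that(len %% 365 == 0, "window must span whole 365-day years")
  block <- forcing[forcing$day >= window[1] & forcing$day <= window[2], ]
  out <- dplyr::bind_rows(rep(list(block), reps))
  out$day <- start_day + seq_len(nrow(out)) - 1
  out$doy <- doy365(out$day)
  out
}

#' Scale the external phosphorus load of a forcing series
#'
#' Multiplies the inorganic (PO4) and organic P inlet concentrations by
#' `multiplier`; discharge, nitrogen and meteorology are untouched, so the
#' areal external P load scales exactly linearly.
#'
#' @param forcing Daily forcing tibble.
#' @param multiplier Positive load multiplier.
#' @return Forcing with scaled `c_po4`, `c_orgp`.
#' @export
apply_p_multiplier <- function(forcing, multiplier) {
  assert_that(multiplier > 0, "multiplier must be positive")
  forcing$c_po4 <- forcing$c_po4 * multiplier
  forcing$c_orgp <- forcing$c_orgp * multiplier
  forcing
}

#' Specify one bifurcation scenario
#'
#' @param branch `"turbid"` (oligo-/eutrophication from the turbid
#'   baseline state) or `"clear"` (from an established clear-water state).
#' @param multiplier P-load multiplier for the scenario period.
#' @param baseline_window Day range of the baseline period to loop.
#' @param reps Number of baseline repetitions in the scenario period
#'   (default 12: a 5-yr baseline becomes 60 yr).
#' @param establishment_years Years of -98% load inserted before the
#'   scenario to establish the clear state (clear branch only).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(branch = c("turbid", "clear"), multiplier = 1,
                          baseline_window, reps = 12,
                          establishment_years = if (branch == "clear") 20 else 0) {
  branch <- match.arg(branch)
  assert_that(multiplier > 0, "multiplier must be positive")
  assert_that(reps >= 1, "reps must be >= 1")
  if (branch == "turbid")
    assert_that(establishment_years == 0,
                "turbid branch takes no establishment period")
  structure(list(branch = branch, multiplier = multiplier,
                 baseline_window = baseline_window, reps = reps,
                 establishment_years = establishment_years),
            class = "scenario_spec")
}

#' Assemble the full forcing series for one scenario
#'
#' Turbid branch: history (through the baseline window) followed by the
#' looped, multiplied scenario period. Clear branch: the same with an
#' establishment segment (the baseline looped at the -98% multiplier)
#' inserted between history and scenario.
#'
#' @param history Daily forcing covering warm-up through the baseline
#'   window.
#' @param spec A [scenario_spec()].
#' @return Daily forcing tibble for the whole run.
#' @export
build_branch_forcing <- function(history, spec) {
  hist_part <- history[history$day <= spec$baseline_window[2], ]
  parts <- list(hist_part)
  next_day <- nrow(hist_part) + 1
  if (spec$establishment_years > 0) {
    wlen_yr <- (spec$baseline_window[2] - spec$baseline_window[1] + 1) / 365
    est_reps <- ceiling(spec$establishment_years / wlen_yr)
    est <- loop_baseline(history, spec$baseline_window, est_reps,
                         start_day = next_day)
    est <- est[seq_len(spec$establishment_years * 365), ]
    parts <- c(parts, list(apply_p_multiplier(est, 0.02)))
    next_day <- next_day + nrow(est)
  }
  scen <- loop_baseline(history, spec$baseline_window, spec$reps,
                        start_day = next_day)
  parts <- c(parts, list(apply_p_multiplier(scen, spec$multiplier)))
  dplyr::bind_rows(parts)
}

#' Extract a load-response point from a finished run
#'
#' Summer (1 May - 30 September) means of the diagnostics over the final
#' `last_years` years, the mean areal external P load over the same
#' window, and the macrophyte depth limit from the mean August coverage
#' profile at the 0.1% threshold. A stabilisation diagnostic (relative
#' change of the summer means between the last two `last_years` blocks)
#' is attached; a large value warns that the run is still drifting.
#'
#' @param run A `lake_run` made with `keep_layers` including `"cover"`.
#' @param spec Optional [scenario_spec()]; its branch and multiplier are
#'   carried into the output.
#' @param last_years Averaging window (default 5).
#' @param threshold Coverage threshold (%) for the depth limit.
#' @return One-row tibble: branch, multiplier, `load_p_mg_m2_d`, summer
#'   means of the main diagnostics, `depth_limit_aug_m`, `stab_rel_change`.
#' @export
run_and_extract <- function(run, spec = NULL, last_years = 5, threshold = 0.1) {
  nd <- nrow(run$daily)
  assert_that(nd >= last_years * 365, "run shorter than the averaging window")
  d <- run$daily
  win <- function(years_back_hi, years_back_lo) {
    d[d$day > max(d$day) - years_back_hi * 365 &
        d$day <= max(d$day) - years_back_lo * 365, ]
  }
  block <- win(last_years, 0)
  summer <- block[SUMMER_DOY(block$doy), ]
  vars <- c("chl", "tp", "tn", "po4", "no3", "nh4", "o2_surf", "dia", "cya",
            "oth", "zoo", "fish_jv", "fish_ad", "fish_pi", "benthos",
            "veg_gm2", "cover", "secchi")
  sm <- lapply(summer[vars], mean)
  load <- mean(block$load_p_mg_m2)
  # August mean per-layer coverage profile -> depth limit
  depth_limit <- NA_real_
  if ("cover" %in% names(run$layers)) {
    aug <- block$doy >= 213 & block$doy <= 243
    prof <- colMeans(run$layers$cover[block$day[aug], , drop = FALSE])
    ok <- which(prof >= threshold)
    depth_limit <- if (length(ok))
      run$grid$max_depth - run$grid$interfaces[min(ok)] else 0
  }
  # stabilisation: previous block vs final block summer means
  stab <- NA_real_
  if (nd >= 2 * last_years * 365) {
    prev <- win(2 * last_years, last_years)
    prev_sm <- vapply(prev[SUMMER_DOY(prev$doy), vars], mean, numeric(1))
    cur_sm <- unlist(sm)
    rel <- abs(cur_sm - prev_sm) / pmax(abs(prev_sm), 1e-6)
    stab <- max(rel[c("chl", "tp", "cover")])
  }
  tibble::tibble(
    branch = spec$branch %||% NA_character_,
    multiplier = spec$multiplier %||% NA_real_,
    load_p_mg_m2_d = load,
    !!!sm,
    depth_limit_aug_m = depth_limit,
    stab_rel_change = stab)
}

#' Run a full bifurcation experiment
#'
#' For every multiplier and branch, assembles the scenario forcing
#' ([build_branch_forcing()]), runs the model from the matching initial
#' state, and extracts a load-response point. With the default 75-point
#' grid and both branches this is the 150-run experiment; smaller grids
#' give the desk-scale version.
#'
#' @param grid A `lake_grid`.
#' @param params A `param_set`.
#' @param history Daily forcing through the baseline window.
#' @param baseline_window Day range `c(first, last)` of the baseline.
#' @param multipliers Multiplier vector (default [multiplier_grid()]).
#' @param branches Character subset of `c("turbid", "clear")`.
#' @param reps Baseline repetitions per scenario.
#' @param establishment_years Clear-branch establishment length.
#' @param last_years Extraction window.
#' @param init Initial state: a single `"turbid"`/`"clear"`, or a named
#'   vector giving one per branch (e.g. `c(turbid = "turbid",
#'   clear = "clear")`) for desk-scale runs that shorten the
#'   establishment period by starting the eutrophication branch from an
#'   already clear state.
#' @param progress Print one line per run.
#' @return Tibble of load-response points (one row per branch x
#'   multiplier), of class `load_response`.
#' @export
run_bifurcation <- function(grid, params, history, baseline_window,
                            multipliers = multiplier_grid(),
                            branches = c("turbid", "clear"),
                            reps = 12, establishment_years = 20,
                            last_years = 5, init = "turbid",
                            progress = FALSE) {
  rows <- list()
  for (branch in branches) {
    for (m in multipliers) {
      sp <- scenario_spec(branch, m, baseline_window, reps,
                          if (branch == "clear") establishment_years else 0)
      frc <- build_branch_forcing(history, sp)
      init_b <- if (length(init) > 1) init[[branch]] else init
      run <- simulate_lake(grid, params, frc, init = init_b,
                           n_days = nrow(frc), keep_layers = "cover")
      rows[[length(rows) + 1]] <- run_and_extract(run, sp, last_years)
      if (progress)
        message(sprintf("%s x%.2f: chl %.1f cover %.1f%%", branch, m,
                        rows[[length(rows)]]$chl, rows[[length(rows)]]$cover))
    }
  }
  out <- dplyr::bind_rows(rows)
  load_response(out)
}

#' Order load-response points into curves
#'
#' Ranks points by external P load within each branch (ties broken by
#' multiplier), the form in which load-response curves are plotted.
#'
#' @param points Tibble of points from [run_and_extract()].
#' @return The points sorted, classed `load_response`.
#' @export
load_response <- function(points) {
  assert_that(all(points$load_p_mg_m2_d >= 0), "loads must be non-negative")
  out <- dplyr::arrange(points, .data$branch, .data$load_p_mg_m2_d,
                        .data$multiplier)
  class(out) <- unique(c("load_response", class(out)))
  out
}

#' Detect the hysteresis load range between two branches
#'
#' The largest contiguous run of shared load-grid points where the two
#' branches disagree by more than `rel_tol` relatively,
#' `|oligo - eutro| / max(|eutro|, eps) > rel_tol`, for the chosen
#' variable (chlorophyll a by default). Points are matched by multiplier;
#' the returned interval is in load units (mg P m^-2 d^-1).
#'
#' @param curves A `load_response` tibble containing both branches.
#' @param variable Response variable to compare.
#' @param rel_tol Relative disagreement threshold (default 0.2).
#' @param eps Floor for the relative denominator.
#' @return Tibble with zero rows (no hysteresis) or one row
#'   (`load_low`, `load_high`, `n_points`, `max_rel_diff`).
#' @export
hysteresis_range <- function(curves, variable = "chl", rel_tol = 0.2,
                             eps = 1e-6) {
  br <- split(curves, curves$branch)
  assert_that(length(br) == 2, "curves must contain exactly two branches")
  a <- br[[1]][order(br[[1]]$multiplier), ]
  b <- br[[2]][order(br[[2]]$multiplier), ]
  assert_that(nrow(a) == nrow(b) && all(abs(a$multiplier - b$multiplier) < 1e-9),
              "branches must share the multiplier grid")
  va <- a[[variable]]; vb <- b[[variable]]
  load <- (a$load_p_mg_m2_d + b$load_p_mg_m2_d) / 2
  diff_rel <- abs(va - vb) / pmax(abs(vb), eps)
  hit <- diff_rel > rel_tol
  if (!any(hit)) {
    return(tibble::tibble(load_low = numeric(0), load_high = numeric(0),
                          n_points = integer(0), max_rel_diff = numeric(0)))
  }
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ii <- which(r$values)
  best <- ii[which.max(r$lengths[ii])]
  seg <- starts[best]:ends[best]
  tibble::tibble(load_low = min(load[seg]), load_high = max(load[seg]),
                 n_points = length(seg), max_rel_diff = max(diff_rel[seg]))
}
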