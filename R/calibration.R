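# model-observation comparison, DE optimiser, stepwise calibration ------------

#' Depth-matched model counterparts of pooled observations
#'
#' Field samples are pooled from the surface down to a sampling depth; the
#' simulated counterpart is the volume-weighted mean of the variable over
#' the layers intersecting that depth range, at the nearest daily output.
#' Observations outside the simulated window are dropped (with their count
#' reported as an attribute).
#'
#' @param run A `lake_run` whose `keep_layers` covered the observed
#'   variables.
#' @param obs An `observation_set` (tibble with `variable`, `day`,
#'   `sample_depth_m`, `value`).
#' @return The observation tibble with a `sim` column appended; rows
#'   outside the run are removed, their number in attribute `n_skipped`.
#' @export
depth_matched_extract <- function(run, obs) {
  n_days <- nrow(run$daily)
  inside <- obs$day >= 1 & obs$day <= n_days
  out <- obs[inside, ]
  missing_v <- setdiff(unique(out$variable), names(run$layers))
  assert_that(length(missing_v) == 0,
              paste("run lacks per-layer series for:",
                    paste(missing_v, collapse = ", ")))
  out$sim <- vapply(seq_len(nrow(out)), function(i) {
    pooled_layer_mean(run$layers[[out$variable[i]]][out$day[i], ], run$grid,
                      out$sample_depth_m[i])
  }, numeric(1))
  attr(out, "n_skipped") <- sum(!inside)
  out
}

#' Goodness-of-fit metrics
#'
#' The standard hydro-ecological model evaluation set: coefficient of
#' determination (squared Pearson correlation), mean absolute relative
#' error `MARE = mean(|S - O| / |O|)` over pairs with non-zero
#' observations, relative error `RE = sum(|S - O|) / sum(|O|)`, root mean
#' square error, and percentage bias `100 * sum(S - O) / sum(O)`. MARE is
#' inflated by near-zero observations while RE is not, so seasonally
#' depleted variables (e.g. nitrate) can show MARE far above RE.
#'
#' @param sim,obs Paired simulated and observed values (n >= 2).
#' @return Tibble with `r2`, `mare`, `re`, `rmse`, `bias`, `n`.
#' @export
fit_metrics <- function(sim, obs) {
  assert_that(length(sim) == length(obs) && length(sim) >= 2,
              "need at least 2 paired values")
  ok <- is.finite(sim) & is.finite(obs)
  sim <- sim[ok]; obs <- obs[ok]
  nz <- obs != 0
  denom <- sum(abs(obs))
  tibble::tibble(
    r2 = if (stats::sd(sim) > 0 && stats::sd(obs) > 0)
      stats::cor(sim, obs)^2 else NA_real_,
    mare = if (any(nz)) mean(abs(sim[nz] - obs[nz]) / abs(obs[nz])) else NA_real_,
    re = if (denom > 0) sum(abs(sim - obs)) / denom else NA_real_,
    rmse = sqrt(mean((sim - obs)^2)),
    bias = if (sum(obs) != 0) 100 * sum(sim - obs) / sum(obs) else NA_real_,
    n = length(sim))
}

#' Profiled Gaussian log-likelihood objective
#'
#' Per-variable iid Gaussian log-likelihood with the variance profiled
#' out, `-(n/2) * log(sum((S - O)^2) / n)`, summed over variables with
#' equal weights; higher is better. A zero-residual fit is capped.
#'
#' @param matched Tibble from [depth_matched_extract()] (columns
#'   `variable`, `value`, `sim`), or a list of such.
#' @param cap Cap applied to each per-variable term.
#' @return Scalar objective (higher is better).
#' @export
log_likelihood <- function(matched, cap = 1e6) {
  by_var <- split(matched, matched$variable)
  sum(vapply(by_var, function(d) {
    n <- nrow(d)
    if (n < 2) return(0)
    ssr <- sum((d$sim - d$value)^2)
    if (ssr <= 0) return(cap)
    min(-(n / 2) * log(ssr / n), cap)
  }, numeric(1)))
}

#' Differential evolution (DE/rand/1/bin) within bounds
#'
#' Canonical Storn-Price differential evolution maximising `fn` over a
#' box: mutation `a + f * (b - c)` with reflection at the bounds, binomial
#' crossover with rate `cr`, greedy selection. Deterministic for a given
#' seed; every candidate stays within bounds; the best objective is
#' non-decreasing over generations. Candidates with non-finite objective
#' are rejected.
#'
#' @param fn Objective function of a numeric vector; higher is better.
#' @param lower,upper Finite bound vectors.
#' @param pop_size Population size (>= 4; default `10 * dimension`).
#' @param f_weight Differential weight (default 0.5).
#' @param cr Crossover rate (default 0.9).
#' @param generations Number of generations.
#' @param seed RNG seed.
#' @param init Optional matrix of initial population rows.
#' @return List: `par` (best vector), `value`, `population`, `objectives`,
#'   `trace` (best objective per generation), `n_eval`.
#' @export
differential_evolution <- function(fn, lower, upper, pop_size = NULL,
                                   f_weight = 0.5, cr = 0.9,
                                   generations = 50, seed = 1, init = NULL) {
  d <- length(lower)
  assert_that(length(upper) == d && all(is.finite(c(lower, upper))) &&
                all(upper >= lower), "bounds must be finite with upper >= lower")
  pop_size <- pop_size %||% max(4L, 10L * d)
  assert_that(pop_size >= 4, "pop_size must be >= 4")
  span <- upper - lower
  with_seed(seed, {
    pop <- matrix(stats::runif(pop_size * d), pop_size, d)
    pop <- sweep(sweep(pop, 2, span, "*"), 2, lower, "+")
    if (!is.null(init)) {
      ni <- min(nrow(init), pop_size)
      pop[seq_len(ni), ] <- init[seq_len(ni), , drop = FALSE]
    }
    obj <- apply(pop, 1, fn)
    obj[!is.finite(obj)] <- -Inf
    n_eval <- pop_size
    trace <- numeric(generations)
    for (gen in seq_len(generations)) {
      for (i in seq_len(pop_size)) {
        idx <- sample(setdiff(seq_len(pop_size), i), 3)
        mut <- pop[idx[1], ] + f_weight * (pop[idx[2], ] - pop[idx[3], ])
        # reflect into the box
        mut <- ifelse(mut < lower, 2 * lower - mut, mut)
        mut <- ifelse(mut > upper, 2 * upper - mut, mut)
        mut <- clamp(mut, lower, upper)
        cross <- stats::runif(d) < cr
        cross[sample.int(d, 1)] <- TRUE
        trial <- ifelse(cross, mut, pop[i, ])
        v <- fn(trial)
        n_eval <- n_eval + 1
        if (is.finite(v) && v >= obj[i]) {
          pop[i, ] <- trial
          obj[i] <- v
        }
      }
      trace[gen] <- max(obj)
    }
  })
  best <- which.max(obj)
  list(par = pop[best, ], value = obj[best], population = pop,
       objectives = obj, trace = trace, n_eval = n_eval)
}

#' Narrow parameter ranges from a DE population
#'
#' New bounds are the envelope of the top `keep_frac` of vectors by
#' objective, expanded symmetrically by `expand_frac` of that envelope's
#' span and clipped to the old bounds, so the new range is always inside
#' the old one. A degenerate (single-point) envelope is expanded by
#' `expand_frac` of the old span instead.
#'
#' @param population Matrix of candidate vectors (rows).
#' @param objectives Objective per row (higher better).
#' @param lower,upper Old bounds.
#' @param keep_frac Fraction of the population kept (default 0.1).
#' @param expand_frac Symmetric expansion fraction (default 0.1).
#' @return List with `lower`, `upper`.
#' @export
narrow_ranges <- function(population, objectives, lower, upper,
                          keep_frac = 0.1, expand_frac = 0.1) {
  assert_that(keep_frac > 0 && keep_frac <= 1, "keep_frac must be in (0,1]")
  n_keep <- max(1L, ceiling(keep_frac * nrow(population)))
  top <- population[order(objectives, decreasing = TRUE)[seq_len(n_keep)], ,
                    drop = FALSE]
  lo <- apply(top, 2, min); hi <- apply(top, 2, max)
  span <- hi - lo
  degenerate <- span <= 0
  span[degenerate] <- (upper - lower)[degenerate]
  lo <- pmax(lo - expand_frac * span, lower)
  hi <- pmin(hi + expand_frac * span, upper)
  list(lower = lo, upper = hi)
}

#' Define one calibration step
#'
#' @param name Step label (e.g. "physical processes").
#' @param variables Observed variables compared in this step.
#' @param parameters Names of the parameters searched.
#' @param pop_size,generations DE budget for the step
#'   (evaluations = pop_size * (generations + 1)).
#' @return A `calibration_step` list.
#' @export
calibration_step <- function(name, variables, parameters, pop_size = 10,
                             generations = 20) {
  structure(list(name = name, variables = variables, parameters = parameters,
                 pop_size = pop_size, generations = generations),
            class = "calibration_step")
}

#' Seven-step calibration schedule
#'
#' The default bottom-up schedule: physics against temperature, then
#' mineralisation against dissolved oxygen, nitrogen processes, phosphorus
#' interactions, plankton dynamics, macrophytes, and a final combined
#' refinement of the nutrient and plankton steps. Each step narrows the
#' ranges of its parameters before the next step runs.
#'
#' @param pop_size,generations Per-step DE budget.
#' @return List of [calibration_step()]s.
#' @export
default_calibration_steps <- function(pop_size = 10, generations = 20) {
  cs <- function(...) calibration_step(..., pop_size = pop_size,
                                       generations = generations)
  list(
    cs("physical processes", "temp", c("tau_temp", "c_swr")),
    cs("mineralisation", "o2", c("k_min_dom", "k_min_sed", "theta_min")),
    cs("denitrification and nitrification", c("no3", "nh4", "tn"),
       c("k_nit_w", "k_nit_sed", "k_den_sed")),
    cs("P interactions in water column and sediment", c("po4", "tp"),
       c("k_dif", "k_sorp", "q_ads_max")),
    cs("phyto- and zooplankton seasonal trends", c("chl", "zoo"),
       c("mu_max_dia", "zoo_fmax", "settle_dia")),
    cs("macrophyte dynamics", "cover", c("veg_pmax", "veg_hpar")),
    cs("all nutrient and plankton dynamics",
       c("o2", "no3", "nh4", "po4", "tp", "chl", "zoo"),
       c("k_min_dom", "k_nit_w", "k_dif", "mu_max_dia", "zoo_fmax"))
  )
}

#' Stepwise differential-evolution calibration
#'
#' Runs the stepwise procedure: for each step, a DE search over that
#' step's parameters (within their current, possibly already narrowed
#' ranges) against the step's target variables; the best values are
#' carried forward and the ranges narrowed ([narrow_ranges()]) for any
#' later step touching the same parameters.
#'
#' @param runner Function `params -> lake_run` producing per-layer series
#'   for every observed variable.
#' @param steps List of [calibration_step()]s.
#' @param obs An `observation_set`.
#' @param params Starting `param_set` (bounds = global search space).
#' @param seed Seed; each step uses a derived sub-seed.
#' @param keep_frac,expand_frac Passed to [narrow_ranges()].
#' @return List of class `calibration_result`: `params` (final),
#'   `steps` (per-step tibble: name, best objective, evaluations),
#'   `metrics` (per-variable [fit_metrics()] of the final fit),
#'   `objective` (final).
#' @export
stepwise_calibrate <- function(runner, steps, obs, params, seed = 1,
                               keep_frac = 0.1, expand_frac = 0.1) {
  bad <- setdiff(unlist(lapply(steps, `[[`, "parameters")), params$name)
  assert_that(length(bad) == 0,
              paste("steps reference unknown parameters:",
                    paste(bad, collapse = ", ")))
  step_rows <- list()
  for (si in seq_along(steps)) {
    st <- steps[[si]]
    missing_v <- setdiff(st$variables, unique(obs$variable))
    assert_that(length(missing_v) == 0,
                paste("observations lack variables:",
                      paste(missing_v, collapse = ", ")))
    i <- match(st$parameters, params$name)
    lo <- params$lower[i]; hi <- params$upper[i]
    obs_s <- obs[obs$variable %in% st$variables, ]
    objective <- function(x) {
      pp <- param_update(params, stats::setNames(x, st$parameters))
      run <- runner(pp)
      log_likelihood(depth_matched_extract(run, obs_s))
    }
    de <- differential_evolution(objective, lo, hi,
                                 pop_size = st$pop_size,
                                 generations = st$generations,
                                 seed = seed + si,
                                 init = rbind(params$value[i]))
    params <- param_update(params, stats::setNames(de$par, st$parameters))
    nr <- narrow_ranges(de$population, de$objectives, lo, hi,
                        keep_frac, expand_frac)
    params$lower[i] <- nr$lower
    params$upper[i] <- nr$upper
    step_rows[[si]] <- tibble::tibble(
      step = si, name = st$name, best_objective = de$value,
      n_eval = de$n_eval,
      parameters = paste(st$parameters, collapse = ","))
  }
  final_run <- runner(params)
  matched <- depth_matched_extract(final_run, obs)
  metrics <- matched |>
    dplyr::group_by(.data$variable) |>
    dplyr::reframe(fit_metrics(.data$sim, .data$value))
  structure(list(params = params,
                 steps = dplyr::bind_rows(step_rows),
                 metrics = metrics,
                 objective = log_likelihood(matched)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d steps, final objective %.2f\n",
              nrow(x$steps), x$objective))
  print(x$steps)
  invisible(x)
}

#' @describeIn stepwise_calibrate Per-variable fit metrics of the final fit.
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @export
tidy.calibration_result <- function(x, ...) x$metrics

#' @describeIn stepwise_calibrate One-row summary.
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(n_steps = nrow(x$steps),
                 objective = x$objective,
                 n_eval = sum(x$steps$n_eval))
}

#' Calibration schedule for the twin experiment
#'
#' Four steps over the eight twin parameters, bottom-up and then
#' combined, mirroring the full procedure's final refinement: physics
#' against temperature and oxygen; mineralisation and sediment exchange
#' against oxygen, nutrients and detritus; plankton dynamics against
#' chlorophyll, zooplankton, phosphate and detritus; finally all eight
#' parameters against every observed variable, because the early
#' nutrient steps run while the plankton parameters are still wrong and
#' need a combined polish. The budgets (120 + 120 + 240 + 520 model
#' runs) total 1000 evaluations.
#'
#' @return List of [calibration_step()]s.
#' @export
twin_calibration_steps <- function() {
  all_p <- c("tau_temp", "c_swr", "k_min_dom", "k_dif",
             "mu_max_dia", "zoo_fmax", "zoo_resp", "settle_dia")
  list(
    calibration_step("physical processes", c("temp", "o2"),
                     c("tau_temp", "c_swr"),
                     pop_size = 8, generations = 14),
    calibration_step("mineralisation and sediment exchange",
                     c("o2", "nh4", "no3", "po4", "tp", "pom"),
                     c("k_min_dom", "k_dif"),
                     pop_size = 12, generations = 9),
    calibration_step("plankton dynamics", c("chl", "zoo", "po4", "pom"),
                     c("mu_max_dia", "zoo_fmax", "zoo_resp", "settle_dia"),
                     pop_size = 16, generations = 14),
    calibration_step("all nutrient and plankton dynamics",
                     c("temp", "o2", "chl", "no3", "nh4", "po4", "tn", "tp",
                       "pom", "zoo"),
                     all_p, pop_size = 20, generations = 25)
  )
}
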