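# delimited readers/writers for the forcing and observation formats ----------

MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# canonical day -> "YYYY-MM-DD" (365-day calendar, no leap days)
day_to_iso <- function(day, origin_year = 1990) {
  doy <- doy365(floor(day))
  yr <- origin_year + (floor(day) - 1) %/% 365
  cum <- cumsum(c(0, MONTH_DAYS))
  mo <- findInterval(doy - 1e-9, cum)
  dd <- doy - cum[mo]
  sprintf("%04d-%02d-%02d", yr, mo, dd)
}

# "YYYY-MM-DD" -> canonical day (29 February mapped onto 28 February)
iso_to_day <- function(x, origin_year = 1990) {
  yr <- as.integer(substr(x, 1, 4))
  mo <- as.integer(substr(x, 6, 7))
  dd <- pmin(as.integer(substr(x, 9, 10)), MONTH_DAYS[as.integer(substr(x, 6, 7))])
  cum <- cumsum(c(0, MONTH_DAYS))
  (yr - origin_year) * 365 + cum[mo] + dd
}

read_delim_any <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

ensure_day <- function(d, origin_year = 1990) {
  if (!"day" %in% names(d)) {
    assert_that("time" %in% names(d), "file needs a 'day' or ISO 'time' column")
    d$day <- iso_to_day(as.character(d$time), origin_year)
  }
  d
}

#' Read and write forcing and observation files
#'
#' All formats are tab-delimited text with a header. Time is carried both
#' as the canonical day number (`day`, 365-day years) and an ISO-8601
#' date (`time`); readers accept either. Meteorology: `air_temp`,
#' `pressure`, `dewpoint`, `cloud`, `wind_u`, `wind_v`. Inflow (one row
#' per inlet and month): `inlet`, `discharge_m3s`, `nh4`, `no3`, `po4`,
#' `orgn`, `orgp`. Observations: `variable`, `sample_depth_m`, `value`,
#' `error_fraction`.
#'
#' @param path File path.
#' @param origin_year Year of canonical day 1.
#' @return The corresponding tibble.
#' @export
read_meteo <- function(path, origin_year = 1990) {
  d <- ensure_day(read_delim_any(path), origin_year)
  need <- c("air_temp", "cloud", "wind_u", "wind_v")
  assert_that(all(need %in% names(d)),
              paste("meteo file needs columns:", paste(need, collapse = ", ")))
  d$doy <- doy365(d$day)
  d
}

#' @param meteo,inflow,obs Tibbles to write.
#' @rdname read_meteo
#' @export
write_meteo <- function(meteo, path, origin_year = 1990) {
  meteo$time <- day_to_iso(meteo$day, origin_year)
  readr::write_tsv(meteo, path)
  invisible(path)
}

#' @rdname read_meteo
#' @export
read_inflow <- function(path, origin_year = 1990) {
  d <- ensure_day(read_delim_any(path), origin_year)
  need <- c("inlet", "discharge_m3s", "nh4", "no3", "po4", "orgn", "orgp")
  assert_that(all(need %in% names(d)),
              paste("inflow file needs columns:", paste(need, collapse = ", ")))
  if (!"month" %in% names(d)) d$month <- (d$day - 1) %/% 30 + 1
  d
}

#' @rdname read_meteo
#' @export
write_inflow <- function(inflow, path, origin_year = 1990) {
  inflow$time <- day_to_iso(inflow$day, origin_year)
  readr::write_tsv(inflow, path)
  invisible(path)
}

#' @rdname read_meteo
#' @export
read_observations <- function(path, origin_year = 1990) {
  d <- ensure_day(read_delim_any(path), origin_year)
  need <- c("variable", "sample_depth_m", "value", "error_fraction")
  assert_that(all(need %in% names(d)),
              paste("observation file needs columns:",
                    paste(need, collapse = ", ")))
  assert_that(all(d$value >= 0, na.rm = TRUE), "observed values must be >= 0")
  assert_that(all(d$error_fraction > 0 & d$error_fraction < 1),
              "error_fraction must be in (0,1)")
  class(d) <- c("observation_set", class(d))
  d
}

#' @rdname read_meteo
#' @export
write_observations <- function(obs, path, origin_year = 1990) {
  obs$time <- day_to_iso(obs$day, origin_year)
  readr::write_tsv(tibble::as_tibble(obs), path)
  invisible(path)
}

#' @rdname read_meteo
#' @export
write_daily <- function(run, path) {
  readr::write_tsv(run$daily, path)
  invisible(path)
}
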