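#' Construct a hypsograph
#'
#' A hypsograph is the relationship between lake level (metres above the
#' deepest point) and the horizontal surface area enclosed at that level.
#' It defines the morphometry from which the vertical grid derives layer
#' volumes and the benthic (sediment-contact) area of each layer.
#'
#' @param level_m Numeric vector of levels in metres above the deepest
#'   point; strictly increasing, first element 0.
#' @param area_m2 Numeric vector of horizontal areas (m^2) at each level;
#'   non-negative and non-decreasing.
#'
#' @return A tibble of class `hypsograph` with columns `level_m`, `area_m2`.
#' @examples
#' hyp <- hypsograph(c(0, 1.3, 2.6), c(0, 4.5e5, 9.1e5))
#' lake_volume(hyp)
#' @export
hypsograph <- function(level_m, area_m2) {
  assert_that(length(level_m) == length(area_m2),
              "level_m and area_m2 must have equal length")
  assert_that(length(level_m) >= 2, "a hypsograph needs at least 2 points")
  assert_that(all(is.finite(level_m)) && all(is.finite(area_m2)),
              "hypsograph values must be finite")
  assert_that(all(diff(level_m) > 0), "levels must be strictly increasing")
  assert_that(level_m[1] == 0, "first level must be 0 (the deepest point)")
  assert_that(all(area_m2 >= 0), "areas must be non-negative")
  assert_that(all(diff(area_m2) >= 0), "areas must be non-decreasing with level")
  out <- tibble::tibble(level_m = as.numeric(level_m),
                        area_m2 = as.numeric(area_m2))
  class(out) <- c("hypsograph", class(out))
  out
}

#' @export
print.hypsograph <- function(x, ...) {
  cat(sprintf("<hypsograph> %d levels, max depth %.2f m, surface area %.3g m^2\n",
              nrow(x), max(x$level_m), max(x$area_m2)))
  NextMethod()
}

# piecewise-linear area at arbitrary levels
hyps_area_at <- function(hyps, z) {
  stats::approx(hyps$level_m, hyps$area_m2, xout = z, rule = 2)$y
}

# exact integral of the piecewise-linear area function from 0 to z
hyps_volume_to <- function(hyps, z) {
  vapply(z, function(zz) {
    brk <- sort(unique(c(hyps$level_m[hyps$level_m < zz], zz)))
    brk <- c(brk[brk >= 0])
    if (length(brk) < 2) brk <- c(0, zz)
    a <- hyps_area_at(hyps, brk)
    sum(diff(brk) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)
  }, numeric(1))
}

#' Total lake volume implied by a hypsograph
#'
#' Trapezoidal (exact for the piecewise-linear hypsograph) integral of area
#' over level from the deepest point to the surface.
#'
#' @param hyps A [hypsograph()].
#' @return Volume in m^3.
#' @export
lake_volume <- function(hyps) {
  hyps_volume_to(hyps, max(hyps$level_m))
}

#' Read / write a hypsograph file
#'
#' Plain two-column delimited text with a header line (`level_m`, `area_m2`).
#'
#' @param path File path.
#' @return `read_hypsograph()` returns a [hypsograph()].
#' @export
read_hypsograph <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_double()),
                       progress = FALSE)
  assert_that(all(c("level_m", "area_m2") %in% names(d)),
              "hypsograph file needs columns level_m, area_m2")
  hypsograph(d$level_m, d$area_m2)
}

#' @param hyps A [hypsograph()] to write.
#' @rdname read_hypsograph
#' @export
write_hypsograph <- function(hyps, path) {
  readr::write_tsv(tibble::as_tibble(hyps)[c("level_m", "area_m2")], path)
  invisible(path)
}

#' Box (0D) morphometry
#'
#' A flat-bottomed, vertical-walled basin with the given surface area and
#' depth. With `build_grid(hypsograph_box(A, z), 1, 0)` this is the fully
#' mixed box configuration: one layer of the lake's mean depth whose
#' benthic area equals the surface area, the classical 0D counterpart of
#' the depth-resolved setup.
#'
#' @param surface_area_m2 Surface (= bottom) area.
#' @param depth_m Box depth (use the lake's mean depth for volume
#'   equivalence).
#' @return A [hypsograph()].
#' @export
hypsograph_box <- function(surface_area_m2, depth_m) {
  hypsograph(c(0, depth_m), c(surface_area_m2, surface_area_m2))
}
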