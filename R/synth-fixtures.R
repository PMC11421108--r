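#' Generate a reference monthly presence series
#'
#' Smooth sinusoidal annual cycle of percent-of-days presence with stated
#' extrema, standing in for an empirical seasonal curve at a fixed
#' listening station. The southern-station defaults anchor the cycle at a
#' 59.3 percent January maximum and 31.1 percent July minimum; the northern
#' station defaults to the opposite phase (July maximum).
#'
#' @param winter_max maximum percent presence, at `peak_month`.
#' @param summer_min minimum percent presence, six months later.
#' @param station_id `"south"` or `"north"`.
#' @param peak_month month (1--12) of the maximum.
#' @return data.frame with `station_id`, `month`, `mean_percent_present`.
#' @export
gen_reference_series <- function(winter_max = 59.3, summer_min = 31.1,
                                 station_id = c("south", "north"),
                                 peak_month = if (match.arg(station_id) == "south") 1L else 7L) {
  station_id <- match.arg(station_id)
  .assert(is.numeric(winter_max) && is.numeric(summer_min),
          "extrema must be numeric")
  .assert(summer_min >= 0 && winter_max <= 100 && summer_min <= winter_max,
          "require 0 <= summer_min <= winter_max <= 100")
  .assert(peak_month %in% 1:12, "peak_month must be in 1..12")
  month <- 1:12
  mid <- (winter_max + summer_min) / 2
  amp <- (winter_max - summer_min) / 2
  vals <- mid + amp * cos(2 * pi * (month - peak_month) / 12)
  data.frame(station_id = station_id, month = month,
             mean_percent_present = vals)
}

#' Reference monthly presence table for both stations
#'
#' Convenience wrapper returning the two-station fixture in the wide
#' 12 x 2 layout used by [rmsd()] and [compare_strategies()].
#'
#' @param south,north single-station series from [gen_reference_series()];
#'   defaults use the printed southern anchors and their mirrored northern
#'   counterpart.
#' @return data.frame with columns `month`, `south`, `north` (percent).
#' @export
reference_table <- function(south = gen_reference_series(station_id = "south"),
                            north = gen_reference_series(station_id = "north")) {
  .assert(nrow(south) == 12 && nrow(north) == 12, "series must have 12 rows")
  data.frame(month = 1:12,
             south = south$mean_percent_present[order(south$month)],
             north = north$mean_percent_present[order(north$month)])
}

#' Generate a synthetic gridded SST field
#'
#' Linear meridional temperature gradient pinned so the 18 degree C
#' isotherm sits at a chosen latitude, plus optional iid Gaussian noise.
#' Used to exercise [nptz_latitude()] with a known answer.
#'
#' @param iso18_lat latitude (deg N) of the noise-free 18 C isotherm.
#' @param meridional_gradient degrees C per degree latitude (< 0: cooler
#'   northward).
#' @param noise_sd iid noise standard deviation (deg C).
#' @param lons,lats grid coordinates; longitudes in 0--360 convention.
#' @param month month index attached to the grid.
#' @param rng_seed optional integer seed.
#' @return object of class `sst_grid`: list with `lats`, `lons`, `sst`
#'   (lat x lon matrix, deg C) and `month`.
#' @export
gen_sst_grid <- function(iso18_lat = 40, meridional_gradient = -0.5,
                         noise_sd = 0, lons = seq(180, 200, by = 1),
                         lats = seq(25, 55, by = 0.5), month = 1L,
                         rng_seed = NULL) {
  .assert(meridional_gradient < 0, "meridional_gradient must be < 0 (SST decreases northward)")
  .assert(iso18_lat >= min(lats) && iso18_lat <= max(lats),
          "iso18_lat lies outside the latitude grid")
  .assert(!is.unsorted(lats), "lats must be ascending")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sst <- outer(lats, lons, function(la, lo) 18 + meridional_gradient * (la - iso18_lat))
  if (noise_sd > 0) sst <- sst + matrix(rnorm(length(sst), 0, noise_sd), nrow(sst))
  structure(list(lats = lats, lons = lons, sst = sst, month = as.integer(month)),
            class = "sst_grid")
}

#' @export
print.sst_grid <- function(x, ...) {
  cat(sprintf("SST grid, month %d: %d lats [%.1f, %.1f] x %d lons [%.1f, %.1f], %.1f--%.1f degC\n",
              x$month, length(x$lats), min(x$lats), max(x$lats),
              length(x$lons), min(x$lons), max(x$lons),
              min(x$sst), max(x$sst)))
  invisible(x)
}
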