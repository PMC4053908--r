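# Synthetic fixed-site monitoring stations: 30-min NO2 series for one street
# and one urban background site over the weekdays of a year.

#' Generate monitoring-station NO2 time series
#'
#' Produces one weekday series of 30-min averages per station. The street
#' station sits at a road centreline (annual mean = background +
#' road increment) and follows the `main` diurnal profile; the urban
#' background station has the background annual mean and the flatter `side`
#' profile. Each 30-min value is
#' `annual_mean * profile[hour] / mean(profile) + N(0, noise_sd)`, truncated
#' at zero, so the annual weekday hourly mean of hour h divided by the
#' overall weekday mean recovers `profile[h] / mean(profile)` exactly in the
#' noiseless case.
#'
#' @param config a [scenario_config()]; uses `background_level`,
#'   `road_increment`, `diurnal_profile`, `noise_sd`, `n_weekdays`, `seed`.
#' @return named list with elements `street` and `background`, each a
#'   `station_series` data.frame (columns `date`, `hour`, `minute`, `value`)
#'   with attributes `site_type` and `annual_mean`.
#' @export
generate_station_series <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  abort_if(length(config$diurnal_profile$main) != 24L ||
             length(config$diurnal_profile$side) != 24L,
           "diurnal_profile must have 24 entries per road class")
  rng <- local_seed(config$seed, "stations")
  on.exit(rng(), add = TRUE)

  dates <- weekday_calendar(config$n_weekdays)
  make_series <- function(site_type, annual_mean, profile) {
    rel <- profile / mean(profile)
    hour <- rep(rep(0:23, each = 2L), times = length(dates))
    minute <- rep(c(0L, 30L), times = 24L * length(dates))
    mu <- annual_mean * rel[hour + 1L]
    value <- pmax(0, mu + stats::rnorm(length(mu), 0, config$noise_sd))
    structure(data.frame(date = rep(dates, each = 48L), hour = hour,
                         minute = minute, value = value),
              site_type = site_type, annual_mean = annual_mean,
              class = c("station_series", "data.frame"))
  }
  list(
    street = make_series("street",
                         config$background_level + config$road_increment,
                         config$diurnal_profile$main),
    background = make_series("background", config$background_level,
                             config$diurnal_profile$side)
  )
}

#' Sequence of n weekdays starting Monday 2010-01-04
#' @keywords internal
weekday_calendar <- function(n) {
  start <- as.Date("2010-01-04")
  days <- start + seq_len(ceiling(n * 7 / 5) + 7L) - 1L
  days <- days[!format(days, "%u") %in% c("6", "7")]
  days[seq_len(n)]
}
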