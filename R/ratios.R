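# Temporal adjustment factors: hour-of-day ratios of the annual weekday
# hourly mean to the annual weekday mean, per road class.

#' Construct a ratio table
#'
#' @param ratio_m,ratio_s 24 strictly positive dimensionless factors (hour 0
#'   first) for main and side streets.
#' @return `ratio_table` data.frame with columns `hour`, `ratio_m`,
#'   `ratio_s`.
#' @export
ratio_table <- function(ratio_m, ratio_s) {
  abort_if(length(ratio_m) != 24L || length(ratio_s) != 24L,
           "ratio tables need one entry per hour 0-23")
  abort_if(any(ratio_m <= 0) || any(ratio_s <= 0),
           "adjustment ratios must be strictly positive")
  structure(data.frame(hour = 0:23, ratio_m = as.numeric(ratio_m),
                       ratio_s = as.numeric(ratio_s)),
            class = c("ratio_table", "data.frame"))
}

#' Identity ratio table (all factors 1)
#' @export
identity_ratio_table <- function() ratio_table(rep(1, 24), rep(1, 24))

#' Hourly mean of one station series by clock hour, divided by overall mean
#' @keywords internal
hourly_ratio_one <- function(series, include_weekends = FALSE) {
  stopifnot(all(c("date", "hour", "value") %in% names(series)))
  if (!include_weekends && "date" %in% names(series)) {
    wd <- !format(as.Date(series$date), "%u") %in% c("6", "7")
    series <- series[wd, , drop = FALSE]
  }
  abort_if(nrow(series) == 0L, "station series contains no usable weekdays")
  counts <- tabulate(series$hour + 1L, nbins = 24L)
  if (any(counts == 0L)) {
    stop(sprintf("no observations for hour %d",
                 min(which(counts == 0L)) - 1L), call. = FALSE)
  }
  hm <- vapply(0:23, function(h) mean(series$value[series$hour == h]),
               numeric(1))
  hm / mean(series$value)
}

#' Derive hour-of-day adjustment factors from two monitoring stations
#'
#' For each station the 24 ratios are the annual weekday mean of each clock
#' hour divided by the overall weekday mean; the street station provides the
#' main-road factors (`ratio_m`), the urban background station the
#' side-street factors (`ratio_s`). Weekends, if present in the series, are
#' excluded from numerator and denominator unless `include_weekends` is set.
#'
#' @param street,background `station_series` data.frames (columns `date`,
#'   `hour`, `value`) for the street and urban background site.
#' @param include_weekends include weekend observations (default FALSE: the
#'   annual mean in the denominator is the weekday annual mean).
#' @return a [ratio_table()].
#' @export
#' @examples
#' s <- generate_station_series(scenario_config(noise_sd = 0, seed = 1))
#' rt <- compute_hourly_ratios(s$street, s$background)
#' round(rt$ratio_m[8 + 1], 3)  # hour-8 street factor
compute_hourly_ratios <- function(street, background,
                                  include_weekends = FALSE) {
  ratio_table(hourly_ratio_one(street, include_weekends),
              hourly_ratio_one(background, include_weekends))
}

#' Look up the temporal adjustment factor for a leg
#'
#' @param table a [ratio_table()].
#' @param road_class "main" or "side" ("unset" is an error: the leg must be
#'   classified first).
#' @param hour start hour of the leg, 0-23.
#' @return dimensionless adjustment factor.
#' @export
lookup_ratio <- function(table, road_class, hour) {
  abort_if(!is.numeric(hour) || hour < 0 || hour > 23 ||
             hour != floor(hour), "hour must be an integer in 0-23")
  if (identical(road_class, "main")) {
    table$ratio_m[hour + 1L]
  } else if (identical(road_class, "side")) {
    table$ratio_s[hour + 1L]
  } else {
    stop("road class is unset; classify the leg before applying ratios",
         call. = FALSE)
  }
}
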