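#' Daily growing degree days
#'
#' De Candolle thermal-time increment: the amount by which the daily mean
#' temperature exceeds the base development temperature, clamped at zero so
#' cold days never subtract accumulated heat.
#'
#' @param tmean Daily mean air temperature (degrees C). Vectorized.
#' @param tbase Base development temperature (degrees C). Chia develops
#'   above 10 degrees C, the default.
#' @param tceiling Optional upper cutoff (degrees C); daily mean temperatures
#'   above it are capped before the subtraction. Off (`NULL`) by default.
#' @return Daily growing degree days (degree C days), `>= 0`.
#' @examples
#' daily_gdd(15)          # 5
#' daily_gdd(8)           # 0, clamped
#' @seealso [accumulate_gdd()]
#' @export
daily_gdd <- function(tmean, tbase = 10, tceiling = NULL) {
  check_number(tmean, "tmean")
  check_number(tbase, "tbase")
  if (!is.null(tceiling)) tmean <- pmin(tmean, tceiling)
  pmax(0, tmean - tbase)
}

#' Accumulate thermal time over a weather record
#'
#' Walks a contiguous daily weather table from the sowing date onward and
#' returns the running sum of clamped daily growing degree days (accumulated
#' degree days, ADD). Day 0 of the series is the sowing day, so `add` is
#' thermal time since sowing.
#'
#' @param weather Data frame with columns `date` (Date or ISO-8601 string),
#'   `tmin`, `tmax` and optionally `tmean`. When `tmean` is absent or `NA`
#'   it defaults to `(tmin + tmax) / 2`.
#' @param tbase,tceiling Passed to [daily_gdd()].
#' @param start_date Sowing date; defaults to the first date in `weather`.
#'   Rows before it are dropped.
#' @return A data frame of class `thermal_time` with columns `date`, `das`
#'   (days after sowing, starting at 0), `daily_gdd` and `add` (cumulative
#'   degree C days).
#' @export
accumulate_gdd <- function(weather, tbase = 10, start_date = NULL,
                           tceiling = NULL) {
  weather <- validate_weather(weather)
  start_date <- as.Date(start_date %||% weather$date[1])
  weather <- weather[weather$date >= start_date, , drop = FALSE]
  if (nrow(weather) == 0L || weather$date[1] != start_date) {
    stop("weather record does not cover start_date ", format(start_date),
         call. = FALSE)
  }
  gaps <- which(diff(as.integer(weather$date)) != 1L)
  if (length(gaps)) {
    stop("gap in weather dates: first missing date is ",
         format(weather$date[gaps[1]] + 1L), call. = FALSE)
  }
  g <- daily_gdd(weather$tmean, tbase = tbase, tceiling = tceiling)
  out <- data.frame(
    date = weather$date,
    das = seq_len(nrow(weather)) - 1L,
    daily_gdd = g,
    add = cumsum(g)
  )
  class(out) <- c("thermal_time", "data.frame")
  attr(out, "tbase") <- tbase
  out
}

#' Thermal time at a (possibly fractional) day after sowing
#'
#' Linear interpolation of accumulated degree days between daily grid
#' points, used to place harvest dates and interval midpoints on the
#' thermal-time axis.
#'
#' @param series A `thermal_time` data frame from [accumulate_gdd()].
#' @param das Days after sowing, fractional allowed. Vectorized.
#' @return Accumulated degree days at `das`.
#' @export
das_to_add <- function(series, das) {
  check_columns(series, c("das", "add"), "series")
  check_number(das, "das")
  if (any(das < min(series$das)) || any(das > max(series$das))) {
    stop("das out of range [", min(series$das), ", ", max(series$das), "]",
         call. = FALSE)
  }
  stats::approx(series$das, series$add, xout = das, method = "linear")$y
}

#' Phenology stage table on the thermal axis
#'
#' Looks up accumulated degree days at the observed days-after-sowing of the
#' five phenological stages (E emergence, B branching, F flowering, G grain
#' filling, M maturity/harvest) and enforces their ordering.
#'
#' @param series A `thermal_time` data frame.
#' @param stage_das Named numeric vector mapping stage codes (a subset of
#'   `c("E","B","F","G","M")`, in that order) to days after sowing.
#' @return Data frame with columns `stage`, `das`, `add`.
#' @export
stage_table <- function(series, stage_das) {
  stages <- c("E", "B", "F", "G", "M")
  if (is.null(names(stage_das)) || !all(names(stage_das) %in% stages)) {
    stop("stage_das must be named with codes among E, B, F, G, M",
         call. = FALSE)
  }
  ord <- stages[stages %in% names(stage_das)]
  das <- unname(stage_das[ord])
  if (is.unsorted(das, strictly = TRUE)) {
    stop("stage days must be strictly increasing in the order E < B < F < G < M",
         call. = FALSE)
  }
  out <- data.frame(stage = ord, das = das, add = das_to_add(series, das))
  if (is.unsorted(out$add)) {
    # cannot happen for a valid series (add is non-decreasing) but guards
    # against hand-edited tables
    stop("accumulated degree days are not ordered across stages", call. = FALSE)
  }
  out
}

# Validate a daily weather table and fill derivable columns (tmean, and for
# the ETo side ea from rh_mean). Shared by thermal and ETo modules.
validate_weather <- function(weather) {
  check_columns(weather, c("date", "tmin", "tmax"), "weather")
  weather <- as.data.frame(weather)
  weather$date <- as.Date(weather$date)
  if (anyNA(weather$date)) stop("unparseable weather dates", call. = FALSE)
  weather <- weather[order(weather$date), , drop = FALSE]
  rownames(weather) <- NULL
  check_number(weather$tmin, "tmin")
  check_number(weather$tmax, "tmax")
  if (any(weather$tmin > weather$tmax)) {
    stop("tmin > tmax in weather record", call. = FALSE)
  }
  if (is.null(weather$tmean)) weather$tmean <- NA_real_
  miss <- is.na(weather$tmean)
  weather$tmean[miss] <- (weather$tmin[miss] + weather$tmax[miss]) / 2
  if (any(weather$tmean < weather$tmin - 1e-9) ||
      any(weather$tmean > weather$tmax + 1e-9)) {
    stop("tmean outside [tmin, tmax]", call. = FALSE)
  }
  if (!is.null(weather$rh_mean) &&
      any(!is.na(weather$rh_mean) &
            (weather$rh_mean < 0 | weather$rh_mean > 100))) {
    stop("rh_mean must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(weather$u2) && any(!is.na(weather$u2) & weather$u2 < 0)) {
    stop("u2 must be >= 0", call. = FALSE)
  }
  weather
}

#' Read a daily weather CSV
#'
#' Expected columns: `date,tmin,tmax,tmean,rh_mean,ea,u2,rn,g,pressure`
#' (ISO-8601 dates; optional columns may be empty). Only `date`, `tmin`
#' and `tmax` are mandatory.
#'
#' @param path Path to the CSV file.
#' @return Validated weather data frame.
#' @export
read_weather_csv <- function(path) {
  validate_weather(utils::read.csv(path, stringsAsFactors = FALSE))
}
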