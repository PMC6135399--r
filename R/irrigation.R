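# Deficit-irrigation scheduling by accumulated-ETo trigger. The trial
# criterion: irrigate whenever 5-10 mm of reference evapotranspiration has
# accumulated, applying that accumulation (1 mm = 1 L m-2) times the
# treatment fraction (1.0 for the fully irrigated treatment, 0.4 for the
# deficit treatment).

#' Schedule irrigation events from a daily ETo series
#'
#' Walks the series accumulating daily ETo. Each time the running sum first
#' reaches or exceeds `trigger`, an event is emitted with an applied water
#' depth of `fraction * accumulated` (L per m2, numerically mm) and the
#' accumulator resets to zero. A trailing sub-trigger accumulation emits no
#' event.
#'
#' @param eto Either a data frame with columns `date` and `eto_mm` (as
#'   returned by [eto_from_weather()]) or a numeric vector of daily ETo; in
#'   the latter case supply `dates`.
#' @param fraction Fraction of accumulated ETo demand applied, in `(0, 1]`.
#'   1.0 replaces the full demand; 0.4 is the deficit treatment.
#' @param trigger Accumulation threshold in mm, default 8 (within the 5-10
#'   mm criterion band).
#' @param dates Optional Date vector when `eto` is numeric.
#' @param clamp_negative If `TRUE` (default) negative ETo days contribute 0
#'   to the accumulator.
#' @return Data frame of class `irrigation_schedule` with columns `date`,
#'   `accumulated_eto_mm`, `applied_depth_lm2`, `fraction`. With an
#'   accumulation of exactly 8 mm, fraction 1.0 applies 8 L m-2 and
#'   fraction 0.4 applies 3.2 L m-2.
#' @export
schedule_irrigation <- function(eto, fraction, trigger = 8, dates = NULL,
                                clamp_negative = TRUE) {
  if (is.data.frame(eto)) {
    check_columns(eto, c("date", "eto_mm"), "eto")
    dates <- as.Date(eto$date)
    eto <- eto$eto_mm
  } else {
    if (is.null(dates)) dates <- seq_along(eto)
  }
  check_number(eto, "eto")
  check_number(fraction, "fraction")
  if (length(fraction) != 1L || fraction <= 0 || fraction > 1) {
    stop("fraction must be a single value in (0, 1]", call. = FALSE)
  }
  check_number(trigger, "trigger")
  if (trigger <= 0) stop("trigger must be positive", call. = FALSE)
  contrib <- if (clamp_negative) pmax(0, eto) else eto
  acc <- 0
  idx <- integer(0)
  accs <- numeric(0)
  for (i in seq_along(contrib)) {
    acc <- acc + contrib[i]
    if (acc >= trigger) {
      idx <- c(idx, i)
      accs <- c(accs, acc)
      acc <- 0
    }
  }
  out <- data.frame(
    date = dates[idx],
    accumulated_eto_mm = accs,
    applied_depth_lm2 = fraction * accs,
    fraction = rep(fraction, length(idx))
  )
  class(out) <- c("irrigation_schedule", "data.frame")
  out
}

#' Season total of applied irrigation water
#'
#' @param events An `irrigation_schedule` data frame (or anything with an
#'   `applied_depth_lm2` column).
#' @return Total applied depth in L per m2; 0 for an empty schedule.
#' @export
season_water_total <- function(events) {
  if (is.null(events) || nrow(events) == 0L) return(0)
  check_columns(events, "applied_depth_lm2", "events")
  sum(events$applied_depth_lm2)
}
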