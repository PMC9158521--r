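#' Chilling-unit models
#'
#' A chilling model maps an hourly temperature to a chilling unit (CU) in
#' `[0, 1]`. Three forms are supported, following the classical sequential
#' chilling literature:
#'
#' * `threshold`: CU = 1 when `T <= T1`, else 0.
#' * `range`: CU = 1 when `T2 <= T <= T3`, else 0.
#' * `triangular`: CU rises linearly from 0 at `Tmi = Top - half_width` to 1
#'   at the optimum `Top`, falls linearly back to 0 at
#'   `Tma = Top + half_width`, and is 0 outside `[Tmi, Tma]`.
#'
#' Boundary temperatures count as chilling (the inequalities are inclusive).
#'
#' @param kind one of `"threshold"`, `"range"`, `"triangular"`.
#' @param T1 threshold temperature, deg C (`threshold` kind).
#' @param T2,T3 range bounds, deg C, `T2 < T3` (`range` kind).
#' @param Top optimum temperature, deg C (`triangular` kind).
#' @param half_width distance from `Top` to the zero points, deg C; default 7.
#' @return A `chill_model` object.
#' @examples
#' m <- chill_model("triangular", Top = 5)
#' chill_unit(m, c(-2, 1.5, 5, 12))
#' @export
chill_model <- function(kind = c("threshold", "range", "triangular"),
                        T1 = NULL, T2 = NULL, T3 = NULL, Top = NULL,
                        half_width = 7) {
  kind <- match.arg(kind)
  m <- switch(kind,
    threshold = {
      if (is.null(T1)) stop("threshold model needs T1", call. = FALSE)
      list(kind = kind, T1 = as.numeric(T1))
    },
    range = {
      if (is.null(T2) || is.null(T3))
        stop("range model needs T2 and T3", call. = FALSE)
      if (T2 >= T3) stop("range model requires T2 < T3", call. = FALSE)
      list(kind = kind, T2 = as.numeric(T2), T3 = as.numeric(T3))
    },
    triangular = {
      if (is.null(Top)) stop("triangular model needs Top", call. = FALSE)
      if (half_width <= 0) stop("half_width must be > 0", call. = FALSE)
      list(kind = kind, Top = as.numeric(Top),
           half_width = as.numeric(half_width))
    })
  structure(m, class = "chill_model")
}

#' @export
print.chill_model <- function(x, ...) {
  desc <- switch(x$kind,
    threshold = sprintf("threshold (T1 = %g degC)", x$T1),
    range = sprintf("range (T2 = %g, T3 = %g degC)", x$T2, x$T3),
    triangular = sprintf("triangular (Top = %g degC, half-width %g)",
                         x$Top, x$half_width))
  cat("Chilling model:", desc, "\n")
  invisible(x)
}

#' Chilling unit at given temperatures
#'
#' @param model a [chill_model].
#' @param temp numeric vector of temperatures, deg C.
#' @return Numeric vector of chilling units in `[0, 1]`, same length as
#'   `temp`.
#' @export
chill_unit <- function(model, temp) {
  stopifnot(inherits(model, "chill_model"))
  temp <- as.numeric(temp)
  switch(model$kind,
    threshold = as.numeric(temp <= model$T1),
    range = as.numeric(temp >= model$T2 & temp <= model$T3),
    triangular = {
      tmi <- model$Top - model$half_width
      tma <- model$Top + model$half_width
      up <- (temp - tmi) / (model$Top - tmi)
      down <- (tma - temp) / (tma - model$Top)
      pmax(pmin(up, down, 1), 0)
    })
}

#' Accumulation window over an hourly series
#'
#' A closed window of hours, addressed by (date, hour) endpoints. Both
#' endpoints are included in any accumulation.
#'
#' @param start_date,end_date calendar dates.
#' @param start_hour,end_hour local hours 0-23; defaults span whole days
#'   (00:00 of `start_date` to 23:00 of `end_date`).
#' @return An `accum_window` object.
#' @export
accum_window <- function(start_date, end_date, start_hour = 0L,
                         end_hour = 23L) {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date > end_date ||
      (start_date == end_date && start_hour > end_hour))
    stop("window start must not be after its end", call. = FALSE)
  structure(list(start_date = start_date, start_hour = as.integer(start_hour),
                 end_date = end_date, end_hour = as.integer(end_hour)),
            class = "accum_window")
}

window_slice <- function(hs, window) {
  i0 <- hour_index(hs, window$start_date, window$start_hour)
  i1 <- hour_index(hs, window$end_date, window$end_hour)
  hs$temps[i0:i1]
}

#' Chilling accumulation over a window
#'
#' Sums the chilling unit of every hour in the closed window; each hour
#' contributes its single representative temperature.
#'
#' @param hourly an [hourly_series] covering the window.
#' @param model a [chill_model].
#' @param window an [accum_window].
#' @return Chilling accumulation (CA), in chilling units (weighted hours).
#' @export
accumulate_chill <- function(hourly, model, window) {
  sum(chill_unit(model, window_slice(hourly, window)))
}

#' Growing-degree-hour accumulation over a window
#'
#' Sums `max(T - Tb, 0)` over every hour in the closed window.
#'
#' @param hourly an [hourly_series] covering the window.
#' @param Tb base temperature, deg C (default 5).
#' @param window an [accum_window].
#' @return Accumulated growing degree hours, deg C hours.
#' @export
accumulate_gdh <- function(hourly, Tb = 5, window) {
  sum(pmax(window_slice(hourly, window) - Tb, 0))
}

#' First day of the chilling season for a date
#'
#' The phenological year runs from 1 November of the preceding calendar year
#' through the spring event. For a date in Nov/Dec the season opened on 1
#' November of that same year; for a date in Jan-Jun it opened on 1 November
#' of the previous year.
#'
#' @param date a calendar date within the phenological year.
#' @return The `Date` of the season's 1 November.
#' @export
season_start <- function(date) {
  date <- as.Date(date)
  y <- year_of(date) - ifelse(month_of(date) >= 11, 0L, 1L)
  as.Date(sprintf("%d-11-01", y))
}

#' Forcing accumulated from sampling to a chamber onset
#'
#' Computes the forcing requirement (FR) realised by a twig sampled on
#' `sample_date` and flushing in the growth chamber on `onset_date`. For
#' twigs sampled before 1 January, only chamber heat counts, from the
#' sampling date through the onset date. For twigs sampled on or after 1
#' January, outdoor growing degree hours from 00:00 on 1 January through
#' 23:00 of the day before sampling are added, so forcing already received in
#' natural conditions is included. The sampling date itself is the twig's
#' first chamber day.
#'
#' @param outdoor an [hourly_series] of outdoor temperatures covering 1
#'   January to the sampling date (only needed for post-January samples).
#' @param chamber a [chamber_profile] giving the daily chamber temperatures.
#' @param sample_date date the twig was cut and moved to the chamber.
#' @param onset_date date the spring event was observed in the chamber.
#' @param Tb base temperature, deg C.
#' @param jan1_rule if `TRUE` (default), apply the 1-January outdoor-forcing
#'   rule; if `FALSE`, count chamber heat only regardless of sampling date.
#' @return FR in deg C hours.
#' @export
forcing_to_event <- function(outdoor, chamber, sample_date, onset_date,
                             Tb = 5, jan1_rule = TRUE) {
  sample_date <- as.Date(sample_date); onset_date <- as.Date(onset_date)
  if (onset_date < sample_date)
    stop("onset precedes sampling", call. = FALSE)
  n_days <- as.integer(onset_date - sample_date) + 1L
  chamber_term <- n_days * chamber_gdh_per_day(chamber, Tb)
  jan1 <- as.Date(sprintf("%d-01-01", year_of(season_start(sample_date)) + 1L))
  outdoor_term <- 0
  if (jan1_rule && sample_date > jan1) {
    w <- accum_window(jan1, sample_date - 1L)
    outdoor_term <- accumulate_gdh(outdoor, Tb, w)
  }
  outdoor_term + chamber_term
}
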