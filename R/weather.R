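#' Daily minimum/maximum temperature series
#'
#' Construct a validated daily weather series, the sole climate input of the
#' package. A series is a data frame with one row per calendar day and columns
#' `date` (class `Date`), `tmin` and `tmax` (degrees Celsius). The span must be
#' gap-free: every day between the first and last date is present exactly once.
#'
#' @param date vector coercible to `Date`, strictly increasing, gap-free.
#' @param tmin,tmax numeric vectors of daily extremes, deg C; `tmin <= tmax`
#'   must hold row-wise.
#' @param label free-text label carried as an attribute (e.g. `"observed"`,
#'   `"rcp45"`).
#' @return A `daily_weather` data frame.
#' @examples
#' dw <- daily_weather(as.Date("2020-01-01") + 0:9, tmin = 0, tmax = 10)
#' range(dw$date)
#' @export
daily_weather <- function(date, tmin, tmax, label = "unlabelled") {
  date <- as.Date(date)
  n <- length(date)
  x <- data.frame(date = date,
                  tmin = as.numeric(rep_len(tmin, n)),
                  tmax = as.numeric(rep_len(tmax, n)))
  validate_daily_weather(x)
  attr(x, "label") <- as.character(label)[1]
  class(x) <- c("daily_weather", "data.frame")
  x
}

validate_daily_weather <- function(x) {
  stopifnot(is.data.frame(x), all(c("date", "tmin", "tmax") %in% names(x)))
  if (anyNA(x$date) || anyNA(x$tmin) || anyNA(x$tmax))
    stop("daily weather series contains missing values", call. = FALSE)
  d <- as.numeric(diff(x$date))
  if (any(d <= 0))
    stop("dates must be strictly increasing", call. = FALSE)
  if (any(d > 1)) {
    first_gap <- x$date[which(d > 1)[1]] + 1
    stop("gap in daily series: first missing date is ", format(first_gap),
         call. = FALSE)
  }
  bad <- which(x$tmin > x$tmax)
  if (length(bad))
    stop("tmin > tmax on ", format(x$date[bad[1]]), call. = FALSE)
  invisible(x)
}

#' @export
print.daily_weather <- function(x, ...) {
  cat(sprintf("Daily weather series '%s': %d days, %s to %s\n",
              attr(x, "label"), nrow(x),
              format(min(x$date)), format(max(x$date))))
  cat(sprintf("  tmin %.1f..%.1f degC, tmax %.1f..%.1f degC\n",
              min(x$tmin), max(x$tmin), min(x$tmax), max(x$tmax)))
  invisible(x)
}

#' Read or write a daily weather series CSV
#'
#' The on-disk format is a CSV with header `date,tmin,tmax`, ISO-8601 dates
#' and temperatures in deg C. The reader tolerates extra columns; the writer
#' emits exactly these three.
#'
#' @param path file path.
#' @param label label attached to the series read.
#' @return `read_daily_weather()` returns a [daily_weather] object;
#'   `write_daily_weather()` returns `path` invisibly.
#' @export
read_daily_weather <- function(path, label = basename(path)) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "tmin", "tmax") %in% names(x)))
    stop("weather CSV must have columns date, tmin, tmax", call. = FALSE)
  daily_weather(x$date, x$tmin, x$tmax, label = label)
}

#' @param x a [daily_weather] object.
#' @rdname read_daily_weather
#' @export
write_daily_weather <- function(x, path) {
  stopifnot(inherits(x, "daily_weather"))
  out <- data.frame(date = format(x$date), tmin = x$tmin, tmax = x$tmax)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hourly temperature series
#'
#' An hourly series holds one temperature per local hour (hour 0 =
#' 00:00-00:59) over a contiguous span of days. It is stored compactly as a
#' start date plus a numeric vector of length `24 * n_days`; hour `h` of day
#' `d` sits at position `24 * (d - start) + h + 1`.
#'
#' @param start first calendar date covered.
#' @param temps numeric vector, length a multiple of 24.
#' @param label free-text label.
#' @return An `hourly_series` object.
#' @export
hourly_series <- function(start, temps, label = "unlabelled") {
  start <- as.Date(start)
  temps <- as.numeric(temps)
  if (length(temps) %% 24L != 0L)
    stop("hourly series length must be a multiple of 24", call. = FALSE)
  structure(list(start = start, temps = temps, label = as.character(label)[1]),
            class = "hourly_series")
}

#' @export
print.hourly_series <- function(x, ...) {
  nd <- length(x$temps) / 24
  cat(sprintf("Hourly series '%s': %d days (%d hours), %s to %s\n",
              x$label, nd, length(x$temps), format(x$start),
              format(x$start + nd - 1)))
  invisible(x)
}

#' Position of a (date, hour) in an hourly series
#'
#' @param hs an [hourly_series].
#' @param date calendar date.
#' @param hour local hour, 0-23.
#' @return 1-based integer index into `hs$temps`.
#' @export
hour_index <- function(hs, date, hour = 0L) {
  stopifnot(inherits(hs, "hourly_series"))
  i <- as.integer(as.Date(date) - hs$start) * 24L + as.integer(hour) + 1L
  if (any(i < 1L) || any(i > length(hs$temps)))
    stop("requested (date, hour) outside the hourly series span", call. = FALSE)
  i
}

#' Hourly temperatures from daily extremes by diurnal sine interpolation
#'
#' Each day's 24 hourly temperatures follow a single symmetric sine wave
#' through that day's extremes:
#' `T(h) = (tmax + tmin)/2 - (tmax - tmin)/2 * cos(2*pi*(h - trough_hour)/24)`,
#' so the trough falls at `trough_hour` (default 03:00) and the peak twelve
#' hours later (15:00). The per-day minimum and maximum of the output equal
#' the day's `tmin` and `tmax` exactly, and the wave is periodic across day
#' boundaries when consecutive days share extremes.
#'
#' @param daily a [daily_weather] series, gap-free.
#' @param trough_hour local hour of the daily minimum, default 3.
#' @return An [hourly_series] of length `24 * nrow(daily)`.
#' @examples
#' dw <- daily_weather(as.Date("2020-06-01"), tmin = 0, tmax = 10)
#' hs <- hourly_from_daily(dw)
#' hs$temps[c(4, 16)]  # 03:00 trough and 15:00 peak
#' @export
hourly_from_daily <- function(daily, trough_hour = 3) {
  validate_daily_weather(daily)
  n <- nrow(daily)
  mid <- (daily$tmax + daily$tmin) / 2
  amp <- (daily$tmax - daily$tmin) / 2
  shape <- cos(2 * pi * ((0:23) - trough_hour) / 24)
  temps <- rep(mid, each = 24L) - rep(amp, each = 24L) * rep(shape, times = n)
  hourly_series(daily$date[1], temps, label = attr(daily, "label"))
}

#' Square-wave growth-chamber temperature profile
#'
#' One day of chamber temperatures: `day_temp` for `day_hours` consecutive
#' hours starting at `day_start_hour` (wrapping past midnight if needed) and
#' `night_temp` otherwise. Defaults reproduce a 25/15 deg C chamber with a
#' 14 h photoperiod beginning at 06:00, so hours 06-19 sit at 25 deg C and
#' hours 20-05 at 15 deg C.
#'
#' @param day_temp,night_temp chamber temperatures, deg C.
#' @param day_hours length of the warm (lit) period, hours; `0 < day_hours
#'   <= 24`.
#' @param day_start_hour local hour at which the warm period begins.
#' @return A `chamber_profile`: numeric vector of length 24, names `"0"`..
#'   `"23"`.
#' @examples
#' p <- chamber_profile()
#' sum(pmax(p - 5, 0))  # growing degree hours per chamber day
#' @export
chamber_profile <- function(day_temp = 25, night_temp = 15, day_hours = 14,
                            day_start_hour = 6) {
  if (day_hours <= 0 || day_hours > 24)
    stop("day_hours must be in (0, 24]", call. = FALSE)
  hours <- 0:23
  lit <- ((hours - day_start_hour) %% 24) < day_hours
  temps <- ifelse(lit, day_temp, night_temp)
  structure(stats::setNames(as.numeric(temps), hours),
            class = "chamber_profile")
}

#' Growing degree hours of one chamber day
#' @param profile a [chamber_profile].
#' @param Tb base temperature, deg C.
#' @return deg C hours accumulated over the 24-hour profile.
#' @export
chamber_gdh_per_day <- function(profile, Tb = 5) {
  sum(pmax(unclass(profile) - Tb, 0))
}

#' Delta-method bias correction of a scenario temperature series
#'
#' Shifts a scenario series by a single constant offset so that its mean
#' daily midpoint temperature `(tmin + tmax)/2` over an overlap period of
#' calendar years equals that of an observed series. The same offset is added
#' to `tmin` and `tmax` of every scenario day, so diurnal range and
#' variability are preserved.
#'
#' @param observed,scenario [daily_weather] series; both must fully cover the
#'   overlap years.
#' @param overlap integer vector of calendar years, e.g. `2011:2020`.
#' @param monthly if `TRUE`, apply a separate offset per calendar month
#'   instead of one annual constant.
#' @return The corrected scenario as a [daily_weather] series; the offset(s)
#'   are attached as attribute `"delta"`.
#' @export
bias_correct <- function(observed, scenario, overlap, monthly = FALSE) {
  validate_daily_weather(observed)
  validate_daily_weather(scenario)
  overlap <- as.integer(overlap)
  if (!length(overlap)) stop("empty overlap period", call. = FALSE)
  yo <- year_of(observed$date); ys <- year_of(scenario$date)
  for (y in overlap) {
    if (!all(c(y) %in% yo) || !all(c(y) %in% ys))
      stop("overlap year ", y, " not covered by both series", call. = FALSE)
  }
  mid_o <- (observed$tmin + observed$tmax) / 2
  mid_s <- (scenario$tmin + scenario$tmax) / 2
  sel_o <- yo %in% overlap
  sel_s <- ys %in% overlap
  out <- scenario
  if (monthly) {
    mo <- month_of(observed$date); ms <- month_of(scenario$date)
    delta <- vapply(1:12, function(m) {
      mean(mid_o[sel_o & mo == m]) - mean(mid_s[sel_s & ms == m])
    }, numeric(1))
    shift <- delta[month_of(scenario$date)]
  } else {
    delta <- mean(mid_o[sel_o]) - mean(mid_s[sel_s])
    shift <- delta
  }
  out$tmin <- out$tmin + shift
  out$tmax <- out$tmax + shift
  attr(out, "delta") <- delta
  attr(out, "label") <- paste0(attr(scenario, "label"), "_corrected")
  class(out) <- c("daily_weather", "data.frame")
  out
}

# calendar helpers (local time, leap days retained)
year_of <- function(d) as.integer(format(d, "%Y"))
month_of <- function(d) as.integer(format(d, "%m"))
doy_of <- function(d) as.integer(format(d, "%j"))
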