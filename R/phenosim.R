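#' Simulate the spring onset date of one species-year
#'
#' From 00:00 on 1 November of the preceding calendar year, chilling
#' accumulates hourly under the species' chilling model; from 00:00 on 1
#' January, growing degree hours accumulate above `Tb`. The onset is the
#' first hour at which accumulated forcing reaches the moving forcing
#' requirement `FR(CA) = a + b * exp(-c * CA)` evaluated at the chilling
#' accumulated up to that same hour. Because `FR(CA(t))` is non-increasing
#' while GDH is non-decreasing, the first crossing is well defined; ties are
#' broken by the earliest hour.
#'
#' By default chilling keeps accruing past 1 January until the onset
#' (`chill_parallel = TRUE`); setting it `FALSE` freezes CA at its 31
#' December value, for sensitivity analysis.
#'
#' @param hourly an [hourly_series] covering 1 November of `year - 1`
#'   through `search_end`.
#' @param fit a `ca_fr_fit` (elements `a`, `b`, `c`).
#' @param model the species' [chill_model].
#' @param year calendar year of the spring event.
#' @param Tb base temperature for forcing, deg C.
#' @param search_end last date searched (default 31 July of `year`); if the
#'   requirement is not met by then the year is flagged `"no_onset"`.
#' @param chill_parallel keep accumulating chilling after 1 January.
#' @return A list with `P` (onset day of year), `FR_i` (the forcing
#'   requirement at the onset hour, deg C hours), `onset_date`, `onset_hour`
#'   and `flag` (`"ok"` or `"no_onset"`).
#' @export
simulate_onset <- function(hourly, fit, model, year, Tb = 5,
                           search_end = NULL, chill_parallel = TRUE) {
  year <- as.integer(year)
  if (is.null(search_end)) search_end <- as.Date(sprintf("%d-07-31", year))
  nov1 <- as.Date(sprintf("%d-11-01", year - 1L))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  i0 <- hour_index(hourly, nov1, 0L)
  i1 <- hour_index(hourly, search_end, 23L)
  temps <- hourly$temps[i0:i1]
  cumca <- cumsum(chill_unit(model, temps))
  j0 <- as.integer(jan1 - nov1) * 24L + 1L
  cumg <- cumsum(pmax(temps[j0:length(temps)] - Tb, 0))
  ca_path <- if (chill_parallel) cumca[j0:length(temps)] else cumca[j0 - 1L]
  target <- predict_fr(fit, ca_path)
  k <- which(cumg >= target)[1]
  if (is.na(k)) {
    return(list(P = NA_real_, FR_i = NA_real_, onset_date = as.Date(NA),
                onset_hour = NA_integer_, flag = "no_onset"))
  }
  onset_date <- jan1 + (k - 1L) %/% 24L
  list(P = as.numeric(doy_of(onset_date)),
       FR_i = if (chill_parallel) target[k] else target[1],
       onset_date = onset_date, onset_hour = (k - 1L) %% 24L, flag = "ok")
}

#' Simulate onset under a fixed forcing requirement
#'
#' As [simulate_onset()] but with a constant requirement `FR_ref` instead of
#' the chilling-dependent curve: the onset is the first hour at which
#' accumulated GDH from 1 January reaches `FR_ref`. Used to isolate the
#' forcing contribution in the chilling/forcing decomposition.
#'
#' @inheritParams simulate_onset
#' @param FR_ref constant forcing requirement, deg C hours.
#' @return A list with `P`, `onset_date`, `onset_hour` and `flag`.
#' @export
simulate_onset_fixed_fr <- function(hourly, FR_ref, year, Tb = 5,
                                    search_end = NULL) {
  year <- as.integer(year)
  if (is.null(search_end)) search_end <- as.Date(sprintf("%d-07-31", year))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  i0 <- hour_index(hourly, jan1, 0L)
  i1 <- hour_index(hourly, search_end, 23L)
  cumg <- cumsum(pmax(hourly$temps[i0:i1] - Tb, 0))
  k <- which(cumg >= FR_ref)[1]
  if (is.na(k)) {
    return(list(P = NA_real_, onset_date = as.Date(NA),
                onset_hour = NA_integer_, flag = "no_onset"))
  }
  onset_date <- jan1 + (k - 1L) %/% 24L
  list(P = as.numeric(doy_of(onset_date)), onset_date = onset_date,
       onset_hour = (k - 1L) %% 24L, flag = "ok")
}

#' Reference-period phenology statistics
#'
#' Arithmetic means of the simulated onset day and of the realised forcing
#' requirement over the reference years (default length 30, mirroring a
#' 1961-1990 climatology).
#'
#' @param annual data frame with columns `year`, `P`, `FR_i` (one row per
#'   simulated year of one species).
#' @param ref_years integer vector of reference calendar years.
#' @return A list `P_ref`, `FR_ref`, `ref_years`.
#' @export
reference_stats <- function(annual, ref_years) {
  sel <- annual$year %in% ref_years
  if (sum(sel) != length(ref_years))
    stop("reference years not all present in the simulated table",
         call. = FALSE)
  if (anyNA(annual$P[sel]) || anyNA(annual$FR_i[sel]))
    stop("no-onset year inside the reference period; decomposition undefined",
         call. = FALSE)
  list(P_ref = mean(annual$P[sel]), FR_ref = mean(annual$FR_i[sel]),
       ref_years = ref_years)
}

#' Chilling/forcing decomposition of an onset anomaly
#'
#' Splits a year's simulated onset `P` into `P = C + F + P_ref`: the
#' chilling effect `C = P - P_fixed` (the shift attributable to that year's
#' forcing requirement differing from the reference mean, i.e. to chilling),
#' and the forcing effect `F = P_fixed - P_ref` (the shift a fixed
#' requirement would have experienced from forcing-season temperatures
#' alone). The identity holds exactly by construction.
#'
#' @param P simulated onset day of year.
#' @param P_fixed onset day simulated under the constant reference
#'   requirement (from [simulate_onset_fixed_fr()]).
#' @param ref a [reference_stats()] result.
#' @return A list with components `C` and `F`, in days.
#' @export
decompose_onset <- function(P, P_fixed, ref) {
  list(C = P - P_fixed, F = P_fixed - ref$P_ref)
}

#' Simulate and decompose annual phenology over a climate series
#'
#' Runs the full per-species annual loop over a multi-year daily temperature
#' series: hourly interpolation, onset simulation from the fitted
#' chilling-forcing curve, reference statistics, fixed-requirement
#' re-simulation and the chilling/forcing decomposition. Deterministic given
#' its inputs.
#'
#' @param daily a [daily_weather] series spanning all requested phenological
#'   years (1 November before the first year through 31 July of the last).
#' @param species_fits list of species entries, each a list with elements
#'   `species` (id), `fit` (a `ca_fr_fit`) and `model` (a [chill_model]).
#' @param years calendar years to simulate; default all years fully covered
#'   by `daily`.
#' @param ref_years reference period for the decomposition (default
#'   `1961:1990`; must be a subset of `years`).
#' @param Tb base temperature, deg C.
#' @param trough_hour hour of the diurnal temperature minimum.
#' @param chill_parallel see [simulate_onset()].
#' @return An `annual_phenology` data frame with columns `species, year, P,
#'   FR_i, P_fixed, C, F, flag`. Years whose requirement is never met are
#'   flagged `"no_onset"` with `NA` values (an error if inside `ref_years`).
#' @export
run_scenario <- function(daily, species_fits, years = NULL,
                         ref_years = 1961:1990, Tb = 5, trough_hour = 3,
                         chill_parallel = TRUE) {
  validate_daily_weather(daily)
  hourly <- hourly_from_daily(daily, trough_hour = trough_hour)
  y_min <- year_of(min(daily$date)); y_max <- year_of(max(daily$date))
  if (is.null(years)) {
    years <- (y_min + 1L):y_max
    # keep only years whose Nov-Jul span is fully on record
    ok <- as.Date(sprintf("%d-11-01", years - 1L)) >= min(daily$date) &
      as.Date(sprintf("%d-07-31", years)) <= max(daily$date)
    years <- years[ok]
  }
  if (!all(ref_years %in% years))
    stop("reference period not within the simulated years", call. = FALSE)
  out <- vector("list", length(species_fits))
  for (s in seq_along(species_fits)) {
    sp <- species_fits[[s]]
    sim <- lapply(years, function(y)
      simulate_onset(hourly, sp$fit, sp$model, y, Tb = Tb,
                     chill_parallel = chill_parallel))
    ann <- data.frame(species = sp$species, year = years,
                      P = vapply(sim, `[[`, numeric(1), "P"),
                      FR_i = vapply(sim, `[[`, numeric(1), "FR_i"),
                      flag = vapply(sim, `[[`, character(1), "flag"))
    ref <- reference_stats(ann, ref_years)
    fixed <- lapply(years, function(y)
      simulate_onset_fixed_fr(hourly, ref$FR_ref, y, Tb = Tb))
    ann$P_fixed <- vapply(fixed, `[[`, numeric(1), "P")
    dec <- decompose_onset(ann$P, ann$P_fixed, ref)
    ann$C <- dec$C
    ann$F <- dec$F
    ann$flag[ann$flag == "ok" &
               vapply(fixed, `[[`, character(1), "flag") != "ok"] <- "no_onset"
    ann <- ann[c("species", "year", "P", "FR_i", "P_fixed", "C", "F", "flag")]
    attr(ann, "refs") <- c(P_ref = ref$P_ref, FR_ref = ref$FR_ref)
    out[[s]] <- ann
  }
  res <- do.call(rbind, lapply(out, function(a) { attr(a, "refs") <- NULL; a }))
  rownames(res) <- NULL
  sp_names <- vapply(species_fits, `[[`, character(1), "species")
  refs <- vapply(out, attr, numeric(2), "refs")
  attr(res, "ref_years") <- ref_years
  attr(res, "P_ref") <- stats::setNames(refs["P_ref", ], sp_names)
  attr(res, "FR_ref") <- stats::setNames(refs["FR_ref", ], sp_names)
  class(res) <- c("annual_phenology", "data.frame")
  res
}
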