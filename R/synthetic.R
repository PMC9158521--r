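# run code under a temporary RNG state so generators are pure in their seed
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic daily climate
#'
#' Parameters of the seeded weather generator: a sinusoidal seasonal cycle
#' around an annual mean, a fixed diurnal range, linear warming (overall or
#' per meteorological season), and AR(1) day-to-day noise on the daily
#' midpoint. Defaults emulate a continental temperate site: annual mean
#' 12 deg C, seasonal amplitude 15 deg C peaking in mid-July (day 197),
#' diurnal range 9 deg C.
#'
#' @param years integer vector of calendar years to generate (contiguous).
#' @param mean_annual long-term annual mean of the daily midpoint, deg C.
#' @param seasonal_amplitude half-range of the seasonal cycle, deg C.
#' @param peak_doy day of year of the seasonal maximum.
#' @param diurnal_range `tmax - tmin`, deg C, held constant.
#' @param warming_per_decade linear warming applied to every day, deg
#'   C/decade, stepping by calendar year.
#' @param seasonal_warming optional named list/vector with any of `DJF`,
#'   `MAM`, `JJA`, `SON` (deg C/decade) overriding the overall rate for
#'   those seasons (months 12-2, 3-5, 6-8, 9-11).
#' @param noise_sd marginal standard deviation of the AR(1) midpoint noise,
#'   deg C.
#' @param ar1 lag-1 autocorrelation of the noise, in `[0, 1)`.
#' @param seed integer seed; identical specs generate identical series.
#' @return A `climate_spec` list.
#' @export
climate_spec <- function(years, mean_annual = 12, seasonal_amplitude = 15,
                         peak_doy = 197, diurnal_range = 9,
                         warming_per_decade = 0, seasonal_warming = NULL,
                         noise_sd = 0, ar1 = 0, seed = 1) {
  stopifnot(noise_sd >= 0, abs(ar1) < 1, diurnal_range >= 0,
            all(diff(as.integer(years)) == 1L) || length(years) == 1L)
  structure(list(years = as.integer(years), mean_annual = mean_annual,
                 seasonal_amplitude = seasonal_amplitude, peak_doy = peak_doy,
                 diurnal_range = diurnal_range,
                 warming_per_decade = warming_per_decade,
                 seasonal_warming = seasonal_warming,
                 noise_sd = noise_sd, ar1 = ar1, seed = as.integer(seed)),
            class = "climate_spec")
}

met_season <- function(month) {
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA", "JJA", "JJA",
    "SON", "SON", "SON", "DJF")[month]
}

#' Generate a synthetic daily weather series
#'
#' Daily midpoint temperature = annual mean + seasonal cosine + linear
#' warming trend (per season if configured) + AR(1) noise; `tmin`/`tmax` sit
#' symmetrically half a diurnal range below/above the midpoint. A pure
#' function of its spec: the same seed reproduces the series bit for bit.
#'
#' @param spec a [climate_spec].
#' @param label label of the returned series.
#' @return A [daily_weather] series covering 1 January of the first year to
#'   31 December of the last.
#' @examples
#' dw <- gen_daily_weather(climate_spec(2000:2001, noise_sd = 1, seed = 42))
#' head(dw)
#' @export
gen_daily_weather <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "climate_spec"))
  dates <- seq(as.Date(sprintf("%d-01-01", min(spec$years))),
               as.Date(sprintf("%d-12-31", max(spec$years))), by = "day")
  doy <- doy_of(dates)
  yr <- year_of(dates)
  seasonal <- spec$seasonal_amplitude *
    cos(2 * pi * (doy - spec$peak_doy) / 365.25)
  rate <- rep(spec$warming_per_decade, length(dates))
  if (!is.null(spec$seasonal_warming)) {
    sw <- spec$seasonal_warming
    seas <- met_season(month_of(dates))
    for (s in names(sw)) rate[seas == s] <- sw[[s]]
  }
  trend <- rate * (yr - min(spec$years)) / 10
  noise <- 0
  if (spec$noise_sd > 0) {
    noise <- with_local_seed(spec$seed, {
      n <- length(dates)
      innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
      e <- numeric(n)
      z <- stats::rnorm(n)
      e[1] <- spec$noise_sd * z[1]
      if (n > 1) for (t in 2:n) e[t] <- spec$ar1 * e[t - 1] + innov_sd * z[t]
      e
    })
  }
  mid <- spec$mean_annual + seasonal + trend + noise
  daily_weather(dates, tmin = mid - spec$diurnal_range / 2,
                tmax = mid + spec$diurnal_range / 2, label = label)
}

#' Specification of a synthetic twig experiment
#'
#' Parameters for generating chamber-forcing experiments from a known true
#' exponential chilling-forcing curve `FR(CA) = a + b * exp(-c * CA)`.
#'
#' @param true_a,true_b,true_c true curve parameters (`b, c >= 0`).
#' @param model the species' [chill_model] used both to generate and (round
#'   trip) to analyse.
#' @param sampling_dates collection dates through the winter (typically every
#'   3-7 days, November-April).
#' @param twigs_per_sample twigs forced per collection, default 3.
#' @param fr_noise_sd additive noise on each twig's realised forcing
#'   requirement, deg C hours.
#' @param seed integer seed.
#' @param species species id attached to the generated records.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(true_a, true_b, true_c, model, sampling_dates,
                            twigs_per_sample = 3, fr_noise_sd = 0, seed = 1,
                            species = "synthetic") {
  stopifnot(true_b >= 0, true_c >= 0, twigs_per_sample >= 1,
            inherits(model, "chill_model"))
  structure(list(true_a = true_a, true_b = true_b, true_c = true_c,
                 model = model, sampling_dates = as.Date(sampling_dates),
                 twigs_per_sample = as.integer(twigs_per_sample),
                 fr_noise_sd = fr_noise_sd, seed = as.integer(seed),
                 species = species),
            class = "experiment_spec")
}

#' Generate a synthetic twig experiment
#'
#' For each sampling date, chilling accumulated outdoors up to that date is
#' computed with the package's own thermal machinery, the true curve gives
#' the forcing requirement, and each twig receives a noisy copy of it. The
#' chamber onset date is the first day on which the realised forcing (the 1
#' January outdoor term included for post-January samples) reaches the
#' twig's requirement, so onsets are quantised to whole days exactly as in a
#' real experiment (one chamber day under the default 25/15 deg C, 14 h
#' regime is 380 deg C hours).
#'
#' @param spec an [experiment_spec].
#' @param winter a [daily_weather] series covering 1 November before the
#'   first sampling date through the last sampling date.
#' @param chamber a [chamber_profile].
#' @param Tb base temperature, deg C.
#' @param trough_hour diurnal sine trough hour for the outdoor series.
#' @return A data frame in the experiment-table schema `species,
#'   sample_date, twig_id, onset_date, season`, suitable for
#'   [experiment_from_table()].
#' @export
gen_experiment <- function(spec, winter, chamber = chamber_profile(), Tb = 5,
                           trough_hour = 3) {
  stopifnot(inherits(spec, "experiment_spec"))
  hourly <- hourly_from_daily(winter, trough_hour = trough_hour)
  gday <- chamber_gdh_per_day(chamber, Tb)
  if (gday <= 0) stop("chamber profile accumulates no forcing", call. = FALSE)
  rows <- with_local_seed(spec$seed, {
    lapply(spec$sampling_dates, function(s) {
      t0 <- season_start(s)
      ca <- accumulate_chill(hourly, spec$model, accum_window(t0, s))
      fr_true <- spec$true_a + spec$true_b * exp(-spec$true_c * ca)
      jan1 <- as.Date(sprintf("%d-01-01", year_of(t0) + 1L))
      outdoor <- if (s > jan1)
        accumulate_gdh(hourly, Tb, accum_window(jan1, s - 1L)) else 0
      targets <- pmax(fr_true + stats::rnorm(spec$twigs_per_sample, 0,
                                             spec$fr_noise_sd), 1)
      n_days <- pmax(ceiling((targets - outdoor) / gday), 1)
      if (any(n_days > 365))
        stop("forcing target unreachable within 365 chamber days",
             call. = FALSE)
      data.frame(species = spec$species, sample_date = s,
                 twig_id = seq_len(spec$twigs_per_sample),
                 onset_date = s + n_days - 1L,
                 season = sprintf("%d-%02d", year_of(t0),
                                  (year_of(t0) + 1L) %% 100L))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a panel of synthetic species with prescribed traits
#'
#' Back-solves exponential chilling-forcing curves so that each species'
#' chilling sensitivity and basic forcing requirement, evaluated at the
#' designated low/high chilling conditions, hit evenly spaced targets in the
#' requested ranges: with decay `c` fixed, `b = FR_high * (CS - 1) /
#' (exp(-c * lowc) - exp(-c * highc))` and `a = FR_high - b * exp(-c *
#' highc)`. Life forms alternate shrub/tree. The construction is
#' deterministic.
#'
#' @param n number of species (>= 2).
#' @param cs_range low/high chilling-sensitivity targets (each >= 1).
#' @param fr_range low/high basic-FR targets, deg C hours.
#' @param lowc,highc designated chilling conditions, chilling units.
#' @param c_decay decay rate(s) per chilling unit; recycled to `n`.
#' @param model a [chill_model] shared by the panel (or a list of one per
#'   species).
#' @return A `species_panel`: list of entries `list(species, life_form, fit,
#'   model, cs_target, fr_target)` directly usable as `species_fits` in
#'   [run_scenario()].
#' @examples
#' panel <- gen_species_panel(2, cs_range = c(1.2, 2.6),
#'                            fr_range = c(4000, 4000))
#' chilling_sensitivity(panel[[1]]$fit, 720, 2160)$cs
#' @export
gen_species_panel <- function(n, cs_range = c(1.2, 2.6),
                              fr_range = c(2400, 8600), lowc = 720,
                              highc = 2160, c_decay = 0.002,
                              model = chill_model("threshold", T1 = 5)) {
  if (n < 2) stop("panel needs at least 2 species", call. = FALSE)
  cs <- seq(cs_range[1], cs_range[2], length.out = n)
  fr <- seq(fr_range[1], fr_range[2], length.out = n)
  cc <- rep_len(c_decay, n)
  if (any(cs < 1))
    stop("infeasible trait combination: CS targets must be >= 1",
         call. = FALSE)
  models <- if (inherits(model, "chill_model")) rep(list(model), n) else model
  panel <- lapply(seq_len(n), function(i) {
    el <- exp(-cc[i] * lowc); eh <- exp(-cc[i] * highc)
    b <- if (cs[i] == 1) 0 else fr[i] * (cs[i] - 1) / (el - eh)
    a <- fr[i] - b * eh
    if (a < 0)
      stop("infeasible trait combination: implied asymptote a < 0",
           call. = FALSE)
    fit <- structure(list(a = a, b = b, c = cc[i], r2 = NA_real_,
                          n_points = NA_integer_, sse = NA_real_,
                          insensitive = b == 0), class = "ca_fr_fit")
    list(species = sprintf("sp%02d", i),
         life_form = if (i %% 2 == 1) "shrub" else "tree",
         fit = fit, model = models[[i]], cs_target = cs[i],
         fr_target = fr[i])
  })
  class(panel) <- c("species_panel", "list")
  panel
}
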