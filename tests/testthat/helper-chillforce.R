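# constant-temperature daily series over a date span
const_weather <- function(from, to, tmin, tmax = tmin, label = "const") {
  daily_weather(seq(as.Date(from), as.Date(to), by = "day"),
                tmin = tmin, tmax = tmax, label = label)
}

# Beijing-like winter covering one experiment season (Nov year0 - Apr year0+1)
winter_weather <- function(year0, noise_sd = 0, ar1 = 0, seed = 1) {
  gen_daily_weather(climate_spec((year0):(year0 + 1), noise_sd = noise_sd,
                                 ar1 = ar1, seed = seed))
}

# independent brute-force hourly scan: walks every hour one at a time,
# accumulating chilling from 1 Nov and forcing from 1 Jan, and stops at the
# first hour whose forcing total reaches a + b*exp(-c * CA-so-far)
oracle_onset <- function(hourly, fit, model, year, Tb = 5,
                         search_end = NULL) {
  if (is.null(search_end)) search_end <- as.Date(sprintf("%d-07-31", year))
  nov1 <- as.Date(sprintf("%d-11-01", year - 1L))
  jan1 <- as.Date(sprintf("%d-01-01", year))
  ca <- 0
  for (i in hour_index(hourly, nov1, 0L):(hour_index(hourly, jan1, 0L) - 1L))
    ca <- ca + chill_unit(model, hourly$temps[i])
  g <- 0
  i0 <- hour_index(hourly, jan1, 0L)
  i1 <- hour_index(hourly, search_end, 23L)
  for (i in i0:i1) {
    ca <- ca + chill_unit(model, hourly$temps[i])
    g <- g + max(hourly$temps[i] - Tb, 0)
    if (g >= fit$a + fit$b * exp(-fit$c * ca)) {
      k <- i - i0  # hours since 00:00 Jan 1
      return(list(onset_date = jan1 + k %/% 24L, onset_hour = k %% 24L,
                  flag = "ok"))
    }
  }
  list(onset_date = as.Date(NA), onset_hour = NA_integer_, flag = "no_onset")
}

# a random small climate + species for oracle cross-checks
random_case <- function(seed) {
  set.seed(seed)
  dates <- seq(as.Date("2000-11-01"), as.Date("2001-05-31"), by = "day")
  tmin <- runif(length(dates), -10, 12)
  dw <- daily_weather(dates, tmin = tmin, tmax = tmin + runif(length(dates), 0, 12))
  model <- switch(sample(3, 1),
                  chill_model("threshold", T1 = runif(1, 0, 8)),
                  chill_model("range", T2 = runif(1, -6, 0), T3 = runif(1, 1, 8)),
                  chill_model("triangular", Top = runif(1, 0, 6)))
  fit <- list(a = runif(1, 500, 2500), b = runif(1, 0, 4000),
              c = runif(1, 1e-4, 5e-3))
  list(hourly = hourly_from_daily(dw), model = model, fit = fit)
}
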