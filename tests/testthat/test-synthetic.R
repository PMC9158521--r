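test_that("the weather generator is a pure function of its spec", {
  sp <- climate_spec(2000:2002, noise_sd = 2, ar1 = 0.6, seed = 13)
  a <- gen_daily_weather(sp)
  b <- gen_daily_weather(sp)
  expect_identical(a$tmin, b$tmin)
  expect_identical(a$tmax, b$tmax)
  c <- gen_daily_weather(climate_spec(2000:2002, noise_sd = 2, ar1 = 0.6,
                                      seed = 14))
  expect_false(identical(a$tmin, c$tmin))
  # generation does not disturb the caller's RNG stream
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(gen_daily_weather(sp)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("noise-free generation reproduces the configured structure", {
  # identical years without warming or noise
  dw <- gen_daily_weather(climate_spec(2001:2002))
  y1 <- dw[format(dw$date, "%Y") == "2001", ]
  y2 <- dw[format(dw$date, "%Y") == "2002", ]
  expect_equal(y1$tmin, y2$tmin)
  expect_equal(y1$tmax - y1$tmin, rep(9, 365))  # fixed diurnal range

  # warming of 0.5 degC/decade steps the annual mean by exactly 0.05 degC
  dww <- gen_daily_weather(climate_spec(2001:2003, warming_per_decade = 0.5))
  mids <- tapply((dww$tmin + dww$tmax) / 2, format(dww$date, "%Y"), mean)
  expect_equal(as.numeric(diff(mids)), c(0.05, 0.05))

  # per-season warming touches only its months
  dws <- gen_daily_weather(climate_spec(2001:2002,
                                        seasonal_warming = list(DJF = 1)))
  base <- gen_daily_weather(climate_spec(2001:2002))
  m <- as.integer(format(dws$date, "%m"))
  yr <- as.integer(format(dws$date, "%Y"))
  djf2 <- m %in% c(12, 1, 2) & yr == 2002
  expect_equal(dws$tmin[djf2], base$tmin[djf2] + 0.1)
  expect_equal(dws$tmin[!djf2], base$tmin[!djf2])

  expect_error(climate_spec(2001, ar1 = 1), "ar1")
})

test_that("synthetic experiments invert the true curve up to day steps", {
  dw <- winter_weather(2018, noise_sd = 3, ar1 = 0.7, seed = 11)
  samp <- seq(as.Date("2018-11-05"), as.Date("2019-03-20"), by = 5)
  m <- chill_model("threshold", T1 = 5)
  hs <- hourly_from_daily(dw)
  ch <- chamber_profile()

  es <- experiment_spec(2500, 5000, 0.002, m, samp, fr_noise_sd = 0, seed = 1)
  tab <- gen_experiment(es, dw)
  expect_equal(nrow(tab), 3 * length(samp))
  pts <- samples_to_points(experiment_from_table(tab), hs, ch, m)
  # each realised FR overshoots its target by less than one chamber day
  fr_true <- 2500 + 5000 * exp(-0.002 * pts$CA)
  expect_true(all(pts$FR >= fr_true - 1e-9))
  expect_true(all(pts$FR < fr_true + 380))
  f <- fit_ca_fr(pts)
  expect_lt(abs(f$a - 2500), 380)
  expect_lt(abs(f$b - 5000), 380)

  # a chilling-insensitive truth yields flat FR up to quantisation
  es0 <- experiment_spec(2500, 0, 0, m, samp, fr_noise_sd = 0, seed = 1)
  pts0 <- samples_to_points(experiment_from_table(gen_experiment(es0, dw)),
                            hs, ch, m)
  expect_lt(diff(range(pts0$FR)), 380 + 1e-9)

  # seeds move individual onsets but not the underlying curve
  esa <- experiment_spec(2500, 5000, 0.002, m, samp, fr_noise_sd = 150,
                         seed = 2)
  esb <- experiment_spec(2500, 5000, 0.002, m, samp, fr_noise_sd = 150,
                         seed = 3)
  ta <- gen_experiment(esa, dw); tb <- gen_experiment(esb, dw)
  expect_false(identical(ta$onset_date, tb$onset_date))
  fa <- fit_ca_fr(samples_to_points(experiment_from_table(ta), hs, ch, m))
  fb <- fit_ca_fr(samples_to_points(experiment_from_table(tb), hs, ch, m))
  expect_equal(fa$b, fb$b, tolerance = 0.2)
})

test_that("experiment generation refuses unreachable forcing targets", {
  dw <- winter_weather(2018)
  m <- chill_model("threshold", T1 = 5)
  es <- experiment_spec(380 * 400, 0, 0, m, as.Date("2018-11-15"))
  expect_error(gen_experiment(es, dw), "unreachable")
})

test_that("species panels hit their prescribed trait targets", {
  panel <- gen_species_panel(2, cs_range = c(1.2, 2.6),
                             fr_range = c(4000, 4000))
  for (i in 1:2) {
    s <- chilling_sensitivity(panel[[i]]$fit, 720, 2160)
    expect_equal(s$cs, panel[[i]]$cs_target, tolerance = 1e-6)
    expect_equal(s$fr_high, 4000, tolerance = 1e-6)
  }
  expect_equal(panel[[1]]$life_form, "shrub")
  expect_equal(panel[[2]]$life_form, "tree")

  # CS target of exactly 1 produces the b = 0 curve
  p1 <- gen_species_panel(2, cs_range = c(1, 1), fr_range = c(3000, 5000))
  expect_equal(p1[[1]]$fit$b, 0)
  expect_true(p1[[1]]$fit$insensitive)

  expect_error(gen_species_panel(3, cs_range = c(0.8, 1.5)), "infeasible")
  expect_error(gen_species_panel(1), "at least 2")
})

test_that("recovered chilling sensitivity tracks the truth at low noise", {
  dw <- winter_weather(2018, noise_sd = 3, ar1 = 0.7, seed = 17)
  samp <- seq(as.Date("2018-11-03"), as.Date("2019-03-25"), by = 6)
  m <- chill_model("threshold", T1 = 5)
  hs <- hourly_from_daily(dw)
  true_fit <- list(a = 3000, b = 5000, c = 0.002)
  cs_true <- chilling_sensitivity(true_fit, 720, 2160)$cs
  es <- experiment_spec(3000, 5000, 0.002, m, samp,
                        fr_noise_sd = 0.02 * 5000, seed = 4)
  pts <- samples_to_points(experiment_from_table(gen_experiment(es, dw)),
                           hs, chamber_profile(), m)
  f <- fit_ca_fr(pts)
  cs_hat <- chilling_sensitivity(f, 720, 2160)$cs
  expect_lt(abs(cs_hat / cs_true - 1), 0.05)
})
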