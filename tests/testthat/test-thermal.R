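test_that("chilling-unit models follow their piecewise definitions", {
  th <- chill_model("threshold", T1 = 5)
  expect_equal(chill_unit(th, c(5.0, 5.1, -20)), c(1, 0, 1))

  rg <- chill_model("range", T2 = -5, T3 = 5)
  expect_equal(chill_unit(rg, c(0, -5, 5, -6, 5.5)), c(1, 1, 1, 0, 0))

  tr <- chill_model("triangular", Top = 5)  # Tmi = -2, Tma = 12
  expect_equal(chill_unit(tr, 1.5), 0.5)    # (1.5 - (-2)) / 7
  expect_equal(chill_unit(tr, c(-2, 5, 12, -3, 13)), c(0, 1, 0, 0, 0))
  expect_equal(chill_unit(tr, 8.5), 0.5)

  # CU stays in [0, 1] for all models over a wide temperature sweep
  temps <- seq(-40, 45, by = 0.37)
  for (m in list(th, rg, tr)) {
    cu <- chill_unit(m, temps)
    expect_true(all(cu >= 0 & cu <= 1))
  }

  # triangular response is continuous (no jump exceeds the local slope)
  cu <- chill_unit(tr, seq(-5, 15, by = 0.01))
  expect_lt(max(abs(diff(cu))), 0.01 / 7 + 1e-12)

  expect_error(chill_model("range", T2 = 5, T3 = -5), "T2 < T3")
  expect_error(chill_model("triangular", Top = 5, half_width = 0),
               "half_width")
})

test_that("chilling and forcing accumulate over closed hourly windows", {
  th <- chill_model("threshold", T1 = 5)
  hs <- hourly_from_daily(const_weather("2020-11-01", "2020-11-30", 0))
  w100 <- accum_window("2020-11-01", "2020-11-05", end_hour = 3L)  # 100 h
  expect_equal(accumulate_chill(hs, th, w100), 100)

  warm <- hourly_from_daily(const_weather("2020-11-01", "2020-11-30", 10))
  expect_equal(accumulate_chill(warm, th, w100), 0)

  tr <- chill_model("triangular", Top = 5)
  hs15 <- hourly_from_daily(const_weather("2020-11-01", "2020-11-02", 1.5))
  expect_equal(accumulate_chill(hs15, tr,
                                accum_window("2020-11-01", "2020-11-01")),
               12)

  hot <- hourly_from_daily(const_weather("2021-01-01", "2021-01-10", 25))
  expect_equal(accumulate_gdh(hot, 5, accum_window("2021-01-01", "2021-01-01",
                                                   end_hour = 0L)), 20)
  cold <- hourly_from_daily(const_weather("2021-01-01", "2021-01-10", 2))
  expect_equal(accumulate_gdh(cold, 5, accum_window("2021-01-01",
                                                    "2021-01-10")), 0)

  expect_error(accumulate_chill(hs, th, accum_window("2020-10-01",
                                                     "2020-11-02")),
               "outside")
})

test_that("accumulation is additive over adjacent windows", {
  set.seed(42)
  d <- as.Date("2020-11-01") + 0:59
  tmin <- runif(60, -8, 8)
  hs <- hourly_from_daily(daily_weather(d, tmin, tmin + runif(60, 0, 10)))
  models <- list(chill_model("threshold", T1 = 5),
                 chill_model("range", T2 = -5, T3 = 5),
                 chill_model("triangular", Top = 3))
  for (i in 1:10) {
    cut <- sample(2:58, 1)
    wa <- accum_window(d[1], d[cut], end_hour = 11L)
    wb <- accum_window(d[cut], d[60], start_hour = 12L)
    wall <- accum_window(d[1], d[60])
    for (m in models) {
      expect_equal(accumulate_chill(hs, m, wa) + accumulate_chill(hs, m, wb),
                   accumulate_chill(hs, m, wall))
    }
    expect_equal(accumulate_gdh(hs, 5, wa) + accumulate_gdh(hs, 5, wb),
                 accumulate_gdh(hs, 5, wall))
  }
})

test_that("warming raises forcing and cannot raise threshold chilling", {
  set.seed(7)
  d <- as.Date("2020-11-01") + 0:29
  tmin <- runif(30, -5, 10)
  dw <- daily_weather(d, tmin, tmin + 8)
  warm <- daily_weather(d, tmin + 1.5, tmin + 9.5)
  w <- accum_window(d[1], d[30])
  expect_gte(accumulate_gdh(hourly_from_daily(warm), 5, w),
             accumulate_gdh(hourly_from_daily(dw), 5, w))
  th <- chill_model("threshold", T1 = 5)
  expect_lte(accumulate_chill(hourly_from_daily(warm), th, w),
             accumulate_chill(hourly_from_daily(dw), th, w))
})

test_that("forcing to a chamber event follows the 1-January rule", {
  ch <- chamber_profile()
  outdoor0 <- hourly_from_daily(const_weather("2020-11-01", "2021-03-01", 0))

  # sampled before 1 Jan: chamber heat only (10 chamber days at 380 each)
  expect_equal(forcing_to_event(outdoor0, ch, "2020-12-01", "2020-12-10"),
               3800)

  # sampled after 1 Jan over a sub-threshold winter: outdoor term is zero
  expect_equal(forcing_to_event(outdoor0, ch, "2021-01-15", "2021-01-19"),
               5 * 380)

  # warm outdoor January contributes 5 degC-hours per hour for 2 full days
  outdoor10 <- hourly_from_daily(const_weather("2020-11-01", "2021-03-01", 10))
  expect_equal(forcing_to_event(outdoor10, ch, "2021-01-03", "2021-01-07"),
               48 * 5 + 5 * 380)

  # disabling the rule drops the outdoor term
  expect_equal(forcing_to_event(outdoor10, ch, "2021-01-03", "2021-01-07",
                                jan1_rule = FALSE), 5 * 380)

  expect_error(forcing_to_event(outdoor0, ch, "2021-01-10", "2021-01-05"),
               "onset precedes sampling")
})
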