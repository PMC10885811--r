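test_that("stomatal conductance unit conversion uses the molar density of air", {
  expect_equal(gsw_to_ms(0.2, "mol_m2_s", t_air = 25, p = 98.726),
               0.00502161, tolerance = 1e-5)
  expect_equal(gsw_to_ms(0, "mol_m2_s", t_air = 25, p = 98.726), 0)
  expect_equal(gsw_to_ms(0.003, "m_s", t_air = 25, p = 98.726), 0.003)
  # homogeneous of degree 1 in the value
  v <- c(0.05, 0.1, 0.2, 0.4)
  expect_equal(gsw_to_ms(3 * v, "mol_m2_s", 25, 98.726),
               3 * gsw_to_ms(v, "mol_m2_s", 25, 98.726))
  expect_error(gsw_to_ms(0.2, "cm_s", 25, 98.726), "unknown g_sw unit")
  expect_error(gsw_to_ms(-0.1, "m_s", 25, 98.726), "non-negative")
})

test_that("canopy-side aggregation averages converted samples per timestamp", {
  meteo <- data.frame(
    timestamp = as_clock_time(c("2021-07-08 10:00", "2021-07-08 11:00",
                                "2021-07-08 12:00")),
    t_air_c = c(25, 27, 29)
  )
  leaf <- data.frame(
    timestamp = as_clock_time(c("2021-07-08 10:00", "2021-07-08 10:00",
                                "2021-07-08 11:00",
                                "2021-07-08 12:00", "2021-07-08 12:00",
                                "2021-07-08 12:00")),
    side = c("east", "west", "east", "east", "west", "east"),
    gsw_value = c(0.004, 0.006, 0.005, 0.003, 0.004, 0.005),
    gsw_unit = "m_s",
    stringsAsFactors = FALSE
  )
  agg <- aggregate_leaf_conductance(leaf, meteo, site_params())
  expect_identical(nrow(agg), 3L)
  expect_equal(agg$gsw_m_s, c(0.005, 0.005, 0.004))
  expect_identical(agg$n_samples, c(2L, 1L, 3L))
  expect_identical(agg$qc_flag, c("ok", "one_side_only", "ok"))

  # molar samples are converted at the concurrent temperature before averaging
  leaf_mol <- data.frame(
    timestamp = as_clock_time(c("2021-07-08 10:00", "2021-07-08 10:00")),
    side = c("east", "west"), gsw_value = c(0.15, 0.25),
    gsw_unit = "mol_m2_s", stringsAsFactors = FALSE
  )
  agg_mol <- aggregate_leaf_conductance(leaf_mol, meteo, site_params())
  expect_equal(agg_mol$gsw_m_s,
               0.2 / molar_density_air(25, site_params()$pressure))

  leaf_orphan <- leaf
  leaf_orphan$timestamp[1] <- as_clock_time("2021-07-09 10:00")
  expect_error(aggregate_leaf_conductance(leaf_orphan, meteo, site_params()),
               "concurrent meteorological record")
})

test_that("daylight window and radiation threshold are enforced independently", {
  hours <- 9:19
  day <- data.frame(
    timestamp = as_clock_time(sprintf("2021-07-08 %02d:00:00", hours)),
    rn_mj_m2_h = rep(2, 11)
  )
  kept <- daylight_radiation_filter(day)
  expect_identical(nrow(kept), 9L)  # 10:00-18:00 inclusive
  expect_identical(attr(kept, "dropped")$reason,
                   c("outside_window", "outside_window"))

  # low radiation inside the window is dropped with its own reason
  day$rn_mj_m2_h[4] <- 0.5  # 12:00
  kept2 <- daylight_radiation_filter(day)
  expect_identical(nrow(kept2), 8L)
  d <- attr(kept2, "dropped")
  expect_true("rn_below_min" %in% d$reason[format(d$timestamp, "%H") == "12"])

  # one minute before the window bound is out; the bound itself is in
  edge <- data.frame(
    timestamp = as_clock_time(c("2021-07-08 09:59", "2021-07-08 10:00",
                                "2021-07-08 18:00", "2021-07-08 18:01")),
    rn_mj_m2_h = 2
  )
  kept3 <- daylight_radiation_filter(edge)
  expect_identical(format(kept3$timestamp, "%H:%M"), c("10:00", "18:00"))

  # a record failing both criteria carries both reasons
  both <- data.frame(timestamp = as_clock_time("2021-07-08 08:00"),
                     rn_mj_m2_h = 0.1)
  expect_warning(kept4 <- daylight_radiation_filter(both), "all records")
  expect_identical(attr(kept4, "dropped")$reason, "outside_window,rn_below_min")

  # idempotence and the counting identity
  again <- daylight_radiation_filter(kept2)
  expect_identical(nrow(again), nrow(kept2))
  expect_identical(nrow(attr(again, "dropped")), 0L)
  expect_identical(nrow(kept2) + nrow(attr(kept2, "dropped")), nrow(day))
})

test_that("IQR mask matches a brute-force quartile oracle", {
  expect_identical(iqr_outlier_mask(c(1, 2, 3, 4, 5)), rep(FALSE, 5))
  expect_identical(iqr_outlier_mask(c(1, 2, 3, 4, 100)),
                   c(rep(FALSE, 4), TRUE))
  expect_identical(iqr_outlier_mask(rep(7, 6)), rep(FALSE, 6))
  expect_error(iqr_outlier_mask(c(1, 2, 3)), "insufficient data")
  expect_error(iqr_outlier_mask(c(1, 2, 3, 4), k = 0), "positive")

  set.seed(401)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    x <- sample(0:10, n, replace = TRUE)
    expect_identical(iqr_outlier_mask(x), oracle_iqr_mask(x),
                     label = paste("vector", paste(x, collapse = ",")))
  }
})

test_that("alignment joins on the configured cadence and reports misses", {
  day <- nine_hour_fixture()
  meteo <- day[c("timestamp", "t_air_c", "rh_pct", "rn_mj_m2_h", "u_m_s")]
  leaf_agg <- day[c("timestamp", "gsw_m_s")]
  flux <- day[c("timestamp", "ec_mm_h")]

  j <- align_records(meteo, leaf_agg, flux)
  expect_identical(nrow(j), 9L)
  expect_identical(attr(j, "unmatched"), character(0))

  expect_message(j2 <- align_records(meteo[-4, ], leaf_agg, flux),
                 "1 timestamp\\(s\\) unmatched")
  expect_identical(nrow(j2), 8L)
  expect_identical(length(attr(j2, "unmatched")), 1L)

  # minute-cadence meteorology averages into the hourly bins
  minutes <- as_clock_time("2021-07-08 10:00") + seq(0, 119) * 60
  m_min <- data.frame(timestamp = minutes,
                      t_air_c = rep(c(24, 26), each = 60) +
                        rep(c(-0.5, 0.5), 60),
                      rh_pct = 50, rn_mj_m2_h = 2, u_m_s = 2)
  two <- leaf_agg[1:2, ]
  two$timestamp <- as_clock_time(c("2021-07-08 10:00", "2021-07-08 11:00"))
  j3 <- align_records(m_min, two, data.frame(timestamp = two$timestamp,
                                             ec_mm_h = 0.2))
  expect_identical(nrow(j3), 2L)
  expect_equal(j3$t_air_c, c(24, 26))  # known within-hour means

  late <- flux
  late$timestamp <- late$timestamp + 86400 * 30
  expect_error(suppressMessages(align_records(meteo, leaf_agg, late)),
               "empty join")
})
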