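test_that("declination follows Cooper's formula and its solstice bounds", {
  # frozen from direct evaluation of 23.45*sin(2*pi*(284+n)/365)
  expect_within(solar_declination(81), 0, tol = 0.5)
  expect_within(solar_declination(172), 23.45, tol = 0.05)
  expect_within(solar_declination(355), -23.45, tol = 0.05)
  days <- 1:365
  expect_true(all(abs(solar_declination(days)) <= 23.45 + 1e-12))
  expect_error(solar_declination(0), "day_of_year")
  expect_error(solar_declination(366), "day_of_year")
})

test_that("zenith geometry: overhead sun, midnight clip, closed form", {
  expect_within(solar_cos_zenith(0, 0, 12), 1, tol = 1e-12)
  expect_equal(solar_cos_zenith(0, 0, 0), 0)
  expect_equal(solar_cos_zenith(36.8, 0, 12), cos(36.8 * pi / 180),
    tolerance = 1e-12
  )
  expect_error(solar_cos_zenith(91, 0, 12), "latitude")
})

test_that("extraterrestrial irradiance matches the orbital closed form", {
  expect_equal(solar_extraterrestrial(100, 0), 0)
  expect_equal(solar_extraterrestrial(1, 1),
    1367 * (1 + 0.033 * cos(2 * pi / 365)),
    tolerance = 1e-12
  )
  expect_equal(solar_extraterrestrial(182, 1),
    1367 * (1 + 0.033 * cos(2 * pi * 182 / 365)),
    tolerance = 1e-12
  )
  expect_error(solar_extraterrestrial(1, 1.5), "cos_zenith")
})

test_that("clearness index scales global irradiance between its limits", {
  hours <- seq(0, 24, by = 0.25)
  expect_true(all(solar_global(36.8, 0, 172, hours) == 0))
  g0 <- solar_extraterrestrial(
    172, solar_cos_zenith(36.8, solar_declination(172), hours)
  )
  expect_equal(solar_global(36.8, 1, 172, hours), g0, tolerance = 1e-12)
  expect_equal(solar_global(0, 0.8, 81, 12),
    0.8 * solar_extraterrestrial(81, solar_cos_zenith(0, solar_declination(81), 12)),
    tolerance = 1e-12
  )
  expect_error(solar_global(36.8, 1.2, 172, 12), "clearness")
})

test_that("Erbs split: identities, low-kt branch, monotone diffuse fraction", {
  z <- split_direct_diffuse(0, 0.5, 1)
  expect_equal(z$direct, 0)
  expect_equal(z$diffuse, 0)
  # low-kt branch: fd = 1 - 0.09 kt
  s <- split_direct_diffuse(100, 0.1, 1)
  expect_equal(s$diffuse / 100, 1 - 0.09 * 0.1, tolerance = 1e-12)
  # polynomial branch frozen from the correlation at kt = 0.5
  fd05 <- 0.9511 - 0.1604 * 0.5 + 4.388 * 0.25 - 16.638 * 0.125 +
    12.336 * 0.0625
  s5 <- split_direct_diffuse(100, 0.5, 1)
  expect_equal(s5$diffuse / 100, fd05, tolerance = 1e-12)
  # direct + diffuse = global everywhere; the diffuse fraction decreases
  # with clearness up to the correlation's minimum (near kt = 0.73; the
  # quartic turns up slightly before the constant clear-sky branch)
  kts <- seq(0.22, 0.80, by = 0.01)
  sp <- split_direct_diffuse(rep(500, length(kts)), kts, 1)
  expect_equal(sp$direct + sp$diffuse, rep(500, length(kts)),
    tolerance = 1e-12
  )
  expect_true(all(diff(sp$diffuse[kts <= 0.73]) <= 1e-9))
  expect_lt(sp$diffuse[length(kts)], sp$diffuse[1])
  # night forces both to zero
  night <- split_direct_diffuse(50, 0.5, 0)
  expect_equal(night$direct + night$diffuse, 0)
})

test_that("generated forcing satisfies the series invariants", {
  f <- generate_forcing(36.8, -2.4, 0.8, start_day = 172, n_days = 2,
    step = 300
  )
  expect_true(all(diff(f$time_s) > 0))
  expect_equal(max(f$time_s), 2 * 86400)
  expect_equal(f$global_Wm2, f$direct_Wm2 + f$diffuse_Wm2,
    tolerance = 1e-9
  )
  # night: sun below the horizon means zero irradiance
  hour <- (f$time_s %% 86400) / 3600
  night <- hour < 4 | hour > 20
  expect_true(all(f$global_Wm2[night] == 0))
  # argmax at solar noon (within one step)
  day1 <- f$time_s < 86400
  expect_within(hour[day1][which.max(f$global_Wm2[day1])], 12,
    tol = 300 / 3600
  )
  # day-to-day periodicity up to the slow declination drift
  m1 <- max(f$global_Wm2[day1])
  m2 <- max(f$global_Wm2[!day1])
  expect_lt(abs(m1 - m2) / m1, 0.01)
  # daily integral linear in kt by construction
  f4 <- generate_forcing(36.8, -2.4, 0.4, start_day = 172, n_days = 1,
    step = 300
  )
  f8 <- generate_forcing(36.8, -2.4, 0.8, start_day = 172, n_days = 1,
    step = 300
  )
  expect_equal(sum(f4$global_Wm2), 0.5 * sum(f8$global_Wm2),
    tolerance = 1e-12
  )
  # kt = 0: dark series
  f0 <- generate_forcing(36.8, -2.4, 0, start_day = 172, n_days = 1,
    step = 600
  )
  expect_true(all(f0$global_Wm2 == 0))
  # global never exceeds extraterrestrial
  g0 <- solar_extraterrestrial(
    172 + f$time_s %/% 86400,
    solar_cos_zenith(36.8, solar_declination(172 + f$time_s %/% 86400), hour)
  )
  expect_true(all(f$global_Wm2 <= g0 + 1e-9))
})

test_that("profile loading round-trips and rejects malformed files", {
  f <- generate_forcing(36.8, 0, 0.7, start_day = 100, n_days = 1, step = 600)
  csv <- tempfile(fileext = ".csv")
  writeLines("# recorded profile", csv)
  suppressWarnings(utils::write.table(
    data.frame(time_s = f$time_s, global_Wm2 = f$global_Wm2,
      ambient_C = f$ambient_C
    ),
    csv, sep = ",", row.names = FALSE, append = TRUE, quote = FALSE
  ))
  lp <- load_profile(csv, latitude = 36.8, start_day = 100)
  expect_equal(lp$global_Wm2, f$global_Wm2, tolerance = 1e-9)
  expect_equal(lp$ambient_C, f$ambient_C, tolerance = 1e-9)
  expect_equal(lp$global_Wm2, lp$direct_Wm2 + lp$diffuse_Wm2,
    tolerance = 1e-9
  )

  # two-row zero file is a valid all-dark hour
  z <- tempfile(fileext = ".csv")
  writeLines(c("time_s,global_Wm2", "0,0", "3600,0"), z)
  expect_true(all(load_profile(z)$global_Wm2 == 0))

  bad_t <- tempfile(fileext = ".csv")
  writeLines(c("time_s,global_Wm2", "0,100", "600,100", "300,50"), bad_t)
  expect_error(load_profile(bad_t), "strictly increasing at data row 3")

  bad_g <- tempfile(fileext = ".csv")
  writeLines(c("time_s,global_Wm2", "0,100", "600,-5"), bad_g)
  expect_error(load_profile(bad_g), "negative irradiance")

  bad_v <- tempfile(fileext = ".csv")
  writeLines(c("time_s,global_Wm2", "0,abc"), bad_v)
  expect_error(load_profile(bad_v), "unparsable|missing")

  bad_h <- tempfile(fileext = ".csv")
  writeLines(c("t,g", "0,1"), bad_h)
  expect_error(load_profile(bad_h), "header")
})
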