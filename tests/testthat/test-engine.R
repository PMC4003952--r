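test_that("a dead system stays exactly where it started", {
  cfg <- pbr_config(
    environment = list(clearness_index = 0),
    kinetics = list(respiration_rate = 0),
    chemistry = list(kla_o2 = 0, kla_co2 = 0),
    operation = list(air_flow_L_min = 0)
  )
  res <- run_simulation(cfg)
  expect_equal(diff(range(res$biomass_g_m3)), 0, tolerance = 1e-9)
  expect_equal(diff(range(res$ph_preinjection)), 0, tolerance = 1e-6)
  expect_true(all(res$irradiance_Wm2 == 0))
})

test_that("identical config gives byte-identical output files", {
  cfg <- pbr_config(simulation = list(duration_days = 0.02))
  f1 <- tempfile()
  f2 <- tempfile()
  write_timeseries(run_simulation(cfg), f1)
  write_timeseries(run_simulation(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("configuration validates, merges and round-trips", {
  # empty file: the full default plant
  empty <- tempfile()
  writeLines(character(0), empty)
  cfg <- read_config(empty)
  expect_equal(cfg$geometry$tube_length_m, 400)
  expect_equal(cfg$operation$velocity_m_s, 0.9)

  expect_error(pbr_config(geometry = list(tube_length_m = -1)), "positive")
  expect_error(pbr_config(nonsense = list(a = 1)), "unknown configuration")
  expect_error(pbr_config(control = list(ph = list(mode = "fuzzy"))), "mode")

  f <- tempfile()
  writeLines(c(
    "[geometry]",
    "tube_length_m = 250 # shorter demo loop",
    "n_elements = 25",
    "",
    "[control.ph]",
    'mode = "onoff"',
    "setpoint = 7.8",
    "",
    "[[harvest]]",
    "time_h = 10",
    "fraction = 0.25"
  ), f)
  cfg2 <- read_config(f)
  expect_equal(cfg2$geometry$tube_length_m, 250)
  expect_equal(cfg2$control$ph$mode, "onoff")
  expect_equal(cfg2$harvest$fraction, 0.25)

  # write -> read -> write is idempotent
  g1 <- tempfile()
  g2 <- tempfile()
  write_config(cfg2, g1)
  cfg3 <- read_config(g1)
  write_config(cfg3, g2)
  expect_identical(readLines(g1), readLines(g2))
  expect_equal(cfg3$control$ph$setpoint, 7.8)

  bad <- tempfile()
  writeLines(c("[geometry]", "tube_length_m = banana"), bad)
  expect_error(read_config(bad), "cannot parse")
  orphan <- tempfile()
  writeLines("x = 1", orphan)
  expect_error(read_config(orphan), "outside any section")
})

test_that("time-series files round-trip through CSV", {
  res <- run_simulation(pbr_config(simulation = list(duration_days = 0.01)))
  f <- tempfile(fileext = ".csv")
  write_timeseries(res, f)
  back <- read_timeseries(f)
  expect_equal(ncol(back), 30)
  expect_identical(names(back), names(res))
  for (cn in names(res)) {
    expect_equal(back[[cn]], res[[cn]], tolerance = 1e-10)
  }
  # metadata lines present
  expect_true(any(grepl("^# config_hash", readLines(f))))
})

test_that("conservation audits close on the reference day", {
  aud <- check_audits(run_manual_steps())
  expect_true(all(aud$rel_mismatch < 1e-6))
  aud0 <- check_audits(run_default_day())
  expect_true(all(aud0$rel_mismatch < 1e-6))
})

test_that("halving the time step moves the end of day by < 0.5 %", {
  ref <- run_default_day()
  fine <- run_simulation(pbr_config(
    simulation = list(dt_s = 0.5, output_stride = 120)
  ))
  last <- nrow(ref)
  for (v in c("ph_preinjection", "biomass_g_m3", "temp_column_C")) {
    expect_equal(fine[[v]][nrow(fine)], ref[[v]][last],
      tolerance = 5e-3
    )
  }
})

test_that("doubling the loop resolution moves the end of day by < 1 %", {
  ref <- run_default_day()
  fine <- run_simulation(pbr_config(geometry = list(n_elements = 100)))
  for (v in c("ph_preinjection", "biomass_g_m3")) {
    expect_equal(fine[[v]][nrow(fine)], ref[[v]][nrow(ref)],
      tolerance = 1e-2
    )
  }
})

test_that("a single-element loop degenerates to a mixed tank and still runs", {
  cfg <- pbr_config(
    geometry = list(n_elements = 1),
    simulation = list(duration_days = 0.05)
  )
  res <- run_simulation(cfg)
  expect_equal(nrow(res), 72)
  expect_true(all(check_audits(res)$rel_mismatch < 1e-6))
})

test_that("fixture generation is seeded and self-consistent", {
  f1 <- tempfile()
  f2 <- tempfile()
  generate_fixtures("noisy_radiation", f1, seed = 7)
  generate_fixtures("noisy_radiation", f2, seed = 7)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile()
  generate_fixtures("noisy_radiation", f3, seed = 8)
  expect_false(identical(readLines(f1), readLines(f3)))
  # zero noise reproduces the clean model radiation
  clean <- tempfile()
  noise0 <- tempfile()
  generate_fixtures("radiation", clean)
  generate_fixtures("noisy_radiation", noise0, noise_sd = 0)
  expect_identical(read.csv(clean, comment.char = "#"),
    read.csv(noise0, comment.char = "#")
  )
  # generated profiles pass the loader's validation
  lp <- load_profile(f1, latitude = 36.8, start_day = 172)
  expect_true(all(lp$global_Wm2 >= 0))
  expect_equal(lp$global_Wm2, lp$direct_Wm2 + lp$diffuse_Wm2,
    tolerance = 1e-9
  )
  st <- tempfile()
  generate_fixtures("step_test", st)
  expect_equal(nrow(read.csv(st, comment.char = "#")), 5)
})

test_that("the CLI runs, writes output, and signals usage errors", {
  withr::with_tempdir({
    writeLines(c("[simulation]", "duration_days = 0.01"), "cfg.toml")
    out <- capture.output(
      code <- pbr_cli(c("run", "--config", "cfg.toml", "--out", "run.csv"))
    )
    expect_equal(code, 0L)
    expect_true(file.exists("run.csv"))
    expect_true(any(grepl("resolved configuration", out)))

    capture.output(
      code2 <- pbr_cli(c("profile", "--kt", "0", "--day", "81",
        "--out", "dark.csv"
      ))
    )
    expect_equal(code2, 0L)
    expect_true(all(read.csv("dark.csv")$global_Wm2 == 0))

    expect_equal(suppressMessages(pbr_cli(c("run", "--bogus", "1"))), 2L)
    expect_gt(length(capture.output(pbr_cli(character(0)))), 0)
  })
})
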