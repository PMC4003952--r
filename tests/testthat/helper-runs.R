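# Full-day reference runs are expensive (~15 s each); cache them once per
# test session and share across files.
.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, make_cfg) {
  if (is.null(.run_cache[[name]])) {
    .run_cache[[name]] <- run_simulation(make_cfg())
  }
  .run_cache[[name]]
}

run_default_day <- function() {
  cached_run("default", pbr_config)
}

run_manual_steps <- function() {
  cached_run("manual", function() co2_step_scenario("manual"))
}

run_pi_time <- function() {
  cached_run("pi_time", function() co2_step_scenario("pi_time"))
}

run_pi_event <- function() {
  cached_run("pi_event", function() co2_step_scenario("pi_event"))
}

# First-order test plant dy/dt = (K u - y) / tau, explicit Euler.
make_test_plant <- function(K = 2, tau = 50, y0 = 0) {
  y <- y0
  function(u, dt) {
    y <<- y + dt * (K * u - y) / tau
    y
  }
}

# Absolute-band comparison (testthat 3e's expect_equal tolerance is
# relative); reads as |object - expected| <= tol.
expect_within <- function(object, expected, tol) {
  expect_lte(max(abs(object - expected)), tol)
}
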