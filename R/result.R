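# Polynomial rolling hash of a character vector; stamps outputs with a
# config fingerprint without external dependencies (not cryptographic).
config_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 0
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write a simulation result to CSV
#'
#' Fixed column order, '.' decimal, one unit-bearing header row, and
#' '#'-prefixed metadata lines (package version, seed, config hash).
#'
#' @param result A `pbr_result` from [run_simulation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  cfg <- attr(result, "config")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  meta <- c(
    sprintf("# pbrsim %s", as.character(utils::packageVersion("pbrsim"))),
    sprintf("# seed: %d", cfg$simulation$seed),
    sprintf("# config_hash: %s", config_hash(readLines(tmp)))
  )
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(meta, con)
  utils::write.table(as.data.frame(result), con,
    sep = ",", dec = ".",
    row.names = FALSE, col.names = TRUE, quote = FALSE
  )
  invisible(path)
}

#' Read back a result CSV
#'
#' @param path File written by [write_timeseries()].
#' @return data.frame of the logged series (metadata lines skipped).
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' @export
print.pbr_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "<pbr_result> %d logged steps over %.3g day(s), dt = %g s, N = %d\n",
    nrow(x), cfg$simulation$duration_days, cfg$simulation$dt_s,
    cfg$geometry$n_elements
  ))
  cat(sprintf(
    "  final pH (pre-injection) %.3f | biomass %.1f g/m3 | dO2 %.3f mol/m3\n",
    x$ph_preinjection[nrow(x)], x$biomass_g_m3[nrow(x)],
    x$do2_column_mol_m3[nrow(x)]
  ))
  invisible(x)
}

#' Plot the main variables of a simulation result
#'
#' @param x A `pbr_result`.
#' @param vars Character vector of columns to plot against time (hours).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pbr_result <- function(x, vars = c("irradiance_Wm2", "ph_preinjection",
                                        "do2_column_mol_m3", "biomass_g_m3"),
                            ...) {
  vars <- intersect(vars, names(x))
  old <- graphics::par(mfrow = c(length(vars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    graphics::plot(x$time_h, x[[v]], type = "l", xlab = "time (h)",
      ylab = v, ...
    )
  }
  invisible(x)
}

#' Settling time of a logged series
#'
#' First time the series enters and thereafter remains within `band` of its
#' final value (the mean over the trailing `final_window_h` hours).
#'
#' @param result A `pbr_result` (or any data.frame with `time_h`).
#' @param var Column name.
#' @param band Half-width of the settling band, units of `var`.
#' @param final_window_h Trailing window defining the final value, hours.
#' @param from_h Ignore the series before this time (default 0).
#' @return List with `final` (the settled value) and `settling_h` (NA when
#'   the series never settles).
#' @export
settling_time <- function(result, var = "ph_preinjection", band = 0.05,
                          final_window_h = 1, from_h = 0) {
  t <- result$time_h
  y <- result[[var]]
  keep <- t >= from_h
  t <- t[keep]
  y <- y[keep]
  final <- mean(y[t >= max(t) - final_window_h])
  inside <- abs(y - final) <= band
  # last excursion outside the band decides the settling instant
  out_idx <- which(!inside)
  settling <- if (length(out_idx) == 0) {
    t[1]
  } else if (max(out_idx) == length(y)) {
    NA_real_
  } else {
    t[max(out_idx) + 1L]
  }
  list(final = final, settling_h = settling)
}
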