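#' Photobioreactor geometry
#'
#' Fence-type tubular plant: a solar-receiver loop (tube) discretised into
#' `n_elements` perfectly mixed differential elements, and a bubble column
#' (mixing/degassing unit). Derived volumes and areas are attached.
#'
#' @param tube_length_m Loop tube length, m (default the 400 m plant).
#' @param tube_diameter_m Tube inner diameter, m.
#' @param column_height_m Bubble column height, m.
#' @param column_diameter_m Bubble column diameter, m.
#' @param n_elements Number of plug-flow differential elements (>= 1).
#' @param liquid_fraction_column Fraction of the column volume holding
#'   liquid.
#' @param gas_fraction_column Fraction of the column volume holding gas
#'   (sparged air holdup).
#' @return List of class `pbr_geometry` with derived fields: `a_tube`
#'   (cross-section, m2), `dx` (element length, m), `v_elem`, `v_loop`,
#'   `v_column_liq`, `v_column_gas` (m3), `n_gas_mol` (column gas holdup at
#'   1 atm, 25 C).
#' @export
pbr_geometry <- function(tube_length_m = 400, tube_diameter_m = 0.09,
                         column_height_m = 3.5, column_diameter_m = 0.4,
                         n_elements = 50L,
                         liquid_fraction_column = 0.9,
                         gas_fraction_column = 0.1) {
  vals <- c(tube_length_m, tube_diameter_m, column_height_m,
            column_diameter_m, n_elements, liquid_fraction_column)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry values must be positive and finite", call. = FALSE)
  }
  if (liquid_fraction_column > 1) {
    stop("`liquid_fraction_column` must be in (0, 1]", call. = FALSE)
  }
  n_elements <- as.integer(n_elements)
  a_tube <- pi * (tube_diameter_m / 2)^2
  v_col <- pi * (column_diameter_m / 2)^2 * column_height_m
  v_gas <- gas_fraction_column * v_col
  structure(
    list(
      tube_length_m = tube_length_m, tube_diameter_m = tube_diameter_m,
      column_height_m = column_height_m, column_diameter_m = column_diameter_m,
      n_elements = n_elements,
      liquid_fraction_column = liquid_fraction_column,
      gas_fraction_column = gas_fraction_column,
      a_tube = a_tube,
      dx = tube_length_m / n_elements,
      v_elem = a_tube * tube_length_m / n_elements,
      v_loop = a_tube * tube_length_m,
      v_column_liq = liquid_fraction_column * v_col,
      v_column_gas = v_gas,
      n_gas_mol = v_gas * 1000 / GAS_MOLAR_VOLUME_L
    ),
    class = "pbr_geometry"
  )
}

#' Growth-kinetics parameter set
#'
#' Photosynthetic O2 evolution follows a Hill-type light response on the
#' Beer-Lambert average irradiance, multiplied by a clipped dissolved-oxygen
#' inhibition factor, minus a constant dark respiration. The default values
#' are calibration constants of this simulator (they are not literature
#' measurements) and can all be overridden in the configuration.
#'
#' @param r_o2_max Maximum specific O2 evolution rate, mol O2/(g s).
#' @param i_half Half-saturation average irradiance, W/m2.
#' @param hill_n Hill exponent of the light response.
#' @param o2_inhibition_conc Dissolved O2 at which photosynthesis is fully
#'   inhibited, mol/m3.
#' @param inhibition_exponent Exponent of the inhibition term.
#' @param extinction_coeff Biomass extinction coefficient `Ka`, m2/g.
#' @param yield_x_per_o2 Biomass yield on evolved O2, g/mol.
#' @param photosynthetic_quotient Mol O2 evolved per mol CO2 fixed.
#' @param respiration_rate Dark specific O2 uptake, mol O2/(g s).
#' @param column_light_factor Fraction of surface irradiance reaching the
#'   column culture (0 = dark column, the default: photosynthesis happens in
#'   the solar receiver).
#' @return List of class `pbr_kinetics`.
#' @export
kinetic_params <- function(r_o2_max = 2.14e-7, i_half = 280, hill_n = 2,
                           o2_inhibition_conc = 0.95,
                           inhibition_exponent = 4,
                           extinction_coeff = 0.06,
                           yield_x_per_o2 = 26,
                           photosynthetic_quotient = 1,
                           respiration_rate = 2e-8,
                           column_light_factor = 0) {
  vals <- c(r_o2_max, i_half, hill_n, o2_inhibition_conc,
            inhibition_exponent, extinction_coeff, yield_x_per_o2,
            photosynthetic_quotient)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("kinetic parameters must be positive and finite", call. = FALSE)
  }
  if (respiration_rate < 0) stop("respiration_rate must be >= 0", call. = FALSE)
  structure(
    list(
      r_o2_max = r_o2_max, i_half = i_half, hill_n = hill_n,
      o2_inhibition_conc = o2_inhibition_conc,
      inhibition_exponent = inhibition_exponent,
      extinction_coeff = extinction_coeff,
      yield_x_per_o2 = yield_x_per_o2,
      photosynthetic_quotient = photosynthetic_quotient,
      respiration_rate = respiration_rate,
      column_light_factor = column_light_factor
    ),
    class = "pbr_kinetics"
  )
}

#' Beer-Lambert average irradiance inside the culture
#'
#' Irradiance averaged over a light path `p` through a culture of biomass
#' `Cb` with extinction coefficient `Ka`:
#' `Iav = I0 (1 - exp(-Ka Cb p)) / (Ka Cb p)`, with the transparent-culture
#' limit `Iav -> I0` handled analytically. The light path is the tube
#' diameter.
#'
#' @param surface_irradiance `I0`, W/m2 (vectorised).
#' @param biomass `Cb`, g/m3 (vectorised).
#' @param extinction_coeff `Ka`, m2/g.
#' @param light_path `p`, m.
#' @return Average irradiance in `[0, I0]`, W/m2.
#' @export
average_irradiance <- function(surface_irradiance, biomass,
                               extinction_coeff, light_path) {
  if (any(surface_irradiance < 0) || any(biomass < 0) ||
      extinction_coeff < 0 || light_path < 0) {
    stop("average_irradiance inputs must be >= 0", call. = FALSE)
  }
  x <- extinction_coeff * biomass * light_path
  fac <- ifelse(x < 1e-8, 1 - x / 2, (1 - exp(-x)) / pmax(x, 1e-300))
  surface_irradiance * fac
}

#' Volumetric photosynthetic O2 rate
#'
#' `R = Cb r_max I^n/(i_half^n + I^n) max(0, 1 - (dO2/o2_inh)^m) - Cb r_resp`.
#' The net rate is negative in the dark when respiration is enabled.
#'
#' @param i_av Average irradiance, W/m2 (vectorised).
#' @param dissolved_o2 Dissolved O2, mol/m3 (vectorised).
#' @param biomass `Cb`, g/m3 (vectorised).
#' @param kin A [kinetic_params()] object.
#' @return List with `gross` (light-driven term, >= 0), `net`
#'   (gross - respiration), both mol O2/(m3 s).
#' @export
photosynthesis_o2_rate <- function(i_av, dissolved_o2, biomass, kin) {
  if (any(i_av < 0) || any(dissolved_o2 < 0)) {
    stop("`i_av` and `dissolved_o2` must be >= 0", call. = FALSE)
  }
  light <- i_av^kin$hill_n / (kin$i_half^kin$hill_n + i_av^kin$hill_n)
  inhib <- pmax(0, 1 - (dissolved_o2 / kin$o2_inhibition_conc)^
                  kin$inhibition_exponent)
  gross <- biomass * kin$r_o2_max * light * inhib
  list(gross = gross, net = gross - biomass * kin$respiration_rate)
}

#' Biomass growth rate from O2 evolution
#'
#' Growth is taken directly proportional to the gross photosynthetic rate,
#' `dCb/dt = yield_x_per_o2 * gross`; dark respiration does not erode
#' biomass unless `dark_decay` is enabled, in which case a negative net rate
#' is converted with the same yield.
#'
#' @param o2_rates The list returned by [photosynthesis_o2_rate()].
#' @param kin A [kinetic_params()] object.
#' @param dark_decay Logical; convert negative net rates into biomass loss.
#' @return Biomass rate, g/(m3 s).
#' @export
biomass_rate <- function(o2_rates, kin, dark_decay = FALSE) {
  r <- if (dark_decay) pmin(o2_rates$net, o2_rates$gross) else o2_rates$gross
  kin$yield_x_per_o2 * r
}

#' Time derivatives of the bubble-column state
#'
#' The column is a perfectly mixed tank in both phases: the liquid balance
#' combines advection (loop return in, column exit out), gas-liquid transfer
#' for O2 and CO2, and (dark-column default) respiration; the gas balances
#' track O2 and CO2 mole fractions under a constant molar holdup with a
#' quasi-steady vent flow `F_out = F_in + net transfer`, so the vented
#' composition equals the holdup composition.
#'
#' @param state List with `biomass`, `dissolved_o2`, `total_inorganic_carbon`
#'   (mol/m3; biomass g/m3), `gas_y_o2`, `gas_y_co2`.
#' @param loop_return State list of the last loop element entering the column
#'   (same liquid fields).
#' @param liquid_flow Culture circulation flow, m3/s.
#' @param air_flow_L_min Air sparged into the column, L/min.
#' @param irradiance Surface irradiance on the column, W/m2 (scaled by the
#'   kinetics' `column_light_factor`).
#' @param geom,kin,chem Parameter objects.
#' @param air_y_o2,air_y_co2 Inlet air composition (mole fractions).
#' @return List of derivatives (`d_biomass`, `d_o2`, `d_ct`, `d_y_o2`,
#'   `d_y_co2`) plus diagnostic flows: `transfer_o2`, `transfer_co2`
#'   (mol/(m3 s) into the liquid), `vent_o2`, `vent_co2`, `f_out` (mol/s),
#'   and the liquid-phase pH speciation at the column (`ph`).
#' @export
column_derivatives <- function(state, loop_return, liquid_flow,
                               air_flow_L_min, irradiance, geom, kin, chem,
                               air_y_o2 = 0.2095, air_y_co2 = 4.2e-4) {
  if (liquid_flow < 0 || air_flow_L_min < 0) {
    stop("flows must be >= 0", call. = FALSE)
  }
  v <- geom$v_column_liq
  sp <- ph_from_carbonate(state$total_inorganic_carbon, chem)
  # photosynthesis (column is dark by default: column_light_factor = 0)
  i_av <- average_irradiance(irradiance * kin$column_light_factor,
    state$biomass, kin$extinction_coeff, geom$column_diameter_m
  )
  rates <- photosynthesis_o2_rate(i_av, state$dissolved_o2, state$biomass, kin)
  transfer_o2 <- gas_liquid_transfer(chem$kla_o2,
    chem$henry_o2 * state$gas_y_o2, state$dissolved_o2
  )
  transfer_co2 <- gas_liquid_transfer(chem$kla_co2,
    chem$henry_co2 * state$gas_y_co2, sp$co2_aq
  )
  adv <- liquid_flow / v
  d_biomass <- adv * (loop_return$biomass - state$biomass) +
    biomass_rate(rates, kin)
  d_o2 <- adv * (loop_return$dissolved_o2 - state$dissolved_o2) +
    rates$net + transfer_o2
  d_ct <- adv * (loop_return$total_inorganic_carbon -
                   state$total_inorganic_carbon) -
    rates$net / kin$photosynthetic_quotient + transfer_co2
  # gas phase: constant holdup, quasi-steady vent
  f_in <- air_flow_L_min / GAS_MOLAR_VOLUME_L / 60
  s_o2 <- -transfer_o2 * v # mol/s into the gas
  s_co2 <- -transfer_co2 * v
  f_out <- max(f_in + s_o2 + s_co2, 0)
  d_y_o2 <- (f_in * air_y_o2 - f_out * state$gas_y_o2 + s_o2) / geom$n_gas_mol
  d_y_co2 <- (f_in * air_y_co2 - f_out * state$gas_y_co2 + s_co2) /
    geom$n_gas_mol
  list(
    d_biomass = d_biomass, d_o2 = d_o2, d_ct = d_ct,
    d_y_o2 = d_y_o2, d_y_co2 = d_y_co2,
    transfer_o2 = transfer_o2, transfer_co2 = transfer_co2,
    vent_o2 = f_out * state$gas_y_o2, vent_co2 = f_out * state$gas_y_co2,
    f_in = f_in, f_out = f_out, ph = sp$ph
  )
}

#' Time derivatives of the plug-flow loop elements
#'
#' The solar receiver is a plug-flow reactor discretised into `n_elements`
#' perfectly mixed elements chained by first-order upwind advection; element
#' 1 is fed by the column exit plus the CO2 injection, the last element feeds
#' the column. Each element adds local photosynthesis on its own average
#' irradiance; the closed tube has no gas exchange, so photosynthetic O2
#' accumulates along the loop until it is stripped in the column.
#'
#' @param elements List of numeric vectors `biomass`, `dissolved_o2`,
#'   `total_inorganic_carbon` of length `n_elements`.
#' @param velocity Culture velocity in the tube, m/s (>= 0).
#' @param column_exit State list of the column liquid feeding element 1.
#' @param injection_rate Dissolved CO2 molar rate added to element 1, mol/s.
#' @param irradiance Surface irradiance on the loop, W/m2.
#' @param geom,kin Parameter objects.
#' @param dt Intended integration step, s; used only to check the advective
#'   CFL bound.
#' @return List of per-element derivative vectors `d_biomass`, `d_o2`,
#'   `d_ct`, plus `gross_o2` (mol/(m3 s)).
#' @export
loop_derivatives <- function(elements, velocity, column_exit, injection_rate,
                             irradiance, geom, kin, dt = NULL) {
  if (velocity < 0) stop("`velocity` must be >= 0", call. = FALSE)
  if (!is.null(dt)) {
    cfl <- velocity * dt / geom$dx
    if (cfl > 1) {
      stop(sprintf(
        "advective CFL %.2f > 1; use dt <= %.3g s or sub-step",
        cfl, geom$dx / velocity
      ), call. = FALSE)
    }
  }
  n <- geom$n_elements
  i_av <- average_irradiance(irradiance, elements$biomass,
    kin$extinction_coeff, geom$tube_diameter_m
  )
  rates <- photosynthesis_o2_rate(i_av, elements$dissolved_o2,
    elements$biomass, kin
  )
  a <- velocity / geom$dx # advection rate 1/s
  up <- function(x, inlet) c(inlet, x[-n])
  d_biomass <- a * (up(elements$biomass, column_exit$biomass) -
                      elements$biomass) + biomass_rate(rates, kin)
  d_o2 <- a * (up(elements$dissolved_o2, column_exit$dissolved_o2) -
                 elements$dissolved_o2) + rates$net
  d_ct <- a * (up(elements$total_inorganic_carbon,
                  column_exit$total_inorganic_carbon) -
                 elements$total_inorganic_carbon) -
    rates$net / kin$photosynthetic_quotient
  d_ct[1] <- d_ct[1] + injection_rate / geom$v_elem
  list(d_biomass = d_biomass, d_o2 = d_o2, d_ct = d_ct,
       gross_o2 = rates$gross)
}
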