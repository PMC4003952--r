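#' Carbonate chemistry parameter set
#'
#' Dissociation constants are given as pK values on the mol/L scale and
#' converted internally to the mol/m3 working scale (K1' = K1 * 1e3,
#' Kw' = Kw * 1e6). Alkalinity is fixed over a run: the medium's acid
#' neutralising capacity, dominated here by bicarbonate added with the
#' growth medium.
#'
#' @param pk1,pk2 First and second carbonate dissociation pK (mol/L scale).
#' @param pkw Water ion-product pK (mol/L scale).
#' @param alkalinity_mol_m3 Total alkalinity, mol/m3 (= meq/L).
#' @param henry_o2,henry_co2 Saturation concentration per unit mole fraction
#'   at 1 atm, mol/m3.
#' @param kla_o2,kla_co2 Volumetric gas-liquid transfer coefficients in the
#'   bubble column, 1/s.
#' @param co2_absorption_eff Fraction of injected CO2 that dissolves; the
#'   rest is reported as CO2 losses.
#' @return A list of class `pbr_chemistry` with the mol/m3-scale constants
#'   `k1`, `k2`, `kw` added.
#' @export
chemistry_params <- function(pk1 = 6.35, pk2 = 10.33, pkw = 14,
                             alkalinity_mol_m3 = 13,
                             henry_o2 = 1.3, henry_co2 = 34,
                             kla_o2 = 0.02, kla_co2 = 0.021,
                             co2_absorption_eff = 0.9) {
  k1 <- 10^(-pk1) * 1e3
  k2 <- 10^(-pk2) * 1e3
  kw <- 10^(-pkw) * 1e6
  if (!(k1 > k2 && k2 > 0)) stop("need k1 > k2 > 0", call. = FALSE)
  if (kla_o2 < 0 || kla_co2 < 0) stop("kla must be >= 0", call. = FALSE)
  if (alkalinity_mol_m3 <= 0) stop("alkalinity must be > 0", call. = FALSE)
  if (co2_absorption_eff < 0 || co2_absorption_eff > 1) {
    stop("co2_absorption_eff must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      pk1 = pk1, pk2 = pk2, pkw = pkw,
      k1 = k1, k2 = k2, kw = kw,
      alkalinity = alkalinity_mol_m3,
      henry_o2 = henry_o2, henry_co2 = henry_co2,
      kla_o2 = kla_o2, kla_co2 = kla_co2,
      co2_absorption_eff = co2_absorption_eff
    ),
    class = "pbr_chemistry"
  )
}

# Charge-balance residual Alk - (HCO3 + 2 CO3 + OH - H) as a function of
# [H+] in mol/m3. Vectorised over h and ct.
carbonate_residual <- function(h, ct, chem) {
  d <- h * h + chem$k1 * h + chem$k1 * chem$k2
  hco3 <- ct * chem$k1 * h / d
  co3 <- ct * chem$k1 * chem$k2 / d
  hco3 + 2 * co3 + chem$kw / h - h - chem$alkalinity
}

#' Solve culture pH from total inorganic carbon and alkalinity
#'
#' Solves the charge balance
#' `Alk = [HCO3-] + 2 [CO3 2-] + [OH-] - [H+]` for `[H+]`, with the carbonate
#' fractions the usual functions of `[H+]`, `K1`, `K2` and the species summing
#' to the total inorganic carbon `CT`. Bisection bracketed on pH in `[2, 12]`,
#' run to a residual below 1e-10 mol/m3 (and machine precision on pH).
#'
#' @param total_inorganic_carbon `CT` >= 0, mol/m3 (vectorised).
#' @param chem A [chemistry_params()] object.
#' @return A data.frame with columns `ph`, `co2_aq`, `hco3`, `co3` (mol/m3).
#' @examples
#' chem <- chemistry_params()
#' ph_from_carbonate(13, chem)
#' @export
ph_from_carbonate <- function(total_inorganic_carbon, chem) {
  ct <- total_inorganic_carbon
  if (any(ct < 0)) stop("`total_inorganic_carbon` must be >= 0", call. = FALSE)
  lo <- rep_len(2, length(ct)) # pH bounds
  hi <- rep_len(12, length(ct))
  f_lo <- carbonate_residual(10^(3 - lo), ct, chem)
  f_hi <- carbonate_residual(10^(3 - hi), ct, chem)
  # residual is increasing in pH (decreasing in [H+])
  if (any(f_lo > 0) || any(f_hi < 0)) {
    stop("pH solution outside bracket [2, 12]; check alkalinity/CT config",
      call. = FALSE
    )
  }
  for (i in 1:60) {
    mid <- 0.5 * (lo + hi)
    f_mid <- carbonate_residual(10^(3 - mid), ct, chem)
    up <- f_mid < 0
    lo <- ifelse(up, mid, lo)
    hi <- ifelse(up, hi, mid)
  }
  ph <- 0.5 * (lo + hi)
  h <- 10^(3 - ph)
  d <- h * h + chem$k1 * h + chem$k1 * chem$k2
  data.frame(
    ph = ph,
    co2_aq = ct * h * h / d,
    hco3 = ct * chem$k1 * h / d,
    co3 = ct * chem$k1 * chem$k2 / d
  )
}

#' Total inorganic carbon that gives a target pH
#'
#' Inverse of [ph_from_carbonate()] at fixed alkalinity; closed form, since at
#' given `[H+]` the charge balance is linear in `CT`.
#'
#' @param ph Target pH (vectorised).
#' @param chem A [chemistry_params()] object.
#' @return `CT` in mol/m3.
#' @export
ct_from_ph <- function(ph, chem) {
  h <- 10^(3 - ph)
  d <- h * h + chem$k1 * h + chem$k1 * chem$k2
  frac <- (chem$k1 * h + 2 * chem$k1 * chem$k2) / d
  ct <- (chem$alkalinity - chem$kw / h + h) / frac
  if (any(ct < 0)) stop("no non-negative CT reaches this pH", call. = FALSE)
  ct
}

# Warm-started Newton update for [H+] given CT; used in the engine's inner
# loop where the previous step's h is an excellent starting point. Falls back
# to full bisection if Newton leaves the bracket.
carbonate_h_newton <- function(h, ct, chem, iters = 3L) {
  k1 <- chem$k1
  k2 <- chem$k2
  kw <- chem$kw
  alk <- chem$alkalinity
  for (i in seq_len(iters)) {
    d <- h * h + k1 * h + k1 * k2
    num <- k1 * h + 2 * k1 * k2
    f <- ct * num / d + kw / h - h - alk
    dd <- 2 * h + k1
    fp <- ct * (k1 * d - num * dd) / (d * d) - kw / (h * h) - 1
    h_new <- h - f / fp
    if (!is.finite(h_new) || h_new <= 1e-9 || h_new >= 10) {
      return(10^(3 - ph_from_carbonate(ct, chem)$ph))
    }
    h <- h_new
  }
  h
}

#' Gas-liquid transfer rate
#'
#' Linear two-film rate `kla * (C* - C)`, positive when the species is
#' absorbed into the liquid. The saturation concentration is
#' `C* = henry * y` for gas mole fraction `y` at 1 atm.
#'
#' @param kla Volumetric transfer coefficient, 1/s (>= 0).
#' @param saturation_conc `C*`, mol/m3.
#' @param dissolved Current dissolved concentration `C`, mol/m3.
#' @return Transfer rate into the liquid, mol/(m3 s).
#' @export
gas_liquid_transfer <- function(kla, saturation_conc, dissolved) {
  if (any(kla < 0)) stop("`kla` must be >= 0", call. = FALSE)
  kla * (saturation_conc - dissolved)
}

#' Molar rate of CO2 dissolution from the injection valve
#'
#' Converts the valve command into a molar flow at 1 atm, 25 C
#' (24.465 L/mol). The absorbed fraction enters the culture's inorganic
#' carbon pool at the injection point; the rest is reported as CO2 losses.
#'
#' @param valve_command Valve opening in `[0, 1]`.
#' @param max_flow_L_min Full-open CO2 flow, L/min.
#' @param absorption_efficiency Fraction absorbed, `[0, 1]`.
#' @return List with `supplied`, `dissolved`, `losses` (all mol/s).
#' @examples
#' co2_injection_flow(1, 5, 1)$supplied # about 3.41e-3 mol/s
#' @export
co2_injection_flow <- function(valve_command, max_flow_L_min,
                               absorption_efficiency = 1) {
  if (any(valve_command < 0 | valve_command > 1)) {
    stop("`valve_command` must be in [0, 1]", call. = FALSE)
  }
  supplied <- valve_command * max_flow_L_min / 24.465 / 60
  dissolved <- supplied * absorption_efficiency
  list(supplied = supplied, dissolved = dissolved,
       losses = supplied - dissolved)
}

# Molar volume (L/mol) at 1 atm, 25 C used for all gas-flow conversions.
GAS_MOLAR_VOLUME_L <- 24.465
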