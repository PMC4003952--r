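#' Ideal instantaneous harvest
#'
#' User-triggered ideal harvesting: a fraction `f` of the biomass is removed
#' from every liquid compartment simultaneously and replaced by fresh medium
#' at constant volume, so biomass becomes `(1 - f) * Cb` and every other
#' liquid species is diluted to `(1 - f) * old + f * medium`.
#'
#' @param loop List of loop element vectors (`biomass`, `dissolved_o2`,
#'   `total_inorganic_carbon`).
#' @param column Column liquid state list (same fields).
#' @param fraction Harvested fraction `f` in `[0, 1]`.
#' @param medium Fresh-medium composition: list with `total_inorganic_carbon`
#'   and `dissolved_o2` (mol/m3). Fresh medium carries no biomass.
#' @param geom A [pbr_geometry()] object (for the compartment volumes).
#' @return List with updated `loop`, `column` and `harvested_biomass_g`,
#'   the biomass mass removed.
#' @export
apply_harvest <- function(loop, column, fraction, medium, geom) {
  if (fraction < 0 || fraction > 1) {
    stop("harvest `fraction` must be in [0, 1]", call. = FALSE)
  }
  keep <- 1 - fraction
  harvested <- fraction * (sum(loop$biomass) * geom$v_elem +
                             column$biomass * geom$v_column_liq)
  loop$biomass <- keep * loop$biomass
  column$biomass <- keep * column$biomass
  for (f in c("dissolved_o2", "total_inorganic_carbon")) {
    loop[[f]] <- keep * loop[[f]] + fraction * medium[[f]]
    column[[f]] <- keep * column[[f]] + fraction * medium[[f]]
  }
  list(loop = loop, column = column, harvested_biomass_g = harvested)
}
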