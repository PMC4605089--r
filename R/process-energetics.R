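# Process energetics of HTL: sensible heat demand of the reactor slurry
# under a constant-heat-capacity model, critical points of water-alcohol
# binary solvents, and the chemical-energy balance over the product slate.

#' Slurry heating specification
#'
#' Describes a biomass-water slurry to be heated from ambient to reaction
#' temperature.  The default constants (water cp 4.18 and solids cp
#' 2.0 kJ kg-1 K-1, density 1000 kg m-3, ambient 25 degrees C) define a
#' deliberately simple constant-cp model; saturated-liquid steam-table
#' enthalpies overshoot typical literature sensible-heat figures by more
#' than 10 %, so the constant-cp form is the package default and every
#' constant is overridable.
#'
#' @param solids_mass_frac Solids mass fraction of the slurry (0 to 1).
#' @param t_target_c Reaction temperature, degrees C.
#' @param t_initial_c Starting temperature, degrees C (default 25).
#' @param cp_water,cp_solids Specific heats, kJ kg-1 K-1.
#' @param density_kg_m3 Slurry density, kg m-3.
#' @return An object of class `slurry_spec`.
#' @export
slurry_spec <- function(solids_mass_frac, t_target_c, t_initial_c = 25,
                        cp_water = 4.18, cp_solids = 2.0,
                        density_kg_m3 = 1000) {
  check_num(solids_mass_frac, "solids_mass_frac", 0, 1)
  check_num(t_initial_c, "t_initial_c")
  check_num(t_target_c, "t_target_c")
  if (t_target_c < t_initial_c)
    stop_domain("t_target_c must be >= t_initial_c")
  check_num(cp_water, "cp_water", 1e-12)
  check_num(cp_solids, "cp_solids", 1e-12)
  check_num(density_kg_m3, "density_kg_m3", 1e-12)
  structure(list(solids_mass_frac = solids_mass_frac,
                 t_initial_c = t_initial_c, t_target_c = t_target_c,
                 cp_water = cp_water, cp_solids = cp_solids,
                 density_kg_m3 = density_kg_m3),
            class = "slurry_spec")
}

#' Sensible heat demand of an HTL slurry
#'
#' Heat required to raise one cubic metre of slurry from its initial to its
#' target temperature under the constant-cp mixture model:
#' `rho * [(1 - f) cp_water + f cp_solids] * dT / 1000` in MJ m-3.
#' With the default constants a 10 wt% slurry heated 25 to 350 degrees C
#' needs about 1288 MJ m-3.
#'
#' @param spec A [slurry_spec()].
#' @return Sensible heat in MJ m-3.
#' @export
sensible_heat_mj_per_m3 <- function(spec) {
  if (!inherits(spec, "slurry_spec")) stop_domain("`spec` must be a slurry_spec")
  f <- spec$solids_mass_frac
  cp_mix <- (1 - f) * spec$cp_water + f * spec$cp_solids      # kJ kg-1 K-1
  spec$density_kg_m3 * cp_mix * (spec$t_target_c - spec$t_initial_c) / 1000
}

critical_anchor_table <- function() {
  # critical point of the 1:1 (by mass) alcohol-water mixture
  data.frame(alcohol = "isopropanol", t_c = 311.3, p_mpa = 10.2,
             stringsAsFactors = FALSE)
}

#' Critical point of a water-alcohol binary solvent
#'
#' Two-anchor lookup: pure water (374.1 degrees C, 22.1 MPa) at alcohol
#' mass fraction 0 and the tabulated 1:1-mixture value at fraction 0.5
#' (isopropanol: 311.3 degrees C, 10.2 MPa), with linear interpolation on
#' the same line elsewhere.  Interpolated (non-anchor) results are
#' flagged; this is a lookup convenience, not a thermodynamic mixing
#' model.
#'
#' @param alcohol_label Alcohol identity (currently `"isopropanol"`).
#' @param alcohol_mass_frac Alcohol mass fraction of the solvent, 0 to 1.
#' @return A list with `t_critical_c`, `p_critical_mpa` and logical
#'   `interpolated`.
#' @export
critical_point <- function(alcohol_label, alcohol_mass_frac) {
  check_num(alcohol_mass_frac, "alcohol_mass_frac", 0, 1)
  water <- c(t_c = 374.1, p_mpa = 22.1)
  if (alcohol_mass_frac == 0)
    return(list(t_critical_c = water[["t_c"]],
                p_critical_mpa = water[["p_mpa"]], interpolated = FALSE))
  tab <- critical_anchor_table()
  hit <- tab[tab$alcohol == alcohol_label, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop_domain("no critical-point anchor for alcohol `", alcohol_label, "`")
  w <- alcohol_mass_frac / 0.5
  list(t_critical_c = water[["t_c"]] + w * (hit$t_c - water[["t_c"]]),
       p_critical_mpa = water[["p_mpa"]] + w * (hit$p_mpa - water[["p_mpa"]]),
       interpolated = alcohol_mass_frac != 0.5)
}

#' Chemical-energy balance over the product slate
#'
#' Tabulates the chemical energy (mass times HHV) carried by the feed and
#' by each product stream, and the product total as a percentage of the
#' feed energy.  On the conventional 100 kg dry-feed basis the feed energy
#' equals `100 * HHV_feed` MJ.
#'
#' @param feed_mass_kg,feed_hhv Feed mass (kg) and HHV (MJ per kg).
#' @param products A data frame with columns `label`, `mass_kg`,
#'   `hhv_mj_per_kg` (zero rows allowed).
#' @return A list with `rows` (data frame of streams incl. the feed and
#'   their `chemical_energy_mj`), `feed_energy_mj`, `product_energy_mj`,
#'   and `product_share_pct`.
#' @export
chemical_energy_table <- function(feed_mass_kg, feed_hhv, products) {
  check_num(feed_mass_kg, "feed_mass_kg", 0)
  check_num(feed_hhv, "feed_hhv", 1e-12)
  if (!is.data.frame(products) ||
      !all(c("label", "mass_kg", "hhv_mj_per_kg") %in% names(products)))
    stop_domain("`products` needs columns label, mass_kg, hhv_mj_per_kg")
  if (nrow(products) &&
      (any(products$mass_kg < 0) || any(products$hhv_mj_per_kg < 0)))
    stop_domain("product masses and HHVs must be non-negative")
  feed_e <- feed_mass_kg * feed_hhv
  prod_e <- products$mass_kg * products$hhv_mj_per_kg
  rows <- rbind(
    data.frame(stream = "feed", mass_kg = feed_mass_kg,
               hhv_mj_per_kg = feed_hhv, chemical_energy_mj = feed_e,
               stringsAsFactors = FALSE),
    data.frame(stream = products$label, mass_kg = products$mass_kg,
               hhv_mj_per_kg = products$hhv_mj_per_kg,
               chemical_energy_mj = prod_e, stringsAsFactors = FALSE))
  list(rows = rows,
       feed_energy_mj = feed_e,
       product_energy_mj = sum(prod_e),
       product_share_pct = 100 * sum(prod_e) / feed_e)
}
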