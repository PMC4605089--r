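# Conceptual fermentation -> HTL -> upgrading biorefinery: fixed-coefficient
# biocrude upgrading, platform-level mass flows with nutrient recycle, and
# nutrient-recovery accounting for the aqueous co-phase.

#' Biocrude upgrading coefficients
#'
#' Fixed mass coefficients converting HTL biocrude to renewable fuel, coke
#' and process gases under catalytic hydrotreating, with hydrogen and
#' catalyst demand per kg of biocrude.  The default coefficients
#' (75 % fuel, 14 % coke, 10 % gas, 0.035 kg H2 and 0.004 kg catalyst per
#' kg biocrude) do not close to 100 %; the flows report the residual
#' rather than renormalising, since the coefficients are stated
#' independently of one another.
#'
#' @param fuel_yield_frac,coke_yield_frac,gas_yield_frac kg of product per
#'   kg of biocrude.
#' @param h2_consumption kg H2 consumed per kg biocrude.
#' @param catalyst_input kg catalyst per kg biocrude.
#' @return An object of class `upgrading_spec`.
#' @export
upgrading_spec <- function(fuel_yield_frac = 0.75, coke_yield_frac = 0.14,
                           gas_yield_frac = 0.10, h2_consumption = 0.035,
                           catalyst_input = 0.004) {
  for (nm in c("fuel_yield_frac", "coke_yield_frac", "gas_yield_frac",
               "h2_consumption", "catalyst_input"))
    check_num(get(nm), nm, 0)
  if (fuel_yield_frac + coke_yield_frac + gas_yield_frac >
      1 + h2_consumption + 0.02)
    stop_domain("product fractions exceed closure with hydrogen addition")
  structure(list(fuel_yield_frac = fuel_yield_frac,
                 coke_yield_frac = coke_yield_frac,
                 gas_yield_frac = gas_yield_frac,
                 h2_consumption = h2_consumption,
                 catalyst_input = catalyst_input),
            class = "upgrading_spec")
}

#' Upgrade a biocrude stream to fuel, coke and gas
#'
#' Applies the fixed upgrading coefficients to a biocrude mass.  The
#' closure residual `m + H2_in - (fuel + coke + gas)` is reported
#' explicitly (about 1 % of the biocrude plus the added hydrogen under
#' default coefficients), never hidden by renormalisation.
#'
#' @param biocrude_mass_kg Biocrude mass, kg (non-negative).
#' @param spec An [upgrading_spec()].
#' @return A list of stream masses in kg: `fuel_kg`, `coke_kg`,
#'   `process_gas_kg`, `h2_in_kg`, `catalyst_in_kg`, `closure_residual_kg`.
#' @export
upgrade_biocrude <- function(biocrude_mass_kg, spec = upgrading_spec()) {
  check_num(biocrude_mass_kg, "biocrude_mass_kg", 0)
  if (!inherits(spec, "upgrading_spec"))
    stop_domain("`spec` must be an upgrading_spec")
  m <- biocrude_mass_kg
  fuel <- spec$fuel_yield_frac * m
  coke <- spec$coke_yield_frac * m
  gas <- spec$gas_yield_frac * m
  h2 <- spec$h2_consumption * m
  list(fuel_kg = fuel, coke_kg = coke, process_gas_kg = gas,
       h2_in_kg = h2, catalyst_in_kg = spec$catalyst_input * m,
       closure_residual_kg = m + h2 - (fuel + coke + gas))
}

#' Platform-level mass flow: feed to fuel with nutrient recycle
#'
#' Chains the HTL yields into upgrading for a given feed tonnage and
#' accounts for the dissolved nitrogen (Kjeldahl N) and phosphorus (total
#' P) in the recovered aqueous co-phase as recycle streams back to the
#' fermentation step.  Solid char is routed to a process-heat sink.  The
#' recovered ACP volume must be supplied by the caller; it is a measured
#' quantity with no sensible default.
#'
#' @param feed_tonnes Dry feed to HTL, tonnes.
#' @param biocrude_yield_frac,solids_yield_frac HTL mass-yield fractions
#'   of dry feed (0 to 1).
#' @param acp Optional [acp_profile()]; required for nutrient recycle
#'   streams.
#' @param acp_volume_l Recovered aqueous-phase volume, litres.
#' @param spec An [upgrading_spec()].
#' @return A list of class `mass_flow_result`: stream masses in kg
#'   (`feed_kg`, `biocrude_kg`, `char_to_heat_kg`, `fuel_kg`, `coke_kg`,
#'   `process_gas_kg`, `h2_in_kg`, `catalyst_in_kg`, `recycle_n_kg`,
#'   `recycle_p_kg`) and `closure_residual_kg` from the upgrading step.
#' @export
platform_flow <- function(feed_tonnes, biocrude_yield_frac,
                          solids_yield_frac, acp = NULL, acp_volume_l = 0,
                          spec = upgrading_spec()) {
  check_num(feed_tonnes, "feed_tonnes", 0)
  check_num(biocrude_yield_frac, "biocrude_yield_frac", 0, 1)
  check_num(solids_yield_frac, "solids_yield_frac", 0, 1)
  check_num(acp_volume_l, "acp_volume_l", 0)
  if (!is.null(acp) && !inherits(acp, "acp_profile"))
    stop_domain("`acp` must be an acp_profile or NULL")
  feed_kg <- feed_tonnes * 1000
  biocrude_kg <- biocrude_yield_frac * feed_kg
  up <- upgrade_biocrude(biocrude_kg, spec)
  # mg L-1 * L -> mg -> kg
  recycle_n <- if (is.null(acp)) 0 else acp$kjeldahl_n_mg_l * acp_volume_l / 1e6
  recycle_p <- if (is.null(acp)) 0 else acp$total_p_mg_l * acp_volume_l / 1e6
  structure(list(feed_kg = feed_kg, biocrude_kg = biocrude_kg,
                 char_to_heat_kg = solids_yield_frac * feed_kg,
                 fuel_kg = up$fuel_kg, coke_kg = up$coke_kg,
                 process_gas_kg = up$process_gas_kg,
                 h2_in_kg = up$h2_in_kg, catalyst_in_kg = up$catalyst_in_kg,
                 recycle_n_kg = recycle_n, recycle_p_kg = recycle_p,
                 closure_residual_kg = up$closure_residual_kg),
            class = "mass_flow_result")
}

#' Nutrient recovery in the aqueous co-phase
#'
#' Dissolved element mass in the ACP as a percentage of the mass of that
#' element charged with the feed: `100 * dissolved / (feed * pct / 100)`.
#'
#' @param dissolved_mass_kg Dissolved element mass, kg.
#' @param feed_mass_kg Feed mass, kg.
#' @param feed_element_pct Element content of the feed, mass percent (> 0).
#' @return Recovery in percent.
#' @export
nutrient_recovery_pct <- function(dissolved_mass_kg, feed_mass_kg,
                                  feed_element_pct) {
  if (any(dissolved_mass_kg < 0)) stop_domain("dissolved mass must be >= 0")
  if (any(feed_mass_kg * feed_element_pct <= 0))
    stop_domain("feed element mass must be > 0")
  100 * dissolved_mass_kg / (feed_mass_kg * feed_element_pct / 100)
}
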