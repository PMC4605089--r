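# Fixture builders: randomized-but-valid HTL run records used by the
# round-trip and property tests.

random_run <- function(i = 1L, with_acp = TRUE, with_gas = TRUE) {
  feed <- runif(1, 5, 100)
  # fraction yields that always close below 105 %
  y <- runif(4, 0, 0.25)
  structure(list(
    condition_id = paste0("run_", i),
    condition = htl_condition(
      temperature_c = runif(1, 150, 350),
      residence_min = runif(1, 5, 120),
      reactor_label = sample(c("2-L", "2-chamber"), 1),
      catalyst_loading_frac = runif(1, 0, 0.2),
      cosolvent_name = sample(c("none", "isopropanol"), 1),
      cosolvent_water_mass_ratio = runif(1, 0, 2),
      biomass_to_solvent_ratio = runif(1, 0.05, 0.3)),
    slate = product_slate(
      feed_dry_mass_g = feed,
      biocrude1_mass_g = y[1] * feed, biocrude2_mass_g = y[2] * feed,
      solids_mass_g = y[3] * feed,
      gas_mass_g = if (runif(1) < 0.5) NA_real_ else runif(1, 0, 0.02) * feed,
      nvr_mass_g = y[4] * feed),
    crude = fraction_properties(
      carbon_pct = runif(1, 60, 80), hydrogen_pct = runif(1, 8, 13),
      nitrogen_pct = runif(1, 0, 3), oxygen_pct = runif(1, 5, 20),
      ash_pct = runif(1, 0, 0.2), hhv_mj_per_kg = runif(1, 30, 40)),
    acp = if (with_acp) acp_profile(
      no3_no2_mg_l = runif(1, 0, 25), nh3_n_mg_l = runif(1, 300, 700),
      kjeldahl_n_mg_l = runif(1, 700, 1300), total_p_mg_l = runif(1, 1000, 2000),
      toc_mg_l = runif(1, 4000, 6000), ph = runif(1, 3, 5),
      nvr_pct = runif(1, 0.5, 20)) else NULL,
    gas = if (with_gas) gas_profile(c(CO2 = runif(1, 0.9, 0.99),
                                      CO = runif(1, 0, 0.05),
                                      CH4 = runif(1, 0, 0.02),
                                      C2H6 = runif(1, 0, 0.02))) else NULL),
    class = "htl_run")
}

expect_run_equal <- function(a, b, tol = 1e-9) {
  num_fields <- function(x) {
    unlist(lapply(
      list(x$condition[c("temperature_c", "residence_min",
                         "catalyst_loading_frac", "cosolvent_water_mass_ratio",
                         "biomass_to_solvent_ratio")],
           x$slate, x$crude[c("carbon_pct", "hydrogen_pct", "nitrogen_pct",
                              "ash_pct", "hhv_mj_per_kg")],
           if (is.null(x$acp)) list() else unclass(x$acp),
           if (is.null(x$gas)) list() else as.list(x$gas$fractions)),
      unlist))
  }
  fa <- num_fields(a); fb <- num_fields(b)
  expect_identical(names(fa), names(fb))
  expect_equal(unname(fa), unname(fb), tolerance = tol)
  expect_identical(is.null(a$acp), is.null(b$acp))
  expect_identical(is.null(a$gas), is.null(b$gas))
}
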