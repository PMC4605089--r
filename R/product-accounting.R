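# Derived quantities of the HTL product slate: fraction yields, mass-recovery
# closure, chemical energy recovery in biocrude, carbon-hydrogen recovery,
# elemental atomic ratios, and the replicate-yield one-way ANOVA.

#' Product yield as percent of dry feed
#'
#' Mass recovery of a product fraction (biocrude, char, gas or NVR) defined
#' as the ratio of the product mass to the dry mass of the starting
#' feedstock, in percent.
#'
#' @param product_mass_g Product mass, g (non-negative).
#' @param feed_dry_mass_g Dry feed mass, g (> 0).
#' @return Yield in percent.
#' @export
yield_pct <- function(product_mass_g, feed_dry_mass_g) {
  if (any(feed_dry_mass_g <= 0)) stop_domain("feed_dry_mass_g must be > 0")
  if (any(product_mass_g < 0, na.rm = TRUE))
    stop_domain("product_mass_g must be >= 0")
  100 * product_mass_g / feed_dry_mass_g
}

#' Mass-recovery closure of a product slate
#'
#' Sums the component yields (biocrude = B1 + B2, solids, gas, NVR) and
#' complements to the mass lost (water-soluble organics, unmeasured gases,
#' produced water, experimental error).  An absent gas mass (vented
#' reactor) contributes zero to the total but is reported as `NA`.
#' Catalyst mass is never part of either feed or product masses.
#'
#' @param slate A [product_slate()].
#' @return A list with `biocrude_yield_pct`, `solids_yield_pct`,
#'   `gas_yield_pct`, `nvr_yield_pct`, `total_recovery_pct` and
#'   `mass_lost_pct`.
#' @export
mass_closure <- function(slate) {
  if (!inherits(slate, "product_slate"))
    stop_domain("`slate` must be a product_slate")
  feed <- slate$feed_dry_mass_g
  bio <- yield_pct(slate$biocrude1_mass_g + slate$biocrude2_mass_g, feed)
  sol <- yield_pct(slate$solids_mass_g, feed)
  gas <- if (is.na(slate$gas_mass_g)) NA_real_ else
    yield_pct(slate$gas_mass_g, feed)
  nvr <- yield_pct(slate$nvr_mass_g, feed)
  total <- bio + sol + (if (is.na(gas)) 0 else gas) + nvr
  list(biocrude_yield_pct = bio, solids_yield_pct = sol,
       gas_yield_pct = gas, nvr_yield_pct = nvr,
       total_recovery_pct = total, mass_lost_pct = 100 - total)
}

#' Chemical energy recovery in biocrude
#'
#' Fraction of the feedstock's chemical energy recovered in the biocrude:
#' `ER = 100 * (HHV_biocrude * m_biocrude) / (HHV_feed * m_feed)`, which for
#' a mass-yield fraction `y = m_biocrude / m_feed` reduces to
#' `100 * y * HHV_biocrude / HHV_feed`.  Values above 100 % are possible
#' when co-solvent mass (isopropyl esters) is incorporated into the
#' products.
#'
#' @param biocrude_yield_frac Biocrude yield as a fraction of dry feed
#'   (0 to 1.05).
#' @param hhv_biocrude,hhv_feed Higher heating values, MJ per kg
#'   (`hhv_feed` > 0).
#' @return Energy recovery in percent.
#' @export
energy_recovery <- function(biocrude_yield_frac, hhv_biocrude, hhv_feed) {
  if (any(hhv_feed <= 0)) stop_domain("hhv_feed must be > 0")
  if (any(biocrude_yield_frac < 0 | biocrude_yield_frac > 1.05))
    stop_domain("biocrude_yield_frac must lie in [0, 1.05]")
  if (any(hhv_biocrude < 0)) stop_domain("hhv_biocrude must be >= 0")
  100 * biocrude_yield_frac * hhv_biocrude / hhv_feed
}

#' Carbon-hydrogen recovery in biocrude
#'
#' Ratio of the carbon plus hydrogen recovered in the biocrude to the
#' carbon plus hydrogen present in the feedstock, in percent, on the
#' as-printed mass-percent basis:
#' `100 * y * (C_crude + H_crude) / (C_feed + H_feed)`.
#'
#' @param biocrude_yield_frac Biocrude yield fraction of dry feed.
#' @param crude A [fraction_properties()] for the biocrude.
#' @param feed A [feedstock_composition()].
#' @return Recovery in percent.
#' @export
ch_recovery <- function(biocrude_yield_frac, crude, feed) {
  if (!inherits(crude, "fraction_properties"))
    stop_domain("`crude` must be a fraction_properties")
  if (!inherits(feed, "feedstock_composition"))
    stop_domain("`feed` must be a feedstock_composition")
  denom <- feed$carbon_pct + feed$hydrogen_pct
  if (denom <= 0) stop_domain("feed carbon + hydrogen must be > 0")
  100 * biocrude_yield_frac *
    (crude$carbon_pct + crude$hydrogen_pct) / denom
}

#' Atomic ratio of two elements from mass percentages
#'
#' Converts mass percentages to molar amounts and returns the X/C atomic
#' ratio `(x/Mx) / (c/Mc)`.  Default atomic masses are the IUPAC standard
#' values; reported tables typically round the ratio to two decimals.
#'
#' @param element_pct_x Mass percent of element X.
#' @param element_pct_c Mass percent of carbon (> 0).
#' @param atomic_mass_x,atomic_mass_c Atomic masses, g per mol.
#' @return Dimensionless atomic ratio.
#' @export
atomic_ratio <- function(element_pct_x, element_pct_c,
                         atomic_mass_x, atomic_mass_c = 12.011) {
  if (any(element_pct_c <= 0)) stop_domain("element_pct_c must be > 0")
  if (any(atomic_mass_x <= 0) || any(atomic_mass_c <= 0))
    stop_domain("atomic masses must be > 0")
  (element_pct_x / atomic_mass_x) / (element_pct_c / atomic_mass_c)
}

#' Oxygen content by difference
#'
#' `100 - C - H - N` (optionally `- ash`), floored at zero.  A result below
#' -2 indicates grossly inconsistent inputs and is an error.  This function
#' never overwrites a measured oxygen value; use it to cross-check printed
#' compositions (see [account_experiments()], which reports the gap).
#'
#' @param c_pct,h_pct,n_pct Mass percentages of C, H, N.
#' @param include_ash Subtract ash as well?
#' @param ash_pct Ash mass percent (used when `include_ash` is `TRUE`).
#' @return Oxygen mass percent by difference.
#' @export
oxygen_by_difference <- function(c_pct, h_pct, n_pct,
                                 include_ash = FALSE, ash_pct = 0) {
  for (x in list(c_pct, h_pct, n_pct, ash_pct))
    if (any(x < 0 | x > 100)) stop_domain("inputs must lie in [0, 100]")
  o <- 100 - c_pct - h_pct - n_pct - (if (include_ash) ash_pct else 0)
  if (any(o < -2))
    stop_domain("composition sums beyond 102 %: oxygen by difference = ",
                format(min(o)))
  pmax(o, 0)
}

#' Relative change between two yields
#'
#' `100 * (b - a) / a`, the percent change of yield `b` relative to
#' baseline `a` (e.g. the effect of adding catalyst).
#'
#' @param yield_a_pct Baseline yield, percent (> 0).
#' @param yield_b_pct Comparison yield, percent.
#' @return Percent change.
#' @export
relative_yield_change <- function(yield_a_pct, yield_b_pct) {
  if (any(yield_a_pct <= 0)) stop_domain("baseline yield must be > 0")
  100 * (yield_b_pct - yield_a_pct) / yield_a_pct
}

#' One-way ANOVA on replicate yields
#'
#' Classical equal-variance one-way analysis of variance across treatment
#' groups of replicate yields, as used to test for a treatment effect on
#' biocrude yield at the 0.05 significance level.
#'
#' @param groups A list of numeric vectors, one per treatment, each with at
#'   least two replicates.
#' @return A list with `f_statistic`, `p_value`, `df_between`, `df_within`.
#' @export
anova_one_way <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_domain("need at least two groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2L)) stop_domain("every group needs >= 2 replicates")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), n))
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(f_statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df_between = unname(ht$parameter[1]),
       df_within = unname(ht$parameter[2]))
}

#' Normalize a gas composition to mole fractions
#'
#' Rescales a non-negative composition vector so its components sum to
#' one, preserving species order.  Idempotent on an already-normalized
#' profile.
#'
#' @param gas A [gas_profile()] with at least one positive component.
#' @return A normalized `gas_profile`.
#' @export
normalize_gas <- function(gas) {
  if (!inherits(gas, "gas_profile")) stop_domain("`gas` must be a gas_profile")
  s <- sum(gas$fractions)
  if (s <= 0) stop_domain("gas profile has no positive component")
  gas_profile(gas$fractions / s)
}

#' Derived-quantity table for a set of HTL runs
#'
#' Recomputes, per run, every derived quantity of the experiment summary
#' from raw masses: component yields and closure, energy recovery,
#' carbon-hydrogen recovery, O/C and N/C atomic ratios, and the gap
#' between the recorded biocrude oxygen and oxygen-by-difference (a
#' validation column, surfaced rather than silently reconciled).
#'
#' @param records List of `htl_run` records (see [read_experiment_table()]).
#' @param feed A [feedstock_composition()] for the common feedstock.
#' @return A data frame with one row per run.
#' @export
account_experiments <- function(records, feed = yeast_feedstock()) {
  rows <- lapply(records, function(r) {
    cl <- mass_closure(r$slate)
    yfrac <- cl$biocrude_yield_pct / 100
    data.frame(
      condition_id = r$condition_id,
      biocrude_yield_pct = cl$biocrude_yield_pct,
      solids_yield_pct = cl$solids_yield_pct,
      gas_yield_pct = cl$gas_yield_pct,
      nvr_yield_pct = cl$nvr_yield_pct,
      total_recovery_pct = cl$total_recovery_pct,
      mass_lost_pct = cl$mass_lost_pct,
      er_biocrude_pct = energy_recovery(yfrac, r$crude$hhv_mj_per_kg,
                                        feed$hhv_mj_per_kg),
      ch_recovery_pct = ch_recovery(yfrac, r$crude, feed),
      oc_atomic_ratio = atomic_ratio(r$crude$oxygen_pct, r$crude$carbon_pct,
                                     atomic_mass_x = 15.999),
      nc_atomic_ratio = atomic_ratio(r$crude$nitrogen_pct, r$crude$carbon_pct,
                                     atomic_mass_x = 14.007),
      o_by_difference_gap_pct = r$crude$oxygen_pct -
        oxygen_by_difference(r$crude$carbon_pct, r$crude$hydrogen_pct,
                             r$crude$nitrogen_pct, include_ash = TRUE,
                             ash_pct = r$crude$ash_pct),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
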