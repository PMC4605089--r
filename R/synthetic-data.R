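# Synthetic replicate generator: emulates duplicate batch HTL runs with
# independent truncated-Gaussian noise per fraction, reproducing the
# statistical structure of the reference study without any raw data.

#' Configuration of the synthetic experiment generator
#'
#' Per-condition mean yields and replicate standard deviations, replicate
#' count, dry-feed basis and feedstock.  Defaults reproduce the reference
#' study design: four treatment conditions run in duplicate, with the
#' printed biocrude SDs (0.4 % for the non-catalytic run without
#' co-solvent, 0.1 % with co-solvent) and 0.2 % where no SD was printed.
#'
#' @param conditions Data frame in the layout of [htl_reference_table()]
#'   (condition descriptors plus `*_pct` means and `*_sd` columns).
#' @param n_replicates Replicate runs per condition (>= 2).
#' @param feed_dry_mass_g Dry feed charged per run, g.
#' @param feed A [feedstock_composition()].
#' @param crude_c_sd,crude_h_sd,crude_n_sd,crude_ash_sd,crude_hhv_sd
#'   Replicate SDs of the biocrude elemental composition and HHV
#'   (elemental-analyzer and bomb-calorimeter repeatability).
#' @param gas_means Named mole-fraction means of the vented gas for 2-L
#'   reactor runs (CO2-dominant, > 93 %).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(conditions = htl_reference_table(),
                             n_replicates = 2,
                             feed_dry_mass_g = 40,
                             feed = yeast_feedstock(),
                             crude_c_sd = 0.4, crude_h_sd = 0.15,
                             crude_n_sd = 0.05, crude_ash_sd = 0.01,
                             crude_hhv_sd = 0.2,
                             gas_means = c(CO2 = 0.94, CO = 0.04,
                                           CH4 = 0.01, C2H6 = 0.01)) {
  check_num(n_replicates, "n_replicates", 2)
  check_num(feed_dry_mass_g, "feed_dry_mass_g", 1e-9)
  if (!inherits(feed, "feedstock_composition"))
    stop_domain("`feed` must be a feedstock_composition")
  need <- c("condition_id", "temperature_c", "reactor", "residence_min",
            "catalyst_frac", "cosolvent", "cosolvent_ratio",
            "biomass_solvent_ratio",
            "biocrude_pct", "biocrude_sd", "solids_pct", "solids_sd",
            "gas_pct", "gas_sd", "nvr_pct", "nvr_sd",
            "crude_c_pct", "crude_h_pct", "crude_n_pct", "crude_ash_pct",
            "crude_hhv")
  if (!is.data.frame(conditions) || !all(need %in% names(conditions)))
    stop_domain("`conditions` is missing column(s): ",
                paste(setdiff(need, names(conditions)), collapse = ", "))
  sds <- unlist(conditions[c("biocrude_sd", "solids_sd", "gas_sd", "nvr_sd")])
  if (any(sds < 0, na.rm = TRUE)) stop_domain("yield SDs must be >= 0")
  means <- unlist(conditions[c("biocrude_pct", "solids_pct", "gas_pct",
                               "nvr_pct")])
  if (any(means < 0 | means > 100, na.rm = TRUE))
    stop_domain("mean yields must lie in [0, 100]")
  for (nm in c("crude_c_sd", "crude_h_sd", "crude_n_sd", "crude_ash_sd",
               "crude_hhv_sd"))
    check_num(get(nm), nm, 0)
  structure(list(conditions = conditions,
                 n_replicates = as.integer(n_replicates),
                 feed_dry_mass_g = feed_dry_mass_g, feed = feed,
                 crude_c_sd = crude_c_sd, crude_h_sd = crude_h_sd,
                 crude_n_sd = crude_n_sd, crude_ash_sd = crude_ash_sd,
                 crude_hhv_sd = crude_hhv_sd, gas_means = gas_means),
            class = "synthetic_config")
}

# normal draw truncated at zero (rejection; lower bound only)
rnorm_trunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < 0
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, 0)
}

#' Generate a synthetic HTL experiment table
#'
#' Draws, for each condition and replicate, each product-fraction yield
#' from an independent normal truncated at zero, converts yields to raw
#' masses on the configured dry-feed basis, and draws the biocrude
#' elemental composition and HHV the same way.  Draws whose fraction
#' yields sum beyond 105 % of the feed are rejected and redrawn (the soft
#' closure constraint).  A gas block is attached only to runs in the
#' "2-L" reactor; 2-chamber runs vented their gases.  Deterministic under
#' a fixed `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return A list of `htl_run` records (the [read_experiment_table()]
#'   format); replicate ids are appended to the condition id as
#'   `<condition_id>_r<k>`.
#' @export
generate_experiments <- function(config = synthetic_config(), seed = NULL) {
  if (!inherits(config, "synthetic_config"))
    stop_domain("`config` must be a synthetic_config")
  if (!is.null(seed)) set.seed(seed)
  tab <- config$conditions
  feed_g <- config$feed_dry_mass_g
  b1_share <- 0.725
  out <- vector("list", nrow(tab) * config$n_replicates)
  idx <- 0L
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    cond <- htl_condition(
      temperature_c = r$temperature_c, residence_min = r$residence_min,
      reactor_label = r$reactor, catalyst_loading_frac = r$catalyst_frac,
      cosolvent_name = r$cosolvent,
      cosolvent_water_mass_ratio = r$cosolvent_ratio,
      biomass_to_solvent_ratio = r$biomass_solvent_ratio)
    for (k in seq_len(config$n_replicates)) {
      for (attempt in 1:100) {
        bio <- rnorm_trunc0(1, r$biocrude_pct, r$biocrude_sd)
        sol <- rnorm_trunc0(1, r$solids_pct, r$solids_sd)
        gas <- if (is.na(r$gas_pct)) NA_real_ else
          rnorm_trunc0(1, r$gas_pct, r$gas_sd)
        nvr <- rnorm_trunc0(1, r$nvr_pct, r$nvr_sd)
        tot <- bio + sol + (if (is.na(gas)) 0 else gas) + nvr
        if (tot <= 105) break
      }
      slate <- product_slate(
        feed_dry_mass_g = feed_g,
        biocrude1_mass_g = bio / 100 * feed_g * b1_share,
        biocrude2_mass_g = bio / 100 * feed_g * (1 - b1_share),
        solids_mass_g = sol / 100 * feed_g,
        gas_mass_g = if (is.na(gas)) NA_real_ else gas / 100 * feed_g,
        nvr_mass_g = nvr / 100 * feed_g)
      crude <- fraction_properties(
        carbon_pct = rnorm_trunc0(1, r$crude_c_pct, config$crude_c_sd),
        hydrogen_pct = rnorm_trunc0(1, r$crude_h_pct, config$crude_h_sd),
        nitrogen_pct = rnorm_trunc0(1, r$crude_n_pct, config$crude_n_sd),
        ash_pct = rnorm_trunc0(1, r$crude_ash_pct, config$crude_ash_sd),
        hhv_mj_per_kg = rnorm_trunc0(1, r$crude_hhv, config$crude_hhv_sd))
      gasprof <- if (identical(r$reactor, "2-L"))
        normalize_gas(gas_profile(config$gas_means)) else NULL
      idx <- idx + 1L
      out[[idx]] <- structure(
        list(condition_id = paste0(r$condition_id, "_r", k),
             condition = cond, slate = slate, crude = crude,
             acp = NULL, gas = gasprof),
        class = "htl_run")
    }
  }
  out
}

#' Recover per-condition yield statistics from a run table
#'
#' Groups replicate runs by their parent condition (the condition id with
#' any `_r<k>` replicate suffix stripped) and returns the sample mean and
#' SD of each fraction yield, recomputed from raw masses.  Estimates are
#' invariant to row order.
#'
#' @param records List of `htl_run` records with >= 2 replicates per
#'   condition.
#' @return A data frame with one row per condition: replicate count and
#'   `<fraction>_mean` / `<fraction>_sd` columns for biocrude, solids,
#'   gas and NVR yields (percent of dry feed).
#' @export
recover_parameters <- function(records) {
  if (!length(records)) stop_domain("no records supplied")
  yields <- lapply(records, function(r) {
    cl <- mass_closure(r$slate)
    data.frame(condition = sub("_r[0-9]+$", "", r$condition_id),
               biocrude = cl$biocrude_yield_pct,
               solids = cl$solids_yield_pct,
               gas = cl$gas_yield_pct, nvr = cl$nvr_yield_pct,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, yields)
  split_df <- split(df, df$condition)
  if (any(vapply(split_df, nrow, integer(1)) < 2L))
    stop_domain("every condition needs >= 2 replicates")
  rows <- lapply(split_df, function(d) {
    stat <- function(x, f) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
    data.frame(
      condition = d$condition[1], n = nrow(d),
      biocrude_mean = stat(d$biocrude, mean), biocrude_sd = stat(d$biocrude, stats::sd),
      solids_mean = stat(d$solids, mean), solids_sd = stat(d$solids, stats::sd),
      gas_mean = stat(d$gas, mean), gas_sd = stat(d$gas, stats::sd),
      nvr_mean = stat(d$nvr, mean), nvr_sd = stat(d$nvr, stats::sd),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition), , drop = FALSE]
}
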