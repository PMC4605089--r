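# Typed records for HTL experiments and the tabular formats the rest of the
# package consumes.  Constructors validate on creation; readers validate per
# row and report the offending row/column.

stop_domain <- function(...) stop(..., call. = FALSE)

check_num <- function(x, name, lower = -Inf, upper = Inf, allow_na = FALSE) {
  if (is.null(x) || length(x) != 1L)
    stop_domain("`", name, "` must be a single number")
  if (is.na(x)) {
    if (allow_na) return(invisible(x))
    stop_domain("`", name, "` must not be NA")
  }
  if (!is.numeric(x) || !is.finite(x))
    stop_domain("`", name, "` must be a finite number")
  if (x < lower || x > upper)
    stop_domain("`", name, "` = ", format(x), " outside [", lower, ", ", upper, "]")
  invisible(x)
}

#' Feedstock composition of dry yeast biomass
#'
#' Bundles the ultimate (CHNO), proximate (moisture/volatiles/fixed
#' carbon/ash) and biochemical (lipid/protein/carbohydrate) composition of
#' the HTL feedstock together with its higher heating value, all on an
#' as-received mass basis.
#'
#' @param carbon_pct,hydrogen_pct,nitrogen_pct,oxygen_pct Elemental mass
#'   percentages (as received).
#' @param moisture_pct,volatiles_pct,fixed_carbon_pct,ash_pct Proximate
#'   analysis mass percentages.
#' @param lipid_pct,protein_pct,carbohydrate_pct Biochemical composition,
#'   mass percent.
#' @param hhv_mj_per_kg Higher heating value, MJ per kg.
#' @param fatty_acid_profile Optional named numeric vector of fatty-acid
#'   chain fractions (fractions of total fatty acids, summing to 1).
#' @param proximate_tol Allowed deviation of the proximate sum
#'   (moisture + volatiles + fixed carbon + ash) from 100. Instrumental
#'   repeatability on a thermogravimetric analyzer justifies the default of
#'   2 percentage points; transcribed literature values occasionally need a
#'   wider band.
#' @return An object of class `feedstock_composition`.
#' @seealso [yeast_feedstock()] for the bundled reference composition.
#' @export
feedstock_composition <- function(carbon_pct, hydrogen_pct, nitrogen_pct,
                                  oxygen_pct,
                                  moisture_pct, volatiles_pct,
                                  fixed_carbon_pct, ash_pct,
                                  lipid_pct, protein_pct, carbohydrate_pct,
                                  hhv_mj_per_kg,
                                  fatty_acid_profile = numeric(),
                                  proximate_tol = 2) {
  for (nm in c("carbon_pct", "hydrogen_pct", "nitrogen_pct", "oxygen_pct",
               "moisture_pct", "volatiles_pct", "fixed_carbon_pct",
               "ash_pct", "lipid_pct", "protein_pct", "carbohydrate_pct"))
    check_num(get(nm), nm, 0, 100)
  check_num(hhv_mj_per_kg, "hhv_mj_per_kg", 0)
  prox <- moisture_pct + volatiles_pct + fixed_carbon_pct + ash_pct
  if (abs(prox - 100) > proximate_tol)
    stop_domain("proximate analysis sums to ", format(prox),
                ", outside 100 ± ", proximate_tol)
  if (length(fatty_acid_profile)) {
    if (any(fatty_acid_profile < 0))
      stop_domain("fatty_acid_profile fractions must be non-negative")
    if (abs(sum(fatty_acid_profile) - 1) > 0.02)
      stop_domain("fatty_acid_profile must sum to 1 ± 0.02, got ",
                  format(sum(fatty_acid_profile)))
  }
  structure(
    list(carbon_pct = carbon_pct, hydrogen_pct = hydrogen_pct,
         nitrogen_pct = nitrogen_pct, oxygen_pct = oxygen_pct,
         moisture_pct = moisture_pct, volatiles_pct = volatiles_pct,
         fixed_carbon_pct = fixed_carbon_pct, ash_pct = ash_pct,
         lipid_pct = lipid_pct, protein_pct = protein_pct,
         carbohydrate_pct = carbohydrate_pct,
         hhv_mj_per_kg = hhv_mj_per_kg,
         fatty_acid_profile = fatty_acid_profile),
    class = "feedstock_composition")
}

#' HTL reaction condition
#'
#' Describes one hydrothermal liquefaction treatment: temperature, residence
#' time, reactor, catalyst loading and co-solvent make-up.
#'
#' @param temperature_c Reaction temperature, degrees C (subcritical water
#'   regime, 100-374).
#' @param residence_min Residence time at temperature, minutes.
#' @param reactor_label Free-text reactor identifier (e.g. `"2-L"` for a
#'   stirred Parr vessel, `"2-chamber"` for the drop-in reactor).
#' @param catalyst_loading_frac Catalyst mass as a fraction of dry feed
#'   (0 for non-catalytic runs; at most 0.2).
#' @param cosolvent_name Co-solvent identity, or `"none"`.
#' @param cosolvent_water_mass_ratio Co-solvent to water mass ratio
#'   (1 for a 1:1 mixture; 0 when no co-solvent).
#' @param biomass_to_solvent_ratio Dry biomass to total solvent mass ratio
#'   (e.g. 0.1 for 1:10).
#' @param pressure_mpa Optional autogenous pressure, MPa (informational).
#' @return An object of class `htl_condition`.
#' @export
htl_condition <- function(temperature_c, residence_min = 30,
                          reactor_label = "2-L",
                          catalyst_loading_frac = 0,
                          cosolvent_name = "none",
                          cosolvent_water_mass_ratio = 0,
                          biomass_to_solvent_ratio = 0.1,
                          pressure_mpa = NA_real_) {
  check_num(temperature_c, "temperature_c", 100, 374)
  check_num(residence_min, "residence_min", 0)
  check_num(catalyst_loading_frac, "catalyst_loading_frac", 0, 0.2)
  check_num(cosolvent_water_mass_ratio, "cosolvent_water_mass_ratio", 0)
  check_num(biomass_to_solvent_ratio, "biomass_to_solvent_ratio", 1e-12)
  check_num(pressure_mpa, "pressure_mpa", 0, allow_na = TRUE)
  structure(
    list(temperature_c = temperature_c, pressure_mpa = pressure_mpa,
         residence_min = residence_min,
         reactor_label = as.character(reactor_label),
         catalyst_loading_frac = catalyst_loading_frac,
         cosolvent_name = as.character(cosolvent_name),
         cosolvent_water_mass_ratio = cosolvent_water_mass_ratio,
         biomass_to_solvent_ratio = biomass_to_solvent_ratio),
    class = "htl_condition")
}

#' Product slate of one HTL run
#'
#' Raw recovered masses of the product fractions relative to the dry feed
#' charged.  Biocrude is split into the dichloromethane-soluble (B1) and
#' acetone-soluble (B2) fractions of the separation protocol; gas mass may
#' be absent when the reactor vents (2-chamber runs).  Percent yields are
#' always computed downstream, never stored.
#'
#' @param feed_dry_mass_g Dry feed mass charged, g (> 0).
#' @param biocrude1_mass_g,biocrude2_mass_g DCM- and acetone-soluble
#'   biocrude masses, g.
#' @param solids_mass_g Solid char mass, g.
#' @param gas_mass_g Gas mass, g, or `NA` when not captured.
#' @param nvr_mass_g Non-volatile residue mass, g.
#' @return An object of class `product_slate`.
#' @export
product_slate <- function(feed_dry_mass_g, biocrude1_mass_g, biocrude2_mass_g,
                          solids_mass_g, gas_mass_g = NA_real_, nvr_mass_g) {
  check_num(feed_dry_mass_g, "feed_dry_mass_g", 1e-12)
  check_num(biocrude1_mass_g, "biocrude1_mass_g", 0)
  check_num(biocrude2_mass_g, "biocrude2_mass_g", 0)
  check_num(solids_mass_g, "solids_mass_g", 0)
  check_num(gas_mass_g, "gas_mass_g", 0, allow_na = TRUE)
  check_num(nvr_mass_g, "nvr_mass_g", 0)
  tot <- biocrude1_mass_g + biocrude2_mass_g + solids_mass_g +
    (if (is.na(gas_mass_g)) 0 else gas_mass_g) + nvr_mass_g
  # small >100 % closures are legitimate: co-solvent carbon is incorporated
  # into the products as isopropyl esters
  if (tot > feed_dry_mass_g * 1.05)
    stop_domain("recovered product mass ", format(tot),
                " g exceeds 105 % of dry feed (", format(feed_dry_mass_g), " g)")
  structure(
    list(feed_dry_mass_g = feed_dry_mass_g,
         biocrude1_mass_g = biocrude1_mass_g,
         biocrude2_mass_g = biocrude2_mass_g,
         solids_mass_g = solids_mass_g,
         gas_mass_g = gas_mass_g,
         nvr_mass_g = nvr_mass_g),
    class = "product_slate")
}

#' Elemental composition and heating value of a product fraction
#'
#' CHNO (+ash) mass percentages and HHV of a biocrude or char fraction.
#' When `oxygen_pct` is omitted it is computed by difference
#' (`100 - C - H - N - ash`) and flagged as such; a supplied (measured or
#' transcribed) oxygen value is never overwritten.
#'
#' @param carbon_pct,hydrogen_pct,nitrogen_pct,ash_pct Mass percentages.
#' @param oxygen_pct Oxygen mass percent, or `NULL` to derive by difference.
#' @param hhv_mj_per_kg Higher heating value, MJ per kg.
#' @return An object of class `fraction_properties` with logical field
#'   `oxygen_is_by_difference`.
#' @seealso [oxygen_by_difference()]
#' @export
fraction_properties <- function(carbon_pct, hydrogen_pct, nitrogen_pct,
                                oxygen_pct = NULL, ash_pct = 0,
                                hhv_mj_per_kg) {
  check_num(carbon_pct, "carbon_pct", 0, 100)
  check_num(hydrogen_pct, "hydrogen_pct", 0, 100)
  check_num(nitrogen_pct, "nitrogen_pct", 0, 100)
  check_num(ash_pct, "ash_pct", 0, 100)
  check_num(hhv_mj_per_kg, "hhv_mj_per_kg", 0)
  by_diff <- is.null(oxygen_pct)
  if (by_diff) {
    oxygen_pct <- oxygen_by_difference(carbon_pct, hydrogen_pct, nitrogen_pct,
                                       include_ash = TRUE, ash_pct = ash_pct)
  } else {
    check_num(oxygen_pct, "oxygen_pct", 0, 100)
  }
  structure(
    list(carbon_pct = carbon_pct, hydrogen_pct = hydrogen_pct,
         nitrogen_pct = nitrogen_pct, oxygen_pct = oxygen_pct,
         ash_pct = ash_pct, hhv_mj_per_kg = hhv_mj_per_kg,
         oxygen_is_by_difference = by_diff),
    class = "fraction_properties")
}

#' Aqueous co-phase product (ACP) analysis
#'
#' Dissolved nitrogen and phosphorus species, organic carbon, pH and
#' non-volatile residue of the water phase recovered from an HTL run.
#'
#' @param no3_no2_mg_l,nh3_n_mg_l,kjeldahl_n_mg_l,total_p_mg_l,toc_mg_l
#'   Concentrations, mg per litre.
#' @param ph pH of the aqueous phase.
#' @param nvr_pct Non-volatile residue, mass percent of dry feed.
#' @return An object of class `acp_profile`.
#' @export
acp_profile <- function(no3_no2_mg_l, nh3_n_mg_l, kjeldahl_n_mg_l,
                        total_p_mg_l, toc_mg_l, ph, nvr_pct) {
  for (nm in c("no3_no2_mg_l", "nh3_n_mg_l", "kjeldahl_n_mg_l",
               "total_p_mg_l", "toc_mg_l", "nvr_pct"))
    check_num(get(nm), nm, 0)
  check_num(ph, "ph", 0, 14)
  structure(
    list(no3_no2_mg_l = no3_no2_mg_l, nh3_n_mg_l = nh3_n_mg_l,
         kjeldahl_n_mg_l = kjeldahl_n_mg_l, total_p_mg_l = total_p_mg_l,
         toc_mg_l = toc_mg_l, ph = ph, nvr_pct = nvr_pct),
    class = "acp_profile")
}

#' Non-condensable gas composition
#'
#' Mole fractions of the permanent gases produced by HTL (CO2-dominant).
#' The constructor accepts any non-negative composition vector;
#' [normalize_gas()] rescales it to sum to one.
#'
#' @param fractions Named numeric vector of mole fractions, names drawn
#'   from `CO2`, `CO`, `CH4`, `C2H6`, `H2`.
#' @return An object of class `gas_profile`.
#' @export
gas_profile <- function(fractions) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop_domain("gas fractions must be a named vector")
  if (any(!is.finite(fractions)) || any(fractions < 0))
    stop_domain("gas fractions must be finite and non-negative")
  structure(list(fractions = fractions), class = "gas_profile")
}

# ---- experiment table I/O ---------------------------------------------------

experiment_csv_columns <- function() {
  list(
    mandatory = c("condition_id", "temperature_c", "residence_min", "reactor",
                  "catalyst_frac", "cosolvent", "cosolvent_ratio",
                  "biomass_solvent_ratio", "feed_dry_mass_g", "b1_g", "b2_g",
                  "solids_g", "gas_g", "nvr_g", "crude_c_pct", "crude_h_pct",
                  "crude_n_pct", "crude_ash_pct", "crude_hhv"),
    acp = c("acp_nh3", "acp_kn", "acp_no3no2", "acp_tp", "acp_toc",
            "acp_ph", "acp_nvr_pct"),
    gas = c("gas_co2", "gas_co", "gas_ch4", "gas_c2h6"),
    character = c("condition_id", "reactor", "cosolvent"))
}

num_cell <- function(raw, row, col) {
  x <- trimws(raw)
  if (!nzchar(x) || is.na(x) || toupper(x) %in% c("NA", "ND")) return(NA_real_)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v))
    stop_domain("row ", row, ", column `", col, "`: cannot parse \"",
                raw, "\" as a number")
  v
}

#' Read an HTL experiment table
#'
#' Parses the per-run experiment CSV (one row per HTL run, raw masses in
#' grams plus crude properties and optional ACP/gas blocks) into a list of
#' validated run records.  Every type invariant is enforced; a violation is
#' reported with the offending row and column.
#'
#' @param path Path to a CSV file following the experiment schema (see
#'   [write_experiment_table()] for the column set).
#' @return A list of `htl_run` records, each a list with elements
#'   `condition_id`, `condition` ([htl_condition()]), `slate`
#'   ([product_slate()]), `crude` ([fraction_properties()]), and optionally
#'   `acp` and `gas` (`NULL` when absent from the row).
#' @export
read_experiment_table <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  cols <- experiment_csv_columns()
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  missing <- setdiff(cols$mandatory, names(df))
  if (length(missing))
    stop_domain("missing mandatory column(s): ",
                paste0("`", missing, "`", collapse = ", "))
  if (nrow(df) == 0L) return(list())

  numeric_cols <- setdiff(c(cols$mandatory, cols$acp, cols$gas), cols$character)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    v <- list()
    for (cn in intersect(numeric_cols, names(df)))
      v[[cn]] <- num_cell(row[[cn]], i, cn)
    rec <- tryCatch({
      cond <- htl_condition(
        temperature_c = v$temperature_c, residence_min = v$residence_min,
        reactor_label = row$reactor, catalyst_loading_frac = v$catalyst_frac,
        cosolvent_name = row$cosolvent,
        cosolvent_water_mass_ratio = v$cosolvent_ratio,
        biomass_to_solvent_ratio = v$biomass_solvent_ratio)
      slate <- product_slate(
        feed_dry_mass_g = v$feed_dry_mass_g,
        biocrude1_mass_g = v$b1_g, biocrude2_mass_g = v$b2_g,
        solids_mass_g = v$solids_g, gas_mass_g = v$gas_g,
        nvr_mass_g = v$nvr_g)
      crude <- fraction_properties(
        carbon_pct = v$crude_c_pct, hydrogen_pct = v$crude_h_pct,
        nitrogen_pct = v$crude_n_pct, ash_pct = v$crude_ash_pct,
        hhv_mj_per_kg = v$crude_hhv)
      acp <- NULL
      if (all(cols$acp %in% names(df)) &&
          all(!is.na(unlist(v[cols$acp])))) {
        acp <- acp_profile(
          no3_no2_mg_l = v$acp_no3no2, nh3_n_mg_l = v$acp_nh3,
          kjeldahl_n_mg_l = v$acp_kn, total_p_mg_l = v$acp_tp,
          toc_mg_l = v$acp_toc, ph = v$acp_ph, nvr_pct = v$acp_nvr_pct)
      }
      gas <- NULL
      if (all(cols$gas %in% names(df)) &&
          all(!is.na(unlist(v[cols$gas])))) {
        gas <- gas_profile(c(CO2 = v$gas_co2, CO = v$gas_co,
                             CH4 = v$gas_ch4, C2H6 = v$gas_c2h6))
      }
      structure(list(condition_id = row$condition_id, condition = cond,
                     slate = slate, crude = crude, acp = acp, gas = gas),
                class = "htl_run")
    }, error = function(e) {
      stop_domain("row ", i, ": ", conditionMessage(e))
    })
    rec
  })
}

#' Write an HTL experiment table
#'
#' Inverse of [read_experiment_table()]: serialises run records to the
#' experiment CSV schema.  Numeric fields round-trip to better than 1e-9;
#' absent optional blocks are written as empty cells.
#'
#' @param records List of `htl_run` records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(records, path) {
  cols <- experiment_csv_columns()
  all_cols <- c(cols$mandatory, cols$acp, cols$gas)
  fmt <- function(x) {
    if (is.null(x) || (length(x) == 1L && is.na(x))) "" else
      sprintf("%.*g", 15L, x)
  }
  rows <- lapply(records, function(r) {
    if (!inherits(r, "htl_run")) stop_domain("records must be `htl_run` objects")
    cnd <- r$condition; sl <- r$slate; cr <- r$crude
    out <- c(
      condition_id = r$condition_id,
      temperature_c = fmt(cnd$temperature_c),
      residence_min = fmt(cnd$residence_min),
      reactor = cnd$reactor_label,
      catalyst_frac = fmt(cnd$catalyst_loading_frac),
      cosolvent = cnd$cosolvent_name,
      cosolvent_ratio = fmt(cnd$cosolvent_water_mass_ratio),
      biomass_solvent_ratio = fmt(cnd$biomass_to_solvent_ratio),
      feed_dry_mass_g = fmt(sl$feed_dry_mass_g),
      b1_g = fmt(sl$biocrude1_mass_g), b2_g = fmt(sl$biocrude2_mass_g),
      solids_g = fmt(sl$solids_mass_g), gas_g = fmt(sl$gas_mass_g),
      nvr_g = fmt(sl$nvr_mass_g),
      crude_c_pct = fmt(cr$carbon_pct), crude_h_pct = fmt(cr$hydrogen_pct),
      crude_n_pct = fmt(cr$nitrogen_pct), crude_ash_pct = fmt(cr$ash_pct),
      crude_hhv = fmt(cr$hhv_mj_per_kg))
    if (!is.null(r$acp)) {
      a <- r$acp
      out <- c(out, acp_nh3 = fmt(a$nh3_n_mg_l), acp_kn = fmt(a$kjeldahl_n_mg_l),
               acp_no3no2 = fmt(a$no3_no2_mg_l), acp_tp = fmt(a$total_p_mg_l),
               acp_toc = fmt(a$toc_mg_l), acp_ph = fmt(a$ph),
               acp_nvr_pct = fmt(a$nvr_pct))
    } else out <- c(out, stats::setNames(rep("", length(cols$acp)), cols$acp))
    if (!is.null(r$gas)) {
      g <- r$gas$fractions
      pick <- function(sp) if (sp %in% names(g)) fmt(g[[sp]]) else ""
      out <- c(out, gas_co2 = pick("CO2"), gas_co = pick("CO"),
               gas_ch4 = pick("CH4"), gas_c2h6 = pick("C2H6"))
    } else out <- c(out, stats::setNames(rep("", length(cols$gas)), cols$gas))
    out[all_cols]
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!length(records))
    df <- as.data.frame(stats::setNames(rep(list(character()), length(all_cols)),
                                        all_cols))
  names(df) <- all_cols
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a feedstock composition from a JSON or YAML config
#'
#' Field names mirror the arguments of [feedstock_composition()].
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @param proximate_tol Passed to [feedstock_composition()].
#' @return A `feedstock_composition` object.
#' @export
read_feedstock_config <- function(path, proximate_tol = 2) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop_domain("unsupported config extension: .", ext))
  fa <- cfg$fatty_acid_profile
  fa <- if (is.null(fa)) numeric() else unlist(fa)
  args <- cfg[setdiff(names(cfg), "fatty_acid_profile")]
  do.call(feedstock_composition,
          c(args, list(fatty_acid_profile = fa, proximate_tol = proximate_tol)))
}
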