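# Discounted-cash-flow techno-economic engine: process-level cost
# allocation, phased capital deployment, a yearly cash-flow table, a
# bisection solver for the minimum fuel selling price (MFSP), and
# one-at-a-time sensitivity analysis.

#' Financial assumptions for the discounted cash flow
#'
#' BETO-style plant finance assumptions: target internal rate of return,
#' income tax rate, plant life, capital phasing over the build years,
#' annual fuel output, and straight-line depreciation.  Defaults follow
#' the reference plant: 10 % IRR, 35 % tax, 30-year life, 8/60/32 %
#' capital phasing over a 3-year build, 72 million litres of fuel per
#' year, and a biomass production cost of $1205 per tonne.
#'
#' @param irr Internal rate of return used as the discount rate
#'   (fraction, > 0).
#' @param income_tax_rate Income tax rate, fraction in [0, 1).
#' @param plant_life_years Number of production years (>= 1).
#' @param build_phase_fractions Fractions of capital spent in each build
#'   year (must sum to 1); `numeric(0)` collapses phasing to a single
#'   year-0 outlay (the analytic limit used by the closed-form checks).
#' @param annual_fuel_liters Fuel output per production year, litres.
#' @param liters_per_gallon Volume conversion constant (3.78541 L/gal).
#' @param biomass_cost_usd_per_tonne Upstream biomass production cost,
#'   carried for reporting and sensitivity work.
#' @param depreciation_years Straight-line depreciation period, years.
#' @param working_capital_frac Working capital as a fraction of capex
#'   (0 disables it; spent in the last build year, recovered in the final
#'   production year, not depreciated).
#' @return An object of class `financial_assumptions`.
#' @export
financial_assumptions <- function(irr = 0.10, income_tax_rate = 0.35,
                                  plant_life_years = 30,
                                  build_phase_fractions = c(0.08, 0.60, 0.32),
                                  annual_fuel_liters = 72e6,
                                  liters_per_gallon = 3.78541,
                                  biomass_cost_usd_per_tonne = 1205,
                                  depreciation_years = 10,
                                  working_capital_frac = 0) {
  check_num(irr, "irr", 1e-9)
  check_num(income_tax_rate, "income_tax_rate", 0, 1 - 1e-12)
  check_num(plant_life_years, "plant_life_years", 1)
  check_num(annual_fuel_liters, "annual_fuel_liters", 1e-9)
  check_num(liters_per_gallon, "liters_per_gallon", 1e-9)
  check_num(biomass_cost_usd_per_tonne, "biomass_cost_usd_per_tonne", 0)
  check_num(depreciation_years, "depreciation_years", 1)
  check_num(working_capital_frac, "working_capital_frac", 0, 1)
  if (length(build_phase_fractions)) {
    if (any(build_phase_fractions < 0) ||
        abs(sum(build_phase_fractions) - 1) > 1e-9)
      stop_domain("build_phase_fractions must be non-negative and sum to 1")
  }
  structure(list(irr = irr, income_tax_rate = income_tax_rate,
                 plant_life_years = plant_life_years,
                 build_phase_fractions = build_phase_fractions,
                 annual_fuel_liters = annual_fuel_liters,
                 liters_per_gallon = liters_per_gallon,
                 biomass_cost_usd_per_tonne = biomass_cost_usd_per_tonne,
                 depreciation_years = depreciation_years,
                 working_capital_frac = working_capital_frac),
            class = "financial_assumptions")
}

#' Allocate plant totals across processes
#'
#' Splits total capital and operating costs across the plant's processes
#' (fermentation, harvesting, HTL, upgrading, ...) by fixed fractions.
#' Each fraction set must sum to one within 1e-6; the allocated amounts
#' reproduce the totals exactly.
#'
#' @param total_capex_usd,total_opex_usd Plant totals, USD.
#' @param fractions Data frame with columns `process_label`,
#'   `capex_fraction`, `opex_fraction`.
#' @return The `fractions` data frame with added `capex_usd` and
#'   `opex_usd` columns.
#' @export
allocate_costs <- function(total_capex_usd, total_opex_usd, fractions) {
  check_num(total_capex_usd, "total_capex_usd", 0)
  check_num(total_opex_usd, "total_opex_usd", 0)
  need <- c("process_label", "capex_fraction", "opex_fraction")
  if (!is.data.frame(fractions) || !all(need %in% names(fractions)))
    stop_domain("`fractions` needs columns ", paste(need, collapse = ", "))
  for (col in c("capex_fraction", "opex_fraction")) {
    f <- fractions[[col]]
    if (any(f < 0 | f > 1))
      stop_domain("`", col, "` values must lie in [0, 1]")
    if (abs(sum(f) - 1) > 1e-6)
      stop_domain("`", col, "` must sum to 1, got ", format(sum(f)))
  }
  fractions$capex_usd <- total_capex_usd * fractions$capex_fraction
  fractions$opex_usd <- total_opex_usd * fractions$opex_fraction
  fractions
}

#' Yearly discounted cash-flow table
#'
#' Builds the project cash flow at a given fuel price: phased capital in
#' the build years (no revenue), then production years with revenue
#' `price x annual gallons`, operating cost, straight-line depreciation,
#' and tax `rate x max(0, revenue - opex - depreciation)`.  Flows use the
#' end-of-year convention and are discounted to year 0 at the IRR.  With
#' empty `build_phase_fractions` the full capital is an undiscounted
#' year-0 outlay and production runs over years 1 to `plant_life_years`.
#'
#' @param assumptions A [financial_assumptions()].
#' @param total_capex Total capital investment, USD.
#' @param annual_opex Annual operating cost, USD per production year.
#' @param fuel_price_usd_per_gal Fuel selling price, USD per gallon.
#' @return An object of class `cash_flow_table`: list with `table` (one
#'   row per year: `year`, `capital_outlay`, `operating_cost`, `revenue`,
#'   `depreciation`, `taxable_income`, `tax`, `net_cash_flow`) and scalar
#'   `npv`.
#' @export
build_cash_flow <- function(assumptions, total_capex, annual_opex,
                            fuel_price_usd_per_gal) {
  if (!inherits(assumptions, "financial_assumptions"))
    stop_domain("`assumptions` must be a financial_assumptions")
  check_num(total_capex, "total_capex", 0)
  check_num(annual_opex, "annual_opex", 0)
  check_num(fuel_price_usd_per_gal, "fuel_price_usd_per_gal", 0)
  a <- assumptions
  nb <- length(a$build_phase_fractions)
  n_prod <- a$plant_life_years
  gallons <- a$annual_fuel_liters / a$liters_per_gallon
  wc <- a$working_capital_frac * total_capex

  years <- if (nb == 0L) 0:n_prod else 1:(nb + n_prod)
  k <- length(years)
  capital <- numeric(k); opex <- numeric(k); revenue <- numeric(k)
  dep <- numeric(k)
  if (nb == 0L) {
    capital[1] <- total_capex + wc
    prod_idx <- 2:k
  } else {
    capital[1:nb] <- a$build_phase_fractions * total_capex
    capital[nb] <- capital[nb] + wc
    prod_idx <- (nb + 1):k
  }
  opex[prod_idx] <- annual_opex
  revenue[prod_idx] <- fuel_price_usd_per_gal * gallons
  n_dep <- min(a$depreciation_years, n_prod)
  dep[prod_idx[seq_len(n_dep)]] <- total_capex / a$depreciation_years
  taxable <- revenue - opex - dep
  tax <- a$income_tax_rate * pmax(0, taxable)
  tax[-prod_idx] <- 0
  net <- revenue - opex - tax - capital
  net[k] <- net[k] + wc                     # working capital recovered
  disc <- (1 + a$irr)^(-years)
  structure(list(
    table = data.frame(year = years, capital_outlay = capital,
                       operating_cost = opex, revenue = revenue,
                       depreciation = dep, taxable_income = taxable,
                       tax = tax, net_cash_flow = net),
    npv = sum(net * disc)),
    class = "cash_flow_table")
}

#' Net present value at a given fuel price
#'
#' Convenience wrapper returning only the NPV of [build_cash_flow()].
#'
#' @inheritParams build_cash_flow
#' @return NPV in USD.
#' @export
project_npv <- function(assumptions, total_capex, annual_opex,
                        fuel_price_usd_per_gal) {
  build_cash_flow(assumptions, total_capex, annual_opex,
                  fuel_price_usd_per_gal)$npv
}

#' Capital recovery factor
#'
#' The annuity factor `r (1+r)^n / ((1+r)^n - 1)` converting a capital sum
#' into an equivalent constant annual cost over `n` years at rate `r`.
#' In the no-tax, no-phasing limit the minimum fuel selling price equals
#' `(CRF x capex + opex) / annual gallons`, which serves as the engine's
#' closed-form cross-check.
#'
#' @param rate Discount rate, fraction (> 0).
#' @param n_years Number of years (>= 1).
#' @return The capital recovery factor.
#' @export
capital_recovery_factor <- function(rate, n_years) {
  check_num(rate, "rate", 1e-12)
  check_num(n_years, "n_years", 1)
  rate * (1 + rate)^n_years / ((1 + rate)^n_years - 1)
}

#' Minimum fuel selling price
#'
#' Solves for the fuel price at which the project NPV is zero at the
#' target IRR, by bisection.  The NPV is piecewise linear and strictly
#' increasing in price, so the root is unique; the bracket starts at
#' [0, 100] USD per gallon and the upper end is doubled until the NPV
#' changes sign.  Iteration stops when the NPV at the candidate price is
#' within `npv_tol` dollars of zero (well inside $0.001/gal on the price).
#'
#' @inheritParams build_cash_flow
#' @param npv_tol Convergence tolerance on |NPV|, USD.
#' @param max_iter Maximum bisection iterations.
#' @return MFSP in USD per gallon.
#' @export
solve_mfsp <- function(assumptions, total_capex, annual_opex,
                       npv_tol = 0.01, max_iter = 500L) {
  f <- function(p) project_npv(assumptions, total_capex, annual_opex, p)
  lo <- 0; flo <- f(lo)
  if (abs(flo) <= npv_tol) return(lo)
  if (flo > 0)
    stop_domain("NPV is positive at zero price; costs are degenerate")
  hi <- 100; fhi <- f(hi)
  while (fhi < 0 && hi < 1e9) { hi <- hi * 2; fhi <- f(hi) }
  if (fhi < 0) stop_domain("no sign change in price bracket after expansion")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) <= npv_tol || (hi - lo) < 1e-13 * max(1, mid)) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' One-at-a-time sensitivity of the MFSP
#'
#' Perturbs each named input by plus/minus a fraction, recomputes the
#' MFSP, and returns the deltas ranked by magnitude (tornado ordering).
#' Perturbable inputs are `total_capex`, `annual_opex`, and any numeric
#' field of the [financial_assumptions()] (e.g. `irr`,
#' `income_tax_rate`, `annual_fuel_liters` as the fuel-yield lever).  A
#' perturbation that produces invalid assumptions is recorded as an error
#' on that row and the run continues.
#'
#' @inheritParams build_cash_flow
#' @param perturbations Named numeric vector of relative perturbations
#'   (e.g. `c(total_capex = 0.1, irr = 0.1)`).
#' @return A data frame with one row per input: the perturbed MFSPs, the
#'   signed deltas from the base MFSP, `max_abs_delta` (sort key,
#'   descending) and an `error` message column (`NA` when clean).
#' @export
sensitivity_oat <- function(assumptions, total_capex, annual_opex,
                            perturbations) {
  if (is.null(names(perturbations)) || any(!nzchar(names(perturbations))))
    stop_domain("`perturbations` must be a named numeric vector")
  base_mfsp <- solve_mfsp(assumptions, total_capex, annual_opex)
  eval_one <- function(input, frac, sign) {
    capex <- total_capex; opex <- annual_opex; a <- unclass(assumptions)
    mult <- 1 + sign * frac
    if (input == "total_capex") capex <- capex * mult
    else if (input == "annual_opex") opex <- opex * mult
    else if (input %in% names(a) && is.numeric(a[[input]]))
      a[[input]] <- a[[input]] * mult
    else stop_domain("unknown sensitivity input `", input, "`")
    solve_mfsp(do.call(financial_assumptions, a), capex, opex)
  }
  rows <- lapply(names(perturbations), function(input) {
    frac <- perturbations[[input]]
    res <- tryCatch({
      lo <- eval_one(input, frac, -1)
      hi <- eval_one(input, frac, +1)
      list(lo = lo, hi = hi, err = NA_character_)
    }, error = function(e)
      list(lo = NA_real_, hi = NA_real_, err = conditionMessage(e)))
    data.frame(input = input, perturbation_frac = frac,
               mfsp_minus = res$lo, mfsp_plus = res$hi,
               delta_minus = res$lo - base_mfsp,
               delta_plus = res$hi - base_mfsp,
               max_abs_delta = max(abs(c(res$lo, res$hi) - base_mfsp),
                                   na.rm = !is.na(res$lo)),
               error = res$err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$max_abs_delta[is.na(out$mfsp_minus)] <- NA_real_
  out[order(-out$max_abs_delta, na.last = TRUE), , drop = FALSE]
}
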