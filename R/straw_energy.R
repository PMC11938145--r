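# Straw circular-economy stage: allocation of collected biomass to field
# return, biochar preparation, power generation and sale, plus the energy
# conversion chain and the straw/electricity revenue terms.

#' Straw allocation weights
#'
#' @param pr_straw,pr_biochar,pr_ele,pr_sell fractions of the collected
#'   biomass routed to field return, biochar preparation, electricity
#'   generation and direct sale.  Each lies in `[0, 1]` and they sum to 1.
#' @return A named numeric vector of class `"straw_allocation"`.
#' @export
straw_allocation <- function(pr_straw, pr_biochar, pr_ele, pr_sell) {
  w <- c(pr_straw = pr_straw, pr_biochar = pr_biochar,
         pr_ele = pr_ele, pr_sell = pr_sell)
  .check(all(w >= 0 & w <= 1), "allocation weights must lie in [0, 1]")
  .check(abs(sum(w) - 1) <= 1e-9, "allocation weights must sum to 1")
  structure(w, class = c("straw_allocation", "numeric"))
}

#' Packaged straw-allocation scenarios
#'
#' Returns the five canonical allocation scenarios (equal weights, field
#' return prioritized, biochar prioritized, power generation prioritized,
#' sale prioritized) shipped with the package as a CSV table.
#'
#' @return A data.frame with columns `scenario`, `pr_straw`, `pr_biochar`,
#'   `pr_ele`, `pr_sell`.
#' @export
straw_scenarios <- function() {
  path <- system.file("extdata", "straw_scenarios.csv", package = "strawcycle")
  .check(nzchar(path), "packaged scenario table not found")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Straw mass returned to the field
#'
#' @param pr_straw return fraction in `[0, 1]`.
#' @param Q_biomass collected biomass (kg).
#' @return kg of straw returned.
#' @export
straw_returned <- function(pr_straw, Q_biomass) {
  .check(all(pr_straw >= 0 & pr_straw <= 1), "pr_straw must lie in [0, 1]")
  .check(all(Q_biomass >= 0), "Q_biomass must be non-negative")
  pr_straw * Q_biomass
}

#' Electricity from direct straw combustion
#'
#' `Q_ele_com = Hv * zeta_the * rho_com * pr_ele * Q / 3.6` (kJ -> kWh).
#'
#' @param params energy parameter list with `Hv` (kJ/kg), `zeta_the`
#'   (thermal efficiency), `rho_com` (combustion ratio).
#' @param pr_ele fraction of biomass routed to power generation.
#' @param Q collected biomass (kg).
#' @return Electricity (kWh).
#' @export
electricity_combustion <- function(params, pr_ele, Q) {
  .check(all(Q >= 0), "Q must be non-negative")
  params$Hv * params$zeta_the * params$rho_com * pr_ele * Q / 3.6
}

#' Electricity from straw gasification
#'
#' `Q_ele_gas = Hv * zeta_the * zeta_com * rho_gas * pr_ele * Q / 3.6`,
#' with `zeta_com` the mechanical-to-electrical conversion coefficient.
#'
#' @inheritParams electricity_combustion
#' @return Electricity (kWh).
#' @export
electricity_gasification <- function(params, pr_ele, Q) {
  .check(all(Q >= 0), "Q must be non-negative")
  params$Hv * params$zeta_the * params$zeta_com * params$rho_gas *
    pr_ele * Q / 3.6
}

#' Biochar produced for field application
#'
#' Two sources: the gasification byproduct of the biochar-allocated straw
#' net of the electricity offset (`eta_gas * pr * Q - eta_gas_ele *
#' Q_ele_gas`, floored at zero with a warning when the offset dominates)
#' plus pyrolysis output `eta_pyr * pr * Q`.
#'
#' @param params energy parameter list with `eta_gas`, `eta_pyr`,
#'   `eta_gas_ele`.
#' @param pr_biochar fraction of biomass routed to biochar.
#' @param Q collected biomass (kg).
#' @param Q_ele_gas electricity generated by gasification (kWh).
#' @return Biochar (kg).
#' @export
biochar_output <- function(params, pr_biochar, Q, Q_ele_gas) {
  .check(all(Q >= 0) && all(Q_ele_gas >= 0), "inputs must be non-negative")
  gas_term <- params$eta_gas * pr_biochar * Q - params$eta_gas_ele * Q_ele_gas
  if (any(gas_term < 0)) {
    warning("gasification biochar fully offset by electricity term; floored at 0")
    gas_term <- pmax(gas_term, 0)
  }
  gas_term + params$eta_pyr * pr_biochar * Q
}

#' Revenue from electricity sales
#'
#' @param price_sell selling price of electricity (10^3 yuan/kWh).
#' @param Q_com,Q_gas electricity from combustion and gasification (kWh).
#' @return Revenue (10^3 yuan).
#' @export
electricity_revenue <- function(price_sell, Q_com, Q_gas) {
  .check(all(c(price_sell, Q_com, Q_gas) >= 0), "inputs must be non-negative")
  price_sell * (Q_com + Q_gas)
}

#' Revenue from straw sales
#'
#' Initial stage: the sale-allocated share of the collected biomass,
#' `price * pr_sell * Q_st`.  Recycling stage: all collected straw is sold,
#' `price * Q_st1`.
#'
#' @param price straw price (10^3 yuan/kg).
#' @param pr_sell sale fraction in the initial stage.
#' @param Q_st,Q_st1 collected biomass in the two stages (kg).
#' @return Named vector with `initial` and `recycle` revenues (10^3 yuan).
#' @export
straw_sale_revenue <- function(price, pr_sell, Q_st, Q_st1) {
  .check(all(c(price, pr_sell, Q_st, Q_st1) >= 0), "inputs must be non-negative")
  c(initial = price * pr_sell * Q_st, recycle = price * Q_st1)
}
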