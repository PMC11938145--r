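# Net-economic-benefit accounting: revenues minus material, electricity
# and irrigation-water costs.  All costs and revenues are carried per
# hectare; planted area multiplies in exactly once, at aggregation.

#' Material cost per hectare
#'
#' Initial stage: seed, fertilizer, pesticide, diesel, agricultural film
#' and labor, each `price * usage`.  Recycling stage: the same basket plus
#' purchased biochar and straw at their per-hectare application amounts.
#'
#' @param usage list with `D_see`, `D_fer`, `D_pes`, `D_fue`, `D_fil`
#'   (kg/ha) and `D_lab` (h/ha).
#' @param prices list with `P_see`, `P_fer`, `P_pes`, `P_fue`, `P_fil`
#'   (10^3 yuan/kg), `P_lab` (10^3 yuan/h), `P_biochar`, `P_straw`.
#' @param stage `"initial"` or `"recycle"`.
#' @param biochar_amt,straw_amt recycling-stage applications (kg/ha).
#' @return Cost (10^3 yuan/ha).
#' @export
material_cost <- function(usage, prices, stage = "initial",
                          biochar_amt = 0, straw_amt = 0) {
  .check(stage %in% c("initial", "recycle"), "stage must be initial or recycle")
  base <- prices$P_see * usage$D_see + prices$P_fer * usage$D_fer +
    prices$P_pes * usage$D_pes + prices$P_fue * usage$D_fue +
    prices$P_fil * usage$D_fil + prices$P_lab * usage$D_lab
  if (stage == "recycle") {
    base <- base + prices$P_biochar * biochar_amt + prices$P_straw * straw_amt
  }
  base
}

#' Electricity cost per hectare
#'
#' `P_ele_pur * (D_lig * H_lig + D_irr * V_irr + D_rol * tau_rol)` with the
#' irrigation volume `V_irr = 10 * sum(I)` converting mm depth to m3/ha.
#'
#' @param usage list with `D_ele_lig` (kW/h), `H_lig` (h/ha), `D_ele_irr`
#'   (kWh/m3), `D_ele_rol` (kW/ha) and `tau_rol` (roller efficiency).
#' @param prices list with `P_ele_pur` (10^3 yuan/kWh).
#' @param total_irrigation_mm seasonal irrigation depth (mm).
#' @return Cost (10^3 yuan/ha).
#' @export
electricity_cost <- function(usage, prices, total_irrigation_mm) {
  .check(all(total_irrigation_mm >= 0), "irrigation must be non-negative")
  kwh <- usage$D_ele_lig * usage$H_lig +
    usage$D_ele_irr * 10 * total_irrigation_mm +
    usage$D_ele_rol * usage$tau_rol
  prices$P_ele_pur * kwh
}

# electricity demand (kWh/ha) implied by the same terms; used by the
# electricity-supply constraint, which compares demand with availability
electricity_demand_kwh <- function(usage, total_irrigation_mm) {
  usage$D_ele_lig * usage$H_lig +
    usage$D_ele_irr * 10 * total_irrigation_mm +
    usage$D_ele_rol * usage$tau_rol
}

#' Irrigation water cost per hectare
#'
#' @param price_wat water price (10^3 yuan/m3).
#' @param total_irrigation_mm seasonal irrigation depth (mm); priced as
#'   `10 * mm` m3/ha.
#' @return Cost (10^3 yuan/ha).
#' @export
water_cost <- function(price_wat, total_irrigation_mm) {
  .check(all(c(price_wat, total_irrigation_mm) >= 0),
         "price and irrigation must be non-negative")
  price_wat * 10 * total_irrigation_mm
}

#' Total system revenue
#'
#' Crop sales over both stages plus straw revenues of both stages plus
#' electricity sales: `sum_c P_c * A_c * (Y_st + Y_st1) + S_straw_st +
#' S_straw_st1 + E_ele`.
#'
#' @param areas planted area per crop (ha).
#' @param yields_st,yields_st1 per-crop yields in the two stages (kg/ha).
#' @param crop_prices per-crop prices (10^3 yuan/kg).
#' @param straw_rev total straw revenue, both stages (10^3 yuan).
#' @param ele_rev electricity revenue (10^3 yuan).
#' @return Revenue (10^3 yuan).
#' @export
total_revenue <- function(areas, yields_st, yields_st1, crop_prices,
                          straw_rev = 0, ele_rev = 0) {
  .check(length(areas) == length(yields_st) &&
           length(areas) == length(yields_st1) &&
           length(areas) == length(crop_prices),
         "per-crop vectors must have equal length")
  sum(crop_prices * areas * (yields_st + yields_st1)) + straw_rev + ele_rev
}

#' Net economic benefit
#'
#' @param revenue,cost totals in the same currency unit.
#' @return `revenue - cost` (may be negative).
#' @export
net_economic_benefit <- function(revenue, cost) revenue - cost
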