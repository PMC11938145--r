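# Environmental objectives: greenhouse-gas inventory (CO2, CH4, N2O with
# GWP aggregation) net of soil/crop carbon sequestration, and the
# green/blue/gray water footprint of production.

#' CO2 emissions from production inputs
#'
#' Initial stage: `A * sum(sigma_x * D_x)` over seed, fertilizer,
#' pesticide, diesel, film and labor.  Recycling stage: the initial
#' inventory scaled by `(1 + amendment_alpha)`, the amendment response of
#' the CO2 flux to biochar/straw application (typically negative).
#'
#' @param usage list with `D_see`, `D_fer`, `D_pes`, `D_fue`, `D_fil`,
#'   `D_lab` (per-ha usages).
#' @param factors list with `sigma_see`, `sigma_fer`, `sigma_pes`,
#'   `sigma_fue`, `sigma_fil` (kg CO2/kg) and `sigma_lab` (kg CO2/h).
#' @param area planted area (ha).
#' @param stage `"initial"` or `"recycle"`.
#' @param amendment_alpha amendment response of the flux (recycle stage).
#' @return kg CO2.
#' @export
co2_emissions <- function(usage, factors, area, stage = "initial",
                          amendment_alpha = 0) {
  .check(stage %in% c("initial", "recycle"), "stage must be initial or recycle")
  base <- area * (factors$sigma_see * usage$D_see +
                    factors$sigma_fer * usage$D_fer +
                    factors$sigma_pes * usage$D_pes +
                    factors$sigma_fue * usage$D_fue +
                    factors$sigma_fil * usage$D_fil +
                    factors$sigma_lab * usage$D_lab)
  if (stage == "recycle") base <- recycled_stage_value(base, amendment_alpha)
  base
}

#' CH4 emissions
#'
#' Area-based: `A * omicron`, amended in the recycling stage.
#'
#' @param area planted area (ha).
#' @param omicron CH4 emission per unit area (kg/ha).
#' @param stage `"initial"` or `"recycle"`.
#' @param amendment_alpha amendment response (recycle stage).
#' @return kg CH4.
#' @export
ch4_emissions <- function(area, omicron, stage = "initial",
                          amendment_alpha = 0) {
  .check(all(c(area, omicron) >= 0), "inputs must be non-negative")
  base <- area * omicron
  if (stage == "recycle") base <- recycled_stage_value(base, amendment_alpha)
  base
}

#' N2O emissions
#'
#' `A * (nu + D_fer * nu_fer)`: crop background emission plus the
#' fertilizer-induced term; amended in the recycling stage.
#'
#' @param area planted area (ha).
#' @param nu crop N2O emission factor (kg/ha-equivalent background term).
#' @param D_fer nitrogen fertilizer applied (kg/ha).
#' @param nu_fer fertilizer N2O emission factor (kg/kg).
#' @param stage `"initial"` or `"recycle"`.
#' @param amendment_alpha amendment response (recycle stage).
#' @return kg N2O.
#' @export
n2o_emissions <- function(area, nu, D_fer, nu_fer, stage = "initial",
                          amendment_alpha = 0) {
  .check(all(c(area, nu, D_fer, nu_fer) >= 0), "inputs must be non-negative")
  base <- area * (nu + D_fer * nu_fer)
  if (stage == "recycle") base <- recycled_stage_value(base, amendment_alpha)
  base
}

#' Total greenhouse-gas emissions in CO2 equivalents
#'
#' `f_TCE = sum over stages of (CO2 + gwp_ch4 * CH4 + gwp_n2o * N2O)`,
#' with the standard 100-year global warming potentials 28 (CH4) and
#' 298 (N2O) as defaults.
#'
#' @param co2_st,ch4_st,n2o_st initial-stage emissions (kg of each gas).
#' @param co2_st1,ch4_st1,n2o_st1 recycling-stage emissions.
#' @param gwp_ch4,gwp_n2o global warming potentials.
#' @return kg CO2e.
#' @export
total_ghg <- function(co2_st, ch4_st, n2o_st,
                      co2_st1 = 0, ch4_st1 = 0, n2o_st1 = 0,
                      gwp_ch4 = 28, gwp_n2o = 298) {
  .check(all(c(co2_st, ch4_st, n2o_st, co2_st1, ch4_st1, n2o_st1) >= 0),
         "emissions must be non-negative")
  (co2_st + gwp_ch4 * ch4_st + gwp_n2o * n2o_st) +
    (co2_st1 + gwp_ch4 * ch4_st1 + gwp_n2o * n2o_st1)
}

#' Carbon sequestered by crops, biochar and straw return
#'
#' Crop term per stage: `Y * Cc * A * (1 - W) * (1 + Rrsr) / Hc` (biomass
#' carbon back-calculated from grain yield via moisture `W`, root-shoot
#' ratio `Rrsr` and harvest index `Hc`).  The recycling stage adds the
#' fixed carbon of applied biochar and returned straw.
#'
#' @param Y_st,Y_st1 grain yields in the two stages (kg/ha).
#' @param seq_params list with `Cc`, `Hc`, `Rrsr`, `W`, `Cq_biochar`,
#'   `Cq_straw`.
#' @param biochar,straw recycling-stage applications (kg/ha).
#' @param area planted area (ha).
#' @return kg C (CO2-equivalent basis of the inventory).
#' @export
carbon_sequestration <- function(Y_st, Y_st1, seq_params, biochar = 0,
                                 straw = 0, area = 1) {
  p <- seq_params
  .check(p$Hc > 0, "harvest index Hc must be positive")
  .check(all(c(Y_st, Y_st1, biochar, straw, area) >= 0),
         "inputs must be non-negative")
  crop_st <- Y_st * p$Cc * area * (1 - p$W) * (1 + p$Rrsr) / p$Hc
  crop_st1 <- (Y_st1 * p$Cc * (1 - p$W) * (1 + p$Rrsr) / p$Hc +
                 biochar * p$Cq_biochar + straw * p$Cq_straw) * area
  crop_st + crop_st1
}

#' Carbon footprint intensity
#'
#' `F_CF = sum_c (f_TCE - f_CS) / (Y_st + Y_st1)`; negative values mean
#' the system is a net sink.  Vectorized over crops and summed.
#'
#' @param f_TCE total GHG emissions per crop (kg CO2e).
#' @param f_CS carbon sequestration per crop (kg).
#' @param Y_st,Y_st1 per-crop yields (kg/ha), with `Y_st + Y_st1 > 0`.
#' @return kg CO2e per kg of yield.
#' @export
carbon_footprint <- function(f_TCE, f_CS, Y_st, Y_st1) {
  tot <- Y_st + Y_st1
  .check(all(tot > 0), "total yield must be positive")
  sum((f_TCE - f_CS) / tot)
}

#' Green water footprint
#'
#' Effective rainfall per unit yield: `10 * sum(P) / sum(Y)` (mm -> m3/ha).
#'
#' @param P_mm total effective rainfall over both stages (mm).
#' @param Y_total total yield over both stages (kg/ha), > 0.
#' @return m3/kg.
#' @export
green_wf <- function(P_mm, Y_total) {
  .check(all(Y_total > 0), "yield must be positive")
  .check(all(P_mm >= 0), "rainfall must be non-negative")
  10 * P_mm / Y_total
}

#' Blue water footprint
#'
#' Irrigation water per unit yield: `10 * sum(I) / sum(Y)`.
#'
#' @param I_mm total irrigation over both stages (mm).
#' @param Y_total total yield over both stages (kg/ha), > 0.
#' @return m3/kg.
#' @export
blue_wf <- function(I_mm, Y_total) {
  .check(all(Y_total > 0), "yield must be positive")
  .check(all(I_mm >= 0), "irrigation must be non-negative")
  10 * I_mm / Y_total
}

#' Gray water footprint
#'
#' Dilution water needed to bring leached nitrogen to the acceptable
#' concentration: `nu_LRNF * (N_st + N_st1) / (Y_total * (C_max - C_n))`
#' with concentrations in kg/m3.
#'
#' @param gray_params list with `nu_LRNF` (leaching fraction), `C_max` and
#'   `C_n` (kg/m3, `C_max > C_n`).
#' @param N_st,N_st1 nitrogen applied in the two stages (kg/ha).
#' @param Y_total total yield (kg/ha), > 0.
#' @return m3/kg.
#' @export
gray_wf <- function(gray_params, N_st, N_st1, Y_total) {
  g <- gray_params
  .check(g$C_max > g$C_n, "C_max must exceed C_n")
  .check(all(Y_total > 0), "yield must be positive")
  .check(all(c(N_st, N_st1) >= 0), "nitrogen must be non-negative")
  g$nu_LRNF * (N_st + N_st1) / (Y_total * (g$C_max - g$C_n))
}

#' Total water footprint
#'
#' @param green,blue,gray component footprints (m3/kg, non-negative).
#' @return `green + blue + gray` (m3/kg).
#' @export
water_footprint <- function(green, blue, gray) {
  .check(all(c(green, blue, gray) >= 0), "components must be non-negative")
  green + blue + gray
}

#' Convert a concentration from mg/L to kg/m3
#'
#' @param mg_per_l concentration in mg/L.
#' @return kg/m3 (numerically `mg_per_l * 1e-3`).
#' @export
mg_per_l_to_kg_per_m3 <- function(mg_per_l) mg_per_l * 1e-3
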