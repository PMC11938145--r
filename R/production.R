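# Crop production stage: irrigation quota, field water balance, Jensen
# water-production model, quadratic nitrogen response, equivalent yield,
# residue biomass and amendment-driven recycling-stage responses.

#' Soil parameter set
#'
#' @param theta_fc field capacity (cm3/cm3, volumetric fraction).
#' @param theta_rwp wilting point (cm3/cm3).
#' @param theta_v pre-irrigation soil water content (cm3/cm3).
#' @param bulk_density soil bulk density (g/cm3).
#' @param z_r designed depth of the wetted layer (cm).
#' @param wetting_ratio wetted fraction of the surface under drip emitters.
#' @return A validated list of class `"soil_params"`.
#' @export
soil_params <- function(theta_fc = 0.3054, theta_rwp = 0.1272, theta_v = 0.20,
                        bulk_density = 1.20, z_r = 40, wetting_ratio = 0.6) {
  .check(theta_rwp > 0 && theta_rwp < theta_fc && theta_fc < 1,
         "need 0 < theta_rwp < theta_fc < 1")
  .check(z_r > 0, "z_r must be positive")
  .check(wetting_ratio > 0 && wetting_ratio <= 1, "wetting_ratio in (0, 1]")
  structure(list(theta_fc = theta_fc, theta_rwp = theta_rwp, theta_v = theta_v,
                 bulk_density = bulk_density, z_r = z_r,
                 wetting_ratio = wetting_ratio), class = "soil_params")
}

#' Full irrigation quota per application
#'
#' `I = 10 * (0.9 * theta_fc - theta_v) * z_r * wetting_ratio`, the amount
#' (mm) that refills the wetted layer to 90% of field capacity, used as the
#' upper irrigation limit of the fully irrigated treatment.
#'
#' @param soil a [soil_params()] object.
#' @return Quota in mm (zero, with a warning, if the soil is already at or
#'   above 90% of field capacity).
#' @examples
#' full_irrigation_quota(soil_params(theta_fc = 0.30, theta_v = 0.15,
#'                                   z_r = 40, wetting_ratio = 0.6)) # 28.8
#' @export
full_irrigation_quota <- function(soil) {
  target <- 0.9 * soil$theta_fc
  if (soil$theta_v >= target) {
    warning("soil water already at/above 90% of field capacity; zero quota")
    return(0)
  }
  10 * (target - soil$theta_v) * soil$z_r * soil$wetting_ratio
}

#' Actual evapotranspiration from the field water balance
#'
#' Rearranges the stage water balance
#' `dW = P + I + G - D - R - ET_a` to `ET_a = P + I + G - D - R - dW`.
#' A negative result signals inconsistent balance inputs and is an error.
#'
#' @param P,I,G effective rainfall, irrigation, groundwater recharge (mm).
#' @param D,R deep seepage and surface runoff (mm).
#' @param dW change in stored soil water (mm, any sign).
#' @return `ET_a` in mm.
#' @export
actual_et_from_balance <- function(P, I, G = 0, D = 0, R = 0, dW = 0) {
  .check(all(c(P, I, G, D, R) >= 0), "water fluxes must be non-negative")
  et <- P + I + G - D - R - dW
  .check(all(et >= 0), "negative ET_a: inconsistent water-balance inputs")
  et
}

#' Nitrogen-limited potential yield
#'
#' Quadratic response `Y_m = a*N^2 + b*N + c` with `a < 0` (concave); a
#' negative value is floored at zero with a warning so that an optimizer
#' probing extreme N rates cannot produce nonphysical output.
#'
#' @param params list with quadratic coefficients `a`, `b`, `c`.
#' @param N nitrogen application (kg/ha); vectorized.
#' @return Potential yield `Y_m` (kg/ha).
#' @export
nitrogen_potential_yield <- function(params, N) {
  .check(all(N >= 0), "N must be non-negative")
  y <- params$a * N^2 + params$b * N + params$c
  if (any(y < 0)) {
    warning("nitrogen response fell below zero; floored at 0")
    y <- pmax(y, 0)
  }
  y
}

#' Jensen multiplicative water production model
#'
#' `Y = Y_m * prod_t (ET_a(t)/ET_m(t))^lambda(t)`.  Stage ratios are
#' clipped to `[0, 1]` before exponentiation: sensitivity exponents reward
#' meeting, not exceeding, stage water demand, and ratios above one would
#' credit waterlogging.
#'
#' @param Y_m nitrogen-limited potential yield (kg/ha).
#' @param ET_a,ET_m actual and potential stage evapotranspiration vectors
#'   (mm, equal length; `ET_m > 0`).
#' @param lambda stage water-sensitivity exponents (>= 0).
#' @return Yield (kg/ha).
#' @export
jensen_yield <- function(Y_m, ET_a, ET_m, lambda) {
  .check(length(ET_a) == length(ET_m) && length(ET_m) == length(lambda),
         "stage vectors must have equal length")
  .check(all(ET_m > 0), "ET_m must be positive")
  .check(all(ET_a >= 0), "ET_a must be non-negative")
  .check(all(lambda >= 0), "lambda must be non-negative")
  r <- pmin(pmax(ET_a / ET_m, 0), 1)
  Y_m * prod(r^lambda)
}

#' Price-equivalent yield
#'
#' Rescales a crop's yield by its price relative to the reference crop
#' (tomato) so that yields of different crops can be compared and summed.
#'
#' @param yield crop yield (kg/ha).
#' @param price_crop crop price (same currency unit as `price_tomato`).
#' @param price_tomato reference (tomato) price, > 0.
#' @return Equivalent yield (kg/ha).
#' @export
equivalent_yield <- function(yield, price_crop, price_tomato) {
  .check(price_tomato > 0, "reference price must be positive")
  yield * price_crop / price_tomato
}

#' Generic quadratic amendment response
#'
#' The shared bivariate quadratic used for the yield, quality and per-gas
#' emission responses to biochar (`x`) and straw (`y`) application:
#' `alpha = a*x^2 + b*y^2 + c*x*y + d*x + e*y + f`.
#'
#' @param coeffs list with `a`..`f`.
#' @param biochar_amt,straw_amt application amounts (t/ha in the packaged
#'   defaults; the form itself is unit-agnostic).
#' @return The unitless response `alpha`.
#' @export
amendment_factor <- function(coeffs, biochar_amt, straw_amt) {
  .check(all(c(biochar_amt, straw_amt) >= 0), "amounts must be non-negative")
  x <- biochar_amt; y <- straw_amt
  coeffs$a * x^2 + coeffs$b * y^2 + coeffs$c * x * y +
    coeffs$d * x + coeffs$e * y + coeffs$f
}

#' Apply an amendment response to a recycling-stage value
#'
#' `value_{st+1} = (1 + alpha) * base`; `alpha <= -1` would flip the sign
#' of a physical quantity and is rejected.
#'
#' @param base non-negative initial-stage value.
#' @param alpha amendment response from [amendment_factor()].
#' @return Amended value.
#' @export
recycled_stage_value <- function(base, alpha) {
  .check(all(base >= 0), "base must be non-negative")
  .check(all(alpha > -1), "amendment response <= -1 is nonphysical")
  (1 + alpha) * base
}

#' Collectible residue biomass
#'
#' `Q = area * Y * omega * xi * psi`: grain yield scaled by the
#' grass-to-grain ratio, the recovery (collection) coefficient and the
#' straw-to-biomass ratio.
#'
#' @param area planted area (ha).
#' @param Y grain yield (kg/ha).
#' @param omega grass-to-grain ratio.
#' @param xi straw recovery coefficient (in (0, 1]).
#' @param psi straw-to-biomass ratio.
#' @return Biomass (kg).
#' @export
biomass_production <- function(area, Y, omega, xi, psi) {
  .check(all(c(area, Y, omega, xi, psi) >= 0), "inputs must be non-negative")
  area * Y * omega * xi * psi
}
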