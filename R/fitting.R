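# Recovery of generating coefficients from (noisy) observations.  Each
# fit divides the observed response by the parts of the forward model that
# are treated as known, then solves an ordinary least-squares problem for
# the remaining quadratic.  At zero noise the recovery is exact.

# mean observed value per treatment for one crop
.treatment_means <- function(observations, crop, column) {
  obs <- observations[observations$crop == crop, ]
  tapply(obs[[column]], obs$treatment, base::mean)
}

# known Jensen water factor and amendment yield factor for a design row
.known_yield_factor <- function(bundle, row, P_annual = NULL) {
  c_i <- match(row$crop, bundle$crops)
  annual <- P_annual %||% bundle$precip$mean
  P <- .stage_rainfall(bundle, annual)[c_i, ]
  I <- row$irrigation_mm * bundle$stage_frac
  et_m <- bundle$et_m[c_i, ]
  et_a <- pmin(P + I, et_m)
  jp <- bundle$jensen[[c_i]]
  jens <- prod(pmin(pmax(et_a / et_m, 0), 1)^jp$lambda)
  a_y <- amendment_factor(bundle$amendment[[c_i]]$yield,
                          row$biochar_t_ha, row$straw_t_ha)
  jens * (1 + a_y)
}

#' Refit the nitrogen-response quadratic from observations
#'
#' Divides observed yields by the known Jensen water factor and amendment
#' factor, averages replicates, and fits `Y_m = a N^2 + b N + c` by least
#' squares over the design's nitrogen levels.
#'
#' @param observations output of [generate_observations()].
#' @param bundle the generating [generate_parameters()] bundle.
#' @param design the design the observations were generated from.
#' @param crop crop name to fit.
#' @return List with `a`, `b`, `c` and the vertex `-b/(2a)`.
#' @export
fit_n_response <- function(observations, bundle, design, crop) {
  d <- design[design$crop == crop, ]
  ym_hat <- .treatment_means(observations, crop, "yield")
  ym_hat <- ym_hat[d$treatment] /
    vapply(seq_len(nrow(d)), function(i) .known_yield_factor(bundle, d[i, ]), 0)
  N <- d$nitrogen_kg_ha
  fit <- stats::lm(ym_hat ~ I(N^2) + N)
  co <- stats::coef(fit)
  list(a = unname(co["I(N^2)"]), b = unname(co["N"]),
       c = unname(co["(Intercept)"]),
       vertex = -unname(co["N"]) / (2 * unname(co["I(N^2)"])))
}

#' Refit the quality response surface from observations
#'
#' Divides observed quality scores by the known amendment quality factor
#' and fits the six-coefficient bivariate quadratic in (N, total I).
#' Requires a design spanning at least a 3 x 3 (N, I) grid.
#'
#' @inheritParams fit_n_response
#' @return List with `ac`, `bc`, `cc`, `dc`, `ec`, `fc`.
#' @export
fit_quality_surface <- function(observations, bundle, design, crop) {
  d <- design[design$crop == crop, ]
  c_i <- match(crop, bundle$crops)
  q_hat <- .treatment_means(observations, crop, "quality")[d$treatment]
  a_q <- vapply(seq_len(nrow(d)), function(i)
    amendment_factor(bundle$amendment[[c_i]]$tcq,
                     d$biochar_t_ha[i], d$straw_t_ha[i]), 0)
  q0 <- q_hat / (1 + a_q)
  N <- d$nitrogen_kg_ha
  I <- d$irrigation_mm
  fit <- stats::lm(q0 ~ I(N^2) + I(I^2) + N + I + I(N * I))
  co <- stats::coef(fit)
  list(ac = unname(co["I(N^2)"]), bc = unname(co["I(I^2)"]),
       cc = unname(co["N"]), dc = unname(co["I"]),
       ec = unname(co["I(N * I)"]), fc = unname(co["(Intercept)"]))
}

#' Refit an amendment quadratic from observations
#'
#' For each design point the amendment response is backed out as
#' `alpha_hat = observed / known_base - 1`, where the base is the forward
#' model without the amendment; the six-coefficient quadratic in
#' (biochar, straw) is then fit by least squares.  Needs a full-rank
#' amendment design such as [generate_amendment_design()].
#'
#' @inheritParams fit_n_response
#' @param response `"yield"` or `"quality"` surface to back out.
#' @return List with `a`..`f`.
#' @export
fit_amendment <- function(observations, bundle, design, crop,
                          response = "yield") {
  d <- design[design$crop == crop, ]
  c_i <- match(crop, bundle$crops)
  obs <- .treatment_means(observations, crop, response)[d$treatment]
  base <- vapply(seq_len(nrow(d)), function(i) {
    row <- d[i, ]
    row$biochar_t_ha <- 0; row$straw_t_ha <- 0
    unname(.forward_observe(bundle, row)[response])
  }, 0)
  alpha_hat <- obs / base - 1
  B <- d$biochar_t_ha
  S <- d$straw_t_ha
  fit <- stats::lm(alpha_hat ~ I(B^2) + I(S^2) + I(B * S) + B + S)
  co <- stats::coef(fit)
  list(a = unname(co["I(B^2)"]), b = unname(co["I(S^2)"]),
       c = unname(co["I(B * S)"]), d = unname(co["B"]),
       e = unname(co["S"]), f = unname(co["(Intercept)"]))
}
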