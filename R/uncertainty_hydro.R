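#' Triangular intuitionistic fuzzy number
#'
#' A TIFN `<(l, m, u); w, v>` carries a triangular support (lower bound,
#' mode, upper bound) together with a membership degree `w` and a
#' non-membership degree `v`.  They are used to encode vague economic and
#' environmental parameters (prices, emission factors) that are known only
#' approximately; [tifn_defuzzify()] turns them back into crisp numbers
#' before optimization.
#'
#' @param l,m,u lower support, mode and upper support (`l <= m <= u`).
#' @param w membership degree in `[0, 1]`.
#' @param v non-membership degree in `[0, 1]`, with `w + v <= 1`.
#' @return An object of class `"tifn"`.
#' @examples
#' tifn(1, 2, 3, w = 0.8, v = 0.1)
#' @export
tifn <- function(l, m, u, w = 1, v = 0) {
  .check(.is_num(c(l, m, u, w, v)), "tifn components must be finite numbers")
  .check(l <= m && m <= u, "tifn requires l <= m <= u")
  .check(w >= 0 && w <= 1 && v >= 0 && v <= 1, "w and v must lie in [0, 1]")
  .check(w + v <= 1, "tifn requires w + v <= 1")
  structure(list(l = l, m = m, u = u, w = w, v = v), class = "tifn")
}

#' @export
print.tifn <- function(x, ...) {
  cat(sprintf("<(%g, %g, %g); w=%g, v=%g>\n", x$l, x$m, x$u, x$w, x$v))
  invisible(x)
}

#' Defuzzify a triangular intuitionistic fuzzy number
#'
#' Crisp value by the accuracy-function form
#' `((l + 2m + u) / 4) * ((1 + w - v) / 2)`: the first factor is the usual
#' value index of a triangular number, the second discounts it by the net
#' confidence `w - v`.  For a crisp input `(m, m, m; 1, 0)` it returns `m`.
#'
#' @param x a [tifn()], or a plain number (returned unchanged).
#' @return A crisp numeric value.
#' @examples
#' tifn_defuzzify(tifn(1, 2, 3, w = 0.8, v = 0.1)) # 1.7
#' @export
tifn_defuzzify <- function(x) {
  if (is.numeric(x)) return(x)
  .check(inherits(x, "tifn"), "x must be a tifn or numeric")
  ((x$l + 2 * x$m + x$u) / 4) * ((1 + x$w - x$v) / 2)
}

#' Replace every TIFN in a nested parameter list by its crisp value
#'
#' @param x a list (possibly nested) whose leaves may be [tifn()] objects.
#' @return The same structure with all TIFNs defuzzified.
#' @export
defuzzify_bundle <- function(x) {
  if (inherits(x, "tifn")) return(tifn_defuzzify(x))
  if (is.list(x)) {
    out <- lapply(x, defuzzify_bundle)
    attributes(out) <- attributes(x)
    return(out)
  }
  x
}

# ---- Pearson type III hydrological frequency analysis -----------------------
#
# Parameterized hydrologically by (mean, Cv, Cs) and realized as a shifted
# gamma: X = a0 + G, G ~ Gamma(shape = 4/Cs^2, scale = mean*Cv*Cs/2),
# a0 = mean*(1 - 2*Cv/Cs).  Cs = 0 degenerates to Normal(mean, mean*Cv).

.p3_gamma <- function(mean, cv, cs) {
  .check(mean > 0 && cv > 0, "mean and Cv must be positive")
  if (abs(cs) < 1e-12) return(NULL) # normal limit
  .check(cs > 0, "only non-negative skew Cs is supported")
  list(shape = 4 / cs^2, scale = mean * cv * cs / 2, shift = mean * (1 - 2 * cv / cs))
}

#' Draw annual precipitation from a Pearson type III model
#'
#' Values are strictly positive: when the support's lower bound lies below
#' zero, non-positive draws are rejected and resampled (documented
#' truncation choice; negligible for realistic precipitation parameters).
#'
#' @param n_years number of annual values to draw.
#' @param mean mean annual precipitation (mm).
#' @param cv coefficient of variation.
#' @param cs skew coefficient (>= 0; 0 gives the normal limit).
#' @param seed integer RNG seed.
#' @return Numeric vector of `n_years` positive annual totals (mm).
#' @export
generate_precip_record <- function(n_years, mean = 553.2, cv = 0.25, cs = 0.5,
                                   seed = 1L) {
  .check(n_years >= 1, "n_years must be >= 1")
  g <- .p3_gamma(mean, cv, cs)
  set.seed(seed)
  draw <- function(m) {
    if (is.null(g)) stats::rnorm(m, mean, mean * cv)
    else g$shift + stats::rgamma(m, shape = g$shape, scale = g$scale)
  }
  x <- draw(n_years)
  for (i in 1:100) {
    bad <- x <= 0
    if (!any(bad)) break
    x[bad] <- draw(sum(bad))
  }
  .check(all(x > 0), "could not produce a positive precipitation sample")
  x
}

#' Fit a Pearson type III model by the method of moments
#'
#' @param annual_series numeric vector of annual precipitation (>= 3 values,
#'   non-constant).
#' @return A list with class `"pearson3"` holding `mean`, `cv` and `cs`.
#' @export
fit_pearson3 <- function(annual_series) {
  x <- annual_series
  .check(.is_num(x) && length(x) >= 3, "need >= 3 finite annual values")
  .check(stats::sd(x) > 0, "constant series: P-III parameters undefined")
  n <- length(x)
  m <- base::mean(x)
  s <- stats::sd(x)
  # adjusted Fisher-Pearson sample skew
  cs <- (n / ((n - 1) * (n - 2))) * sum(((x - m) / s)^3)
  structure(list(mean = m, cv = s / m, cs = cs), class = "pearson3")
}

#' Precipitation quantile at a given exceedance probability
#'
#' Returns the precipitation amount P with `Pr(X >= P) = exceedance_prob`
#' (the "precipitation guarantee rate" of hydrological practice), so the
#' result is strictly decreasing in the probability.
#'
#' @param params a `"pearson3"` object or list with `mean`, `cv`, `cs`.
#' @param exceedance_prob exceedance probability in (0, 1).
#' @return Precipitation (mm).
#' @export
quantile_pearson3 <- function(params, exceedance_prob) {
  p <- exceedance_prob
  .check(all(p > 0 & p < 1), "exceedance_prob must lie strictly in (0, 1)")
  g <- .p3_gamma(params$mean, params$cv, params$cs)
  if (is.null(g)) {
    stats::qnorm(1 - p, params$mean, params$mean * params$cv)
  } else {
    g$shift + stats::qgamma(1 - p, shape = g$shape, scale = g$scale)
  }
}

#' Cumulative distribution of the fitted Pearson type III model
#'
#' @param params a `"pearson3"` object.
#' @param q precipitation value (mm).
#' @return `Pr(X <= q)`.
#' @export
cdf_pearson3 <- function(params, q) {
  g <- .p3_gamma(params$mean, params$cv, params$cs)
  if (is.null(g)) stats::pnorm(q, params$mean, params$mean * params$cv)
  else stats::pgamma(q - g$shift, shape = g$shape, scale = g$scale)
}

#' Classify a hydrological year as wet, normal or dry
#'
#' A year is wet (water-abundant) when annual precipitation reaches the
#' 25% exceedance amount, dry (water-depleted) when it falls at or below
#' the 75% exceedance amount, and normal (water-flat) otherwise.
#'
#' @param P_annual annual precipitation (mm); vectorized.
#' @param thresholds list or vector with `P25` and `P75` (mm, `P25 > P75`).
#' @return Character vector in `{"wet", "normal", "dry"}`.
#' @examples
#' th <- list(P25 = 448.1, P75 = 271.2)
#' classify_hydro_year(c(512.6, 419.5, 212.9), th) # wet, normal, dry
#' @export
classify_hydro_year <- function(P_annual, thresholds) {
  p25 <- thresholds$P25 %||% thresholds[[1]]
  p75 <- thresholds$P75 %||% thresholds[[2]]
  .check(p25 > p75, "thresholds require P25 > P75")
  ifelse(P_annual >= p25, "wet", ifelse(P_annual <= p75, "dry", "normal"))
}

#' Monte Carlo simulation of hydrological year classes
#'
#' Draws `n` annual totals from the P-III model, derives the 25%/75%
#' exceedance thresholds from the same parameters, and classifies every
#' draw.  With a well-specified model the class proportions converge to
#' (0.25, 0.50, 0.25).
#'
#' @param params a `"pearson3"` object.
#' @param n number of simulated years.
#' @param seed integer RNG seed.
#' @return List with `sample` (mm), `class` (labels), `proportions`
#'   (named wet/normal/dry fractions) and `thresholds`.
#' @export
monte_carlo_years <- function(params, n, seed = 1L) {
  .check(n >= 1, "n must be >= 1")
  th <- list(P25 = quantile_pearson3(params, 0.25),
             P75 = quantile_pearson3(params, 0.75))
  x <- generate_precip_record(n, params$mean, params$cv, params$cs, seed = seed)
  cls <- classify_hydro_year(x, th)
  prop <- c(wet = base::mean(cls == "wet"),
            normal = base::mean(cls == "normal"),
            dry = base::mean(cls == "dry"))
  list(sample = x, class = cls, proportions = prop, thresholds = th)
}
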