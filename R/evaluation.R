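# Model-agreement metrics, coupling coordination-degree analysis and
# scenario comparison tables.

#' Coefficient of determination between simulated and observed series
#'
#' Squared Pearson correlation; symmetric in the two series.
#'
#' @param S simulated values.
#' @param O observed values (same length, n >= 2, nonzero variance).
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(S, O) {
  .check(length(S) == length(O) && length(S) >= 2, "need paired series, n >= 2")
  .check(stats::sd(S) > 0 && stats::sd(O) > 0, "zero variance in a series")
  stats::cor(S, O)^2
}

#' Normalized root mean square error (percent)
#'
#' `100 * sqrt(mean((S - O)^2)) / mean(O)`.
#'
#' @inheritParams r_squared
#' @return nRMSE in percent.
#' @export
nrmse <- function(S, O) {
  .check(length(S) == length(O) && length(S) >= 2, "need paired series, n >= 2")
  .check(base::mean(O) != 0, "observed mean is zero")
  100 * sqrt(base::mean((S - O)^2)) / base::mean(O)
}

#' Willmott consistency (agreement) index
#'
#' `1 - sum((S - O)^2) / sum((|S - Obar| + |O - Obar|)^2)`; equals 1 for
#' identical series and 0 when the simulation is the constant observed
#' mean.
#'
#' @inheritParams r_squared
#' @return Index `<= 1` (in `[0, 1]` for non-degenerate series).
#' @export
wci <- function(S, O) {
  .check(length(S) == length(O) && length(S) >= 2, "need paired series, n >= 2")
  if (all(S == O)) return(1)
  ob <- base::mean(O)
  denom <- sum((abs(S - ob) + abs(O - ob))^2)
  .check(denom > 0, "degenerate denominator in WCI")
  1 - sum((S - O)^2) / denom
}

#' Normalize objective values to [0, 1] subsystem scores
#'
#' Benefit-type objectives map as `(x - worst)/(best - worst)`, cost-type
#' (water and carbon footprint) as `(worst - x)/(worst - best)`; clipped
#' to the unit interval.
#'
#' @param x objective values (vectorized).
#' @param best,worst anchors (payoff table or min-max of the compared set).
#' @param sense `"max"` or `"min"`.
#' @return Scores in `[0, 1]`.
#' @export
normalize_objective <- function(x, best, worst, sense = "max") {
  membership(x, list(sense = sense, best = best, worst = worst))
}

#' Coupling coordination degree
#'
#' Coupling `C = (prod(u) / mean(u)^k)^(1/k)`, comprehensive index
#' `T = sum(beta * u)`, coordination degree `D = sqrt(C * T)` in
#' `[0, 1]`.  Grade bands are configurable; the defaults label
#' `D >= 0.8` advanced, `[0.6, 0.8)` secondary, `[0.4, 0.6)` marginal
#' and below that imbalanced.
#'
#' @param u subsystem scores in `[0, 1]` (length k >= 2).
#' @param beta subsystem weights (default equal; must sum to 1).
#' @param breaks,labels grade-band definition.
#' @return List with `C`, `T`, `D` and `grade`.
#' @export
coordination_degree <- function(u, beta = NULL,
                                breaks = c(0, 0.4, 0.6, 0.8, 1),
                                labels = c("imbalanced", "marginal",
                                           "secondary", "advanced")) {
  k <- length(u)
  .check(k >= 2, "need at least two subsystems")
  .check(all(is.finite(u)) && all(u >= 0 & u <= 1), "u must lie in [0, 1]")
  beta <- beta %||% rep(1 / k, k)
  .check(abs(sum(beta) - 1) <= 1e-9 && all(beta >= 0), "invalid beta weights")
  C <- if (any(u == 0)) 0 else (prod(u) / base::mean(u)^k)^(1 / k)
  Tv <- sum(beta * u)
  D <- sqrt(C * Tv)
  grade <- as.character(cut(D, breaks = breaks, labels = labels,
                            include.lowest = TRUE, right = FALSE))
  if (D >= breaks[length(breaks)]) grade <- labels[length(labels)]
  list(C = C, T = Tv, D = D, grade = grade)
}

#' Compare optimization results across scenarios
#'
#' Normalizes the four objectives across the compared results (min-max,
#' footprints inverted), computes each scenario's coordination degree,
#' ranks by D and reports percent differences against the best.
#'
#' @param results data.frame with columns `scenario`, `NEB`, `TCQ`, `WF`,
#'   `CF` (one row per scenario, optionally also per hydrological year —
#'   extra columns are carried through).
#' @param beta subsystem weights for the coordination index.
#' @return The input with added `u_NEB`..`u_CF`, `C`, `T`, `D`, `grade`,
#'   `rank` and `pct_diff_vs_best` columns, ordered by rank.
#' @export
scenario_compare <- function(results, beta = NULL) {
  .check(is.data.frame(results) && nrow(results) >= 1,
         "results must be a non-empty data.frame")
  senses <- c(NEB = "max", TCQ = "max", WF = "min", CF = "min")
  U <- vapply(names(senses), function(o) {
    x <- results[[o]]
    if (length(x) < 2 || diff(range(x)) == 0) return(rep(1, length(x)))
    best <- if (senses[[o]] == "max") max(x) else min(x)
    worst <- if (senses[[o]] == "max") min(x) else max(x)
    normalize_objective(x, best, worst, senses[[o]])
  }, numeric(nrow(results)))
  if (nrow(results) == 1) U <- matrix(U, nrow = 1,
                                      dimnames = list(NULL, names(senses)))
  cd <- lapply(seq_len(nrow(results)), function(i)
    coordination_degree(U[i, ], beta))
  out <- cbind(results,
               stats::setNames(as.data.frame(U), paste0("u_", names(senses))),
               C = vapply(cd, `[[`, 0, "C"),
               T = vapply(cd, `[[`, 0, "T"),
               D = vapply(cd, `[[`, 0, "D"),
               grade = vapply(cd, `[[`, "", "grade"))
  out$rank <- as.integer(rank(-out$D, ties.method = "first"))
  out$pct_diff_vs_best <- 100 * (max(out$D) - out$D) / max(out$D)
  out[order(out$rank), ]
}
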