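# Composite crop quality and the indicator/scenario weighting machinery:
# AHP with Saaty consistency test, entropy weights, and their
# game-theoretic (least-squares) combination.

#' Composite crop quality score
#'
#' Bivariate quadratic in seasonal nitrogen and total irrigation:
#' `Cq = ac*N^2 + bc*I^2 + cc*N + dc*I + ec*N*I + fc`, clipped to `[0, 1]`
#' (with a warning) since the score is interpreted on the unit interval.
#'
#' @param coeffs list with `ac`, `bc`, `cc`, `dc`, `ec`, `fc`.
#' @param N seasonal nitrogen (kg/ha).
#' @param total_irrigation seasonal irrigation depth (mm).
#' @param clip clip to the unit interval (default TRUE).
#' @return Quality score in `[0, 1]`.
#' @export
crop_quality <- function(coeffs, N, total_irrigation, clip = TRUE) {
  .check(all(N >= 0) && all(total_irrigation >= 0),
         "N and irrigation must be non-negative")
  I <- total_irrigation
  q <- coeffs$ac * N^2 + coeffs$bc * I^2 + coeffs$cc * N +
    coeffs$dc * I + coeffs$ec * N * I + coeffs$fc
  if (clip && any(q < 0 | q > 1)) {
    warning("quality score outside [0, 1]; clipped")
    q <- pmin(pmax(q, 0), 1)
  }
  q
}

#' Recycling-stage quality after amendment
#'
#' `(1 + alpha_TCQ) * Cq_st`, clipped to `[0, 1]`; the amendment response
#' comes from [amendment_factor()] with the crop's quality coefficients.
#'
#' @param Cq_st initial-stage quality in `[0, 1]`.
#' @param coeffs amendment quadratic coefficients (`a`..`f`).
#' @param biochar,straw application amounts (t/ha).
#' @return Amended quality in `[0, 1]`.
#' @export
recycled_quality <- function(Cq_st, coeffs, biochar, straw) {
  .check(all(Cq_st >= 0 & Cq_st <= 1), "Cq_st must lie in [0, 1]")
  alpha <- amendment_factor(coeffs, biochar, straw)
  pmin(pmax(recycled_stage_value(Cq_st, alpha), 0), 1)
}

#' Total comprehensive quality of the system
#'
#' Equal-stage average of the crop-weighted quality scores:
#' `0.5 * sum(w_st * Cq_st) + 0.5 * sum(w_st1 * Cq_st1)`.
#'
#' @param crop_weights per-crop weights (non-negative, sum 1); either one
#'   vector shared by both stages or a list with `st` and `st1`.
#' @param Cq_st,Cq_st1 per-crop quality scores for the two stages.
#' @return `F_TCQ` in `[0, 1]` when the inputs are.
#' @export
total_comprehensive_quality <- function(crop_weights, Cq_st, Cq_st1) {
  if (is.list(crop_weights)) {
    w_st <- crop_weights$st; w_st1 <- crop_weights$st1
  } else {
    w_st <- w_st1 <- crop_weights
  }
  .check(length(w_st) == length(Cq_st) && length(w_st1) == length(Cq_st1),
         "weight/quality length mismatch")
  .check(abs(sum(w_st) - 1) <= 1e-9 && abs(sum(w_st1) - 1) <= 1e-9,
         "crop weights must sum to 1")
  0.5 * sum(w_st * Cq_st) + 0.5 * sum(w_st1 * Cq_st1)
}

# Saaty random consistency indices, n = 1..10
.saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' AHP priority weights with consistency test
#'
#' Principal-eigenvector weights of a positive reciprocal pairwise
#' comparison matrix, with Saaty's consistency ratio
#' `CR = ((lambda_max - n)/(n - 1)) / RI(n)`; `CR < 0.1` passes.
#'
#' @param pairwise_matrix square positive reciprocal matrix
#'   (`A[j,i] = 1/A[i,j]`).
#' @return List with `weights` (sums to 1), `lambda_max`, `cr` and
#'   `consistent`.
#' @export
ahp_weights <- function(pairwise_matrix) {
  A <- as.matrix(pairwise_matrix)
  n <- nrow(A)
  .check(n == ncol(A), "matrix must be square")
  .check(all(A > 0), "matrix entries must be positive")
  .check(max(abs(A * t(A) - 1)) < 1e-8, "matrix must be reciprocal")
  e <- eigen(A)
  i <- which.max(Re(e$values))
  lambda_max <- Re(e$values[i])
  w <- abs(Re(e$vectors[, i]))
  w <- w / sum(w)
  cr <- if (n <= 2) 0 else ((lambda_max - n) / (n - 1)) / .saaty_ri[min(n, 10)]
  list(weights = w, lambda_max = lambda_max, cr = cr, consistent = cr < 0.1)
}

#' Reconstruct a consistent pairwise matrix from published weights
#'
#' `A[i,j] = w[i]/w[j]` is perfectly consistent (CR = 0) and its principal
#' eigenvector reproduces `w`; used to back out comparison matrices for
#' the packaged allocation scenarios.
#'
#' @param w positive weight vector.
#' @return Reciprocal matrix.
#' @export
ahp_matrix_from_weights <- function(w) {
  .check(all(w > 0), "weights must be positive")
  outer(w, w, "/")
}

#' Entropy weights of an indicator matrix
#'
#' Min-max normalizes each indicator column (cost-type columns are
#' reversed), converts to column shares, computes the Shannon entropy
#' `e_j = -(1/ln m) * sum p ln p` and weights by the divergence `1 - e_j`.
#'
#' @param indicator_matrix numeric matrix, rows = alternatives, columns =
#'   indicators (>= 2 alternatives).
#' @param benefit logical per column, `TRUE` when larger is better
#'   (default all benefit-type).
#' @return Weight vector summing to 1.
#' @export
entropy_weights <- function(indicator_matrix, benefit = NULL) {
  X <- as.matrix(indicator_matrix)
  m <- nrow(X)
  .check(m >= 2, "need at least two alternatives")
  benefit <- benefit %||% rep(TRUE, ncol(X))
  rng <- apply(X, 2, function(col) diff(range(col)))
  .check(any(rng > 0), "all indicators constant: entropy weights undefined")
  norm <- vapply(seq_len(ncol(X)), function(j) {
    col <- X[, j]
    if (rng[j] == 0) return(rep(1, m)) # constant column carries no information
    z <- (col - min(col)) / rng[j]
    if (!benefit[j]) z <- 1 - z
    z
  }, numeric(m))
  ent <- apply(norm, 2, function(z) {
    p <- z / sum(z)
    p <- p[p > 0]
    -sum(p * log(p)) / log(m)
  })
  d <- 1 - ent
  if (sum(d) <= 0) stop("zero total divergence: entropy weights undefined")
  d / sum(d)
}

#' Game-theoretic combination of weight vectors
#'
#' Combines `k` candidate weightings `w_k` as `w* = sum alpha_k w_k`,
#' where `alpha` solves the least-squares Nash-equilibrium system
#' `G alpha = diag(G)` with Gram matrix `G[i,j] = w_i . w_j`, then is
#' normalized to sum 1.  Singular systems fall back to equal alpha.
#'
#' @param weight_sets list of >= 2 equal-length weight vectors.
#' @return List with `weights` (combined, sums to 1) and `alpha`.
#' @export
game_combination <- function(weight_sets) {
  .check(is.list(weight_sets) && length(weight_sets) >= 2,
         "need at least two weight vectors")
  len <- vapply(weight_sets, length, 1L)
  .check(all(len == len[1]), "weight vectors must have equal length")
  W <- do.call(rbind, weight_sets)
  G <- W %*% t(W)
  alpha <- tryCatch(solve(G, diag(G)),
                    error = function(e) rep(1, nrow(W)))
  alpha <- abs(alpha)
  if (sum(alpha) <= 0) alpha <- rep(1, nrow(W))
  alpha <- alpha / sum(alpha)
  w <- as.numeric(t(W) %*% alpha)
  w <- pmax(w, 0)
  list(weights = w / sum(w), alpha = alpha)
}
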