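# Multi-objective solver: fuzzy linear memberships anchored by a payoff
# table of single-objective optima, max-min (Zimmermann) scalarization,
# multistart penalized L-BFGS-B, and a brute-force grid oracle.

.obj_senses <- c(NEB = "max", TCQ = "max", WF = "min", CF = "min")

#' Soil-moisture irrigation bounds
#'
#' `W_min = 10 * bulk_density * z_r * theta_rwp` and
#' `W_max = 10 * bulk_density * z_r * theta_fc`: the per-stage irrigation
#' amounts that keep the wetted layer between wilting point and field
#' capacity.
#'
#' @param soil a [soil_params()] object.
#' @return Named vector `c(W_min, W_max)` in mm.
#' @export
soil_water_bounds <- function(soil) {
  w <- 10 * soil$bulk_density * soil$z_r * c(soil$theta_rwp, soil$theta_fc)
  stats::setNames(w, c("W_min", "W_max"))
}

#' Linear fuzzy membership of an objective value
#'
#' For a maximized objective `mu = (F - worst)/(best - worst)`; for a
#' minimized one the mirror image.  Clipped to `[0, 1]`.
#'
#' @param F objective value (vectorized).
#' @param spec list with `sense` ("max"/"min"), `best`, `worst`
#'   (`best != worst`).
#' @return Membership in `[0, 1]`.
#' @export
membership <- function(F, spec) {
  .check(spec$best != spec$worst, "membership anchors must differ")
  mu <- if (spec$sense == "max") {
    (F - spec$worst) / (spec$best - spec$worst)
  } else {
    (spec$worst - F) / (spec$worst - spec$best)
  }
  pmin(pmax(mu, 0), 1)
}

# unclipped variant: keeps a gradient signal outside [0, 1] for the solver
.membership_raw <- function(F, spec) {
  if (spec$sense == "max") (F - spec$worst) / (spec$best - spec$worst)
  else (spec$worst - F) / (spec$worst - spec$best)
}

#' Max-min scalarization of membership degrees
#'
#' @param memberships vector of membership degrees in `[0, 1]`.
#' @return The overall satisfaction `lambda = min(mu)`.
#' @export
scalarize_maxmin <- function(memberships) {
  .check(all(memberships >= 0 & memberships <= 1),
         "memberships must lie in [0, 1]")
  min(memberships)
}

# ---- decision packing -------------------------------------------------------

.pack <- function(decision) {
  c(as.vector(decision$I_st), as.vector(decision$I_st1),
    decision$N_st, decision$N_st1)
}

.unpack <- function(x, bundle, alloc) {
  nc <- bundle$n_crops; nt <- bundle$n_stages
  k <- nc * nt
  decision_vector(matrix(x[1:k], nc, nt), matrix(x[(k + 1):(2 * k)], nc, nt),
                  x[(2 * k + 1):(2 * k + nc)],
                  x[(2 * k + nc + 1):(2 * k + 2 * nc)], alloc)
}

.box_bounds <- function(bundle) {
  nc <- bundle$n_crops; nt <- bundle$n_stages
  w <- soil_water_bounds(bundle$soil)
  list(lower = c(rep(w[["W_min"]], 2 * nc * nt),
                 rep(bundle$bounds$N_min, 2)),
       upper = c(rep(w[["W_max"]], 2 * nc * nt),
                 rep(bundle$bounds$N_max, 2)))
}

#' Constraint residuals for a decision
#'
#' Returns an evaluator producing the slack of every model constraint
#' (non-negative slack means satisfied): electricity supply in both
#' stages, per-stage irrigation within the soil-moisture window, nitrogen
#' bounds, biochar and straw-return supply, allocation sum (absolute
#' deviation from 1, satisfied within 1e-9) and non-negativity.
#'
#' @param bundle a [generate_parameters()] bundle.
#' @param alloc a straw allocation (checked by the `alloc_sum` residual;
#'   may violate the sum constraint).
#' @return `function(decision, hydro)` returning a named list with
#'   `slack` (numeric vector) and `feasible`.
#' @export
build_constraints <- function(bundle, alloc = c(0.25, 0.25, 0.25, 0.25)) {
  w <- soil_water_bounds(bundle$soil)
  .check(w[["W_min"]] < w[["W_max"]], "infeasible soil water bounds")
  .check(all(bundle$bounds$N_min <= bundle$bounds$N_max),
         "infeasible nitrogen bounds")
  bb <- bundle$bounds
  function(decision, hydro) {
    obj <- evaluate_objectives(decision, bundle, hydro, detail = TRUE)
    el <- obj$electricity
    y_straw <- vapply(obj$detail, `[[`, 0, "y_straw")
    Q_st1 <- vapply(obj$detail, `[[`, 0, "Q_st1")
    Q_st <- vapply(obj$detail, `[[`, 0, "Q_st")
    en <- bundle$energy
    biochar_cap <- sum((en$eta_gas + en$eta_pyr) * Q_st1) # kg/ha produced
    slack <- c(
      ele_supply_st = bb$a_frac * bb$TAE - el$demand_st,
      ele_avail_st = bb$AP - el$demand_st,
      ele_supply_st1 = bb$a_frac * bb$TAE - (el$demand_st1 - el$generated_st),
      irr_lower = min(c(decision$I_st, decision$I_st1) - w[["W_min"]]),
      irr_upper = min(w[["W_max"]] - c(decision$I_st, decision$I_st1)),
      n_lower = min(c(decision$N_st - bb$N_min, decision$N_st1 - bb$N_min)),
      n_upper = min(c(bb$N_max - decision$N_st, bb$N_max - decision$N_st1)),
      biochar_supply = biochar_cap - sum(vapply(obj$detail, `[[`, 0, "y_biochar")),
      straw_supply = sum(Q_st1) - sum(y_straw),
      alloc_sum = 1e-9 - abs(sum(decision$alloc) - 1),
      nonneg = min(c(decision$I_st, decision$I_st1,
                     decision$N_st, decision$N_st1)))
    list(slack = slack, feasible = all(slack >= -1e-6))
  }
}

# electricity-supply penalty (the only constraint not native to the box)
.ele_penalty <- function(obj, bundle) {
  bb <- bundle$bounds
  el <- obj$electricity
  v <- c(max(0, el$demand_st - min(bb$AP, bb$a_frac * bb$TAE)),
         max(0, (el$demand_st1 - el$generated_st) -
               min(bb$AP, bb$a_frac * bb$TAE)))
  1e4 * sum(v^2)
}

.ele_penalty_core <- function(core, bb) {
  cap <- min(bb$AP, bb$a_frac * bb$TAE)
  v <- c(max(0, core$demand_st - cap),
         max(0, core$demand_st1 - core$generated_st - cap))
  1e4 * sum(v^2)
}

# raw evaluation of a packed parameter vector against a precomputed
# context; no validation, used inside optimization loops
.core_of_x <- function(x, ctx, al) {
  nc <- ctx$nc; nt <- ctx$nt; k <- nc * nt
  .eval_core(matrix(x[1:k], nc, nt), matrix(x[(k + 1):(2 * k)], nc, nt),
             x[(2 * k + 1):(2 * k + nc)],
             x[(2 * k + nc + 1):(2 * k + 2 * nc)], al, ctx)
}

.multistart_optim <- function(fn, bounds, seed, n_starts, maxit) {
  d <- length(bounds$lower)
  best <- NULL
  for (s in seq_len(n_starts)) {
    set.seed(.derive_seed(seed, s))
    x0 <- if (s == 1) (bounds$lower + bounds$upper) / 2 else
      stats::runif(d, bounds$lower, bounds$upper)
    res <- tryCatch(
      stats::optim(x0, fn, method = "L-BFGS-B", lower = bounds$lower,
                   upper = bounds$upper,
                   control = list(fnscale = -1, maxit = maxit, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value > best$value)) best <- res
  }
  .check(!is.null(best), "no feasible point found")
  best
}

#' Single-objective optimum (payoff-table anchor)
#'
#' @param bundle,hydro,alloc problem instance.
#' @param objective one of `"NEB"`, `"TCQ"`, `"WF"`, `"CF"`.
#' @param seed,n_starts,maxit solver controls.
#' @return List with `decision`, `value` and the full `objectives`.
#' @export
solve_single_objective <- function(bundle, hydro, alloc, objective,
                                   seed = 1L, n_starts = 4L, maxit = 60L) {
  sense <- .obj_senses[[objective]]
  bounds <- .box_bounds(bundle)
  ctx <- .make_ctx(bundle, hydro)
  al <- as.numeric(alloc)
  sgn <- if (sense == "max") 1 else -1
  fn <- function(x) {
    core <- .core_of_x(x, ctx, al)
    v <- sgn * core[[objective]] - .ele_penalty_core(core, ctx$bounds)
    if (!is.finite(v)) -1e9 else v
  }
  res <- .multistart_optim(fn, bounds, seed, n_starts, maxit)
  dec <- .unpack(res$par, bundle, alloc)
  obj <- evaluate_objectives(dec, bundle, hydro)
  list(decision = dec, value = obj[[objective]], objectives = obj)
}

#' Payoff table of single-objective optima
#'
#' Solves each objective on its own; the best anchor of an objective is
#' its own optimum, the worst anchor the most adverse value it takes at
#' the other objectives' optima (slightly widened when degenerate).
#'
#' @inheritParams solve_single_objective
#' @return Named list of membership specs (`sense`, `best`, `worst`) plus
#'   attribute `"solutions"`.
#' @export
payoff_table <- function(bundle, hydro, alloc, seed = 1L, n_starts = 4L,
                         maxit = 60L) {
  objs <- names(.obj_senses)
  sols <- lapply(seq_along(objs), function(i)
    solve_single_objective(bundle, hydro, alloc, objs[i],
                           seed = .derive_seed(seed, i), n_starts = n_starts,
                           maxit = maxit))
  names(sols) <- objs
  vals <- vapply(objs, function(o)
    vapply(sols, function(s) s$objectives[[o]], 0), numeric(length(objs)))
  # vals[solution, objective]
  specs <- lapply(objs, function(o) {
    sense <- .obj_senses[[o]]
    col <- vals[, o]
    best <- if (sense == "max") max(col) else min(col)
    worst <- if (sense == "max") min(col) else max(col)
    if (abs(best - worst) < 1e-12) {
      delta <- max(1e-6, abs(best) * 0.01)
      worst <- if (sense == "max") best - delta else best + delta
    }
    list(sense = sense, best = best, worst = worst)
  })
  names(specs) <- objs
  attr(specs, "solutions") <- sols
  specs
}

# smooth surrogate of min() used inside the gradient-based solver
# (shifted for numerical stability at large |mu|)
.softmin <- function(mu, beta = 60) {
  m <- min(mu)
  m - log(sum(exp(-beta * (mu - m)))) / beta
}

#' Solve the fuzzy max-min compromise problem
#'
#' Computes the payoff table, then maximizes the minimum membership over
#' the box of irrigation and nitrogen decisions (allocation fixed to the
#' scenario weights) by multistart L-BFGS-B on a soft-min surrogate, with
#' a quadratic penalty for the electricity-supply constraint.
#'
#' @param bundle a [generate_parameters()] bundle.
#' @param hydro a [hydro_scenario()].
#' @param alloc scenario straw allocation (4 weights summing to 1).
#' @param seed RNG seed for the multistarts.
#' @param n_starts number of multistarts (default 8).
#' @param maxit L-BFGS-B iteration cap per start.
#' @param specs optional precomputed membership specs (skips the payoff
#'   table).
#' @return List with `decision`, `objectives`, `lambda`, `memberships`,
#'   `specs` and `residuals`.
#' @export
solve_allocation <- function(bundle, hydro, alloc, seed = 1L, n_starts = 8L,
                             maxit = 80L, specs = NULL) {
  if (!inherits(alloc, "straw_allocation")) {
    alloc <- straw_allocation(alloc[1], alloc[2], alloc[3], alloc[4])
  }
  specs <- specs %||% payoff_table(bundle, hydro, alloc, seed = seed,
                                   n_starts = max(2L, n_starts %/% 2L),
                                   maxit = maxit)
  bounds <- .box_bounds(bundle)
  ctx <- .make_ctx(bundle, hydro)
  al <- as.numeric(alloc)
  mu_of <- function(obj) vapply(names(.obj_senses), function(o)
    membership(obj[[o]], specs[[o]]), 0)
  fn <- function(x) {
    core <- .core_of_x(x, ctx, al)
    mu_raw <- vapply(names(.obj_senses), function(o)
      .membership_raw(core[[o]], specs[[o]]), 0)
    v <- .softmin(pmin(mu_raw, 1)) - .ele_penalty_core(core, ctx$bounds)
    if (!is.finite(v)) -1e9 else v
  }
  res <- .multistart_optim(fn, bounds, .derive_seed(seed, 99), n_starts, maxit)
  dec <- .unpack(res$par, bundle, alloc)
  obj <- evaluate_objectives(dec, bundle, hydro)
  mu <- mu_of(obj)
  resid <- build_constraints(bundle, alloc)(dec, hydro)
  list(decision = dec, objectives = obj, lambda = scalarize_maxmin(mu),
       memberships = mu, specs = specs, residuals = resid)
}

#' Brute-force grid oracle
#'
#' Exhaustively evaluates the max-min satisfaction on a regular grid over
#' the decision box (allocation fixed), keeping only
#' electricity-feasible points.  Intended for small instances; guards
#' against grids larger than `2e5` points.
#'
#' @param bundle,hydro,alloc problem instance (small: the grid dimension
#'   is `2 * n_crops * (n_stages + 1)`).
#' @param grid_resolution points per dimension.
#' @param specs membership specs shared with the solver under test.
#' @return List with `decision`, `lambda`, `objectives`, `n_evaluated`;
#'   `lambda = -Inf` and `decision = NULL` if no feasible grid point.
#' @export
brute_force_oracle <- function(bundle, hydro, alloc, grid_resolution, specs) {
  if (!inherits(alloc, "straw_allocation")) {
    alloc <- straw_allocation(alloc[1], alloc[2], alloc[3], alloc[4])
  }
  bounds <- .box_bounds(bundle)
  d <- length(bounds$lower)
  .check(grid_resolution^d <= 2e5,
         sprintf("grid too large: %d^%d points", grid_resolution, d))
  axes <- lapply(seq_len(d), function(i)
    seq(bounds$lower[i], bounds$upper[i], length.out = grid_resolution))
  grid <- as.matrix(expand.grid(axes))
  ctx <- .make_ctx(bundle, hydro)
  al <- as.numeric(alloc)
  best <- list(x = NULL, lambda = -Inf)
  for (i in seq_len(nrow(grid))) {
    core <- .core_of_x(grid[i, ], ctx, al)
    if (.ele_penalty_core(core, ctx$bounds) > 0) next
    mu <- vapply(names(.obj_senses), function(o)
      membership(core[[o]], specs[[o]]), 0)
    lam <- scalarize_maxmin(mu)
    if (lam > best$lambda) best <- list(x = grid[i, ], lambda = lam)
  }
  out <- list(decision = NULL, lambda = best$lambda, objectives = NULL,
              n_evaluated = nrow(grid))
  if (!is.null(best$x)) {
    out$decision <- .unpack(best$x, bundle, alloc)
    out$objectives <- evaluate_objectives(out$decision, bundle, hydro)
  }
  out
}
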