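# Assembly of the four system objectives (NEB, TCQ, WF, CF) from a
# decision, a parameter bundle and a hydrological scenario.  The heavy
# lifting happens in a vectorized core working on a precomputed context,
# so the optimizer can evaluate candidate decisions cheaply.

#' Construct a decision vector
#'
#' @param I_st,I_st1 per-crop, per-stage irrigation matrices (mm) for the
#'   initial and recycling stages (`n_crops x n_stages`).
#' @param N_st,N_st1 per-crop seasonal nitrogen (kg/ha) for the two stages.
#' @param alloc a [straw_allocation()] (or 4-vector summing to 1).
#' @return A list of class `"decision"`.
#' @export
decision_vector <- function(I_st, I_st1, N_st, N_st1, alloc) {
  I_st <- as.matrix(I_st); I_st1 <- as.matrix(I_st1)
  .check(all(dim(I_st) == dim(I_st1)), "stage matrices must share dimensions")
  .check(nrow(I_st) == length(N_st) && length(N_st) == length(N_st1),
         "crop dimensions disagree")
  .check(all(I_st >= 0) && all(I_st1 >= 0) && all(N_st >= 0) && all(N_st1 >= 0),
         "decision variables must be non-negative")
  if (!inherits(alloc, "straw_allocation")) {
    alloc <- straw_allocation(alloc[1], alloc[2], alloc[3], alloc[4])
  }
  structure(list(I_st = I_st, I_st1 = I_st1, N_st = N_st, N_st1 = N_st1,
                 alloc = alloc), class = "decision")
}

# a sensible reference decision: recommended N and full irrigation split
# across stages by the demand fractions
reference_decision <- function(bundle, alloc) {
  I <- outer(bundle$full_irrigation, bundle$stage_frac)
  decision_vector(I, I, bundle$recommended_N, bundle$recommended_N, alloc)
}

# Precompute every decision-independent quantity as per-crop vectors and
# matrices.  Row order follows bundle$crops throughout.
.make_ctx <- function(bundle, hydro) {
  nc <- bundle$n_crops; nt <- bundle$n_stages
  getv <- function(lst, field) vapply(lst, `[[`, 0, field)
  amat <- function(field) t(vapply(bundle$amendment, function(a)
    unlist(a[[field]][c("a", "b", "c", "d", "e", "f")]), numeric(6)))
  jp <- bundle$jensen
  us <- bundle$usage
  pr <- bundle$prices
  em <- bundle$emission
  sq <- bundle$seq
  list(
    nc = nc, nt = nt,
    A = bundle$area, A_tot = sum(bundle$area),
    P = hydro$P_stage,
    et_m = bundle$et_m,
    lambda = t(vapply(jp, `[[`, numeric(nt), "lambda")),
    qa = getv(jp, "a"), qb = getv(jp, "b"), qc = getv(jp, "c"),
    qual = t(vapply(bundle$quality, function(q)
      unlist(q[c("ac", "bc", "cc", "dc", "ec", "fc")]), numeric(6))),
    am_yield = amat("yield"), am_tcq = amat("tcq"),
    am_co2 = amat("co2"), am_ch4 = amat("ch4"), am_n2o = amat("n2o"),
    sppp = getv(bundle$straw, "omega") * getv(bundle$straw, "xi") *
      getv(bundle$straw, "psi"),
    ele_kg = bundle$energy$Hv * bundle$energy$zeta_the / 3.6,
    en = bundle$energy,
    P_crop = pr$P_crop, prices = pr,
    mat_fixed = vapply(us, function(u)
      pr$P_see * u$D_see + pr$P_pes * u$D_pes + pr$P_fue * u$D_fue +
        pr$P_fil * u$D_fil + pr$P_lab * u$D_lab, 0),
    kwh_fixed = vapply(us, function(u)
      u$D_ele_lig * u$H_lig + u$D_ele_rol * u$tau_rol, 0),
    d_irr = vapply(us, `[[`, 0, "D_ele_irr"),
    co2_fixed = vapply(us, function(u)
      em$sigma_see * u$D_see + em$sigma_pes * u$D_pes +
        em$sigma_fue * u$D_fue + em$sigma_fil * u$D_fil +
        em$sigma_lab * u$D_lab, 0),
    sigma_fer = em$sigma_fer, omicron = em$omicron, nu = em$nu,
    nu_fer = em$nu_fer, gwp_ch4 = em$gwp_ch4, gwp_n2o = em$gwp_n2o,
    fseq = getv(sq, "Cc") * (1 - getv(sq, "W")) * (1 + getv(sq, "Rrsr")) /
      getv(sq, "Hc"),
    cq_biochar = getv(sq, "Cq_biochar"), cq_straw = getv(sq, "Cq_straw"),
    gray = bundle$gray, w_crop = bundle$crop_weights,
    bounds = bundle$bounds)
}

.rowprod <- function(M) {
  out <- M[, 1]
  if (ncol(M) > 1) for (t in 2:ncol(M)) out <- out * M[, t]
  out
}

# Fully vectorized objective core.  I1/I2 are nc x nt matrices, N1/N2
# per-crop vectors, al the 4 allocation weights.
.eval_core <- function(I1, I2, N1, N2, al, ctx) {
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  jens <- function(I) {
    r <- pmin((ctx$P + I) / ctx$et_m, 1)
    .rowprod(r^ctx$lambda)
  }
  SI1 <- rowSums(I1); SI2 <- rowSums(I2)
  Ym1 <- pmax(ctx$qa * N1^2 + ctx$qb * N1 + ctx$qc, 0)
  Ym2 <- pmax(ctx$qa * N2^2 + ctx$qb * N2 + ctx$qc, 0)
  Y1 <- Ym1 * jens(I1)
  Q1 <- Y1 * ctx$sppp # straw pool, kg/ha

  en <- ctx$en
  q_com <- ctx$ele_kg * en$rho_com * al[3] * Q1
  q_gas <- ctx$ele_kg * en$zeta_com * en$rho_gas * al[3] * Q1
  y_straw <- al[1] * Q1
  y_biochar <- pmax(en$eta_gas * al[2] * Q1 - en$eta_gas_ele * q_gas, 0) +
    en$eta_pyr * al[2] * Q1
  bt <- y_biochar / 1000; st <- y_straw / 1000 # t/ha for the quadratics
  amend <- function(M) M[, 1] * bt^2 + M[, 2] * st^2 + M[, 3] * bt * st +
    M[, 4] * bt + M[, 5] * st + M[, 6]
  a_y <- amend(ctx$am_yield); a_q <- amend(ctx$am_tcq)
  a_co2 <- amend(ctx$am_co2); a_ch4 <- amend(ctx$am_ch4)
  a_n2o <- amend(ctx$am_n2o)

  Y2 <- pmax(1 + a_y, 0) * Ym2 * jens(I2)
  Q2 <- Y2 * ctx$sppp
  Ytot <- Y1 + Y2

  qsurf <- function(N, SI) ctx$qual[, 1] * N^2 + ctx$qual[, 2] * SI^2 +
    ctx$qual[, 3] * N + ctx$qual[, 4] * SI + ctx$qual[, 5] * N * SI +
    ctx$qual[, 6]
  cq1 <- clip01(qsurf(N1, SI1))
  cq2 <- clip01((1 + a_q) * clip01(qsurf(N2, SI2)))
  TCQ <- 0.5 * sum(ctx$w_crop * cq1) + 0.5 * sum(ctx$w_crop * cq2)

  pr <- ctx$prices
  revenue <- sum(ctx$P_crop * ctx$A * Ytot) +
    sum(ctx$A * (pr$P_straw * (al[4] * Q1 + Q2) +
                   pr$P_ele_sal * (q_com + q_gas)))
  kwh1 <- ctx$kwh_fixed + ctx$d_irr * 10 * SI1
  kwh2 <- ctx$kwh_fixed + ctx$d_irr * 10 * SI2
  cost <- sum(ctx$A * (2 * ctx$mat_fixed + pr$P_fer * (N1 + N2) +
                         pr$P_biochar * y_biochar + pr$P_straw * y_straw +
                         pr$P_ele_pur * (kwh1 + kwh2) +
                         pr$P_wat * 10 * (SI1 + SI2)))
  NEB <- (revenue - cost) / ctx$A_tot

  co2_1 <- ctx$A * (ctx$co2_fixed + ctx$sigma_fer * N1)
  ch4_1 <- ctx$A * ctx$omicron
  n2o_1 <- ctx$A * (ctx$nu + N1 * ctx$nu_fer)
  ghg <- co2_1 * (2 + a_co2) + ctx$gwp_ch4 * ch4_1 * (2 + a_ch4) +
    ctx$gwp_n2o * n2o_1 * (2 + a_n2o)
  cs <- Y1 * ctx$fseq * ctx$A +
    (Y2 * ctx$fseq + y_biochar * ctx$cq_biochar + y_straw * ctx$cq_straw) *
    ctx$A
  CF <- sum((ghg - cs) / Ytot)

  Ptot <- 2 * rowSums(ctx$P)
  gray <- ctx$gray
  WF <- sum((10 * Ptot + 10 * (SI1 + SI2) +
               gray$nu_LRNF * (N1 + N2) / (gray$C_max - gray$C_n)) / Ytot)

  list(NEB = NEB, TCQ = TCQ, WF = WF, CF = CF,
       Y1 = Y1, Y2 = Y2, Q1 = Q1, Q2 = Q2, cq1 = cq1, cq2 = cq2,
       y_biochar = y_biochar, y_straw = y_straw,
       q_com = q_com, q_gas = q_gas, ghg = ghg, cs = cs,
       revenue = revenue, cost = cost,
       demand_st = sum(ctx$A * kwh1), demand_st1 = sum(ctx$A * kwh2),
       generated_st = sum(ctx$A * (q_com + q_gas)))
}

#' Evaluate the four system objectives for a decision
#'
#' Composes the production, straw-energy, economics, quality and
#' footprint components into the objective vector
#' (NEB 10^3 yuan/ha, TCQ unitless, WF m3/kg, CF kg CO2e/kg).
#' The evaluation is unconditional: infeasible decisions are evaluated
#' too, feasibility is the optimizer's concern.
#'
#' @param decision a [decision_vector()].
#' @param bundle a [generate_parameters()] bundle.
#' @param hydro a [hydro_scenario()].
#' @param detail return per-crop intermediate quantities as `$detail`.
#' @return List of class `"objective_vector"` with `NEB`, `TCQ`, `WF`,
#'   `CF`, an `electricity` block (and optionally `detail`).
#' @export
evaluate_objectives <- function(decision, bundle, hydro, detail = FALSE) {
  ctx <- .make_ctx(bundle, hydro)
  core <- .eval_core(decision$I_st, decision$I_st1,
                     decision$N_st, decision$N_st1,
                     as.numeric(decision$alloc), ctx)
  if (any(core$Y1 + core$Y2 <= 0)) {
    bad <- bundle$crops[core$Y1 + core$Y2 <= 0]
    stop("zero total yield for crop ", paste(bad, collapse = ", "),
         ": footprint intensities undefined", call. = FALSE)
  }
  out <- list(NEB = core$NEB, TCQ = core$TCQ, WF = core$WF, CF = core$CF,
              electricity = core[c("demand_st", "demand_st1", "generated_st")])
  if (detail) {
    Ptot <- 2 * rowSums(ctx$P)
    Ytot <- core$Y1 + core$Y2
    out$detail <- lapply(seq_len(bundle$n_crops), function(c_i) list(
      crop = bundle$crops[c_i],
      Y_st = core$Y1[c_i], Y_st1 = core$Y2[c_i],
      Q_st = core$Q1[c_i], Q_st1 = core$Q2[c_i],
      Cq_st = core$cq1[c_i], Cq_st1 = core$cq2[c_i],
      y_biochar = core$y_biochar[c_i], y_straw = core$y_straw[c_i],
      q_com = core$q_com[c_i], q_gas = core$q_gas[c_i],
      ghg = core$ghg[c_i], sequestration = core$cs[c_i],
      green = green_wf(Ptot[c_i], Ytot[c_i]),
      blue = blue_wf(sum(decision$I_st[c_i, ]) + sum(decision$I_st1[c_i, ]),
                     Ytot[c_i]),
      gray = gray_wf(bundle$gray, decision$N_st[c_i], decision$N_st1[c_i],
                     Ytot[c_i])))
  }
  structure(out, class = "objective_vector")
}

#' @export
print.objective_vector <- function(x, ...) {
  cat(sprintf(
    "NEB %.2f 10^3 yuan/ha | TCQ %.3f | WF %.3f m3/kg | CF %.3f kg CO2e/kg\n",
    x$NEB, x$TCQ, x$WF, x$CF))
  invisible(x)
}
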