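# Shared fixtures, built in code.  Bundles are cached per seed so test
# files do not pay the generation cost repeatedly.

.fixture_env <- new.env(parent = emptyenv())

default_bundle <- function(seed = 42L) {
  key <- paste0("b", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_parameters(study_config(seed = seed))
  }
  .fixture_env[[key]]
}

# small 1-crop, 2-stage instance for solver/oracle work (6 decision dims)
toy_instance <- function(seed = 1L) {
  cfg <- study_config(seed = seed, n_crops = 1L, n_stages = 2L,
                      recommended_N = 200, full_irrigation = 300)
  bundle <- generate_parameters(cfg)
  list(config = cfg, bundle = bundle,
       hydro = hydro_scenario(bundle, "normal"))
}

equal_alloc <- function() straw_allocation(0.25, 0.25, 0.25, 0.25)

table2_allocations <- function() {
  scen <- straw_scenarios()
  lapply(seq_len(nrow(scen)), function(i)
    straw_allocation(scen$pr_straw[i], scen$pr_biochar[i],
                     scen$pr_ele[i], scen$pr_sell[i]))
}

# Independent route through the exported module primitives, mirroring the
# model definition step by step.  Used as a spreadsheet-style oracle for
# the vectorized evaluate_objectives().
eval_by_hand <- function(decision, bundle, hydro) {
  nc <- bundle$n_crops
  al <- decision$alloc
  pr <- bundle$prices
  em <- bundle$emission
  revenue <- cost <- 0
  cq1 <- cq2 <- numeric(nc)
  ghg_v <- cs_v <- y1_v <- y2_v <- numeric(nc)
  wf <- 0
  for (ci in seq_len(nc)) {
    P <- hydro$P_stage[ci, ]
    et_m <- bundle$et_m[ci, ]
    jp <- bundle$jensen[[ci]]
    I1 <- decision$I_st[ci, ]; I2 <- decision$I_st1[ci, ]
    N1 <- decision$N_st[ci]; N2 <- decision$N_st1[ci]
    A <- bundle$area[ci]

    Y1 <- jensen_yield(nitrogen_potential_yield(jp, N1), P + I1, et_m,
                       jp$lambda)
    sw <- bundle$straw[[ci]]
    Q1 <- biomass_production(1, Y1, sw$omega, sw$xi, sw$psi)
    en <- bundle$energy; en$Hv <- bundle$energy$Hv[ci]
    q_com <- electricity_combustion(en, al[["pr_ele"]], Q1)
    q_gas <- electricity_gasification(en, al[["pr_ele"]], Q1)
    y_straw <- straw_returned(al[["pr_straw"]], Q1)
    y_biochar <- suppressWarnings(
      biochar_output(en, al[["pr_biochar"]], Q1, q_gas))
    am <- bundle$amendment[[ci]]
    bt <- y_biochar / 1000; st <- y_straw / 1000
    Y2 <- recycled_stage_value(
      jensen_yield(nitrogen_potential_yield(jp, N2), P + I2, et_m, jp$lambda),
      amendment_factor(am$yield, bt, st))
    Q2 <- biomass_production(1, Y2, sw$omega, sw$xi, sw$psi)

    qp <- bundle$quality[[ci]]
    cq1[ci] <- suppressWarnings(crop_quality(qp, N1, sum(I1)))
    cq2[ci] <- recycled_quality(
      suppressWarnings(crop_quality(qp, N2, sum(I2))), am$tcq, bt, st)

    s_rev <- straw_sale_revenue(pr$P_straw, al[["pr_sell"]], Q1, Q2)
    e_rev <- electricity_revenue(pr$P_ele_sal, q_com, q_gas)
    revenue <- revenue + total_revenue(A, Y1, Y2, pr$P_crop[ci],
                                       A * sum(s_rev), A * e_rev)
    us1 <- bundle$usage[[ci]]; us1$D_fer <- N1
    us2 <- bundle$usage[[ci]]; us2$D_fer <- N2
    cost <- cost + A * (material_cost(us1, pr, "initial") +
                          material_cost(us2, pr, "recycle", y_biochar, y_straw) +
                          electricity_cost(us1, pr, sum(I1)) +
                          electricity_cost(us2, pr, sum(I2)) +
                          water_cost(pr$P_wat, sum(I1)) +
                          water_cost(pr$P_wat, sum(I2)))

    a_co2 <- amendment_factor(am$co2, bt, st)
    a_ch4 <- amendment_factor(am$ch4, bt, st)
    a_n2o <- amendment_factor(am$n2o, bt, st)
    ghg_v[ci] <- total_ghg(
      co2_emissions(us1, em, A), ch4_emissions(A, em$omicron[ci]),
      n2o_emissions(A, em$nu[ci], N1, em$nu_fer),
      co2_emissions(us1, em, A, "recycle", a_co2),
      ch4_emissions(A, em$omicron[ci], "recycle", a_ch4),
      n2o_emissions(A, em$nu[ci], N1, em$nu_fer, "recycle", a_n2o),
      em$gwp_ch4, em$gwp_n2o)
    cs_v[ci] <- carbon_sequestration(Y1, Y2, bundle$seq[[ci]],
                                     y_biochar, y_straw, A)
    y1_v[ci] <- Y1; y2_v[ci] <- Y2
    wf <- wf + water_footprint(
      green_wf(2 * sum(P), Y1 + Y2),
      blue_wf(sum(I1) + sum(I2), Y1 + Y2),
      gray_wf(bundle$gray, N1, N2, Y1 + Y2))
  }
  list(NEB = net_economic_benefit(revenue, cost) / sum(bundle$area),
       TCQ = total_comprehensive_quality(bundle$crop_weights, cq1, cq2),
       WF = wf,
       CF = carbon_footprint(ghg_v, cs_v, y1_v, y2_v))
}
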