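# Synthetic study-instance generator.  Emulates the statistical structure
# the analysis assumes: a 3-crop x 5-stage cropping system, the nine-
# treatment Latin square of irrigation x nitrogen x additive levels with
# three replicates, concave quadratic yield/quality responses, bounded
# quadratic amendment responses, and a skewed (Pearson III) annual
# precipitation climate.  Everything is deterministic in the seed.

#' Study configuration
#'
#' @param seed master RNG seed (all downstream randomness derives from it).
#' @param n_crops number of crops (default 3: greenhouse tomato, corn,
#'   soybean).
#' @param n_stages number of growth stages (default 5).
#' @param n_replicates replicates per treatment (default 3).
#' @param noise_cv coefficient of variation of the multiplicative
#'   observation noise.
#' @param recommended_N locally recommended nitrogen rates (kg/ha); the
#'   defaults are 200 (tomato), 240 (corn) and 120 (soybean).
#' @param full_irrigation seasonal full-irrigation totals per crop (mm).
#' @param precip_mean,precip_cv,precip_cs annual precipitation model
#'   (mm/yr, coefficient of variation, skew).
#' @return A validated list of class `"study_config"`.
#' @export
study_config <- function(seed = 1L, n_crops = 3L, n_stages = 5L,
                         n_replicates = 3L, noise_cv = 0.05,
                         recommended_N = NULL, full_irrigation = NULL,
                         precip_mean = 553.2, precip_cv = 0.25,
                         precip_cs = 0.5) {
  .check(n_crops >= 1 && n_stages >= 1 && n_replicates >= 1,
         "n_crops, n_stages and n_replicates must be >= 1")
  .check(noise_cv >= 0, "noise_cv must be non-negative")
  recommended_N <- recommended_N %||%
    rep_len(c(200, 240, 120), n_crops)
  full_irrigation <- full_irrigation %||%
    rep_len(c(450, 350, 280), n_crops)
  .check(all(recommended_N > 0), "recommended_N must be positive")
  .check(all(full_irrigation > 0), "full_irrigation must be positive")
  structure(list(seed = as.integer(seed), n_crops = as.integer(n_crops),
                 n_stages = as.integer(n_stages),
                 n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, recommended_N = recommended_N,
                 full_irrigation = full_irrigation,
                 precip_mean = precip_mean, precip_cv = precip_cv,
                 precip_cs = precip_cs), class = "study_config")
}

# additive (biochar + straw) levels, t/ha, in tomato-corn-soybean order:
# B1+S1 = biochar only, B2+S2 = half-and-half, B3+S3 = straw only
.additive_levels <- function(n_crops) {
  full <- rep_len(c(30, 60, 40), n_crops)
  list(B1S1 = list(biochar = full, straw = full * 0),
       B2S2 = list(biochar = full / 2, straw = full / 2),
       B3S3 = list(biochar = full * 0, straw = full))
}

#' Generate the nine-treatment factorial design
#'
#' Irrigation levels I1/I2/I3 = 1.0/0.75/0.5 of the full quota, nitrogen
#' levels N1/N2/N3 = 1.5/1.0/0.5 of the recommended rate, and three
#' additive levels arranged in the canonical Latin square so that every
#' (I, N) pair appears exactly once.
#'
#' @param config a [study_config()].
#' @return A long data.frame, one row per treatment x crop, with the level
#'   labels, multipliers, and absolute per-crop rates
#'   (`irrigation_mm`, `nitrogen_kg_ha`, `biochar_t_ha`, `straw_t_ha`).
#' @export
generate_design <- function(config) {
  .check(inherits(config, "study_config"), "config must be a study_config")
  irr_frac <- c(I1 = 1.0, I2 = 0.75, I3 = 0.5)
  n_frac <- c(N1 = 1.5, N2 = 1.0, N3 = 0.5)
  # Latin-square additive assignment of the published design scheme
  layout <- data.frame(
    id = paste0("T", 1:9),
    irrigation_level = rep(c("I1", "I2", "I3"), each = 3),
    nitrogen_level = rep(c("N1", "N2", "N3"), 3),
    additive_level = c("B3S3", "B1S1", "B2S2",
                       "B2S2", "B3S3", "B1S1",
                       "B1S1", "B2S2", "B3S3"),
    stringsAsFactors = FALSE)
  add <- .additive_levels(config$n_crops)
  crops <- .crop_names(config$n_crops)
  out <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    row <- layout[i, ]
    lv <- add[[row$additive_level]]
    data.frame(treatment = row$id,
               crop = crops,
               irrigation_level = row$irrigation_level,
               irrigation_frac = unname(irr_frac[row$irrigation_level]),
               nitrogen_level = row$nitrogen_level,
               nitrogen_frac = unname(n_frac[row$nitrogen_level]),
               additive_level = row$additive_level,
               irrigation_mm = unname(irr_frac[row$irrigation_level]) *
                 config$full_irrigation,
               nitrogen_kg_ha = unname(n_frac[row$nitrogen_level]) *
                 config$recommended_N,
               biochar_t_ha = lv$biochar,
               straw_t_ha = lv$straw,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Auxiliary full-rank amendment-response design
#'
#' The nine-treatment Latin square confounds additive level with (I, N),
#' so the six-coefficient amendment quadratic is not identifiable from it.
#' This 3 x 3 biochar-by-straw factorial at fixed I2/N2 levels is full
#' rank for the quadratic surface and is used for amendment-coefficient
#' recovery.
#'
#' @param config a [study_config()].
#' @return A data.frame in the same layout as [generate_design()], with
#'   treatments `A1`..`A9`.
#' @export
generate_amendment_design <- function(config) {
  .check(inherits(config, "study_config"), "config must be a study_config")
  full <- rep_len(c(30, 60, 40), config$n_crops)
  crops <- .crop_names(config$n_crops)
  grid <- expand.grid(b = c(0, 0.5, 1), s = c(0, 0.5, 1))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(treatment = paste0("A", i),
               crop = crops,
               irrigation_level = "I2", irrigation_frac = 0.75,
               nitrogen_level = "N2", nitrogen_frac = 1.0,
               additive_level = sprintf("b%.1f_s%.1f", grid$b[i], grid$s[i]),
               irrigation_mm = 0.75 * config$full_irrigation,
               nitrogen_kg_ha = config$recommended_N,
               biochar_t_ha = grid$b[i] * full,
               straw_t_ha = grid$s[i] * full,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.crop_names <- function(n) {
  base <- c("tomato", "corn", "soybean")
  if (n <= 3) base[seq_len(n)] else c(base, paste0("crop", 4:n))
}

# published stage water-sensitivity exponents for the 5-stage system
.lambda_defaults <- list(
  tomato = c(0.086, 0.314, 0.532, 0.208, 0.163),
  corn = c(0.101, 0.225, 0.447, 0.621, 0.307),
  soybean = c(0.018, 0.685, 0.812, 0.416, 0.124))

# a random lambda vector with its maximum at an interior stage
.draw_lambda <- function(n_stages) {
  l <- stats::runif(n_stages, 0.05, 0.7)
  if (n_stages >= 3) {
    imax <- which.max(l)
    interior <- sample(2:(n_stages - 1), 1)
    l[c(imax, interior)] <- l[c(interior, imax)]
  }
  l
}

#' Generate a full parameter bundle
#'
#' Draws every biophysical, economic and emission coefficient the forward
#' model needs.  For the default 3-crop, 5-stage configuration the Jensen
#' sensitivity exponents are the published stage values; coefficients the
#' source study does not publish are drawn uniformly within documented
#' plausible ranges.  The same seed always yields an identical bundle.
#'
#' Sign structure enforced by construction: nitrogen quadratics are
#' concave with vertex at the recommended rate; yield/quality amendment
#' responses are positive and bounded on the design range; per-gas
#' emission responses are negative (mitigation) and bounded; all prices
#' and factors are positive.
#'
#' @param config a [study_config()].
#' @return A list of class `"param_bundle"`.
#' @export
generate_parameters <- function(config) {
  .check(inherits(config, "study_config"), "config must be a study_config")
  set.seed(config$seed)
  nc <- config$n_crops; nt <- config$n_stages
  crops <- .crop_names(nc)

  # stage fractions of seasonal water demand / rainfall (mid-season peak)
  sf <- if (nt == 5) c(0.10, 0.20, 0.30, 0.25, 0.15) else {
    w <- stats::dnorm(seq(-1.2, 1.2, length.out = nt)); w / sum(w)
  }
  et_season <- rep_len(c(480, 520, 420), nc) * stats::runif(nc, 0.95, 1.05)
  et_m <- outer(et_season, sf)
  dimnames(et_m) <- list(crops, paste0("s", seq_len(nt)))

  jensen <- lapply(seq_len(nc), function(c) {
    lam <- if (nt == 5 && crops[c] %in% names(.lambda_defaults)) {
      .lambda_defaults[[crops[c]]]
    } else .draw_lambda(nt)
    recN <- config$recommended_N[c]
    ymax <- rep_len(c(60000, 8900, 2950), nc)[c] * stats::runif(1, 0.9, 1.1)
    gain <- stats::runif(1, 0.25, 0.35) # fraction of Ymax attributable to N
    a <- -ymax * gain / recN^2
    list(lambda = lam, a = a, b = -2 * a * recN, c = ymax * (1 - gain))
  })

  quality <- lapply(seq_len(nc), function(c) {
    recN <- config$recommended_N[c]
    ifull <- config$full_irrigation[c]
    kN <- stats::runif(1, 0.20, 0.28)
    kI <- stats::runif(1, 0.20, 0.28)
    list(ac = -kN / recN^2, bc = -kI / ifull^2,
         cc = 2 * kN / recN, dc = 2 * kI / ifull,
         ec = stats::runif(1, -1e-7, 1e-7),
         fc = stats::runif(1, 0.30, 0.38))
  })

  # bounded quadratic responses to biochar x (t/ha) and straw y (t/ha);
  # vertex placed beyond the design range so the response is monotone on it
  draw_amend <- function(d_rng, e_rng) {
    d <- stats::runif(1, d_rng[1], d_rng[2])
    e <- stats::runif(1, e_rng[1], e_rng[2])
    list(a = -d / 120, b = -e / 160, c = stats::runif(1, -1e-5, 1e-5),
         d = d, e = e, f = 0)
  }
  amendment <- lapply(seq_len(nc), function(c) {
    list(yield = draw_amend(c(0.0040, 0.0070), c(0.0020, 0.0040)),
         tcq = draw_amend(c(0.0020, 0.0040), c(0.0010, 0.0025)),
         co2 = draw_amend(c(-0.0030, -0.0015), c(-0.0020, -0.0010)),
         ch4 = draw_amend(c(-0.0025, -0.0012), c(-0.0015, -0.0008)),
         n2o = draw_amend(c(-0.0028, -0.0014), c(-0.0018, -0.0009)))
  })

  straw <- lapply(seq_len(nc), function(c) {
    list(omega = rep_len(c(0.30, 1.20, 1.50), nc)[c],
         xi = rep_len(c(0.70, 0.90, 0.85), nc)[c],
         psi = 0.90)
  })

  energy <- list(Hv = rep_len(c(15.5, 17.0, 16.2), nc), # MJ/kg
                 zeta_the = 0.35, zeta_com = 0.85,
                 rho_com = 0.90, rho_gas = 0.75,
                 eta_gas = 0.25, eta_pyr = 0.30, eta_gas_ele = 0.02)

  prices <- list(P_crop = rep_len(c(0.0035, 0.0022, 0.0055), nc),
                 P_straw = 0.0002, P_biochar = 0.0015,
                 P_ele_sal = 0.0005, P_ele_pur = 0.0008,
                 P_wat = 0.0005, P_see = 0.04, P_fer = 0.0045,
                 P_pes = 0.08, P_fue = 0.0075, P_fil = 0.012,
                 P_lab = 0.015)

  greenhouse <- c(TRUE, rep(FALSE, nc - 1))[seq_len(nc)]
  usage <- lapply(seq_len(nc), function(c) {
    list(D_see = rep_len(c(1.5, 25, 60), nc)[c],
         D_pes = rep_len(c(8, 5, 4), nc)[c],
         D_fue = rep_len(c(60, 70, 50), nc)[c],
         D_fil = rep_len(c(50, 10, 10), nc)[c],
         D_lab = rep_len(c(1200, 180, 150), nc)[c],
         D_ele_lig = if (greenhouse[c]) 5 else 0,
         H_lig = if (greenhouse[c]) 200 else 0,
         D_ele_irr = 0.35,
         D_ele_rol = if (greenhouse[c]) 40 else 0,
         tau_rol = 0.8)
  })

  emission <- list(sigma_see = 1.2, sigma_fer = 5.6, sigma_pes = 18,
                   sigma_fue = 2.63, sigma_fil = 19, sigma_lab = 0.2,
                   omicron = rep_len(c(5, 2, 1.5), nc),
                   nu = rep_len(c(1.0, 1.2, 0.8), nc),
                   nu_fer = 0.0125, gwp_ch4 = 28, gwp_n2o = 298)

  seq_par <- lapply(seq_len(nc), function(c) {
    list(Cc = 0.45,
         Hc = rep_len(c(0.60, 0.50, 0.45), nc)[c],
         Rrsr = rep_len(c(0.10, 0.15, 0.20), nc)[c],
         W = rep_len(c(0.93, 0.14, 0.13), nc)[c],
         Cq_biochar = 0.65, Cq_straw = 0.42)
  })

  w <- rep_len(c(0.5, 0.3, 0.2), nc)
  bundle <- list(
    seed = config$seed, n_crops = nc, n_stages = nt, crops = crops,
    greenhouse = greenhouse, area = rep(1, nc),
    soil = soil_params(),
    full_irrigation = config$full_irrigation,
    recommended_N = config$recommended_N,
    et_m = et_m, stage_frac = sf, season_frac = 0.6, eff_rain = 0.8,
    jensen = jensen, quality = quality, amendment = amendment,
    straw = straw, energy = energy, prices = prices, usage = usage,
    emission = emission, seq = seq_par,
    gray = list(nu_LRNF = 0.10, C_max = 0.010, C_n = 0.001),
    crop_weights = w / sum(w),
    precip = list(mean = config$precip_mean, cv = config$precip_cv,
                  cs = config$precip_cs),
    bounds = list(N_min = 0.5 * config$recommended_N,
                  N_max = 1.5 * config$recommended_N,
                  AP = 5e4, TAE = 1e5, a_frac = 0.8))
  structure(bundle, class = "param_bundle")
}

# Effective per-stage rainfall for a classified year: annual total scaled
# by the growing-season share and the effective-rainfall coefficient, then
# split by stage fractions.  Greenhouse crops receive zero rainfall.
.stage_rainfall <- function(bundle, annual_mm) {
  p <- annual_mm * bundle$season_frac * bundle$eff_rain * bundle$stage_frac
  P <- matrix(rep(p, each = bundle$n_crops), nrow = bundle$n_crops)
  P[bundle$greenhouse, ] <- 0
  dimnames(P) <- dimnames(bundle$et_m)
  P
}

#' Build a hydrological scenario for the forward model
#'
#' Represents each hydrological year class by its guarantee-rate
#' precipitation (wet = 25%, normal = 50%, dry = 75% exceedance) under the
#' bundle's Pearson III climate, distributed across growth stages.
#'
#' @param bundle a [generate_parameters()] bundle.
#' @param class `"wet"`, `"normal"` or `"dry"`, or a number taken as the
#'   annual precipitation (mm).
#' @return List with `class`, `annual_mm` and the per-crop, per-stage
#'   effective rainfall matrix `P_stage` (mm).
#' @export
hydro_scenario <- function(bundle, class = "normal") {
  if (is.numeric(class)) {
    annual <- class
    p3 <- bundle$precip
    th <- list(P25 = quantile_pearson3(p3, 0.25),
               P75 = quantile_pearson3(p3, 0.75))
    label <- classify_hydro_year(annual, th)
  } else {
    label <- match.arg(class, c("wet", "normal", "dry"))
    prob <- c(wet = 0.25, normal = 0.50, dry = 0.75)[[label]]
    annual <- quantile_pearson3(bundle$precip, prob)
  }
  list(class = label, annual_mm = annual,
       P_stage = .stage_rainfall(bundle, annual))
}

# noise-free forward model for one design row (one treatment x crop):
# returns the observables the field trial would measure
.forward_observe <- function(bundle, row, P_annual = NULL) {
  c_i <- match(row$crop, bundle$crops)
  nt <- bundle$n_stages
  annual <- P_annual %||% bundle$precip$mean
  P <- .stage_rainfall(bundle, annual)[c_i, ]
  I <- row$irrigation_mm * bundle$stage_frac
  N <- row$nitrogen_kg_ha
  et_m <- bundle$et_m[c_i, ]
  et_a <- pmin(P + I, et_m)
  jp <- bundle$jensen[[c_i]]
  Ym <- pmax(jp$a * N^2 + jp$b * N + jp$c, 0)
  Y0 <- Ym * prod(pmin(pmax(et_a / et_m, 0), 1)^jp$lambda)
  am <- bundle$amendment[[c_i]]
  a_y <- amendment_factor(am$yield, row$biochar_t_ha, row$straw_t_ha)
  a_q <- amendment_factor(am$tcq, row$biochar_t_ha, row$straw_t_ha)
  a_co2 <- amendment_factor(am$co2, row$biochar_t_ha, row$straw_t_ha)
  a_ch4 <- amendment_factor(am$ch4, row$biochar_t_ha, row$straw_t_ha)
  a_n2o <- amendment_factor(am$n2o, row$biochar_t_ha, row$straw_t_ha)
  yield <- (1 + a_y) * Y0
  qp <- bundle$quality[[c_i]]
  q0 <- crop_quality(qp, N, sum(I), clip = FALSE)
  quality <- min(max((1 + a_q) * q0, 0), 1)
  sw <- bundle$straw[[c_i]]
  biomass <- yield * sw$omega * sw$xi * sw$psi
  us <- bundle$usage[[c_i]]
  us$D_fer <- N
  co2 <- (1 + a_co2) * co2_emissions(us, bundle$emission, 1)
  ch4 <- (1 + a_ch4) * ch4_emissions(1, bundle$emission$omicron[c_i])
  n2o <- (1 + a_n2o) *
    n2o_emissions(1, bundle$emission$nu[c_i], N, bundle$emission$nu_fer)
  out <- c(yield = yield, quality = quality, biomass = biomass,
           co2 = co2, ch4 = ch4, n2o = n2o)
  c(out, stats::setNames(et_a, paste0("ETa_", seq_len(nt))))
}

#' Generate noisy treatment observations
#'
#' Runs the forward model for every design row and replicate, then
#' applies multiplicative Gaussian noise `value * (1 + N(0, noise_cv))`
#' truncated at zero.  `noise_cv = 0` reproduces the forward model
#' exactly; replicates share the treatment-level truth and differ only in
#' noise.
#'
#' @param bundle a [generate_parameters()] bundle.
#' @param design a design from [generate_design()] or
#'   [generate_amendment_design()].
#' @param noise_cv observation noise coefficient of variation (>= 0).
#' @param seed RNG seed for the noise draws.
#' @param n_replicates replicates per treatment (default 3).
#' @return A long data.frame, one row per treatment x replicate x crop,
#'   with yield (kg/ha), quality ([0,1]), biomass (kg/ha), per-gas
#'   emissions (kg/ha) and per-stage actual ET (mm).
#' @export
generate_observations <- function(bundle, design, noise_cv = 0.05,
                                  seed = 1L, n_replicates = 3L) {
  .check(inherits(bundle, "param_bundle"), "bundle must be a param_bundle")
  .check(noise_cv >= 0, "noise_cv must be non-negative")
  truth <- t(vapply(seq_len(nrow(design)),
                    function(i) .forward_observe(bundle, design[i, ]),
                    .forward_observe(bundle, design[1, ])))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    noisy <- truth
    if (noise_cv > 0) {
      eps <- matrix(stats::rnorm(length(truth), 0, noise_cv), nrow(truth))
      noisy <- pmax(truth * (1 + eps), 0)
      # quality stays a score on the unit interval
      noisy[, "quality"] <- pmin(noisy[, "quality"], 1)
    }
    cbind(design[, c("treatment", "crop")], replicate = r,
          as.data.frame(noisy))
  }))
  rownames(out) <- NULL
  out
}

#' Write a study instance to disk
#'
#' Design and observations as CSV (one row per treatment x replicate x
#' crop), the parameter bundle as JSON.
#'
#' @param bundle,design,observations objects from the generators.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(bundle, design, observations, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(design = file.path(dir, "design.csv"),
             observations = file.path(dir, "observations.csv"),
             parameters = file.path(dir, "parameters.json"))
  utils::write.csv(design, paths["design"], row.names = FALSE)
  utils::write.csv(observations, paths["observations"], row.names = FALSE)
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  jsonlite::write_json(strip(bundle), paths["parameters"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
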