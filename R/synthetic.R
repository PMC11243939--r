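# Synthetic counting campaigns with the statistical structure the analysis
# assumes: plot-level soil activities declining across years, organ
# partitioning ordered root > leaf > stem > grain, Poisson counting at the
# study's detector settings, and a latent sorption factor that links clay,
# humus and moisture to the transfer factor.

crop_organs <- list(
  winter_wheat = c("root", "rest_of_plant"),
  rapeseed     = c("root", "rest_of_plant"),
  maize        = c("root", "stem", "leaf", "grain"),
  soybean      = c("root", "stem", "leaf", "grain"))

# organ whose TF the above-ground (vegetative) comparison uses
vegetative_organ <- c(winter_wheat = "rest_of_plant", rapeseed = "rest_of_plant",
                      maize = "stem", soybean = "stem")

#' Configuration of a synthetic counting campaign
#'
#' Defaults emulate the study conditions: plot-level soil Sr-90 activities
#' of order 1--4 Bq/kg declining year over year, organ partition ordered
#' root > leaf > stem > grain, 35 % counting efficiency, 5400 s counts, a
#' 14-day (336 h) parent-daughter ingrowth wait before separation and a
#' 24 h separation-to-counting delay.
#'
#' @param n_sites number of plots.
#' @param years campaign years.
#' @param crops crop rotation: data.frame with `site_code`, `year`,
#'   `crop_type`, or `NULL` for a default 4-crop rotation.
#' @param soil_A_mean mean soil activity in the first year, Bq/kg.
#' @param soil_A_lognormal_sigma log-scale dispersion of plot activities.
#' @param annual_decline multiplicative activity factor per year.
#' @param organ_partition named TF-like coefficients per organ; must be
#'   ordered root > leaf > stem > grain.
#' @param detector [detector_calibration()].
#' @param count_time_s sample and background counting time, s.
#' @param ingrowth_wait_h wait between Sr/Y separation of the source and
#'   counting-separation, h; 336 h brings the daughter to > 97 % of
#'   equilibrium (recorded for protocol realism, not used in the arithmetic).
#' @param count_delay_h separation-to-counting delay, h (the `t_sep` of the
#'   activity estimator).
#' @param chemical_yield_range uniform range of the chemical yield.
#' @param mass_range_kg uniform range of dry sample mass, kg.
#' @param background_cps true background count rate, 1/s.
#' @param sorption named list linking the latent sorption factor to soil
#'   properties: loadings on `clay`, `humus`, `hh` and the TF log-scale
#'   coefficient `tf_beta`.
#' @param model_params list with `alpha_ex`, `Kc`, `CEC` used to define the
#'   generating uptake coefficients.
#' @param seed RNG seed; the campaign is reproducible bit-for-bit from the
#'   configuration.
#' @return object of class `campaign_config`.
#' @export
campaign_config <- function(n_sites = 16, years = 2013:2015, crops = NULL,
                            soil_A_mean = 2.5, soil_A_lognormal_sigma = 0.2,
                            annual_decline = 0.85,
                            organ_partition = c(root = 0.5, leaf = 0.25,
                                                stem = 0.12, grain = 0.10,
                                                rest_of_plant = 0.13),
                            detector = detector_calibration(),
                            count_time_s = 5400,
                            ingrowth_wait_h = 336, count_delay_h = 24,
                            chemical_yield_range = c(0.6, 0.9),
                            mass_range_kg = c(0.3, 0.7),
                            background_cps = 0.01,
                            sorption = list(clay = 3.5, humus = 0.3,
                                            hh = 0.3, tf_beta = 0.2),
                            model_params = list(alpha_ex = 0.7, Kc = 2.1,
                                                CEC = 30),
                            seed = 1) {
  stopifnot(n_sites >= 1, length(years) >= 1, soil_A_mean > 0,
            soil_A_lognormal_sigma >= 0, annual_decline > 0,
            all(organ_partition > 0),
            organ_partition["root"] > organ_partition["leaf"],
            organ_partition["leaf"] > organ_partition["stem"],
            organ_partition["stem"] > organ_partition["grain"],
            count_time_s > 0, count_delay_h >= 0, background_cps >= 0,
            diff(chemical_yield_range) >= 0, chemical_yield_range[1] > 0,
            chemical_yield_range[2] <= 1, mass_range_kg[1] > 0)
  if (is.null(crops)) {
    rotation <- names(crop_organs)
    crops <- expand.grid(site = seq_len(n_sites), yi = seq_along(years))
    crops <- data.frame(
      site_code = paste0("S", crops$site),
      year = years[crops$yi],
      crop_type = rotation[1 + (crops$site + crops$yi) %% length(rotation)],
      stringsAsFactors = FALSE)
  }
  structure(list(n_sites = n_sites, years = years, crops = crops,
                 soil_A_mean = soil_A_mean,
                 soil_A_lognormal_sigma = soil_A_lognormal_sigma,
                 annual_decline = annual_decline,
                 organ_partition = organ_partition, detector = detector,
                 count_time_s = count_time_s,
                 ingrowth_wait_h = ingrowth_wait_h,
                 count_delay_h = count_delay_h,
                 chemical_yield_range = chemical_yield_range,
                 mass_range_kg = mass_range_kg,
                 background_cps = background_cps, sorption = sorption,
                 model_params = model_params, seed = seed),
            class = "campaign_config")
}

#' Generate a synthetic counting campaign
#'
#' Draws plot-level true soil activities (lognormal around the declining
#' yearly mean), organ activities as soil activity times the organ
#' partition times the plot's latent sorption factor, soil properties
#' loaded on that same factor, and raw gross-beta counting records with
#' Poisson counts at the configured detector settings.  Fully deterministic
#' given the configuration (which includes the seed).
#'
#' @param config [campaign_config()].
#' @param seed optional override of `config$seed`.
#' @return list of class `synthetic_campaign` with elements `truth`
#'   (per-sample true activity and TF, plus per-plot sorption factor and
#'   per-crop generating k), `counting_records`, `soil_properties`, and
#'   `config`.
#' @export
generate_campaign <- function(config = campaign_config(), seed = NULL) {
  stopifnot(inherits(config, "campaign_config"))
  if (!is.null(seed)) config$seed <- seed
  set.seed(config$seed)
  hl <- half_lives()
  cal <- config$detector
  sites <- unique(config$crops$site_code)

  ## plot level: latent sorption factor and correlated soil properties
  z <- stats::rnorm(length(sites))
  sorp <- exp(config$sorption$tf_beta * z)
  clay <- pmin(pmax(31 + config$sorption$clay * z +
                      stats::rnorm(length(sites), 0, 1.5), 5), 55)
  humus <- pmax(2.5 + config$sorption$humus * z +
                  stats::rnorm(length(sites), 0, 0.15), 0.5)
  hh <- pmax(2.8 + config$sorption$hh * z +
               stats::rnorm(length(sites), 0, 0.15), 0.5)
  cs <- stats::runif(length(sites), 3, 15)
  fs <- stats::runif(length(sites), 3, 22)
  oc <- pmax(humus * 0.12 + stats::rnorm(length(sites), 0, 0.03), 0.05)
  och <- oc * stats::runif(length(sites), 0.4, 0.65)
  props <- data.frame(
    site_code = sites, coarse_sand = cs, fine_sand = fs,
    silt = 100 - cs - fs - clay, clay = clay,
    texture_class = ifelse(clay >= 35, "CL", "SCL"),
    hygroscopic_humidity = hh,
    density = stats::runif(length(sites), 1.2, 1.45),
    pH_H2O = stats::runif(length(sites), 6.2, 8.0),
    pH_KCl = stats::runif(length(sites), 6.0, 7.5),
    CaCO3 = round(stats::runif(length(sites), 0, 5), 2),
    humus = humus, total_OC = oc, OC_humic = och, OC_fulvic = oc - och)

  ## sample level: truth
  rows <- list()
  for (yi in seq_along(config$years)) {
    year <- config$years[yi]
    A_soil <- stats::rlnorm(length(sites),
                            log(config$soil_A_mean *
                                  config$annual_decline^(yi - 1)) -
                              config$soil_A_lognormal_sigma^2 / 2,
                            config$soil_A_lognormal_sigma)
    rows[[length(rows) + 1]] <- data.frame(
      site_code = sites, year = year, medium = "soil", crop_type = "none",
      organ = "none", A_true = A_soil, tf_true = NA_real_)
    for (si in seq_along(sites)) {
      ct <- config$crops$crop_type[config$crops$site_code == sites[si] &
                                     config$crops$year == year]
      if (!length(ct)) next
      organs <- crop_organs[[ct]]
      tf <- config$organ_partition[organs] * sorp[si]
      rows[[length(rows) + 1]] <- data.frame(
        site_code = sites[si], year = year, medium = "crop", crop_type = ct,
        organ = organs, A_true = A_soil[si] * tf, tf_true = unname(tf))
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL

  ## counting records: Poisson counts implied by inverting the estimator
  n <- nrow(truth)
  eta_s <- stats::runif(n, config$chemical_yield_range[1],
                        config$chemical_yield_range[2])
  m <- stats::runif(n, config$mass_range_kg[1], config$mass_range_kg[2])
  decay <- exp(-log(2) * config$count_delay_h / hl$T_half_Y90)
  mu <- truth$A_true * cal$epsilon * eta_s * cal$eta * m * decay
  Ns <- stats::rpois(n, (mu + config$background_cps) * config$count_time_s)
  N0 <- stats::rpois(n, config$background_cps * config$count_time_s)
  R <- Ns / config$count_time_s
  R0 <- N0 / config$count_time_s
  net <- R - R0
  dR <- sqrt(Ns + N0) / config$count_time_s
  records <- data.frame(
    truth[, c("site_code", "year", "medium", "crop_type", "organ")],
    R = R, R0 = R0, tS = config$count_time_s, t0 = config$count_time_s,
    t_sep_h = config$count_delay_h, eta_s = eta_s, m_kg = m,
    dR_rel = ifelse(net > 0, dR / net, 0),
    d_eta_s_rel = 0, dm_rel = 0)

  ## generating uptake coefficients per crop (sorption factor 1)
  mp <- config$model_params
  k_true <- vapply(unique(config$crops$crop_type), function(ct)
    k_from_tf(unname(config$organ_partition[vegetative_organ[ct]]),
              mp$alpha_ex, mp$Kc, mp$CEC), numeric(1))

  mda_ref <- minimum_detectable_activity(config$background_cps,
                                         config$count_time_s,
                                         config$count_time_s,
                                         mean(config$chemical_yield_range),
                                         mean(config$mass_range_kg), cal) / decay
  if (all(truth$A_true < mda_ref))
    warning("infeasible configuration: every true activity lies below the ",
            sprintf("achievable detection limit (~%.3g Bq/kg)", mda_ref))

  structure(list(truth = truth, counting_records = records,
                 soil_properties = props,
                 sorption_factor = stats::setNames(sorp, sites),
                 k_true = k_true, config = config),
            class = "synthetic_campaign")
}

#' @export
print.synthetic_campaign <- function(x, ...) {
  cat(sprintf("synthetic campaign: %d plots x %d years, %d samples (seed %d)\n",
              length(unique(x$truth$site_code)), length(x$config$years),
              nrow(x$truth), x$config$seed))
  invisible(x)
}

#' Estimator recovery report for a synthetic campaign
#'
#' Reduces the campaign's counting records, pairs the estimates with the
#' generating truth, and reports bias, RMSE and (for activities) the
#' empirical coverage of the `A +- 2 dA` intervals over uncensored
#' estimates; transfer factors are recovered through [build_tf_table()] and
#' the uptake coefficient through [calibrate_k()] per crop.
#'
#' @param campaign output of [generate_campaign()].
#' @param activities optional pre-computed reduction of
#'   `campaign$counting_records` (defaults to [reduce_counting_records()]
#'   with the campaign's detector).
#' @return data.frame with one row per quantity (`A_soil`, `A_crop`, `TF`,
#'   `k`): `bias`, `rmse`, `coverage` (activities only), `n`.
#' @export
recovery_report <- function(campaign, activities = NULL) {
  stopifnot(inherits(campaign, "synthetic_campaign"))
  if (is.null(activities))
    activities <- reduce_counting_records(campaign$counting_records,
                                          campaign$config$detector)
  truth <- campaign$truth
  key <- function(d) paste(d$site_code, d$year, d$medium, d$organ)
  idx <- match(key(truth), key(activities))
  if (anyNA(idx)) stop("estimate/truth key mismatch", call. = FALSE)
  est <- activities[idx, ]

  row_for <- function(name, true, e, dA = NULL, cens = NULL) {
    ok <- if (is.null(cens)) !is.na(e) else !cens & !is.na(e)
    data.frame(quantity = name, bias = mean(e[ok] - true[ok]),
               rmse = sqrt(mean((e[ok] - true[ok])^2)),
               coverage = if (is.null(dA)) NA_real_ else
                 mean(abs(e[ok] - true[ok]) <= 2 * dA[ok]),
               n = sum(ok))
  }
  soil_i <- truth$medium == "soil"
  out <- rbind(
    row_for("A_soil", truth$A_true[soil_i], est$A[soil_i], est$dA[soil_i],
            est$censored[soil_i]),
    row_for("A_crop", truth$A_true[!soil_i], est$A[!soil_i], est$dA[!soil_i],
            est$censored[!soil_i]))

  tf_est <- build_tf_table(
    data.frame(est[!soil_i, c("site_code", "year")],
               crop_type = truth$crop_type[!soil_i],
               organ = truth$organ[!soil_i], A = est$A[!soil_i],
               censored = est$censored[!soil_i]),
    est[soil_i, c("site_code", "year", "A")])
  out <- rbind(out, row_for("TF", truth$tf_true[!soil_i], tf_est$tf))

  mp <- campaign$config$model_params
  veg <- tf_est$organ == unname(vegetative_organ[tf_est$crop_type])
  kcal <- calibrate_k(tf_est$tf[veg], tf_est$crop_type[veg],
                      mp$alpha_ex, mp$Kc, mp$CEC)
  kt <- campaign$k_true[kcal$group]
  out <- rbind(out, data.frame(quantity = "k", bias = mean(kcal$k - kt),
                               rmse = sqrt(mean((kcal$k - kt)^2)),
                               coverage = NA_real_, n = sum(kcal$n)))
  rownames(out) <- NULL
  out
}
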