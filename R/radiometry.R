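ln2 <- log(2)

#' Sr-90 activity concentration from a gross-beta counting record
#'
#' The Sr-90 activity of a sample is determined by counting the Y-90
#' daughter after radiochemical separation.  The net count rate is corrected
#' for the Y-90 decay between separation and counting and normalised by the
#' counting efficiency, the chemical yield, the method yield factor and the
#' dry sample mass:
#'
#' \deqn{A = \frac{(R - R_0)\, e^{\ln 2\, t / T_{1/2}}}{\varepsilon\, \eta_s\, \eta\, m}}
#'
#' A negative net count rate is clamped to zero activity (such results are
#' reported as censored, i.e. below the detection limit).
#'
#' @param R sample count rate (1/s).
#' @param R0 background count rate (1/s).
#' @param t_sep_h time elapsed since Y-90 separation, hours.
#' @param eta_s chemical yield of the separation, fraction in (0, 1].
#' @param m_kg dry sample mass, kg.
#' @param cal [detector_calibration()].
#' @param hl [half_lives()]; `T_half_Y90` must be in hours, like `t_sep_h`.
#' @return activity concentration, Bq/kg dry mass (vectorised).
#' @examples
#' activity_concentration(0.05, 0.01, 72, eta_s = 0.7, m_kg = 0.5)  # ~0.7104
#' @export
activity_concentration <- function(R, R0, t_sep_h, eta_s, m_kg,
                                   cal = detector_calibration(),
                                   hl = half_lives()) {
  stopifnot(all(R >= 0), all(R0 >= 0), all(t_sep_h >= 0),
            all(eta_s > 0), all(eta_s <= 1), all(m_kg > 0))
  net <- (R - R0) * exp(ln2 * t_sep_h / hl$T_half_Y90)
  pmax(net, 0) / (cal$epsilon * eta_s * cal$eta * m_kg)
}

#' Combined standard uncertainty of an activity concentration
#'
#' Propagates the relative uncertainty budget of the activity estimator in
#' quadrature: net count rate, decay-correction exponent, counting
#' efficiency, chemical yield, method yield and mass,
#'
#' \deqn{\Delta A = A \sqrt{\delta R^2 + \delta T_{1/2}^2 + u(\varepsilon)^2
#'   + \delta\eta_s^2 + \delta\eta^2 + \delta m^2},}
#'
#' with \eqn{\delta T_{1/2} = \ln 2\, t\, \Delta T_{1/2} / T_{1/2}^2}.  The
#' half-life term defaults to zero (`dT_half_h = 0`) when no half-life
#' uncertainty is supplied.
#'
#' @param A activity concentration, Bq/kg.
#' @param dR_rel relative standard uncertainty of the net count rate.
#' @param t_sep_h time since separation, hours.
#' @param d_eta_s_rel relative standard uncertainty of the chemical yield.
#' @param dm_rel relative standard uncertainty of the mass.
#' @param dT_half_h absolute uncertainty of the Y-90 half-life, hours.
#' @inheritParams activity_concentration
#' @return combined standard uncertainty, Bq/kg (expanded value is `2 *` this).
#' @export
activity_uncertainty <- function(A, dR_rel, t_sep_h = 0, d_eta_s_rel = 0,
                                 dm_rel = 0, dT_half_h = 0,
                                 cal = detector_calibration(),
                                 hl = half_lives()) {
  stopifnot(all(A >= 0), all(dR_rel >= 0), all(d_eta_s_rel >= 0),
            all(dm_rel >= 0), all(dT_half_h >= 0))
  dT_rel <- ln2 * t_sep_h * dT_half_h / hl$T_half_Y90^2
  A * sqrt(dR_rel^2 + dT_rel^2 + cal$u_epsilon_rel^2 +
             d_eta_s_rel^2 + cal$d_eta_rel^2 + dm_rel^2)
}

#' Currie-type minimum detectable activity
#'
#' \deqn{MDA = \frac{2.71 + 4.65\sqrt{R_0 t_0}}{\varepsilon\, \eta_s\, m\, t_S}}
#'
#' expressed in Bq/kg at the measurement date (no decay correction and no
#' method yield factor enter this expression).
#'
#' @param R0 background count rate (1/s).
#' @param t0_s background counting time, s.
#' @param tS_s sample counting time, s.
#' @inheritParams activity_concentration
#' @return MDA in Bq/kg; decreasing in efficiency, yield, mass and counting
#'   time, increasing in the background rate.
#' @examples
#' minimum_detectable_activity(0.01, 5400, 5400, eta_s = 0.7, m_kg = 0.5)
#' @export
minimum_detectable_activity <- function(R0, t0_s, tS_s, eta_s, m_kg,
                                        cal = detector_calibration()) {
  stopifnot(all(R0 >= 0), all(t0_s > 0), all(tS_s > 0),
            all(eta_s > 0), all(m_kg > 0))
  (2.71 + 4.65 * sqrt(R0 * t0_s)) / (cal$epsilon * eta_s * m_kg * tS_s)
}

#' Y-90 ingrowth towards secular equilibrium
#'
#' Fraction of the parent (Sr-90) activity reached by the Y-90 daughter a
#' time `t_h` after a complete chemical separation:
#' \eqn{f(t) = 1 - e^{-\ln 2\, t / T_{1/2}}}.  At 14 days (336 h) the
#' fraction exceeds 0.97, which is why equilibrium is assumed after a
#' two-week ingrowth wait.
#'
#' @param t_h time since separation, hours (non-negative).
#' @inheritParams activity_concentration
#' @return ingrowth fraction in \[0, 1).
#' @export
ingrowth_fraction <- function(t_h, hl = half_lives()) {
  if (any(t_h < 0)) stop("ingrowth time must be non-negative")
  1 - exp(-ln2 * t_h / hl$T_half_Y90)
}

#' Correct a Sr-90 activity back to the sampling date
#'
#' Undoes the Sr-90 decay between sampling and measurement:
#' \eqn{A_{sampling} = A\, e^{+\ln 2\, \Delta t / T_{1/2}}}.
#'
#' @param A activity at the measurement date, Bq/kg.
#' @param elapsed_days days between sampling and measurement.
#' @inheritParams activity_concentration
#' @return activity at the sampling date, Bq/kg.
#' @export
decay_correct <- function(A, elapsed_days, hl = half_lives()) {
  stopifnot(all(elapsed_days >= 0))
  A * exp(ln2 * (elapsed_days / 365.25) / hl$T_half_Sr90)
}

#' Reduce counting records to activity results
#'
#' Applies the activity estimator, the uncertainty budget and the MDA to a
#' table of counting records and flags censored results.  For the censoring
#' decision the Eq.-3 MDA (a measurement-date quantity) is put on the same
#' reference basis as the activity by applying the Y-90 decay-correction
#' factor and the method yield; a result is censored when the net count rate
#' is non-positive or the activity falls below that threshold, and its
#' reported bound is the threshold itself.
#'
#' @param records data.frame in the `counting_records.csv` schema (see
#'   [read_counting_records()]).
#' @param k coverage factor for the expanded uncertainty (default 2,
#'   approximately 95 % confidence).
#' @inheritParams activity_concentration
#' @return data.frame with the key columns of `records` plus
#'   `A`, `dA`, `dA_expanded`, `MDA`, `censored`.
#' @export
reduce_counting_records <- function(records, cal = detector_calibration(),
                                    hl = half_lives(), k = 2) {
  validate_counting_records(records)
  A <- activity_concentration(records$R, records$R0, records$t_sep_h,
                              records$eta_s, records$m_kg, cal, hl)
  dA <- activity_uncertainty(A, records$dR_rel, records$t_sep_h,
                             records$d_eta_s_rel, records$dm_rel,
                             dT_half_h = 0, cal = cal, hl = hl)
  mda <- minimum_detectable_activity(records$R0, records$t0, records$tS,
                                     records$eta_s, records$m_kg, cal)
  mda_ref <- mda * exp(ln2 * records$t_sep_h / hl$T_half_Y90) / cal$eta
  cens <- records$R <= records$R0 | A < mda_ref
  out <- records[, intersect(c("site_code", "year", "medium", "crop_type",
                               "organ"), names(records)), drop = FALSE]
  out$A <- ifelse(cens, mda_ref, A)   # censored results report the bound
  out$dA <- ifelse(cens, NA_real_, dA)
  out$dA_expanded <- k * out$dA
  out$MDA <- mda_ref
  out$censored <- cens
  out
}
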