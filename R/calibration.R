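#' Half-life constants
#'
#' Default values are the ones the campaign data reduction was performed
#' with: 64.2 h for the Y-90 daughter and 28.8 years for Sr-90.
#'
#' @param T_half_Y90 Y-90 half-life in hours.
#' @param T_half_Sr90 Sr-90 half-life in years.
#' @return object of class `half_lives`.
#' @export
half_lives <- function(T_half_Y90 = 64.2, T_half_Sr90 = 28.8) {
  stopifnot(is.numeric(T_half_Y90), T_half_Y90 > 0,
            is.numeric(T_half_Sr90), T_half_Sr90 > 0)
  structure(list(T_half_Y90 = T_half_Y90, T_half_Sr90 = T_half_Sr90),
            class = "half_lives")
}

#' Detector and method calibration
#'
#' Gas-flow proportional counter calibration for gross-beta counting:
#' beta counting efficiency (default 35 %), method yield factor, and their
#' relative standard uncertainties.
#'
#' @param epsilon beta counting efficiency, fraction in (0, 1].
#' @param u_epsilon_rel relative standard uncertainty of `epsilon`.
#' @param eta method yield factor, fraction in (0, 1].
#' @param d_eta_rel relative standard uncertainty of `eta`.
#' @return object of class `detector_calibration`.
#' @export
detector_calibration <- function(epsilon = 0.35, u_epsilon_rel = 0,
                                 eta = 1, d_eta_rel = 0) {
  stopifnot(epsilon > 0, epsilon <= 1, eta > 0, eta <= 1,
            u_epsilon_rel >= 0, d_eta_rel >= 0)
  structure(list(epsilon = epsilon, u_epsilon_rel = u_epsilon_rel,
                 eta = eta, d_eta_rel = d_eta_rel),
            class = "detector_calibration")
}

#' @export
print.detector_calibration <- function(x, ...) {
  cat(sprintf("detector calibration: epsilon = %g (u_rel %g), eta = %g (u_rel %g)\n",
              x$epsilon, x$u_epsilon_rel, x$eta, x$d_eta_rel))
  invisible(x)
}

#' @export
print.half_lives <- function(x, ...) {
  cat(sprintf("half-lives: Y-90 %g h, Sr-90 %g y\n",
              x$T_half_Y90, x$T_half_Sr90))
  invisible(x)
}
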