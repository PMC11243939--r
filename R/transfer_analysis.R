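#' Soil-crop transfer factor
#'
#' Ratio of the Sr-90 activity concentration in a plant compartment to that
#' in the soil it grew in, both on a dry-mass basis: `TF = A_crop / A_soil`.
#' A censored crop activity gives an undefined transfer factor (`NA`), never
#' zero: a detection bound is not a measurement.
#'
#' @param A_crop crop activity, Bq/kg dry mass (non-negative).
#' @param A_soil soil activity, Bq/kg dry mass (strictly positive).
#' @param censored logical; is the crop activity a censoring bound?
#' @return numeric transfer factor(s); `NA` where censored.
#' @examples
#' transfer_factor(1.72, 2.98)          # 0.577...
#' transfer_factor(0.14, 2.13, censored = TRUE)  # NA
#' @export
transfer_factor <- function(A_crop, A_soil, censored = FALSE) {
  if (any(A_soil <= 0)) stop("soil activity must be positive", call. = FALSE)
  if (any(A_crop < 0, na.rm = TRUE)) stop("crop activity must be non-negative",
                                          call. = FALSE)
  ifelse(censored, NA_real_, A_crop / A_soil)
}

#' Build the organ-level transfer-factor table of a campaign
#'
#' Pairs every crop activity with the soil activity of the same plot and
#' year and computes the transfer factor per organ.  Censored crop cells
#' yield undefined records (`defined = FALSE`), rendered `"/"` in reports.
#'
#' @param crop_activity data.frame with `site_code`, `year`, `crop_type`,
#'   `organ`, `A`, `censored`.
#' @param soil_activity data.frame with `site_code`, `year`, `A`.
#' @return data.frame with the crop key columns plus `tf` and `defined`.
#' @export
build_tf_table <- function(crop_activity, soil_activity) {
  check_columns(crop_activity, c("site_code", "year", "crop_type", "organ", "A"),
                "crop activities")
  check_columns(soil_activity, c("site_code", "year", "A"), "soil activities")
  if (is.null(crop_activity$censored)) crop_activity$censored <- FALSE
  key_c <- paste(crop_activity$site_code, crop_activity$year)
  key_s <- paste(soil_activity$site_code, soil_activity$year)
  idx <- match(key_c, key_s)
  if (anyNA(idx))
    stop("no soil partner for crop sample(s): ",
         paste(unique(key_c[is.na(idx)]), collapse = "; "), call. = FALSE)
  out <- crop_activity[, c("site_code", "year", "crop_type", "organ")]
  out$tf <- transfer_factor(crop_activity$A, soil_activity$A[idx],
                            crop_activity$censored)
  out$defined <- !crop_activity$censored
  out
}

#' Relative-frequency histogram of transfer factors
#'
#' Half-open bins `[lo, lo + w)` starting at zero; relative frequencies sum
#' to one.  The modal bin and its relative frequency are attached as
#' attributes `modal_bin` and `modal_rel_freq`.
#'
#' @param tf numeric transfer factors; `NA` (undefined) entries are dropped.
#' @param bin_width positive bin width (default 0.05, resolving the
#'   two-decimal report resolution without empty-bin artefacts).
#' @return data.frame with `bin_lo`, `bin_hi`, `count`, `rel_freq`.
#' @export
tf_frequency <- function(tf, bin_width = 0.05) {
  stopifnot(bin_width > 0)
  tf <- tf[!is.na(tf)]
  if (!length(tf)) stop("no defined transfer factors", call. = FALSE)
  lo <- seq(0, max(tf) + bin_width, by = bin_width)
  idx <- floor(tf / bin_width) + 1L
  count <- tabulate(idx, nbins = length(lo) - 1L)
  out <- data.frame(bin_lo = lo[-length(lo)], bin_hi = lo[-1], count = count,
                    rel_freq = count / sum(count))
  attr(out, "modal_bin") <- out$bin_lo[which.max(out$count)]
  attr(out, "modal_rel_freq") <- max(out$rel_freq)
  out
}

#' Model-vs-experiment agreement by site
#'
#' Forms the yearly ratio `tf_mod / tf_exp` and its per-site arithmetic
#' mean.  Years with `tf_exp = 0` or an undefined value are excluded from
#' the mean with a warning.
#'
#' @param comparison data.frame with `site_code`, `year`, `tf_mod`, `tf_exp`.
#' @return data.frame with `site_code`, `n_years`, `mean_ratio`; the yearly
#'   ratios are attached as attribute `ratios` (long data.frame).
#' @export
model_agreement <- function(comparison) {
  check_columns(comparison, c("site_code", "year", "tf_mod", "tf_exp"),
                "agreement table")
  ok <- !is.na(comparison$tf_exp) & comparison$tf_exp > 0 &
    !is.na(comparison$tf_mod)
  if (any(!ok))
    warning(sprintf("%d site-year(s) without a defined experimental TF excluded",
                    sum(!ok)))
  ratios <- comparison[ok, c("site_code", "year")]
  ratios$ratio <- comparison$tf_mod[ok] / comparison$tf_exp[ok]
  agg <- stats::aggregate(ratio ~ site_code, ratios, mean)
  n <- stats::aggregate(ratio ~ site_code, ratios, length)
  out <- data.frame(site_code = agg$site_code, n_years = n$ratio,
                    mean_ratio = agg$ratio)
  out <- out[order(match(out$site_code, unique(comparison$site_code))), ]
  rownames(out) <- NULL
  attr(out, "ratios") <- ratios
  out
}

#' Compare a computed TF table against a printed reference
#'
#' Rounds the computed transfer factors to two decimals and tabulates the
#' discrepancies against the printed golden table, cell for cell; used to
#' audit the reproduction of the published table rather than silently
#' absorbing differences.
#'
#' @param tf_table output of [build_tf_table()].
#' @param printed data.frame with the same key columns and `tf_printed`
#'   (`NA` for `/` cells).
#' @param mode rounding mode for the rendered value.
#' @return list with `n_defined`, `n_exact`, `max_abs_diff`,
#'   `censoring_matches` (logical), and `discrepancies` (data.frame of
#'   non-exact cells).
#' @export
compare_tf_tables <- function(tf_table, printed, mode = "half-even") {
  key <- c("site_code", "year", "crop_type", "organ")
  m <- merge(tf_table, printed[, c(key, "tf_printed")], by = key)
  stopifnot(nrow(m) == nrow(tf_table))
  def <- m$defined
  r <- round_decimal(m$tf[def], 2, mode)
  diff <- round(abs(r - m$tf_printed[def]), 9)  # both sides are 2-decimal values
  disc <- m[def, ][r != m$tf_printed[def], , drop = FALSE]
  list(n_defined = sum(def),
       n_exact = sum(r == m$tf_printed[def]),
       max_abs_diff = max(diff),
       censoring_matches = identical(is.na(m$tf_printed), !m$defined),
       discrepancies = disc)
}
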