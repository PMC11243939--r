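# CSV interchange: comma separator, "." decimal mark, UTF-8, mandatory header.
# Censored values travel as a numeric bound plus a logical flag, never as "<x".

counting_record_cols <- c("site_code", "year", "medium", "crop_type", "organ",
                          "R", "R0", "tS", "t0", "t_sep_h", "eta_s", "m_kg",
                          "dR_rel", "d_eta_s_rel", "dm_rel")

soil_property_cols <- c("site_code", "coarse_sand", "fine_sand", "silt",
                        "clay", "texture_class", "hygroscopic_humidity",
                        "density", "pH_H2O", "pH_KCl", "CaCO3", "humus",
                        "total_OC", "OC_humic", "OC_fulvic")

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

check_nonneg <- function(df, cols, what, strict = character()) {
  for (cc in cols) {
    x <- df[[cc]]
    bad <- which(!is.na(x) & (x < 0 | (cc %in% strict & x <= 0)))
    if (length(bad))
      stop(sprintf("%s: invalid value in column '%s' at row %d (%g)",
                   what, cc, bad[1], x[bad[1]]), call. = FALSE)
  }
  invisible(df)
}

validate_counting_records <- function(records) {
  check_columns(records, counting_record_cols, "counting records")
  check_nonneg(records, c("R", "R0", "tS", "t0", "t_sep_h", "eta_s", "m_kg",
                          "dR_rel", "d_eta_s_rel", "dm_rel"),
               "counting records", strict = c("tS", "t0", "eta_s", "m_kg"))
  if (any(records$eta_s > 1))
    stop("counting records: chemical yield eta_s must not exceed 1",
         call. = FALSE)
  invisible(records)
}

validate_soil_properties <- function(props) {
  check_columns(props, soil_property_cols, "soil properties")
  mech <- c("coarse_sand", "fine_sand", "silt", "clay")
  check_nonneg(props, c(mech, "hygroscopic_humidity", "density", "CaCO3",
                        "humus", "total_OC", "OC_humic", "OC_fulvic"),
               "soil properties", strict = "density")
  if (any(unlist(props[mech]) > 100, na.rm = TRUE))
    stop("soil properties: mechanical fractions must lie in [0, 100]",
         call. = FALSE)
  s <- rowSums(props[mech])
  bad <- which(!is.na(s) & (s < 99 | s > 101))
  if (length(bad))
    stop(sprintf("soil properties: mechanical fractions of row %d sum to %g (need [99, 101])",
                 bad[1], s[bad[1]]), call. = FALSE)
  ph <- unlist(props[c("pH_H2O", "pH_KCl")])
  if (any(ph < 0 | ph > 14, na.rm = TRUE))
    stop("soil properties: pH outside [0, 14]", call. = FALSE)
  invisible(props)
}

read_campaign_csv <- function(path, cols, validate, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, cols, what)
  validate(df)
  df
}

#' Read and write counting-record tables
#'
#' The schema carries one gross-beta measurement per row: the sample key
#' (`site_code`, `year`, `medium`, `crop_type`, `organ`), count rates `R` and
#' `R0` (1/s), counting times `tS` and `t0` (s), the separation-to-counting
#' delay `t_sep_h` (h), the chemical yield `eta_s`, the dry mass `m_kg` (kg)
#' and the relative standard uncertainties `dR_rel`, `d_eta_s_rel`, `dm_rel`.
#' Validation failures name the offending column and row.
#'
#' @param path CSV file path.
#' @param records data.frame in the same schema.
#' @return `read_counting_records()` a validated data.frame;
#'   `write_counting_records()` the path, invisibly.
#' @export
read_counting_records <- function(path) {
  read_campaign_csv(path, counting_record_cols, validate_counting_records,
                    "counting records")
}

#' @rdname read_counting_records
#' @export
write_counting_records <- function(records, path) {
  validate_counting_records(records)
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write soil-property tables
#'
#' One row per plot: mechanical fractions (%), texture class, hygroscopic
#' humidity (%), density (g/cm3), pH in water and KCl, CaCO3 (%, may be
#' missing), humus (%) and the organic-carbon fractions (%).
#'
#' @param path CSV file path.
#' @param props data.frame in the soil-property schema.
#' @return a validated data.frame (read) or the path, invisibly (write).
#' @export
read_soil_properties <- function(path) {
  read_campaign_csv(path, soil_property_cols, validate_soil_properties,
                    "soil properties")
}

#' @rdname read_soil_properties
#' @export
write_soil_properties <- function(props, path) {
  validate_soil_properties(props)
  utils::write.csv(props, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write activity tables
#'
#' Activity results keyed by plot/year (and crop/organ for crop samples),
#' with the activity `A` (Bq/kg dry mass), its uncertainty columns when
#' present, and the `censored` flag; a censored row stores the reporting
#' bound in `A`.
#'
#' @param path CSV file path.
#' @param activities data.frame with at least `site_code`, `year`, `A` and
#'   `censored`.
#' @return a validated data.frame (read) or the path, invisibly (write).
#' @export
read_activities <- function(path) {
  act <- read_campaign_csv(path, c("site_code", "year", "A"),
                           function(df) {
                             check_nonneg(df, "A", "activities")
                             invisible(df)
                           }, "activities")
  if (is.null(act$censored)) act$censored <- FALSE
  act$censored <- as.logical(act$censored)
  act
}

#' @rdname read_activities
#' @export
write_activities <- function(activities, path) {
  check_columns(activities, c("site_code", "year", "A"), "activities")
  utils::write.csv(activities, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a result table in the printed-report layout
#'
#' Formats numeric cells at two decimals (decimal rounding, see
#' [round_decimal()]), renders censored activities as `"<bound"` and
#' undefined transfer factors as `"/"`, and writes a deterministic CSV.
#'
#' @param records non-empty data.frame of results.
#' @param style one of `"activity"` (needs `A`, optional `censored`),
#'   `"tf"` (needs `tf`, optional `defined`), `"agreement"` (needs
#'   `mean_ratio`), `"frequency"` (needs `rel_freq`).
#' @param path output CSV path.
#' @param mode tie-breaking rule passed to [format_decimal()].
#' @return `path`, invisibly.
#' @export
write_report_table <- function(records, style = c("activity", "tf",
                                                  "agreement", "frequency"),
                               path, mode = "half-even") {
  style <- match.arg(style)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("write_report_table: empty record set", call. = FALSE)
  out <- records
  fmt <- function(x) format_decimal(x, 2, mode)
  if (style == "activity") {
    check_columns(records, "A", "report table")
    cens <- if (is.null(records$censored)) rep(FALSE, nrow(records)) else records$censored
    out$A <- ifelse(cens, paste0("<", fmt(records$A)), fmt(records$A))
    if (!is.null(out$dA)) out$dA <- ifelse(cens, "", fmt(records$dA))
  } else if (style == "tf") {
    check_columns(records, "tf", "report table")
    def <- if (is.null(records$defined)) !is.na(records$tf) else records$defined
    out$tf <- ifelse(def, fmt(records$tf), "/")
  } else if (style == "agreement") {
    check_columns(records, "mean_ratio", "report table")
    out$mean_ratio <- fmt(records$mean_ratio)
  } else {
    check_columns(records, "rel_freq", "report table")
    out$rel_freq <- fmt(records$rel_freq)
  }
  key <- intersect(c("site_code", "year", "organ"), names(out))
  if (length(key))
    out <- out[do.call(order, unname(out[key])), , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
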