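# Packaged campaign fixtures: the printed three-year tables of the two
# experimental fields (16 plots), entered verbatim from the published report.

fixture_md5 <- c(
  soil_activity.csv            = "93b6ff7819c8319c460098681e1aaee2",
  crop_activity.csv            = "56664bd7402ecd9282049d8659bb2b6d",
  soil_properties.csv          = "f4c193ba82c0f6309967148545b27586",
  model_params.csv             = "3f501bb4716801ad00fd542d12cfdefc",
  tf_table_printed.csv         = "ee26f77e48884d0163760acc93d76a4a",
  model_agreement_printed.csv  = "7895864fa714577ea80af0f2f5cc13e2")

#' Load the packaged campaign fixtures
#'
#' Returns the published campaign bundle: plot-level soil Sr-90 activities
#' for 16 plots over 2013--2015, organ-level crop activities (including the
#' eight left-censored maize-grain cells), the plot soil physico-chemical
#' properties, the two fields' transfer-model parameter sets
#' (Kc, alpha_ex, CEC), and the printed transfer-factor and
#' model-vs-experiment tables kept as golden references for regression
#' comparison.  File integrity is verified by checksum before parsing.
#'
#' @param check_integrity verify the packaged files' md5 checksums
#'   (default `TRUE`).
#' @return list with elements `soil_activity`, `crop_activity`,
#'   `soil_properties`, `model_params`, `tf_printed`, `agreement_printed`.
#' @examples
#' fx <- load_campaign_fixtures()
#' subset(fx$soil_activity, site_code == "R1" & year == 2013)
#' @export
load_campaign_fixtures <- function(check_integrity = TRUE) {
  dir <- system.file("extdata", package = "radtransfer", mustWork = TRUE)
  files <- names(fixture_md5)
  paths <- file.path(dir, files)
  if (check_integrity) {
    got <- unname(tools::md5sum(paths))
    bad <- files[is.na(got) | got != unname(fixture_md5)]
    if (length(bad))
      stop("fixture integrity failure: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  fx <- list(
    soil_activity = read_activities(paths[1]),
    crop_activity = read_activities(paths[2]),
    soil_properties = read_soil_properties(paths[3]),
    model_params = utils::read.csv(paths[4], stringsAsFactors = FALSE),
    tf_printed = utils::read.csv(paths[5], stringsAsFactors = FALSE),
    agreement_printed = utils::read.csv(paths[6], stringsAsFactors = FALSE))
  stopifnot(nrow(fx$soil_activity) == 48,      # 16 plots x 3 years
            nrow(fx$crop_activity) == 138,
            sum(fx$crop_activity$censored) == 8,
            nrow(fx$soil_properties) == 16)
  fx
}

#' Field membership of a plot code
#'
#' Maps plot codes (`R1`--`R6`, `NS1`--`NS10`) to their experimental field.
#'
#' @param site_code character vector of plot codes.
#' @param params the `model_params` fixture (or a compatible table with
#'   `field` and `site_prefix`).
#' @return character vector of field names.
#' @export
site_field <- function(site_code, params = load_campaign_fixtures()$model_params) {
  prefix <- sub("[0-9]+$", "", site_code)
  params$field[match(prefix, params$site_prefix)]
}
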