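# Packaged deployment metadata for the 26-seal Kotzebue Sound cohort
# (2004-2006), used by the ingest tests and the fixture-path summaries.

# "5-Oct-04" style day-month-2-digit-year dates, years 2004-2007
parse_fixture_date <- function(x) {
  x[x %in% c("n/a", "", "NA")] <- NA
  months <- c(Jan = 1, Feb = 2, Mar = 3, Apr = 4, May = 5, Jun = 6,
              Jul = 7, Aug = 8, Sep = 9, Oct = 10, Nov = 11, Dec = 12)
  out <- as.Date(rep(NA_real_, length(x)))
  ok <- !is.na(x)
  if (any(ok)) {
    parts <- do.call(rbind, strsplit(x[ok], "-", fixed = TRUE))
    out[ok] <- as.Date(sprintf("%04d-%02d-%02d",
                               2000L + as.integer(parts[, 3]),
                               months[parts[, 2]],
                               as.integer(parts[, 1])))
  }
  out
}

#' Deployment metadata for the 26 tagged seals
#'
#' The packaged per-seal deployment table: SDR id and type, sex, body
#' measurements, capture date, Bering Sea entry date (NA when the seal
#' never entered before its tag stopped), last-location date, record
#' duration in days, days with a location, location-days in the Bering
#' Sea, and the habitat-analysis inclusion mark. Dates are parsed to ISO
#' `Date`s.
#'
#' @return A 26-row data frame.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_seals.csv", package = "sealrsf",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  data.frame(
    animal_id = raw$sdr_id,
    sdr_type = raw$sdr_type,
    sex = raw$sex,
    std_length_cm = as.numeric(raw$std_length_cm),
    girth_axillary_cm = as.numeric(raw$girth_axillary_cm),
    girth_max_cm = as.numeric(raw$girth_max_cm),
    date_captured = parse_fixture_date(raw$date_captured),
    date_entered_bering = parse_fixture_date(raw$date_entered_bering),
    date_last_location = parse_fixture_date(raw$date_last_location),
    duration_days = as.integer(raw$duration_days),
    days_with_location = as.integer(raw$days_with_location),
    bering_location_days = as.integer(raw$bering_location_days),
    used_in_habitat_analysis = raw$used_in_habitat_analysis == "X",
    stringsAsFactors = FALSE
  )
}

#' Reference final-model coefficients
#'
#' The packaged final habitat-selection model for the young bearded seal
#' Bering Sea cohort: per-term logit-scale estimates with Monte Carlo
#' standard errors, z values and printed p-values. Terms use the package's
#' canonical names (`sea_ice` is the open-water dummy). Useful as a known
#' coefficient set for selection curves and the quadratic
#' ice-concentration optimum.
#'
#' @return Data frame with columns `term`, `estimate`, `std_err`,
#'   `z_value`, `p_printed`.
#' @export
reference_final_model <- function() {
  path <- system.file("extdata", "reference_final_model.csv",
                      package = "sealrsf", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Cohort summary of the deployment metadata
#'
#' Applies the inclusion rule on the metadata path (a seal is included
#' when it has a Bering Sea entry date) and summarizes record durations.
#'
#' @param meta Metadata table (default [table1_fixture()]).
#' @return List: `n_seals`, `n_included`, `included_ids`, duration
#'   `mean`/`min`/`max`.
#' @export
table1_summary <- function(meta = table1_fixture()) {
  included <- !is.na(meta$date_entered_bering)
  list(
    n_seals = nrow(meta),
    n_included = sum(included),
    included_ids = meta$animal_id[included],
    duration_mean = mean(meta$duration_days),
    duration_min = min(meta$duration_days),
    duration_max = max(meta$duration_days)
  )
}
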