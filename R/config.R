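#' Analysis configuration
#'
#' Every threshold the rest-period and rest-quality pipeline uses lives here,
#' so the published defaults are defaults rather than constants.  Defaults
#' reflect the DMS patch analysis rules: a per-minute record counts as rest
#' when its posture angle is strictly less than 30 degrees from horizontal; a
#' 15-minute interval is analyzable when the patch was never pairing with the
#' phone during the interval, at least 10 accelerometer records and at least 2
#' ECG records were collected; an analyzable interval is REST when strictly
#' more than 70% of its collected accelerometer records are rest minutes.
#'
#' @param rest_angle_deg posture-angle threshold in degrees; a minute is rest
#'   when `theta < rest_angle_deg` (strict).
#' @param interval_minutes length of the non-overlapping analysis intervals.
#' @param rest_fraction fraction of rest minutes (of *collected* records)
#'   strictly above which an analyzable interval is REST.
#' @param min_accel_records minimum accelerometer records per analyzable
#'   interval.
#' @param min_ecg_records minimum ECG (mean heart rate) records per analyzable
#'   interval.
#' @param gap_search_intervals how many intervals outward from each end of the
#'   current rest period the extension step searches for further rest runs.
#' @param min_rescue_run minimum length (intervals) of a candidate rest run
#'   annexed across a gap containing exactly one ACTIVE interval.
#' @param rolling_window_minutes width of the rolling feature windows.
#' @param day_boundary_clock_time `"HH:MM"` local clock time at which one
#'   patient-day ends and the next begins.  Noon by default so a night of
#'   sleep is never split at midnight.
#' @param outlier_z z-score magnitude strictly above which a day is an
#'   outlier.
#' @param outlier_lag_days maximum day separation for a rest/ingestion
#'   outlier coincidence.
#' @param kmeans_restarts number of random restarts for the k-means fit.
#' @param rng_seed seed used for the k-means restarts (and anywhere else the
#'   pipeline draws random numbers), making fits reproducible.
#' @param two_active_blocks if `TRUE` (default) a gap containing two or more
#'   ACTIVE intervals blocks annexation at that end of the rest period.
#' @param single_pass_extension if `TRUE` each end of the rest period is
#'   extended at most once instead of iterating to a fixed point; provided
#'   for sensitivity analysis.
#' @param feature_sd_ddof degrees-of-freedom correction for the rolling-window
#'   standard-deviation features (0 = population SD over the 3 minutes).
#' @param score_sd_ddof degrees-of-freedom correction for the per-day z-score
#'   SDs (1 = sample SD).
#' @param fit_scope `"lrp"` fits the k-means rest-reference model on the
#'   3-minute windows inside the patient's longest rest periods (default);
#'   `"all"` fits on windows from every analyzable interval, day and night.
#' @param single_day_outliers if `TRUE` an outlier day only counts when its
#'   calendar neighbours are not themselves outliers.
#' @param robust_outliers if `TRUE` (default) outlier detection standardizes
#'   the composite and ingestion-time series robustly (median/MAD) before
#'   applying `outlier_z`; `FALSE` thresholds the raw composite and the
#'   classical ingestion z-score instead (see [outlier_coincidences()]).
#' @param min_patch_days minimum number of distinct calendar days with patch
#'   data for a patient to be eligible.
#'
#' @return an object of class `rest_config` (a validated named list).
#' @examples
#' cfg <- rest_config()
#' cfg$rest_angle_deg
#' rest_config(rest_fraction = 0.6)$rest_fraction
#' @export
rest_config <- function(rest_angle_deg = 30,
                        interval_minutes = 15,
                        rest_fraction = 0.70,
                        min_accel_records = 10,
                        min_ecg_records = 2,
                        gap_search_intervals = 5,
                        min_rescue_run = 4,
                        rolling_window_minutes = 3,
                        day_boundary_clock_time = "12:00",
                        outlier_z = 2.0,
                        outlier_lag_days = 1,
                        kmeans_restarts = 25,
                        rng_seed = 1,
                        two_active_blocks = TRUE,
                        single_pass_extension = FALSE,
                        feature_sd_ddof = 0,
                        score_sd_ddof = 1,
                        fit_scope = c("lrp", "all"),
                        single_day_outliers = TRUE,
                        robust_outliers = TRUE,
                        min_patch_days = 7) {
  cfg <- list(
    rest_angle_deg = as.numeric(rest_angle_deg),
    interval_minutes = as.integer(interval_minutes),
    rest_fraction = as.numeric(rest_fraction),
    min_accel_records = as.integer(min_accel_records),
    min_ecg_records = as.integer(min_ecg_records),
    gap_search_intervals = as.integer(gap_search_intervals),
    min_rescue_run = as.integer(min_rescue_run),
    rolling_window_minutes = as.integer(rolling_window_minutes),
    day_boundary_clock_time = as.character(day_boundary_clock_time),
    outlier_z = as.numeric(outlier_z),
    outlier_lag_days = as.integer(outlier_lag_days),
    kmeans_restarts = as.integer(kmeans_restarts),
    rng_seed = as.integer(rng_seed),
    two_active_blocks = isTRUE(two_active_blocks),
    single_pass_extension = isTRUE(single_pass_extension),
    feature_sd_ddof = as.integer(feature_sd_ddof),
    score_sd_ddof = as.integer(score_sd_ddof),
    fit_scope = match.arg(fit_scope),
    single_day_outliers = isTRUE(single_day_outliers),
    robust_outliers = isTRUE(robust_outliers),
    min_patch_days = as.integer(min_patch_days)
  )
  validate_rest_config(cfg)
  structure(cfg, class = "rest_config")
}

validate_rest_config <- function(cfg) {
  pos <- c("rest_angle_deg", "interval_minutes", "min_accel_records",
           "min_ecg_records", "gap_search_intervals", "min_rescue_run",
           "rolling_window_minutes", "outlier_z", "kmeans_restarts",
           "min_patch_days")
  for (nm in pos) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("config field '", nm, "' must be positive", call. = FALSE)
    }
  }
  if (cfg$rest_fraction <= 0 || cfg$rest_fraction >= 1) {
    stop("rest_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$outlier_lag_days < 0) stop("outlier_lag_days must be >= 0", call. = FALSE)
  if (cfg$rolling_window_minutes > cfg$interval_minutes) {
    stop("rolling window cannot exceed the interval length", call. = FALSE)
  }
  bm <- parse_clock_minutes(cfg$day_boundary_clock_time)
  if (bm < 0 || bm >= 1440) stop("day boundary must be a clock time", call. = FALSE)
  invisible(cfg)
}

#' @export
print.rest_config <- function(x, ...) {
  cat("<rest_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# minutes after midnight at which a patient-day starts
day_boundary_minutes <- function(cfg) parse_clock_minutes(cfg$day_boundary_clock_time)

#' Read / write a configuration as JSON
#'
#' `config.json` mirrors [rest_config()]; fields absent from the file keep
#' their defaults.
#'
#' @param path file path.
#' @param cfg a `rest_config` object.
#' @return `read_rest_config()` returns a `rest_config`;
#'   `write_rest_config()` returns `path` invisibly.
#' @export
read_rest_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(rest_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    warning("ignoring unknown config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(rest_config, raw[intersect(names(raw), known)])
}

#' @rdname read_rest_config
#' @export
write_rest_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "rest_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# hex stamp identifying a configuration; recorded in every output file set
config_hash <- function(cfg) {
  fnv1a_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}
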