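# Data model and CSV I/O for DMS patch streams.
#
# A patient stream bundles the four channels the patch produces:
#   accel       one row per minute: steps, mean a_x/a_y/a_z (g), posture angle
#   hr          one row per 5 minutes: mean heart rate (bpm)
#   pairing     spans during which the patch was pairing with the phone app
#   ingestions  time-stamped medication ingestion events

#' Construct a validated patient stream
#'
#' Sorts every channel by time, canonicalizes (or derives) the posture angle,
#' and collapses multiple ingestion events on one calendar day to the
#' earliest — ingestion analyses count days, and the regimen is once daily.
#'
#' @param patient_id opaque identifier.
#' @param accel data.frame with columns `timestamp` (POSIXct or ISO 8601
#'   character), `steps`, `ax`, `ay`, `az` and optionally `theta_deg` in
#'   degrees (0 = lying/horizontal); derived from the acceleration vector
#'   when absent.
#' @param hr data.frame with `timestamp`, `mean_hr` (bpm, must be positive).
#' @param pairing data.frame with `start`, `end` instants, `start < end`.
#' @param ingestions data.frame with a `timestamp` column.
#' @return an object of class `patient_stream`.
#' @examples
#' acc <- data.frame(
#'   timestamp = c("2024-01-01T22:00:00", "2024-01-01T22:01:00"),
#'   steps = 0, ax = 0, ay = 0, az = 1
#' )
#' ps <- patient_stream("p1", acc)
#' ps$accel$theta
#' @export
patient_stream <- function(patient_id, accel,
                           hr = empty_hr(), pairing = empty_pairing(),
                           ingestions = empty_ingestions()) {
  accel <- validate_accel(accel)
  hr <- validate_hr(hr)
  pairing <- validate_pairing(pairing)
  ingestions <- validate_ingestions(ingestions)
  structure(
    list(patient_id = as.character(patient_id), accel = accel, hr = hr,
         pairing = pairing, ingestions = ingestions),
    class = "patient_stream"
  )
}

empty_hr <- function() data.frame(timestamp = as.POSIXct(character(), tz = AR_TZ),
                                  mean_hr = numeric())
empty_pairing <- function() data.frame(start = as.POSIXct(character(), tz = AR_TZ),
                                       end = as.POSIXct(character(), tz = AR_TZ))
empty_ingestions <- function() data.frame(timestamp = as.POSIXct(character(), tz = AR_TZ))

as_instant_col <- function(x) {
  if (inherits(x, "POSIXct")) as.POSIXct(format(x, tz = AR_TZ), tz = AR_TZ) else parse_instant(x)
}

validate_accel <- function(accel) {
  req <- c("timestamp", "steps", "ax", "ay", "az")
  missing_cols <- setdiff(req, names(accel))
  if (length(missing_cols)) {
    stop("accelerometer table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  accel$timestamp <- as_instant_col(accel$timestamp)
  bad <- is.na(accel$timestamp)
  if (any(bad)) {
    warning(sum(bad), " accelerometer row(s) with unparseable timestamps dropped")
    accel <- accel[!bad, , drop = FALSE]
  }
  accel <- accel[order(accel$timestamp), , drop = FALSE]
  if (anyDuplicated(accel$timestamp)) {
    warning("duplicate accelerometer timestamps collapsed to the first record")
    accel <- accel[!duplicated(accel$timestamp), , drop = FALSE]
  }
  if (is.null(accel$theta_deg) || all(is.na(accel$theta_deg))) {
    accel$theta <- derive_theta(accel$ax, accel$ay, accel$az)
  } else {
    accel$theta <- canonicalize_theta(as.numeric(accel$theta_deg))
    # fill occasional missing angles from the acceleration vector
    na <- is.na(accel$theta)
    if (any(na)) accel$theta[na] <- derive_theta(accel$ax[na], accel$ay[na], accel$az[na])
  }
  accel$steps <- pmax(0, as.numeric(accel$steps))
  rownames(accel) <- NULL
  accel[c("timestamp", "steps", "ax", "ay", "az", "theta")]
}

validate_hr <- function(hr) {
  if (is.null(hr) || !nrow(hr)) return(empty_hr())
  if (!all(c("timestamp", "mean_hr") %in% names(hr))) {
    stop("heart-rate table must have columns timestamp, mean_hr", call. = FALSE)
  }
  hr$timestamp <- as_instant_col(hr$timestamp)
  hr <- hr[!is.na(hr$timestamp) & hr$mean_hr > 0, c("timestamp", "mean_hr"), drop = FALSE]
  hr <- hr[order(hr$timestamp), , drop = FALSE]
  rownames(hr) <- NULL
  hr
}

validate_pairing <- function(pairing) {
  if (is.null(pairing) || !nrow(pairing)) return(empty_pairing())
  if (!all(c("start", "end") %in% names(pairing))) {
    stop("pairing table must have columns start, end", call. = FALSE)
  }
  pairing$start <- as_instant_col(pairing$start)
  pairing$end <- as_instant_col(pairing$end)
  ok <- !is.na(pairing$start) & !is.na(pairing$end) & pairing$start < pairing$end
  if (!all(ok)) warning(sum(!ok), " invalid pairing span(s) dropped")
  pairing <- pairing[ok, c("start", "end"), drop = FALSE]
  pairing <- pairing[order(pairing$start), , drop = FALSE]
  rownames(pairing) <- NULL
  pairing
}

validate_ingestions <- function(ingestions) {
  if (is.null(ingestions) || !nrow(ingestions)) return(empty_ingestions())
  if (!"timestamp" %in% names(ingestions)) {
    stop("ingestion table must have a timestamp column", call. = FALSE)
  }
  ts <- as_instant_col(ingestions$timestamp)
  ts <- sort(ts[!is.na(ts)])
  day <- as.Date(ts, tz = AR_TZ)
  ts <- ts[!duplicated(day)]  # earliest event per calendar day counts
  out <- data.frame(timestamp = ts)
  rownames(out) <- NULL
  out
}

#' @export
print.patient_stream <- function(x, ...) {
  nd <- n_patch_days(x)
  cat(sprintf("<patient_stream> %s: %d accel min over %d day(s), %d HR, %d pairing span(s), %d ingestion day(s)\n",
              x$patient_id, nrow(x$accel), nd, nrow(x$hr), nrow(x$pairing),
              nrow(x$ingestions)))
  invisible(x)
}

#' Number of distinct calendar days with patch data
#'
#' @param stream a `patient_stream`.
#' @return integer count of distinct calendar days with at least one
#'   accelerometer record.
#' @export
n_patch_days <- function(stream) {
  length(unique(as.Date(stream$accel$timestamp, tz = AR_TZ)))
}

#' Is a stream eligible for metric computation?
#'
#' Patients with fewer than `cfg$min_patch_days` distinct days of patch data
#' (7 by default) are excluded from cohort metrics, mirroring the clinical
#' eligibility rule.
#'
#' @param stream a `patient_stream`.
#' @param cfg a [rest_config()].
#' @return logical scalar.
#' @export
is_eligible <- function(stream, cfg = rest_config()) {
  n_patch_days(stream) >= cfg$min_patch_days
}

#' Read a patient stream from CSV files
#'
#' File dialects (ISO 8601 timestamps throughout):
#' * `accel.csv`: `timestamp,steps,ax,ay,az,theta_deg` (`theta_deg` optional);
#' * `hr.csv`: `timestamp,mean_hr`;
#' * `pairing.csv`: `start,end`;
#' * `ingestions.csv`: `timestamp`.
#'
#' Rows with unparseable timestamps are dropped with a warning; a missing or
#' `NULL` path for the optional channels yields an empty channel.
#'
#' @param accel_path path to the accelerometer CSV (required, must be
#'   non-empty).
#' @param hr_path,pairing_path,ingestion_path optional channel CSVs.
#' @param patient_id identifier; defaults to the accel file's directory name.
#' @return a validated [patient_stream()].
#' @export
read_patient_stream <- function(accel_path, hr_path = NULL, pairing_path = NULL,
                                ingestion_path = NULL, patient_id = NULL) {
  if (!file.exists(accel_path)) stop("no such file: ", accel_path, call. = FALSE)
  accel <- utils::read.csv(accel_path, stringsAsFactors = FALSE)
  if (!nrow(accel)) stop("accelerometer file is empty: ", accel_path, call. = FALSE)
  read_opt <- function(path) {
    if (is.null(path) || !file.exists(path)) return(NULL)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (is.null(patient_id)) patient_id <- basename(dirname(normalizePath(accel_path)))
  patient_stream(
    patient_id, accel,
    hr = read_opt(hr_path) %||% empty_hr(),
    pairing = read_opt(pairing_path) %||% empty_pairing(),
    ingestions = read_opt(ingestion_path) %||% empty_ingestions()
  )
}

# fixed output column order; consumers rely on it
DAILY_SCORES_COLS <- c("patient_id", "day", "lrp_start", "lrp_duration_min",
                       "lrp_quality", "quality_z", "start_z", "duration_z",
                       "composite_z", "ingestion_time_min", "ingestion_z")

#' Write / read the per-day score table
#'
#' One row per patient-day in chronological order, empty fields where a day
#' has no rest period or no ingestion.  Values round-trip through the file to
#' at least 1e-9 relative precision.
#'
#' @param scores data.frame with the columns listed in Details (as produced
#'   by [analyze_patient()]'s `daily` element).
#' @param path output path.
#' @return `write_daily_scores()` returns `path` invisibly;
#'   `read_daily_scores()` returns the parsed data.frame.
#' @export
write_daily_scores <- function(scores, path) {
  if (is.null(scores) || !nrow(scores)) {
    out <- as.data.frame(stats::setNames(rep(list(character()), length(DAILY_SCORES_COLS)),
                                         DAILY_SCORES_COLS))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    return(invisible(path))
  }
  missing_cols <- setdiff(DAILY_SCORES_COLS, names(scores))
  if (length(missing_cols)) {
    stop("scores table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- scores[order(scores$patient_id, scores$day), DAILY_SCORES_COLS]
  out$day <- as.character(out$day)
  out$lrp_start <- ifelse(is.na(out$lrp_start), "", format_instant(out$lrp_start))
  num_cols <- setdiff(DAILY_SCORES_COLS, c("patient_id", "day", "lrp_start"))
  for (nm in num_cols) out[[nm]] <- ifelse(is.na(out[[nm]]), "",
                                           sprintf("%.12g", out[[nm]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_daily_scores
#' @export
read_daily_scores <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  out <- raw
  out$day <- as.Date(raw$day)
  out$lrp_start <- parse_instant(raw$lrp_start)
  num_cols <- setdiff(DAILY_SCORES_COLS, c("patient_id", "day", "lrp_start"))
  for (nm in num_cols) out[[nm]] <- as.numeric(raw[[nm]])
  out
}

#' Write a patient stream to the four channel CSVs
#'
#' Inverse of [read_patient_stream()]; used by the simulator and the
#' `simulate` CLI subcommand.
#'
#' @param stream a `patient_stream`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_patient_stream <- function(stream, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  acc <- stream$accel
  out <- data.frame(timestamp = format_instant(acc$timestamp),
                    steps = acc$steps,
                    ax = sprintf("%.12g", acc$ax), ay = sprintf("%.12g", acc$ay),
                    az = sprintf("%.12g", acc$az),
                    theta_deg = sprintf("%.12g", acc$theta))
  utils::write.csv(out, file.path(dir, "accel.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(timestamp = format_instant(stream$hr$timestamp),
               mean_hr = sprintf("%.12g", stream$hr$mean_hr)),
    file.path(dir, "hr.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(start = format_instant(stream$pairing$start),
               end = format_instant(stream$pairing$end)),
    file.path(dir, "pairing.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(timestamp = format_instant(stream$ingestions$timestamp)),
    file.path(dir, "ingestions.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
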