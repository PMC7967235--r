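# Partition patient-days into 15-minute intervals and label each one
# REST, ACTIVE, or MISSING.
#
# A day runs from the configured boundary clock time (noon by default) to the
# same clock time next day, so a night of sleep stays within one day.  Each
# day is cut into non-overlapping intervals of `interval_minutes`; interval
# membership is half-open [start, end).  An interval is analyzable only when
# the patch was never pairing during it, it holds >= min_accel_records
# accelerometer records and >= min_ecg_records heart-rate records; otherwise
# it is MISSING.  Analyzable intervals are REST when strictly more than
# rest_fraction of their collected records are rest minutes, else ACTIVE.

STATE_LEVELS <- c("REST", "ACTIVE", "MISSING")

#' Is a per-minute record a rest minute?
#'
#' A minute is rest when its canonical posture angle is strictly less than
#' `rest_angle_deg` away from horizontal (0 = lying).
#'
#' @param theta posture angle(s) in degrees, canonicalized to `[0, 180]`.
#' @param cfg a [rest_config()].
#' @return logical vector.
#' @examples
#' minute_is_rest(c(0, 29.99, 30, 90))
#' @export
minute_is_rest <- function(theta, cfg = rest_config()) {
  theta < cfg$rest_angle_deg
}

#' Is a 15-minute interval analyzable?
#'
#' All three data-quality conditions must hold: no pairing overlap at any
#' point of the interval, at least `min_accel_records` accelerometer records,
#' and at least `min_ecg_records` ECG records.
#'
#' @param n_accel,n_ecg record counts inside the interval.
#' @param pairing_overlap logical, any non-zero intersection of a pairing
#'   span with the interval.
#' @param cfg a [rest_config()].
#' @return logical vector.
#' @export
is_analyzable <- function(n_accel, n_ecg, pairing_overlap, cfg = rest_config()) {
  !pairing_overlap & n_accel >= cfg$min_accel_records & n_ecg >= cfg$min_ecg_records
}

#' Classify an interval from its counts and rest fraction
#'
#' @param n_accel,n_ecg,pairing_overlap analyzability inputs
#'   (see [is_analyzable()]).
#' @param n_rest number of rest minutes among the collected records.
#' @param cfg a [rest_config()].
#' @return character vector over `REST`, `ACTIVE`, `MISSING`.  The rest
#'   fraction denominator is the number of *collected* records, not the
#'   nominal interval length.
#' @export
classify_interval <- function(n_accel, n_ecg, pairing_overlap, n_rest,
                              cfg = rest_config()) {
  analyzable <- is_analyzable(n_accel, n_ecg, pairing_overlap, cfg)
  frac <- ifelse(n_accel > 0, n_rest / n_accel, 0)
  ifelse(!analyzable, "MISSING",
         ifelse(frac > cfg$rest_fraction, "REST", "ACTIVE"))
}

#' Day windows covering a patient stream
#'
#' @param stream a `patient_stream` with at least one accelerometer record.
#' @param cfg a [rest_config()].
#' @return data.frame with `day_id` (the calendar date on which the window
#'   starts), `start`, `end` (POSIXct); windows tile the accel record span.
#' @export
day_windows <- function(stream, cfg = rest_config()) {
  if (!nrow(stream$accel)) {
    return(data.frame(day_id = as.Date(character()),
                      start = as.POSIXct(character(), tz = AR_TZ),
                      end = as.POSIXct(character(), tz = AR_TZ)))
  }
  bmin <- day_boundary_minutes(cfg)
  ts_min <- min(stream$accel$timestamp)
  ts_max <- max(stream$accel$timestamp)
  d0 <- as.Date(ts_min, tz = AR_TZ)
  first <- as.POSIXct(as.character(d0), tz = AR_TZ) + bmin * 60
  if (first > ts_min) first <- first - 86400
  starts <- seq(first, ts_max, by = 86400)
  data.frame(day_id = as.Date(starts, tz = AR_TZ),
             start = starts, end = starts + 86400)
}

#' Partition one day window into intervals
#'
#' Cuts `[day_start, day_end)` into intervals of `interval_minutes` and
#' assigns each accelerometer / heart-rate record to the interval containing
#' its timestamp (half-open convention: a record exactly on a boundary
#' belongs to the interval it starts).
#'
#' @param stream a `patient_stream`.
#' @param day_start,day_end window bounds; the window length must be a
#'   multiple of `interval_minutes`.
#' @param cfg a [rest_config()].
#' @return a `day_grid`: list with `day_id`, `start` (interval starts),
#'   `n_accel`, `n_ecg`, `pairing_overlap`, `n_rest`, `rest_fraction`,
#'   `state`, and `accel_idx` (list of row indices into `stream$accel`).
#' @export
partition_day <- function(stream, day_start, day_end, cfg = rest_config()) {
  len_min <- as.numeric(difftime(day_end, day_start, units = "mins"))
  if (len_min <= 0 || len_min %% cfg$interval_minutes != 0) {
    stop("day window must be a positive multiple of interval_minutes", call. = FALSE)
  }
  n_iv <- as.integer(len_min / cfg$interval_minutes)
  iv_start <- day_start + (seq_len(n_iv) - 1L) * cfg$interval_minutes * 60
  breaks <- c(iv_start, day_end)

  in_day <- which(stream$accel$timestamp >= day_start & stream$accel$timestamp < day_end)
  bin <- findInterval(as.numeric(stream$accel$timestamp[in_day]), as.numeric(breaks))
  accel_idx <- unname(split(in_day, factor(bin, levels = seq_len(n_iv))))
  n_accel <- lengths(accel_idx)

  hr_ts <- stream$hr$timestamp
  hr_in <- hr_ts[hr_ts >= day_start & hr_ts < day_end]
  n_ecg <- tabulate(findInterval(as.numeric(hr_in), as.numeric(breaks)), nbins = n_iv)

  pairing_overlap <- rep(FALSE, n_iv)
  if (nrow(stream$pairing)) {
    for (k in seq_len(nrow(stream$pairing))) {
      ps <- stream$pairing$start[k]; pe <- stream$pairing$end[k]
      ov <- iv_start < pe & (iv_start + cfg$interval_minutes * 60) > ps
      pairing_overlap <- pairing_overlap | ov
    }
  }

  rest_min <- minute_is_rest(stream$accel$theta, cfg)
  n_rest <- vapply(accel_idx, function(ii) sum(rest_min[ii]), integer(1))
  state <- classify_interval(n_accel, n_ecg, pairing_overlap, n_rest, cfg)
  structure(
    list(day_id = as.Date(day_start, tz = AR_TZ),
         day_start = day_start,
         start = iv_start,
         n_accel = as.integer(n_accel),
         n_ecg = as.integer(n_ecg),
         pairing_overlap = pairing_overlap,
         n_rest = as.integer(n_rest),
         rest_fraction = ifelse(n_accel > 0, n_rest / n_accel, NA_real_),
         state = state,
         accel_idx = accel_idx),
    class = "day_grid"
  )
}

#' Classify every interval of every day of a stream
#'
#' @param stream a `patient_stream`.
#' @param cfg a [rest_config()].
#' @return list of `day_grid` objects, one per day window (see
#'   [day_windows()]), named by `day_id`.
#' @export
classify_intervals <- function(stream, cfg = rest_config()) {
  dw <- day_windows(stream, cfg)
  grids <- lapply(seq_len(nrow(dw)), function(i) {
    partition_day(stream, dw$start[i], dw$end[i], cfg)
  })
  names(grids) <- as.character(dw$day_id)
  grids
}

#' Flatten day grids into an interval table
#'
#' One row per interval: `day,interval,interval_start,state,n_accel,n_ecg,`
#' `rest_fraction`.  Feeds the state-raster plot and the interval dump CSV.
#'
#' @param grids list of `day_grid` objects from [classify_intervals()].
#' @return data.frame.
#' @export
interval_table <- function(grids) {
  do.call(rbind, lapply(grids, function(g) {
    data.frame(day = g$day_id, interval = seq_along(g$state),
               interval_start = g$start, state = g$state,
               n_accel = g$n_accel, n_ecg = g$n_ecg,
               rest_fraction = g$rest_fraction, row.names = NULL)
  }))
}
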