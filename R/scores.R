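# Daily z-scores, the composite rest score, and ingestion metrics.
#
# For each patient, the LRP quality, start time (minutes from the day-window
# start) and duration are standardized against that patient's own mean and
# SD across days.  The composite rest score for a day is
# |quality z| + |start z| + |duration z|: the combined magnitude of deviation
# from the patient's typical rest pattern.  Ingestion behaviour is summarized
# by the observed ingestion rate (days with a recorded dose over the regimen
# span) and by a z-score of daily ingestion clock time; single-day outliers
# in the composite rest score are matched against single-day outliers in
# ingestion time within a +/- 1-day lag.

#' Standardize a per-day series
#'
#' `z = (x - mean) / SD` over the non-missing days, sample SD by default
#' (`ddof = 1`).  A constant series yields all-zero z-scores with a warning;
#' fewer than two non-missing days yields all-`NA`.
#'
#' @param values numeric vector (may contain `NA` for missing days).
#' @param ddof degrees-of-freedom correction for the SD.
#' @return numeric vector of z-scores, `NA` where `values` is `NA`.
#' @examples
#' zscore_series(c(10, 20, 30))
#' @export
zscore_series <- function(values, ddof = 1L) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) {
    warning("fewer than 2 non-missing days: no z-scores")
    return(rep(NA_real_, length(values)))
  }
  s <- sd_ddof(values[ok], ddof)
  if (!is.finite(s) || s == 0) {
    warning("constant series: z-scores set to 0")
    z <- ifelse(ok, 0, NA_real_)
    return(z)
  }
  (values - mean(values[ok])) / s
}

#' Composite rest score
#'
#' Sum of the absolute quality, start-time and duration z-scores; `NA` when
#' any component is missing for the day.
#'
#' @param quality_z,start_z,duration_z per-day z-score vectors.
#' @return non-negative numeric vector.
#' @export
composite_rest <- function(quality_z, start_z, duration_z) {
  abs(quality_z) + abs(start_z) + abs(duration_z)
}

#' Observed ingestion rate
#'
#' Number of calendar days with a recorded ingestion divided by the regimen
#' span: first day with patch data through last day with an ingestion record,
#' inclusive (once-daily regimen assumed).
#'
#' @param stream a `patient_stream`.
#' @return list with `rate`, `n_ingestion_days`, `span_days`, `span_start`,
#'   `span_end`.  With no ingestion events the rate is 0 over the patch-data
#'   span (flagged with a warning).
#' @export
ingestion_rate <- function(stream) {
  if (!nrow(stream$accel)) stop("stream has no patch data", call. = FALSE)
  patch_days <- as.Date(stream$accel$timestamp, tz = AR_TZ)
  first_day <- min(patch_days)
  if (!nrow(stream$ingestions)) {
    warning("no ingestion events: rate 0 over the patch-data span")
    last_day <- max(patch_days)
    span <- as.integer(last_day - first_day) + 1L
    return(list(rate = 0, n_ingestion_days = 0L, span_days = span,
                span_start = first_day, span_end = last_day))
  }
  ing_days <- unique(as.Date(stream$ingestions$timestamp, tz = AR_TZ))
  last_ing <- max(ing_days)
  span <- as.integer(last_ing - first_day) + 1L
  if (span < 1L) {
    warning("all ingestions precede the first patch-data day")
    span <- 1L
  }
  list(rate = length(ing_days) / span,
       n_ingestion_days = length(ing_days),
       span_days = span, span_start = first_day, span_end = last_ing)
}

#' Daily ingestion times and their z-scores
#'
#' Ingestion clock time in minutes after midnight (one counted event per
#' calendar day), standardized with [zscore_series()] across the patient's
#' ingestion days.
#'
#' @param stream a `patient_stream`.
#' @param ddof SD degrees-of-freedom correction.
#' @return data.frame with `day` (Date), `ingestion_time_min`, `ingestion_z`;
#'   zero rows when there are no ingestions, all-`NA` z with fewer than two
#'   ingestion days.
#' @export
ingestion_time_z <- function(stream, ddof = 1L) {
  ing <- stream$ingestions
  if (!nrow(ing)) {
    return(data.frame(day = as.Date(character()), ingestion_time_min = numeric(),
                      ingestion_z = numeric()))
  }
  day <- as.Date(ing$timestamp, tz = AR_TZ)
  mins <- as.numeric(difftime(ing$timestamp,
                              as.POSIXct(as.character(day), tz = AR_TZ),
                              units = "mins"))
  z <- if (length(mins) >= 2L) zscore_series(mins, ddof) else rep(NA_real_, length(mins))
  data.frame(day = day, ingestion_time_min = mins, ingestion_z = z)
}

# Robust standardization for outlier *detection*: (x - median) / (1.4826 *
# MAD).  Mean/SD thresholds self-mask in contaminated series (the outliers
# sought inflate the SD); the modified z-score does not.  Falls back to
# mean/SD when the MAD degenerates to 0.
robust_z <- function(x) {
  med <- stats::median(x, na.rm = TRUE)
  s <- stats::mad(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - med) / s
}

# single-day outlier flags: value beyond the threshold while neither calendar
# neighbour is (absent neighbours count as non-outliers)
single_day_outliers <- function(days, flag, strict = TRUE) {
  if (!strict) return(flag)
  flag[is.na(flag)] <- FALSE
  prev <- flag[match(days - 1L, days)]
  nxt <- flag[match(days + 1L, days)]
  prev[is.na(prev)] <- FALSE
  nxt[is.na(nxt)] <- FALSE
  flag & !prev & !nxt
}

#' Rest / ingestion outlier coincidences
#'
#' Finds all pairs of a single-day composite rest outlier and a single-day
#' ingestion-time outlier at most `outlier_lag_days` calendar days apart.
#' With `cfg$single_day_outliers` a day only counts as an outlier when its
#' calendar neighbours are not outliers themselves.
#'
#' With the default `robust_outliers = TRUE`, a day is an outlier when its
#' robust (median/MAD) standardized value exceeds `outlier_z` — one-sided
#' for the non-negative composite, two-sided for ingestion time.  The
#' classical alternative (`robust_outliers = FALSE`) thresholds the raw
#' composite and the mean/SD ingestion z directly; it self-masks in series
#' that contain the very excursions being searched for, because those
#' excursions inflate the SD (and the composite's null level, a sum of three
#' absolute z-scores, already sits near 2).
#'
#' @param composite data.frame with `day` (Date) and `composite_z`.
#' @param ingestion data.frame with `day` (Date) and `ingestion_z` (e.g. from
#'   [ingestion_time_z()]).
#' @param cfg a [rest_config()].
#' @return data.frame `rest_day`, `ingestion_day`, `composite_z`,
#'   `ingestion_z` (the reported classical values); zero rows when there is
#'   no coincidence.
#' @export
outlier_coincidences <- function(composite, ingestion, cfg = rest_config()) {
  empty <- data.frame(rest_day = as.Date(character()),
                      ingestion_day = as.Date(character()),
                      composite_z = numeric(), ingestion_z = numeric())
  if (!nrow(composite) || !nrow(ingestion)) return(empty)
  if (cfg$robust_outliers) {
    r_val <- robust_z(composite$composite_z)
    i_val <- robust_z(ingestion$ingestion_z)
  } else {
    r_val <- composite$composite_z
    i_val <- ingestion$ingestion_z
  }
  r_flag <- !is.na(r_val) & r_val > cfg$outlier_z
  r_flag <- single_day_outliers(composite$day, r_flag, cfg$single_day_outliers)
  i_flag <- !is.na(i_val) & abs(i_val) > cfg$outlier_z
  i_flag <- single_day_outliers(ingestion$day, i_flag, cfg$single_day_outliers)
  rd <- composite$day[r_flag]
  id <- ingestion$day[i_flag]
  if (!length(rd) || !length(id)) return(empty)
  pairs <- expand.grid(r = seq_along(rd), i = seq_along(id))
  keep <- abs(as.integer(rd[pairs$r] - id[pairs$i])) <= cfg$outlier_lag_days
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  out <- data.frame(
    rest_day = rd[pairs$r],
    ingestion_day = id[pairs$i],
    composite_z = composite$composite_z[r_flag][pairs$r],
    ingestion_z = ingestion$ingestion_z[i_flag][pairs$i]
  )
  out[order(out$rest_day, out$ingestion_day), , drop = FALSE]
}

#' Analyze one patient end to end
#'
#' Runs interval classification, daily LRP detection, the cluster-based
#' quality metric, per-day z-scores, the composite rest score, ingestion
#' metrics and outlier-coincidence matching for a single stream.
#'
#' @param stream a `patient_stream`.
#' @param cfg a [rest_config()].
#' @param check_eligibility error when the stream has fewer than
#'   `cfg$min_patch_days` distinct days of patch data (default `TRUE`).
#' @return object of class `rest_analysis`: list with
#'   * `daily` — one row per day from the first to the last observed day,
#'     with the `daily_scores.csv` columns;
#'   * `grids`, `lrps`, `quality` (see the stage functions);
#'   * `model` — the patient's `rest_cluster_model`;
#'   * `ingestion` — output of [ingestion_rate()];
#'   * `coincidences` — output of [outlier_coincidences()];
#'   * `summary` — one-row data.frame
#'     (`patient_id,n_patch_days,ingestion_rate,mean_composite,n_coincidences`).
#' @export
analyze_patient <- function(stream, cfg = rest_config(), check_eligibility = TRUE) {
  stopifnot(inherits(stream, "patient_stream"))
  if (check_eligibility && !is_eligible(stream, cfg)) {
    stop("patient ", stream$patient_id, " has fewer than ", cfg$min_patch_days,
         " days of patch data", call. = FALSE)
  }
  grids <- classify_intervals(stream, cfg)
  lrps <- daily_lrps(grids, cfg)
  qual <- score_quality(stream, grids, lrps, cfg)

  lrps2 <- merge(lrps, qual$daily, by = "day", all.x = TRUE)
  ddof <- cfg$score_sd_ddof
  quality_z <- zscore_series(lrps2$lrp_quality, ddof)
  start_z <- zscore_series(lrps2$start_min, ddof)
  duration_z <- zscore_series(lrps2$duration_min, ddof)
  comp <- composite_rest(quality_z, start_z, duration_z)

  ing <- ingestion_time_z(stream, ddof)
  rate <- ingestion_rate_quiet(stream)

  all_days <- c(lrps2$day, ing$day)
  days <- if (length(all_days)) seq(min(all_days), max(all_days), by = "day")
          else as.Date(character())
  daily <- data.frame(patient_id = rep(stream$patient_id, length(days)), day = days)
  mi <- match(days, lrps2$day)
  daily$lrp_start <- lrps2$lrp_start[mi]
  daily$lrp_duration_min <- lrps2$duration_min[mi]
  daily$lrp_quality <- lrps2$lrp_quality[mi]
  daily$quality_z <- quality_z[mi]
  daily$start_z <- start_z[mi]
  daily$duration_z <- duration_z[mi]
  daily$composite_z <- comp[mi]
  mj <- match(days, ing$day)
  daily$ingestion_time_min <- ing$ingestion_time_min[mj]
  daily$ingestion_z <- ing$ingestion_z[mj]

  coin <- outlier_coincidences(
    data.frame(day = lrps2$day, composite_z = comp), ing, cfg)

  summary <- data.frame(
    patient_id = stream$patient_id,
    n_patch_days = n_patch_days(stream),
    ingestion_rate = rate$rate,
    mean_composite = if (all(is.na(comp))) NA_real_ else mean(comp, na.rm = TRUE),
    n_coincidences = nrow(coin)
  )
  structure(
    list(daily = daily, grids = grids, lrps = lrps2, quality = qual,
         model = qual$model, ingestion = rate, coincidences = coin,
         summary = summary, config = cfg),
    class = "rest_analysis"
  )
}

# ingestion_rate() without the no-ingestion warning noise inside the driver
ingestion_rate_quiet <- function(stream) {
  if (nrow(stream$ingestions)) ingestion_rate(stream)
  else suppressWarnings(ingestion_rate(stream))
}

#' @export
print.rest_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<rest_analysis> %s: %d patch day(s), %d LRP day(s), ingestion rate %.3f, mean composite %.3f, %d outlier coincidence(s)\n",
    s$patient_id, s$n_patch_days, sum(!is.na(x$daily$lrp_start)),
    s$ingestion_rate, s$mean_composite, s$n_coincidences))
  invisible(x)
}
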