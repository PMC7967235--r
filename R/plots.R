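# Diagnostic figures, drawn from the pipeline dump CSVs (never recomputed).

#' Day-by-interval rest state raster
#'
#' One row per day, one tile per 15-minute interval, colored by its
#' REST/ACTIVE/MISSING state.
#'
#' @param intervals data.frame as written to `intervals.csv` (columns `day`,
#'   `interval`, `state`), optionally for one patient.
#' @return a ggplot object.
#' @export
plot_state_raster <- function(intervals) {
  intervals$day <- as.Date(intervals$day)
  intervals$state <- factor(intervals$state, levels = STATE_LEVELS)
  ggplot2::ggplot(intervals,
                  ggplot2::aes(x = .data$interval, y = .data$day,
                               fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(REST = "#2c7fb8", ACTIVE = "#fdae61",
                                          MISSING = "grey85"), drop = FALSE) +
    ggplot2::labs(x = "15-minute interval of day (from day boundary)",
                  y = NULL, fill = "state",
                  title = "Rest state interval designations") +
    ggplot2::theme_minimal()
}

#' Daily longest rest periods colored by interval quality
#'
#' One horizontal bar per day spanning the LRP's intervals; scored intervals
#' are shaded by their rest-quality sum (lower = better rest).  Days without
#' an LRP appear as gaps.
#'
#' @param lrps data.frame as written to `lrps.csv`.
#' @param windows data.frame as written to `windows.csv` (per-window
#'   distances; summed here per interval for display only).
#' @param cfg a [rest_config()] (interval geometry).
#' @return a ggplot object.
#' @export
plot_lrp_quality <- function(lrps, windows, cfg = rest_config()) {
  lrps$day <- as.Date(lrps$day)
  lrps$lrp_start <- parse_instant(as.character(lrps$lrp_start))
  lrps$lrp_end <- parse_instant(as.character(lrps$lrp_end))
  base <- data.frame(day = lrps$day,
                     x0 = clock_hours(lrps$lrp_start),
                     x1 = clock_hours(lrps$lrp_start) +
                       lrps$duration_min / 60)
  p <- ggplot2::ggplot(base) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x0, xend = .data$x1,
                                       y = .data$day, yend = .data$day),
                          linewidth = 4, color = "grey80")
  if (!is.null(windows) && nrow(windows)) {
    windows$day <- as.Date(windows$day)
    key <- interaction(windows$day, windows$interval, drop = TRUE)
    q <- tapply(windows$distance, key, sum)
    first <- !duplicated(key)
    ivq <- data.frame(day = windows$day[first],
                      interval = windows$interval[first],
                      quality = as.numeric(q[as.character(key[first])]))
    ivq <- merge(ivq, base, by = "day")
    m <- match(ivq$day, lrps$day)
    start_iv <- floor(as.numeric(difftime(
      lrps$lrp_start[m], trunc(lrps$lrp_start[m], "days"),
      units = "mins")) / cfg$interval_minutes)
    day_iv <- clock_hours(lrps$lrp_start[m]) -
      (start_iv * cfg$interval_minutes) / 60
    ivq$x0 <- day_iv + (ivq$interval - 1) * cfg$interval_minutes / 60
    p <- p + ggplot2::geom_segment(
      data = ivq,
      ggplot2::aes(x = .data$x0, xend = .data$x0 + cfg$interval_minutes / 60,
                   y = .data$day, yend = .data$day, color = .data$quality),
      linewidth = 4) +
      ggplot2::scale_color_viridis_c(direction = -1)
  }
  p + ggplot2::labs(x = "hours (clock time, wrapping past midnight)", y = NULL,
                  color = "interval\nquality",
                  title = "Daily longest rest periods",
                  subtitle = "lower quality values = better rest") +
    ggplot2::theme_minimal()
}

# hours since midnight of the timestamp's own day, allowed past 24 for bars
clock_hours <- function(ts) {
  as.numeric(difftime(ts, trunc(ts, "days"), units = "hours"))
}

#' Composite rest and ingestion-time z-scores across days
#'
#' Overlays the two standardized series and marks outlier days (|z| above
#' the configured threshold).
#'
#' @param daily data.frame as written to `daily_scores.csv` (one patient).
#' @param cfg a [rest_config()] (outlier threshold).
#' @return a ggplot object.
#' @export
plot_z_overlay <- function(daily, cfg = rest_config()) {
  daily$day <- as.Date(daily$day)
  long <- rbind(
    data.frame(day = daily$day, z = daily$composite_z, series = "composite rest"),
    data.frame(day = daily$day, z = daily$ingestion_z, series = "ingestion time")
  )
  long <- long[!is.na(long$z), , drop = FALSE]
  out <- long[(long$series == "composite rest" & long$z > cfg$outlier_z) |
                (long$series == "ingestion time" & abs(long$z) > cfg$outlier_z), ,
              drop = FALSE]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$z,
                                          color = .data$series)) +
    ggplot2::geom_hline(yintercept = c(-cfg$outlier_z, cfg$outlier_z),
                        linetype = "dashed", color = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1)
  if (nrow(out)) {
    p <- p + ggplot2::geom_point(data = out, shape = 21, size = 3,
                                 stroke = 1, fill = NA)
  }
  p + ggplot2::labs(x = NULL, y = "z score",
                    title = "Composite rest and ingestion-time z scores") +
    ggplot2::theme_minimal()
}

#' Write the three diagnostic figures for a pipeline run
#'
#' Reads the dump CSVs under `out_dir` and writes
#' `raster_<patient>.png`, `lrp_<patient>.png`, `zscores_<patient>.png`.
#'
#' @param out_dir a directory produced by [run_pipeline()].
#' @param cfg the [rest_config()] used for the run.
#' @param patients patient ids to plot (default: all present).
#' @return character vector of written files, invisibly.
#' @export
plot_rasters <- function(out_dir, cfg = rest_config(), patients = NULL) {
  ivs <- utils::read.csv(file.path(out_dir, "intervals.csv"))
  lrps <- utils::read.csv(file.path(out_dir, "lrps.csv"))
  wins <- utils::read.csv(file.path(out_dir, "windows.csv"))
  daily <- read_daily_scores(file.path(out_dir, "daily_scores.csv"))
  if (is.null(patients)) patients <- unique(ivs$patient_id)
  written <- character()
  for (p in patients) {
    fr <- file.path(out_dir, paste0("raster_", p, ".png"))
    ggplot2::ggsave(fr, plot_state_raster(ivs[ivs$patient_id == p, ]),
                    width = 8, height = 5, dpi = 120)
    fl <- file.path(out_dir, paste0("lrp_", p, ".png"))
    ggplot2::ggsave(fl, plot_lrp_quality(lrps[lrps$patient_id == p, ],
                                         wins[wins$patient_id == p, ], cfg),
                    width = 8, height = 5, dpi = 120)
    fz <- file.path(out_dir, paste0("zscores_", p, ".png"))
    ggplot2::ggsave(fz, plot_z_overlay(daily[daily$patient_id == p, ], cfg),
                    width = 8, height = 4, dpi = 120)
    written <- c(written, fr, fl, fz)
  }
  invisible(written)
}
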