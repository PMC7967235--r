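# Pipeline orchestration: run every stage for a set of patients and write
# the output file set.  Plots are drawn from these dump files only, so the
# figures can never disagree with the numbers.

#' Run the full rest-quality pipeline
#'
#' Executes interval classification, LRP detection, feature extraction,
#' cluster-based quality scoring, z-scores and ingestion metrics for each
#' patient and writes:
#' `daily_scores.csv`, `intervals.csv`, `lrps.csv`, `windows.csv`,
#' `patient_summary.csv`, `coincidences.csv`, `models.json`, `config.json`.
#' Every file set is stamped with the hash of the configuration that
#' produced it (`config.json` carries the hash; the run log repeats it).
#'
#' Ineligible patients (fewer than `cfg$min_patch_days` days of patch data)
#' are skipped with a logged reason; the run still succeeds.
#'
#' @param streams a `patient_stream`, a list of them, or a directory whose
#'   subdirectories each hold the four channel CSVs
#'   (`accel.csv`, `hr.csv`, `pairing.csv`, `ingestions.csv`).
#' @param cfg a [rest_config()].
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `analyses` (per eligible patient),
#'   `skipped` (ids), `out_dir` and `config_hash`.
#' @export
run_pipeline <- function(streams, cfg = rest_config(), out_dir, quiet = FALSE) {
  if (is.character(streams)) {
    if (!dir.exists(streams)) stop("no such input directory: ", streams, call. = FALSE)
    subdirs <- list.dirs(streams, recursive = FALSE)
    subdirs <- subdirs[file.exists(file.path(subdirs, "accel.csv"))]
    if (!length(subdirs)) stop("no patient subdirectories with accel.csv under ",
                               streams, call. = FALSE)
    streams <- lapply(subdirs, function(d) {
      read_patient_stream(file.path(d, "accel.csv"), file.path(d, "hr.csv"),
                          file.path(d, "pairing.csv"),
                          file.path(d, "ingestions.csv"),
                          patient_id = basename(d))
    })
  }
  if (inherits(streams, "patient_stream")) streams <- list(streams)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  say <- function(...) if (!quiet) message(...)
  say("pipeline config ", hash)

  analyses <- list(); skipped <- character()
  for (s in streams) {
    if (!is_eligible(s, cfg)) {
      say("skipping ", s$patient_id, ": fewer than ", cfg$min_patch_days,
          " days of patch data")
      skipped <- c(skipped, s$patient_id)
      next
    }
    t0 <- Sys.time()
    analyses[[s$patient_id]] <- analyze_patient(s, cfg)
    say(sprintf("analyzed %s in %.2fs", s$patient_id,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  daily <- do.call(rbind, c(lapply(analyses, `[[`, "daily"),
                            make.row.names = FALSE))
  write_daily_scores(daily, file.path(out_dir, "daily_scores.csv"))

  ivs <- do.call(rbind, lapply(analyses, function(a) {
    cbind(patient_id = a$summary$patient_id, interval_table(a$grids))
  }))
  write_dump(ivs, file.path(out_dir, "intervals.csv"),
             time_cols = "interval_start")

  lrp_tab <- do.call(rbind, lapply(analyses, function(a) {
    x <- a$lrps
    data.frame(patient_id = a$summary$patient_id, day = x$day,
               lrp_start = x$lrp_start, lrp_end = x$lrp_end,
               duration_min = x$duration_min, n_rest = x$n_rest,
               n_bridged_missing = x$n_bridged_missing,
               n_bridged_active = x$n_bridged_active)
  }))
  write_dump(lrp_tab, file.path(out_dir, "lrps.csv"),
             time_cols = c("lrp_start", "lrp_end"))

  win_tab <- do.call(rbind, lapply(analyses, function(a) {
    w <- a$quality$windows
    if (!nrow(w)) return(NULL)
    cbind(patient_id = a$summary$patient_id, w)
  }))
  write_dump(win_tab, file.path(out_dir, "windows.csv"))

  summ <- do.call(rbind, lapply(analyses, `[[`, "summary"))
  write_dump(summ, file.path(out_dir, "patient_summary.csv"))

  coin <- do.call(rbind, lapply(analyses, function(a) {
    if (!nrow(a$coincidences)) return(NULL)
    cbind(patient_id = a$summary$patient_id, a$coincidences)
  }))
  write_dump(coin, file.path(out_dir, "coincidences.csv"))

  models <- lapply(analyses, function(a) {
    m <- a$model
    if (is.null(m)) return(NULL)
    list(feature_names = m$feature_names,
         ranges = list(min = unname(m$ranges[1L, ]), max = unname(m$ranges[2L, ])),
         centroid_rr = unname(m$centers["RR", ]),
         centroid_dfr = unname(m$centers["DFR", ]),
         rr_label_rule = m$rr_label_rule)
  })
  jsonlite::write_json(list(config_hash = hash, models = models),
                       file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(c(list(config_hash = hash), unclass(cfg)),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(analyses = analyses, skipped = skipped, out_dir = out_dir,
                 config_hash = hash))
}

# CSV dump with stable formatting (times as ISO 8601, numerics at 12
# significant digits) so reruns with the same inputs are byte-identical
write_dump <- function(df, path, time_cols = character()) {
  if (is.null(df) || !nrow(df)) {
    if (is.null(df)) df <- data.frame()
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    return(invisible(path))
  }
  for (nm in names(df)) {
    if (nm %in% time_cols || inherits(df[[nm]], "POSIXct")) {
      df[[nm]] <- format_instant(df[[nm]])
    } else if (inherits(df[[nm]], "Date")) {
      df[[nm]] <- as.character(df[[nm]])
    } else if (is.double(df[[nm]])) {
      df[[nm]] <- ifelse(is.na(df[[nm]]), "", sprintf("%.12g", df[[nm]]))
    }
  }
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
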