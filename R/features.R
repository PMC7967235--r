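# Rolling-window accelerometer features.
#
# Rest quality is scored on 3-minute rolling windows (stride 1 minute) of the
# per-minute accelerometer records inside each 15-minute interval; a fully
# sampled interval yields 15 - 3 + 1 = 13 windows.  Windows never span an
# interval boundary, and a window overlapping a missing minute slot is
# dropped rather than imputed.
#
# Four canonical features are computed per window:
#   * y-z circular deviation (mean): rest with the torso horizontal puts
#     gravity in the y-z plane, so sqrt(a_y^2 + a_z^2) sits near 1 g and its
#     deviation from the unit circle is near 0; larger values indicate
#     movement or uprightness.
#   * posture angle (mean), degrees from horizontal.
#   * acceleration norm (mean), g.
#   * x acceleration (SD), g — movement along the longitudinal body axis.
# A wider registry of candidate rolling-window statistics supports the
# optional agglomeration-based feature selection.

CANONICAL_FEATURES <- c("yz_circ_dev_mean", "theta_mean", "accel_norm_mean", "ax_sd")

#' Canonical rolling-window features
#'
#' Each takes a block of consecutive per-minute records (a data.frame with
#' columns `ax`, `ay`, `az`, `theta`, `steps`) and returns one number.
#'
#' @param block data.frame of per-minute records (typically 3 rows).
#' @param ddof degrees-of-freedom correction for [feat_ax_sd()] (0 =
#'   population SD, the default used by the pipeline).
#' @return numeric scalar.
#' @examples
#' b <- data.frame(ax = c(-1, 0, 1), ay = 0, az = 1, theta = c(10, 20, 30),
#'                 steps = 0)
#' feat_yz_circ_dev(b)   # 0: (ay, az) sits on the unit circle
#' feat_theta_mean(b)    # 20
#' feat_ax_sd(b)         # sqrt(2/3)
#' @export
feat_yz_circ_dev <- function(block) mean(abs(sqrt(block$ay^2 + block$az^2) - 1))

#' @rdname feat_yz_circ_dev
#' @export
feat_theta_mean <- function(block) mean(block$theta)

#' @rdname feat_yz_circ_dev
#' @export
feat_accel_norm_mean <- function(block) mean(sqrt(block$ax^2 + block$ay^2 + block$az^2))

#' @rdname feat_yz_circ_dev
#' @export
feat_ax_sd <- function(block, ddof = 0L) sd_ddof(block$ax, ddof)

#' Rolling windows of an interval's minute records
#'
#' Minute records are mapped to slots `1..interval_minutes` by their offset
#' from the interval start; a window is every run of `rolling_window_minutes`
#' consecutive *occupied* slots, stride one.
#'
#' @param records data.frame of the interval's accelerometer records (sorted).
#' @param interval_start POSIXct start of the interval.
#' @param cfg a [rest_config()].
#' @return data.frame with `window` (slot offset of the window start) and a
#'   list column `rows` of record row numbers; zero rows when no complete
#'   window exists.
#' @export
rolling_windows <- function(records, interval_start, cfg = rest_config()) {
  w <- cfg$rolling_window_minutes
  n_slots <- cfg$interval_minutes
  occ <- integer(n_slots)
  if (nrow(records)) {
    slot <- floor(as.numeric(difftime(records$timestamp, interval_start,
                                      units = "mins"))) + 1L
    keep <- slot >= 1L & slot <= n_slots
    occ[slot[keep]] <- which(keep)  # last record wins; streams are deduplicated
  }
  offsets <- seq_len(n_slots - w + 1L)
  full <- vapply(offsets, function(i) all(occ[i:(i + w - 1L)] > 0L), logical(1))
  offsets <- offsets[full]
  data.frame(
    window = offsets,
    rows = I(lapply(offsets, function(i) occ[i:(i + w - 1L)]))
  )
}

# Vectorized canonical feature computation for one interval.
# Returns a data.frame with one row per complete window.
interval_features <- function(records, interval_start, cfg = rest_config()) {
  w <- cfg$rolling_window_minutes
  n_slots <- cfg$interval_minutes
  # per-slot minute values (NA where the slot has no record)
  v <- matrix(NA_real_, nrow = n_slots, ncol = 4L)
  if (nrow(records)) {
    slot <- floor(as.numeric(difftime(records$timestamp, interval_start,
                                      units = "mins"))) + 1L
    keep <- slot >= 1L & slot <= n_slots
    sl <- slot[keep]
    v[sl, 1L] <- abs(sqrt(records$ay[keep]^2 + records$az[keep]^2) - 1)
    v[sl, 2L] <- records$theta[keep]
    v[sl, 3L] <- sqrt(records$ax[keep]^2 + records$ay[keep]^2 + records$az[keep]^2)
    v[sl, 4L] <- records$ax[keep]
  }
  occupied <- !is.na(v[, 2L])
  offsets <- seq_len(n_slots - w + 1L)
  full <- offsets[vapply(offsets, function(i) all(occupied[i:(i + w - 1L)]),
                         logical(1))]
  if (!length(full)) {
    return(data.frame(window = integer(), yz_circ_dev_mean = numeric(),
                      theta_mean = numeric(), accel_norm_mean = numeric(),
                      ax_sd = numeric()))
  }
  win_mean <- function(x) {
    cs <- c(0, cumsum(ifelse(is.na(x), 0, x)))
    (cs[full + w] - cs[full]) / w
  }
  ax_m1 <- win_mean(v[, 4L])
  ax_m2 <- win_mean(v[, 4L]^2)
  corr <- if (cfg$feature_sd_ddof > 0) sqrt(w / (w - cfg$feature_sd_ddof)) else 1
  data.frame(
    window = full,
    yz_circ_dev_mean = win_mean(v[, 1L]),
    theta_mean = win_mean(v[, 2L]),
    accel_norm_mean = win_mean(v[, 3L]),
    ax_sd = sqrt(pmax(0, ax_m2 - ax_m1^2)) * corr
  )
}

#' Canonical feature windows for a classified stream
#'
#' @param stream a `patient_stream`.
#' @param grids day grids from [classify_intervals()].
#' @param lrps daily rest periods from [daily_lrps()].
#' @param cfg a [rest_config()].
#' @param scope `"lrp"` scores the REST intervals inside each day's longest
#'   rest period (the quality pipeline's scope); `"all"` scores every
#'   analyzable (REST or ACTIVE) interval.
#' @return data.frame with `day`, `interval`, `window` and one column per
#'   canonical feature.
#' @export
compute_feature_windows <- function(stream, grids, lrps, cfg = rest_config(),
                                    scope = c("lrp", "all")) {
  scope <- match.arg(scope)
  out <- list()
  for (g in grids) {
    if (scope == "lrp") {
      row <- lrps[lrps$day == g$day_id, , drop = FALSE]
      if (!nrow(row)) next
      ivs <- row$rest_iv[[1L]]
    } else {
      ivs <- which(g$state != "MISSING")
    }
    for (iv in ivs) {
      recs <- stream$accel[g$accel_idx[[iv]], , drop = FALSE]
      fw <- interval_features(recs, g$start[iv], cfg)
      if (nrow(fw)) {
        out[[length(out) + 1L]] <- cbind(
          data.frame(day = g$day_id, interval = iv), fw)
      }
    }
  }
  if (!length(out)) {
    return(cbind(data.frame(day = as.Date(character()), interval = integer()),
                 interval_features(data.frame(), Sys.time(), cfg)[0, ]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Candidate feature registry
#'
#' Thirty-five documented rolling-window statistics of the per-minute
#' channels (means, SDs, ranges, successive differences, step statistics and
#' circular statistics of the y-z acceleration angle).  The four canonical
#' features are marked `canonical = TRUE`; the remaining thirty-one are
#' standard actigraphy-style candidates for the optional agglomeration-based
#' selection and are *not* part of the published feature set.
#'
#' @return data.frame with columns `name`, `units`, `canonical`,
#'   `description`, and a list column `fn` of functions `block -> numeric`.
#' @export
feature_registry <- function() {
  masd <- function(col) function(b) if (nrow(b) < 2) 0 else mean(abs(diff(b[[col]])))
  yz_angle <- function(b) atan2(b$az, b$ay)
  defs <- list(
    list("yz_circ_dev_mean", "g", TRUE,
         "mean |sqrt(ay^2+az^2) - 1|: deviation of the y-z acceleration from the 1-g circle",
         feat_yz_circ_dev),
    list("theta_mean", "deg", TRUE, "mean posture angle from horizontal",
         feat_theta_mean),
    list("accel_norm_mean", "g", TRUE, "mean 3D acceleration norm",
         feat_accel_norm_mean),
    list("ax_sd", "g", TRUE, "population SD of the x (longitudinal) acceleration",
         function(b) feat_ax_sd(b, 0L)),
    list("ax_mean", "g", FALSE, "mean x acceleration", function(b) mean(b$ax)),
    list("ay_mean", "g", FALSE, "mean y acceleration", function(b) mean(b$ay)),
    list("az_mean", "g", FALSE, "mean z acceleration", function(b) mean(b$az)),
    list("ay_sd", "g", FALSE, "population SD of y acceleration",
         function(b) sd_ddof(b$ay, 0L)),
    list("az_sd", "g", FALSE, "population SD of z acceleration",
         function(b) sd_ddof(b$az, 0L)),
    list("theta_sd", "deg", FALSE, "population SD of posture angle",
         function(b) sd_ddof(b$theta, 0L)),
    list("accel_norm_sd", "g", FALSE, "population SD of acceleration norm",
         function(b) sd_ddof(sqrt(b$ax^2 + b$ay^2 + b$az^2), 0L)),
    list("yz_mag_mean", "g", FALSE, "mean sqrt(ay^2+az^2)",
         function(b) mean(sqrt(b$ay^2 + b$az^2))),
    list("yz_mag_sd", "g", FALSE, "population SD of sqrt(ay^2+az^2)",
         function(b) sd_ddof(sqrt(b$ay^2 + b$az^2), 0L)),
    list("yz_circ_dev_sd", "g", FALSE, "population SD of |sqrt(ay^2+az^2) - 1|",
         function(b) sd_ddof(abs(sqrt(b$ay^2 + b$az^2) - 1), 0L)),
    list("steps_sum", "count", FALSE, "total step count", function(b) sum(b$steps)),
    list("steps_mean", "count/min", FALSE, "mean step count", function(b) mean(b$steps)),
    list("steps_sd", "count/min", FALSE, "population SD of step count",
         function(b) sd_ddof(b$steps, 0L)),
    list("steps_max", "count/min", FALSE, "max per-minute step count",
         function(b) max(b$steps)),
    list("theta_min", "deg", FALSE, "min posture angle", function(b) min(b$theta)),
    list("theta_max", "deg", FALSE, "max posture angle", function(b) max(b$theta)),
    list("theta_range", "deg", FALSE, "posture angle range",
         function(b) diff(range(b$theta))),
    list("accel_norm_min", "g", FALSE, "min acceleration norm",
         function(b) min(sqrt(b$ax^2 + b$ay^2 + b$az^2))),
    list("accel_norm_max", "g", FALSE, "max acceleration norm",
         function(b) max(sqrt(b$ax^2 + b$ay^2 + b$az^2))),
    list("accel_norm_range", "g", FALSE, "acceleration norm range",
         function(b) diff(range(sqrt(b$ax^2 + b$ay^2 + b$az^2)))),
    list("ax_abs_mean", "g", FALSE, "mean |ax|", function(b) mean(abs(b$ax))),
    list("ay_abs_mean", "g", FALSE, "mean |ay|", function(b) mean(abs(b$ay))),
    list("az_abs_mean", "g", FALSE, "mean |az|", function(b) mean(abs(b$az))),
    list("ax_rms", "g", FALSE, "root-mean-square x acceleration",
         function(b) sqrt(mean(b$ax^2))),
    list("ax_masd", "g", FALSE, "mean |successive difference| of ax", masd("ax")),
    list("ay_masd", "g", FALSE, "mean |successive difference| of ay", masd("ay")),
    list("az_masd", "g", FALSE, "mean |successive difference| of az", masd("az")),
    list("theta_masd", "deg", FALSE, "mean |successive difference| of theta",
         masd("theta")),
    list("norm_masd", "g", FALSE, "mean |successive difference| of accel norm",
         function(b) {
           nrm <- sqrt(b$ax^2 + b$ay^2 + b$az^2)
           if (length(nrm) < 2) 0 else mean(abs(diff(nrm)))
         }),
    list("yz_angle_resultant", "unitless", FALSE,
         "circular mean resultant length of atan2(az, ay)",
         function(b) { a <- yz_angle(b); sqrt(mean(cos(a))^2 + mean(sin(a))^2) }),
    list("yz_angle_circ_sd", "rad", FALSE,
         "circular SD of atan2(az, ay): sqrt(-2 log R)",
         function(b) {
           a <- yz_angle(b)
           r <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
           sqrt(-2 * log(pmax(r, 1e-12)))
         })
  )
  data.frame(
    name = vapply(defs, `[[`, character(1), 1L),
    units = vapply(defs, `[[`, character(1), 2L),
    canonical = vapply(defs, `[[`, logical(1), 3L),
    description = vapply(defs, `[[`, character(1), 4L),
    fn = I(lapply(defs, `[[`, 5L))
  )
}

#' Evaluate registry features over a set of windows
#'
#' @param stream a `patient_stream`.
#' @param windows data.frame with list column `rows` of accel row indices
#'   (e.g. from [rolling_windows()]).
#' @param registry a [feature_registry()] (or subset of its rows).
#' @return numeric matrix, one row per window, one column per feature.
#' @export
evaluate_registry <- function(stream, windows, registry = feature_registry()) {
  mat <- matrix(NA_real_, nrow = nrow(windows), ncol = nrow(registry),
                dimnames = list(NULL, registry$name))
  for (i in seq_len(nrow(windows))) {
    block <- stream$accel[windows$rows[[i]], , drop = FALSE]
    mat[i, ] <- vapply(registry$fn, function(f) f(block), numeric(1))
  }
  mat
}

#' Agglomeration-based feature selection
#'
#' For each patient, features are hierarchically merged using the
#' dissimilarity `1 - |Pearson r|` between feature columns (average linkage)
#' and cut into `k` clusters — agglomeration over features rather than
#' samples.  A consensus over patients (features merge in proportion to how
#' often they co-clustered) is cut into `k` groups, and each group's most
#' distinct member (lowest mean co-clustering rate with features outside the
#' group; ties broken by registry order) is returned.
#'
#' The default pipeline uses the four canonical features without selection;
#' this path exists to reproduce the selection procedure on candidate
#' registries.
#'
#' @param feature_mats list of per-patient numeric matrices (windows x
#'   features, shared column names).
#' @param k number of features to select.
#' @return character vector of `k` selected feature names, in registry order.
#' @export
select_features <- function(feature_mats, k) {
  stopifnot(length(feature_mats) >= 1L, k >= 1L)
  nms <- colnames(feature_mats[[1L]])
  # features degenerate (zero variance) in any patient cannot be clustered
  degenerate <- Reduce(`|`, lapply(feature_mats, function(m) {
    apply(m, 2L, function(x) length(unique(x)) < 2L)
  }))
  keep <- nms[!degenerate]
  if (length(keep) < k) {
    stop("fewer than k candidate features with nonzero variance", call. = FALSE)
  }
  if (length(keep) == k) return(keep)
  p <- length(keep)
  co <- matrix(0, p, p, dimnames = list(keep, keep))
  for (m in feature_mats) {
    d <- 1 - abs(stats::cor(m[, keep, drop = FALSE]))
    lab <- stats::cutree(stats::hclust(stats::as.dist(d), method = "average"), k)
    co <- co + outer(lab, lab, `==`)
  }
  rate <- co / length(feature_mats)
  consensus <- stats::cutree(
    stats::hclust(stats::as.dist(1 - rate), method = "average"), k)
  picked <- vapply(seq_len(k), function(cl) {
    members <- which(consensus == cl)
    if (length(members) == 1L) return(keep[members])
    outside <- which(consensus != cl)
    score <- rowMeans(rate[members, outside, drop = FALSE])
    keep[members[which.min(score)]]  # ties: first by registry order
  }, character(1))
  keep[keep %in% picked]
}
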