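# Cluster-based relative rest quality.
#
# Per patient: the four canonical features of every scored 3-minute window
# are min-max normalized to the patient's own ranges, then k-means with k = 2
# splits the windows into a rest-reference (RR) cluster — the one whose
# centroid posture angle is closer to horizontal — and a deviation-from-rest
# (DFR) cluster.  Every window assigned to RR scores 0; every DFR window
# scores its Euclidean distance to the RR centroid in the normalized 4-D
# space.  Distances are summed within each 15-minute interval and averaged
# over the intervals of a day's longest rest period.  Lower values mean
# better rest.

#' Min-max normalize feature columns
#'
#' Each feature is mapped to `(x - min) / (max - min)` using the patient's
#' own range over the supplied windows.  A zero-range (constant) feature is
#' set to 0 for all points, with a warning.
#'
#' @param mat numeric matrix (windows x features).
#' @return list with `points` (normalized matrix, entries in `[0, 1]`) and
#'   `ranges` (2 x features matrix of min / max).
#' @examples
#' normalize_features(cbind(f = c(2, 4, 6)))$points
#' @export
normalize_features <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 windows to normalize", call. = FALSE)
  rng <- apply(mat, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  degenerate <- span <= 0
  if (any(degenerate)) {
    warning("degenerate (constant) feature(s) set to 0: ",
            paste(colnames(mat)[degenerate], collapse = ", "))
  }
  pts <- sweep(mat, 2L, rng[1L, ], `-`)
  pts <- sweep(pts, 2L, ifelse(degenerate, 1, span), `/`)
  pts[, degenerate] <- 0
  list(points = pts, ranges = rng)
}

# apply previously-fitted ranges to new points (same degenerate rule)
apply_normalization <- function(mat, ranges) {
  mat <- as.matrix(mat)
  span <- ranges[2L, ] - ranges[1L, ]
  degenerate <- span <= 0
  pts <- sweep(mat, 2L, ranges[1L, ], `-`)
  pts <- sweep(pts, 2L, ifelse(degenerate, 1, span), `/`)
  pts[, degenerate] <- 0
  pts
}

#' Fit the rest-reference / deviation-from-rest cluster model
#'
#' k-means with k = 2 on the normalized feature windows, `kmeans_restarts`
#' random restarts seeded by `rng_seed` (deterministic given the seed).  The
#' cluster whose centroid has the smaller posture-angle coordinate is
#' designated the rest-reference (RR) cluster; the other is the
#' deviation-from-rest (DFR) cluster.
#'
#' @param points normalized matrix from [normalize_features()] with a column
#'   named `theta_mean` (or pass `theta_col`).
#' @param cfg a [rest_config()].
#' @param theta_col name (or index) of the posture-angle coordinate.
#' @param ranges optional min/max matrix stored alongside the model.
#' @return object of class `rest_cluster_model`: list with `centers` (2 x
#'   features; row `"RR"` first), `ranges`, `feature_names`, and
#'   `rr_label_rule` recording why the RR cluster was chosen.
#' @export
fit_clusters <- function(points, cfg = rest_config(), theta_col = "theta_mean",
                         ranges = NULL) {
  points <- as.matrix(points)
  if (nrow(unique(points)) < 2L) {
    stop("all windows identical: a single rest cluster cannot be split (k = 2)",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$rng_seed)
  km <- stats::kmeans(points, centers = 2L, nstart = cfg$kmeans_restarts,
                      iter.max = 100L)
  th <- km$centers[, theta_col]
  rr <- which.min(th)
  centers <- km$centers[c(rr, 3L - rr), , drop = FALSE]
  rownames(centers) <- c("RR", "DFR")
  structure(
    list(centers = centers,
         ranges = ranges,
         feature_names = colnames(points),
         rr_label_rule = sprintf(
           "RR = cluster with smaller normalized posture-angle centroid (%.4f vs %.4f)",
           th[rr], th[3L - rr])),
    class = "rest_cluster_model"
  )
}

#' @export
print.rest_cluster_model <- function(x, ...) {
  cat("<rest_cluster_model>\n  features:", paste(x$feature_names, collapse = ", "),
      "\n ", x$rr_label_rule, "\n")
  invisible(x)
}

#' Rest-quality distance of normalized points
#'
#' Points assigned (nearest centroid; ties go to RR) to the rest-reference
#' cluster score exactly 0; all other points score their Euclidean distance
#' to the RR centroid across the full feature space.
#'
#' @param points normalized matrix (or single point) in the model's space.
#' @param model a `rest_cluster_model`.
#' @return non-negative numeric vector, one distance per point.
#' @export
rest_distance <- function(points, model) {
  points <- if (is.null(dim(points))) matrix(points, nrow = 1L) else as.matrix(points)
  if (ncol(points) != ncol(model$centers)) {
    stop("point dimension does not match the cluster model", call. = FALSE)
  }
  d_rr <- sqrt(rowSums(sweep(points, 2L, model$centers["RR", ])^2))
  d_dfr <- sqrt(rowSums(sweep(points, 2L, model$centers["DFR", ])^2))
  ifelse(d_rr <= d_dfr, 0, d_rr)
}

#' Interval rest quality from its window distances
#'
#' Distances of the 3-minute windows inside one 15-minute interval are
#' summed; intervals observed with fewer than the nominal 13 windows are
#' rescaled by `13 / n` so interval sums stay comparable.
#'
#' @param distances numeric vector of the interval's window distances.
#' @param cfg a [rest_config()] (supplies the nominal window count).
#' @return numeric scalar, `NA` when the interval has no scored window.
#' @examples
#' window_quality(rep(0.5, 10))  # 0.5 * 10 * 13/10 = 6.5
#' @export
window_quality <- function(distances, cfg = rest_config()) {
  n <- length(distances)
  if (!n) return(NA_real_)
  nominal <- cfg$interval_minutes - cfg$rolling_window_minutes + 1L
  sum(distances) * if (n < nominal) nominal / n else 1
}

#' LRP rest quality: mean over its scored intervals
#'
#' Bridged MISSING/ACTIVE intervals inside the rest period contribute no
#' windows and therefore no terms to the mean.
#'
#' @param interval_qualities numeric vector of the LRP's interval qualities.
#' @return numeric scalar, `NA` when nothing was scored.
#' @export
lrp_quality <- function(interval_qualities) {
  q <- interval_qualities[!is.na(interval_qualities)]
  if (!length(q)) return(NA_real_)
  mean(q)
}

#' Score a patient's rest quality
#'
#' Runs the quality stage end to end for one patient: canonical feature
#' windows (fit scope per `cfg$fit_scope`), min-max normalization, the k = 2
#' RR/DFR cluster fit, per-window distances, interval sums and per-day LRP
#' quality.
#'
#' @param stream a `patient_stream`.
#' @param grids day grids from [classify_intervals()].
#' @param lrps daily rest periods from [daily_lrps()].
#' @param cfg a [rest_config()].
#' @return list with `model` (`rest_cluster_model`), `windows` (the scored
#'   LRP window table with `distance`), `intervals` (per day x interval
#'   quality) and `daily` (`day`, `lrp_quality`).
#' @export
score_quality <- function(stream, grids, lrps, cfg = rest_config()) {
  fit_fw <- compute_feature_windows(stream, grids, lrps, cfg,
                                    scope = if (cfg$fit_scope == "all") "all" else "lrp")
  lrp_fw <- if (cfg$fit_scope == "all") {
    compute_feature_windows(stream, grids, lrps, cfg, scope = "lrp")
  } else fit_fw
  if (nrow(fit_fw) < 2L || nrow(lrp_fw) == 0L) {
    return(list(model = NULL, windows = lrp_fw,
                intervals = data.frame(day = as.Date(character()),
                                       interval = integer(), quality = numeric()),
                daily = data.frame(day = as.Date(character()),
                                   lrp_quality = numeric())))
  }
  nz <- normalize_features(as.matrix(fit_fw[CANONICAL_FEATURES]))
  model <- fit_clusters(nz$points, cfg, ranges = nz$ranges)
  pts <- apply_normalization(as.matrix(lrp_fw[CANONICAL_FEATURES]), model$ranges)
  lrp_fw$distance <- rest_distance(pts, model)

  key <- interaction(lrp_fw$day, lrp_fw$interval, drop = TRUE)
  iv_sum <- tapply(lrp_fw$distance, key, function(d) window_quality(d, cfg))
  iv_info <- !duplicated(key)
  intervals <- data.frame(day = lrp_fw$day[iv_info],
                          interval = lrp_fw$interval[iv_info])
  intervals$quality <- as.numeric(iv_sum[as.character(key[iv_info])])
  daily_q <- tapply(intervals$quality, intervals$day, lrp_quality)
  daily <- data.frame(day = as.Date(names(daily_q)),
                      lrp_quality = as.numeric(daily_q), row.names = NULL)
  list(model = model, windows = lrp_fw, intervals = intervals, daily = daily)
}
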