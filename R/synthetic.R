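# Synthetic DMS patch streams with ground truth.
#
# The simulator emulates the patch's channels at their native cadences
# (per-minute accelerometer summaries, 5-minute mean heart rate), a nightly
# rest block with Gaussian start-time and duration variability, brief
# nocturnal awakenings, missing spans, daily app-pairing spans and a
# once-daily ingestion regimen with Bernoulli adherence and Gaussian dose
# times.  During rest, gravity lies in the y-z plane (the torso is
# horizontal): (a_y, a_z) sits on the 1-g circle at a nightly orientation
# angle plus axis noise, a_x is near 0, the posture angle is near 5 degrees
# and steps are 0.  While active, gravity loads the x (longitudinal) axis,
# the posture angle is near 80 degrees and steps are Poisson.  Every draw is
# governed by `rng_seed`, so a seeded run is byte-identical.

#' Simulation configuration
#'
#' Defaults describe a realistic adherent patient: rest starts around 23:00
#' (SD 30 min) and lasts about 8 h (SD 45 min), with on average 1.5 brief
#' awakenings per night (1 min plus an exponential tail of mean 2 min, capped
#' at 20 min — nocturnal arousals visible at per-minute resolution are mostly
#' a few minutes long), one 10-minute app-pairing span per evening,
#' occasional missing spans of 20-60 min, and a 9:00 dose (SD 45 min) taken
#' with probability 0.9.
#'
#' @param n_days number of simulated nights.
#' @param start_date first calendar date.
#' @param rest_start_mean mean rest onset clock time (`"HH:MM"`).
#' @param rest_start_sd_min SD of rest onset, minutes.
#' @param rest_duration_mean_min,rest_duration_sd_min rest duration, minutes.
#' @param awakening_rate expected awakenings per night (Poisson).
#' @param awakening_mean_min mean of the exponential awakening-duration tail.
#' @param awakening_max_min awakening duration cap, minutes.
#' @param rest_theta_mean_deg,active_theta_mean_deg mean posture angle while
#'   resting / active, degrees from horizontal.
#' @param theta_jitter_sd_deg posture-angle noise SD, degrees.
#' @param accel_noise_sd_g per-axis acceleration noise SD, g.
#' @param missing_span_rate expected missing spans per day (Poisson).
#' @param missing_min_min,missing_max_min missing-span length range, minutes.
#' @param pairing_clock daily pairing-span start (`"HH:MM"`, `NA` for none).
#' @param pairing_minutes pairing-span length.
#' @param adherence_prob probability a day's dose is taken.
#' @param dose_time_mean mean dose clock time (`"HH:MM"`).
#' @param dose_time_sd_min dose-time SD, minutes.
#' @param outlier_days integer day indices (1-based) planted as joint
#'   rest/ingestion outliers: the dose is shifted by `outlier_dose_shift_sd`
#'   dose-time SDs and, when `outlier_disrupt_rest`, the night is shortened
#'   by 4 duration SDs, delayed by 4 onset SDs and made restless.
#' @param outlier_dose_shift_sd dose shift on outlier days, in SD units.
#' @param outlier_disrupt_rest disrupt rest on outlier days?
#' @param restless_nights integer night indices simulated with
#'   `restless_factor` times the posture jitter and acceleration noise but an
#'   undisturbed schedule — matched restless counterparts to quiet nights.
#' @param restless_factor noise multiplier for restless (and disrupted
#'   outlier) nights.
#' @param rng_seed integer seed.
#' @return object of class `sim_config` (named list).
#' @export
sim_config <- function(n_days = 28,
                       start_date = "2024-03-01",
                       rest_start_mean = "23:00",
                       rest_start_sd_min = 30,
                       rest_duration_mean_min = 480,
                       rest_duration_sd_min = 45,
                       awakening_rate = 1.5,
                       awakening_mean_min = 2,
                       awakening_max_min = 20,
                       rest_theta_mean_deg = 5,
                       active_theta_mean_deg = 80,
                       theta_jitter_sd_deg = 3,
                       accel_noise_sd_g = 0.05,
                       missing_span_rate = 0.5,
                       missing_min_min = 20,
                       missing_max_min = 60,
                       pairing_clock = "20:00",
                       pairing_minutes = 10,
                       adherence_prob = 0.9,
                       dose_time_mean = "09:00",
                       dose_time_sd_min = 45,
                       outlier_days = integer(),
                       outlier_dose_shift_sd = 4,
                       outlier_disrupt_rest = TRUE,
                       restless_nights = integer(),
                       restless_factor = 4,
                       rng_seed = 1) {
  cfg <- as.list(environment())
  cfg$n_days <- as.integer(cfg$n_days)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg$outlier_days <- as.integer(cfg$outlier_days)
  cfg$restless_nights <- as.integer(cfg$restless_nights)
  stopifnot(cfg$n_days >= 1L,
            cfg$rest_start_sd_min >= 0, cfg$rest_duration_sd_min >= 0,
            cfg$theta_jitter_sd_deg >= 0, cfg$accel_noise_sd_g >= 0,
            cfg$adherence_prob >= 0, cfg$adherence_prob <= 1,
            cfg$dose_time_sd_min >= 0, cfg$awakening_rate >= 0,
            cfg$missing_span_rate >= 0)
  if (cfg$rest_duration_mean_min >= 1440) {
    stop("rest duration must be shorter than a day", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate one patient stream with ground truth
#'
#' @param cfg a [sim_config()].
#' @param patient_id identifier for the generated stream.
#' @return list with
#'   * `stream` — a [patient_stream()];
#'   * `truth` — list with `rest` (data.frame `day`, `rest_start`,
#'     `rest_end` POSIXct: the planted rest block of each night, labeled by
#'     the calendar day it starts on), `doses` (data.frame `day`,
#'     `dose_time` POSIXct or `NA` when skipped), `minute` (data.frame
#'     `timestamp`, `regime` in rest/active/missing for every simulated
#'     minute), and `outlier_days` (planted calendar dates);
#'   * `config` — the `sim_config` used.
#' @export
simulate_patient <- function(cfg = sim_config(), patient_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$rng_seed)

  d0 <- as.Date(cfg$start_date)
  t0 <- as.POSIXct(as.character(d0), tz = AR_TZ)
  # minute grid covers day 1 00:00 through noon after the last night
  n_min <- (cfg$n_days + 1L) * 1440L - 720L
  ts <- t0 + (seq_len(n_min) - 1L) * 60

  regime <- rep("active", n_min)  # per-minute truth label
  night_of <- rep(NA_integer_, n_min)  # which night's rest block a minute is in
  rest_rows <- vector("list", cfg$n_days)
  dose_rows <- vector("list", cfg$n_days)
  rest_start_min <- parse_clock_minutes(cfg$rest_start_mean)
  dose_mean_min <- parse_clock_minutes(cfg$dose_time_mean)

  for (d in seq_len(cfg$n_days)) {
    is_outlier <- d %in% cfg$outlier_days
    onset <- rest_start_min + stats::rnorm(1, 0, cfg$rest_start_sd_min)
    dur <- stats::rnorm(1, cfg$rest_duration_mean_min, cfg$rest_duration_sd_min)
    if (is_outlier && cfg$outlier_disrupt_rest) {
      onset <- onset + 4 * cfg$rest_start_sd_min
      dur <- dur - 4 * cfg$rest_duration_sd_min
    }
    dur <- max(60, min(dur, 1200))
    rs <- t0 + ((d - 1L) * 1440 + onset) * 60
    re <- rs + round(dur) * 60
    rest_rows[[d]] <- data.frame(day = d0 + (d - 1L), rest_start = rs, rest_end = re)
    in_block <- ts >= rs & ts < re
    regime[in_block] <- "rest"
    night_of[in_block] <- d

    # brief awakenings inside the rest block
    n_awake <- stats::rpois(1, cfg$awakening_rate)
    if (n_awake > 0) {
      for (k in seq_len(n_awake)) {
        len <- min(cfg$awakening_max_min,
                   1 + round(stats::rexp(1, 1 / cfg$awakening_mean_min)))
        at <- rs + stats::runif(1, 0, max(1, dur - len)) * 60
        regime[ts >= at & ts < at + len * 60] <- "active"
      }
    }

    # dose event
    took <- stats::runif(1) < cfg$adherence_prob || is_outlier
    if (took) {
      dt <- dose_mean_min + stats::rnorm(1, 0, cfg$dose_time_sd_min)
      if (is_outlier) dt <- dt + cfg$outlier_dose_shift_sd * cfg$dose_time_sd_min
      dose_rows[[d]] <- data.frame(day = d0 + (d - 1L),
                                   dose_time = t0 + ((d - 1L) * 1440 + dt) * 60)
    } else {
      dose_rows[[d]] <- data.frame(day = d0 + (d - 1L),
                                   dose_time = as.POSIXct(NA_character_, tz = AR_TZ))
    }
  }

  # missing spans blank accel + HR
  n_miss <- stats::rpois(1, cfg$missing_span_rate * cfg$n_days)
  if (n_miss > 0) {
    for (k in seq_len(n_miss)) {
      len <- stats::runif(1, cfg$missing_min_min, cfg$missing_max_min)
      at <- t0 + stats::runif(1, 0, n_min - len) * 60
      regime[ts >= at & ts < at + len * 60] <- "missing"
    }
  }

  restless <- !is.na(night_of) &
    ((night_of %in% cfg$outlier_days & cfg$outlier_disrupt_rest) |
       night_of %in% cfg$restless_nights)
  is_rest <- regime == "rest"
  is_active <- regime == "active"
  noise <- cfg$accel_noise_sd_g * ifelse(is_rest & restless, cfg$restless_factor, 1)
  jitter <- cfg$theta_jitter_sd_deg * ifelse(is_rest & restless, cfg$restless_factor, 1)

  # nightly torso orientation: where gravity points in the y-z plane
  day_idx <- as.integer(as.Date(ts, tz = AR_TZ) - d0) + 1L
  phi_night <- stats::runif(cfg$n_days + 1L, 0, 2 * pi)
  phi <- phi_night[pmin(day_idx, cfg$n_days + 1L)]

  n <- n_min
  ax <- ay <- az <- theta <- steps <- numeric(n)
  eps <- matrix(stats::rnorm(3L * n, 0, 1), ncol = 3L) * noise
  # rest: gravity on the y-z unit circle, x quiet, lying posture
  ax[is_rest] <- eps[is_rest, 1L]
  ay[is_rest] <- cos(phi[is_rest]) + eps[is_rest, 2L]
  az[is_rest] <- sin(phi[is_rest]) + eps[is_rest, 3L]
  theta[is_rest] <- abs(stats::rnorm(sum(is_rest), cfg$rest_theta_mean_deg,
                                     jitter[is_rest]))
  # active: gravity mostly longitudinal, larger movement noise, steps
  mov <- 3 * cfg$accel_noise_sd_g + 0.1
  ax[is_active] <- stats::rnorm(sum(is_active), 0.95, mov)
  ay[is_active] <- stats::rnorm(sum(is_active), 0, mov)
  az[is_active] <- stats::rnorm(sum(is_active), 0.2, mov)
  theta[is_active] <- pmin(180, pmax(0, stats::rnorm(
    sum(is_active), cfg$active_theta_mean_deg, 3 * cfg$theta_jitter_sd_deg)))
  steps[is_active] <- stats::rpois(sum(is_active), 12)

  keep <- regime != "missing"
  accel <- data.frame(timestamp = ts[keep], steps = steps[keep],
                      ax = ax[keep], ay = ay[keep], az = az[keep],
                      theta_deg = theta[keep])

  hr_ts <- ts[seq(1L, n, by = 5L)]
  hr_keep <- regime[seq(1L, n, by = 5L)] != "missing"
  hr_rest <- is_rest[seq(1L, n, by = 5L)]
  hr <- data.frame(timestamp = hr_ts[hr_keep],
                   mean_hr = round(stats::rnorm(sum(hr_keep),
                                                ifelse(hr_rest[hr_keep], 58, 76), 4), 1))
  hr$mean_hr <- pmax(30, hr$mean_hr)

  pairing <- empty_pairing()
  if (!is.na(cfg$pairing_clock) && cfg$pairing_minutes > 0) {
    pm <- parse_clock_minutes(cfg$pairing_clock)
    pstart <- t0 + (((seq_len(cfg$n_days) - 1L) * 1440) + pm) * 60
    pairing <- data.frame(start = pstart, end = pstart + cfg$pairing_minutes * 60)
  }

  doses <- do.call(rbind, dose_rows)
  ing <- data.frame(timestamp = doses$dose_time[!is.na(doses$dose_time)])

  stream <- patient_stream(patient_id, accel, hr = hr, pairing = pairing,
                           ingestions = ing)
  truth <- list(rest = do.call(rbind, rest_rows),
                doses = doses,
                minute = data.frame(timestamp = ts, regime = regime),
                outlier_days = d0 + cfg$outlier_days - 1L)
  list(stream = stream, truth = truth, config = cfg)
}

#' Simulate a cohort of patients
#'
#' Per-patient seeds follow a documented counter scheme —
#' `seed_i = master_seed * 1000 + i` — so any patient can be regenerated in
#' isolation from the master seed and its index.
#'
#' @param n_patients cohort size.
#' @param config_fn function `i -> sim_config` supplying each patient's
#'   parameters (its `rng_seed` is overwritten by the counter scheme);
#'   defaults to `sim_config()` for everyone.
#' @param seed master seed.
#' @return list of [simulate_patient()] results, plus an attribute
#'   `manifest`: data.frame of each patient's id, seed and key true
#'   parameters.
#' @export
simulate_cohort <- function(n_patients, config_fn = function(i) sim_config(),
                            seed = 1) {
  stopifnot(n_patients >= 1L)
  out <- vector("list", n_patients)
  manifest <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    cfg <- config_fn(i)
    cfg$rng_seed <- as.integer((seed * 1000 + i) %% 2147483647)
    pid <- sprintf("p%03d", i)
    out[[i]] <- simulate_patient(cfg, patient_id = pid)
    manifest[[i]] <- data.frame(
      patient_id = pid, seed = cfg$rng_seed, n_days = cfg$n_days,
      adherence_prob = cfg$adherence_prob,
      rest_duration_mean_min = cfg$rest_duration_mean_min,
      theta_jitter_sd_deg = cfg$theta_jitter_sd_deg,
      awakening_rate = cfg$awakening_rate)
  }
  names(out) <- vapply(manifest, `[[`, character(1), "patient_id")
  attr(out, "manifest") <- do.call(rbind, manifest)
  out
}
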