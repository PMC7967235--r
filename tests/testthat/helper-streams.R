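# Builders for tiny in-code fixtures.

T0 <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")

# stream of consecutive minute records with given posture angles; rest
# minutes lie flat with gravity on z, upright minutes carry gravity on x
theta_stream <- function(theta, start = T0, id = "t", with_hr = TRUE,
                         steps = 0) {
  n <- length(theta)
  ts <- start + (seq_len(n) - 1L) * 60
  accel <- data.frame(
    timestamp = ts, steps = rep_len(steps, n),
    ax = sin(theta * pi / 180), ay = rep(0, n), az = cos(theta * pi / 180),
    theta_deg = theta
  )
  nh <- if (with_hr) ceiling(n / 5) else 0L
  hr <- data.frame(timestamp = start + (seq_len(nh) - 1L) * 300,
                   mean_hr = rep(60, nh))
  patient_stream(id, accel, hr = hr)
}

# minute block for feature-function tests
feat_block <- function(ax = 0, ay = 0, az = 1, theta = 0, steps = 0, n = 3) {
  data.frame(ax = rep_len(ax, n), ay = rep_len(ay, n), az = rep_len(az, n),
             theta = rep_len(theta, n), steps = rep_len(steps, n))
}
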