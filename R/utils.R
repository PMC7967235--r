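# Internal helpers: timestamp handling, posture-angle canonicalization,
# small numeric utilities shared across modules.

# All timestamps live in one patient-local timezone; we store them as UTC
# POSIXct so day arithmetic is plain (no DST transitions inside a stream).
AR_TZ <- "UTC"

#' Parse ISO 8601 timestamps
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` or the space-separated variant, with optional
#' fractional seconds.  Unparseable entries become `NA` (callers decide whether
#' to drop or error).
#'
#' @param x character vector of timestamps.
#' @return POSIXct vector (UTC).
#' @keywords internal
parse_instant <- function(x) {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = AR_TZ, format = "%Y-%m-%d %H:%M:%OS")
  # date-only fallback (midnight)
  miss <- is.na(out) & !is.na(x)
  if (any(miss)) {
    out[miss] <- as.POSIXct(x[miss], tz = AR_TZ, format = "%Y-%m-%d")
  }
  out
}

format_instant <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = AR_TZ)

#' Parse "HH:MM" clock time to minutes after midnight
#' @keywords internal
parse_clock_minutes <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L || anyNA(suppressWarnings(as.numeric(parts)))) {
    stop("clock time must be 'HH:MM', got '", x, "'", call. = FALSE)
  }
  as.numeric(parts[1L]) * 60 + as.numeric(parts[2L])
}

#' Canonicalize posture angles to [0, 180] with 0 = horizontal/lying
#'
#' The patch reports the body's longitudinal-axis angle from horizontal;
#' devices may emit signed values or values past 180 after calibration flips.
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector in `[0, 180]`.
#' @keywords internal
canonicalize_theta <- function(theta) {
  th <- abs(theta) %% 360
  ifelse(th > 180, 360 - th, th)
}

#' Derive posture angle from the acceleration vector
#'
#' When the input file carries no `theta_deg` column the angle is recovered
#' from gravity: the x axis is approximately aligned with the longitudinal
#' body axis, so theta = |asin(a_x / ||a||)| in degrees.
#'
#' @param ax,ay,az per-minute mean accelerations in g.
#' @return posture angle in degrees, `NA` where the norm is zero.
#' @keywords internal
derive_theta <- function(ax, ay, az) {
  nrm <- sqrt(ax^2 + ay^2 + az^2)
  ratio <- ifelse(nrm > 0, pmin(1, pmax(-1, ax / nrm)), NA_real_)
  abs(asin(ratio)) * 180 / pi
}

# Population (ddof = 0) or sample (ddof = 1) standard deviation.
sd_ddof <- function(x, ddof = 0L) {
  n <- length(x)
  if (n <= ddof) return(NA_real_)
  m <- mean(x)
  sqrt(sum((x - m)^2) / (n - ddof))
}

# Jaccard overlap of two half-open time spans given as c(start, end).
span_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  union <- (a[2] - a[1]) + (b[2] - b[1]) - inter
  if (union <= 0) return(0)
  as.numeric(inter) / as.numeric(union)
}

# FNV-1a hash of a string, hex-encoded; used to stamp outputs with the
# configuration that produced them.  32-bit arithmetic done in doubles with a
# 16-bit split so no intermediate exceeds 2^53.
fnv1a_hash <- function(s) {
  mul32 <- function(h, p) {
    hi <- h %/% 65536
    lo <- h %% 65536
    (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
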