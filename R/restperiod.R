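# Longest rest period detection.
#
# Per day, the longest continuous rest period (LCRP) is the longest run of
# REST intervals containing no ACTIVE or MISSING interval (ties broken by
# earliest start).  Because missing data can artificially shorten it, and a
# single active interval need not end a night's rest, the LCRP is then
# extended into the longest rest period (LRP): from each end, nearby runs of
# consecutive REST intervals are annexed when
#   * the intervening gap is at most `gap_search_intervals` intervals long, and
#   * the gap is all MISSING (no ACTIVE interval), or
#   * the gap contains exactly one ACTIVE interval and the candidate run has
#     at least `min_rescue_run` consecutive REST intervals;
# a gap containing two or more ACTIVE intervals blocks annexation at that
# end.  Each successful annexation restarts the scan from the new end, so the
# period grows to a fixed point.

# states are handled internally as integer codes 1=REST, 2=ACTIVE, 3=MISSING
as_state_code <- function(states) {
  if (is.integer(states)) return(states)
  if (is.numeric(states)) return(as.integer(states))
  code <- match(toupper(substr(as.character(states), 1L, 1L)), c("R", "A", "M"))
  if (anyNA(code)) {
    stop("states must be REST/ACTIVE/MISSING (or R/A/M)", call. = FALSE)
  }
  code
}

#' Longest continuous rest period of a state sequence
#'
#' @param states character (`"REST"/"ACTIVE"/"MISSING"` or `"R"/"A"/"M"`) or
#'   integer codes (1/2/3) for one day's intervals, in order.
#' @return integer `c(first, last)` (1-based, inclusive) of the longest run
#'   of REST intervals, the earliest in case of ties; `NULL` when the day has
#'   no REST interval.
#' @examples
#' find_lcrp(c("R", "R", "R", "A", "R", "R"))
#' find_lcrp(c("A", "M", "A"))
#' @export
find_lcrp <- function(states) {
  st <- as_state_code(states)
  r <- rle(st == 1L)
  if (!any(r$values)) return(NULL)
  ends <- cumsum(r$lengths)
  rest_runs <- which(r$values)
  best <- rest_runs[which.max(r$lengths[rest_runs])]  # which.max: first max = earliest
  c(ends[best] - r$lengths[best] + 1L, ends[best])
}

#' Extend an LCRP into the longest rest period
#'
#' Applies the gap-bridging rules described above iteratively at both ends
#' until neither end can annex a further rest run.  The returned span covers
#' the first through last annexed interval; bridged MISSING/ACTIVE intervals
#' inside it count toward the duration but are not scored for quality.
#'
#' @param states state sequence as in [find_lcrp()].
#' @param lcrp starting run, `c(first, last)`; defaults to the day's LCRP.
#' @param cfg a [rest_config()].  `gap_search_intervals` bounds the gap
#'   length, `min_rescue_run` the one-active rescue; with
#'   `two_active_blocks = FALSE` a two-active gap is treated like the
#'   one-active case (only three or more block).  `single_pass_extension`
#'   limits each end to one annexation.
#' @return an object of class `rest_period`: list with `span` (`c(first,
#'   last)`), `rest_idx` (REST interval indices inside the span),
#'   `n_bridged_active`, `n_bridged_missing`, and the originating `lcrp`;
#'   `NULL` if `lcrp` is `NULL`.
#' @examples
#' extend_lrp(c("R","R","R","R","R","M","M","R","R"))$span
#' extend_lrp(c("R","R","R","R","R","A","R","R","R"))$span  # 3-run not rescued
#' @export
extend_lrp <- function(states, lcrp = find_lcrp(states), cfg = rest_config()) {
  if (is.null(lcrp)) return(NULL)
  st <- as_state_code(states)
  n <- length(st)
  s <- as.integer(lcrp[1L]); e <- as.integer(lcrp[2L])
  if (s < 1L || e > n || s > e || any(st[s:e] != 1L)) {
    stop("lcrp must be a valid all-REST run", call. = FALSE)
  }
  gap_max <- cfg$gap_search_intervals
  min_run <- cfg$min_rescue_run
  block_at <- if (cfg$two_active_blocks) 2L else 3L
  single <- cfg$single_pass_extension

  # one annexation attempt in direction dir (+1 right, -1 left);
  # returns new boundary index or NA when the end is closed
  annex <- function(bound, dir) {
    # locate the first REST interval beyond the boundary
    j <- bound + dir
    gap <- 0L
    while (j >= 1L && j <= n && st[j] != 1L) {
      gap <- gap + 1L
      if (gap > gap_max) return(NA_integer_)
      j <- j + dir
    }
    if (j < 1L || j > n) return(NA_integer_)          # no rest run in reach
    gap_states <- if (gap > 0L) st[seq(bound + dir, by = dir, length.out = gap)] else integer()
    n_active <- sum(gap_states == 2L)
    if (n_active >= block_at) return(NA_integer_)     # active gap blocks this end
    # length of the candidate run of consecutive REST
    k <- j
    while (k + dir >= 1L && k + dir <= n && st[k + dir] == 1L) k <- k + dir
    run_len <- abs(k - j) + 1L
    if (n_active >= 1L && run_len < min_run) return(NA_integer_)
    k
  }

  left_open <- TRUE; right_open <- TRUE
  repeat {
    grew <- FALSE
    if (right_open) {
      new_e <- annex(e, +1L)
      if (is.na(new_e)) right_open <- FALSE
      else { e <- new_e; grew <- TRUE; if (single) right_open <- FALSE }
    }
    if (left_open) {
      new_s <- annex(s, -1L)
      if (is.na(new_s)) left_open <- FALSE
      else { s <- new_s; grew <- TRUE; if (single) left_open <- FALSE }
    }
    if (!grew || (!left_open && !right_open)) break
  }

  inside <- st[s:e]
  structure(
    list(span = c(s, e),
         rest_idx = (s:e)[inside == 1L],
         n_bridged_active = sum(inside == 2L),
         n_bridged_missing = sum(inside == 3L),
         lcrp = c(lcrp[1L], lcrp[2L])),
    class = "rest_period"
  )
}

#' Daily longest rest periods for a classified stream
#'
#' @param grids list of `day_grid` objects from [classify_intervals()].
#' @param cfg a [rest_config()].
#' @return data.frame with one row per day that has at least one REST
#'   interval: `day`, `span_first`, `span_last` (interval indices),
#'   `lrp_start`, `lrp_end` (POSIXct), `duration_min`, `start_min` (minutes
#'   from the day-window start), `n_rest`, `n_bridged_missing`,
#'   `n_bridged_active`, and a list column `rest_iv` of scored REST interval
#'   indices.  Days with no REST interval are omitted.
#' @export
daily_lrps <- function(grids, cfg = rest_config()) {
  rows <- lapply(grids, function(g) {
    lcrp <- find_lcrp(g$state)
    if (is.null(lcrp)) return(NULL)
    rp <- extend_lrp(g$state, lcrp, cfg)
    s <- rp$span[1L]; e <- rp$span[2L]
    lrp_start <- g$start[s]
    data.frame(
      day = g$day_id,
      span_first = s, span_last = e,
      lrp_start = lrp_start,
      lrp_end = g$start[e] + cfg$interval_minutes * 60,
      duration_min = (e - s + 1L) * cfg$interval_minutes,
      start_min = as.numeric(difftime(lrp_start, g$day_start, units = "mins")),
      n_rest = length(rp$rest_idx),
      n_bridged_missing = rp$n_bridged_missing,
      n_bridged_active = rp$n_bridged_active,
      rest_iv = I(list(rp$rest_idx)),
      row.names = NULL
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(day = as.Date(character()), span_first = integer(),
                      span_last = integer(),
                      lrp_start = as.POSIXct(character(), tz = AR_TZ),
                      lrp_end = as.POSIXct(character(), tz = AR_TZ),
                      duration_min = numeric(), start_min = numeric(),
                      n_rest = integer(), n_bridged_missing = integer(),
                      n_bridged_active = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
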