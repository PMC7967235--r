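# Independent oracles for the rest-period algorithm.
#
# oracle_lcrp enumerates every contiguous all-REST span directly;
# oracle_lrp re-implements the extension rules on an rle run table, a
# different code path from the package's boundary-scan implementation.

oracle_lcrp <- function(st) {
  n <- length(st)
  best <- NULL
  best_len <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (st[j] != "R") break
      if (j - i + 1L > best_len) {
        best <- c(i, j)
        best_len <- j - i + 1L
      }
    }
  }
  best
}

oracle_lrp <- function(st, gap_max = 5L, min_run = 4L, block_at = 2L) {
  lcrp <- oracle_lcrp(st)
  if (is.null(lcrp)) return(NULL)
  r <- rle(st)
  re <- cumsum(r$lengths)
  rs <- re - r$lengths + 1L
  val <- r$values
  nr <- length(val)
  cur_lo <- which(rs <= lcrp[1L] & re >= lcrp[1L])
  cur_hi <- cur_lo
  # cand_run is the run being annexed; the >= min_run rescue applies to it
  annexable <- function(from_run, to_run, cand_run) {
    gap_len <- rs[to_run] - re[from_run] - 1L
    if (gap_len < 1L) return(TRUE)
    gap <- st[(re[from_run] + 1L):(rs[to_run] - 1L)]
    if (length(gap) > gap_max) return(FALSE)
    n_act <- sum(gap == "A")
    if (n_act >= block_at) return(FALSE)
    if (n_act >= 1L && (re[cand_run] - rs[cand_run] + 1L) < min_run) return(FALSE)
    TRUE
  }
  right_ok <- TRUE
  left_ok <- TRUE
  repeat {
    grew <- FALSE
    if (right_ok) {
      j <- cur_hi + 1L
      while (j <= nr && val[j] != "R") j <- j + 1L
      if (j > nr || rs[j] - re[cur_hi] - 1L > gap_max ||
          !annexable(cur_hi, j, j)) {
        right_ok <- FALSE
      } else {
        cur_hi <- j
        grew <- TRUE
      }
    }
    if (left_ok) {
      j <- cur_lo - 1L
      while (j >= 1L && val[j] != "R") j <- j - 1L
      if (j < 1L || rs[cur_lo] - re[j] - 1L > gap_max ||
          !annexable(j, cur_lo, j)) {
        left_ok <- FALSE
      } else {
        cur_lo <- j
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  unname(c(rs[cur_lo], re[cur_hi]))
}

# random state sequence, REST-heavy enough to exercise the extension rules
random_states <- function(n, p = c(R = 0.4, A = 0.3, M = 0.3)) {
  sample(c("R", "A", "M"), n, replace = TRUE, prob = p)
}

lrp_span <- function(states, cfg = rest_config()) {
  rp <- extend_lrp(states, cfg = cfg)
  if (is.null(rp)) NULL else rp$span
}
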