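# Rule-based gait event detection on the filtered shank gyro channel.
#
# Detection order per gait cycle: the mid-swing peak (MSW) is the maximum
# between an upward and the paired downward crossing of the swing
# threshold; mid-stance (MS) is the first near-zero, near-constant sample
# after an MSW; heel-strike (HS) is the minimum between an MSW and its MS;
# toe-off (TO) is the minimum between an MS and the next MSW.

#' Find matched threshold crossings
#'
#' Returns the start index of every maximal run where the signal rises
#' from below `threshold` to at or above it (`rising`), paired with the
#' index where it first returns below (`falling`). Unpaired leading
#' falling or trailing rising crossings are discarded.
#'
#' @param gyro Numeric series (deg/s).
#' @param threshold Positive crossing level (deg/s).
#' @return List with integer vectors `rising` and `falling`, equal length.
#' @export
find_threshold_crossings <- function(gyro, threshold) {
  stopifnot(length(gyro) >= 2, threshold > 0)
  above <- gyro >= threshold
  d <- diff(above)
  rising <- which(d == 1) + 1L   # first index at/above threshold
  falling <- which(d == -1) + 1L # first index back below
  # pair in order: each rising with the first later falling
  if (length(falling) && length(rising) && falling[1] < rising[1]) {
    falling <- falling[falling > rising[1]]
  }
  k <- min(length(rising), length(falling))
  list(rising = rising[seq_len(k)], falling = falling[seq_len(k)])
}

#' Detect mid-swing peaks
#'
#' One MSW per matched crossing pair: the argmax of the gyro on
#' `[rising_i, falling_i]`, ties broken to the earliest index.
#'
#' @param gyro Numeric series.
#' @param rising,falling Matched crossing indices from
#'   [find_threshold_crossings()].
#' @return Integer vector of MSW indices.
#' @export
detect_msw <- function(gyro, rising, falling) {
  stopifnot(length(rising) == length(falling))
  if (!length(rising)) return(integer(0))
  vapply(seq_along(rising), function(i) {
    seg <- rising[i]:falling[i]
    seg[which.max(gyro[seg])]
  }, integer(1))
}

#' Detect mid-stance points
#'
#' For each MSW, MS is the first index `j` strictly after it (and before
#' the next MSW, or the record end for the last one) with
#' `|gyro[j]| <= ms_band` and backward difference
#' `|gyro[j] - gyro[j-1]| < ms_diff_threshold`. A cycle with no
#' qualifying sample yields `NA` and is dropped downstream.
#'
#' @param gyro Numeric series.
#' @param msw MSW indices.
#' @param cfg A [pipeline_config()].
#' @return Integer vector, same length as `msw`, `NA` where no MS found.
#' @export
detect_ms <- function(gyro, msw, cfg = pipeline_config()) {
  stopifnot(length(msw) >= 1)
  n <- length(gyro)
  vapply(seq_along(msw), function(k) {
    lo <- msw[k] + 1L
    hi <- if (k < length(msw)) msw[k + 1] - 1L else n
    if (lo > hi || lo < 2L) return(NA_integer_)
    j <- lo:hi
    ok <- abs(gyro[j]) <= cfg$ms_band &
      abs(gyro[j] - gyro[j - 1L]) < cfg$ms_diff_threshold
    if (!any(ok)) NA_integer_ else j[which(ok)[1]]
  }, integer(1))
}

#' Detect heel strikes
#'
#' HS is the minimum of the gyro strictly between each MSW and its MS
#' (earliest index on ties).
#'
#' @param gyro Numeric series.
#' @param msw,ms Paired MSW and MS indices (`ms` may contain `NA`).
#' @return Integer vector, `NA` where `ms` is `NA`.
#' @export
detect_hs <- function(gyro, msw, ms) {
  stopifnot(length(msw) == length(ms))
  vapply(seq_along(msw), function(k) {
    if (is.na(ms[k]) || ms[k] - msw[k] < 2L) return(NA_integer_)
    seg <- (msw[k] + 1L):(ms[k] - 1L)
    seg[which.min(gyro[seg])]
  }, integer(1))
}

#' Detect toe offs
#'
#' TO is the minimum of the gyro strictly between each MS and the next
#' MSW (earliest index on ties). The last cycle has no following MSW and
#' yields `NA`.
#'
#' @param gyro Numeric series.
#' @param ms MS indices (may contain `NA`).
#' @param msw MSW indices, same length.
#' @return Integer vector, `NA` for the last cycle or missing MS.
#' @export
detect_to <- function(gyro, ms, msw) {
  stopifnot(length(msw) == length(ms))
  vapply(seq_along(ms), function(k) {
    if (k == length(ms) || is.na(ms[k])) return(NA_integer_)
    if (msw[k + 1] - ms[k] < 2L) return(NA_integer_)
    seg <- (ms[k] + 1L):(msw[k + 1] - 1L)
    seg[which.min(gyro[seg])]
  }, integer(1))
}

#' Rule-based gait event detection
#'
#' Composes the four detectors on the (already filtered) gyro channel and
#' keeps only cycles whose events are complete and correctly ordered
#' (`MSW_k < HS_k < MS_k < TO_k < MSW_(k+1)`; the final cycle keeps its
#' HS/MS without a TO, closing the last stride).
#'
#' @param rec A [foot_recording()] (apply [lowpass_filter()] first).
#' @param cfg A [pipeline_config()].
#' @return An object of class `gait_events`: integer vectors `rising`,
#'   `falling`, `msw`, `hs`, `ms`, `to` (per retained cycle; `to` is `NA`
#'   for the final cycle), `cycle` (original cycle number, for adjacency),
#'   and the `time` vector they index into.
#' @export
#' @examples
#' walk <- synth_walk(gait_params(n_strides = 6, seed = 1))
#' ev <- detect_events(lowpass_filter(walk$left))
#' ev
detect_events <- function(rec, cfg = pipeline_config()) {
  g <- rec$gyro
  cr <- find_threshold_crossings(g, cfg$msw_threshold)
  if (!length(cr$rising)) stop_no_strides("no swing peaks above threshold")
  msw <- detect_msw(g, cr$rising, cr$falling)
  ms <- detect_ms(g, msw, cfg)
  hs <- detect_hs(g, msw, ms)
  to <- detect_to(g, ms, msw)

  ok <- !is.na(ms) & !is.na(hs) & msw < hs & hs < ms
  # a TO, when present, must fall between its MS and the next MSW
  ok_to <- is.na(to) | (ms < to)
  keep <- ok & ok_to
  if (sum(keep) < 2) stop_no_strides("fewer than 2 complete heel strikes detected")
  structure(
    list(
      rising = cr$rising, falling = cr$falling,
      msw = msw[keep], hs = hs[keep], ms = ms[keep], to = to[keep],
      cycle = which(keep), time = rec$time
    ),
    class = "gait_events"
  )
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d cycles (%d with toe-off)\n",
              length(x$hs), sum(!is.na(x$to))))
  invisible(x)
}

#' Per-stride stance fraction from detected events
#'
#' Stance fraction of each complete stride, `(TO - HS) / (HS' - HS)`,
#' where `HS'` is the closing heel strike. Canonically about 0.60 in
#' normal gait.
#'
#' @param ev A `gait_events` object.
#' @return Numeric vector, one value per complete stride.
#' @export
stance_fractions <- function(ev) {
  stopifnot(inherits(ev, "gait_events"))
  out <- numeric(0)
  for (j in seq_len(length(ev$hs) - 1L)) {
    if (ev$cycle[j + 1] != ev$cycle[j] + 1L || is.na(ev$to[j])) next
    t0 <- ev$time[ev$hs[j]]; t1 <- ev$time[ev$hs[j + 1]]
    out <- c(out, (ev$time[ev$to[j]] - t0) / (t1 - t0))
  }
  out
}

#' Tabulate detected events with times
#'
#' @param ev A `gait_events` object.
#' @return A data.frame with one row per retained cycle and columns
#'   `cycle`, `msw`, `hs`, `ms`, `to` (indices) plus `*_time` columns in
#'   seconds.
#' @export
events_table <- function(ev) {
  stopifnot(inherits(ev, "gait_events"))
  idx_time <- function(i) ifelse(is.na(i), NA_real_, ev$time[i])
  data.frame(
    cycle = ev$cycle, msw = ev$msw, hs = ev$hs, ms = ev$ms, to = ev$to,
    msw_time = idx_time(ev$msw), hs_time = idx_time(ev$hs),
    ms_time = idx_time(ev$ms), to_time = idx_time(ev$to)
  )
}
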