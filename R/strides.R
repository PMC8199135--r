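# HS-to-HS stride extraction, 0-100% cycle resampling (PCHIP), averaging,
# z-standardization and gyro+pressure superposition.

#' Extract HS-to-HS stride segments
#'
#' One segment per pair of consecutive retained cycles whose opening cycle
#' has a toe-off. Segments are half-open at the sample level (consecutive
#' strides share no samples) but keep the closing heel-strike sample as the
#' right interpolation endpoint.
#'
#' @param rec A [foot_recording()].
#' @param ev A `gait_events` object from [detect_events()] on the same
#'   recording.
#' @param channel `"gyro"` or `"pressure"`.
#' @return List of `stride_segment` objects with fields `channel`,
#'   `samples`, `rel_pos` (0-1 position of each sample in the stride),
#'   `duration` (s), `swing_duration` (s) and, for gyro,
#'   `max_angular_velocity` (deg/s).
#' @export
extract_strides <- function(rec, ev, channel = c("gyro", "pressure")) {
  channel <- match.arg(channel)
  if (is.null(rec[[channel]])) stop_channel(paste("no channel", channel))
  if (length(ev$hs) < 2) stop_no_strides("need at least 2 heel strikes")
  vals <- rec[[channel]]
  out <- list()
  for (j in seq_len(length(ev$hs) - 1L)) {
    if (ev$cycle[j + 1] != ev$cycle[j] + 1L) next  # dropped cycle in between
    if (is.na(ev$to[j])) next
    i0 <- ev$hs[j]; i1 <- ev$hs[j + 1]
    t0 <- rec$time[i0]; t1 <- rec$time[i1]
    idx <- i0:i1
    seg <- structure(
      list(
        channel = channel,
        samples = vals[idx],
        rel_pos = (rec$time[idx] - t0) / (t1 - t0),
        duration = t1 - t0,
        swing_duration = t1 - rec$time[ev$to[j]]
      ),
      class = "stride_segment"
    )
    if (channel == "gyro") seg$max_angular_velocity <- max(seg$samples)
    out[[length(out) + 1L]] <- seg
  }
  if (!length(out)) stop_no_strides("no complete stride segments")
  out
}

#' Resample a stride onto the 0-100% gait-cycle grid
#'
#' Shape-preserving piecewise cubic Hermite (PCHIP) interpolation onto `n`
#' equally spaced cycle points; endpoints are reproduced exactly and the
#' interpolant does not overshoot local extrema of the data.
#'
#' @param seg A `stride_segment` from [extract_strides()].
#' @param n Number of grid points (>= 3).
#' @return A `normalized_stride` with fields `grid` (percent, 0-100) and
#'   `values`.
#' @export
resample_stride <- function(seg, n = 101) {
  if (n < 3) stop_config("resample_points must be >= 3")
  stopifnot(length(seg$samples) >= 2)
  grid <- seq(0, 100, length.out = n)
  values <- pracma::pchip(seg$rel_pos * 100, seg$samples, grid)
  structure(list(grid = grid, values = values), class = "normalized_stride")
}

#' Pointwise mean of normalized strides
#'
#' @param strides Non-empty list of `normalized_stride` objects on the
#'   same grid.
#' @return A `normalized_stride`.
#' @export
mean_stride <- function(strides) {
  if (!length(strides)) stop_no_strides("empty stride list")
  g <- strides[[1]]$grid
  for (s in strides) {
    if (length(s$grid) != length(g) || max(abs(s$grid - g)) > 1e-9) {
      stop_grid("strides are not on a common grid")
    }
  }
  m <- rowMeans(vapply(strides, `[[`, numeric(length(g)), "values"))
  structure(list(grid = g, values = m), class = "normalized_stride")
}

#' Z-score standardization
#'
#' `Z = (X - mu) / sigma` with the population (divide-by-N) standard
#' deviation, giving mean 0 and unit variance so heterogeneous channels
#' can be superposed.
#'
#' @param w A `normalized_stride`.
#' @return A standardized `normalized_stride`.
#' @export
standardize <- function(w) {
  x <- w$values
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) stop_degenerate("cannot standardize a constant signal")
  w$values <- (x - mu) / sigma
  w
}

#' Superpose standardized gyro and pressure strides
#'
#' @param gyro_std,pressure_std Standardized `normalized_stride`s on the
#'   same grid.
#' @param side `"left"` or `"right"`.
#' @param n_strides Number of strides averaged upstream.
#' @return A `fused_stride`: `grid`, `values` (elementwise sum), `side`,
#'   `n_strides`.
#' @export
fuse <- function(gyro_std, pressure_std, side = c("left", "right"),
                 n_strides = NA_integer_) {
  side <- match.arg(side)
  if (length(gyro_std$grid) != length(pressure_std$grid) ||
      max(abs(gyro_std$grid - pressure_std$grid)) > 1e-9) {
    stop_grid("gyro and pressure strides are on different grids")
  }
  structure(
    list(grid = gyro_std$grid,
         values = gyro_std$values + pressure_std$values,
         side = side, n_strides = as.integer(n_strides)),
    class = "fused_stride"
  )
}

#' @export
print.fused_stride <- function(x, ...) {
  cat(sprintf("<fused_stride> %s foot, %d strides averaged, %d grid points\n",
              x$side, x$n_strides, length(x$grid)))
  invisible(x)
}

#' Full per-foot pipeline: filter, detect, extract, resample, fuse
#'
#' Runs the complete per-foot processing chain: zero-phase low-pass filter
#' of the gyro, rule-based event detection, HS-to-HS extraction of both
#' channels (pressure is cut with the gyro-derived events), PCHIP
#' resampling to the cycle grid, per-channel averaging over strides,
#' standardization of each mean channel and superposition.
#'
#' @param rec A [foot_recording()].
#' @param cfg A [pipeline_config()].
#' @return A `fused_stride`.
#' @export
#' @examples
#' walk <- synth_walk(gait_params(n_strides = 6, seed = 2))
#' fs <- build_fused_stride(walk$left)
#' round(range(fs$values), 2)
build_fused_stride <- function(rec, cfg = pipeline_config()) {
  filt <- lowpass_filter(rec, cfg)
  ev <- detect_events(filt, cfg)
  n <- cfg$resample_points
  gyro_segs <- extract_strides(filt, ev, "gyro")
  pres_segs <- extract_strides(filt, ev, "pressure")
  gyro_mean <- standardize(mean_stride(lapply(gyro_segs, resample_stride, n = n)))
  pres_mean <- standardize(mean_stride(lapply(pres_segs, resample_stride, n = n)))
  fuse(gyro_mean, pres_mean, rec$side, n_strides = length(gyro_segs))
}
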