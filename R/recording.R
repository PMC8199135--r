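#' Per-foot sensor recording
#'
#' Container for one foot's synchronized gyroscope and pressure time
#' series. The gyro channel is the x-axis (sagittal-plane) angular velocity
#' of the shank in deg/s; the pressure channel is the single heel/forefoot
#' voltage-divider signal after removal of the half-supply offset, so that
#' heel load is negative, forefoot load positive and swing exactly zero.
#'
#' @param time Numeric vector of sample times in seconds, strictly
#'   increasing with a uniform step.
#' @param gyro Numeric vector, angular velocity in deg/s.
#' @param pressure Numeric vector, offset-removed pressure in arbitrary
#'   units.
#' @param side `"left"` or `"right"`.
#' @return An object of class `foot_recording` with fields `side`, `time`,
#'   `gyro`, `pressure` and inferred `rate` (Hz).
#' @export
#' @examples
#' rec <- foot_recording(seq(0, 1, by = 0.01), sin(seq(0, 1, by = 0.01)),
#'                       numeric(101), "left")
#' rec$rate
foot_recording <- function(time, gyro, pressure, side = c("left", "right")) {
  side <- match.arg(side)
  n <- length(time)
  if (n < 2) stop_empty_recording("recording needs at least 2 samples")
  if (length(gyro) != n || length(pressure) != n) {
    stop_format("time, gyro and pressure must have equal length")
  }
  if (anyNA(time) || anyNA(gyro) || anyNA(pressure)) {
    stop_format("recording channels must not contain NA")
  }
  steps <- diff(time)
  if (any(steps <= 0)) stop_sampling("time must be strictly increasing")
  step <- steps[1]
  if (max(abs(steps - step)) > 1e-9) {
    stop_sampling("sampling step is not uniform to within 1e-9 s")
  }
  structure(
    list(
      side = side,
      time = as.numeric(time),
      gyro = as.numeric(gyro),
      pressure = as.numeric(pressure),
      rate = 1 / step
    ),
    class = "foot_recording"
  )
}

#' Two-foot walk container
#'
#' @param left,right `foot_recording` objects for each foot; they must
#'   share the sampling rate and overlap in time.
#' @param label Free-text condition label (e.g. `"symmetric"`).
#' @return An object of class `walk_recording`.
#' @export
walk_recording <- function(left, right, label = "") {
  stopifnot(inherits(left, "foot_recording"), inherits(right, "foot_recording"))
  if (abs(left$rate - right$rate) > 1e-6) {
    stop_format("both feet must share the same sampling rate")
  }
  if (min(left$time) > max(right$time) || min(right$time) > max(left$time)) {
    stop_format("left and right recordings do not overlap in time")
  }
  structure(list(left = left, right = right, label = label),
            class = "walk_recording")
}

#' @export
print.foot_recording <- function(x, ...) {
  cat(sprintf("<foot_recording> %s foot: %d samples @ %.6g Hz, %.2f s\n",
              x$side, length(x$time), x$rate,
              x$time[length(x$time)] - x$time[1]))
  invisible(x)
}

#' @export
print.walk_recording <- function(x, ...) {
  cat(sprintf("<walk_recording> '%s'\n", x$label))
  print(x$left); print(x$right)
  invisible(x)
}

REC_COLUMNS <- c("time_s", "gyro_dps", "pressure_au")

#' Read a per-foot recording from CSV
#'
#' The file must have a single header row with columns `time_s`,
#' `gyro_dps`, `pressure_au` (comma separated, `.` decimal, UTF-8).
#'
#' @param path CSV file path.
#' @param side `"left"` or `"right"`.
#' @return A [foot_recording()].
#' @export
read_recording <- function(path, side = c("left", "right")) {
  side <- match.arg(side)
  if (!file.exists(path)) stop_format(paste("no such file:", path))
  df <- read.csv(path, header = TRUE)
  missing <- setdiff(REC_COLUMNS, names(df))
  if (length(missing)) {
    stop_format(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  for (cl in REC_COLUMNS) {
    if (!is.numeric(df[[cl]])) stop_format(paste("non-numeric column:", cl))
  }
  foot_recording(df$time_s, df$gyro_dps, df$pressure_au, side)
}

#' Write a per-foot recording to CSV
#'
#' Full double precision is preserved (17 significant digits), so
#' `read_recording(write_recording(rec))` round-trips bit-exactly.
#'
#' @param rec A [foot_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "foot_recording")) {
    stop_empty_recording("rec must be a foot_recording")
  }
  df <- data.frame(
    time_s = sprintf("%.17g", rec$time),
    gyro_dps = sprintf("%.17g", rec$gyro),
    pressure_au = sprintf("%.17g", rec$pressure)
  )
  tryCatch(
    write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop(gait_error("gaitdtw_io_error", conditionMessage(e)))
  )
  invisible(path)
}

#' Zero-phase low-pass filter of the gyro channel
#'
#' Applies a Butterworth low-pass (order and cutoff from `cfg`)
#' forward-backward so event locations are not phase shifted. The signal is
#' extended by odd reflection at both ends before filtering and trimmed
#' afterwards, which suppresses the start-up transient of the direct-form
#' filter on signals with a nonzero initial value. Pressure and time are
#' untouched.
#'
#' @param rec A [foot_recording()].
#' @param cfg A [pipeline_config()].
#' @return A new `foot_recording` with the filtered gyro channel.
#' @export
lowpass_filter <- function(rec, cfg = pipeline_config()) {
  nyq <- rec$rate / 2
  if (cfg$filter_cutoff >= nyq) {
    stop_config(sprintf("filter cutoff %.3g Hz >= Nyquist %.3g Hz",
                        cfg$filter_cutoff, nyq))
  }
  bf <- signal::butter(cfg$filter_order, cfg$filter_cutoff / nyq)
  x <- rec$gyro
  n <- length(x)
  npad <- min(n - 1L, 100L)
  if (npad > 0) {
    head_pad <- 2 * x[1] - x[(npad + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
    xx <- c(head_pad, x, tail_pad)
  } else {
    xx <- x
  }
  y <- signal::filtfilt(bf, xx)
  rec$gyro <- y[(npad + 1):(npad + n)]
  rec
}

#' Voltage-divider pressure model and offset removal
#'
#' Two force-sensing resistors (heel and forefoot) form a voltage divider
#' fed with `vin` volts; with both sensors unloaded the output sits at
#' `vin / 2`. `pressure_to_voltage()` maps an offset-removed pressure
#' signal (arbitrary units, zero in swing) onto this raw scale and
#' `remove_pressure_offset()` undoes it, the convention used during data
#' acquisition.
#'
#' @param pressure Offset-removed pressure signal (a.u.).
#' @param voltage Raw divider output (V).
#' @param vin Divider supply voltage (V), default 5.
#' @return The converted signal.
#' @export
pressure_to_voltage <- function(pressure, vin = 5) vin / 2 + pressure

#' @rdname pressure_to_voltage
#' @export
remove_pressure_offset <- function(voltage, vin = 5) voltage - vin / 2
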