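#' Pipeline configuration
#'
#' Holds every tunable parameter of the analysis pipeline. Defaults follow
#' the rule-based detector's published thresholds (mid-swing peak threshold
#' 5 deg/s; mid-stance band +/- 1.5 deg/s with a 0.25 deg/s
#' sample-to-sample difference threshold) and the package's own choices
#' where the method leaves a parameter open (4th-order zero-phase
#' Butterworth low-pass at 10 Hz before detection; 101-point 0-100% cycle
#' grid; squared-difference DTW local cost; left foot as symmetry-index
#' numerator).
#'
#' @param msw_threshold Mid-swing detection threshold on angular velocity
#'   (deg/s). Swing peaks are searched between upward/downward crossings of
#'   this level.
#' @param ms_band Half-width of the near-zero band used for mid-stance
#'   (deg/s).
#' @param ms_diff_threshold Maximum absolute backward difference
#'   `|x[j] - x[j-1]|` (deg/s) for a sample to qualify as mid-stance.
#' @param filter_cutoff Low-pass cutoff frequency (Hz) applied to the gyro
#'   channel before detection.
#' @param filter_order Butterworth filter order.
#' @param resample_points Number of equally spaced points on the 0-100%
#'   gait-cycle grid (must be >= 3).
#' @param dtw_local_cost `"squared"` (default) or `"absolute"` local cost.
#' @param si_form Symmetry-index form; only `"log_ratio_x100"` is defined.
#' @param si_numerator Which side goes in the log-ratio numerator,
#'   `"left"` or `"right"`.
#' @return An object of class `pipeline_config` (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$msw_threshold
pipeline_config <- function(msw_threshold = 5,
                            ms_band = 1.5,
                            ms_diff_threshold = 0.25,
                            filter_cutoff = 10,
                            filter_order = 4,
                            resample_points = 101,
                            dtw_local_cost = c("squared", "absolute"),
                            si_form = "log_ratio_x100",
                            si_numerator = c("left", "right")) {
  dtw_local_cost <- match.arg(dtw_local_cost)
  si_numerator <- match.arg(si_numerator)
  if (!identical(si_form, "log_ratio_x100")) {
    stop_config("si_form must be 'log_ratio_x100'")
  }
  if (!(msw_threshold > ms_band && ms_band > ms_diff_threshold &&
        ms_diff_threshold > 0)) {
    stop_config("need msw_threshold > ms_band > ms_diff_threshold > 0")
  }
  if (resample_points < 3) stop_config("resample_points must be >= 3")
  if (filter_cutoff <= 0 || filter_order < 1) {
    stop_config("filter_cutoff must be > 0 and filter_order >= 1")
  }
  structure(
    list(
      msw_threshold = msw_threshold,
      ms_band = ms_band,
      ms_diff_threshold = ms_diff_threshold,
      filter_cutoff = filter_cutoff,
      filter_order = filter_order,
      resample_points = as.integer(resample_points),
      dtw_local_cost = dtw_local_cost,
      si_form = si_form,
      si_numerator = si_numerator
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Any field omitted from the file keeps its default, so a config file is
#' optional everywhere one is accepted.
#'
#' @param path Path to a YAML file whose keys match [pipeline_config()]
#'   arguments, or `NULL` for all defaults.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  if (!file.exists(path)) stop_config(paste("config file not found:", path))
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop_config("config file must be a YAML mapping")
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop_config(paste("unknown config keys:", paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
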