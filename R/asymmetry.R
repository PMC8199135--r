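# Per-walk asymmetry metrics (three classical log-ratio symmetry indices
# plus the DTW distance between fused mean strides) and Mann-Whitney
# comparison of walk groups.

#' Log-ratio symmetry index
#'
#' `100 * ln(numerator / denominator)` for a positive scalar gait
#' parameter measured on each foot. Zero for perfect symmetry; swapping
#' the feet negates the index.
#'
#' @param left_value,right_value Positive per-foot values.
#' @param cfg A [pipeline_config()]; `cfg$si_numerator` selects the
#'   numerator side.
#' @return Dimensionless index.
#' @export
#' @examples
#' symmetry_index(2, 1)  # 100 * log(2) = 69.31
symmetry_index <- function(left_value, right_value, cfg = pipeline_config()) {
  if (left_value <= 0 || right_value <= 0) {
    stop_domain("symmetry index requires positive values")
  }
  if (cfg$si_numerator == "left") {
    100 * log(left_value / right_value)
  } else {
    100 * log(right_value / left_value)
  }
}

#' Per-walk asymmetry metrics
#'
#' Computes, for one walk, the three classical symmetry indices (mean
#' stride duration, mean swing duration, mean per-stride maximum angular
#' velocity, each per foot, then the 100*log ratio) and the DTW distance
#' between the left and right fused mean strides. All four are exactly 0
#' when the two recordings are identical.
#'
#' @param walk A [walk_recording()].
#' @param cfg A [pipeline_config()].
#' @return A `walk_metrics` object: `stride_duration_si`,
#'   `swing_duration_si`, `max_angular_velocity_si`, `dtw_distance`.
#' @export
walk_metrics <- function(walk, cfg = pipeline_config()) {
  stopifnot(inherits(walk, "walk_recording"))
  per_foot <- function(rec) {
    filt <- lowpass_filter(rec, cfg)
    ev <- detect_events(filt, cfg)
    segs <- extract_strides(filt, ev, "gyro")
    list(
      stride = mean(vapply(segs, `[[`, numeric(1), "duration")),
      swing = mean(vapply(segs, `[[`, numeric(1), "swing_duration")),
      maxav = mean(vapply(segs, `[[`, numeric(1), "max_angular_velocity")),
      fused = {
        pres <- extract_strides(filt, ev, "pressure")
        n <- cfg$resample_points
        g <- standardize(mean_stride(lapply(segs, resample_stride, n = n)))
        p <- standardize(mean_stride(lapply(pres, resample_stride, n = n)))
        fuse(g, p, rec$side, length(segs))
      }
    )
  }
  L <- per_foot(walk$left)
  R <- per_foot(walk$right)
  structure(
    list(
      stride_duration_si = symmetry_index(L$stride, R$stride, cfg),
      swing_duration_si = symmetry_index(L$swing, R$swing, cfg),
      max_angular_velocity_si = symmetry_index(L$maxav, R$maxav, cfg),
      dtw_distance = dtw_distance(L$fused, R$fused, cfg$dtw_local_cost)
    ),
    class = "walk_metrics"
  )
}

#' @export
print.walk_metrics <- function(x, ...) {
  cat("<walk_metrics>\n")
  cat(sprintf("  stride duration SI         %8.3f\n", x$stride_duration_si))
  cat(sprintf("  swing duration SI          %8.3f\n", x$swing_duration_si))
  cat(sprintf("  max angular velocity SI    %8.3f\n", x$max_angular_velocity_si))
  cat(sprintf("  DTW distance               %8.3f\n", x$dtw_distance))
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two samples
#'
#' Two-sided rank-sum test: exact enumeration when both samples have at
#' most 10 untied observations, normal approximation with tie and
#' continuity correction otherwise. If every observation in both groups is
#' identical there is no separation and p = 1 by convention.
#'
#' @param a,b Nonempty numeric vectors.
#' @param metric Optional metric name carried into the result.
#' @return A `group_comparison`: `metric`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `u` (Mann-Whitney U for group `a`), `p_value`.
#' @export
mann_whitney_u <- function(a, b, metric = "") {
  if (!length(a) || !length(b)) stop_empty_group("empty group")
  ties <- any(duplicated(c(a, b)))
  if (length(unique(c(a, b))) == 1L) {
    u <- length(a) * length(b) / 2
    p <- 1
  } else {
    exact <- length(a) <= 10 && length(b) <= 10 && !ties
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    u <- unname(wt$statistic)
    p <- wt$p.value
  }
  structure(
    list(metric = metric,
         mean_a = mean(a), sd_a = stats::sd(a),
         mean_b = mean(b), sd_b = stats::sd(b),
         u = u, p_value = p),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%-24s %8.2f +/- %-8.2f %8.2f +/- %-8.2f U=%-6g p=%.4g\n",
              x$metric, x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$u, x$p_value))
  invisible(x)
}

METRIC_NAMES <- c("stride_duration_si", "swing_duration_si",
                  "max_angular_velocity_si", "dtw_distance")

#' Metrics for a list of walks
#'
#' @param walks List of [walk_recording()]s.
#' @param cfg A [pipeline_config()].
#' @return A data.frame with one row per walk and one column per metric.
#' @export
cohort_metrics <- function(walks, cfg = pipeline_config()) {
  if (!length(walks)) stop_empty_group("no walks")
  rows <- lapply(walks, function(w) {
    m <- walk_metrics(w, cfg)
    as.data.frame(m[METRIC_NAMES])
  })
  do.call(rbind, rows)
}

#' Compare two groups of walks on every asymmetry metric
#'
#' Produces the standard results-table shape: per-metric mean and standard
#' deviation in each condition plus a two-sided Mann-Whitney p-value.
#'
#' @param symmetric_walks,asymmetric_walks Lists of [walk_recording()]s
#'   (at least 2 each for a meaningful sd).
#' @param cfg A [pipeline_config()].
#' @return List of `group_comparison` objects, one per metric, named by
#'   metric.
#' @export
compare_groups <- function(symmetric_walks, asymmetric_walks,
                           cfg = pipeline_config()) {
  ma <- cohort_metrics(symmetric_walks, cfg)
  mb <- cohort_metrics(asymmetric_walks, cfg)
  out <- lapply(METRIC_NAMES, function(nm) {
    mann_whitney_u(ma[[nm]], mb[[nm]], metric = nm)
  })
  names(out) <- METRIC_NAMES
  out
}
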