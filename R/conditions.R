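# Classed conditions so callers can distinguish failure modes.
# All inherit from "gaitdtw_error".

gait_error <- function(class, message, call = sys.call(-1)) {
  structure(
    class = c(class, "gaitdtw_error", "error", "condition"),
    list(message = message, call = call)
  )
}

stop_format <- function(msg) stop(gait_error("gaitdtw_format_error", msg))
stop_sampling <- function(msg) stop(gait_error("gaitdtw_sampling_error", msg))
stop_empty_recording <- function(msg) stop(gait_error("gaitdtw_empty_recording_error", msg))
stop_config <- function(msg) stop(gait_error("gaitdtw_config_error", msg))
stop_no_strides <- function(msg) stop(gait_error("gaitdtw_no_strides_error", msg))
stop_channel <- function(msg) stop(gait_error("gaitdtw_channel_error", msg))
stop_degenerate <- function(msg) stop(gait_error("gaitdtw_degenerate_signal_error", msg))
stop_grid <- function(msg) stop(gait_error("gaitdtw_grid_error", msg))
stop_empty_sequence <- function(msg) stop(gait_error("gaitdtw_empty_sequence_error", msg))
stop_domain <- function(msg) stop(gait_error("gaitdtw_domain_error", msg))
stop_empty_group <- function(msg) stop(gait_error("gaitdtw_empty_group_error", msg))
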