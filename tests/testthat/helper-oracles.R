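# Independent test oracles, kept deliberately naive.

# Exhaustive minimum over all monotone warp paths from (i, j) to (m, n):
# plain tree recursion, no dynamic programming, feasible for m * n <= 64.
dtw_brute <- function(x, y, kind = "squared") {
  m <- length(x); n <- length(y)
  d <- function(i, j) if (kind == "squared") (x[i] - y[j])^2 else abs(x[i] - y[j])
  rec <- function(i, j) {
    if (i == m && j == n) return(d(i, j))
    best <- Inf
    if (i < m) best <- min(best, rec(i + 1, j))
    if (j < n) best <- min(best, rec(i, j + 1))
    if (i < m && j < n) best <- min(best, rec(i + 1, j + 1))
    d(i, j) + best
  }
  rec(1, 1)
}

# sum of local costs along an explicit warp path
path_cost <- function(x, y, path, kind = "squared") {
  sum(local_cost(x[path[, "i"]], y[path[, "j"]], kind))
}

# default small synthetic walk used across tests
quiet_params <- function(...) {
  gait_params(noise_sd_gyro = 0, noise_sd_pressure = 0, stride_jitter_sd = 0,
              amp_jitter_sd = 0, ...)
}

# match each planted time to the nearest detected time; TRUE if within tol_s
matched_within <- function(planted, detected, tol_s) {
  vapply(planted, function(p) {
    length(detected) && min(abs(detected - p)) <= tol_s
  }, logical(1))
}
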