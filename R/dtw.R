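# Dynamic Time Warping: accumulated cost matrix, optimal warp path and
# DTW distance between the left- and right-foot fused mean strides.
#
# D(i, j) = Dist(i, j) + min{ D(i-1, j), D(i, j-1), D(i-1, j-1) }
# with Dist the squared (default) or absolute sample difference; first
# row/column accumulate along their only predecessor; the DTW distance is
# the terminal entry D(m, n), with no path-length normalization.

#' Local cost between two samples
#'
#' @param x,y Finite numeric values.
#' @param kind `"squared"` (default) or `"absolute"`.
#' @return Nonnegative cost; vectorized over `x`/`y`.
#' @export
local_cost <- function(x, y, kind = c("squared", "absolute")) {
  kind <- match.arg(kind)
  if (kind == "squared") (x - y)^2 else abs(x - y)
}

#' Accumulated DTW cost matrix
#'
#' Dynamic-programming fill of the m x n accumulated cost matrix.
#'
#' @param x,y Nonempty finite numeric sequences (left/right).
#' @param kind Local cost, `"squared"` or `"absolute"`.
#' @return A `dtw_cost_matrix`: `D` (m x n matrix) and `local_cost`.
#' @export
cost_matrix <- function(x, y, kind = c("squared", "absolute")) {
  kind <- match.arg(kind)
  if (!length(x) || !length(y)) stop_empty_sequence("empty input sequence")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_empty_sequence("sequences must be finite")
  }
  m <- length(x); n <- length(y)
  dist <- outer(x, y, local_cost, kind = kind)
  D <- matrix(0, m, n)
  D[1, 1] <- dist[1, 1]
  if (m > 1) D[, 1] <- cumsum(dist[, 1])
  if (n > 1) D[1, ] <- cumsum(dist[1, ])
  for (i in seq_len(m)[-1]) {
    for (j in seq_len(n)[-1]) {
      D[i, j] <- dist[i, j] + min(D[i - 1L, j], D[i, j - 1L], D[i - 1L, j - 1L])
    }
  }
  structure(list(D = D, local_cost = kind), class = "dtw_cost_matrix")
}

#' Optimal warp path by backtrace
#'
#' Backtraces from the terminal corner `(m, n)` to `(1, 1)`, at each step
#' choosing the minimal predecessor with the deterministic tie order
#' diagonal > up > left. Every step decrements `i`, `j` or both by 1.
#'
#' @param cm A `dtw_cost_matrix` from [cost_matrix()].
#' @return Integer matrix with columns `i`, `j`, rows ordered from
#'   `(1, 1)` to `(m, n)`.
#' @export
warp_path <- function(cm) {
  D <- cm$D
  m <- nrow(D); n <- ncol(D)
  path <- matrix(NA_integer_, m + n - 1L, 2L)
  k <- m + n - 1L
  i <- m; j <- n
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    if (i == 1L) {
      j <- j - 1L
    } else if (j == 1L) {
      i <- i - 1L
    } else {
      cand <- c(D[i - 1L, j - 1L], D[i - 1L, j], D[i, j - 1L])
      pick <- which.min(cand)  # ties: diagonal, then up, then left
      if (pick == 1L) { i <- i - 1L; j <- j - 1L }
      else if (pick == 2L) i <- i - 1L
      else j <- j - 1L
    }
    k <- k - 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:(m + n - 1L), , drop = FALSE]
  colnames(path) <- c("i", "j")
  path
}

#' DTW distance
#'
#' Terminal accumulated cost `D(m, n)`; identical sequences give exactly 0.
#'
#' @param x,y Nonempty finite numeric sequences, or `fused_stride`s (their
#'   `values` are used).
#' @param kind Local cost, `"squared"` (default) or `"absolute"`.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' dtw_distance(c(1, 2, 3), c(1, 2, 2, 3))  # 0: warping absorbs the repeat
dtw_distance <- function(x, y, kind = c("squared", "absolute")) {
  x <- as_dtw_sequence(x); y <- as_dtw_sequence(y)
  cm <- cost_matrix(x, y, kind)
  cm$D[nrow(cm$D), ncol(cm$D)]
}

#' Full DTW alignment
#'
#' @param x,y As in [dtw_distance()].
#' @param kind Local cost kind.
#' @param keep_matrix Retain the accumulated cost matrix in the result.
#' @return A `dtw_result`: `distance`, `path` (see [warp_path()]) and
#'   optionally `matrix`.
#' @export
dtw_align <- function(x, y, kind = c("squared", "absolute"),
                      keep_matrix = FALSE) {
  x <- as_dtw_sequence(x); y <- as_dtw_sequence(y)
  cm <- cost_matrix(x, y, kind)
  res <- list(
    distance = cm$D[nrow(cm$D), ncol(cm$D)],
    path = warp_path(cm),
    matrix = if (keep_matrix) cm else NULL
  )
  structure(res, class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> distance %.6g, path length %d\n",
              x$distance, nrow(x$path)))
  invisible(x)
}

as_dtw_sequence <- function(x) {
  if (inherits(x, c("fused_stride", "normalized_stride"))) x$values
  else as.numeric(x)
}
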