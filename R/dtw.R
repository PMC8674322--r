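#' DtwResult: a DTW distance and its warping path
#'
#' @slot distance nonnegative path cost (sum of local absolute differences
#'   along the optimal path).
#' @slot path integer matrix, one (i, j) index pair per row (1-based), in path
#'   order: first row (1, 1), last row (T_a, T_b), successive rows differing
#'   by (1,0), (0,1) or (1,1).
#' @aliases DtwResult DtwResult-class
#' @export
setClass("DtwResult", representation(distance = "numeric", path = "matrix"))

setMethod("show", "DtwResult", function(object) {
  cat("DtwResult: distance", format(object@distance, digits = 6),
      "| path length", nrow(object@path), "\n")
})

.check_series <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L)
    stop("'", name, "' must be a non-empty numeric vector")
  if (!all(is.finite(x)))
    stop("'", name, "' must contain only finite values")
}

.band_arg <- function(band, na, nb) {
  if (is.null(band) || is.infinite(band)) return(-1L)
  band <- as.integer(band)
  if (band < 0L) stop("'band' must be nonnegative")
  if (band < abs(na - nb))
    stop("band (", band, ") is smaller than the length difference (",
         abs(na - nb), "): no admissible warping path")
  band
}

#' Dynamic time warping distance and path
#'
#' Exact dynamic time warping between two series under the boundary,
#' monotonicity and continuity constraints, optionally restricted to a
#' Sakoe-Chiba band `|i - j| <= band` around the diagonal. Local cost is the
#' absolute difference `|a_i - b_j|`; the reported distance is the
#' unnormalized sum of local costs along one optimal path (ties while
#' backtracking are broken deterministically: diagonal first, then the step
#' that advances `a`). The cost matrix need not be square: series of unequal
#' length are supported as long as the band admits a path.
#'
#' @param a,b non-empty numeric series without missing values.
#' @param band Sakoe-Chiba half-width (samples); `NULL` or `Inf` for
#'   unconstrained DTW. Must be at least `abs(length(a) - length(b))`.
#' @param return_path set to `FALSE` to skip path backtracking (the `path`
#'   slot is then a 0-row matrix); the distance is identical and the
#'   computation uses O(T) memory.
#' @return A [DtwResult] object.
#' @examples
#' r <- dtwDistance(c(0, 0, 1, 0), c(0, 1, 0, 0))
#' r@distance   # 0: the shifted impulse is absorbed by warping
#' dtwDistance(c(0, 0, 1, 0), c(0, 1, 0, 0), band = 0)@distance  # 2
#' @export
dtwDistance <- function(a, b, band = NULL, return_path = TRUE) {
  .check_series(a, "a"); .check_series(b, "b")
  w <- .band_arg(band, length(a), length(b))
  if (return_path) {
    r <- .dtw_path_cpp(as.numeric(a), as.numeric(b), w)
    methods::new("DtwResult", distance = r$distance, path = r$path)
  } else {
    methods::new("DtwResult",
                 distance = .dtw_dist_cpp(as.numeric(a), as.numeric(b), w),
                 path = matrix(integer(0), 0, 2))
  }
}

#' Exhaustive-enumeration DTW oracle
#'
#' Minimal warping-path cost found by enumerating *all* admissible paths
#' recursively, with no dynamic programming and no shared code with
#' [dtwDistance()]. Exponential cost, so only short series are accepted;
#' intended as an independent reference in tests.
#'
#' @param a,b numeric series of length at most 8.
#' @return The minimal path cost (numeric scalar).
#' @export
dtwOracle <- function(a, b) {
  .check_series(a, "a"); .check_series(b, "b")
  n <- length(a); m <- length(b)
  if (n > 8L || m > 8L)
    stop("dtwOracle enumerates all paths; series must have length <= 8")
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == n && j == m) return(c0)
    best <- Inf
    if (i < n)          best <- min(best, rec(i + 1L, j))
    if (j < m)          best <- min(best, rec(i, j + 1L))
    if (i < n && j < m) best <- min(best, rec(i + 1L, j + 1L))
    c0 + best
  }
  rec(1L, 1L)
}
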