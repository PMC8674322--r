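#' Quantization error
#'
#' Root-mean-square error of moving each input to its cluster centroid (the
#' assigned best-matching unit's weight vector), always measured with the
#' Euclidean norm so the training variants are directly comparable:
#' `QE = sqrt(mean_i ||x_i - W_bmu(i)||^2)` with the full-series norm
#' (`mode = "series_norm"`, the default). `mode = "per_timestamp"` divides the
#' squared norm by the series length first, giving a per-minute RMSE.
#'
#' @param grid a [SomGrid].
#' @param dataset `T x M` matrix or [ExposureDays] the assignment refers to.
#' @param assignment assignment table (as in [assignmentTable()]) covering
#'   every dataset column, in column order.
#' @param mode `"series_norm"` or `"per_timestamp"`.
#' @return nonnegative scalar.
#' @export
quantizationError <- function(grid, dataset, assignment,
                              mode = c("series_norm", "per_timestamp")) {
  mode <- match.arg(mode)
  X <- .as_day_matrix(dataset)
  if (ncol(X) == 0L) stop("'dataset' is empty")
  if (nrow(assignment) != ncol(X))
    stop("assignment (", nrow(assignment), " rows) does not cover the dataset (",
         ncol(X), " columns)")
  W <- somWeights(grid)
  r2 <- vapply(seq_len(ncol(X)),
               function(j) sum((X[, j] - W[assignment$neuron[j], ])^2),
               numeric(1))
  if (mode == "per_timestamp") r2 <- r2 / nrow(X)
  sqrt(mean(r2))
}

#' Quantization error across grid sizes
#'
#' Trains one map per requested lattice size (same configuration and seed
#' policy for each) and reports the final quantization error, for elbow /
#' inflection-point selection of the output-space size. A max-curvature
#' suggestion is attached as attribute `"elbow"` (neuron count), but the
#' choice is left to the analyst.
#'
#' @param dataset `T x M` matrix or [ExposureDays].
#' @param sizes list of `c(rows, cols)` pairs.
#' @param config a [trainConfig()] applied to every size.
#' @return data.frame with `rows`, `cols`, `neurons`, `qe`, ordered by neuron
#'   count.
#' @export
tuneGridSize <- function(dataset, sizes, config = trainConfig()) {
  if (!length(sizes)) stop("'sizes' must be a non-empty list of c(rows, cols)")
  X <- .as_day_matrix(dataset)
  res <- lapply(sizes, function(sz) {
    fit <- trainSom(X, sz[1], sz[2], config)
    data.frame(rows = sz[1], cols = sz[2], neurons = sz[1] * sz[2],
               qe = quantizationError(fit@grid, X, fit@assignment))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$neurons), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) >= 3) {
    curv <- abs(diff(diff(out$qe)))
    attr(out, "elbow") <- out$neurons[which.max(curv) + 1L]
  }
  out
}

#' Mean Moore-neighbor distance
#'
#' For every neuron, the mean Euclidean distance between its weight vector and
#' those of its existing Moore (8-surrounding) lattice neighbors — edge
#' neurons have fewer — averaged over neurons. Lower values indicate stronger
#' neighborhood relationships (smoother topology) in the trained map.
#'
#' @param grid a [SomGrid] with at least two neurons.
#' @return nonnegative scalar.
#' @export
mooreNeighborDistance <- function(grid) {
  stopifnot(methods::is(grid, "SomGrid"))
  R <- grid@rows; C <- grid@cols
  if (R * C < 2L) stop("Moore-neighbor distance needs at least 2 neurons")
  W <- grid@weights
  idx <- function(r, c) (r - 1L) * C + c
  per_neuron <- numeric(R * C)
  for (r in seq_len(R)) for (c in seq_len(C)) {
    ds <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > R || cc < 1 || cc > C) next
      ds <- c(ds, sqrt(sum((W[idx(r, c), ] - W[idx(rr, cc), ])^2)))
    }
    per_neuron[idx(r, c)] <- mean(ds)
  }
  mean(per_neuron)
}

.shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Intra-cluster label entropy
#'
#' Two Shannon entropies (bits) of a categorical label (e.g. season) against
#' the map assignment: `entropy_weighted` is the count-weighted mean of the
#' within-neuron label entropies (0 when every neuron is pure, at most
#' `log2(#labels)`), and `entropy_joint` is the entropy of the joint
#' (neuron, label) distribution. Lower weighted entropy means purer clusters.
#'
#' @param assignment assignment table (one row per input).
#' @param labels categorical vector aligned with the assignment rows; missing
#'   labels are rejected.
#' @return named list `entropy_weighted`, `entropy_joint`.
#' @export
clusterEntropy <- function(assignment, labels) {
  if (length(labels) != nrow(assignment))
    stop("'labels' must have one entry per assigned input")
  if (anyNA(labels)) stop("'labels' contains missing values")
  M <- nrow(assignment)
  tab <- table(assignment$neuron, labels)
  within <- apply(tab, 1, function(cnt) .shannon_bits(cnt / sum(cnt)))
  wts <- rowSums(tab) / M
  list(entropy_weighted = sum(wts * within),
       entropy_joint = .shannon_bits(as.numeric(tab) / M))
}

#' Per-neuron outcome fractions
#'
#' For each neuron: the number of assigned days with a known binary outcome
#' (denominator), how many of those are positive (numerator), and their ratio
#' — `NA`, not 0, when no outcome-labeled day maps to the neuron. This is the
#' overlay used to eyeball which diurnal patterns co-occur with, e.g., days of
#' inhaler use.
#'
#' @param assignment assignment table (one row per input).
#' @param outcomes binary vector (0/1/NA) aligned with the assignment rows.
#' @param grid optional [SomGrid]; when given, every lattice neuron appears in
#'   the output (otherwise only neurons receiving inputs do).
#' @return data.frame with `neuron`, `row`, `col`, `denominator`, `numerator`,
#'   `fraction`.
#' @export
outcomeFraction <- function(assignment, outcomes, grid = NULL) {
  if (length(outcomes) != nrow(assignment))
    stop("'outcomes' must have one entry per assigned input")
  if (!is.null(grid)) {
    pos <- neuronPositions(grid)
    base <- data.frame(neuron = seq_len(nrow(pos)), row = pos[, 1], col = pos[, 2])
  } else {
    base <- unique(assignment[, c("neuron", "row", "col")])
    base <- base[order(base$neuron), ]
  }
  known <- !is.na(outcomes)
  den <- tapply(known, assignment$neuron, sum)
  num <- tapply(known & outcomes == 1, assignment$neuron, sum, na.rm = TRUE)
  base$denominator <- as.integer(den[as.character(base$neuron)])
  base$denominator[is.na(base$denominator)] <- 0L
  base$numerator <- as.integer(num[as.character(base$neuron)])
  base$numerator[is.na(base$numerator)] <- 0L
  base$fraction <- ifelse(base$denominator > 0,
                          base$numerator / base$denominator, NA_real_)
  rownames(base) <- NULL
  base
}

#' Band-constrained vs exact DTW approximation error on diurnal pairs
#'
#' Generates pairs of synthetic minute-resolution diurnal temperature-like
#' day-series — two independently warped, noised copies of a randomly chosen
#' seasonal prototype — and measures, per pair, the relative difference
#' between the Sakoe-Chiba band-constrained DTW distance and the exact DTW
#' distance, in percent. With a band comfortably wider than the warp
#' magnitude, the constrained distance is expected to be within 1% of exact
#' (typically identical).
#'
#' @param n_pairs number of pairs.
#' @param len series length (1440 = minute-resolution day).
#' @param warp_magnitude maximum timestamp displacement (samples) per copy.
#' @param noise_sd additive Gaussian noise SD.
#' @param band Sakoe-Chiba half-width under test.
#' @param seed integer seed.
#' @return numeric vector of per-pair relative differences
#'   `100 * |d_band - d_exact| / d_exact`.
#' @export
bandApproximationError <- function(n_pairs = 50, len = 1440,
                                   warp_magnitude = 30, noise_sd = 0.02,
                                   band = 60, seed = 1L) {
  sm <- defaultSeasonModel()
  withr::with_seed(seed, {
    vapply(seq_len(n_pairs), function(i) {
      s <- sample(names(sm), 1)
      proto <- .temperature_prototype(len, sm[[s]]$baseline,
                                      sm[[s]]$amplitude, 1200)
      a <- as.numeric(applyWarp(proto, warp_magnitude)) +
        stats::rnorm(len, 0, noise_sd)
      b <- as.numeric(applyWarp(proto, warp_magnitude)) +
        stats::rnorm(len, 0, noise_sd)
      de <- dtwDistance(a, b, return_path = FALSE)@distance
      dc <- dtwDistance(a, b, band = band, return_path = FALSE)@distance
      100 * abs(dc - de) / de
    }, numeric(1))
  })
}

#' Assemble an evaluation report
#'
#' Collects the comparison metrics for a trained map: quantization error,
#' Moore-neighbor distance (grids with >= 2 neurons), per-neuron input counts,
#' and — when labels/outcomes are supplied — season-stratified entropies and
#' outcome fractions.
#'
#' @param fit a [SomFit].
#' @param dataset the `T x M` matrix or [ExposureDays] the fit was trained on.
#' @param labels optional categorical vector (e.g. seasons) per input.
#' @param outcomes optional binary vector per input.
#' @return named list (a `MetricsReport`): `quantization_error`,
#'   `neighbor_distance`, `entropy_weighted`, `entropy_joint`, `per_neuron`.
#' @export
metricsReport <- function(fit, dataset, labels = NULL, outcomes = NULL) {
  stopifnot(methods::is(fit, "SomFit"))
  X <- .as_day_matrix(dataset)
  asg <- fit@assignment
  qe <- quantizationError(fit@grid, X, asg)
  nd <- if (fit@grid@rows * fit@grid@cols >= 2L)
    mooreNeighborDistance(fit@grid) else NA_real_
  ent <- if (!is.null(labels)) clusterEntropy(asg, labels)
  else list(entropy_weighted = NA_real_, entropy_joint = NA_real_)
  pos <- neuronPositions(fit@grid)
  per <- data.frame(neuron = seq_len(nrow(pos)), row = pos[, 1], col = pos[, 2])
  cnt <- table(asg$neuron)
  per$count <- as.integer(cnt[as.character(per$neuron)])
  per$count[is.na(per$count)] <- 0L
  if (!is.null(outcomes)) {
    of <- outcomeFraction(asg, outcomes, grid = fit@grid)
    per <- merge(per, of[, c("neuron", "denominator", "numerator", "fraction")],
                 by = "neuron", sort = TRUE)
  }
  list(quantization_error = qe, neighbor_distance = nd,
       entropy_weighted = ent$entropy_weighted,
       entropy_joint = ent$entropy_joint, per_neuron = per)
}
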