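.as_day_matrix <- function(dataset) {
  if (methods::is(dataset, "ExposureDays")) return(daySeries(dataset))
  dataset <- as.matrix(dataset)
  if (ncol(dataset) < 1L) stop("'dataset' is empty")
  if (!is.numeric(dataset))
    stop("'dataset' must be a numeric matrix with one day-series per column")
  if (!all(is.finite(dataset))) stop("'dataset' must be all finite")
  dataset
}

.init_grid_impl <- function(R, C, dataset, config) {
  K <- R * C; M <- ncol(dataset); Tn <- nrow(dataset)
  if (config@init == "sample") {
    if (M == 0L) stop("init = 'sample' needs a non-empty dataset")
    if (K > M) {
      warning("grid has more neurons (", K, ") than inputs (", M,
              "): sampling initial weights with replacement")
      idx <- sample.int(M, K, replace = TRUE)
    } else idx <- sample.int(M, K)
    W <- t(dataset[, idx, drop = FALSE])
  } else {
    rng <- range(dataset)
    W <- matrix(stats::runif(K * Tn, rng[1], rng[2]), K, Tn)
  }
  methods::new("SomGrid", rows = as.integer(R), cols = as.integer(C), weights = W)
}

#' Initialize a SOM grid
#'
#' `init = "sample"` draws `R*C` distinct input series as initial weights
#' (with replacement, and a warning, when the grid outnumbers the inputs);
#' `init = "random"` draws i.i.d. uniform weights over the dataset range.
#' Deterministic given `config@seed`.
#'
#' @param R,C positive integer lattice dimensions.
#' @param dataset `T x M` matrix of day-series columns, or an [ExposureDays].
#' @param config a [trainConfig()].
#' @return A [SomGrid].
#' @export
initGrid <- function(R, C, dataset, config = trainConfig()) {
  dataset <- .as_day_matrix(dataset)
  withr::with_seed(config@seed, .init_grid_impl(R, C, dataset, config))
}

.neuron_dists <- function(W, x, variant, band) {
  if (variant == "euclidean") {
    sqrt(rowSums((W - matrix(x, nrow(W), length(x), byrow = TRUE))^2))
  } else {
    w <- .band_arg(band, ncol(W), length(x))
    vapply(seq_len(nrow(W)), function(k) .dtw_dist_cpp(W[k, ], x, w),
           numeric(1))
  }
}

#' Find the best-matching unit
#'
#' The neuron whose weight vector is closest to `x` under the variant's
#' metric: full-series Euclidean norm for `"euclidean"`, DTW distance (with
#' the configured Sakoe-Chiba band) for `"dtw_match"` and `"dtw_full"`. Ties
#' go to the lowest row-major neuron index.
#'
#' @param grid a [SomGrid].
#' @param x numeric series of the grid's weight length.
#' @param variant `"euclidean"`, `"dtw_match"` or `"dtw_full"`.
#' @param band Sakoe-Chiba half-width for the DTW variants.
#' @return list with `index`, `row`, `col`, `distance`.
#' @export
findBmu <- function(grid, x, variant = "dtw_full", band = 60) {
  stopifnot(methods::is(grid, "SomGrid"))
  if (length(x) != ncol(grid@weights))
    stop("'x' has length ", length(x), " but grid weights have length ",
         ncol(grid@weights))
  d <- unname(.neuron_dists(grid@weights, x, variant, band))
  k <- unname(which.min(d))
  pos <- neuronPositions(grid)[k, ]
  list(index = k, row = unname(pos["row"]), col = unname(pos["col"]),
       distance = d[k])
}

#' Gaussian neighborhood kernel weight
#'
#' `h = exp(-delta^2 / (2 sigma^2))`, maximal (1) when `r` is the
#' best-matching unit itself. `delta` is the Euclidean distance between the
#' two neurons' lattice positions (`kernel_space = "lattice"`, the standard
#' SOM choice that gives the map its 2-D topology) or the DTW distance
#' between their weight vectors (`kernel_space = "dtw_weightspace"`).
#'
#' @param grid a [SomGrid].
#' @param r,s neuron indices (row-major), `s` the best-matching unit.
#' @param sigma positive kernel width.
#' @param kernel_space `"lattice"` or `"dtw_weightspace"`.
#' @param band Sakoe-Chiba half-width for weight-space DTW.
#' @return kernel weight in `(0, 1]`.
#' @export
neighborhoodWeight <- function(grid, r, s, sigma, kernel_space = "lattice",
                               band = 60) {
  stopifnot(methods::is(grid, "SomGrid"), sigma > 0)
  if (r == s) return(1.0)
  if (kernel_space == "lattice") {
    pos <- neuronPositions(grid)
    delta2 <- sum((pos[r, ] - pos[s, ])^2)
  } else {
    delta2 <- .dtw_dist_cpp(grid@weights[r, ], grid@weights[s, ],
                            .band_arg(band, ncol(grid@weights), ncol(grid@weights)))^2
  }
  exp(-delta2 / (2 * sigma^2))
}

#' Timestamp-aligned weight update
#'
#' The classic SOM rule: `W_new = W + epsilon * h * (x - W)`, elementwise at
#' matching timestamps.
#'
#' @param W,x numeric vectors of equal length.
#' @param epsilon learning rate.
#' @param h kernel weight; `0 <= epsilon * h <= 1` required so the update is
#'   a convex combination.
#' @return updated weight vector.
#' @export
updateEuclidean <- function(W, x, epsilon, h = 1) {
  if (length(W) != length(x)) stop("'W' and 'x' must have equal length")
  eh <- epsilon * h
  if (eh < 0 || eh > 1) stop("epsilon * h must lie in [0, 1]")
  W + eh * (x - W)
}

#' Warping-aligned weight update
#'
#' Moves the neuron toward the input along the DTW alignment instead of
#' timestamp-by-timestamp, so sharp features shift in time rather than being
#' averaged flat. For each alignment pair `(t, t-bar)` of the optimal path
#' between `W` and `x`, the updated value
#' `v = W[t] + eh * (x[t-bar] - W[t])` is placed at the pseudo-timestamp
#' `t~ = t + eh * (t-bar - t)` — both value and timing move toward the input
#' by the same fraction `eh = epsilon * h`, so `eh = 0` is the identity and
#' `eh = 1` reproduces `x` exactly. Many-to-one alignments give repeated
#' pseudo-timestamps, whose values are averaged; the resulting piecewise
#' linear curve is resampled back onto the integer timestamps
#' `0..length(W)-1` (the boundary path pairs guarantee coverage, so this is
#' interpolation, never extrapolation).
#'
#' @param W neuron weight vector.
#' @param x input series.
#' @param epsilon learning rate.
#' @param h kernel weight; `0 <= epsilon * h <= 1` required.
#' @param band Sakoe-Chiba half-width for the alignment path.
#' @return updated weight vector of `length(W)`.
#' @export
updateDtw <- function(W, x, epsilon, h = 1, band = Inf) {
  eh <- epsilon * h
  if (eh < 0 || eh > 1) stop("epsilon * h must lie in [0, 1]")
  if (eh == 0) return(W)
  res <- dtwDistance(W, x, band = band)
  p <- res@path
  t0 <- p[, 1] - 1                      # weight timestamps, 0-based
  tb <- p[, 2] - 1                      # aligned input timestamps
  v <- W[p[, 1]] + eh * (x[p[, 2]] - W[p[, 1]])
  tt <- t0 + eh * (tb - t0)
  # collapse duplicate pseudo-timestamps (many-to-one alignment) by averaging
  o <- order(tt)
  tts <- tt[o]; vs <- v[o]
  grp <- cumsum(c(TRUE, diff(tts) > 0))
  tu <- tts[!duplicated(grp)]
  vu <- as.numeric(tapply(vs, grp, mean))
  if (length(tu) == 1L) return(rep(vu, length(W)))
  stats::approx(tu, vu, xout = seq.int(0, length(W) - 1), rule = 2)$y
}

.decay <- function(start, end, i, iterations) {
  if (iterations == 1L) return(start)
  start * (end / start)^((i - 1) / (iterations - 1))
}

# Euclidean-norm quantization error of the current weights against the whole
# dataset (proxy trace; BMUs under the Euclidean norm).
.qe_proxy <- function(W, dataset, xn) {
  cross <- W %*% dataset
  wn <- rowSums(W^2)
  d2 <- outer(wn, xn, "+") - 2 * cross
  sqrt(mean(pmax(apply(d2, 2, min), 0)))
}

#' Train a self-organizing map
#'
#' Online competitive learning: at each iteration one input (shuffled cycling
#' over the dataset) is matched to its best-matching unit under the variant's
#' metric, and every neuron whose kernel weight exceeds
#' `config@kernel_cutoff` is updated — timestamp-aligned ([updateEuclidean()])
#' for `euclidean` and `dtw_match`, warping-aligned ([updateDtw()]) for
#' `dtw_full`, where each updated neuron uses its *own* DTW path to the
#' input. Learning rate and kernel width decay exponentially across
#' iterations. The final assignment is recomputed with the trained grid under
#' the variant's metric.
#'
#' Because every update is a convex combination and the warping-aligned
#' resampling interpolates, trained weights never leave the dataset's value
#' range.
#'
#' @param dataset `T x M` numeric matrix (day-series in columns) or an
#'   [ExposureDays].
#' @param R,C lattice dimensions.
#' @param config a [trainConfig()].
#' @return A [SomFit].
#' @export
trainSom <- function(dataset, R, C, config = trainConfig()) {
  X <- .as_day_matrix(dataset)
  M <- ncol(X)
  if (M == 0L) stop("'dataset' is empty")
  R <- as.integer(R); C <- as.integer(C)
  sig <- config@sigma
  if (is.na(sig[1])) sig[1] <- max(R, C) / 2
  if (sig[2] > sig[1]) sig[1] <- sig[2]
  iters <- config@iterations

  withr::with_seed(config@seed, {
    grid <- .init_grid_impl(R, C, X, config)
    W <- grid@weights
    K <- R * C
    pos <- neuronPositions(grid)
    latd2 <- as.matrix(stats::dist(pos))^2
    xn <- colSums(X^2)
    wband <- .band_arg(config@band, nrow(X), nrow(X))

    qe_trace <- numeric(0)
    ord <- integer(0)
    for (i in seq_len(iters)) {
      if (!length(ord)) ord <- sample.int(M)
      xi <- ord[1]; ord <- ord[-1]
      x <- X[, xi]

      eps <- .decay(config@epsilon[1], config@epsilon[2], i, iters)
      sg <- .decay(sig[1], sig[2], i, iters)

      d <- .neuron_dists(W, x, config@variant, config@band)
      s <- which.min(d)

      if (config@kernel_space == "lattice") {
        h <- exp(-latd2[, s] / (2 * sg^2))
      } else {
        dw <- vapply(seq_len(K), function(k)
          if (k == s) 0 else .dtw_dist_cpp(W[k, ], W[s, ], wband), numeric(1))
        h <- exp(-dw^2 / (2 * sg^2))
      }
      for (k in which(h >= config@kernel_cutoff)) {
        W[k, ] <- if (config@variant == "dtw_full")
          updateDtw(W[k, ], x, eps, h[k], band = config@band)
        else
          updateEuclidean(W[k, ], x, eps, h[k])
      }
      if (i %% config@qe_every == 0L || i == iters)
        qe_trace <- c(qe_trace, .qe_proxy(W, X, xn))
    }
  })

  grid <- methods::new("SomGrid", rows = R, cols = C, weights = W)
  assignment <- .assign_all(grid, X, config@variant, config@band)
  methods::new("SomFit", grid = grid, assignment = assignment,
               qe_trace = qe_trace, config = config)
}

.assign_all <- function(grid, X, variant, band) {
  pos <- neuronPositions(grid)
  ids <- colnames(X)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(X)))
  res <- lapply(seq_len(ncol(X)), function(j) {
    d <- .neuron_dists(grid@weights, X[, j], variant, band)
    k <- which.min(d)
    data.frame(id = ids[j], neuron = k, row = pos[k, 1], col = pos[k, 2],
               distance = d[k])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
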