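#' ExposureDays: complete daily exposure series
#'
#' A [SummarizedExperiment::SummarizedExperiment]-derived container holding
#' complete, cleaned daily observations: the `"values"` assay is a
#' `T x M` matrix (one column per day-series, rows are minutes of the day
#' window, typically 1440 starting at 20:00), and `colData` carries one row of
#' metadata per day-series: `site`, `date`, `variable`, `location`, `season`
#' and (optionally) a binary `outcome`.
#'
#' Every value is finite: days with residual missingness are excluded upstream
#' by [windowDays()], so validity enforces completeness.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @aliases ExposureDays ExposureDays-class
#' @export
setClass("ExposureDays", contains = "SummarizedExperiment")

setValidity("ExposureDays", function(object) {
  msg <- character(0)
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "values"))))
    msg <- c(msg, "assay 'values' must be all finite (no missing values)")
  need <- c("site", "date", "variable", "location", "season")
  have <- colnames(SummarizedExperiment::colData(object))
  if (!all(need %in% have))
    msg <- c(msg, paste0("colData must contain columns: ",
                         paste(setdiff(need, have), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ExposureDays container
#'
#' @param values numeric matrix, `T x M`, one day-series per column, all
#'   finite.
#' @param info data.frame with `M` rows and at least the columns `site`,
#'   `date`, `variable`, `location`, `season`; an `outcome` column (0/1/NA)
#'   is optional and added as all-`NA` when absent.
#' @param metadata optional named list stored in the object metadata
#'   (e.g. scaling ranges, removed gap intervals).
#' @return An [ExposureDays] object.
#' @export
ExposureDays <- function(values, info, metadata = list()) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  info <- as.data.frame(info)
  if (nrow(info) != ncol(values))
    stop("nrow(info) must equal ncol(values)")
  if (!"outcome" %in% colnames(info)) info$outcome <- NA_integer_
  ids <- paste(info$site, info$date, info$location, info$variable, sep = "|")
  colnames(values) <- make.unique(ids)
  rownames(info) <- colnames(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    colData = S4Vectors::DataFrame(info),
    metadata = metadata)
  methods::new("ExposureDays", se)
}

#' @describeIn ExposureDays the `T x M` matrix of day series.
#' @param x an `ExposureDays` object.
#' @export
daySeries <- function(x) {
  stopifnot(methods::is(x, "ExposureDays"))
  SummarizedExperiment::assay(x, "values")
}

#' @describeIn ExposureDays per-day metadata as a plain data.frame.
#' @export
dayInfo <- function(x) {
  stopifnot(methods::is(x, "ExposureDays"))
  as.data.frame(SummarizedExperiment::colData(x))
}

setMethod("show", "ExposureDays", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("ExposureDays:", ncol(object), "day-series of length", nrow(object), "\n")
  if (ncol(object)) {
    cat("  sites:", length(unique(cd$site)),
        "| variables:", paste(sort(unique(paste(cd$location, cd$variable))),
                              collapse = ", "), "\n")
    cat("  seasons:", paste(names(table(cd$season)), table(cd$season),
                            sep = "=", collapse = ", "), "\n")
    n_out <- sum(!is.na(cd$outcome))
    cat("  days with outcome labels:", n_out, "\n")
  }
})

#' SomGrid: a rectangular lattice of neurons
#'
#' Weight vectors live in the rows of `weights` (`R*C x T`); neuron `k` sits
#' at lattice position `row = (k-1) %/% C + 1`, `col = (k-1) %% C + 1`
#' (row-major order, which is also the tie-break order for best-matching-unit
#' searches).
#'
#' @slot rows,cols integer lattice dimensions.
#' @slot weights numeric matrix `R*C x T`, all finite.
#' @aliases SomGrid SomGrid-class
#' @export
setClass("SomGrid", representation(rows = "integer", cols = "integer",
                                   weights = "matrix"))

setValidity("SomGrid", function(object) {
  msg <- character(0)
  if (length(object@rows) != 1L || object@rows < 1L) msg <- c(msg, "rows must be a positive integer")
  if (length(object@cols) != 1L || object@cols < 1L) msg <- c(msg, "cols must be a positive integer")
  if (nrow(object@weights) != object@rows * object@cols)
    msg <- c(msg, "weights must have rows*cols rows")
  if (!all(is.finite(object@weights))) msg <- c(msg, "weights must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn SomGrid neuron weight matrix (`R*C x T`, row-major neurons).
#' @param grid a `SomGrid`.
#' @export
somWeights <- function(grid) {
  stopifnot(methods::is(grid, "SomGrid"))
  grid@weights
}

#' @describeIn SomGrid lattice dimensions `c(rows, cols)`.
#' @export
gridDims <- function(grid) {
  stopifnot(methods::is(grid, "SomGrid"))
  c(rows = grid@rows, cols = grid@cols)
}

#' @describeIn SomGrid `R*C x 2` matrix of (row, col) lattice positions.
#' @export
neuronPositions <- function(grid) {
  stopifnot(methods::is(grid, "SomGrid"))
  k <- seq_len(grid@rows * grid@cols)
  cbind(row = (k - 1L) %/% grid@cols + 1L, col = (k - 1L) %% grid@cols + 1L)
}

setMethod("show", "SomGrid", function(object) {
  cat("SomGrid:", object@rows, "x", object@cols, "neurons, weight length",
      ncol(object@weights), "\n")
  cat("  weight range: [", format(min(object@weights), digits = 4), ", ",
      format(max(object@weights), digits = 4), "]\n", sep = "")
})

#' TrainConfig: self-organizing map training parameters
#'
#' @slot variant `"euclidean"` (classic SOM), `"dtw_match"` (DTW used only to
#'   pick the best-matching unit, timestamp-aligned updates) or `"dtw_full"`
#'   (DTW used for matching *and* for the alignment-path weight update).
#' @slot iterations number of online updates (one input per iteration).
#' @slot epsilon learning-rate schedule `c(start, end)`, exponential decay,
#'   `0 < end <= start <= 1`.
#' @slot sigma neighborhood-width schedule `c(start, end)`; an `NA` start is
#'   resolved to `max(R, C)/2` at training time.
#' @slot kernel_space `"lattice"` (Gaussian kernel on lattice distance, the
#'   default) or `"dtw_weightspace"` (kernel on DTW distance between weight
#'   vectors).
#' @slot band Sakoe-Chiba half-width in samples; `Inf` disables the band.
#' @slot init `"sample"` (draw initial weights from the data) or `"random"`.
#' @slot seed integer seed; the whole training run is deterministic given it.
#' @slot kernel_cutoff updates with kernel weight below this are skipped.
#' @slot qe_every record the quantization-error trace every this many
#'   iterations.
#' @aliases TrainConfig TrainConfig-class
#' @export
setClass("TrainConfig", representation(
  variant = "character", iterations = "integer", epsilon = "numeric",
  sigma = "numeric", kernel_space = "character", band = "numeric",
  init = "character", seed = "integer", kernel_cutoff = "numeric",
  qe_every = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (!object@variant %in% c("euclidean", "dtw_match", "dtw_full"))
    msg <- c(msg, "variant must be euclidean, dtw_match or dtw_full")
  if (object@iterations < 1L) msg <- c(msg, "iterations must be >= 1")
  e <- object@epsilon
  if (length(e) != 2L || !(e[2] > 0 && e[2] <= e[1] && e[1] <= 1))
    msg <- c(msg, "epsilon must be c(start, end) with 0 < end <= start <= 1")
  s <- object@sigma
  if (length(s) != 2L || !(s[2] > 0) || (!is.na(s[1]) && s[1] <= 0))
    msg <- c(msg, "sigma values must be > 0")
  if (!object@kernel_space %in% c("lattice", "dtw_weightspace"))
    msg <- c(msg, "kernel_space must be lattice or dtw_weightspace")
  if (!(is.infinite(object@band) || object@band >= 0))
    msg <- c(msg, "band must be a nonnegative radius or Inf")
  if (!object@init %in% c("sample", "random"))
    msg <- c(msg, "init must be sample or random")
  if (object@kernel_cutoff <= 0) msg <- c(msg, "kernel_cutoff must be > 0")
  if (object@qe_every < 1L) msg <- c(msg, "qe_every must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Build a training configuration
#'
#' Defaults follow the reference analysis: 3000 online iterations, a
#' Sakoe-Chiba band of 60 samples (one hour at minute resolution), Gaussian
#' neighborhood on the lattice, learning rate decaying 0.5 to 0.01 and
#' neighborhood width decaying from half the larger grid dimension to 0.2
#' (so the final phase is effectively winner-only fine tuning).
#'
#' @param variant one of `"dtw_full"`, `"dtw_match"`, `"euclidean"`.
#' @param iterations positive integer.
#' @param epsilon learning-rate schedule `c(start, end)`.
#' @param sigma neighborhood schedule `c(start, end)`; `NULL` means
#'   `c(NA, 0.2)` with the start resolved to `max(R, C)/2` when training.
#' @param kernel_space `"lattice"` or `"dtw_weightspace"`.
#' @param band Sakoe-Chiba half-width (samples); `Inf` for unconstrained DTW.
#' @param init `"sample"` or `"random"`.
#' @param seed integer seed.
#' @param kernel_cutoff skip updates whose kernel weight falls below this.
#' @param qe_every record the quantization-error trace every `qe_every`
#'   iterations.
#' @return A [TrainConfig] object.
#' @export
trainConfig <- function(variant = c("dtw_full", "dtw_match", "euclidean"),
                        iterations = 3000L, epsilon = c(0.5, 0.01),
                        sigma = NULL, kernel_space = c("lattice", "dtw_weightspace"),
                        band = 60, init = c("sample", "random"), seed = 1L,
                        kernel_cutoff = 1e-3, qe_every = 1L) {
  variant <- match.arg(variant)
  kernel_space <- match.arg(kernel_space)
  init <- match.arg(init)
  if (is.null(sigma)) sigma <- c(NA_real_, 0.2)
  if (is.null(band)) band <- Inf
  methods::new("TrainConfig", variant = variant,
               iterations = as.integer(iterations), epsilon = as.numeric(epsilon),
               sigma = as.numeric(sigma), kernel_space = kernel_space,
               band = as.numeric(band), init = init, seed = as.integer(seed),
               kernel_cutoff = as.numeric(kernel_cutoff),
               qe_every = as.integer(qe_every))
}

setMethod("show", "TrainConfig", function(object) {
  cat("TrainConfig:", object@variant, "|", object@iterations, "iterations",
      "| band", object@band, "\n")
  cat("  epsilon", paste(object@epsilon, collapse = " -> "),
      "| sigma", paste(object@sigma, collapse = " -> "),
      "| kernel", object@kernel_space, "| init", object@init,
      "| seed", object@seed, "\n")
})

#' SomFit: a trained self-organizing map
#'
#' @slot grid the trained [SomGrid].
#' @slot assignment data.frame mapping each input to its best-matching unit:
#'   columns `id`, `neuron`, `row`, `col`, `distance` (under the training
#'   variant's metric).
#' @slot qe_trace quantization-error trace recorded during training
#'   (Euclidean-norm proxy computed every `qe_every` iterations).
#' @slot config the [TrainConfig] used.
#' @aliases SomFit SomFit-class
#' @export
setClass("SomFit", representation(grid = "SomGrid", assignment = "data.frame",
                                  qe_trace = "numeric", config = "TrainConfig"))

#' @describeIn SomFit the trained grid.
#' @param fit a `SomFit`.
#' @export
somGrid <- function(fit) { stopifnot(methods::is(fit, "SomFit")); fit@grid }

#' @describeIn SomFit the input-to-neuron assignment table.
#' @export
assignmentTable <- function(fit) { stopifnot(methods::is(fit, "SomFit")); fit@assignment }

#' @describeIn SomFit the recorded quantization-error trace.
#' @export
qeTrace <- function(fit) { stopifnot(methods::is(fit, "SomFit")); fit@qe_trace }

setMethod("show", "SomFit", function(object) {
  cat("SomFit (", object@config@variant, "): ", object@grid@rows, " x ",
      object@grid@cols, " grid, ", nrow(object@assignment), " inputs\n", sep = "")
  if (length(object@qe_trace))
    cat("  final traced QE:", format(utils::tail(object@qe_trace, 1), digits = 5), "\n")
})
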