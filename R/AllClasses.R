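#' @import methods
#' @importFrom stats median sd quantile runif rnorm rpois cor cor.test
#'   wilcox.test lm.fit filter approx setNames rlnorm
#' @importFrom utils head tail read.csv write.csv
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Tail-angle trace
#'
#' A uniformly sampled, signed tail-angle time series recorded by the
#' behavior camera (default 300 Hz). Positive angles denote a tail
#' deflection toward the animal's left side; this left-positive convention
#' propagates to turn labels (a positive maximum bend is a left turn).
#'
#' @slot time numeric vector of sample times in seconds, strictly increasing
#'   and uniform.
#' @slot angle numeric vector, signed tail angle in degrees.
#' @slot rate sampling rate in Hz.
#' @slot curvature optional matrix of per-segment angles
#'   (segments x time), or a 0x0 matrix when absent.
#'
#' @seealso [TailTrace()] constructor, [detectBends()], [extractBouts()]
#' @export
setClass("TailTrace",
  representation(
    time = "numeric",
    angle = "numeric",
    rate = "numeric",
    curvature = "matrix"
  ),
  prototype(curvature = matrix(numeric(0), 0, 0))
)

setValidity("TailTrace", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (n == 0L) msg <- c(msg, "empty input: trace has no samples")
  if (length(object@angle) != n)
    msg <- c(msg, "time and angle must have equal length")
  if (any(!is.finite(object@angle)))
    msg <- c(msg, "angle must be finite everywhere")
  if (length(object@rate) != 1L || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (n > 1L) {
    dt <- diff(object@time)
    if (any(dt <= 0)) {
      msg <- c(msg, "time must be strictly increasing")
    } else if (max(dt) - min(dt) > 1e-9) {
      msg <- c(msg, "non-uniform sampling: time grid must be uniform within 1e-9 s")
    }
  }
  if (nrow(object@curvature) > 0 && ncol(object@curvature) != n)
    msg <- c(msg, "curvature must have one column per time sample")
  if (length(msg)) msg else TRUE
})

#' Construct a TailTrace
#'
#' @param angle signed tail angle in degrees.
#' @param rate sampling rate in Hz (default 300).
#' @param time optional explicit time vector; defaults to a uniform grid
#'   starting at 0 with spacing `1/rate`.
#' @param curvature optional per-segment angle matrix (segments x time).
#' @return A [TailTrace-class] object.
#' @examples
#' tr <- TailTrace(sin(2 * pi * 20 * seq(0, 0.25, by = 1 / 300)) * 15)
#' tr
#' @export
TailTrace <- function(angle, rate = 300, time = NULL, curvature = NULL) {
  angle <- as.numeric(angle)
  if (is.null(time)) time <- (seq_along(angle) - 1L) / rate
  if (!is.null(curvature)) curvature <- as.matrix(curvature)
  else curvature <- matrix(numeric(0), 0, 0)
  new("TailTrace", time = as.numeric(time), angle = angle,
      rate = as.numeric(rate), curvature = curvature)
}

#' @describeIn TailTrace sample times in seconds.
#' @param x,object a `TailTrace`.
#' @export
setGeneric("tailTime", function(x) standardGeneric("tailTime"))

#' @rdname TailTrace
#' @export
setMethod("tailTime", "TailTrace", function(x) x@time)

#' @describeIn TailTrace signed tail angle in degrees.
#' @export
setGeneric("tailAngle", function(x) standardGeneric("tailAngle"))

#' @rdname TailTrace
#' @export
setMethod("tailAngle", "TailTrace", function(x) x@angle)

#' @describeIn TailTrace sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname TailTrace
#' @export
setMethod("sampleRate", "TailTrace", function(x) x@rate)

setMethod("show", "TailTrace", function(object) {
  dur <- if (length(object@time)) diff(range(object@time)) else 0
  cat(sprintf("TailTrace: %d samples at %g Hz (%.2f s), angle range [%.1f, %.1f] deg\n",
              length(object@angle), object@rate, dur,
              suppressWarnings(min(object@angle)),
              suppressWarnings(max(object@angle))))
  if (nrow(object@curvature) > 0)
    cat(sprintf("  curvature: %d segments\n", nrow(object@curvature)))
})

#' ROI fluorescence set
#'
#' Container for per-ROI fluorescence recordings at the imaging frame rate,
#' built on [SummarizedExperiment::SummarizedExperiment]. Rows are ROIs,
#' columns are imaging frames. Assays hold raw fluorescence (`fraw`),
#' surround/neuropil fluorescence (`fneuropil`) and, after preprocessing,
#' `dff` (delta-F/F) and `spikeRate`. Per-ROI baseline (`f0`) and noise
#' (`noiseSigma`, the s.d. of delta-F/F during an inactivity period) live in
#' `rowData`; frame times and the artifact mask live in `colData`.
#'
#' @seealso [FluoSet()], [preprocessFluo()], [inferSpikeRate()]
#' @export
setClass("FluoSet", contains = "SummarizedExperiment")

setValidity("FluoSet", function(object) {
  msg <- character(0)
  if (!"fraw" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'fraw' is required")
  if (!"frameTime" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'frameTime' is required")
  rd <- SummarizedExperiment::rowData(object)
  if ("f0" %in% colnames(rd) && any(!is.na(rd$f0) & rd$f0 <= 0))
    msg <- c(msg, "f0 must be positive")
  if ("noiseSigma" %in% colnames(rd) && any(!is.na(rd$noiseSigma) & rd$noiseSigma < 0))
    msg <- c(msg, "noiseSigma must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a FluoSet
#'
#' @param fraw ROI x frame matrix of raw fluorescence.
#' @param fneuropil ROI x frame matrix of surround (neuropil) fluorescence;
#'   defaults to zeros.
#' @param frameTime frame times in seconds; defaults to a uniform grid at
#'   `rate` Hz starting at 0.
#' @param rate imaging frame rate in Hz (default 10).
#' @param roiId ROI identifiers (default `roi_1..roi_n`).
#' @return A [FluoSet-class].
#' @examples
#' fs <- FluoSet(matrix(100 + rnorm(200), nrow = 2))
#' fs
#' @export
FluoSet <- function(fraw, fneuropil = NULL, frameTime = NULL, rate = 10,
                    roiId = NULL) {
  fraw <- as.matrix(fraw)
  if (is.null(fneuropil)) fneuropil <- matrix(0, nrow(fraw), ncol(fraw))
  fneuropil <- as.matrix(fneuropil)
  stopifnot(all(dim(fraw) == dim(fneuropil)))
  if (is.null(frameTime)) frameTime <- (seq_len(ncol(fraw)) - 1L) / rate
  if (is.null(roiId)) roiId <- paste0("roi_", seq_len(nrow(fraw)))
  rownames(fraw) <- rownames(fneuropil) <- roiId
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fraw = fraw, fneuropil = fneuropil),
    rowData = S4Vectors::DataFrame(roiId = roiId,
                                   f0 = rep(NA_real_, nrow(fraw)),
                                   noiseSigma = rep(NA_real_, nrow(fraw))),
    colData = S4Vectors::DataFrame(frameTime = as.numeric(frameTime),
                                   artifact = rep(FALSE, ncol(fraw)))
  )
  S4Vectors::metadata(se)$rate <- rate
  new("FluoSet", se)
}

#' @describeIn FluoSet imaging frame times in seconds.
#' @param x a `FluoSet`.
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname FluoSet
#' @export
setMethod("frameTimes", "FluoSet",
          function(x) SummarizedExperiment::colData(x)$frameTime)

#' @describeIn FluoSet delta-F/F assay (error if not yet computed).
#' @export
setGeneric("dff", function(x) standardGeneric("dff"))

#' @rdname FluoSet
#' @export
setMethod("dff", "FluoSet", function(x) {
  if (!"dff" %in% SummarizedExperiment::assayNames(x))
    stop("dff not computed; run preprocessFluo() first")
  SummarizedExperiment::assay(x, "dff")
})

#' @describeIn FluoSet inferred spike-rate assay.
#' @export
setGeneric("spikeRate", function(x) standardGeneric("spikeRate"))

#' @rdname FluoSet
#' @export
setMethod("spikeRate", "FluoSet", function(x) {
  if (!"spikeRate" %in% SummarizedExperiment::assayNames(x))
    stop("spike rate not inferred; run inferSpikeRate() first")
  SummarizedExperiment::assay(x, "spikeRate")
})

#' @describeIn FluoSet per-ROI noise sigma (s.d. of delta-F/F at rest).
#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))

#' @rdname FluoSet
#' @export
setMethod("noiseSigma", "FluoSet",
          function(x) SummarizedExperiment::rowData(x)$noiseSigma)

#' @describeIn FluoSet imaging frame rate in Hz.
#' @export
setMethod("sampleRate", "FluoSet",
          function(x) S4Vectors::metadata(x)$rate)

setMethod("show", "FluoSet", function(object) {
  cat(sprintf("FluoSet: %d ROIs x %d frames at %g Hz\n",
              nrow(object), ncol(object), S4Vectors::metadata(object)$rate))
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
})
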