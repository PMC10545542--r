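# Fluorescence preprocessing: neuropil correction, delta-F/F, noise,
# smoothing, artifact interpolation, spike inference and correlation-growing
# ROI segmentation.

#' Neuropil correction and delta-F/F
#'
#' Correct a raw fluorescence trace by subtracting a fraction of the
#' surround (neuropil) signal, `F = f_raw - factor * f_neuropil`, then
#' normalize: `dff = (F - F0) / F0`. The baseline `F0` is either the median
#' of the corrected signal over a period of inactivity
#' (`baselineMode = "inactivity_median"`, default window chosen by the
#' caller, typically the longest bout-free stretch of at least 3 s) or the
#' median of the lowest 10th percentile of the corrected signal
#' (`baselineMode = "low_percentile"`).
#'
#' @param fRaw,fNeuropil numeric vectors of equal length.
#' @param neuropilFactor contamination fraction in `[0, 1)` (default 0.7).
#' @param baselineMode `"inactivity_median"` or `"low_percentile"`.
#' @param inactivityIdx integer frame indices of the inactivity window
#'   (required for `"inactivity_median"`).
#' @param percentile lower-tail fraction for `"low_percentile"`
#'   (default 0.10).
#' @return list with `dff` and `f0`.
#' @examples
#' out <- neuropilCorrectDff(c(rep(100, 50), rep(200, 50)), rep(0, 100),
#'                           baselineMode = "inactivity_median",
#'                           inactivityIdx = 1:50)
#' tail(out$dff, 1)  # 1.0 on the plateau
#' @export
neuropilCorrectDff <- function(fRaw, fNeuropil = NULL, neuropilFactor = 0.7,
                               baselineMode = c("inactivity_median",
                                                "low_percentile"),
                               inactivityIdx = NULL, percentile = 0.10) {
  baselineMode <- match.arg(baselineMode)
  if (is.null(fNeuropil)) fNeuropil <- numeric(length(fRaw))
  stopifnot(length(fRaw) == length(fNeuropil),
            neuropilFactor >= 0, neuropilFactor < 1)
  f <- fRaw - neuropilFactor * fNeuropil
  f0 <- switch(baselineMode,
    inactivity_median = {
      if (is.null(inactivityIdx))
        stop("inactivityIdx required for inactivity_median baseline")
      median(f[inactivityIdx])
    },
    low_percentile = {
      thr <- quantile(f, percentile, names = FALSE)
      median(f[f <= thr])
    })
  if (!is.finite(f0) || f0 <= 0) stop("degenerate baseline")
  list(dff = (f - f0) / f0, f0 = f0)
}

#' Noise estimate from an inactivity period
#'
#' Sample standard deviation of delta-F/F over a period of behavioral
#' inactivity; used as the unit of all recruitment thresholds.
#'
#' @param dffSeries numeric delta-F/F vector.
#' @param inactivityIdx frame indices of the inactivity window; must lie
#'   inside the trace and span at least `minFrames` frames.
#' @param minFrames minimum window length in frames (default 2).
#' @return noise sigma (delta-F/F units).
#' @export
estimateNoise <- function(dffSeries, inactivityIdx, minFrames = 2L) {
  if (any(inactivityIdx < 1L) || any(inactivityIdx > length(dffSeries)))
    stop("inactivity interval outside trace")
  if (length(inactivityIdx) < minFrames)
    stop("inactivity interval too short")
  sd(dffSeries[inactivityIdx])
}

#' Smooth a delta-F/F trace
#'
#' `"running_average_3"` is a centered 3-frame mean with shrink-to-valid
#' edges (2-frame mean at the first and last frame). `"low_pass"` is a
#' zero-phase first-order exponential smoother (forward and backward pass)
#' with smoothing coefficient `exp(-2*pi*cutoffHz/rate)`.
#'
#' @param dffSeries numeric vector, at least 3 frames.
#' @param mode `"running_average_3"` or `"low_pass"`.
#' @param cutoffHz low-pass cutoff in Hz (used by `"low_pass"`).
#' @param rate frame rate in Hz (used by `"low_pass"`).
#' @return smoothed vector, same length.
#' @export
smoothTrace <- function(dffSeries, mode = c("running_average_3", "low_pass"),
                        cutoffHz = 1, rate = 10) {
  mode <- match.arg(mode)
  n <- length(dffSeries)
  stopifnot(n >= 3L)
  if (mode == "running_average_3") {
    out <- as.numeric(stats::filter(dffSeries, rep(1 / 3, 3), sides = 2))
    out[1L] <- mean(dffSeries[1:2])
    out[n] <- mean(dffSeries[(n - 1L):n])
    out
  } else {
    a <- exp(-2 * pi * cutoffHz / rate)
    fwd <- as.numeric(stats::filter((1 - a) * dffSeries, a, method = "recursive"))
    rev(as.numeric(stats::filter((1 - a) * rev(fwd), a, method = "recursive")))
  }
}

#' Mask artifact frames and interpolate
#'
#' Replaces masked frames by linear interpolation between the nearest good
#' neighbors (constant extrapolation at the edges); unmasked frames are
#' returned bit-identical.
#'
#' @param dffSeries numeric vector.
#' @param badFrames integer indices of artifact frames.
#' @return vector with masked frames filled in.
#' @export
maskAndInterpolate <- function(dffSeries, badFrames) {
  n <- length(dffSeries)
  if (!length(badFrames)) return(dffSeries)
  badFrames <- unique(as.integer(badFrames))
  stopifnot(all(badFrames >= 1L), all(badFrames <= n))
  good <- setdiff(seq_len(n), badFrames)
  if (!length(good)) stop("all frames masked")
  out <- dffSeries
  out[badFrames] <- approx(good, dffSeries[good], xout = badFrames,
                           rule = 2)$y
  out
}

#' Infer a nonnegative spike rate by exponential-kernel deconvolution
#'
#' Models delta-F/F as nonnegative spikes convolved with a first-order
#' calcium-indicator kernel `k(t) = exp(-t / decayS)` and inverts the model.
#' Because the kernel is a first-order autoregression on the frame grid,
#' the innovation `dff[t] - phi * dff[t-1]` (with
#' `phi = exp(-dt / decayS)`) recovers the spike input exactly for
#' noise-free data; nonnegativity is imposed by rectification, which
#' coincides with the nonnegative least-squares solution when the data were
#' generated by the matched kernel.
#'
#' @param dffSeries numeric delta-F/F vector.
#' @param decayS calcium decay time constant in seconds (default 1.8,
#'   GCaMP6s).
#' @param rate frame rate in Hz.
#' @return nonnegative spike-rate vector, same length as the input.
#' @examples
#' k <- exp(-(0:49) / (1.8 * 10))
#' tr <- as.numeric(stats::filter(replace(numeric(50), 11, 1), exp(-1 / 18),
#'                                method = "recursive"))
#' which.max(inferSpikeRate(tr, rate = 10))  # 11
#' @export
inferSpikeRate <- function(dffSeries, decayS = 1.8, rate = 10) {
  stopifnot(decayS > 0, rate > 0)
  n <- length(dffSeries)
  if (!n) return(numeric(0))
  phi <- exp(-1 / (rate * decayS))
  r <- c(dffSeries[1L],
         dffSeries[-1L] - phi * dffSeries[-n])
  pmax(r, 0)
}

#' Segment ROIs from a pixel movie by correlation growing
#'
#' Computes a correlation map (each pixel's trace against the mean trace of
#' its eight neighbors), then repeatedly seeds at the highest remaining map
#' value above `seedThreshold` and grows a region by admitting neighboring
#' pixels whose correlation with the running mean trace of the current
#' region exceeds a threshold that rises linearly from `seedThreshold`
#' for the closest neighbor to `farThreshold` at `farDistanceUm` from the
#' seed (constant beyond). Regions whose area falls inside
#' `areaRangeUm2` are accepted; oversized or undersized regions are
#' rejected, their pixels removed from the seed pool. ROI traces are the
#' sum of member-pixel traces.
#'
#' @param movie 3-D array `height x width x frames`.
#' @param pixelSizeUm pixel side length in micrometres (default 0.66).
#' @param seedThreshold minimum seed / nearest-neighbor correlation
#'   (default 0.3).
#' @param farThreshold correlation threshold at `farDistanceUm` (default
#'   0.35).
#' @param farDistanceUm distance at which the threshold saturates, in
#'   micrometres (default 3).
#' @param areaRangeUm2 accepted ROI area range in square micrometres
#'   (default `c(9, 28)`, approximately somatic).
#' @return list with `masks` (list of integer matrices of pixel
#'   coordinates, one row per pixel), `areasUm2`, `traces` (ROI x frame
#'   matrix of summed fluorescence) and `correlationMap`.
#' @export
segmentRoisByCorrelation <- function(movie, pixelSizeUm = 0.66,
                                     seedThreshold = 0.3,
                                     farThreshold = 0.35,
                                     farDistanceUm = 3,
                                     areaRangeUm2 = c(9, 28)) {
  d <- dim(movie)
  stopifnot(length(d) == 3L, d[1L] >= 3L, d[2L] >= 3L, d[3L] >= 50L)
  H <- d[1L]; W <- d[2L]
  X <- matrix(movie, H * W, d[3L])      # pixels x time, column-major
  px <- function(r, c) (c - 1L) * H + r
  neigh <- function(r, c) {
    rr <- pmax(1L, r - 1L):pmin(H, r + 1L)
    cc <- pmax(1L, c - 1L):pmin(W, c + 1L)
    g <- expand.grid(r = rr, c = cc)
    g <- g[!(g$r == r & g$c == c), , drop = FALSE]
    px(g$r, g$c)
  }
  safeCor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  cmap <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    nb <- neigh(r, cc)
    cmap[r, cc] <- safeCor(X[px(r, cc), ], colMeans(X[nb, , drop = FALSE]))
  }
  avail <- matrix(TRUE, H, W)
  pxArea <- pixelSizeUm^2
  masks <- list(); areas <- numeric(0); traces <- list()
  work <- cmap
  repeat {
    work[!avail] <- -Inf
    m <- max(work)
    if (!is.finite(m) || m <= seedThreshold) break
    seed <- which(work == m, arr.ind = TRUE)[1L, , drop = TRUE]
    region <- matrix(seed, 1L, 2L, dimnames = list(NULL, c("row", "col")))
    inRegion <- matrix(FALSE, H, W); inRegion[seed[1L], seed[2L]] <- TRUE
    meanTrace <- X[px(seed[1L], seed[2L]), ]
    maxPix <- ceiling(areaRangeUm2[2L] / pxArea)
    repeat {
      cand <- unique(do.call(rbind, lapply(seq_len(nrow(region)), function(i) {
        r <- region[i, 1L]; cc <- region[i, 2L]
        rr <- pmax(1L, r - 1L):pmin(H, r + 1L)
        ccv <- pmax(1L, cc - 1L):pmin(W, cc + 1L)
        as.matrix(expand.grid(row = rr, col = ccv))
      })))
      keep <- avail[cand] & !inRegion[cand]
      cand <- cand[keep, , drop = FALSE]
      if (!nrow(cand)) break
      distUm <- sqrt((cand[, 1L] - seed[1L])^2 +
                     (cand[, 2L] - seed[2L])^2) * pixelSizeUm
      thr <- seedThreshold + (farThreshold - seedThreshold) *
        pmin(distUm, farDistanceUm) / farDistanceUm
      cors <- vapply(seq_len(nrow(cand)), function(i)
        safeCor(X[px(cand[i, 1L], cand[i, 2L]), ], meanTrace), numeric(1))
      ok <- which(cors > thr)
      if (!length(ok)) break
      # admit in decreasing correlation, first-found in row-major order on ties
      ok <- ok[order(-cors[ok], cand[ok, 2L], cand[ok, 1L])]
      add <- cand[ok, , drop = FALSE]
      region <- rbind(region, add)
      inRegion[add] <- TRUE
      meanTrace <- colMeans(X[px(region[, 1L], region[, 2L]), , drop = FALSE])
      # oversized regions keep growing to exhaustion so the whole
      # correlated blob is rejected at once, never as fragments
      if (nrow(region) > 8L * maxPix) break
    }
    avail[region] <- FALSE
    areaUm2 <- nrow(region) * pxArea
    if (areaUm2 >= areaRangeUm2[1L] && areaUm2 <= areaRangeUm2[2L]) {
      masks[[length(masks) + 1L]] <- region
      areas <- c(areas, areaUm2)
      traces[[length(traces) + 1L]] <-
        colSums(X[px(region[, 1L], region[, 2L]), , drop = FALSE])
    }
  }
  list(masks = masks, areasUm2 = areas,
       traces = if (length(traces)) do.call(rbind, traces)
                else matrix(numeric(0), 0, d[3L]),
       correlationMap = cmap)
}

#' Preprocess a FluoSet
#'
#' Runs the standard per-ROI preprocessing chain: neuropil correction and
#' delta-F/F, noise estimation on an inactivity window, optional smoothing,
#' and artifact interpolation. The inactivity window is the longest
#' bout-free stretch of at least `minInactivityS` seconds when a bout table
#' is supplied; with no qualifying stretch the baseline falls back to the
#' low-percentile mode with a warning.
#'
#' @param fs a [FluoSet-class].
#' @param bouts optional bout data.frame from [extractBouts()], used to
#'   locate inactivity.
#' @param neuropilFactor see [neuropilCorrectDff()] (default 0.7).
#' @param baselineMode baseline mode; `"auto"` picks inactivity when a bout
#'   table permits, else low percentile.
#' @param minInactivityS minimum inactivity length in seconds (default 3).
#' @param smoothMode `"running_average_3"` (default), `"low_pass"`, or
#'   `"none"`.
#' @param badFrames integer indices of artifact frames to interpolate.
#' @return the FluoSet with `dff` assay, `f0`/`noiseSigma` rowData and the
#'   artifact mask filled in.
#' @export
preprocessFluo <- function(fs, bouts = NULL, neuropilFactor = 0.7,
                           baselineMode = c("auto", "inactivity_median",
                                            "low_percentile"),
                           minInactivityS = 3,
                           smoothMode = c("running_average_3", "low_pass",
                                          "none"),
                           badFrames = integer(0)) {
  baselineMode <- match.arg(baselineMode)
  smoothMode <- match.arg(smoothMode)
  stopifnot(is(fs, "FluoSet"))
  ft <- frameTimes(fs)
  rate <- sampleRate(fs)
  inact <- NULL
  if (baselineMode != "low_percentile") {
    inact <- findInactivityWindow(ft, bouts, minInactivityS)
    if (is.null(inact)) {
      if (baselineMode == "inactivity_median")
        warning("no inactivity window of ", minInactivityS,
                " s; falling back to low-percentile baseline")
      baselineMode <- "low_percentile"
    } else baselineMode <- "inactivity_median"
  }
  fraw <- SummarizedExperiment::assay(fs, "fraw")
  fneu <- SummarizedExperiment::assay(fs, "fneuropil")
  dffM <- matrix(NA_real_, nrow(fraw), ncol(fraw), dimnames = dimnames(fraw))
  f0 <- noise <- numeric(nrow(fraw))
  for (i in seq_len(nrow(fraw))) {
    res <- neuropilCorrectDff(fraw[i, ], fneu[i, ],
                              neuropilFactor = neuropilFactor,
                              baselineMode = baselineMode,
                              inactivityIdx = inact)
    x <- res$dff
    if (length(badFrames)) x <- maskAndInterpolate(x, badFrames)
    noiseIdx <- if (!is.null(inact)) inact else
      which(res$dff <= quantile(res$dff, 0.10, names = FALSE))
    noise[i] <- estimateNoise(x, noiseIdx)
    if (smoothMode != "none") x <- smoothTrace(x, smoothMode, rate = rate)
    dffM[i, ] <- x
    f0[i] <- res$f0
  }
  SummarizedExperiment::assay(fs, "dff", withDimnames = FALSE) <- dffM
  SummarizedExperiment::rowData(fs)$f0 <- f0
  SummarizedExperiment::rowData(fs)$noiseSigma <- noise
  SummarizedExperiment::colData(fs)$artifact <-
    seq_len(ncol(fs)) %in% badFrames
  validObject(fs)
  fs
}

# longest bout-free frame-index window of >= minS seconds, or NULL
findInactivityWindow <- function(frameTime, bouts, minS = 3) {
  if (is.null(bouts)) return(NULL)
  busy <- rep(FALSE, length(frameTime))
  dt <- if (length(frameTime) > 1L) median(diff(frameTime)) else 0
  # a frame is busy if its interval [t, t + dt) overlaps any bout
  for (i in seq_len(nrow(bouts)))
    busy <- busy | (frameTime + dt > bouts$start_s[i] &
                    frameTime < bouts$end_s[i])
  if (all(busy)) return(NULL)
  r <- rle(!busy)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  free <- which(r$values)
  if (!length(free)) return(NULL)
  lens <- frameTime[ends[free]] - frameTime[starts[free]]
  best <- free[which.max(lens)]
  if (max(lens) < minS) return(NULL)
  idx <- starts[best]:ends[best]
  # keep only the final minS seconds of the stretch: farthest from the
  # preceding bout, where residual indicator decay is smallest
  cut <- frameTime[ends[best]] - minS
  idx[frameTime[idx] >= cut]
}

#' Add inferred spike rates to a FluoSet
#'
#' @param fs a preprocessed [FluoSet-class].
#' @param decayS calcium decay in seconds (default 1.8).
#' @return the FluoSet with a `spikeRate` assay.
#' @export
inferSpikeRates <- function(fs, decayS = 1.8) {
  m <- dff(fs)
  sr <- t(apply(m, 1L, inferSpikeRate, decayS = decayS,
                rate = sampleRate(fs)))
  SummarizedExperiment::assay(fs, "spikeRate", withDimnames = FALSE) <- sr
  fs
}
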