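# Motor regressors: behavior-derived predictor series at the imaging rate,
# convolved with a calcium-indicator kernel.

#' Per-frame kinematic series
#'
#' Downsamples tail kinematics to the imaging frame grid. For each frame
#' interval `[t_i, t_{i+1})`: the instantaneous tail-beat amplitude (iTBA)
#' is the maximal absolute tail angle over the behavior samples in the
#' interval; the instantaneous tail-beat frequency (iTBF) is the mean of
#' the per-cycle frequencies whose cycle midpoint falls in the interval
#' (0 when no cycle does).
#'
#' @param trace a [TailTrace-class].
#' @param bends bend table from [detectBends()] for the whole session.
#' @param frameTime imaging frame times in seconds.
#' @return list with numeric vectors `itba_deg` and `itbf_hz`, one value
#'   per frame.
#' @export
frameKinematics <- function(trace, bends, frameTime) {
  t <- tailTime(trace); a <- abs(tailAngle(trace))
  nf <- length(frameTime)
  edges <- c(frameTime, frameTime[nf] + diff(frameTime[nf - c(1, 0)]))
  fr <- findInterval(t, edges, rightmost.closed = FALSE)
  itba <- rep(0, nf)
  agg <- tapply(a, factor(fr, levels = seq_len(nf)), max)
  itba[!is.na(agg)] <- agg[!is.na(agg)]
  ck <- cycleKinematics(bends)
  itbf <- rep(0, nf)
  if (length(ck$itbf_hz)) {
    cf <- findInterval(ck$itbf_t_s, edges, rightmost.closed = FALSE)
    m <- tapply(ck$itbf_hz, factor(cf, levels = seq_len(nf)), mean)
    itbf[!is.na(m)] <- m[!is.na(m)]
  }
  list(itba_deg = as.numeric(itba), itbf_hz = as.numeric(itbf))
}

#' Binary rise indicator of a kinematic series
#'
#' Smooths the series with a 5-frame running mean, differentiates, and
#' applies a Heaviside step: 1 where the smoothed series is increasing,
#' 0 elsewhere.
#'
#' @param series numeric vector.
#' @param smoothFrames running-mean width in frames (default 5).
#' @return 0/1 vector of the same length (first element 0).
#' @export
binaryRise <- function(series, smoothFrames = 5L) {
  stopifnot(length(series) > smoothFrames)
  sm <- as.numeric(stats::filter(series, rep(1 / smoothFrames, smoothFrames),
                                 sides = 2))
  # shrink-to-valid edges
  n <- length(series)
  half <- smoothFrames %/% 2L
  for (i in seq_len(half)) {
    sm[i] <- mean(series[1:(i + half)])
    sm[n - i + 1L] <- mean(series[(n - i + 1L - half):n])
  }
  tol <- 1e-10 * max(1, max(abs(sm)))   # guard against round-off on flats
  as.integer(c(0L, diff(sm) > tol))
}

#' Swim vigor
#'
#' Centered sliding standard deviation of the tail-angle trace (window
#' default 50 ms), a scalar proxy for instantaneous locomotor intensity.
#'
#' @param trace a [TailTrace-class].
#' @param windowS window length in seconds (default 0.050).
#' @return numeric vector at the behavior rate (edges use partial
#'   windows).
#' @export
vigor <- function(trace, windowS = 0.050) {
  a <- tailAngle(trace)
  w <- max(2L, round(windowS * sampleRate(trace)))
  as.numeric(zoo::rollapply(zoo::zoo(a), width = w, FUN = sd,
                            fill = NA, partial = 2, align = "center"))
}

#' Convolve a series with a calcium-indicator kernel
#'
#' Causal convolution with `k(t) = exp(-t / tauS)` sampled on the source
#' grid (implemented as a first-order recursive filter, which is exact for
#' this kernel), optionally sampled down to imaging frame times by taking
#' the instantaneous value at each frame time, and optionally z-scored.
#'
#' @param series numeric vector on a uniform source grid.
#' @param tauS kernel decay in seconds (default 1.5, GCaMP6s).
#' @param sourceRate sampling rate of `series` in Hz.
#' @param frameTime optional imaging frame times for downsampling; the
#'   source grid is assumed to start at t = 0.
#' @param zscore z-score the output (default FALSE).
#' @return convolved (and possibly downsampled / z-scored) vector.
#' @export
convolveKernel <- function(series, tauS = 1.5, sourceRate = 300,
                           frameTime = NULL, zscore = FALSE) {
  stopifnot(tauS > 0)
  phi <- exp(-1 / (sourceRate * tauS))
  y <- as.numeric(stats::filter(series, phi, method = "recursive"))
  if (!is.null(frameTime)) {
    src <- (seq_along(series) - 1L) / sourceRate
    idx <- pmin(pmax(findInterval(frameTime, src), 1L), length(series))
    y <- y[idx]
  }
  if (zscore) y <- as.numeric(scale(y))
  y
}

#' Build the four-regressor motor set plus vigor/bout/stimulus regressors
#'
#' Constructs the encoding-model predictors at the imaging rate: x1 = iTBA,
#' x2 = binary rise of iTBA, x3 = iTBF, x4 = binary rise of iTBF, each
#' convolved with the indicator kernel; plus vigor, bout on/off and
#' stimulus on/off regressors built the same way. Kinematic series are
#' computed per frame first, then convolved on the frame grid and z-scored.
#'
#' @param trace a [TailTrace-class].
#' @param bends session bend table.
#' @param frameTime imaging frame times.
#' @param bouts optional bout table for the bout on/off regressor.
#' @param stim optional stimulation table for the stimulus on/off
#'   regressor.
#' @param tauS indicator decay in seconds (default 1.5).
#' @param zscore z-score all regressors (default TRUE, matching the
#'   encoding-model convention).
#' @return data.frame with columns `frame_time_s`, `x_itba`,
#'   `x_itba_rise`, `x_itbf`, `x_itbf_rise`, `x_vigor`, `x_bout`,
#'   `x_stim`.
#' @export
buildRegressorSet <- function(trace, bends, frameTime, bouts = NULL,
                              stim = NULL, tauS = 1.5, zscore = TRUE) {
  fk <- frameKinematics(trace, bends, frameTime)
  frate <- 1 / median(diff(frameTime))
  conv <- function(x) convolveKernel(x, tauS = tauS, sourceRate = frate,
                                     zscore = FALSE)
  zs <- function(x) if (zscore && sd(x) > 0) as.numeric(scale(x)) else x
  vg <- vigor(trace)
  vgFrame <- convolveKernel(vg, tauS = tauS, sourceRate = sampleRate(trace),
                            frameTime = frameTime)
  boutOn <- rep(0, length(frameTime))
  if (!is.null(bouts) && nrow(bouts)) for (i in seq_len(nrow(bouts)))
    boutOn[frameTime >= bouts$start_s[i] & frameTime < bouts$end_s[i]] <- 1
  stimOn <- rep(0, length(frameTime))
  if (!is.null(stim) && nrow(stim)) for (i in seq_len(nrow(stim)))
    stimOn[frameTime >= stim$train_start_s[i] &
           frameTime < stim$train_end_s[i]] <- 1
  data.frame(
    frame_time_s = frameTime,
    x_itba = zs(conv(fk$itba_deg)),
    x_itba_rise = zs(conv(binaryRise(fk$itba_deg))),
    x_itbf = zs(conv(fk$itbf_hz)),
    x_itbf_rise = zs(conv(binaryRise(fk$itbf_hz))),
    x_vigor = zs(vgFrame),
    x_bout = zs(conv(boutOn)),
    x_stim = zs(conv(stimOn)))
}

#' Classify ROIs as motor- or vigor-correlated
#'
#' Per fish: a ROI is motor-correlated when its Pearson correlation to the
#' motor regressor exceeds the 75th percentile of motor correlations over
#' all ROIs. A ROI is vigor-correlated when its motor correlation exceeds
#' its stimulus correlation and its vigor correlation lies in the top
#' quartile (at or above the 75th percentile) of vigor correlations.
#'
#' @param rMotor,rStim,rVigor per-ROI Pearson correlations (equal length,
#'   at least 4 ROIs).
#' @return data.frame with logical columns `motor_correlated`,
#'   `vigor_correlated`.
#' @export
classifyMotorVigor <- function(rMotor, rStim, rVigor) {
  n <- length(rMotor)
  stopifnot(n >= 4L, length(rStim) == n, length(rVigor) == n)
  mthr <- quantile(rMotor, 0.75, names = FALSE, na.rm = TRUE)
  vthr <- quantile(rVigor, 0.75, names = FALSE, na.rm = TRUE)
  motor <- !is.na(rMotor) & rMotor > mthr
  vig <- !is.na(rMotor) & !is.na(rStim) & !is.na(rVigor) &
    rMotor > rStim & rVigor >= vthr
  data.frame(motor_correlated = motor, vigor_correlated = vig)
}
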