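# Synthetic session generator. Emulates the statistical structure the
# analysis assumes -- beat-and-glide bouts of known type, stimulation
# trains with evoked episodes, and GCaMP-like calcium traces with known
# couplings -- so that every analysis stage has a ground-truth oracle.
#
# Defaults mirror the recorded conditions: behavior at 300 Hz, imaging at
# 10 Hz, forward tail-beat frequency centered near 17 Hz, bout durations a
# few hundred milliseconds, indicator decay 1.8 s for calcium generation.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Synthesize one swim bout
#'
#' Generates a tail-angle segment of a known bout type. `forward` is a
#' lightly damped sine: amplitude below 25 degrees, at least three
#' oscillations, tail-beat frequency 15-30 Hz. `left_turn` / `right_turn`
#' prepend one signed 25-60 degree steering bend to a forward component.
#' `struggle` is a series of large bends (above 60 degrees, so the
#' whole-bout classifier discards it as escape-like) at 5-10 Hz.
#'
#' @param type bout type.
#' @param tbfHz tail-beat frequency in Hz (forward component).
#' @param ampDeg forward oscillation amplitude in degrees (< 25).
#' @param nOsc number of full oscillations (>= 3 for forward).
#' @param steerDeg absolute steering-bend amplitude for turns, in
#'   (25, 60); struggle bend amplitude is drawn separately.
#' @param struggleHz struggle bend frequency (default 7).
#' @param struggleAmpDeg struggle bend amplitude (default 75).
#' @param rate behavior sampling rate in Hz (default 300).
#' @param damp terminal fraction of the initial amplitude (default 0.8).
#' @return list: `angle` (numeric segment), `truth` (list with the type,
#'   expected whole-bout class, expected episode label sequence, true TBF,
#'   amplitude and oscillation count).
#' @export
synthBout <- function(type = c("forward", "left_turn", "right_turn",
                               "struggle"),
                      tbfHz = 17, ampDeg = 15, nOsc = 5, steerDeg = 40,
                      struggleHz = 7, struggleAmpDeg = 75, rate = 300,
                      damp = 0.8) {
  type <- match.arg(type)
  if (type == "forward" && ampDeg >= 25)
    stop("contradictory params: forward amplitude must be below 25 degrees")
  if (type == "forward" && nOsc < 3)
    stop("contradictory params: forward needs at least 3 oscillations")
  if (type %in% c("left_turn", "right_turn") &&
      (steerDeg <= 25 || steerDeg >= 60))
    stop("contradictory params: steering bend must lie in (25, 60) degrees")
  if (type != "struggle" && (tbfHz < 15 || tbfHz > 30))
    stop("contradictory params: forward TBF must lie in [15, 30] Hz")
  fwdSeg <- function() {
    dur <- nOsc / tbfHz
    t <- seq(0, dur, by = 1 / rate)
    env <- 1 + (damp - 1) * t / dur
    ampDeg * env * sin(2 * pi * tbfHz * t)
  }
  if (type == "forward") {
    ang <- fwdSeg()
    truth <- list(type = type, class = "forward",
                  episode_labels = "forward", tbf_hz = tbfHz,
                  amp_deg = ampDeg, n_osc = nOsc)
  } else if (type %in% c("left_turn", "right_turn")) {
    sgn <- if (type == "left_turn") 1 else -1
    tb <- seq(0, 1 / (2 * tbfHz), by = 1 / rate)
    steer <- sgn * steerDeg * sin(pi * tb / max(tb))
    # forward component continues with opposite-sign first half-cycle
    fw <- fwdSeg() * (-sgn)
    ang <- c(steer, fw)
    truth <- list(type = type, class = type,
                  episode_labels = c("struggle", "forward"),
                  tbf_hz = tbfHz, amp_deg = steerDeg, n_osc = nOsc)
  } else {
    nb <- max(2L, round(nOsc * 2))
    dur <- nb / (2 * struggleHz)
    t <- seq(0, dur, by = 1 / rate)
    ang <- struggleAmpDeg * sin(2 * pi * struggleHz * t)
    truth <- list(type = type, class = "discarded",
                  episode_labels = "struggle", tbf_hz = struggleHz,
                  amp_deg = struggleAmpDeg, n_osc = floor(nb / 2))
  }
  list(angle = ang, truth = truth)
}

#' Schedule random bouts
#'
#' Draws a non-overlapping bout schedule with realistic kinematic ranges:
#' forward TBF 15-30 Hz centered near 17, amplitudes 8-22 degrees,
#' durations set by 3-8 oscillations (a few hundred milliseconds), quiet
#' gaps of `gapS` on average.
#'
#' @param n number of bouts.
#' @param types bout types to draw from (with equal probability).
#' @param gapS mean quiet gap between bouts in seconds (default 2).
#' @param startS time of the first bout (default 5).
#' @param seed RNG seed.
#' @return data.frame schedule usable by [synthSession()].
#' @export
scheduleBouts <- function(n, types = c("forward", "left_turn",
                                       "right_turn", "struggle"),
                          gapS = 2, startS = 5, seed = 1L) {
  if (n == 0L)
    return(data.frame(type = character(0), start_s = numeric(0),
                      tbf_hz = numeric(0), amp_deg = numeric(0),
                      n_osc = integer(0), steer_deg = numeric(0)))
  withSeed(seed, {
    type <- sample(types, n, replace = TRUE)
    tbf <- pmin(30, pmax(15, rnorm(n, 17, 3)))
    amp <- runif(n, 8, 22)
    nosc <- sample(3:8, n, replace = TRUE)
    steer <- runif(n, 30, 55)
    dur <- ifelse(type == "struggle", (pmax(2, round(nosc * 2)) / 2) / 7,
                  nosc / tbf + ifelse(type == "forward", 0, 1 / (2 * tbf)))
    gaps <- gapS * (0.5 + runif(n))
    start <- startS + cumsum(c(0, (dur + gaps)[-n]))
    data.frame(type = type, start_s = start, tbf_hz = tbf, amp_deg = amp,
               n_osc = nosc, steer_deg = steer)
  })
}

#' Synthesize a full behavior session
#'
#' Concatenates quiet gaps and scheduled bouts into a 300-Hz tail-angle
#' trace, optionally adds Gaussian angle noise, tags stimulation trains
#' and, when requested, places seconds-long evoked forward episodes inside
#' the trains.
#'
#' @param schedule data.frame from [scheduleBouts()] (columns `type`,
#'   `start_s`, `tbf_hz`, `amp_deg`, `n_osc`, `steer_deg`); must be
#'   non-overlapping.
#' @param stim optional stimulation table from [stimTrials()].
#' @param durationS total session length in seconds (default covers the
#'   schedule plus 5 s).
#' @param rate behavior rate in Hz (default 300).
#' @param noiseSdDeg additive Gaussian angle noise s.d. in degrees
#'   (default 0).
#' @param seed RNG seed.
#' @return list: `trace` (a [TailTrace-class]), `truth` (data.frame with
#'   realized start/end, type, expected class, oscillation count and an
#'   `episode_labels` list-column), `stim`.
#' @export
synthSession <- function(schedule, stim = NULL, durationS = NULL,
                         rate = 300, noiseSdDeg = 0, seed = 1L) {
  if (is.null(durationS))
    durationS <- if (nrow(schedule)) max(schedule$start_s) + 6 else 10
  n <- round(durationS * rate)
  ang <- numeric(n)
  truth <- vector("list", nrow(schedule))
  if (nrow(schedule) > 1L &&
      any(diff(order(schedule$start_s)) != 1L))
    schedule <- schedule[order(schedule$start_s), ]
  lastEnd <- -Inf
  for (i in seq_len(nrow(schedule))) {
    sb <- synthBout(schedule$type[i], tbfHz = schedule$tbf_hz[i],
                    ampDeg = schedule$amp_deg[i],
                    nOsc = schedule$n_osc[i],
                    steerDeg = schedule$steer_deg[i], rate = rate)
    i0 <- round(schedule$start_s[i] * rate) + 1L
    i1 <- i0 + length(sb$angle) - 1L
    if (i0 <= lastEnd || i1 > n) stop("overlapping or out-of-range schedule")
    ang[i0:i1] <- sb$angle
    lastEnd <- i1
    truth[[i]] <- data.frame(
      bout_id = i, type = sb$truth$type, class = sb$truth$class,
      start_s = (i0 - 1L) / rate, end_s = i1 / rate,
      tbf_hz = sb$truth$tbf_hz, amp_deg = sb$truth$amp_deg,
      n_osc = sb$truth$n_osc,
      episode_labels = I(list(sb$truth$episode_labels)))
  }
  if (noiseSdDeg > 0) ang <- withSeed(seed, ang + rnorm(n, 0, noiseSdDeg))
  truthDf <- if (length(truth)) do.call(rbind, truth) else
    data.frame(bout_id = integer(0))
  list(trace = TailTrace(ang, rate = rate), truth = truthDf, stim = stim)
}

# per-frame ground-truth kinematics from the schedule (no analysis code)
truthFrameKinematics <- function(truth, frameTime) {
  nf <- length(frameTime)
  itbf <- itba <- rep(0, nf)
  for (i in seq_len(nrow(truth))) {
    sel <- frameTime >= truth$start_s[i] & frameTime < truth$end_s[i]
    itbf[sel] <- truth$tbf_hz[i]
    itba[sel] <- truth$amp_deg[i]
  }
  list(itbf_hz = itbf, itba_deg = itba)
}

#' Synthesize a population of calcium traces with known couplings
#'
#' Draws per-neuron drive series according to an archetype, convolves with
#' an exponential indicator kernel (decay `decayS`), and assembles raw and
#' neuropil fluorescence: `fraw = F0 * (1 + dff) + contam * fneuropil +
#' noise`. All couplings are recorded as ground truth.
#'
#' Archetypes: `null` (constant low drive), `itbf_coder` (drive
#' proportional to the true per-frame TBF), `itba_rise_coder` (drive on
#' rising true amplitude), `oscillation_counter` (impulse of mass
#' `gain * ln(n_osc)` at each forward-bout start), `forward_component`
#' (drive during every non-discarded bout), `left_steering` /
#' `right_steering` (drive during turns of that side only),
#' `stim_reliable` (impulse after each train with intensity at or above
#' the neuron's threshold), `stim_unreliable` (responds to a random subset
#' of trains above its threshold).
#'
#' @param session output of [synthSession()].
#' @param archetypes character vector, one archetype per neuron.
#' @param rate imaging frame rate in Hz (default 10).
#' @param decayS indicator decay in seconds (default 1.8).
#' @param noiseSd additive Gaussian noise s.d. on F, in F0 units of 1
#'   (default 0.01).
#' @param gain drive gain (delta-F/F scale per unit drive; default 0.5).
#' @param f0 baseline fluorescence (default 100).
#' @param contam neuropil contamination fraction (default 0.7).
#' @param reliableThreshUa threshold intensity assigned to `stim_reliable`
#'   neurons (default 3).
#' @param seed RNG seed.
#' @return list: `fluo` (a [FluoSet-class]), `truth` (data.frame with
#'   archetype, gain, threshold), `drive` (neuron x frame drive matrix),
#'   `dffTrue` (noise-free delta-F/F), `frameTime`.
#' @export
synthNeurons <- function(session, archetypes, rate = 10, decayS = 1.8,
                         noiseSd = 0.01, gain = 0.5, f0 = 100,
                         contam = 0.7, reliableThreshUa = 3, seed = 1L) {
  truth <- session$truth
  dur <- max(tailTime(session$trace)) + 1 / sampleRate(session$trace)
  frameTime <- seq(0, dur - 1 / rate, by = 1 / rate)
  nf <- length(frameTime)
  tk <- truthFrameKinematics(truth, frameTime)
  nn <- length(archetypes)
  drive <- matrix(0, nn, nf)
  thr <- rep(NA_real_, nn)
  stim <- session$stim
  withSeed(seed, {
    for (j in seq_len(nn)) {
      a <- archetypes[j]
      d <- numeric(nf)
      if (a == "null") {
        d[] <- 0
      } else if (a == "itbf_coder") {
        d <- tk$itbf_hz / 20
      } else if (a == "itba_rise_coder") {
        rises <- c(0, diff(tk$itba_deg) > 0)
        d <- rises
      } else if (a == "oscillation_counter") {
        fwd <- truth[truth$class == "forward", , drop = FALSE]
        for (i in seq_len(nrow(fwd))) {
          k <- findInterval(fwd$start_s[i], frameTime)
          d[max(1L, k)] <- d[max(1L, k)] + log(fwd$n_osc[i])
        }
      } else if (a == "forward_component") {
        act <- truth[truth$class != "discarded", , drop = FALSE]
        for (i in seq_len(nrow(act)))
          d[frameTime >= act$start_s[i] & frameTime < act$end_s[i]] <- 1
      } else if (a %in% c("left_steering", "right_steering")) {
        side <- if (a == "left_steering") "left_turn" else "right_turn"
        act <- truth[truth$class == side, , drop = FALSE]
        for (i in seq_len(nrow(act)))
          d[frameTime >= act$start_s[i] & frameTime < act$end_s[i]] <- 1
      } else if (a %in% c("stim_reliable", "stim_unreliable")) {
        if (is.null(stim) || !nrow(stim))
          stop("stim archetypes require a stimulation table")
        thr[j] <- reliableThreshUa
        for (i in seq_len(nrow(stim))) {
          if (stim$intensity_ua[i] < thr[j]) next
          if (a == "stim_unreliable" && runif(1) < 0.5) next
          k <- findInterval(stim$train_start_s[i], frameTime)
          d[max(1L, k)] <- d[max(1L, k)] + 2
        }
        if (a == "stim_unreliable") {
          # guarantee at least one hit and one miss above threshold
          above <- which(stim$intensity_ua >= thr[j])
          if (length(above) >= 2L) {
            kHit <- findInterval(stim$train_start_s[above[1L]], frameTime)
            d[max(1L, kHit)] <- 2
            kMiss <- findInterval(stim$train_start_s[above[length(above)]],
                                  frameTime)
            d[max(1L, kMiss)] <- 0
          }
        }
      } else stop("unknown archetype: ", a)
      drive[j, ] <- d
    }
    phi <- exp(-1 / (rate * decayS))
    dffTrue <- t(apply(drive, 1L, function(d)
      gain * as.numeric(stats::filter(d, phi, method = "recursive"))))
    fneu <- matrix(rep(5 + 2 * (tk$itba_deg > 0), each = nn), nn, nf)
    noise <- matrix(rnorm(nn * nf, 0, noiseSd * f0), nn, nf)
    fraw <- f0 * (1 + dffTrue) + contam * fneu + noise
    fs <- FluoSet(fraw, fneu, frameTime = frameTime, rate = rate)
    list(fluo = fs,
         truth = data.frame(roi = seq_len(nn), archetype = archetypes,
                            gain = gain, threshold_ua = thr),
         drive = drive, dffTrue = dffTrue, frameTime = frameTime)
  })
}

#' Synthesize a pixel movie with planted ROIs
#'
#' Each planted ROI is a disk of pixels sharing one latent fluorescence
#' trace plus per-pixel noise; background pixels are i.i.d. noise.
#'
#' @param height,width movie dimensions in pixels.
#' @param nFrames number of frames (>= 50).
#' @param centers matrix of disk centers (rows: `row`, `col`), possibly
#'   zero rows.
#' @param areaPx planted ROI area in pixels: the `areaPx` grid pixels
#'   nearest each center (default 12, i.e. 12 um2 at 1 um pixels).
#' @param snr ratio of latent-signal s.d. to pixel noise s.d. (default 4).
#' @param pixelSizeUm pixel size (default 1).
#' @param seed RNG seed.
#' @return list: `movie` (array), `masks` (list of planted pixel-index
#'   matrices), `pixelSizeUm`.
#' @export
synthPixelMovie <- function(height, width, nFrames = 120,
                            centers = matrix(numeric(0), 0, 2),
                            areaPx = 12L, snr = 4, pixelSizeUm = 1,
                            seed = 1L) {
  stopifnot(nFrames >= 50L)
  centers <- matrix(as.numeric(centers), ncol = 2)
  withSeed(seed, {
    movie <- array(rnorm(height * width * nFrames), c(height, width, nFrames))
    masks <- list()
    taken <- matrix(FALSE, height, width)
    for (i in seq_len(nrow(centers))) {
      g <- expand.grid(row = seq_len(height), col = seq_len(width))
      d <- sqrt((g$row - centers[i, 1])^2 + (g$col - centers[i, 2])^2)
      sel <- g[order(d, g$col, g$row)[seq_len(areaPx)], , drop = FALSE]
      if (any(taken[as.matrix(sel)])) stop("overlapping ROI layout")
      taken[as.matrix(sel)] <- TRUE
      latent <- rnorm(nFrames, 0, snr)
      for (k in seq_len(nrow(sel)))
        movie[sel$row[k], sel$col[k], ] <-
          movie[sel$row[k], sel$col[k], ] + latent
      masks[[i]] <- as.matrix(sel)
    }
    list(movie = movie, masks = masks, pixelSizeUm = pixelSizeUm)
  })
}
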