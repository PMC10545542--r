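# Tail-kinematics segmentation: bends, bouts, cycles, episodes, bout
# classification and forward indices.
#
# Conventions fixed package-wide:
#  * positive angle = leftward tail deflection; a positive maximum bend is a
#    left turn
#  * intervals are half-open [start, end) in seconds, origin at the first
#    behavior sample
#  * an oscillation (full cycle) is two consecutive opposite-sign bends;
#    instantaneous TBF uses same-side bend spacing 1/(t_i - t_{i-2})

#' Detect tail bends
#'
#' Extracts the timing and signed amplitude of each tail bend (half-cycle
#' extremum) from a tail-angle trace. The trace is first smoothed with a
#' 3-sample median filter, local extrema are located, extrema below
#' `minAmpDeg` are suppressed, and runs of consecutive same-sign extrema are
#' collapsed to the largest one so that surviving bends alternate in sign.
#'
#' @param trace a [TailTrace-class].
#' @param minAmpDeg minimum absolute bend amplitude in degrees (hysteresis
#'   threshold for ripple suppression; default 5).
#' @return A data.frame with columns `t_s` (time of extremum) and `amp_deg`
#'   (signed peak angle), ordered in time. Zero rows if no bend qualifies.
#' @examples
#' tr <- TailTrace(15 * sin(2 * pi * 20 * (0:74) / 300))
#' detectBends(tr)
#' @export
detectBends <- function(trace, minAmpDeg = 5) {
  stopifnot(is(trace, "TailTrace"), minAmpDeg >= 0)
  validObject(trace)
  a <- tailAngle(trace)
  t <- tailTime(trace)
  n <- length(a)
  if (n < 3L) return(data.frame(t_s = numeric(0), amp_deg = numeric(0)))
  sm <- as.numeric(stats::runmed(a, k = 3, endrule = "keep"))
  d <- diff(sm)
  s <- sign(d)
  # carry sign through flat stretches so plateau extrema are found once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  idx <- which(diff(s) != 0) + 1L
  if (!length(idx)) return(data.frame(t_s = numeric(0), amp_deg = numeric(0)))
  # refine each extremum on the raw trace within one sample
  pos <- vapply(idx, function(i) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    (lo:hi)[which.max(abs(a[lo:hi]))]
  }, integer(1))
  amp <- a[pos]
  keep <- abs(amp) >= minAmpDeg & amp != 0
  amp <- amp[keep]; pos <- pos[keep]
  if (!length(amp)) return(data.frame(t_s = numeric(0), amp_deg = numeric(0)))
  # collapse consecutive same-sign bends (sub-threshold ripple around one
  # extremum) to the largest magnitude -- but only when the trace does not
  # relax to baseline in between, so bends of distinct movements survive
  sameEvent <- function(i, j) {
    min(abs(a[pos[i]:pos[j]])) >= minAmpDeg
  }
  grp <- integer(length(amp)); grp[1L] <- 1L
  if (length(amp) > 1L) for (i in 2:length(amp)) {
    grp[i] <- if (sign(amp[i]) == sign(amp[i - 1L]) && sameEvent(i - 1L, i))
      grp[i - 1L] else grp[i - 1L] + 1L
  }
  pick <- vapply(split(seq_along(amp), grp), function(ii) {
    ii[which.max(abs(amp[ii]))]
  }, integer(1))
  pick <- sort(pick)
  data.frame(t_s = t[pos[pick]], amp_deg = amp[pick])
}

#' Extract swim bouts
#'
#' Finds discrete events when the tail is continuously moving: maximal
#' intervals where the absolute tail angle exceeds `motionThresholdDeg`,
#' merged when separated by less than `minQuietS` of quiescence. Each bout
#' carries its bends and cycle-level kinematic summaries, is classified with
#' [classifyBout()], and is tagged evoked when its start falls inside a
#' stimulation train. Bouts starting within `excludeAfterTrainS` after the
#' end of a train are flagged `post_stim` and excluded from the spontaneous
#' pool.
#'
#' @param trace a [TailTrace-class].
#' @param motionThresholdDeg motion threshold in degrees (default 3).
#' @param minQuietS minimum quiet gap in seconds separating bouts
#'   (default 0.1).
#' @param minAmpDeg bend threshold passed to [detectBends()].
#' @param stim optional stimulation-trial data.frame (see [stimTrials()]);
#'   used to tag bouts as evoked/spontaneous.
#' @param excludeAfterTrainS bouts starting within this window after a
#'   train end are excluded from the spontaneous pool (default 60).
#' @return A data.frame with one row per bout: `bout_id`, `start_s`,
#'   `end_s`, `duration_s`, `n_bends`, `n_oscillations`, `max_abs_tba_deg`,
#'   `median_itbf_hz`, `median_itba_deg`, `label`, `provenance`, `stim_id`.
#'   The per-bout bend tables are attached as the `"bends"` attribute (a
#'   list indexed by `bout_id`).
#' @export
extractBouts <- function(trace, motionThresholdDeg = 3, minQuietS = 0.1,
                         minAmpDeg = 5, stim = NULL,
                         excludeAfterTrainS = 60) {
  stopifnot(is(trace, "TailTrace"),
            motionThresholdDeg > 0, minQuietS > 0)
  validObject(trace)
  a <- tailAngle(trace)
  t <- tailTime(trace)
  dt <- 1 / sampleRate(trace)
  # threshold a 5-sample median envelope so isolated noise spikes cannot
  # open a bout
  env <- as.numeric(stats::runmed(abs(a), k = 5, endrule = "keep"))
  active <- env > motionThresholdDeg
  empty <- data.frame(bout_id = integer(0), start_s = numeric(0),
                      end_s = numeric(0), duration_s = numeric(0),
                      n_bends = integer(0), n_oscillations = integer(0),
                      max_abs_tba_deg = numeric(0),
                      median_itbf_hz = numeric(0),
                      median_itba_deg = numeric(0),
                      label = character(0), provenance = character(0),
                      stim_id = integer(0))
  if (!any(active)) { attr(empty, "bends") <- list(); return(empty) }
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < minQuietS
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) for (i in 2:nrow(runs)) {
    gap <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * dt
    if (gap < minQuietS) merged$end[nrow(merged)] <- runs$end[i]
    else merged <- rbind(merged, runs[i, ])
  }
  bends_all <- detectBends(trace, minAmpDeg = minAmpDeg)
  out <- vector("list", nrow(merged))
  bendlist <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    s <- t[merged$start[i]]
    e <- t[merged$end[i]] + dt           # half-open [start, end)
    b <- bends_all[bends_all$t_s >= s & bends_all$t_s < e, , drop = FALSE]
    ck <- cycleKinematics(b)
    maxtba <- if (nrow(b)) max(abs(b$amp_deg)) else 0
    prov <- "spontaneous"; sid <- NA_integer_
    if (!is.null(stim) && nrow(stim)) {
      inTrain <- which(s >= stim$train_start_s & s < stim$train_end_s)
      if (length(inTrain)) {
        prov <- "evoked"; sid <- stim$stim_id[inTrain[1L]]
      } else if (any(s >= stim$train_end_s &
                     s < stim$train_end_s + excludeAfterTrainS)) {
        prov <- "post_stim"
      }
    }
    out[[i]] <- data.frame(
      bout_id = i, start_s = s, end_s = e, duration_s = e - s,
      n_bends = nrow(b), n_oscillations = ck$n_oscillations,
      max_abs_tba_deg = maxtba,
      median_itbf_hz = if (length(ck$itbf_hz)) median(ck$itbf_hz) else NA_real_,
      median_itba_deg = if (length(ck$itba_deg)) median(ck$itba_deg) else NA_real_,
      label = classifyBoutLabel(maxtba, b),
      provenance = prov, stim_id = sid)
    bendlist[[i]] <- b
  }
  res <- do.call(rbind, out)
  # intervals without a single qualifying bend are noise blips, not bouts
  keep <- res$n_bends > 0L
  res <- res[keep, , drop = FALSE]
  bendlist <- bendlist[keep]
  if (nrow(res)) {
    res$bout_id <- seq_len(nrow(res))
    rownames(res) <- NULL
  }
  names(bendlist) <- res$bout_id
  attr(res, "bends") <- bendlist
  res
}

#' Cycle-level kinematics from bends
#'
#' A cycle is two consecutive opposite-sign bends (one left plus one right
#' half-cycle). The instantaneous tail-beat frequency of cycle *i* is the
#' inverse of the same-side bend spacing, `1/(t_i - t_{i-2})`; the
#' instantaneous amplitude is `|amp|` per bend; the oscillation count is
#' `floor(n_bends / 2)`.
#'
#' @param bends bend data.frame from [detectBends()].
#' @return list with `itbf_hz` (per-cycle frequency, one per bend from the
#'   third on), `itbf_t_s` (cycle midpoint times), `itba_deg` (per-bend
#'   absolute amplitude), `n_oscillations`.
#' @examples
#' b <- data.frame(t_s = (0:6) * 0.025, amp_deg = 15 * c(1, -1, 1, -1, 1, -1, 1))
#' cycleKinematics(b)$itbf_hz  # 20 Hz everywhere
#' @export
cycleKinematics <- function(bends) {
  n <- nrow(bends)
  if (is.null(n) || n < 2L)
    return(list(itbf_hz = numeric(0), itbf_t_s = numeric(0),
                itba_deg = if (is.null(n) || n < 1L) numeric(0) else abs(bends$amp_deg),
                n_oscillations = 0L))
  itbf <- numeric(0); tmid <- numeric(0)
  if (n >= 3L) {
    i <- 3:n
    itbf <- 1 / (bends$t_s[i] - bends$t_s[i - 2L])
    tmid <- (bends$t_s[i] + bends$t_s[i - 2L]) / 2
  }
  list(itbf_hz = itbf, itbf_t_s = tmid, itba_deg = abs(bends$amp_deg),
       n_oscillations = as.integer(floor(n / 2)))
}

# bout label from max TBA and the signed maximum bend
classifyBoutLabel <- function(maxtba, bends) {
  if (!nrow(bends) || maxtba == 0) return("unclassified")
  if (maxtba < 25) return("forward")
  if (maxtba > 60) return("discarded")
  s <- bends$amp_deg[which.max(abs(bends$amp_deg))]
  if (s > 0) "left_turn" else "right_turn"
}

#' Classify a swim bout
#'
#' Applies the amplitude rule: maximum absolute tail-bend amplitude below
#' 25 degrees is a forward swim; between 25 and 60 degrees is a turn, with
#' the side given by the sign of the maximum-magnitude bend (positive =
#' left under the left-positive convention); above 60 degrees the bout is
#' discarded (escape/struggle-like).
#'
#' @param bout one row of the data.frame from [extractBouts()], or any list
#'   with `max_abs_tba_deg`; the signed side is taken from the `bends`
#'   data.frame argument.
#' @param bends the bout's bend table.
#' @return one of `"forward"`, `"left_turn"`, `"right_turn"`,
#'   `"discarded"`, `"unclassified"`.
#' @export
classifyBout <- function(bout, bends) {
  classifyBoutLabel(bout$max_abs_tba_deg, bends)
}

#' Segment a bout into forward and struggle episodes
#'
#' Implements the three-rule episode segmentation. Rule 1: runs of bends all
#' below 25 degrees with at least three full oscillations become forward
#' episodes. Rule 2: a rare isolated bend above 25 degrees, flanked by at
#' least two sub-threshold oscillations on each side (and no denser than
#' one per six sub-threshold oscillations), does not split a forward
#' episode; such bends are kept inside the episode interval but excluded
#' from its kinematic accounting. Rule 3: consecutive bends above
#' 25 degrees form a single struggle episode, split into several where
#' successive supra-threshold bends are separated by more than 100 ms.
#' Leftover sub-threshold runs too short for rule 1 are merged into the
#' nearest episode of the bout; with no episode to join they are dropped
#' from episode accounting.
#'
#' @param bends the bout's bend table ([detectBends()] restricted to the
#'   bout window).
#' @param boutId identifier copied into the output.
#' @param ampThresholdDeg amplitude gate in degrees (default 25).
#' @param struggleSplitS gap between supra-threshold bends that splits a
#'   struggle, in seconds (default 0.1).
#' @param minForwardOsc minimum full oscillations for a forward episode
#'   (default 3).
#' @param rule2MaxPerOsc maximum isolated supra-threshold bends tolerated
#'   per sub-threshold oscillation within a forward episode (default 1/6).
#' @return data.frame with one row per episode: `bout_id`, `episode_id`,
#'   `start_s`, `end_s`, `label` (forward/struggle), `n_oscillations`,
#'   `max_abs_tba_deg`, `median_itbf_hz`, `median_itba_deg`, `n_bends`.
#' @export
segmentEpisodes <- function(bends, boutId = 1L, ampThresholdDeg = 25,
                            struggleSplitS = 0.1, minForwardOsc = 3,
                            rule2MaxPerOsc = 1 / 6) {
  empty <- data.frame(bout_id = integer(0), episode_id = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      label = character(0), n_oscillations = integer(0),
                      max_abs_tba_deg = numeric(0),
                      median_itbf_hz = numeric(0),
                      median_itba_deg = numeric(0), n_bends = integer(0))
  if (is.null(bends) || !nrow(bends)) return(empty)
  supra <- abs(bends$amp_deg) > ampThresholdDeg
  n <- length(supra)

  # Rule 2: absorb isolated supra bends flanked by >=2 sub oscillations
  # (4 sub bends) on each side, subject to the density cap.
  absorbed <- rep(FALSE, n)
  for (i in which(supra)) {
    left <- if (i > 1L) rev(cumprod(!supra[seq_len(i - 1L)])) else numeric(0)
    right <- if (i < n) cumprod(!supra[(i + 1L):n]) else numeric(0)
    nL <- sum(left); nR <- sum(right)
    if (nL >= 4L && nR >= 4L) absorbed[i] <- TRUE
  }
  # density cap: within each maximal sub+absorbed stretch, allow at most
  # rule2MaxPerOsc supra bends per sub oscillation
  eff_supra <- supra & !absorbed
  grp <- cumsum(c(TRUE, diff(eff_supra) != 0))
  unabsorb <- integer(0)
  for (g in unique(grp[!eff_supra])) {
    ii <- which(grp == g & !eff_supra)
    nsub <- sum(!supra[ii])
    nabs <- sum(absorbed[ii])
    if (nabs > rule2MaxPerOsc * floor(nsub / 2)) unabsorb <- c(unabsorb, ii)
  }
  absorbed[unabsorb] <- FALSE
  eff_supra <- supra & !absorbed

  segs <- list()  # list of (indices, label) in time order
  runs <- split(seq_len(n), cumsum(c(TRUE, diff(eff_supra) != 0)))
  for (ii in runs) {
    if (eff_supra[ii[1L]]) {
      # Rule 3: struggle run, split at gaps > struggleSplitS
      sup_ii <- ii[supra[ii]]
      brk <- which(diff(bends$t_s[sup_ii]) > struggleSplitS)
      parts <- split(sup_ii, cumsum(c(0L, seq_along(sup_ii)[-1L] %in% (brk + 1L))))
      for (p in parts) segs[[length(segs) + 1L]] <- list(idx = p, label = "struggle")
    } else {
      nosc <- floor(sum(!supra[ii]) / 2)
      lab <- if (nosc >= minForwardOsc) "forward" else "short"
      segs[[length(segs) + 1L]] <- list(idx = ii, label = lab)
    }
  }
  # merge "short" leftovers into the nearest episode (by bend-time gap)
  real <- which(vapply(segs, function(s) s$label != "short", logical(1)))
  if (!length(real)) return(empty)
  for (k in which(vapply(segs, function(s) s$label == "short", logical(1)))) {
    tmid <- mean(bends$t_s[segs[[k]]$idx])
    d <- vapply(real, function(r) min(abs(bends$t_s[segs[[r]]$idx] - tmid)),
                numeric(1))
    tgt <- real[which.min(d)]
    segs[[tgt]]$idx <- sort(c(segs[[tgt]]$idx, segs[[k]]$idx))
  }
  segs <- segs[real]

  rows <- lapply(seq_along(segs), function(k) {
    idx <- segs[[k]]$idx
    lab <- segs[[k]]$label
    b <- bends[idx, , drop = FALSE]
    # forward accounting excludes absorbed supra bends
    bk <- if (lab == "forward") b[!supra[idx], , drop = FALSE] else b
    ck <- cycleKinematics(bk)
    data.frame(bout_id = boutId, episode_id = k,
               start_s = min(b$t_s), end_s = max(b$t_s),
               label = lab, n_oscillations = ck$n_oscillations,
               max_abs_tba_deg = max(abs(bk$amp_deg)),
               median_itbf_hz = if (length(ck$itbf_hz)) median(ck$itbf_hz) else NA_real_,
               median_itba_deg = if (length(ck$itba_deg)) median(ck$itba_deg) else NA_real_,
               n_bends = nrow(bk))
  })
  do.call(rbind, rows)
}

#' Behavioral forward index of one stimulation trial
#'
#' `(n_forward - n_struggle) / n_total` over the episodes of the trial;
#' ranges from -1 (pure struggle) to +1 (pure forward swimming).
#'
#' @param episodes episode data.frame (needs a `label` column).
#' @return numeric scalar in `[-1, 1]`.
#' @export
forwardIndex <- function(episodes) {
  if (is.null(episodes) || !nrow(episodes))
    stop("no episodes in stimulation window")
  nf <- sum(episodes$label == "forward")
  ns <- sum(episodes$label == "struggle")
  (nf - ns) / nrow(episodes)
}

#' Median forward index of a stimulation site
#'
#' Median of per-trial forward indices over trials with the optimal
#' stimulation parameters (pulse trains at 10 Hz with current amplitude
#' 1-2 uA); other trials are excluded because they mainly elicit escape or
#' struggle behavior.
#'
#' @param trials data.frame with columns `pulse_freq_hz`, `intensity_ua`,
#'   `forward_index`.
#' @param freqHz required train frequency (default 10).
#' @param intensityRangeUa inclusive intensity window in uA (default
#'   `c(1, 2)`).
#' @return median forward index over qualifying trials, or `NA` when no
#'   trial qualifies.
#' @export
siteMedianForwardIndex <- function(trials, freqHz = 10,
                                   intensityRangeUa = c(1, 2)) {
  stopifnot(nrow(trials) >= 1L)
  ok <- trials$pulse_freq_hz == freqHz &
    trials$intensity_ua >= intensityRangeUa[1L] &
    trials$intensity_ua <= intensityRangeUa[2L]
  if (!any(ok)) return(NA_real_)
  median(trials$forward_index[ok])
}

#' Build a stimulation-trial table
#'
#' @param trainStartS,trainEndS train start/end times in seconds.
#' @param pulseFreqHz pulse frequency within the train in Hz.
#' @param intensityUa current amplitude in uA.
#' @param pulseWidthMs pulse width in ms (default 2).
#' @return data.frame with one row per train, including a `pulse_times_s`
#'   list-column of individual pulse times.
#' @export
stimTrials <- function(trainStartS, trainEndS, pulseFreqHz, intensityUa,
                       pulseWidthMs = 2) {
  stopifnot(length(trainStartS) == length(trainEndS),
            all(trainEndS > trainStartS))
  df <- data.frame(stim_id = seq_along(trainStartS),
                   train_start_s = trainStartS, train_end_s = trainEndS,
                   pulse_freq_hz = pulseFreqHz, intensity_ua = intensityUa,
                   pulse_width_ms = pulseWidthMs)
  df$pulse_times_s <- lapply(seq_len(nrow(df)), function(i)
    seq(df$train_start_s[i], df$train_end_s[i], by = 1 / df$pulse_freq_hz[i]))
  df
}
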