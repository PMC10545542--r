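# Event-locked recruitment statistics: single-pulse responses and
# reliability classes, rising slopes, episode-locked recruitment, the
# forward activity index and clustering to isolate the forward cluster.

#' Detect a single-pulse calcium response
#'
#' A ROI responds to a stimulation if the maximal delta-F/F between the
#' stimulation start and 3 s after exceeds the baseline (mean delta-F/F
#' over the 1.5 s before the stimulation) plus three times the noise sigma.
#'
#' @param dffSeries delta-F/F vector (raw, i.e. unfiltered, recommended).
#' @param frameTime frame times in seconds.
#' @param stimTimeS stimulation time in seconds.
#' @param noiseSigmaVal ROI noise sigma.
#' @param responseWindowS response window after the stimulation (default 3).
#' @param baselineWindowS baseline window before the stimulation
#'   (default 1.5).
#' @param k response threshold in noise units (default 3).
#' @return list: `responded`, `peak_dff`, `baseline_dff`.
#' @export
detectPulseResponse <- function(dffSeries, frameTime, stimTimeS,
                                noiseSigmaVal, responseWindowS = 3,
                                baselineWindowS = 1.5, k = 3) {
  if (stimTimeS - baselineWindowS < frameTime[1L] ||
      stimTimeS + responseWindowS > frameTime[length(frameTime)])
    stop("incomplete window")
  post <- frameTime >= stimTimeS & frameTime <= stimTimeS + responseWindowS
  pre <- frameTime >= stimTimeS - baselineWindowS & frameTime < stimTimeS
  peak <- max(dffSeries[post])
  base <- mean(dffSeries[pre])
  list(responded = peak > base + k * noiseSigmaVal,
       peak_dff = peak, baseline_dff = base)
}

#' Classify recruitment reliability across stimulation intensities
#'
#' A ROI is `non_recruited` if it responded to no stimulation at any
#' intensity; `reliable` if, from the first intensity at which it
#' responded at all (its threshold intensity I*), every trial at every
#' intensity at or above I* responded; `unreliable` otherwise (it
#' responded somewhere but not systematically above its threshold).
#'
#' @param responsesByIntensity named list (names = intensity in uA,
#'   strictly increasing) of logical vectors, one response flag per trial.
#' @param maxFailures trials allowed to fail above threshold while still
#'   counting as reliable (default 0, the strict rule).
#' @return list: `label` in `{reliable, unreliable, non_recruited}` and
#'   `threshold_intensity_ua` (`NA` unless reliable).
#' @export
classifyReliability <- function(responsesByIntensity, maxFailures = 0L) {
  ints <- as.numeric(names(responsesByIntensity))
  stopifnot(!is.unsorted(ints, strictly = TRUE),
            all(lengths(responsesByIntensity) >= 1L))
  anyResp <- vapply(responsesByIntensity, any, logical(1))
  if (!any(anyResp))
    return(list(label = "non_recruited", threshold_intensity_ua = NA_real_))
  j <- which(anyResp)[1L]
  fails <- sum(!unlist(responsesByIntensity[j:length(ints)]))
  if (fails <= maxFailures)
    return(list(label = "reliable", threshold_intensity_ua = ints[j]))
  list(label = "unreliable", threshold_intensity_ua = NA_real_)
}

#' Rising slope of a stimulus-evoked calcium transient
#'
#' `(dff(t_peak) - dff(t_onset)) / (t_peak - t_onset)`, computed on the raw
#' (unfiltered) delta-F/F because filtering lags the signal.
#'
#' @param dffSeries raw delta-F/F vector.
#' @param frameTime frame times in seconds.
#' @param tOnsetS,tPeakS onset and peak times; `tPeakS > tOnsetS`, both
#'   inside the trace.
#' @return slope in delta-F/F per second.
#' @export
risingSlope <- function(dffSeries, frameTime, tOnsetS, tPeakS) {
  if (tPeakS <= tOnsetS) stop("t_peak must exceed t_onset")
  if (tOnsetS < frameTime[1L] || tPeakS > frameTime[length(frameTime)])
    stop("onset/peak outside trace")
  at <- function(ts) dffSeries[which.min(abs(frameTime - ts))]
  (at(tPeakS) - at(tOnsetS)) / (tPeakS - tOnsetS)
}

#' Automated onset and peak detection for an evoked transient
#'
#' The onset is the first frame after the stimulation where delta-F/F
#' exceeds baseline + 1 noise sigma and keeps rising for at least two
#' frames; the peak is the delta-F/F argmax within `responseWindowS` of the
#' onset. This automates the semiautomatic annotation step; outputs should
#' be treated as automated estimates.
#'
#' @inheritParams detectPulseResponse
#' @return list `t_onset_s`, `t_peak_s`.
#' @export
onsetPeakDetect <- function(dffSeries, frameTime, stimTimeS, noiseSigmaVal,
                            responseWindowS = 3, baselineWindowS = 1.5) {
  pre <- frameTime >= stimTimeS - baselineWindowS & frameTime < stimTimeS
  base <- mean(dffSeries[pre])
  idx <- which(frameTime >= stimTimeS)
  thr <- base + noiseSigmaVal
  n <- length(dffSeries)
  for (i in idx) {
    if (i + 2L > n) break
    rising <- dffSeries[i + 1L] > dffSeries[i] &&
      dffSeries[i + 2L] > dffSeries[i + 1L]
    if (dffSeries[i] > thr && rising) {
      win <- frameTime >= frameTime[i] &
        frameTime <= frameTime[i] + responseWindowS
      j <- which(win)[which.max(dffSeries[win])]
      return(list(t_onset_s = frameTime[i], t_peak_s = frameTime[j]))
    }
  }
  stop("no transient")
}

#' Episode-locked recruitment
#'
#' The per-episode response is the maximum delta-F/F between 0.5 s before
#' the episode start and 2 s after its end, corrected by subtracting the
#' median delta-F/F over the 300 ms preceding the episode (residual decay
#' from a previous episode). A ROI is recruited in an episode when the
#' corrected maximum reaches `k` times its noise sigma (default 5).
#'
#' @param dffSeries delta-F/F vector.
#' @param frameTime frame times in seconds.
#' @param startS,endS episode interval in seconds.
#' @param noiseSigmaVal ROI noise sigma.
#' @param preS window before start for the max (default 0.5).
#' @param postS window after end for the max (default 2).
#' @param baselineS pre-episode baseline window (default 0.3).
#' @param k recruitment threshold in noise units (default 5).
#' @return list: `corrected_max_dff`, `recruited`.
#' @export
episodeRecruitment <- function(dffSeries, frameTime, startS, endS,
                               noiseSigmaVal, preS = 0.5, postS = 2,
                               baselineS = 0.3, k = 5) {
  if (startS - preS < frameTime[1L] - 1e-9 ||
      endS + postS > frameTime[length(frameTime)] + 1e-9)
    stop("incomplete window")
  win <- frameTime >= startS - preS & frameTime <= endS + postS
  pre <- frameTime >= startS - baselineS & frameTime < startS
  base <- if (any(pre)) median(dffSeries[pre]) else 0
  cm <- max(dffSeries[win]) - base
  list(corrected_max_dff = cm, recruited = cm >= k * noiseSigmaVal)
}

#' Forward activity index of a ROI
#'
#' Normalized contrast of episode-locked response amplitude between
#' forward and struggle episodes:
#' `(A_f - A_s) / (A_f + A_s)`, where `A_f` and `A_s` are the means over
#' episodes of the per-episode corrected maximum delta-F/F (floored at
#' zero so the index stays within `[-1, 1]`). Positive values indicate a
#' larger average response during forward swimming.
#'
#' @param dffSeries,frameTime,noiseSigmaVal as in [episodeRecruitment()].
#' @param forwardEpisodes,struggleEpisodes episode data.frames with
#'   `start_s`, `end_s`; each must have at least one row.
#' @param ... passed to [episodeRecruitment()].
#' @return index in `[-1, 1]`, or `NA` when both means are zero.
#' @export
forwardActivityIndex <- function(dffSeries, frameTime, noiseSigmaVal,
                                 forwardEpisodes, struggleEpisodes, ...) {
  stopifnot(nrow(forwardEpisodes) >= 1L, nrow(struggleEpisodes) >= 1L)
  epMax <- function(ep) vapply(seq_len(nrow(ep)), function(i)
    max(0, episodeRecruitment(dffSeries, frameTime, ep$start_s[i],
                              ep$end_s[i], noiseSigmaVal,
                              ...)$corrected_max_dff), numeric(1))
  af <- mean(epMax(forwardEpisodes))
  as_ <- mean(epMax(struggleEpisodes))
  if (af + as_ == 0) return(NA_real_)
  (af - as_) / (af + as_)
}

#' Cluster ROIs and identify the forward cluster
#'
#' Hierarchical agglomerative clustering (Ward linkage on Euclidean
#' distances between z-scored delta-F/F traces) into `k` clusters
#' (typically 3-6); the forward cluster is the one whose members have the
#' highest mean forward activity index, and that mean is asserted to be
#' positive.
#'
#' @param dffMatrix ROI x frame matrix.
#' @param k number of clusters.
#' @param fwdIndex per-ROI forward activity index vector.
#' @return list: `cluster` (integer per ROI), `forward_cluster_id`,
#'   `cluster_mean_index`.
#' @export
clusterForward <- function(dffMatrix, k, fwdIndex) {
  stopifnot(nrow(dffMatrix) >= k, length(fwdIndex) == nrow(dffMatrix))
  sds <- apply(dffMatrix, 1L, sd)
  if (any(sds == 0)) stop("degenerate matrix: constant rows")
  z <- t(scale(t(dffMatrix)))
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  means <- tapply(fwdIndex, cl, mean, na.rm = TRUE)
  fid <- as.integer(names(means)[which.max(means)])
  if (!is.na(max(means)) && max(means) <= 0)
    warning("forward cluster mean activity index is not positive")
  list(cluster = cl, forward_cluster_id = fid,
       cluster_mean_index = means)
}
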