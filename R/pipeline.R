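# Pipeline orchestration: a validated configuration object and the three
# end-to-end analyses (stimulation-recruitment, encoding model, bout-type
# mapping), with deterministic CSV/JSON outputs.

.configDefaults <- list(
  behavior_rate_hz = 300,
  imaging_rate_hz = 10,
  motion_threshold_deg = 3,
  min_quiet_s = 0.1,
  min_bend_amp_deg = 5,
  episode_amp_threshold_deg = 25,
  struggle_split_s = 0.1,
  min_forward_osc = 3,
  turn_max_deg = 60,
  neuropil_factor = 0.7,
  min_inactivity_s = 3,
  smooth_mode = "running_average_3",
  decay_deconv_s = 1.8,
  kernel_tau_s = 1.5,
  pulse_response_window_s = 3,
  pulse_baseline_window_s = 1.5,
  pulse_threshold_noise = 3,
  episode_recruit_threshold_noise = 5,
  n_perm = 999,
  perm_alpha = 0.05,
  rest_epsilon_deg = 0.5,
  bout_pre_s = 0.2,
  bouttype_alpha = 0.01,
  min_session_bouts = 50,
  n_clusters = 4,
  alignment_offset_s = 0,
  seed = 1L)

#' Pipeline configuration
#'
#' Builds a validated configuration carrying every tunable of the pipeline
#' with its standard default. Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults (see
#'   `swimConfig()` with no arguments for the full list).
#' @return a list of class `swim_config` with a `hash` attribute (MD5 of
#'   the canonical JSON serialization).
#' @examples
#' cfg <- swimConfig(n_perm = 199)
#' cfg$n_perm
#' @export
swimConfig <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all config overrides must be named")
  unknown <- setdiff(names(over), names(.configDefaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- .configDefaults
  cfg[names(over)] <- over
  class(cfg) <- "swim_config"
  attr(cfg, "hash") <- configHash(cfg)
  cfg
}

#' @export
print.swim_config <- function(x, ...) {
  cat("swim_config (", attr(x, "hash"), ")\n", sep = "")
  for (k in names(x)) cat(sprintf("  %-32s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' MD5 hash of a configuration
#'
#' @param cfg a `swim_config` (or plain named list).
#' @return MD5 string of the canonical JSON serialization.
#' @export
configHash <- function(cfg) {
  x <- unclass(cfg)
  attr(x, "hash") <- NULL
  j <- jsonlite::toJSON(x[order(names(x))], auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(j, tf)
  unname(tools::md5sum(tf))
}

#' Read a configuration from YAML
#'
#' @param path YAML file with config keys; unknown keys are rejected.
#' @return a `swim_config`.
#' @export
readSwimConfig <- function(path) {
  do.call(swimConfig, yaml::read_yaml(path))
}

# shared behavioral front end: bends, bouts, per-bout episodes
analyzeBehavior <- function(trace, cfg, stim = NULL) {
  bouts <- extractBouts(trace,
                        motionThresholdDeg = cfg$motion_threshold_deg,
                        minQuietS = cfg$min_quiet_s,
                        minAmpDeg = cfg$min_bend_amp_deg, stim = stim)
  bendlist <- attr(bouts, "bends")
  eps <- lapply(seq_len(nrow(bouts)), function(i)
    segmentEpisodes(bendlist[[i]], boutId = bouts$bout_id[i],
                    ampThresholdDeg = cfg$episode_amp_threshold_deg,
                    struggleSplitS = cfg$struggle_split_s,
                    minForwardOsc = cfg$min_forward_osc))
  episodes <- if (length(eps)) do.call(rbind, eps) else
    segmentEpisodes(NULL)
  list(bouts = bouts, episodes = episodes, bends = bendlist)
}

#' Stimulation-recruitment pipeline
#'
#' End-to-end analysis of a stimulation session: bout/episode
#' segmentation, per-trial forward indices with the site median,
#' per-ROI pulse responses, reliability classes and rising slopes.
#'
#' @param trace a [TailTrace-class].
#' @param fluo a [FluoSet-class] (raw; preprocessing is run here).
#' @param stim stimulation table from [stimTrials()].
#' @param config a [swimConfig()].
#' @param outDir optional directory for CSV/JSON outputs.
#' @return list: `bouts`, `episodes`, `trial_index` (per-trial forward
#'   index), `site_median_index`, `responses` (ROI x trial), `reliability`
#'   per ROI, `fluo` (preprocessed), `manifest`.
#' @export
runStimPipeline <- function(trace, fluo, stim, config = swimConfig(),
                            outDir = NULL) {
  beh <- analyzeBehavior(trace, config, stim = stim)
  trialIdx <- data.frame(stim_id = integer(0), forward_index = numeric(0))
  if (!is.null(stim) && nrow(stim)) {
    rows <- lapply(seq_len(nrow(stim)), function(i) {
      ep <- beh$episodes[
        beh$episodes$start_s >= stim$train_start_s[i] &
        beh$episodes$start_s < stim$train_end_s[i], , drop = FALSE]
      if (!nrow(ep)) return(NULL)
      data.frame(stim_id = stim$stim_id[i],
                 pulse_freq_hz = stim$pulse_freq_hz[i],
                 intensity_ua = stim$intensity_ua[i],
                 forward_index = forwardIndex(ep))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) trialIdx <- do.call(rbind, rows)
  }
  siteMed <- if (nrow(trialIdx)) siteMedianForwardIndex(trialIdx) else NA_real_
  fluo <- preprocessFluo(fluo, bouts = beh$bouts,
                         neuropilFactor = config$neuropil_factor,
                         minInactivityS = config$min_inactivity_s,
                         smoothMode = "none")
  ft <- frameTimes(fluo) + config$alignment_offset_s
  dffM <- dff(fluo); ns <- noiseSigma(fluo)
  responses <- NULL; reliability <- NULL
  if (!is.null(stim) && nrow(stim)) {
    res <- lapply(seq_len(nrow(fluo)), function(j) {
      per <- lapply(seq_len(nrow(stim)), function(i) {
        pr <- detectPulseResponse(dffM[j, ], ft, stim$train_start_s[i],
                ns[j], responseWindowS = config$pulse_response_window_s,
                baselineWindowS = config$pulse_baseline_window_s,
                k = config$pulse_threshold_noise)
        data.frame(roi = j, stim_id = stim$stim_id[i],
                   intensity_ua = stim$intensity_ua[i],
                   responded = pr$responded, peak_dff = pr$peak_dff,
                   baseline_dff = pr$baseline_dff)
      })
      do.call(rbind, per)
    })
    responses <- do.call(rbind, res)
    reliability <- do.call(rbind, lapply(seq_len(nrow(fluo)), function(j) {
      rj <- responses[responses$roi == j, ]
      byInt <- split(rj$responded, rj$intensity_ua)
      cl <- classifyReliability(byInt)
      data.frame(roi = j, label = cl$label,
                 threshold_intensity_ua = cl$threshold_intensity_ua)
    }))
  }
  out <- list(bouts = beh$bouts, episodes = beh$episodes,
              trial_index = trialIdx, site_median_index = siteMed,
              responses = responses, reliability = reliability,
              fluo = fluo,
              manifest = runManifest(config, "stim"))
  if (!is.null(outDir)) writePipelineOutputs(out, outDir,
    c("bouts", "episodes", "trial_index", "responses", "reliability"))
  out
}

#' Encoding-model pipeline
#'
#' Builds the four motor regressors from the behavior trace, fits the
#' per-neuron encoding model with permutation significance, computes
#' per-ROI forward activity indices and isolates the forward cluster.
#'
#' @inheritParams runStimPipeline
#' @return list: `regressors`, `results` (per-ROI coefficient table),
#'   `forward_index` per ROI, `clusters`, `fluo`, `manifest`.
#' @export
runEncodingPipeline <- function(trace, fluo, config = swimConfig(),
                                stim = NULL, outDir = NULL) {
  beh <- analyzeBehavior(trace, config, stim = stim)
  fluo <- preprocessFluo(fluo, bouts = beh$bouts,
                         neuropilFactor = config$neuropil_factor,
                         minInactivityS = config$min_inactivity_s,
                         smoothMode = "none")
  ft <- frameTimes(fluo) + config$alignment_offset_s
  allBends <- do.call(rbind, attr(beh$bouts, "bends"))
  if (is.null(allBends)) allBends <- data.frame(t_s = numeric(0),
                                                amp_deg = numeric(0))
  reg <- buildRegressorSet(trace, allBends, ft, bouts = beh$bouts,
                           stim = stim, tauS = config$kernel_tau_s)
  dffM <- dff(fluo)
  results <- do.call(rbind, lapply(seq_len(nrow(dffM)), function(j) {
    ps <- permutationSignificance(dffM[j, ], reg,
            nPerm = config$n_perm, seed = config$seed + j,
            tauS = config$kernel_tau_s, rate = config$imaging_rate_hz,
            alpha = config$perm_alpha)
    data.frame(roi = j, t(ps$coef), r2 = ps$r2,
               t(setNames(ps$p_perm, paste0("p_", names(ps$p_perm)))),
               t(setNames(as.integer(ps$significant),
                          paste0("sig_", names(ps$significant)))))
  }))
  fwd <- beh$episodes[beh$episodes$label == "forward", , drop = FALSE]
  str <- beh$episodes[beh$episodes$label == "struggle", , drop = FALSE]
  ns <- noiseSigma(fluo)
  fwdIdx <- rep(NA_real_, nrow(dffM))
  if (nrow(fwd) && nrow(str))
    fwdIdx <- vapply(seq_len(nrow(dffM)), function(j)
      forwardActivityIndex(dffM[j, ], ft, ns[j], fwd, str), numeric(1))
  clusters <- NULL
  if (nrow(dffM) >= config$n_clusters && all(apply(dffM, 1, sd) > 0) &&
      any(is.finite(fwdIdx)))
    clusters <- clusterForward(dffM, config$n_clusters, fwdIdx)
  out <- list(regressors = reg, results = results, forward_index = fwdIdx,
              clusters = clusters, episodes = beh$episodes, bouts = beh$bouts,
              fluo = fluo, manifest = runManifest(config, "encode"))
  if (!is.null(outDir)) writePipelineOutputs(out, outDir,
    c("results", "bouts", "episodes"))
  out
}

#' Bout-type mapping pipeline
#'
#' Applies the session inclusion rule (at least 50 bouts, one of each
#' class), infers spike rates, samples the resting rate, runs the per-type
#' rank-sum activity tests and assigns functional groups.
#'
#' @inheritParams runStimPipeline
#' @return list: `qualifies`, `labels` (per-ROI group table),
#'   `proportions`, `bouts`, `fluo`, `manifest`; when the session fails
#'   the inclusion rule only `qualifies` (with its reason) and `bouts` are
#'   returned.
#' @export
runBouttypePipeline <- function(trace, fluo, config = swimConfig(),
                                outDir = NULL) {
  beh <- analyzeBehavior(trace, config)
  q <- sessionQualifies(beh$bouts, minBouts = config$min_session_bouts)
  if (!isTRUE(as.logical(q))) {
    message("session excluded: ", attr(q, "reason"))
    return(list(qualifies = q, bouts = beh$bouts,
                manifest = runManifest(config, "bouttype")))
  }
  fluo <- preprocessFluo(fluo, bouts = beh$bouts,
                         neuropilFactor = config$neuropil_factor,
                         minInactivityS = config$min_inactivity_s,
                         smoothMode = "none")
  fluo <- inferSpikeRates(fluo, decayS = config$decay_deconv_s)
  ft <- frameTimes(fluo) + config$alignment_offset_s
  sr <- spikeRate(fluo)
  types <- list(forward = "forward", left = "left_turn",
                right = "right_turn")
  labels <- do.call(rbind, lapply(seq_len(nrow(sr)), function(j) {
    rest <- restSpikeSample(sr[j, ], ft, trace, beh$bouts,
                            restEpsilon = config$rest_epsilon_deg)
    det <- lapply(types, function(tt)
      detectActive(sr[j, ], ft,
                   beh$bouts[beh$bouts$label == tt, , drop = FALSE],
                   rest, alpha = config$bouttype_alpha,
                   preS = config$bout_pre_s))
    data.frame(roi = j,
               active_forward = det$forward$active,
               active_left = det$left$active,
               active_right = det$right$active,
               p_forward = det$forward$p, p_left = det$left$p,
               p_right = det$right$p)
  }))
  grp <- assignGroups(labels$active_forward, labels$active_left,
                      labels$active_right)
  labels$group <- grp$group
  out <- list(qualifies = TRUE, labels = labels,
              proportions = grp$proportions, bouts = beh$bouts,
              fluo = fluo, manifest = runManifest(config, "bouttype"))
  if (!is.null(outDir)) writePipelineOutputs(out, outDir,
    c("labels", "bouts"))
  out
}

runManifest <- function(cfg, stage) {
  list(stage = stage, config = unclass(cfg),
       config_hash = attr(cfg, "hash") %||% configHash(cfg),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("swimcal")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writePipelineOutputs <- function(out, outDir, tables) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (nm in tables) {
    x <- out[[nm]]
    if (is.null(x) || !is.data.frame(x)) next
    x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
    write.csv(x, file.path(outDir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(out$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Read a tail trace from CSV
#'
#' Expects columns `time_s`, `angle_deg` and optionally `seg_00..seg_19`.
#'
#' @param path CSV file path.
#' @return a [TailTrace-class].
#' @export
readTailTrace <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "angle_deg") %in% names(df)))
  rate <- 1 / median(diff(df$time_s))
  segs <- grep("^seg_", names(df), value = TRUE)
  curv <- if (length(segs)) t(as.matrix(df[, segs])) else NULL
  TailTrace(df$angle_deg, rate = round(rate), time = df$time_s,
            curvature = curv)
}

#' Write a tail trace to CSV
#'
#' @param trace a [TailTrace-class].
#' @param path output CSV path.
#' @export
writeTailTrace <- function(trace, path) {
  df <- data.frame(time_s = tailTime(trace), angle_deg = tailAngle(trace))
  cv <- trace@curvature
  if (nrow(cv)) {
    segs <- t(cv)
    colnames(segs) <- sprintf("seg_%02d", seq_len(ncol(segs)) - 1L)
    df <- cbind(df, segs)
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read ROI fluorescence from a long-format CSV
#'
#' Expects columns `roi_id`, `frame`, `f_raw`, `f_neuropil`.
#'
#' @param path CSV file path.
#' @param rate imaging frame rate in Hz.
#' @return a [FluoSet-class].
#' @export
readFluoCsv <- function(path, rate = 10) {
  df <- read.csv(path)
  stopifnot(all(c("roi_id", "frame", "f_raw", "f_neuropil") %in% names(df)))
  rois <- sort(unique(df$roi_id))
  frames <- sort(unique(df$frame))
  shape <- function(col) {
    m <- matrix(NA_real_, length(rois), length(frames))
    m[cbind(match(df$roi_id, rois), match(df$frame, frames))] <- df[[col]]
    m
  }
  FluoSet(shape("f_raw"), shape("f_neuropil"), rate = rate,
          roiId = as.character(rois))
}
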