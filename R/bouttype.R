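# Bout-type activity mapping: rest spike sampling, per-type activity
# detection by rank-sum test, and functional group assignment.

#' Sample the resting spike rate
#'
#' Collects inferred spike-rate values at imaging frames whose behavior
#' interval is quiescent: maximal absolute tail angle below `restEpsilon`
#' and no overlap with any detected bout.
#'
#' @param spikeSeries spike-rate vector (one value per imaging frame).
#' @param frameTime imaging frame times.
#' @param trace a [TailTrace-class].
#' @param bouts bout table from [extractBouts()].
#' @param restEpsilon maximum absolute angle counted as rest, in degrees
#'   (default 0.5).
#' @param minRestS minimum total rest required, in seconds (default 5).
#' @return numeric vector of rest spike rates.
#' @export
restSpikeSample <- function(spikeSeries, frameTime, trace, bouts,
                            restEpsilon = 0.5, minRestS = 5) {
  t <- tailTime(trace); a <- abs(tailAngle(trace))
  nf <- length(frameTime)
  dt <- if (nf > 1L) median(diff(frameTime)) else 1
  restFrame <- logical(nf)
  for (i in seq_len(nf)) {
    lo <- frameTime[i]; hi <- frameTime[i] + dt
    sel <- t >= lo & t < hi
    quiet <- !any(sel) || max(a[sel]) < restEpsilon
    inBout <- nrow(bouts) > 0 &&
      any(hi > bouts$start_s & lo < bouts$end_s)
    restFrame[i] <- quiet && !inBout
  }
  if (sum(restFrame) * dt < minRestS)
    stop("insufficient rest in session")
  spikeSeries[restFrame]
}

#' Detect activity during bouts of one type
#'
#' Pools inferred spike rates over the window from 200 ms before bout
#' start to bout end, across all bouts of a type, and compares them to the
#' rest sample with a one-sided Wilcoxon rank-sum test (bout > rest). The
#' neuron is active for the type when `p < alpha` (default 0.01).
#'
#' @param spikeSeries spike-rate vector per imaging frame.
#' @param frameTime imaging frame times.
#' @param bouts bout table restricted to one type; fewer than `minBouts`
#'   rows yields an undefined marker (`active = NA`), not an error.
#' @param restSample rest spike-rate vector from [restSpikeSample()].
#' @param alpha significance level (default 0.01).
#' @param preS pre-bout margin in seconds (default 0.2).
#' @param minBouts minimum bouts of the type (default 3).
#' @return list: `active` (logical or NA), `p`, `n_bouts`, `n_frames`.
#' @export
detectActive <- function(spikeSeries, frameTime, bouts, restSample,
                         alpha = 0.01, preS = 0.2, minBouts = 3L) {
  stopifnot(length(restSample) >= 1L)
  if (is.null(bouts) || nrow(bouts) < minBouts)
    return(list(active = NA, p = NA_real_, n_bouts = if (is.null(bouts)) 0L
                else nrow(bouts), n_frames = 0L))
  sel <- logical(length(frameTime))
  for (i in seq_len(nrow(bouts)))
    sel <- sel | (frameTime >= bouts$start_s[i] - preS &
                  frameTime <= bouts$end_s[i])
  x <- spikeSeries[sel]
  if (!length(x))
    return(list(active = NA, p = NA_real_, n_bouts = nrow(bouts),
                n_frames = 0L))
  p <- suppressWarnings(
    wilcox.test(x, restSample, alternative = "greater")$p.value)
  list(active = p < alpha, p = p, n_bouts = nrow(bouts),
       n_frames = length(x))
}

#' Assign functional groups from per-type activity flags
#'
#' Forward-component neurons are active during forward bouts and during
#' both turn directions; left (right) steering neurons are active during
#' left (right) turns but not during forward bouts. Groups are mutually
#' exclusive, forward-component taking precedence.
#'
#' @param activeForward,activeLeft,activeRight logical vectors (NA =
#'   undefined; treated as not active).
#' @return list: `group` (character vector: `forward_component`,
#'   `left_steering`, `right_steering`, `other`) and `proportions`
#'   (fraction of ROIs per group).
#' @export
assignGroups <- function(activeForward, activeLeft, activeRight) {
  n <- length(activeForward)
  stopifnot(length(activeLeft) == n, length(activeRight) == n)
  f <- !is.na(activeForward) & activeForward
  l <- !is.na(activeLeft) & activeLeft
  r <- !is.na(activeRight) & activeRight
  group <- rep("other", n)
  group[l & !f] <- "left_steering"
  group[r & !f & !(l & !f)] <- "right_steering"
  group[f & l & r] <- "forward_component"
  props <- vapply(c("forward_component", "left_steering",
                    "right_steering", "other"),
                  function(g) mean(group == g), numeric(1))
  list(group = group, proportions = props)
}

#' Session inclusion rule for bout-type mapping
#'
#' A session qualifies when it contains at least `minBouts` swim bouts and
#' at least one bout of each class (forward, left turn, right turn).
#'
#' @param bouts bout table from [extractBouts()].
#' @param minBouts minimum bout count (default 50).
#' @return logical scalar with a `reason` attribute when excluded.
#' @export
sessionQualifies <- function(bouts, minBouts = 50L) {
  if (nrow(bouts) < minBouts) {
    out <- FALSE; attr(out, "reason") <- sprintf(
      "only %d bouts (need %d)", nrow(bouts), minBouts)
    return(out)
  }
  need <- c("forward", "left_turn", "right_turn")
  missing <- setdiff(need, unique(bouts$label))
  if (length(missing)) {
    out <- FALSE
    attr(out, "reason") <- paste("no bout of class:",
                                 paste(missing, collapse = ", "))
    return(out)
  }
  TRUE
}
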