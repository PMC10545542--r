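test_that("detectPulseResponse applies the 3-sigma windowed-max rule", {
  ft <- seq(0, 20, by = 0.1)
  sig <- 0.05
  # transient peaking at baseline + 4 sigma: responds
  y <- numeric(length(ft)); y[ft >= 10.5 & ft < 11] <- 4 * sig
  r <- detectPulseResponse(y, ft, 10, sig)
  expect_true(r$responded)
  expect_equal(r$peak_dff, 4 * sig)
  expect_equal(r$baseline_dff, 0)
  # flat trace: no response
  expect_false(detectPulseResponse(numeric(length(ft)), ft, 10,
                                   sig)$responded)
  # window truncated by the trace edge: error
  expect_error(detectPulseResponse(y, ft, 19, sig), "incomplete window")
  expect_error(detectPulseResponse(y, ft, 1, sig), "incomplete window")
})

test_that("null false-positive rate matches a Monte-Carlo exceedance oracle", {
  set.seed(20)
  ft <- seq(0, 10, by = 0.1)
  sig <- 0.05
  n <- 500
  post <- ft >= 5 & ft <= 8
  pre <- ft >= 3.5 & ft < 5
  hits <- 0; oracleHits <- 0
  for (i in seq_len(n)) {
    y <- rnorm(length(ft), 0, sig)
    hits <- hits + detectPulseResponse(y, ft, 5, sig)$responded
    # brute-force restatement of the rule, independent arithmetic
    oracleHits <- oracleHits + (max(y[post]) > mean(y[pre]) + 3 * sig)
  }
  expect_equal(hits, oracleHits)
  phat <- oracleHits / n
  se <- sqrt(phat * (1 - phat) / n)
  expect_true(abs(hits / n - phat) <= 2 * se + 1e-12)
})

test_that("classifyReliability distinguishes reliable, unreliable, silent", {
  mk <- function(v) setNames(as.list(as.logical(v)), 1:5)
  expect_equal(classifyReliability(mk(c(0, 0, 1, 1, 1))),
               list(label = "reliable", threshold_intensity_ua = 3))
  expect_equal(classifyReliability(mk(c(0, 1, 0, 1, 1)))$label, "unreliable")
  expect_equal(classifyReliability(mk(c(0, 0, 0, 0, 0)))$label,
               "non_recruited")
  # responding at every intensity: reliable from the lowest
  expect_equal(classifyReliability(mk(c(1, 1, 1, 1, 1))),
               list(label = "reliable", threshold_intensity_ua = 1))
  # multiple trials per intensity: one failure above threshold demotes
  r <- list(`1` = c(FALSE, FALSE), `2` = c(TRUE, TRUE),
            `3` = c(TRUE, FALSE))
  expect_equal(classifyReliability(r)$label, "unreliable")
  expect_equal(classifyReliability(r, maxFailures = 1L)$label, "reliable")
})

test_that("classifyReliability is monotone in added high-intensity responses", {
  set.seed(21)
  for (i in 1:25) {
    v <- sample(c(TRUE, FALSE), 4, replace = TRUE)
    base <- classifyReliability(setNames(as.list(v), 1:4))$label
    ext <- classifyReliability(setNames(as.list(c(v, TRUE)), 1:5))$label
    if (base == "reliable") expect_equal(ext, "reliable")
    expect_false(base != "non_recruited" && ext == "non_recruited")
  }
})

test_that("risingSlope is the finite difference of raw dff", {
  ft <- seq(0, 5, by = 0.1)
  y <- numeric(length(ft)); y[ft >= 2.0] <- 0.1; y[ft >= 2.5] <- 1.1
  expect_equal(risingSlope(y, ft, 2.0, 2.5), 2.0)
  expect_equal(risingSlope(numeric(length(ft)), ft, 1, 2), 0)
  expect_error(risingSlope(y, ft, 2.5, 2.0), "exceed")
  # synthetic kernel transient: matches a finite-difference oracle exactly
  tau <- 1.8; rate <- 10
  phi <- exp(-1 / (rate * tau))
  spikes <- numeric(51); spikes[21] <- 1
  yk <- as.numeric(stats::filter(spikes, phi, method = "recursive"))
  ftk <- (0:50) / rate
  expect_equal(risingSlope(yk, ftk, 1.9, 2.0),
               (yk[21] - yk[20]) / 0.1)
})

test_that("onsetPeakDetect finds the first sustained rise", {
  rate <- 10; ft <- (0:99) / rate
  sig <- 0.02
  y <- numeric(100)
  y[41:50] <- c(0.2, 0.5, 0.8, 1.0, 0.9, 0.75, 0.6, 0.5, 0.4, 0.3)
  op <- onsetPeakDetect(y, ft, 3.8, sig)
  expect_equal(op$t_onset_s, 4.0)
  expect_equal(op$t_peak_s, ft[44])
  expect_error(onsetPeakDetect(numeric(100), ft, 3.8, sig), "no transient")
  # two transients: the first is selected
  y2 <- y; y2[81:85] <- c(0.3, 0.6, 0.9, 0.7, 0.4)
  expect_equal(onsetPeakDetect(y2, ft, 3.8, sig)$t_onset_s, 4.0)
})

test_that("episodeRecruitment corrects by the pre-episode baseline", {
  ft <- seq(0, 20, by = 0.1)
  sig <- 0.05
  y <- numeric(length(ft)); y[ft >= 10 & ft < 10.5] <- 6 * sig
  er <- episodeRecruitment(y, ft, 10, 10.4, sig)
  expect_true(er$recruited)
  expect_equal(er$corrected_max_dff, 6 * sig)
  # pre-episode plateau equal to the max: corrected value 0
  y2 <- rep(0.3, length(ft))
  er2 <- episodeRecruitment(y2, ft, 10, 10.4, sig)
  expect_equal(er2$corrected_max_dff, 0)
  expect_false(er2$recruited)
  expect_error(episodeRecruitment(y, ft, 19.5, 19.9, sig),
               "incomplete window")
  # batch: decisions equal a hand-coded restatement of the rule
  set.seed(22)
  for (i in 1:20) {
    yy <- rnorm(length(ft), 0, sig)
    s <- runif(1, 2, 15); e <- s + runif(1, 0.3, 2)
    er3 <- episodeRecruitment(yy, ft, s, e, sig)
    win <- ft >= s - 0.5 & ft <= e + 2
    pre <- ft >= s - 0.3 & ft < s
    cm <- max(yy[win]) - median(yy[pre])
    expect_equal(er3$corrected_max_dff, cm)
    expect_equal(er3$recruited, cm >= 5 * sig)
  }
})

test_that("forwardActivityIndex contrasts episode-locked amplitudes", {
  ft <- seq(0, 60, by = 0.1)
  sig <- 0.01
  mkEp <- function(starts) data.frame(start_s = starts,
                                      end_s = starts + 0.4)
  # responses only in forward episodes -> index 1
  fwd <- mkEp(c(10, 20)); str <- mkEp(c(30, 40))
  y <- numeric(length(ft))
  for (s in fwd$start_s) y[ft >= s & ft < s + 0.4] <- 0.5
  expect_equal(forwardActivityIndex(y, ft, sig, fwd, str), 1)
  # equal responses -> 0
  y2 <- y
  for (s in str$start_s) y2[ft >= s & ft < s + 0.4] <- 0.5
  expect_equal(forwardActivityIndex(y2, ft, sig, fwd, str), 0)
  # antisymmetry under swapping the episode sets
  set.seed(23)
  y3 <- abs(rnorm(length(ft), 0, 0.2))
  v1 <- forwardActivityIndex(y3, ft, sig, fwd, str)
  v2 <- forwardActivityIndex(y3, ft, sig, str, fwd)
  expect_equal(v1, -v2)
  # flat zero trace: undefined
  expect_true(is.na(forwardActivityIndex(numeric(length(ft)), ft, sig,
                                         fwd, str)))
})

test_that("clusterForward separates planted response motifs", {
  set.seed(24)
  nf <- 400
  motifF <- sin(seq(0, 6 * pi, length.out = nf))^2
  motifS <- cos(seq(0, 6 * pi, length.out = nf))^2
  m <- rbind(
    t(replicate(8, motifF + rnorm(nf, 0, 0.05))),
    t(replicate(8, motifS + rnorm(nf, 0, 0.05))))
  fwdIdx <- c(rep(0.8, 8), rep(-0.5, 8))
  cl <- clusterForward(m, 2, fwdIdx)
  expect_equal(length(unique(cl$cluster[1:8])), 1L)
  expect_equal(length(unique(cl$cluster[9:16])), 1L)
  expect_equal(unname(cl$cluster[1]), cl$forward_cluster_id)
  # permuting ROI order permutes labels consistently
  perm <- sample(16)
  cl2 <- clusterForward(m[perm, ], 2, fwdIdx[perm])
  agree <- outer(cl2$cluster, cl2$cluster, "==") ==
    outer(cl$cluster[perm], cl$cluster[perm], "==")
  expect_true(all(agree))
  # degenerate constant rows rejected
  expect_error(clusterForward(matrix(1, 4, 10), 2, rep(0, 4)),
               "degenerate")
})
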