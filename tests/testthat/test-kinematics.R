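test_that("detectBends finds sine extrema with correct timing and amplitude", {
  f <- 20; A <- 15; rate <- 300
  tr <- TailTrace(A * sin(2 * pi * f * (0:74) / rate), rate = rate)
  b <- detectBends(tr)
  expect_equal(nrow(b), 10L)                    # 10 half-cycles in 0.25 s
  expect_true(all(abs(abs(b$amp_deg) - A) < A * 0.01))
  expect_true(all(diff(sign(b$amp_deg)) != 0))  # alternating sides
  # flat trace: no bends
  expect_equal(nrow(detectBends(TailTrace(numeric(100)))), 0L)
})

test_that("detectBends matches a brute-force extremum oracle under noise", {
  f <- 20; A <- 15; rate <- 300
  t <- (0:74) / rate
  clean <- A * sin(2 * pi * f * t)
  set.seed(42)
  noisy <- clean + rnorm(length(t), 0, 0.5)
  b <- detectBends(TailTrace(noisy, rate = rate), minAmpDeg = 5)
  oracle <- bruteExtrema(clean)
  expect_equal(nrow(b), length(oracle))
  # timing within one sample of the clean extrema
  expect_true(all(abs(b$t_s - t[oracle]) <= 1 / rate + 1e-9))
})

test_that("detectBends validates its input", {
  expect_error(detectBends(TailTrace(numeric(0))), "empty input")
  expect_error(TailTrace(numeric(3), rate = 10, time = c(0, 0.1, 0.15)),
               "non-uniform")
})

test_that("extractBouts separates and merges bursts by the quiet gap", {
  rate <- 300
  burst <- 15 * sin(2 * pi * 20 * (0:89) / rate)
  tr2 <- TailTrace(c(rep(0, 150), burst, rep(0, 300), burst, rep(0, 150)),
                   rate = rate)
  expect_equal(nrow(extractBouts(tr2)), 2L)
  tr1 <- TailTrace(c(rep(0, 150), burst, rep(0, 15), burst, rep(0, 150)),
                   rate = rate)
  expect_equal(nrow(extractBouts(tr1)), 1L)
})

test_that("extractBouts recovers a scheduled session within 10 ms", {
  sch <- scheduleBouts(50, seed = 7)
  ss <- synthSession(sch, seed = 7)
  bouts <- extractBouts(ss$trace)
  expect_equal(nrow(bouts), 50L)
  expect_true(all(abs(bouts$start_s - ss$truth$start_s) <= 0.010))
})

test_that("cycleKinematics computes iTBF from same-side bend spacing", {
  b <- data.frame(t_s = (0:6) * 0.025,
                  amp_deg = 15 * c(1, -1, 1, -1, 1, -1, 1))
  ck <- cycleKinematics(b)
  expect_equal(ck$itbf_hz, rep(20, 5))          # 50 ms same-side spacing
  expect_equal(ck$n_oscillations, 3L)           # floor(7/2)
  expect_equal(ck$itba_deg, rep(15, 7))
  # fewer than 2 bends: empty series
  ck0 <- cycleKinematics(b[1, , drop = FALSE])
  expect_length(ck0$itbf_hz, 0)
  expect_equal(ck0$n_oscillations, 0L)
})

test_that("cycleKinematics tracks a frequency ramp", {
  # chirp 15 -> 30 Hz; instantaneous frequency of sin(2*pi*phase(t))
  rate <- 3000                                  # fine grid to isolate math
  dur <- 0.5
  t <- seq(0, dur, by = 1 / rate)
  finst <- 15 + (30 - 15) * t / dur
  phase <- 15 * t + 7.5 * t^2 / dur
  tr <- TailTrace(15 * sin(2 * pi * phase), rate = rate)
  b <- detectBends(tr)
  ck <- cycleKinematics(b)
  expect_gt(length(ck$itbf_hz), 5)
  expect_true(all(diff(ck$itbf_hz) > -1e-9))    # monotone increasing
  fAtMid <- approx(t, finst, xout = ck$itbf_t_s)$y
  expect_true(all(abs(ck$itbf_hz - fAtMid) / fAtMid < 0.10))
})

test_that("classifyBout applies the 25/60 degree rules with signed side", {
  mk <- function(amp) data.frame(t_s = c(0, 0.03), amp_deg = c(amp, -5))
  expect_equal(classifyBout(list(max_abs_tba_deg = 20), mk(20)), "forward")
  expect_equal(classifyBout(list(max_abs_tba_deg = 40), mk(40)), "left_turn")
  expect_equal(classifyBout(list(max_abs_tba_deg = 40), mk(-40)), "right_turn")
  expect_equal(classifyBout(list(max_abs_tba_deg = 70), mk(70)), "discarded")
})

test_that("segmentEpisodes applies the three rules", {
  # 5 oscillations all at 15 degrees -> one forward episode
  b <- data.frame(t_s = (0:9) * 0.03, amp_deg = 15 * rep(c(1, -1), 5))
  ep <- segmentEpisodes(b)
  expect_equal(ep$label, "forward")
  expect_equal(ep$n_oscillations, 5L)
  # three large bends with 50-ms gaps -> one struggle episode
  b2 <- data.frame(t_s = c(0, 0.05, 0.10), amp_deg = c(40, -45, 40))
  expect_equal(segmentEpisodes(b2)$label, "struggle")
  # forward, struggle split by a >100 ms internal gap, forward
  b3 <- rbind(
    data.frame(t_s = (0:7) * 0.03, amp_deg = 15 * rep(c(1, -1), 4)),
    data.frame(t_s = 0.26 + c(0, 0.05, 0.20), amp_deg = c(40, -45, 40)),
    data.frame(t_s = 0.52 + (0:7) * 0.03, amp_deg = 15 * rep(c(1, -1), 4)))
  expect_equal(segmentEpisodes(b3)$label,
               c("forward", "struggle", "struggle", "forward"))
})

test_that("a rare isolated large bend does not split a forward episode", {
  b <- rbind(
    data.frame(t_s = (0:7) * 0.03, amp_deg = 15 * rep(c(1, -1), 4)),
    data.frame(t_s = 0.24, amp_deg = 30),
    data.frame(t_s = 0.27 + (0:7) * 0.03, amp_deg = -15 * rep(c(1, -1), 4)))
  ep <- segmentEpisodes(b)
  expect_equal(ep$label, "forward")
  expect_equal(nrow(ep), 1L)
  # the forward invariant holds on accounting: all counted bends < 25 deg
  expect_lt(ep$max_abs_tba_deg, 25)
  expect_gte(ep$n_oscillations, 3L)
})

test_that("episodes tile the bout without overlap", {
  for (sd in 1:3) {
    sch <- scheduleBouts(20, seed = sd)
    ss <- synthSession(sch, seed = sd)
    bouts <- extractBouts(ss$trace)
    bl <- attr(bouts, "bends")
    for (i in seq_len(nrow(bouts))) {
      ep <- segmentEpisodes(bl[[i]], boutId = i)
      if (nrow(ep) < 2L) next
      expect_true(all(ep$start_s >= bouts$start_s[i] - 1e-9))
      expect_true(all(ep$end_s <= bouts$end_s[i] + 1e-9))
      expect_true(all(ep$start_s[-1L] >= head(ep$end_s, -1L) - 1e-9))
      # forward label implies sub-threshold accounting and >= 3 oscillations
      fwd <- ep[ep$label == "forward", ]
      expect_true(all(fwd$max_abs_tba_deg < 25))
      expect_true(all(fwd$n_oscillations >= 3L))
    }
  }
})

test_that("forwardIndex is the episode-count contrast and is antisymmetric", {
  mk <- function(nf, ns) data.frame(
    label = c(rep("forward", nf), rep("struggle", ns)))
  expect_equal(forwardIndex(mk(5, 0)), 1)
  expect_equal(forwardIndex(mk(0, 4)), -1)
  expect_equal(forwardIndex(mk(3, 1)), 0.5)
  expect_error(forwardIndex(mk(0, 0)), "no episodes")
  # antisymmetry under label swap
  set.seed(3)
  for (i in 1:20) {
    nf <- sample(0:6, 1); ns <- sample(0:6, 1)
    if (nf + ns == 0) next
    expect_equal(forwardIndex(mk(nf, ns)), -forwardIndex(mk(ns, nf)))
  }
})

test_that("siteMedianForwardIndex filters to 10 Hz / 1-2 uA trials", {
  tr <- data.frame(pulse_freq_hz = c(10, 10, 10),
                   intensity_ua = c(1, 1.5, 2),
                   forward_index = c(1, 0.5, -1))
  expect_equal(siteMedianForwardIndex(tr), 0.5)
  tr20 <- transform(tr, pulse_freq_hz = 20)
  expect_true(is.na(siteMedianForwardIndex(tr20)))
  # mixed set equals a hand-filtered median
  set.seed(11)
  mixed <- data.frame(pulse_freq_hz = sample(c(5, 10, 20), 40, TRUE),
                      intensity_ua = sample(c(0.5, 1, 1.5, 2, 4), 40, TRUE),
                      forward_index = runif(40, -1, 1))
  keep <- mixed$pulse_freq_hz == 10 & mixed$intensity_ua >= 1 &
    mixed$intensity_ua <= 2
  expect_equal(siteMedianForwardIndex(mixed),
               median(mixed$forward_index[keep]))
})

test_that("evoked bouts are tagged by their stimulation train", {
  stim <- stimTrials(c(5, 40), c(10, 45), pulseFreqHz = 10, intensityUa = 1)
  sch <- data.frame(type = c("forward", "forward", "forward"),
                    start_s = c(6, 20, 41), tbf_hz = 17, amp_deg = 15,
                    n_osc = 5, steer_deg = 40)
  ss <- synthSession(sch, stim = stim, durationS = 120, seed = 1)
  bouts <- extractBouts(ss$trace, stim = stim)
  expect_equal(bouts$provenance, c("evoked", "post_stim", "evoked"))
  expect_equal(bouts$stim_id[c(1, 3)], c(1L, 2L))
})
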