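test_that("neuropil correction and delta-F/F follow the definition", {
  # constant trace: dff identically zero
  out <- neuropilCorrectDff(rep(100, 60), baselineMode = "inactivity_median",
                            inactivityIdx = 1:30)
  expect_equal(out$dff, rep(0, 60))
  expect_equal(out$f0, 100)
  # step 100 -> 200 with baseline on the first half: plateau dff = 1
  out2 <- neuropilCorrectDff(c(rep(100, 50), rep(200, 50)),
                             baselineMode = "inactivity_median",
                             inactivityIdx = 1:50)
  expect_equal(out2$dff[51:100], rep(1, 50))
  # low-percentile baseline reproduced by a one-line oracle
  set.seed(5)
  f <- 100 + cumsum(rnorm(200)); np <- runif(200, 10, 30)
  out3 <- neuropilCorrectDff(f, np, neuropilFactor = 0.7,
                             baselineMode = "low_percentile")
  corr <- f - 0.7 * np
  f0 <- median(corr[corr <= quantile(corr, 0.10)])
  expect_identical(out3$dff, (corr - f0) / f0)
  expect_identical(out3$f0, f0)
})

test_that("delta-F/F is invariant to common rescaling of F and neuropil", {
  set.seed(6)
  f <- 100 + abs(rnorm(100, 0, 5)); np <- runif(100, 5, 15)
  a <- neuropilCorrectDff(f, np, baselineMode = "low_percentile")$dff
  b <- neuropilCorrectDff(3.7 * f, 3.7 * np,
                          baselineMode = "low_percentile")$dff
  expect_equal(a, b)
  expect_error(neuropilCorrectDff(rep(0, 50),
                                  baselineMode = "low_percentile"),
               "degenerate baseline")
})

test_that("estimateNoise is the inactivity-window standard deviation", {
  expect_equal(estimateNoise(rep(0, 100), 1:50), 0)
  # 30 s of iid Gaussian at 10 Hz: estimate close to the true sigma
  set.seed(7)
  x <- rnorm(300, 0, 0.05)
  expect_true(estimateNoise(x, 1:300) > 0.04 &&
              estimateNoise(x, 1:300) < 0.06)
  # linear ramp: closed-form s.d. of an arithmetic sequence
  n <- 31
  ramp <- seq(0, 0.1, length.out = n)
  expect_equal(estimateNoise(ramp, 1:n),
               (0.1 / (n - 1)) * sqrt(n * (n + 1) / 12))
  expect_error(estimateNoise(ramp, 25:40), "outside")
})

test_that("smoothTrace running average spreads an impulse and cuts variance", {
  expect_equal(smoothTrace(c(0, 1, 0)), c(0.5, 1 / 3, 0.5))
  expect_equal(smoothTrace(rep(2, 10)), rep(2, 10))
  set.seed(8)
  x <- rnorm(1000)
  expect_lt(var(smoothTrace(x)), var(x))
  # low-pass is zero-phase: a symmetric pulse stays centered
  y <- smoothTrace(c(rep(0, 20), 1, rep(0, 20)), mode = "low_pass")
  expect_equal(which.max(y), 21L)
})

test_that("maskAndInterpolate fills gaps linearly and leaves the rest alone", {
  expect_equal(maskAndInterpolate(c(0, 99, 2), 2L), c(0, 1, 2))
  x <- rnorm(50)
  expect_identical(maskAndInterpolate(x, integer(0)), x)
  bad <- c(10L, 11L, 30L)
  y <- maskAndInterpolate(x, bad)
  expect_identical(y[-bad], x[-bad])            # unmasked bit-identical
  expect_error(maskAndInterpolate(x, 1:50), "all frames masked")
  # interpolation error on a smooth signal bounded by its curvature
  t <- seq(0, 2 * pi, length.out = 100)
  s <- sin(t)
  drop <- c(10L, 30L, 50L, 70L, 90L)   # isolated gaps of one sample
  err <- max(abs(maskAndInterpolate(s, drop) - s))
  h <- max(diff(t)) * 2
  expect_lt(err, h^2 / 8 * 1.01)                # (h^2/8) max|f''|
})

test_that("inferSpikeRate inverts the exponential kernel", {
  expect_equal(inferSpikeRate(rep(0, 50)), rep(0, 50))
  rate <- 10; tau <- 1.8
  phi <- exp(-1 / (rate * tau))
  spikes <- numeric(60); spikes[c(11, 41)] <- c(1, 0.5)
  y <- as.numeric(stats::filter(spikes, phi, method = "recursive"))
  r <- inferSpikeRate(y, decayS = tau, rate = rate)
  # mass concentrated at the true frames
  expect_gte(sum(r[c(11, 41)]) / sum(r), 0.9)
  expect_equal(sum(r), sum(spikes), tolerance = 0.1)
  # matches the dense nonnegative least-squares oracle on the small system
  skip_if_not_installed("pracma")
  ro <- nnlsOracle(y, rate * tau)
  expect_equal(r, ro, tolerance = 1e-6)
})

test_that("spike inference recovers mass and timing from matched transients", {
  rate <- 10; tau <- 1.8
  phi <- exp(-1 / (rate * tau))
  set.seed(10)
  for (rep in 1:5) {
    k <- sort(sample(5:95, 3))
    amps <- runif(3, 0.5, 2)
    spikes <- numeric(100); spikes[k] <- amps
    y <- as.numeric(stats::filter(spikes, phi, method = "recursive"))
    r <- inferSpikeRate(y, decayS = tau, rate = rate)
    expect_equal(sum(r), sum(amps), tolerance = 0.1)
    near <- sapply(k, function(j) sum(r[max(1, j - 1):min(100, j + 1)]))
    expect_gte(sum(near) / sum(r), 0.9)
  }
})

test_that("ROI segmentation recovers planted disks and rejects noise", {
  pm <- synthPixelMovie(12, 12, 120, centers = rbind(c(4, 4), c(9, 9)),
                        seed = 11)
  seg <- segmentRoisByCorrelation(pm$movie, pixelSizeUm = pm$pixelSizeUm)
  expect_length(seg$masks, 2L)
  keyify <- function(m) paste(m[, 1], m[, 2])
  ov <- sapply(seg$masks, function(m)
    max(sapply(pm$masks, function(pl)
      length(intersect(keyify(m), keyify(pl))) / nrow(pl))))
  expect_true(all(ov >= 0.9))
  # masks pairwise disjoint
  expect_length(intersect(keyify(seg$masks[[1]]), keyify(seg$masks[[2]])), 0)
  # pure-noise movie yields no ROI
  pm0 <- synthPixelMovie(10, 10, 120, seed = 12)
  expect_length(segmentRoisByCorrelation(pm0$movie, pixelSizeUm = 1)$masks, 0)
})

test_that("oversized correlated regions are rejected by the area gate", {
  # plant a 40-pixel blob at 1 um pixels: above the 28 um2 somatic cap
  pm <- synthPixelMovie(12, 12, 120, centers = rbind(c(6, 6)),
                        areaPx = 40L, seed = 13)
  seg <- segmentRoisByCorrelation(pm$movie, pixelSizeUm = 1)
  expect_length(seg$masks, 0L)
})

test_that("preprocessFluo assembles dff, f0 and noise on a quiet session", {
  sch <- scheduleBouts(10, types = "forward", startS = 8, seed = 14)
  ss <- synthSession(sch, seed = 14)
  sn <- synthNeurons(ss, c("forward_component", "null"), noiseSd = 0.005,
                     seed = 14)
  bouts <- extractBouts(ss$trace)
  fs <- preprocessFluo(sn$fluo, bouts = bouts, smoothMode = "none")
  expect_equal(unname(SummarizedExperiment::rowData(fs)$f0),
               c(100, 100), tolerance = 0.02)
  expect_true(all(noiseSigma(fs) < 0.02))
  expect_true(all(is.finite(dff(fs))))
  # no bout table and no inactivity: falls back to the percentile baseline
  expect_warning(preprocessFluo(sn$fluo, bouts = NULL,
                                baselineMode = "inactivity_median"),
                 "falling back")
})
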