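# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force searches, closed forms and tiny
# dense solvers.

# brute-force local extrema of a sampled series (no filtering)
bruteExtrema <- function(x) {
  idx <- which(diff(sign(diff(x))) != 0) + 1L
  idx[x[idx] != 0]
}

# dense nonnegative least squares via pracma, for small kernel systems
nnlsOracle <- function(y, tauFrames) {
  n <- length(y)
  K <- outer(seq_len(n), seq_len(n),
             function(i, j) ifelse(i >= j, exp(-(i - j) / tauFrames), 0))
  pracma::lsqnonneg(K, y)$x
}

# causal discrete convolution with an exponential kernel, direct sum
convOracle <- function(x, phi) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) out[t] <- sum(x[1:t] * phi^((t - 1):0))
  out
}

# one synthetic noise-free forward/struggle stimulation session shared by
# recruitment-style tests
makeStimSession <- function(nTrains = 15, seed = 1L) {
  starts <- seq(10, 10 + (nTrains - 1) * 20, by = 20)
  stim <- stimTrials(starts, starts + 0.5, pulseFreqHz = 10,
                     intensityUa = rep(1:5, length.out = nTrains))
  ss <- synthSession(scheduleBouts(0), stim = stim,
                     durationS = max(starts) + 15, seed = seed)
  ss
}
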