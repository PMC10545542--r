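# Encoding models: four-regressor OLS per neuron with permutation
# significance, and the max-delta-F/F versus ln(oscillations) regression.

#' Fit the four-regressor encoding model for one neuron
#'
#' Ordinary least squares for
#' `dff(t) = a0 + a1*x_itba + a2*x_itba_rise + a3*x_itbf + a4*x_itbf_rise`,
#' with the regressors z-scored. Artifact frames are dropped from the fit
#' (not interpolated).
#'
#' @param dffSeries delta-F/F vector.
#' @param regressors data.frame from [buildRegressorSet()] (columns
#'   `x_itba`, `x_itba_rise`, `x_itbf`, `x_itbf_rise`).
#' @param mask logical vector; frames marked TRUE are excluded.
#' @return list: `coef` (named a0..a4), `r2`, `fitted`, `used` (logical
#'   frames used).
#' @export
fitEncodingModel <- function(dffSeries, regressors, mask = NULL) {
  X <- as.matrix(regressors[, c("x_itba", "x_itba_rise",
                                "x_itbf", "x_itbf_rise")])
  n <- length(dffSeries)
  stopifnot(nrow(X) == n)
  used <- if (is.null(mask)) rep(TRUE, n) else !mask
  if (sum(used) < 5L * (ncol(X) + 1L))
    stop("too few frames for a 5-parameter fit")
  Xd <- cbind(`(Intercept)` = 1, X)[used, , drop = FALSE]
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):ncol(Xd)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  y <- dffSeries[used]
  fit <- lm.fit(Xd, y)
  cf <- setNames(fit$coefficients,
                 c("a0", "a1_itba", "a2_itba_rise", "a3_itbf",
                   "a4_itbf_rise"))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 0
  list(coef = cf, r2 = r2, fitted = fit$fitted.values, used = used)
}

#' Permutation significance of encoding-model coefficients
#'
#' Builds a null by circular time-shifts of the delta-F/F trace (which
#' preserve its autocorrelation), with the shift drawn uniformly between
#' `10 * tauS` and `T - 10 * tauS`. For each slope coefficient the
#' one-sided p-value is `(1 + #{null a_i >= observed a_i}) / (1 + nPerm)`;
#' a coefficient is significant when it is positive and `p < alpha`.
#'
#' @inheritParams fitEncodingModel
#' @param nPerm number of permutations (default 999; at least 100).
#' @param seed RNG seed.
#' @param tauS indicator decay used to bound the shift (default 1.5).
#' @param rate imaging frame rate in Hz.
#' @param alpha significance level (default 0.05).
#' @return list: `coef`, `r2`, `p_perm` (per slope), `significant`
#'   (positive coefficient and `p < alpha`), `n_permutations`, `seed`.
#' @export
permutationSignificance <- function(dffSeries, regressors, nPerm = 999,
                                    seed = 1L, tauS = 1.5, rate = 10,
                                    alpha = 0.05, mask = NULL) {
  stopifnot(nPerm >= 100L)
  n <- length(dffSeries)
  minShift <- ceiling(10 * tauS * rate)
  if (n <= 2L * minShift)
    stop("trace shorter than 20 * tau; cannot build a shift null")
  obs <- fitEncodingModel(dffSeries, regressors, mask)
  slopes <- obs$coef[-1L]
  # factor the design once; each permutation is a cheap triangular solve
  X <- cbind(1, as.matrix(regressors[, c("x_itba", "x_itba_rise",
                                         "x_itbf", "x_itbf_rise")]))
  used <- if (is.null(mask)) rep(TRUE, n) else !mask
  qrX <- qr(X[used, , drop = FALSE])
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  exceed <- numeric(length(slopes))
  shifts <- sample(seq(minShift, n - minShift), nPerm, replace = TRUE)
  for (s in shifts) {
    ynull <- c(dffSeries[(s + 1L):n], dffSeries[1:s])
    cf <- qr.coef(qrX, ynull[used])[-1L]
    exceed <- exceed + (cf >= slopes)
  }
  p <- setNames((1 + exceed) / (1 + nPerm), names(slopes))
  list(coef = obs$coef, r2 = obs$r2, p_perm = p,
       significant = (slopes > 0) & (p < alpha),
       n_permutations = nPerm, seed = seed)
}

#' Regression of maximum delta-F/F on ln(number of oscillations)
#'
#' Simple linear regression of the per-episode maximum delta-F/F on the
#' natural log of the episode's oscillation count; the log transform
#' reduces the leverage of episodes with very many oscillations.
#'
#' @param maxDff per-episode maximum delta-F/F.
#' @param nOscillations per-episode oscillation counts (all >= 1).
#' @return list: `slope`, `intercept`, `pearson_r`, `p_value`,
#'   `n_episodes`.
#' @export
fitLogOscillations <- function(maxDff, nOscillations) {
  stopifnot(length(maxDff) == length(nOscillations),
            length(maxDff) >= 3L, all(nOscillations >= 1))
  x <- log(nOscillations)
  if (sd(x) == 0) stop("zero variance in ln(oscillations)")
  fit <- lm.fit(cbind(1, x), maxDff)
  if (sd(maxDff) == 0) {
    r <- 0; p <- 1
  } else {
    ct <- suppressWarnings(cor.test(x, maxDff))
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       pearson_r = r, p_value = p,
       n_episodes = length(maxDff))
}

#' Pearson correlation of each ROI trace with a regressor
#'
#' @param traces ROI x frame matrix.
#' @param regressor numeric vector (one value per frame).
#' @param mask logical artifact mask; masked frames excluded.
#' @return per-ROI correlation vector; `NA` for zero-variance traces.
#' @export
pearsonCorrelate <- function(traces, regressor, mask = NULL) {
  stopifnot(ncol(traces) == length(regressor), ncol(traces) >= 10L)
  use <- if (is.null(mask)) rep(TRUE, length(regressor)) else !mask
  apply(traces[, use, drop = FALSE], 1L, function(y) {
    if (sd(y) == 0 || sd(regressor[use]) == 0) return(NA_real_)
    cor(y, regressor[use])
  })
}
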