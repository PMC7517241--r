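#' Plan sliding analysis windows
#'
#' Windows of length tau tile the segment with the requested overlap:
#' starts at 0, step, 2 step, ... while the window still fits. Courses
#' are indexed by window-center times so power- and entropy-based
#' trajectories share one time axis.
#'
#' @param segmentLength analyzed segment length in seconds.
#' @param tau window length in seconds.
#' @param overlap overlap fraction in \code{[0, 1)} (0.9 by default).
#' @param rate sampling rate in Hz.
#' @return A [WindowPlan-class].
#' @examples
#' planWindows(2, 1, 0.9, 250)  # 11 windows, 25-sample step
#' @export
planWindows <- function(segmentLength, tau, overlap = 0.9, rate) {
  stopifnot(tau > 0, overlap >= 0, overlap < 1, rate > 0)
  if (tau > segmentLength + 1e-9)
    stop("tau (", tau, " s) exceeds the segment length (",
         segmentLength, " s)")
  nTau <- as.integer(round(tau * rate))
  nSeg <- as.integer(round(segmentLength * rate))
  step <- max(1L, as.integer(round(tau * (1 - overlap) * rate)))
  starts <- seq.int(1L, nSeg - nTau + 1L, by = step)
  centers <- (starts - 1L + nTau / 2) / rate
  new("WindowPlan", tau = tau, overlap = overlap, rate = rate,
      nSamples = nTau, starts = as.integer(starts), centers = centers)
}

#' Power-ratio ERD/S time-course
#'
#' The classical estimator: per channel and sample, the instantaneous
#' power xi(t) (squared amplitude averaged across trials) expressed as
#' the relative change (xi(t) - xibar) / xibar against the mean power
#' xibar over the baseline reference window. Negative values mark
#' desynchronization (power drop), positive values synchronization.
#' The diagnostics report the variance ratio var(xi) / var(xi | ref)
#' and warn when it falls below \code{varRatioWarn}, i.e. when the
#' baseline scatter is not negligible against the task-related power
#' excursion.
#'
#' @param trials a [TrialSet-class] with a set reference window.
#' @param smooth optional moving-average length in seconds applied to
#'   the course for display (0 = none).
#' @param varRatioWarn threshold of the variance-ratio diagnostic.
#' @return An [ErdsCourse-class] (\code{mode = "power"}, one value per
#'   sample).
#' @export
powerErds <- function(trials, smooth = 0, varRatioWarn = 10) {
  stopifnot(is(trials, "TrialSet"))
  if (anyNA(trials@referenceWindow))
    stop("powerErds needs a reference window on the TrialSet")
  x <- trials@trials
  xi <- apply(x^2, c(2L, 3L), mean)           # channels x samples
  refIdx <- .sampleRange(trials@referenceWindow, trials@sampleInterval,
                         nSamples(trials))
  xibar <- rowMeans(xi[, refIdx, drop = FALSE])
  if (any(xibar <= 0))
    stop("degenerate reference: zero baseline power on channel(s) ",
         paste(channelNames(trials)[xibar <= 0], collapse = ", "))
  zeta <- sweep(sweep(xi, 1L, xibar, `-`), 1L, xibar, `/`)
  if (smooth > 0) {
    w <- max(1L, as.integer(round(smooth * sampleRate(trials))))
    kern <- rep(1 / w, w)
    zeta <- t(apply(zeta, 1L, function(z)
      stats::filter(z, kern, sides = 2L)))
  }
  # diagnostic on a 0.2 s moving average: the raw squared amplitude
  # ripples at twice the oscillation frequency, which would swamp both
  # variances
  wd <- max(1L, as.integer(round(0.2 * sampleRate(trials))))
  xiS <- t(apply(xi, 1L, function(z)
    stats::filter(z, rep(1 / wd, wd), sides = 2L)))
  varRatio <- apply(xiS, 1L, function(v) stats::var(v, na.rm = TRUE)) /
    pmax(apply(xiS[, refIdx, drop = FALSE], 1L,
               function(v) stats::var(v, na.rm = TRUE)),
         .Machine$double.xmin)
  if (any(varRatio < varRatioWarn))
    warning("power-course variance ratio below ", varRatioWarn,
            " on ", sum(varRatio < varRatioWarn),
            " channel(s); the baseline scatter is not negligible")
  tAxis <- (seq_len(nSamples(trials)) - 0.5) * trials@sampleInterval
  new("ErdsCourse", values = zeta, timeAxis = tAxis, mode = "power",
      estimator = "power", channelNames = channelNames(trials),
      perTrial = array(numeric(), c(0L, 0L, 0L)),
      diagnostics = list(varRatio = varRatio, refPower = xibar))
}

# estimator dispatch used by the sliding-window course
.entropyFun <- function(estimator) {
  switch(estimator,
         sampen = function(w, m, rho, rhoAbs)
           suppressWarnings(sampleEntropy(w, m, rho, rhoAbs)),
         fuzzyen = fuzzyEntropy,
         vqent = function(w, m, rho, rhoAbs)
           as.numeric(vqEntropy(w, m, rho, rhoAbs)),
         stop("unknown estimator: ", estimator))
}

#' Sliding-window entropy ERD/S time-course
#'
#' Computes the chosen entropy estimator on every sliding window of
#' every trial and channel, keeps the single-trial courses (used by the
#' classification analyses) and returns their trial average as the
#' course. SampEn windows with no dimension-(M+1) match yield NaN; they
#' stay NaN in the per-trial array and are excluded from the trial
#' average, with the count reported in the diagnostics.
#'
#' The tolerance is resolved per \code{scale}: \code{"trial"} (default)
#' fixes the absolute tolerance at \code{rho} times the per-trial,
#' per-channel standard deviation of the whole analyzed segment, so
#' that amplitude suppression inside the trial (the ERD) lowers the
#' entropy course; \code{"window"} rescales inside every window, which
#' makes the estimate amplitude-invariant window by window.
#'
#' @param trials a [TrialSet-class].
#' @param plan a [WindowPlan-class] covering the trial duration.
#' @param params an [EntropyParams-class].
#' @param scale tolerance scaling, \code{"trial"} or \code{"window"}.
#' @return An [ErdsCourse-class] (\code{mode = "entropy"}) with the
#'   per-trial courses retained. For the vqent estimator the
#'   diagnostics include the median codebook size \code{qPrimeMedian}.
#' @export
entropyErds <- function(trials, plan, params = entropyParams(),
                        scale = c("trial", "window")) {
  stopifnot(is(trials, "TrialSet"), is(plan, "WindowPlan"),
            is(params, "EntropyParams"))
  scale <- match.arg(scale)
  if (max(plan@starts) + plan@nSamples - 1L > nSamples(trials))
    stop("window plan reaches outside the trials")
  minLen <- if (params@estimator == "vqent") params@m + 2L else params@m + 3L
  if (plan@nSamples < minLen)
    stop("windows of ", plan@nSamples, " samples are too short for m = ",
         params@m)
  est <- .entropyFun(params@estimator)
  N <- nTrials(trials); C <- nChannels(trials); W <- length(plan@starts)
  pt <- array(NA_real_, c(N, C, W))
  qprimes <- if (params@estimator == "vqent") integer() else NULL
  for (n in seq_len(N)) {
    for (c in seq_len(C)) {
      sig <- trials@trials[n, c, ]
      rAbs <- if (scale == "trial") params@rho * stats::sd(sig) else NULL
      for (w in seq_len(W)) {
        win <- sig[plan@starts[w]:(plan@starts[w] + plan@nSamples - 1L)]
        if (params@estimator == "vqent") {
          h <- vqEntropy(win, params@m, params@rho, rhoAbs = rAbs)
          qprimes <- c(qprimes, attr(h, "qPrime"))
          pt[n, c, w] <- as.numeric(h)
        } else {
          pt[n, c, w] <- est(win, params@m, params@rho, rAbs)
        }
      }
    }
  }
  avg <- apply(pt, c(2L, 3L), function(v) mean(v, na.rm = TRUE))
  nNaN <- sum(is.nan(pt))
  diag <- list(nanWindows = nNaN, scale = scale,
               m = params@m, rho = params@rho)
  if (nNaN > 0L)
    message(nNaN, " window(s) with undefined entropy excluded from the ",
            "trial average")
  if (!is.null(qprimes)) diag$qPrimeMedian <- stats::median(qprimes)
  new("ErdsCourse", values = avg, timeAxis = plan@centers,
      mode = "entropy", estimator = params@estimator,
      channelNames = channelNames(trials), perTrial = pt,
      diagnostics = diag)
}
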