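#' Specification of a synthetic two-class motor-imagery EEG set
#'
#' Parameter bag for the generator. The defaults emulate the standard
#' cued motor-imagery recording: 22 channels at 250 Hz, 7 s trials with
#' the cue at 2 s, a mu-band (8-13 Hz) sensorimotor oscillation riding
#' on 1/f background noise, and an ERD of \code{erdDepth} (fractional
#' mu-amplitude suppression) on the class-contralateral channel (right
#' hand -> C3, left hand -> C4) inside \code{erdInterval}, ramped with
#' 0.25 s cosine flanks. \code{mixingStrength} adds volume-conduction
#' style leakage by mixing every channel with its montage neighbors
#' (rows of the mixing matrix are normalized).
#'
#' @param nTrialsPerClass trials per class.
#' @param nChannels channel count (2 or more; 22 reproduces the bundled
#'   montage, smaller counts keep the C3/C4 analogues as the first two
#'   channels).
#' @param rate sampling rate in Hz.
#' @param trialDuration trial length in seconds.
#' @param muBand mu rhythm frequency band \code{c(low, high)} in Hz.
#' @param erdDepth fraction of mu amplitude suppressed during MI (0-1).
#' @param erdInterval ERD interval \code{c(t0, t1)} in seconds.
#' @param snr mu-to-noise amplitude ratio on the carrier channels.
#' @param noiseExponent spectral slope of the 1/f background.
#' @param mixingStrength off-diagonal leakage in \code{[0, 1)}.
#' @param ampJitter relative trial-to-trial mu amplitude jitter.
#' @param seed integer seed; the output is bit-reproducible.
#' @return A validated list of class \code{"SynthSpec"}.
#' @export
synthSpec <- function(nTrialsPerClass = 50L, nChannels = 22L, rate = 250,
                      trialDuration = 7, muBand = c(8, 13),
                      erdDepth = 0.6, erdInterval = c(2.5, 4.5),
                      snr = 2, noiseExponent = 1, mixingStrength = 0,
                      ampJitter = 0.2, seed = 1L) {
  spec <- list(nTrialsPerClass = as.integer(nTrialsPerClass),
               nChannels = as.integer(nChannels), rate = rate,
               trialDuration = trialDuration, muBand = muBand,
               erdDepth = erdDepth, erdInterval = erdInterval,
               snr = snr, noiseExponent = noiseExponent,
               mixingStrength = mixingStrength, ampJitter = ampJitter,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(nTrialsPerClass >= 1L, nChannels >= 2L, rate > 0,
              trialDuration > 0, length(muBand) == 2L,
              muBand[1] > 0, muBand[1] < muBand[2],
              erdDepth >= 0, erdDepth <= 1,
              erdInterval[1] >= 0, erdInterval[2] <= trialDuration,
              erdInterval[1] < erdInterval[2],
              snr > 0, mixingStrength >= 0, mixingStrength < 1,
              ampJitter >= 0, ampJitter < 1)
  })
  class(spec) <- "SynthSpec"
  spec
}

#' @export
print.SynthSpec <- function(x, ...) {
  cat(sprintf(
    "SynthSpec: %d+%d trials, %d channels, %g Hz, %g s\n",
    x$nTrialsPerClass, x$nTrialsPerClass, x$nChannels, x$rate,
    x$trialDuration))
  cat(sprintf("ERD depth %g on [%g, %g) s, snr %g, mixing %g, seed %d\n",
              x$erdDepth, x$erdInterval[1], x$erdInterval[2], x$snr,
              x$mixingStrength, x$seed))
  invisible(x)
}

.synthChannelNames <- function(nChannels) {
  if (nChannels == 22L) return(rownames(.iv2aLayout))
  c("C3", "C4", if (nChannels > 2L) paste0("n", seq_len(nChannels - 2L)))
}

#' Montage matching a synthetic trial set
#'
#' The bundled 22-channel layout for \code{nChannels = 22}; otherwise
#' C3/C4 analogues at the lateral sensorimotor positions and the
#' remaining channels spread on a circle.
#'
#' @param spec a [synthSpec()].
#' @return A [Montage-class].
#' @export
synthMontage <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  nm <- .synthChannelNames(spec$nChannels)
  if (spec$nChannels == 22L) return(defaultMontage(nm))
  k <- spec$nChannels - 2L
  ang <- if (k > 0L) 2 * pi * seq_len(k) / k else numeric()
  pos <- rbind(c(-0.4, 0), c(0.4, 0),
               cbind(0.75 * cos(ang), 0.75 * sin(ang)))
  rownames(pos) <- nm
  defaultMontage(nm, positions = pos)
}

# cosine-ramped ERD envelope: 1 outside the interval, 1 - depth on its
# plateau, 0.25 s half-cosine flanks
.erdEnvelope <- function(t, interval, depth, ramp = 0.25) {
  env <- rep(1, length(t))
  t0 <- interval[1L]; t1 <- interval[2L]
  r <- min(ramp, (t1 - t0) / 2)
  inRampUp <- t >= t0 & t < t0 + r
  inPlateau <- t >= t0 + r & t < t1 - r
  inRampDown <- t >= t1 - r & t < t1
  env[inRampUp] <- 1 - depth * (1 - cos(pi * (t[inRampUp] - t0) / r)) / 2
  env[inPlateau] <- 1 - depth
  env[inRampDown] <- 1 - depth * (1 + cos(pi * (t[inRampDown] - (t1 - r)) / r)) / 2
  env
}

# unit-variance 1/f^alpha noise by spectral shaping of white noise
.pinkNoise <- function(n, alpha) {
  white <- stats::rnorm(n)
  if (alpha == 0) return(white)
  spec <- stats::fft(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k)                  # fold to physical frequencies
  f[1L] <- 1                           # DC guarded
  shaped <- spec * f^(-alpha / 2)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a synthetic two-class motor-imagery trial set
#'
#' Each trial is 1/f background noise on every channel plus a mu-band
#' oscillation (random frequency and phase per trial, +/- ampJitter
#' amplitude jitter) on the sensorimotor carrier channels. On the
#' channel contralateral to the trial's class the mu amplitude is
#' multiplied by \code{1 - erdDepth} inside \code{erdInterval} with
#' 0.25 s cosine ramps. When \code{mixingStrength > 0} the channels are
#' then mixed with their montage neighbors (volume conduction). Labels
#' are balanced and the output is fully reproducible from the seed.
#'
#' @param spec a [synthSpec()].
#' @return A [TrialSet-class] with \code{miWindow = erdInterval} and the
#'   default baseline \code{[0.5, 1.5)} s.
#' @export
generateTrials <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  set.seed(spec$seed)

  nm <- .synthChannelNames(spec$nChannels)
  N <- 2L * spec$nTrialsPerClass
  S <- as.integer(round(spec$trialDuration * spec$rate))
  t <- (seq_len(S) - 1L) / spec$rate
  labels <- rep(c("left", "right"), times = spec$nTrialsPerClass)

  # mu carriers: both lateral sensorimotor analogues always; in the full
  # montage the remaining sensorimotor-group channels carry a weaker mu
  carrierAmp <- stats::setNames(numeric(length(nm)), nm)
  carrierAmp[c("C3", "C4")] <- 1
  if (spec$nChannels == 22L) {
    others <- setdiff(unlist(.sensorimotorGroups), c("C3", "C4"))
    carrierAmp[others] <- 0.6
  }
  contra <- c(left = "C4", right = "C3")
  envErd <- .erdEnvelope(t, spec$erdInterval, spec$erdDepth)

  trials <- array(0, c(N, length(nm), S))
  for (n in seq_len(N)) {
    for (ci in seq_along(nm)) {
      x <- .pinkNoise(S, spec$noiseExponent)
      a <- carrierAmp[ci]
      if (a > 0) {
        f <- stats::runif(1, spec$muBand[1], spec$muBand[2])
        ph <- stats::runif(1, 0, 2 * pi)
        amp <- a * spec$snr *
          (1 + stats::runif(1, -spec$ampJitter, spec$ampJitter))
        mu <- amp * sin(2 * pi * f * t + ph)
        if (nm[ci] == contra[[labels[n]]]) mu <- mu * envErd
        x <- x + mu
      }
      trials[n, ci, ] <- x
    }
  }

  if (spec$mixingStrength > 0) {
    mont <- synthMontage(spec)
    A <- diag(1 - spec$mixingStrength, length(nm))
    for (ci in seq_along(nm)) {
      nb <- match(mont@adjacency[[nm[ci]]], nm)
      A[ci, nb] <- spec$mixingStrength / length(nb)
    }
    A <- A / rowSums(A)
    for (n in seq_len(N)) trials[n, , ] <- A %*% trials[n, , ]
  }

  refWin <- if (spec$erdInterval[1L] > 0.6)
    c(0.5, min(1.5, spec$erdInterval[1L])) else c(NA_real_, NA_real_)
  TrialSet(trials, labels, 1 / spec$rate, channelNames = nm,
           cueTime = min(2, spec$erdInterval[1L]),
           miWindow = spec$erdInterval,
           referenceWindow = refWin)
}

#' Ground-truth effect description of a synthetic set
#'
#' Machine-readable description of the programmed ERD effects, used by
#' parameter-recovery tests: one entry per class naming the affected
#' channel, the ERD interval and its depth. Empty when
#' \code{erdDepth = 0}.
#'
#' @param spec a [synthSpec()].
#' @return A list of effect entries (possibly empty).
#' @export
groundTruth <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  if (spec$erdDepth == 0) return(list())
  list(
    list(class = "left", channel = "C4",
         interval = spec$erdInterval, depth = spec$erdDepth),
    list(class = "right", channel = "C3",
         interval = spec$erdInterval, depth = spec$erdDepth)
  )
}
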