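#' Construct a band-pass filter specification
#'
#' Defaults to the 4-40 Hz fifth-order Butterworth band-pass used for
#' motor-imagery EEG.
#'
#' @param band pass band \code{c(low, high)} in Hz.
#' @param order Butterworth design order.
#' @return A [FilterSpec-class].
#' @export
filterSpec <- function(band = c(4, 40), order = 5L) {
  new("FilterSpec", band = as.numeric(band), order = as.integer(order),
      kind = "bandpass-butterworth")
}

# zero-phase Butterworth band-pass of one signal, with reflection
# padding so the forward-backward pass has no edge transients
.zeroPhaseBandpass <- function(x, filt, padLen) {
  n <- length(x)
  x <- x - mean(x)      # exact DC removal; the band-pass has no DC gain

  p <- min(padLen, n - 1L)
  head <- 2 * x[1L] - x[(p + 1L):2L]
  tail <- 2 * x[n] - x[(n - 1L):(n - p)]
  y <- signal::filtfilt(filt, c(head, x, tail))
  y[(p + 1L):(p + n)]
}

#' Band-pass filter all trials
#'
#' Applies the Butterworth band-pass independently to each channel of
#' each trial, forward and backward (zero phase) so that ERD/S latencies
#' are not shifted by group delay; the effective attenuation order is
#' twice the design order. Epoch edges are reflection-padded before
#' filtering.
#'
#' @param trials a [TrialSet-class].
#' @param spec a [FilterSpec-class].
#' @return A [TrialSet-class] of the same shape.
#' @export
bandpass <- function(trials, spec = filterSpec()) {
  stopifnot(is(trials, "TrialSet"), is(spec, "FilterSpec"))
  nyq <- sampleRate(trials) / 2
  if (spec@band[2L] >= nyq)
    stop("band high edge (", spec@band[2L], " Hz) must be below the Nyquist ",
         "frequency (", nyq, " Hz)")
  filt <- signal::butter(spec@order, spec@band / nyq, type = "pass")
  padLen <- as.integer(round(3 * sampleRate(trials) / spec@band[1L]))
  out <- trials@trials
  for (n in seq_len(dim(out)[1L]))
    for (c in seq_len(dim(out)[2L]))
      out[n, c, ] <- .zeroPhaseBandpass(out[n, c, ], filt, padLen)
  ans <- trials
  ans@trials <- out
  ans
}

#' Surface Laplacian spatial filter
#'
#' Re-references every channel to itself minus the mean of its montage
#' neighbors (small surface Laplacian). This sharpens the spatial
#' resolution of scalp EEG and suppresses the volume-conduction leakage
#' that smears sensorimotor rhythms across electrodes. Channels with no
#' neighbors are passed through with a warning. All outputs are computed
#' from the unfiltered input, not sequentially.
#'
#' @param trials a [TrialSet-class].
#' @param montage a [Montage-class] covering all channels of
#'   \code{trials}.
#' @return A [TrialSet-class] of the same shape.
#' @export
laplacian <- function(trials, montage) {
  stopifnot(is(trials, "TrialSet"), is(montage, "Montage"))
  chans <- channelNames(trials)
  miss <- setdiff(chans, channelNames(montage))
  if (length(miss))
    stop("montage does not cover channel(s): ", paste(miss, collapse = ", "))
  x <- trials@trials
  out <- x
  for (ci in seq_along(chans)) {
    nb <- intersect(montage@adjacency[[chans[ci]]], chans)
    if (length(nb) == 0L) {
      warning("channel ", chans[ci], " has no neighbors; passed through")
      next
    }
    nbIdx <- match(nb, chans)
    if (length(nbIdx) == 1L) {
      out[, ci, ] <- x[, ci, ] - x[, nbIdx, ]
    } else {
      out[, ci, ] <- x[, ci, ] -
        apply(x[, nbIdx, , drop = FALSE], c(1L, 3L), mean)
    }
  }
  ans <- trials
  ans@trials <- out
  ans
}

#' Crop trials to a time interval
#'
#' Returns the samples falling in the half-open interval
#' \code{[t0, t1)}; trial time restarts at 0 and the MI/reference
#' window metadata are re-expressed relative to the new origin (and
#' dropped with NA when they fall outside the cropped segment).
#'
#' @param trials a [TrialSet-class].
#' @param interval \code{c(t0, t1)} in seconds, inside the trial.
#' @return A cropped [TrialSet-class].
#' @export
extractWindow <- function(trials, interval) {
  stopifnot(is(trials, "TrialSet"), length(interval) == 2L)
  dur <- trialDuration(trials)
  if (interval[1L] < 0 || interval[2L] > dur + 1e-9 ||
      interval[1L] >= interval[2L])
    stop("interval must be a non-empty subinterval of [0, ", dur, ") s")
  idx <- .sampleRange(interval, trials@sampleInterval, nSamples(trials))
  shift <- function(w) {
    if (anyNA(w)) return(c(NA_real_, NA_real_))
    w2 <- w - interval[1L]
    newDur <- length(idx) * trials@sampleInterval
    if (w2[2L] <= 0 || w2[1L] >= newDur) return(c(NA_real_, NA_real_))
    c(max(0, w2[1L]), min(newDur, w2[2L]))
  }
  mi <- shift(trials@miWindow)
  ref <- shift(trials@referenceWindow)
  # a reference no longer preceding the MI window is meaningless
  if (!anyNA(mi) && !anyNA(ref) && ref[2L] > mi[1L] + 1e-9)
    ref <- c(NA_real_, NA_real_)
  TrialSet(trials@trials[, , idx, drop = FALSE], trials@labels,
           trials@sampleInterval, channelNames = trials@channelNames,
           cueTime = if (is.na(trials@cueTime)) NA_real_ else
             trials@cueTime - interval[1L],
           miWindow = mi, referenceWindow = ref)
}
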