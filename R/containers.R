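#' Construct a continuous Recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param sampleInterval sampling interval in seconds.
#' @param channelNames channel labels; defaults to the matrix row names
#'   or \code{"ch1"..."chC"}.
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(500), 2, 250), 0.004)
#' sampleRate(rec)
#' @export
Recording <- function(data, sampleInterval, channelNames = NULL) {
  data <- as.matrix(data)
  if (is.null(channelNames)) {
    channelNames <- rownames(data)
    if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nrow(data)))
  }
  rownames(data) <- channelNames
  new("Recording", data = data, sampleInterval = as.numeric(sampleInterval),
      channelNames = as.character(channelNames))
}

#' Construct a TrialSet
#'
#' @param trials N x channels x samples numeric array.
#' @param labels per-trial class labels (coerced to factor).
#' @param sampleInterval sampling interval in seconds.
#' @param channelNames channel labels; defaults to array dimnames or
#'   \code{"ch1"..."chC"}.
#' @param cueTime cue onset in seconds from trial start.
#' @param miWindow MI analysis interval \code{c(t0, t1)} in seconds.
#' @param referenceWindow baseline interval in seconds (precedes the MI
#'   window); set \code{c(NA, NA)} if no baseline is available.
#' @return A [TrialSet-class] object.
#' @examples
#' x <- array(rnorm(4 * 2 * 500), c(4, 2, 500))
#' ts <- TrialSet(x, rep(c("left", "right"), 2), 0.004,
#'                miWindow = c(1, 2), referenceWindow = c(0.1, 0.9))
#' nTrials(ts)
#' @export
TrialSet <- function(trials, labels, sampleInterval,
                     channelNames = NULL, cueTime = NA_real_,
                     miWindow = c(NA_real_, NA_real_),
                     referenceWindow = c(NA_real_, NA_real_)) {
  trials <- as.array(trials)
  if (is.null(channelNames)) {
    channelNames <- dimnames(trials)[[2L]]
    if (is.null(channelNames))
      channelNames <- paste0("ch", seq_len(dim(trials)[2L]))
  }
  dimnames(trials) <- list(NULL, channelNames, NULL)
  new("TrialSet",
      trials = trials, labels = factor(labels),
      sampleInterval = as.numeric(sampleInterval),
      channelNames = as.character(channelNames),
      cueTime = as.numeric(cueTime),
      miWindow = as.numeric(miWindow),
      referenceWindow = as.numeric(referenceWindow))
}

# sample-index range of the half-open interval [t0, t1); 1-based,
# guarded against floating-point edges
.sampleRange <- function(interval, dt, nSamples) {
  i0 <- floor(interval[1L] / dt + 1e-9) + 1L
  i1 <- ceiling(interval[2L] / dt - 1e-9)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(as.integer(nSamples), as.integer(i1))
  if (i1 < i0) stop("interval [", interval[1L], ", ", interval[2L],
                    ") contains no samples")
  i0:i1
}

#' @rdname vqerds-accessors
#' @export
setMethod("trialData", "TrialSet", function(x) x@trials)

#' @rdname vqerds-accessors
#' @export
setMethod("trialLabels", "TrialSet", function(x) x@labels)

#' @rdname vqerds-accessors
#' @export
setMethod("sampleInterval", "TrialSet", function(x) x@sampleInterval)

#' @rdname vqerds-accessors
#' @export
setMethod("sampleInterval", "Recording", function(x) x@sampleInterval)

#' @rdname vqerds-accessors
#' @export
setMethod("sampleRate", "TrialSet", function(x) 1 / x@sampleInterval)

#' @rdname vqerds-accessors
#' @export
setMethod("sampleRate", "Recording", function(x) 1 / x@sampleInterval)

#' @rdname vqerds-accessors
#' @export
setMethod("channelNames", "TrialSet", function(x) x@channelNames)

#' @rdname vqerds-accessors
#' @export
setMethod("channelNames", "Recording", function(x) x@channelNames)

#' @rdname vqerds-accessors
#' @export
setMethod("channelNames", "ErdsCourse", function(x) x@channelNames)

#' @rdname vqerds-accessors
#' @export
setMethod("channelNames", "Montage", function(x) rownames(x@positions))

#' @rdname vqerds-accessors
#' @export
setMethod("nTrials", "TrialSet", function(x) dim(x@trials)[1L])

#' @rdname vqerds-accessors
#' @export
setMethod("nChannels", "TrialSet", function(x) dim(x@trials)[2L])

#' @rdname vqerds-accessors
#' @export
setMethod("nChannels", "Recording", function(x) nrow(x@data))

#' @rdname vqerds-accessors
#' @export
setMethod("nSamples", "TrialSet", function(x) dim(x@trials)[3L])

#' @rdname vqerds-accessors
#' @export
setMethod("nSamples", "Recording", function(x) ncol(x@data))

#' @rdname vqerds-accessors
#' @export
setMethod("trialDuration", "TrialSet",
          function(x) dim(x@trials)[3L] * x@sampleInterval)

#' @rdname vqerds-accessors
#' @export
setMethod("miWindow", "TrialSet", function(x) x@miWindow)

#' @rdname vqerds-accessors
#' @export
setMethod("referenceWindow", "TrialSet", function(x) x@referenceWindow)

#' @rdname vqerds-accessors
#' @export
setMethod("timeAxis", "ErdsCourse", function(x) x@timeAxis)

#' @rdname vqerds-accessors
#' @export
setMethod("courseValues", "ErdsCourse", function(x) x@values)

#' @rdname vqerds-accessors
#' @export
setMethod("perTrialCourses", "ErdsCourse", function(x) {
  if (length(x@perTrial) == 0L) NULL else x@perTrial
})

#' @rdname vqerds-accessors
#' @export
setMethod("neighbors", "Montage", function(x, channel) {
  if (!channel %in% rownames(x@positions))
    stop("unknown channel: ", channel)
  x@adjacency[[channel]]
})

#' @rdname vqerds-accessors
#' @export
setMethod("positions", "Montage", function(x) x@positions)

#' @rdname vqerds-accessors
#' @export
setMethod("codebook", "VQModel", function(x) x@codebook)

#' @rdname vqerds-accessors
#' @export
setMethod("qPrime", "VQModel", function(x) nrow(x@codebook))

#' @rdname vqerds-accessors
#' @export
setMethod("posteriorProbs", "VQModel", function(x) x@posterior)

#' @rdname vqerds-accessors
#' @export
setMethod("priorProbs", "VQModel", function(x) x@prior)

#' @rdname vqerds-accessors
#' @export
setMethod("relevanceWeights", "RelevanceMap", function(x) x@weights)

#' @rdname vqerds-accessors
#' @export
setMethod("channelRanking", "RelevanceMap", function(x) x@ranking)

#' Select a channel subset of a TrialSet
#'
#' @param x a [TrialSet-class].
#' @param channels channel labels to keep (order preserved as given).
#' @return A [TrialSet-class] restricted to \code{channels}.
#' @export
selectChannels <- function(x, channels) {
  stopifnot(is(x, "TrialSet"))
  miss <- setdiff(channels, x@channelNames)
  if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
  idx <- match(channels, x@channelNames)
  TrialSet(x@trials[, idx, , drop = FALSE], x@labels, x@sampleInterval,
           channelNames = channels, cueTime = x@cueTime,
           miWindow = x@miWindow, referenceWindow = x@referenceWindow)
}

#' Subset trials of a TrialSet
#'
#' @param x a [TrialSet-class].
#' @param i trial indices or a logical mask.
#' @return A [TrialSet-class] with the selected trials.
#' @export
subsetTrials <- function(x, i) {
  stopifnot(is(x, "TrialSet"))
  TrialSet(x@trials[i, , , drop = FALSE], x@labels[i], x@sampleInterval,
           channelNames = x@channelNames, cueTime = x@cueTime,
           miWindow = x@miWindow, referenceWindow = x@referenceWindow)
}

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples at %g Hz (%.2f s)\n",
              nChannels(object), nSamples(object), sampleRate(object),
              nSamples(object) * object@sampleInterval))
  cat("channels:", paste(utils::head(object@channelNames, 8), collapse = " "),
      if (nChannels(object) > 8) "..." else "", "\n")
})

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d trials x %d channels x %d samples at %g Hz\n",
              nTrials(object), nChannels(object), nSamples(object),
              sampleRate(object)))
  print(table(labels = object@labels))
  fmtWin <- function(w) if (anyNA(w)) "unset" else sprintf("[%g, %g) s", w[1], w[2])
  cat("MI window:", fmtWin(object@miWindow),
      " reference:", fmtWin(object@referenceWindow), "\n")
})

setMethod("show", "Montage", function(object) {
  nb <- lengths(object@adjacency)
  cat(sprintf("Montage: %d channels, %g mean neighbors\n",
              nrow(object@positions), mean(nb)))
})

setMethod("show", "ErdsCourse", function(object) {
  cat(sprintf("ErdsCourse (%s, %s): %d channels x %d time points [%g, %g] s\n",
              object@mode, object@estimator, nrow(object@values),
              ncol(object@values), min(object@timeAxis), max(object@timeAxis)))
  if (length(object@perTrial) > 0L)
    cat(sprintf("per-trial courses retained for %d trials\n",
                dim(object@perTrial)[1L]))
})

setMethod("show", "VQModel", function(object) {
  cat(sprintf("VQModel: Q' = %d codes of dimension %d (rhoAbs = %.4g, %s distance)\n",
              nrow(object@codebook), ncol(object@codebook), object@rhoAbs,
              if (object@squared) "squared" else "euclidean"))
  cat(sprintf("posterior entropy: %.4f nats (max %.4f)\n",
              -sum(object@posterior * log(pmax(object@posterior, 1e-300))),
              log(nrow(object@codebook))))
})

setMethod("show", "RelevanceMap", function(object) {
  cat("RelevanceMap over", length(object@weights), "channels; top:",
      paste(utils::head(object@ranking, 5), collapse = " "), "\n")
})

setMethod("show", "TuningResult", function(object) {
  cat(sprintf("TuningResult (%s): %d configurations\n",
              object@estimator, nrow(object@grid)))
  cat("best:\n")
  print(object@best, row.names = FALSE)
})

setMethod("show", "ClusterTestResult", function(object) {
  cat(sprintf("ClusterTestResult: %d supra-threshold clusters (|t| > %.3f)\n",
              nrow(object@clusters), object@threshold))
  if (nrow(object@clusters)) print(object@clusters, row.names = FALSE)
})
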