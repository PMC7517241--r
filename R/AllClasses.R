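#' @useDynLib vqerds, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Continuous multichannel EEG recording
#'
#' A single continuous recording: a channels-by-samples matrix (in
#' microvolts) with a fixed sampling interval and unique channel labels.
#' Time is measured in seconds from the start of the recording and all
#' intervals in the package are half-open \code{[t0, t1)}.
#'
#' @slot data channels x samples numeric matrix.
#' @slot sampleInterval sampling interval in seconds (e.g. 0.004 for 250 Hz).
#' @slot channelNames ordered, unique channel labels.
#'
#' @seealso [Recording()], [epochRecording()]
#' @export
setClass("Recording",
  representation(
    data = "matrix",
    sampleInterval = "numeric",
    channelNames = "character"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (length(object@sampleInterval) != 1L || !is.finite(object@sampleInterval) ||
      object@sampleInterval <= 0)
    msg <- c(msg, "sampleInterval must be a single positive number")
  if (nrow(object@data) < 1L) msg <- c(msg, "need at least one channel")
  if (ncol(object@data) < 2L) msg <- c(msg, "need at least two samples")
  if (length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "channelNames length must equal the channel count")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (length(msg)) msg else TRUE
})

#' Labeled epoched motor-imagery EEG trials
#'
#' The central container: an N x channels x samples array of epoched EEG
#' trials with per-trial class labels (left/right hand motor imagery),
#' the sampling interval, and the trial timing metadata: the cue time,
#' the motor-imagery (MI) analysis window and the baseline reference
#' window used by the power ERD/S ratio. Trial time starts at 0 s and
#' windows are half-open \code{[t0, t1)} in seconds.
#'
#' @slot trials N x channels x samples numeric array.
#' @slot labels factor of per-trial class labels.
#' @slot sampleInterval sampling interval in seconds.
#' @slot channelNames ordered, unique channel labels.
#' @slot cueTime cue onset in seconds from trial start (NA if unknown).
#' @slot miWindow length-2 numeric, the MI analysis interval (may be NA).
#' @slot referenceWindow length-2 numeric, baseline interval preceding the
#'   MI window (may be NA; required by [powerErds()]).
#'
#' @seealso [TrialSet()], [generateTrials()], [readTrials()]
#' @export
setClass("TrialSet",
  representation(
    trials = "array",
    labels = "factor",
    sampleInterval = "numeric",
    channelNames = "character",
    cueTime = "numeric",
    miWindow = "numeric",
    referenceWindow = "numeric"
  )
)

setValidity("TrialSet", function(object) {
  msg <- character()
  d <- dim(object@trials)
  if (length(d) != 3L)
    return("trials must be an N x channels x samples array")
  if (d[1L] < 1L) msg <- c(msg, "need at least one trial")
  if (d[3L] < 2L) msg <- c(msg, "need at least two samples per trial")
  if (length(object@labels) != d[1L])
    msg <- c(msg, "labels length must equal the trial count")
  if (length(object@channelNames) != d[2L])
    msg <- c(msg, "channelNames length must equal the channel count")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "channelNames must be unique")
  if (length(object@sampleInterval) != 1L || !is.finite(object@sampleInterval) ||
      object@sampleInterval <= 0)
    msg <- c(msg, "sampleInterval must be a single positive number")
  dur <- d[3L] * object@sampleInterval
  chkWin <- function(w, name) {
    if (length(w) != 2L) return(sprintf("%s must have length 2", name))
    if (all(is.na(w))) return(NULL)
    if (anyNA(w)) return(sprintf("%s must be fully set or fully NA", name))
    if (w[1L] >= w[2L]) return(sprintf("%s must satisfy t0 < t1", name))
    if (w[1L] < 0 || w[2L] > dur + 1e-9)
      return(sprintf("%s must lie inside [0, %g] s", name, dur))
    NULL
  }
  msg <- c(msg, chkWin(object@miWindow, "miWindow"),
           chkWin(object@referenceWindow, "referenceWindow"))
  if (!anyNA(object@miWindow) && !anyNA(object@referenceWindow) &&
      object@referenceWindow[2L] > object@miWindow[1L] + 1e-9)
    msg <- c(msg, "referenceWindow must precede miWindow")
  if (length(msg)) msg else TRUE
})

#' Electrode montage: 2-D positions and neighbor structure
#'
#' Per-channel 2-D positions on the unit head disc and a symmetric
#' adjacency (neighbor lists) used by the surface Laplacian and by the
#' spatial clustering of the permutation test.
#'
#' @slot positions channels x 2 numeric matrix with channel row names.
#' @slot adjacency named list; element i holds the labels of channel i's
#'   neighbors.
#'
#' @seealso [defaultMontage()], [laplacian()]
#' @export
setClass("Montage",
  representation(
    positions = "matrix",
    adjacency = "list"
  )
)

setValidity("Montage", function(object) {
  msg <- character()
  nm <- rownames(object@positions)
  if (is.null(nm) || anyDuplicated(nm))
    return("positions must have unique channel row names")
  if (ncol(object@positions) != 2L)
    msg <- c(msg, "positions must be a channels x 2 matrix")
  if (!identical(sort(names(object@adjacency)), sort(nm)))
    msg <- c(msg, "adjacency must be named by the montage channels")
  for (ch in names(object@adjacency)) {
    nb <- object@adjacency[[ch]]
    if (ch %in% nb) msg <- c(msg, sprintf("channel %s is its own neighbor", ch))
    if (!all(nb %in% nm))
      msg <- c(msg, sprintf("channel %s has unknown neighbors", ch))
    for (x in nb) if (!(ch %in% object@adjacency[[x]])) {
      msg <- c(msg, sprintf("adjacency not symmetric for %s - %s", ch, x))
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' Band-pass filter description
#'
#' @slot band length-2 numeric, pass band in Hz.
#' @slot order filter order (Butterworth design order; the zero-phase
#'   forward-backward application doubles the effective order).
#' @slot kind filter family; only \code{"bandpass-butterworth"}.
#' @seealso [filterSpec()], [bandpass()]
#' @export
setClass("FilterSpec",
  representation(band = "numeric", order = "integer", kind = "character")
)

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (length(object@band) != 2L || anyNA(object@band) ||
      object@band[1L] <= 0 || object@band[1L] >= object@band[2L])
    msg <- c(msg, "band must satisfy 0 < low < high")
  if (object@order < 1L) msg <- c(msg, "order must be >= 1")
  if (!identical(object@kind, "bandpass-butterworth"))
    msg <- c(msg, "kind must be 'bandpass-butterworth'")
  if (length(msg)) msg else TRUE
})

#' Entropy estimator parameters
#'
#' @slot m embedding dimension M (>= 1).
#' @slot rho tolerance as a multiple of the signal standard deviation.
#' @slot estimator one of \code{"sampen"}, \code{"fuzzyen"}, \code{"vqent"}.
#' @seealso [entropyParams()]
#' @export
setClass("EntropyParams",
  representation(m = "integer", rho = "numeric", estimator = "character")
)

setValidity("EntropyParams", function(object) {
  msg <- character()
  if (object@m < 1L) msg <- c(msg, "m must be >= 1")
  if (length(object@rho) != 1L || !is.finite(object@rho) || object@rho <= 0)
    msg <- c(msg, "rho must be a single positive number")
  if (!object@estimator %in% c("sampen", "fuzzyen", "vqent"))
    msg <- c(msg, "estimator must be one of sampen, fuzzyen, vqent")
  if (length(msg)) msg else TRUE
})

#' Sliding-window plan
#'
#' Positions of overlapping analysis windows of length tau across a
#' segment, indexed by 1-based start samples and stamped by their center
#' times so power- and entropy-based courses share one time axis.
#'
#' @slot tau window length in seconds.
#' @slot overlap overlap fraction in [0, 1).
#' @slot rate sampling rate in Hz.
#' @slot nSamples samples per window.
#' @slot starts integer vector of 1-based window start samples.
#' @slot centers window-center times in seconds.
#' @seealso [planWindows()]
#' @export
setClass("WindowPlan",
  representation(
    tau = "numeric", overlap = "numeric", rate = "numeric",
    nSamples = "integer", starts = "integer", centers = "numeric"
  )
)

setValidity("WindowPlan", function(object) {
  msg <- character()
  if (length(object@starts) < 1L) msg <- c(msg, "need at least one window")
  if (is.unsorted(object@centers, strictly = TRUE))
    msg <- c(msg, "window centers must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' ERD/S time-course
#'
#' Channel-wise ERD/S trajectories: the relative band-power ratio
#' (\code{mode = "power"}, one value per sample, dimensionless, >= -1)
#' or a sliding-window entropy course (\code{mode = "entropy"}, one
#' value per window, nats). Entropy courses retain the per-trial values
#' (N x channels x windows) used by single-trial classification.
#'
#' @slot values channels x time numeric matrix (trial-averaged course).
#' @slot timeAxis time stamps in seconds (window centers for entropy mode).
#' @slot mode \code{"power"} or \code{"entropy"}.
#' @slot estimator estimator name (entropy mode) or \code{"power"}.
#' @slot channelNames channel labels matching the rows of \code{values}.
#' @slot perTrial N x channels x time array of single-trial courses, or a
#'   zero-length array when not retained.
#' @slot diagnostics list of estimator diagnostics (variance ratio of the
#'   power baseline, NaN-window counts, median codebook size, ...).
#' @seealso [powerErds()], [entropyErds()], [writeCourse()]
#' @export
setClass("ErdsCourse",
  representation(
    values = "matrix",
    timeAxis = "numeric",
    mode = "character",
    estimator = "character",
    channelNames = "character",
    perTrial = "array",
    diagnostics = "list"
  )
)

setValidity("ErdsCourse", function(object) {
  msg <- character()
  if (!object@mode %in% c("power", "entropy"))
    msg <- c(msg, "mode must be 'power' or 'entropy'")
  if (length(object@timeAxis) != ncol(object@values))
    msg <- c(msg, "timeAxis must match the time dimension of values")
  if (length(object@channelNames) != nrow(object@values))
    msg <- c(msg, "channelNames must match the channel dimension of values")
  if (identical(object@mode, "power") &&
      any(object@values < -1 - 1e-9, na.rm = TRUE))
    msg <- c(msg, "power-mode values must be >= -1")
  if (length(object@perTrial) > 0L) {
    d <- dim(object@perTrial)
    if (length(d) != 3L || d[2L] != nrow(object@values) ||
        d[3L] != ncol(object@values))
      msg <- c(msg, "perTrial must be N x channels x time matching values")
  }
  if (length(msg)) msg else TRUE
})

#' Vector-quantized probabilistic model of an embedding
#'
#' Greedy codebook of delay vectors together with the Gaussian-similarity
#' probabilistic model fitted on it: row-stochastic memberships of every
#' input vector to every code, per-code moments, the prior over codes and
#' the Bayes posterior whose Shannon entropy is the VQEnt estimate.
#'
#' @slot codebook Q' x M matrix of admitted code vectors.
#' @slot rhoAbs admission tolerance (compared against the squared
#'   Euclidean distance when \code{squared} is TRUE).
#' @slot squared logical; distance convention used for admission.
#' @slot membership Q x Q' row-stochastic membership matrix.
#' @slot mu Q' x M membership-weighted means.
#' @slot sigma2 Q' membership-weighted scalar variances.
#' @slot prior Q' prior probabilities (sum 1).
#' @slot posterior Q' posterior probabilities (sum 1).
#' @seealso [buildCodebook()], [fitVQModel()], [vqEntropy()]
#' @export
setClass("VQModel",
  representation(
    codebook = "matrix", rhoAbs = "numeric", squared = "logical",
    membership = "matrix", mu = "matrix", sigma2 = "numeric",
    prior = "numeric", posterior = "numeric"
  )
)

setValidity("VQModel", function(object) {
  msg <- character()
  qp <- nrow(object@codebook)
  if (qp < 1L) msg <- c(msg, "codebook must have at least one row")
  if (nrow(object@mu) != qp || length(object@sigma2) != qp ||
      length(object@prior) != qp || length(object@posterior) != qp ||
      ncol(object@membership) != qp)
    msg <- c(msg, "model components must agree with the codebook size")
  if (any(object@sigma2 < 0)) msg <- c(msg, "sigma2 must be >= 0")
  if (abs(sum(object@prior) - 1) > 1e-9)
    msg <- c(msg, "prior must sum to 1")
  if (abs(sum(object@posterior) - 1) > 1e-9)
    msg <- c(msg, "posterior must sum to 1")
  if (nrow(object@membership) > 0L &&
      max(abs(rowSums(object@membership) - 1)) > 1e-9)
    msg <- c(msg, "membership rows must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Per-channel discriminability weights
#'
#' @slot weights named non-negative numeric vector, one per channel.
#' @slot ranking channel labels in decreasing weight order.
#' @seealso [channelRelevance()]
#' @export
setClass("RelevanceMap",
  representation(weights = "numeric", ranking = "character")
)

setValidity("RelevanceMap", function(object) {
  msg <- character()
  if (is.null(names(object@weights)))
    return("weights must be named by channel")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be >= 0")
  if (!setequal(object@ranking, names(object@weights)) ||
      length(object@ranking) != length(object@weights))
    msg <- c(msg, "ranking must be a permutation of the channels")
  if (length(msg)) msg else TRUE
})

#' Trial-similarity matrix between entropy courses
#'
#' Gaussian similarity d(n, n') = exp(-||H_n - H_n'||^2 / sigma2X)
#' between single-trial entropy courses of two estimators on one
#' channel. Entries above the main diagonal compare right-label trials,
#' entries below compare left-label trials; the diagonal is 1.
#'
#' @slot values K x K similarity matrix with entries in (0, 1].
#' @slot sigma2X normalizing variance (trial-set average).
#' @slot methods the two estimator names compared.
#' @slot channel channel label the courses were taken from.
#' @slot convention description of the triangle-label layout.
#' @seealso [trialSimilarity()]
#' @export
setClass("SimilarityMatrix",
  representation(
    values = "matrix", sigma2X = "numeric",
    methods = "character", channel = "character", convention = "character"
  )
)

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (any(v <= 0 | v > 1 + 1e-12)) msg <- c(msg, "values must lie in (0, 1]")
  if (max(abs(diag(v) - 1)) > 1e-12) msg <- c(msg, "diagonal must be 1")
  if (length(msg)) msg else TRUE
})

#' Parameter-grid tuning result
#'
#' @slot grid data.frame with one row per (tau, m, rho) configuration and
#'   columns \code{tau}, \code{m}, \code{rho}, \code{accMean},
#'   \code{accSd}, \code{qPrimeMedian} (NA unless vqent).
#' @slot best single-row data.frame, the argmax configuration.
#' @slot estimator estimator name the grid was run for.
#' @seealso [tuneGrid()]
#' @export
setClass("TuningResult",
  representation(grid = "data.frame", best = "data.frame",
                 estimator = "character")
)

setValidity("TuningResult", function(object) {
  msg <- character()
  if (any(object@grid$accMean < 0 | object@grid$accMean > 100))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (nrow(object@best) == 1L &&
      object@best$accMean < max(object@grid$accMean) - 1e-9)
    msg <- c(msg, "best must attain the maximum accuracy")
  if (length(msg)) msg else TRUE
})

#' Cluster permutation test result
#'
#' @slot clusters data.frame with one row per supra-threshold cluster:
#'   \code{id}, \code{mass} (summed t values), \code{size},
#'   \code{pValue}, plus the channel/time extent.
#' @slot stat channels x windows matrix of two-sample t statistics.
#' @slot threshold the cluster-forming |t| threshold.
#' @slot clusterMap channels x windows integer matrix of cluster ids
#'   (0 = sub-threshold).
#' @slot nullMax permutation null distribution of the maximum |mass|.
#' @seealso [clusterPermutationTest()]
#' @export
setClass("ClusterTestResult",
  representation(
    clusters = "data.frame", stat = "matrix", threshold = "numeric",
    clusterMap = "matrix", nullMax = "numeric"
  )
)
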