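#' @name vqerds-accessors
#' @title Accessors for the package's S4 containers
#' @description Getter generics for the data containers. Slot access via
#'   \code{@} is considered internal; these accessors are the supported
#'   interface.
#' @param x an object of the documented classes.
#' @param object an object of the documented classes.
#' @return The slot value documented for each generic.
NULL

#' @describeIn vqerds-accessors the trial array (N x channels x samples).
#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @describeIn vqerds-accessors the per-trial class labels (factor).
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @describeIn vqerds-accessors sampling interval in seconds.
#' @export
setGeneric("sampleInterval", function(x) standardGeneric("sampleInterval"))

#' @describeIn vqerds-accessors sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @describeIn vqerds-accessors ordered channel labels.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @describeIn vqerds-accessors number of trials.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @describeIn vqerds-accessors number of channels.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @describeIn vqerds-accessors samples per trial.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @describeIn vqerds-accessors trial duration in seconds.
#' @export
setGeneric("trialDuration", function(x) standardGeneric("trialDuration"))

#' @describeIn vqerds-accessors the MI analysis window (seconds).
#' @export
setGeneric("miWindow", function(x) standardGeneric("miWindow"))

#' @describeIn vqerds-accessors the baseline reference window (seconds).
#' @export
setGeneric("referenceWindow", function(x) standardGeneric("referenceWindow"))

#' @describeIn vqerds-accessors time stamps of a course (seconds).
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))

#' @describeIn vqerds-accessors trial-averaged course values
#'   (channels x time).
#' @export
setGeneric("courseValues", function(x) standardGeneric("courseValues"))

#' @describeIn vqerds-accessors single-trial courses
#'   (N x channels x time), if retained.
#' @export
setGeneric("perTrialCourses", function(x) standardGeneric("perTrialCourses"))

#' @describeIn vqerds-accessors neighbor labels of a montage channel.
#' @param channel a channel label.
#' @export
setGeneric("neighbors", function(x, channel) standardGeneric("neighbors"))

#' @describeIn vqerds-accessors channels x 2 electrode positions.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @describeIn vqerds-accessors the admitted code vectors (Q' x M).
#' @export
setGeneric("codebook", function(x) standardGeneric("codebook"))

#' @describeIn vqerds-accessors codebook size Q'.
#' @export
setGeneric("qPrime", function(x) standardGeneric("qPrime"))

#' @describeIn vqerds-accessors posterior over code vectors (sums to 1).
#' @export
setGeneric("posteriorProbs", function(x) standardGeneric("posteriorProbs"))

#' @describeIn vqerds-accessors prior over code vectors (sums to 1).
#' @export
setGeneric("priorProbs", function(x) standardGeneric("priorProbs"))

#' @describeIn vqerds-accessors per-channel relevance weights (named).
#' @export
setGeneric("relevanceWeights", function(x) standardGeneric("relevanceWeights"))

#' @describeIn vqerds-accessors channels in decreasing relevance order.
#' @export
setGeneric("channelRanking", function(x) standardGeneric("channelRanking"))
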