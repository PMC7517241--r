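#' Trial timing schema for epoching
#'
#' Describes where a trial lies relative to its cue event and which
#' analysis windows it carries: by default the standard motor-imagery
#' paradigm timing (7 s trials, cue at 2 s, MI segment from 3.25 s to
#' 6 s, baseline 0.5-1.5 s).
#'
#' @param cueTime cue onset in seconds from trial start.
#' @param trialDuration trial length in seconds.
#' @param miWindow MI segment \code{c(t0, t1)} in trial time.
#' @param referenceWindow baseline interval in trial time.
#' @return A plain list with the four fields.
#' @export
eventSchema <- function(cueTime = 2, trialDuration = 7,
                        miWindow = c(3.25, 6),
                        referenceWindow = c(0.5, 1.5)) {
  stopifnot(trialDuration > 0, cueTime >= 0, cueTime < trialDuration)
  list(cueTime = cueTime, trialDuration = trialDuration,
       miWindow = miWindow, referenceWindow = referenceWindow)
}

#' Cut labeled trials out of a continuous recording
#'
#' Extracts one epoch per labeled cue event. Events whose label is
#' missing, or whose epoch would reach outside the recording, are
#' dropped with a message stating the count.
#'
#' @param recording a [Recording-class].
#' @param eventTimes cue times in seconds from recording start.
#' @param eventLabels per-event class labels; NA marks unlabeled events.
#' @param schema an [eventSchema()] list.
#' @return A [TrialSet-class].
#' @export
epochRecording <- function(recording, eventTimes, eventLabels,
                           schema = eventSchema()) {
  stopifnot(is(recording, "Recording"),
            length(eventTimes) == length(eventLabels))
  dt <- recording@sampleInterval
  nS <- nSamples(recording)
  perTrial <- as.integer(round(schema$trialDuration / dt))
  keep <- logical(length(eventTimes))
  starts <- integer(length(eventTimes))
  for (i in seq_along(eventTimes)) {
    t0 <- eventTimes[i] - schema$cueTime
    s0 <- as.integer(round(t0 / dt)) + 1L
    inside <- s0 >= 1L && (s0 + perTrial - 1L) <= nS
    keep[i] <- inside && !is.na(eventLabels[i])
    starts[i] <- s0
  }
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    message(nDropped, " event(s) dropped (unlabeled or epoch outside recording)")
  if (!any(keep)) stop("no labeled events produce valid epochs")
  idx <- which(keep)
  trials <- array(NA_real_, c(length(idx), nChannels(recording), perTrial))
  for (k in seq_along(idx)) {
    s0 <- starts[idx[k]]
    trials[k, , ] <- recording@data[, s0:(s0 + perTrial - 1L)]
  }
  TrialSet(trials, eventLabels[idx], dt,
           channelNames = recording@channelNames,
           cueTime = schema$cueTime, miWindow = schema$miWindow,
           referenceWindow = schema$referenceWindow)
}

.trialSetToList <- function(x) {
  list(
    type = "TrialSet",
    sampleInterval = x@sampleInterval,
    channelNames = x@channelNames,
    labels = as.character(x@labels),
    labelLevels = levels(x@labels),
    cueTime = x@cueTime,
    miWindow = x@miWindow,
    referenceWindow = x@referenceWindow,
    dim = dim(x@trials),
    trials = as.numeric(x@trials),
    trialsNaN = which(is.nan(x@trials))
  )
}

.trialSetFromList <- function(obj) {
  trials <- array(.restoreNaN(.jsonNum(obj$trials), obj$trialsNaN),
                  dim = as.integer(obj$dim))
  TrialSet(trials,
           factor(obj$labels, levels = obj$labelLevels),
           obj$sampleInterval,
           channelNames = obj$channelNames,
           cueTime = .jsonNum(obj$cueTime),
           miWindow = .jsonNum(obj$miWindow),
           referenceWindow = .jsonNum(obj$referenceWindow))
}

#' Write a TrialSet to the canonical JSON interchange format
#'
#' Arrays are stored flat with their dimensions at full double
#' precision, so the round-trip through [readTrials()] is lossless.
#'
#' @param x a [TrialSet-class].
#' @param path output file path (conventionally \code{.json}).
#' @return \code{path}, invisibly.
#' @export
writeTrials <- function(x, path) {
  stopifnot(is(x, "TrialSet"))
  jsonlite::write_json(.trialSetToList(x), path,
                       auto_unbox = TRUE, digits = I(17), na = "string")
  invisible(path)
}

#' Read epoched EEG trials
#'
#' Reads a [TrialSet-class] from the package's JSON interchange format.
#' A JSON file holding a continuous recording plus cue events
#' (\code{type = "Recording"}) is epoched on the fly through
#' [epochRecording()] using \code{schema}. EDF and GDF are recognized
#' but not bundled: requesting them raises a clear error pointing at a
#' converter.
#'
#' @param path input file.
#' @param format \code{"json"} (default, inferred from the extension),
#'   \code{"edf"} or \code{"gdf"}.
#' @param schema an [eventSchema()] used when the file holds a
#'   continuous recording.
#' @return A [TrialSet-class].
#' @export
readTrials <- function(path, format = c("json", "edf", "gdf"),
                       schema = eventSchema()) {
  format <- if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("edf", "gdf")) ext else "json"
  } else match.arg(format)
  if (format %in% c("edf", "gdf"))
    stop("no ", toupper(format), " reader is installed with this package; ",
         "convert the recording to the JSON interchange format ",
         "(e.g. with MNE-Python) and re-run")
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "TrialSet")) {
    .trialSetFromList(obj)
  } else if (identical(obj$type, "Recording")) {
    data <- matrix(as.numeric(obj$data), nrow = as.integer(obj$dim[1L]))
    rec <- Recording(data, obj$sampleInterval, obj$channelNames)
    lab <- obj$events$labels
    lab[lab %in% c("NA", "")] <- NA
    epochRecording(rec, as.numeric(obj$events$times), lab, schema = schema)
  } else {
    stop("unrecognized file content: expected a TrialSet or Recording object")
  }
}

#' Write a continuous recording with events to JSON
#'
#' @param recording a [Recording-class].
#' @param eventTimes,eventLabels cue events (times in seconds).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(recording, eventTimes, eventLabels, path) {
  stopifnot(is(recording, "Recording"))
  obj <- list(
    type = "Recording",
    sampleInterval = recording@sampleInterval,
    channelNames = recording@channelNames,
    dim = dim(recording@data),
    data = as.numeric(recording@data),
    events = list(times = as.numeric(eventTimes),
                  labels = as.character(eventLabels))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "string")
  invisible(path)
}

#' Export an ERD/S course
#'
#' \code{format = "csv"} writes the long table
#' (\code{channel, window_center_s, value}) of the trial-averaged
#' course; \code{format = "json"} serializes the full object (including
#' per-trial courses) at full precision so that [readCourse()] restores
#' it losslessly.
#'
#' @param course an [ErdsCourse-class].
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
writeCourse <- function(course, path, format = c("csv", "json")) {
  stopifnot(is(course, "ErdsCourse"))
  format <- match.arg(format)
  if (nrow(course@values) == 0L || ncol(course@values) == 0L)
    stop("refusing to write an empty course")
  if (format == "csv") {
    df <- data.frame(
      channel = rep(course@channelNames, times = ncol(course@values)),
      window_center_s = rep(course@timeAxis, each = nrow(course@values)),
      value = as.numeric(course@values)
    )
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    obj <- list(
      type = "ErdsCourse", mode = course@mode, estimator = course@estimator,
      channelNames = course@channelNames, timeAxis = course@timeAxis,
      dim = dim(course@values), values = as.numeric(course@values),
      valuesNaN = which(is.nan(course@values)),
      perTrialDim = if (length(course@perTrial)) dim(course@perTrial) else integer(),
      perTrial = if (length(course@perTrial)) as.numeric(course@perTrial) else numeric(),
      perTrialNaN = which(is.nan(course@perTrial))
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         na = "string")
  }
  invisible(path)
}

#' Read an ERD/S course written by [writeCourse()] in JSON format
#'
#' @param path input file.
#' @return An [ErdsCourse-class].
#' @export
readCourse <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "ErdsCourse"))
    stop("not an ErdsCourse file: ", path)
  vals <- matrix(.restoreNaN(.jsonNum(obj$values), obj$valuesNaN),
                 nrow = as.integer(obj$dim[1L]))
  pt <- if (length(obj$perTrialDim))
    array(.restoreNaN(.jsonNum(obj$perTrial), obj$perTrialNaN),
          dim = as.integer(obj$perTrialDim))
  else array(numeric(), c(0L, 0L, 0L))
  new("ErdsCourse", values = vals, timeAxis = as.numeric(obj$timeAxis),
      mode = obj$mode, estimator = obj$estimator,
      channelNames = obj$channelNames, perTrial = pt, diagnostics = list())
}

# JSON NaN round-trip: numbers serialized with na = "string" come back
# as the string "NA"/"NaN"
.jsonNum <- function(x) {
  x[x %in% c("NA", "NaN")] <- NA
  as.numeric(x)
}

# jsonlite collapses NaN and NA on write; NaN positions are stored
# alongside so the round-trip restores them exactly
.restoreNaN <- function(v, idx) {
  if (length(idx)) v[as.integer(idx)] <- NaN
  v
}
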