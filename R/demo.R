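#' Default run configuration
#'
#' All settings of the standard workflow with their defaults: 4-40 Hz
#' order-5 band-pass, MI analysis interval \[2.5, 4.5) s, baseline
#' \[0.5, 1.5) s, tau = 1 s windows at 90 percent overlap, the
#' (tau, M, rho) tuning grids, and the generator settings of the
#' synthetic demo. Any field can be overridden from a YAML file via
#' [readRunConfig()].
#'
#' @return A named list of settings.
#' @export
runConfig <- function() {
  list(
    band = c(4, 40),
    filterOrder = 5L,
    miWindow = c(2.5, 4.5),
    referenceWindow = c(0.5, 1.5),
    tau = 1,
    overlap = 0.9,
    estimator = "vqent",
    m = 2L,
    rho = 0.3,
    taus = c(1, 1.5, 2),
    ms = 1:3,
    rhos = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9),
    folds = 10L,
    seed = 1L,
    nPermutations = 500L,
    alphaCluster = 0.02,
    synth = list(nTrialsPerClass = 30L, nChannels = 22L,
                 erdDepth = 0.6, snr = 2, mixingStrength = 0)
  )
}

#' Read a YAML run configuration
#'
#' Fields present in the file override the [runConfig()] defaults;
#' unknown fields raise an error so typos do not pass silently.
#'
#' @param path YAML file path.
#' @return A named list of settings.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- runConfig()
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (nm == "synth") {
      bad <- setdiff(names(user$synth), names(cfg$synth))
      if (length(bad))
        stop("unknown synth field(s): ", paste(bad, collapse = ", "))
      cfg$synth[names(user$synth)] <- user$synth
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}

.demoPlot <- function(path, expr) {
  ok <- tryCatch({
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr()
    TRUE
  }, error = function(e) {
    message("plot skipped (", conditionMessage(e), ")")
    FALSE
  })
  invisible(ok)
}

#' One-command synthetic demonstration run
#'
#' Chains the full workflow on generated data: simulate, band-pass,
#' ERD/S courses (power ratio and the three entropy estimators on the
#' C3/C4 analogues), channel relevance, incremental channel accuracy
#' and the cluster permutation test. Results are written to
#' \code{outDir} as CSV/JSON plus PNG figures (entropy courses,
#' relevance bars, accuracy-vs-channels curve) and a \code{config.yaml}
#' restating the settings and seed, so every run is reproducible.
#'
#' @param config a [runConfig()]-style list.
#' @param outDir output directory (created if needed).
#' @param estimators estimator subset to run.
#' @return Invisibly, a list with the main results (courses, relevance,
#'   accuracy curve, cluster test).
#' @export
runDemo <- function(config = runConfig(), outDir = tempfile("vqerds-demo"),
                    estimators = c("sampen", "fuzzyen", "vqent")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))

  synthArgs <- config$synth
  synthArgs$seed <- NULL
  spec <- do.call(synthSpec, c(synthArgs, list(seed = config$seed)))
  trials <- generateTrials(spec)
  montage <- synthMontage(spec)
  trials <- bandpass(trials, filterSpec(config$band, config$filterOrder))

  pw <- powerErds(trials)
  writeCourse(pw, file.path(outDir, "course-power.csv"))

  mi <- extractWindow(trials, config$miWindow)
  plan <- planWindows(trialDuration(mi), config$tau, config$overlap,
                      sampleRate(mi))
  courses <- list()
  for (est in estimators) {
    course <- suppressMessages(entropyErds(
      mi, plan, entropyParams(config$m, config$rho, est)))
    courses[[est]] <- course
    writeCourse(course, file.path(outDir, sprintf("course-%s.csv", est)))
  }

  ref <- courses[[config$estimator]]
  if (is.null(ref)) ref <- courses[[1L]]
  rel <- channelRelevance(ref, trialLabels(mi))
  utils::write.csv(
    data.frame(channel = names(relevanceWeights(rel)),
               weight = relevanceWeights(rel)),
    file.path(outDir, "relevance.csv"), row.names = FALSE)

  curve <- incrementalChannelAccuracy(ref, trialLabels(mi), rel,
                                      folds = config$folds,
                                      seed = config$seed)
  utils::write.csv(curve, file.path(outDir, "accuracy-vs-channels.csv"),
                   row.names = FALSE)

  perm <- clusterPermutationTest(ref, trialLabels(mi), montage,
                                 nPermutations = config$nPermutations,
                                 alphaCluster = config$alphaCluster,
                                 seed = config$seed)
  jsonlite::write_json(perm@clusters, file.path(outDir, "clusters.json"),
                       dataframe = "rows", digits = NA)

  .demoPlot(file.path(outDir, "courses.png"), function() {
    graphics::par(mfrow = c(length(courses), 1), mar = c(4, 4, 2, 1))
    for (est in names(courses)) {
      v <- courseValues(courses[[est]])
      sel <- match(c("C3", "C4"), channelNames(courses[[est]]))
      graphics::matplot(timeAxis(courses[[est]]), t(v[sel, , drop = FALSE]),
                        type = "l", lty = 1, col = c(3, 2),
                        xlab = "time in MI segment [s]",
                        ylab = "entropy [nats]", main = est)
      graphics::legend("bottomleft", c("C3", "C4"), col = c(3, 2), lty = 1)
    }
  })
  .demoPlot(file.path(outDir, "relevance.png"), function() {
    w <- relevanceWeights(rel)
    graphics::barplot(w[channelRanking(rel)], las = 2,
                      ylab = "relevance", main = "channel relevance")
  })
  .demoPlot(file.path(outDir, "accuracy-vs-channels.png"), function() {
    graphics::plot(curve$k, curve$accMean, type = "b", ylim = c(40, 100),
                   xlab = "channels added (relevance order)",
                   ylab = "LDA accuracy [%]")
    graphics::abline(h = 70, lty = 2)
  })

  invisible(list(power = pw, courses = courses, relevance = rel,
                 accuracyCurve = curve, clusterTest = perm,
                 outDir = outDir))
}
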