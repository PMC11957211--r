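## End-to-end orchestration: one configuration drives cohort acquisition
## (synthetic or from files), phenotyping, lick behavior, the ROI-matched
## reward/punishment ratio analysis, facial difference scores, and
## phenotype decoding, and collects every stage's tables into one report.

#' Full-analysis run configuration
#'
#' A validated configuration list for [runFullAnalysis()]. In `"synthetic"`
#' mode the cohort is generated from `cohort`; in `"files"` mode it is read
#' from a directory written by [writeCohort()]. The stage toggles let a run
#' skip the facial or decoding stages; the analysis constants (epoch pair,
#' alignment event, PC counts, folds) surface here rather than being
#' hard-coded in the stages.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param path Cohort directory (file mode only).
#' @param cohort A [cohortConfig()] (synthetic mode only).
#' @param epochPair The two epochs compared by the neural ratio and facial
#'   stages (default baseline vs the post-stress time point).
#' @param decodeEvent Alignment event for the decoding stage.
#' @param decodeWindow Peri-event window (s) whose bins are decoded.
#' @param k Cluster count for phenotyping, or `"auto"` for elbow selection.
#' @param nPcsDecoder,nFolds,nPerm Decoder settings; `nPerm = 0` skips the
#'   shuffle null.
#' @param varianceFractionNeural,varianceFractionFacial PC-count rules for
#'   the trajectory quantifications.
#' @param doBehavior,doNeural,doFacial,doDecoding Stage toggles.
#' @param seed Integer seed for every stochastic stage.
#' @return A classed configuration list.
#' @export
runConfig <- function(mode = c("synthetic", "files"), path = NULL,
                      cohort = cohortConfig(),
                      epochPair = c("baseline", postStressEpoch()),
                      decodeEvent = "reward_US", decodeWindow = c(0, 10),
                      k = 3L, nPcsDecoder = 8L, nFolds = 10L, nPerm = 0L,
                      varianceFractionNeural = 0.6,
                      varianceFractionFacial = 0.9,
                      doBehavior = TRUE, doNeural = TRUE, doFacial = TRUE,
                      doDecoding = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "files") {
    if (is.null(path)) stopf("file mode needs a cohort directory path")
    if (!dir.exists(path)) stopf("cohort directory does not exist: %s", path)
  } else {
    stopifnot(is(cohort, "CohortConfig"))
  }
  if (length(epochPair) != 2L)
    stopf("epochPair must name exactly two epochs")
  cfg <- list(mode = mode, path = path, cohort = cohort,
              epochPair = epochPair, decodeEvent = decodeEvent,
              decodeWindow = decodeWindow, k = k,
              nPcsDecoder = as.integer(nPcsDecoder),
              nFolds = as.integer(nFolds), nPerm = as.integer(nPerm),
              varianceFractionNeural = varianceFractionNeural,
              varianceFractionFacial = varianceFractionFacial,
              doBehavior = doBehavior, doNeural = doNeural,
              doFacial = doFacial, doDecoding = doDecoding,
              seed = as.integer(seed))
  class(cfg) <- "vdRunConfig"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields map one-to-one onto [runConfig()] arguments; the nested
#' `cohort:` block maps onto [cohortConfig()] arguments.
#'
#' @param path YAML file path.
#' @return A [runConfig()] object.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cohortArgs <- y$cohort %||% list()
  y$cohort <- NULL
  args <- y
  args$cohort <- do.call(cohortConfig, cohortArgs)
  if (!is.null(args$epochPair)) args$epochPair <- unlist(args$epochPair)
  if (!is.null(args$decodeWindow)) args$decodeWindow <- unlist(args$decodeWindow)
  do.call(runConfig, args)
}

## Stable hash of the configuration, embedded in every output table.
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(config, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

## Uniform session access for the two input modes.
sessionProvider <- function(config, cohort) {
  if (config$mode == "synthetic") {
    list(
      session = function(m, ep, withNeural = TRUE, withKeypoints = TRUE)
        cohortSession(cohort, m, ep, withNeural = withNeural,
                      withKeypoints = withKeypoints),
      roiMatch = function(a, b) cohortRoiMatch(cohort, a, b),
      mice = cohortMice(cohort), behavior = cohortBehavior(cohort))
  } else {
    dir <- config$path
    mice <- as.data.frame(fread(file.path(dir, "mice.tsv"), sep = "\t"))
    behavior <- as.data.frame(fread(file.path(dir, "behavior.tsv"), sep = "\t"))
    matchPath <- file.path(dir, "roi_match.tsv")
    match <- if (file.exists(matchPath))
      as.data.frame(fread(matchPath, sep = "\t")) else NULL
    list(
      session = function(m, ep, withNeural = TRUE, withKeypoints = TRUE) {
        s <- readCohortSession(dir, m, ep)
        if (!withNeural) s$neural <- NULL
        if (!withKeypoints) s$keypoints <- NULL
        s
      },
      roiMatch = function(a, b) {
        if (is.null(match)) stopf("missing roi_match.tsv in %s", dir)
        sel <- match[(match$epoch_a == a & match$epoch_b == b), , drop = FALSE]
        rev <- match[(match$epoch_a == b & match$epoch_b == a), , drop = FALSE]
        if (nrow(rev)) {
          names(rev)[match(c("epoch_a", "roi_a", "epoch_b", "roi_b"),
                           names(rev))] <- c("epoch_b", "roi_b", "epoch_a",
                                             "roi_a")
          sel <- rbind(sel, rev[names(sel)])
        }
        if (!nrow(sel)) stopf("no ROI matches for epoch pair %s / %s", a, b)
        sel
      },
      mice = mice, behavior = behavior)
  }
}

logLine <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition, sucrose-preference phenotyping
#' (k-means + elbow), lick-behavior summaries (anticipatory/consummatory
#' window probabilities and their Pearson correlation with sucrose
#' preference at the post-stress time point), the ROI-matched
#' reward/punishment trajectory-length ratio across the configured epoch
#' pair, facial difference scores at both epochs, and pairwise phenotype
#' decoding at the first epoch of the pair. Deterministic given the
#' configured seeds; every output table carries the configuration hash.
#'
#' Mandatory-stage failures abort with the stage name; the facial and
#' decoding stages run only when toggled on.
#'
#' @param config A [runConfig()].
#' @param outDir Optional directory; when given, every report table is also
#'   written there as TSV.
#' @return A list of stage results: `phenotype`, `behavior`, `neuralRatio`,
#'   `facial`, `decoding`, plus `configHash` and a timestamped `log`.
#' @export
runFullAnalysis <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "vdRunConfig"))
  hash <- configHash(config)
  log <- sprintf("run start (config %s)", hash)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    log <<- logLine(log, "stage %-10s %6.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  cohort <- stage("cohort", {
    if (config$mode == "synthetic") generateCohort(config$cohort) else NULL
  })
  prov <- sessionProvider(config, cohort)
  epochs <- config$epochPair

  phenotype <- stage("phenotype", {
    phenotypeFromBehavior(prov$behavior, prov$mice, epoch = epochs[2],
                          k = config$k, seed = config$seed)
  })
  ptab <- assignmentTable(phenotype)
  labels <- stats::setNames(ptab$label, ptab$mouse_id)

  ## downstream stages use control / resilient / susceptible mice only
  useMice <- ptab$mouse_id[ptab$label %in% c("control", "resilient",
                                             "susceptible")]

  behaviorTab <- NULL
  if (config$doBehavior) behaviorTab <- stage("behavior", {
    rows <- lapply(useMice, function(m) {
      s <- prov$session(m, epochs[2], withNeural = FALSE,
                        withKeypoints = FALSE)
      spt <- prov$behavior$spt_percent[prov$behavior$mouse_id == m &
                                         prov$behavior$epoch == epochs[2]]
      data.frame(mouse_id = m, label = unname(labels[m]),
                 anticipatory = windowLickProbability(s$licks, s$trials,
                                                      c(0, 2), "reward"),
                 consummatory = windowLickProbability(s$licks, s$trials,
                                                      c(2, 5), "reward"),
                 spt_percent = spt[1], stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    corr <- tryCatch(pearsonCorrelation(tab$anticipatory, tab$spt_percent),
                     error = function(e) list(r = NA_real_, p = NA_real_))
    attr(tab, "spt_correlation") <- corr
    tab
  })

  neuralRatio <- NULL
  if (config$doNeural) neuralRatio <- stage("neural", {
    sess <- lapply(epochs, function(ep)
      lapply(stats::setNames(useMice, useMice), function(m)
        prov$session(m, ep, withKeypoints = FALSE)))
    tab <- rewardPunishmentRatio(
      sessionsA = lapply(sess[[1]], `[[`, "neural"),
      sessionsB = lapply(sess[[2]], `[[`, "neural"),
      trialsA = lapply(sess[[1]], `[[`, "trials"),
      trialsB = lapply(sess[[2]], `[[`, "trials"),
      roiMatch = prov$roiMatch(epochs[1], epochs[2]),
      varianceFraction = config$varianceFractionNeural)
    tab$label <- unname(labels[tab$mouse_id])
    tab
  })

  facialTab <- NULL
  if (config$doFacial) facialTab <- stage("facial", {
    do.call(rbind, lapply(epochs, function(ep) {
      sess <- lapply(stats::setNames(useMice, useMice), function(m)
        prov$session(m, ep, withNeural = FALSE))
      feats <- lapply(sess, function(s) {
        tr <- calibrateTrack(smoothTrack(s$keypoints), 100, 1)
        extractFacialFeatures(tr)
      })
      tab <- facialDifferenceScore(feats, lapply(sess, `[[`, "trials"),
                                   varianceFraction =
                                     config$varianceFractionFacial)
      tab$epoch <- ep
      tab$label <- unname(labels[tab$subject])
      tab
    }))
  })

  decoding <- NULL
  if (config$doDecoding) decoding <- stage("decoding", {
    sess <- lapply(stats::setNames(useMice, useMice), function(m)
      prov$session(m, epochs[1], withKeypoints = FALSE))
    feat <- neuralTrialFeatures(
      sessions = lapply(sess, `[[`, "neural"),
      trialsList = lapply(sess, `[[`, "trials"),
      labels = labels[useMice], event = config$decodeEvent,
      licksList = lapply(sess, `[[`, "licks"),
      nPcs = config$nPcsDecoder, window = c(-10, 10),
      featureWindow = config$decodeWindow)
    comparisons <- list(c("susceptible", "control"),
                        c("resilient", "control"),
                        c("resilient", "susceptible"))
    res <- lapply(comparisons, function(cmp) {
      keep <- feat$labels %in% cmp
      r <- decodeTimecourse(feat$features[keep, , , drop = FALSE],
                            feat$labels[keep], nPcs = config$nPcsDecoder,
                            nFolds = config$nFolds,
                            seed = deriveSeed(config$seed, "decode", cmp[1]),
                            comparison = paste(cmp, collapse = "-vs-"),
                            binTimes = feat$binTimes)
      if (config$nPerm > 0L) {
        r@shuffleAucPerBin <- shuffleNull(
          feat$features[keep, , , drop = FALSE], feat$labels[keep],
          nPerm = config$nPerm, nPcs = config$nPcsDecoder,
          nFolds = config$nFolds,
          seed = deriveSeed(config$seed, "null", cmp[1]))
      }
      r
    })
    names(res) <- vapply(comparisons, paste, "", collapse = "-vs-")
    res
  })

  report <- list(phenotype = phenotype, behavior = behaviorTab,
                 neuralRatio = neuralRatio, facial = facialTab,
                 decoding = decoding, configHash = hash, log = log)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    put <- function(tab, name) {
      if (is.null(tab)) return()
      tab$config_hash <- hash
      fwrite(tab, file.path(outDir, paste0(name, ".tsv")), sep = "\t")
    }
    put(assignmentTable(phenotype), "phenotype")
    put(behaviorTab, "behavior")
    put(neuralRatio, "neural_ratio")
    put(facialTab, "facial_difference_score")
    if (!is.null(decoding)) {
      dtab <- do.call(rbind, lapply(decoding, function(r)
        data.frame(comparison = r@comparison, bin_time = r@binTimes,
                   mean_auc = meanAuc(r),
                   null_mean = if (ncol(r@shuffleAucPerBin))
                     rowMeans(r@shuffleAucPerBin) else NA_real_)))
      put(dtab, "decoding")
    }
    writeLines(log, file.path(outDir, "run.log"))
  }
  report
}
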