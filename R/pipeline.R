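#' Pipeline run configuration
#'
#' One configuration object for an end-to-end run: either paths to input CSVs
#' (counts + metadata, or spikes + metadata, optionally eye traces) or a
#' synthetic-population config; the area counting window; and every
#' analysis threshold with its conventional default (GOF retention p 0.10,
#' separation BF 3, confident winning probability 0.67, population-matrix
#' selection 0.5, outlier exclusion 3 SD, 10000 shuffles).
#'
#' @param synthetic a \code{\link{populationConfig}}, or NULL when reading
#'   files.
#' @param countsPath,spikesPath,metaPath,eyePath input CSV paths (used when
#'   \code{synthetic} is NULL; supply either counts or spikes).
#' @param area "V1" or "V4".
#' @param gofThreshold,bfThreshold,winProbThreshold,matrixThreshold,outlierSD,nShuffles
#'   analysis thresholds.
#' @param quad quadrature settings from \code{\link{mixtureQuad}}.
#' @param minTrials minimum presentations per condition (default 5).
#' @param nMC Monte-Carlo GOF simulations (default 2000).
#' @param seed base RNG seed (default 1).
#' @param outdir output directory, or NULL to skip writing.
#' @return config list with a stable hash.
#' @export
pipelineConfig <- function(synthetic = populationConfig(),
                           countsPath = NULL, spikesPath = NULL,
                           metaPath = NULL, eyePath = NULL,
                           area = c("V1", "V4"), gofThreshold = 0.10,
                           bfThreshold = 3, winProbThreshold = 0.67,
                           matrixThreshold = 0.5, outlierSD = 3,
                           nShuffles = 10000, quad = mixtureQuad(),
                           minTrials = 5, nMC = 2000, seed = 1,
                           outdir = NULL) {
  area <- match.arg(area)
  cfg <- list(synthetic = synthetic, countsPath = countsPath,
              spikesPath = spikesPath, metaPath = metaPath,
              eyePath = eyePath, area = area, gofThreshold = gofThreshold,
              bfThreshold = bfThreshold,
              winProbThreshold = winProbThreshold,
              matrixThreshold = matrixThreshold, outlierSD = outlierSD,
              nShuffles = nShuffles, quad = quad, minTrials = minTrials,
              nMC = nMC, seed = seed, outdir = outdir)
  cfg$hash <- configHash(cfg[setdiff(names(cfg), "outdir")])
  cfg
}

.writeStage <- function(df, cfg, name) {
  if (is.null(cfg$outdir)) return(invisible(NULL))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(df, file.path(cfg$outdir, paste0(name, ".csv")),
                   row.names = FALSE)
}

#' Run the full multiplexing analysis pipeline
#'
#' Ingest (or simulate) -> presentation filtering -> triplet assembly ->
#' Poisson/separation screening -> four-hypothesis classification ->
#' pair records and congruence contrasts -> population summary ->
#' trial-wise score matrices with comparator simulations. Every stage's
#' table is written to \code{cfg$outdir} (when set) along with a manifest
#' carrying the config hash and seed; reruns with an identical config are
#' deterministic.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return list with stage outputs: \code{screen}, \code{classification},
#'   \code{pairRecords}, \code{summary}, \code{winnerProportions},
#'   \code{trialMatrix}, \code{comparators}, \code{report}.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(synthetic = populationConfig(nUnits = 8, seed = 2),
#'                       quad = mixtureQuad(nAlpha = 101, nDraws = 2000))
#' res <- runPipeline(cfg)
#' res$report
#' }
#' @export
runPipeline <- function(cfg) {
  stage <- "ingest"
  res <- tryCatch({
    if (!is.null(cfg$synthetic)) {
      ds <- generateTriplets(cfg$synthetic)
      tripletList <- ds@triplets
      truthTab <- ds@truth
    } else {
      if (is.null(cfg$metaPath)) stop("metaPath required for file input")
      sce <- if (!is.null(cfg$countsPath)) {
        readCountTable(cfg$countsPath, cfg$metaPath)
      } else {
        spikes <- readSpikeEvents(cfg$spikesPath)
        meta <- readPresentationMeta(cfg$metaPath)
        countSpikesInWindow(spikes, meta, areaWindow(cfg$area))
      }
      meta <- as.data.frame(SummarizedExperiment::colData(sce))
      traces <- if (!is.null(cfg$eyePath)) readEyeTraces(cfg$eyePath)
      filt <- filterPresentations(meta, traces)
      .writeStage(filt$exclusions, cfg, "exclusions")
      tripletList <- makeTriplets(sce, keep = filt$kept,
                                  minTrials = cfg$minTrials)
      truthTab <- NULL
      ds <- NULL
    }
    if (!length(tripletList)) stop("no triplets to analyze")

    stage <- "screen"
    screenTab <- screenTriplets(tripletList,
                                gofThreshold = cfg$gofThreshold,
                                bfThreshold = cfg$bfThreshold,
                                minTrials = cfg$minTrials, nMC = cfg$nMC,
                                seed = childSeed(cfg$seed, 1))
    screens <- attr(screenTab, "results")
    .writeStage(screenTab, cfg, "screen")
    keep <- which(screenTab$passed)
    if (!length(keep)) stop("no triplet passed the screen")

    stage <- "classify"
    classTab <- classifyTriplets(tripletList[keep], screens[keep],
                                 quad = cfg$quad,
                                 seed = childSeed(cfg$seed, 2))
    classes <- attr(classTab, "results")
    .writeStage(classTab, cfg, "classification")
    scoreTab <- do.call(rbind, lapply(seq_along(keep), function(i) {
      t <- tripletList[[keep[i]]]
      s <- assignmentScores(classes[[i]])
      data.frame(unit_id = unitId(t), condition_key = conditionKey(t),
                 presentation_id = if (length(t@presAB)) t@presAB
                                   else as.character(seq_along(s)),
                 score = s)
    }))
    .writeStage(scoreTab, cfg, "assignment_scores")

    stage <- "correlate"
    records <- pairRecords(tripletList[keep], classes,
                           outlierSD = cfg$outlierSD)
    .writeStage(records, cfg, "pair_records")

    stage <- "summarize"
    summ <- NULL
    if (nrow(records)) {
      summ <- summarizePopulation(records, nShuffles = cfg$nShuffles,
                                  seed = childSeed(cfg$seed, 3))
      .writeStage(summ$medians, cfg, "medians")
      .writeStage(summ$shuffleTests, cfg, "shuffle_tests")
    }
    confident <- classTab$win_prob >= cfg$winProbThreshold
    winnerProp <- if (any(confident))
      prop.table(table(factor(classTab$winner[confident],
                              levels = c("single", "outside",
                                         "intermediate", "mixture"))))
      else NULL
    if (!is.null(winnerProp))
      .writeStage(data.frame(winner = names(winnerProp),
                             proportion = as.numeric(winnerProp),
                             n_confident = sum(confident),
                             threshold = cfg$winProbThreshold),
                  cfg, "winner_proportions")

    stage <- "popview"
    tm <- NULL; comparators <- NULL
    byKey <- split(seq_along(keep),
                   vapply(tripletList[keep], conditionKey, ""))
    for (ckIdx in byKey) {
      m <- buildTrialMatrix(classes[ckIdx],
                            unitIds = vapply(tripletList[keep][ckIdx],
                                             unitId, ""),
                            selectionThreshold = cfg$matrixThreshold)
      if (nrow(scoreMatrix(m)) >= 2) { tm <- m; break }
    }
    if (!is.null(tm)) {
      comparators <- list(
        attentionLocked = simulateAttentionLocked(
          tm, seed = childSeed(cfg$seed, 4)),
        averaging = simulateAveraging(nrow(scoreMatrix(tm)),
                                      ncol(scoreMatrix(tm)),
                                      seed = childSeed(cfg$seed, 5)))
      .writeStage(as.data.frame(scoreMatrix(tm)), cfg, "trial_matrix")
      .writeStage(as.data.frame(scoreMatrix(comparators$attentionLocked)),
                  cfg, "trial_matrix_attention_locked")
      .writeStage(as.data.frame(scoreMatrix(comparators$averaging)),
                  cfg, "trial_matrix_averaging")
    }

    report <- list(
      config_hash = cfg$hash, seed = cfg$seed,
      n_triplets = length(tripletList), n_screened = length(keep),
      screen_pass_rate = length(keep) / length(tripletList),
      winner_proportions = winnerProp,
      win_prob_threshold = cfg$winProbThreshold,
      shuffle_p = if (!is.null(summ)) summ$shuffleTests$p else NULL)
    if (!is.null(cfg$outdir)) {
      manifest <- list(config_hash = cfg$hash, seed = cfg$seed,
                       stages = c("screen", "classification",
                                  "pair_records", "medians",
                                  "shuffle_tests", "winner_proportions",
                                  "trial_matrix"))
      jsonlite::write_json(manifest,
                           file.path(cfg$outdir, "run_manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      jsonlite::write_json(report[c("config_hash", "seed", "n_triplets",
                                    "n_screened", "screen_pass_rate")],
                           file.path(cfg$outdir, "report.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    list(dataset = ds, truth = truthTab, screen = screenTab,
         classification = classTab, classes = classes,
         keptTriplets = tripletList[keep], pairRecords = records,
         summary = summ, winnerProportions = winnerProp, trialMatrix = tm,
         comparators = comparators, report = report)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
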