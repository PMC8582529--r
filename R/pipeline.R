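# End-to-end reproducible pipeline: simulate -> extract -> train ->
# cross-validate -> evaluate, with every artifact written to a run
# directory stamped with the seed and a hash of the configuration.

#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [runPipeline()].
#' The seed is mandatory; every stochastic stage derives from it.
#'
#' @param seed integer seed (mandatory).
#' @param cohort list of [cohortSimParams()] arguments (seed is filled in
#'   from `seed`).
#' @param images list: `enabled` (default TRUE renders one demonstration
#'   sample and extracts its features), plus [simImageParams()] overrides
#'   (defaults here are desk-scale: one 256 px tile).
#' @param pool candidate pool for model training.
#' @param kMax features to select (default [defaultPoolSize()] of pool).
#' @param loocvMode `"fixed"` or `"nested"` (see [loocvPredict()]).
#' @param cutoff risk cutoff for evaluation; `NULL` (default) uses the
#'   trained model's Youden cutoff, or supply e.g. 0.501.
#' @param thresholds [stringThresholds()] arguments.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(seed, cohort = list(), images = list(),
                           pool = "combined", kMax = NULL,
                           loocvMode = "fixed", cutoff = NULL,
                           thresholds = list()) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory in the pipeline configuration")
  structure(list(seed = as.integer(seed), cohort = cohort, images = images,
                 pool = pool, kMax = kMax, loocvMode = loocvMode,
                 cutoff = cutoff, thresholds = thresholds),
            class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file with the same fields.
#' @export
loadPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipelineConfig, cfg)
}

.stage <- function(name, logCon, expr) {
  t0 <- proc.time()[3]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  writeLines(sprintf("stage %-14s ok (%.1fs)", name,
                     proc.time()[3] - t0), logCon)
  res
}

#' Run the full synthetic pipeline into a run directory
#'
#' Executes simulate (cohort, plus an optional demonstration image) ->
#' extract -> train -> cross-validate -> evaluate, writing every artifact
#' to `outDir`: `cohort.csv`, `features.csv`, `model.json`, `scores.csv`
#' (leave-one-out predicted indices and risk calls), a `report/`
#' directory (ROC and Kaplan-Meier points, confusion metrics, stratum
#' summaries, univariate and multivariate Cox tables, `summary.json`)
#' and `run.log`. Re-running with the same configuration reproduces
#' `features.csv` and `model.json` bit-identically.
#'
#' @param config a [pipelineConfig()] (or path to its YAML form).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the run artifacts (`model`, `scores`,
#'   `report`, paths).
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- loadPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  reportDir <- file.path(outDir, "report")
  dir.create(reportDir, showWarnings = FALSE)
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(unclass(config), cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  writeLines(sprintf("fibroIndex pipeline run: seed %d, config %s",
                     config$seed, cfgHash), logCon)

  taxonomy <- featureTaxonomy()
  thr <- do.call(stringThresholds, config$thresholds)

  cohort <- .stage("simulate", logCon, {
    args <- config$cohort
    args$seed <- config$seed
    generateCohort(do.call(cohortSimParams, args), taxonomy)
  })
  features <- cohortFeatures(cohort)
  records <- cohortRecords(cohort)
  writeFeaturesCSV(features, file.path(outDir, "features.csv"))
  writeCohortCSV(records, file.path(outDir, "cohort.csv"))

  if (!identical(config$images$enabled, FALSE)) {
    .stage("extract", logCon, {
      args <- config$images
      args$enabled <- NULL
      if (is.null(args$tilePx)) args$tilePx <- 256L
      if (is.null(args$nTiles)) args$nTiles <- 1L
      if (is.null(args$fibersPerRegion))
        args$fibersPerRegion <- c(portal = 3L, septal = 2L, fibrillar = 4L)
      if (is.null(args$aggregatePatchCount)) args$aggregatePatchCount <- 1L
      if (is.null(args$fiberLengthRangeUm))
        args$fiberLengthRangeUm <- c(20, 60)
      args$seed <- config$seed + 1L
      dir.create(file.path(outDir, "images"), showWarnings = FALSE)
      s <- generateSample(do.call(simImageParams, args))
      writeSample(s, file.path(outDir, "images", "sample_001.tif"))
      fv <- collagenFeatures(s, taxonomy, thr)
      writeFeaturesCSV(matrix(fv, nrow = 1,
                              dimnames = list("sample_001", names(fv))),
                       file.path(outDir, "images", "image_features.csv"))
    })
  }

  y <- records$early_recurrence
  model <- .stage("train", logCon,
    trainIndexModel(features, y, pool = config$pool, kMax = config$kMax,
                    taxonomy = taxonomy))
  if (!is.null(config$cutoff)) model@cutoff <- config$cutoff
  writeIndexModel(model, file.path(outDir, "model.json"))

  loocv <- .stage("crossvalidate", logCon,
    loocvPredict(features, y, pool = config$pool, kMax = config$kMax,
                 mode = config$loocvMode, taxonomy = taxonomy))
  cutoff <- model@cutoff
  scores <- data.frame(patient_id = records$patient_id,
                       index = as.numeric(loocv),
                       risk = classifyRisk(loocv, riskThreshold(cutoff)))
  utils::write.csv(scores, file.path(outDir, "scores.csv"),
                   row.names = FALSE)

  report <- .stage("evaluate", logCon,
    .evaluateRun(scores$index, model, features, records, cutoff,
                 reportDir, cfgHash, config$seed))
  writeLines("pipeline complete", logCon)
  invisible(list(model = model, scores = scores, report = report,
                 outDir = outDir, configHash = cfgHash))
}

.evaluateRun <- function(index, model, features, records, cutoff,
                         reportDir, cfgHash, seed) {
  y <- records$early_recurrence
  highRisk <- index > cutoff

  roc <- rocAuc(index, y)
  utils::write.csv(data.frame(fpr = roc$fpr, tpr = roc$tpr,
                              threshold = roc$thresholds),
                   file.path(reportDir, "roc_points.csv"),
                   row.names = FALSE)
  trainScores <- scoreIndex(features, model)
  aucTrain <- rocAuc(trainScores, y)$auc

  cm <- confusionMetrics(highRisk, y)
  utils::write.csv(data.frame(metric = c("tp", "fp", "fn", "tn",
                                         "sensitivity_pct",
                                         "specificity_pct", "fpr_pct",
                                         "fnr_pct"),
                              value = c(cm$tp, cm$fp, cm$fn, cm$tn,
                                        round(100 * cm$sensitivity, 1),
                                        round(100 * cm$specificity, 1),
                                        round(100 * cm$fpr, 1),
                                        round(100 * cm$fnr, 1))),
                   file.path(reportDir, "confusion.csv"),
                   row.names = FALSE)

  wt <- wilcoxonRankSum(index[y == 1], index[y == 0])

  km <- kmLogrank(records$df_months, records$recurrence_event,
                  ifelse(highRisk, "high", "low"))
  utils::write.csv(km$curves, file.path(reportDir, "km_points.csv"),
                   row.names = FALSE)

  covs <- data.frame(
    combined_index_high = as.integer(highRisk),
    afp_gt20 = as.integer(records$afp_ng_ml > 20),
    meld_ge10 = as.integer(records$meld >= 10),
    clinical_stage_34 = as.integer(records$clinical_stage %in%
                                     c("III", "IV")),
    vascular_invasion = records$vascular_invasion,
    tumor_gt5cm = as.integer(records$tumor_size_cm > 5),
    cirrhosis = records$cirrhosis)
  usable <- names(covs)[vapply(covs, function(v)
    length(unique(v)) > 1, TRUE)]
  cdat <- cbind(records, covs)
  coxUni <- coxPH(cdat, usable, time = "df_months",
                  event = "recurrence_event", mode = "univariate")
  coxMulti <- coxPH(cdat, usable, time = "df_months",
                    event = "recurrence_event", mode = "multivariate")
  coxOS <- coxPH(cdat, usable, time = "os_months", event = "death_event",
                 mode = "multivariate")
  utils::write.csv(coxUni, file.path(reportDir, "cox_univariate_dfs.csv"),
                   row.names = FALSE)
  utils::write.csv(coxMulti,
                   file.path(reportDir, "cox_multivariate_dfs.csv"),
                   row.names = FALSE)
  utils::write.csv(coxOS, file.path(reportDir, "cox_multivariate_os.csv"),
                   row.names = FALSE)

  strata <- rbind(
    cbind(variable = "combined_index",
          stratumSummary(cbind(records, g = ifelse(highRisk,
                                                   paste0(">", cutoff),
                                                   paste0("<=", cutoff))),
                         "g", "death_event")),
    cbind(variable = "afp",
          stratumSummary(cbind(records,
                               g = ifelse(covs$afp_gt20 == 1, ">20",
                                          "<=20")),
                         "g", "death_event")))
  utils::write.csv(strata, file.path(reportDir, "strata.csv"),
                   row.names = FALSE)

  pc <- pearsonCorr(log(records$afp_ng_ml), index)

  summary <- list(seed = seed, config_hash = cfgHash, n = nrow(records),
                  n_early = sum(y), cutoff = cutoff,
                  auc_loocv = roc$auc, auc_training = aucTrain,
                  sensitivity_pct = round(100 * cm$sensitivity, 1),
                  specificity_pct = round(100 * cm$specificity, 1),
                  wilcoxon_p = wt$p.value,
                  logrank_chisq = km$chisq, logrank_p = km$p.value,
                  afp_log_index_pearson_r = pc$r, afp_pearson_p = pc$p.value)
  jsonlite::write_json(summary, file.path(reportDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  summary
}
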