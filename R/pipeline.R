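#' Configure a full analysis run
#'
#' @param input path to a wide-format study CSV (see [readStudyCsv()]).
#' @param unit measurement unit of the study.
#' @param r2_threshold R-squared validity threshold (default 0.8).
#' @param filter_mode `"complete"`, `"animal_level"` or `"point_level"`.
#' @param severities flag severities acted on by filtering.
#' @param sensitivity optional manual sensitivity level applied to every
#'   group (`"ultra_conservative"`, `"conservative"`, `"moderate"`); `NULL`
#'   selects automatically per group size.
#' @param power_scenarios optional list of `c(n_a, n_b)` vectors for the
#'   resampling power assessment.
#' @param n_subsets subsets per power scenario (default 20).
#' @param target_day optional day to standardize tumor weights to.
#' @param output_dir directory for the exported files.
#' @param seed integer seed driving every random element.
#' @return a list of class `run_config`.
#' @export
runConfig <- function(input, unit = "volume_mm3", r2_threshold = 0.8,
                      filter_mode = c("point_level", "animal_level",
                                      "complete"),
                      severities = c("critical", "high", "medium"),
                      sensitivity = NULL, power_scenarios = NULL,
                      n_subsets = 20, target_day = NULL,
                      output_dir = tempdir(), seed = 1) {
  structure(list(input = input, unit = unit, r2_threshold = r2_threshold,
                 filter_mode = match.arg(filter_mode),
                 severities = severities, sensitivity = sensitivity,
                 power_scenarios = power_scenarios, n_subsets = n_subsets,
                 target_day = target_day, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis workflow
#'
#' Executes the standard pipeline in order: validate and load the study;
#' pre-filter homogeneity assessment; six-criteria outlier detection;
#' filtering per the configured mode; exponential fitting with R-squared
#' filtering; group rate comparison; TGR matrices (per animal and group
#' aggregates) with per-interval statistics and diagonal-only multiplicity
#' corrections; optional resampling power assessment; optional tumor-weight
#' standardization; post-filter homogeneity assessment; export of the
#' enhanced CSV, the TGR CSV and a static HTML report.  Any stage error is
#' re-signalled with the stage name after writing a partial log.
#'
#' @param config a [runConfig()].
#' @return a result bundle (list) with the study, QC tables, fits,
#'   comparisons, matrices, optional power table, predictions, and the
#'   paths of the written files.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$output_dir, "analysis_log.txt")
  logLines <- character()
  note <- function(...) {
    logLines <<- c(logLines, sprintf(...))
    writeLines(logLines, logPath)
  }
  stage <- "validate"
  result <- tryCatch({
    note("stage: validate (%s)", config$input)
    study <- readStudyCsv(config$input, config$unit)

    stage <- "homogeneity_pre"; note("stage: homogeneity_pre")
    homPre <- assessHomogeneity(study, stage = "pre_filter")

    stage <- "outlier_detection"; note("stage: outlier_detection")
    gl <- groupLabels(study)
    sizes <- table(gl)
    profiles <- lapply(as.list(sizes), function(n)
      selectSensitivity(n, level = config$sensitivity))
    names(profiles) <- names(sizes)
    flags <- detectOutliers(study, profiles)
    fdf <- as.data.frame(flags)
    for (k in seq_len(nrow(fdf)))
      note("flag: %s day %s %s [%s] %s", fdf$animal_id[k],
           format(fdf$day[k]), fdf$criterion[k], fdf$severity[k],
           fdf$detail[k])

    stage <- "filter"; note("stage: filter (%s)", config$filter_mode)
    filtered <- applyFilter(study, flags, config$filter_mode,
                            config$severities)
    for (id in setdiff(animalIds(study), animalIds(filtered)))
      note("excluded animal: %s", id)

    stage <- "fit"; note("stage: fit")
    fcfg <- fitConfig(r2_threshold = config$r2_threshold)
    fits <- fitGrowth(filtered, fcfg)

    stage <- "group_stats"; note("stage: group_stats")
    gn <- groupNames(filtered)
    rateComparison <- if (length(gn) >= 2L)
      compareGrowthRates(fits, gn[2L], gn[1L]) else NULL

    stage <- "tgr"; note("stage: tgr")
    matrices <- studyTGRMatrices(filtered)
    glf <- groupLabels(filtered)
    groupMatrices <- lapply(setNames(gn, gn), function(g)
      aggregateTGR(matrices[names(glf)[glf == g]], owner = g))
    intervalStats <- if (length(gn) >= 2L)
      compareAllIntervals(matrices[names(glf)[glf == gn[2L]]],
                          matrices[names(glf)[glf == gn[1L]]]) else NULL

    stage <- "power"; note("stage: power")
    power <- if (!is.null(config$power_scenarios) && length(gn) >= 2L)
      powerScenarios(filtered, config$power_scenarios,
                     n_subsets = config$n_subsets, seed = config$seed,
                     config = fcfg) else NULL

    stage <- "weights"; note("stage: weights")
    predictions <- if (!is.null(config$target_day))
      predictWeights(filtered, fits, config$target_day) else NULL

    stage <- "homogeneity_post"; note("stage: homogeneity_post")
    homPost <- assessHomogeneity(filtered, stage = "post_filter")

    stage <- "export"; note("stage: export")
    enhancedPath <- file.path(config$output_dir, "enhanced_results.csv")
    suppressWarnings(
      writeEnhancedCsv(filtered, fits, flags, predictions, enhancedPath))
    tgrPath <- file.path(config$output_dir, "tgr_matrix.csv")
    writeTgrCsv(matrices, filtered, tgrPath)

    bundle <- list(config = config, study = study, filtered = filtered,
                   homogeneity_pre = homPre, homogeneity_post = homPost,
                   flags = flags, profiles = profiles, fits = fits,
                   rate_comparison = rateComparison, matrices = matrices,
                   group_matrices = groupMatrices,
                   interval_stats = intervalStats, power = power,
                   predictions = predictions,
                   paths = list(enhanced = enhancedPath, tgr = tgrPath))
    stage <- "report"; note("stage: report")
    reportPath <- file.path(config$output_dir, "report.html")
    renderReport(bundle, reportPath)
    bundle$paths$report <- reportPath
    note("done")
    bundle
  }, error = function(e) {
    note("ERROR at stage %s: %s", stage, conditionMessage(e))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}
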