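#' Homogeneity scoring configuration
#'
#' Thresholds for the homogeneity quality score: baseline CV below `epsilon`
#' (percent) is excellent, above `pi` is poor; `s_small` and `s_verysmall`
#' are multiplicative penalties for groups of fewer than 5 and fewer than 3
#' animals.
#'
#' @param epsilon excellent-CV threshold, percent (default 15).
#' @param pi poor-CV threshold, percent (default 30); must exceed `epsilon`.
#' @param s_small factor applied when n < 5 (default 0.9).
#' @param s_verysmall additional factor when n < 3 (default 0.8).
#' @return a list of class `homogeneity_config`.
#' @export
homogeneityConfig <- function(epsilon = 15, pi = 30, s_small = 0.9,
                              s_verysmall = 0.8) {
  stopifnot(epsilon > 0, pi > epsilon,
            s_small > 0, s_small <= 1, s_verysmall > 0, s_verysmall <= 1)
  structure(list(epsilon = epsilon, pi = pi, s_small = s_small,
                 s_verysmall = s_verysmall), class = "homogeneity_config")
}

#' Baseline coefficient of variation of a group
#'
#' Each animal contributes its first recorded (non-missing, non-excluded)
#' measurement; animals whose first recorded value is nonpositive are
#' excluded from the computation.  CV is `100 * sd/mean` (sample SD).
#'
#' @param study a [TumorStudy].
#' @param group group label; `NULL` uses all animals.
#' @return list with `cv` (percent) and `n` (animals contributing).
#' @export
baselineCV <- function(study, group = NULL) {
  ids <- animalIds(study)
  if (!is.null(group)) ids <- ids[groupLabels(study)[ids] == group]
  if (!length(ids)) stop("empty group")
  base <- vapply(ids, function(id) {
    s <- animalSeries(study, id)
    s <- s[!s$excluded, , drop = FALSE]
    if (!nrow(s)) NA_real_ else s$value[1L]
  }, numeric(1))
  base <- base[!is.na(base) & base > 0]
  if (!length(base))
    stop("not computable: no positive baseline values in group")
  cv <- if (length(base) == 1L) 0 else 100 * stats::sd(base) / mean(base)
  list(cv = cv, n = length(base))
}

#' Piecewise base homogeneity score
#'
#' `100` for CV <= epsilon; `95 - (CV - epsilon)` for epsilon < CV <= pi;
#' `max(0, 100 - 2 * (CV - pi))` for CV > pi.  The piecewise form is applied
#' exactly as defined, including its discontinuity at `CV = pi` (the score is
#' 80 at CV = pi but jumps toward 100 just above it); see the package
#' vignette.
#'
#' @param cv baseline coefficient of variation, percent, non-negative.
#' @param config a [homogeneityConfig()].
#' @return score in \[0, 100\].
#' @examples
#' homogeneityBaseScore(10)  # 100
#' homogeneityBaseScore(20)  # 90
#' @export
homogeneityBaseScore <- function(cv, config = homogeneityConfig()) {
  stopifnot(all(cv >= 0))
  ifelse(cv <= config$epsilon, 100,
         ifelse(cv <= config$pi, 95 - (cv - config$epsilon),
                pmax(0, 100 - 2 * (cv - config$pi))))
}

#' Small-sample score factor
#'
#' Product of the two conditional penalties: `s_small` when n < 5 and
#' additionally `s_verysmall` when n < 3.
#'
#' @param n number of animals contributing.
#' @param config a [homogeneityConfig()].
#' @return factor in (0, 1\].
#' @export
sampleSizeFactor <- function(n, config = homogeneityConfig()) {
  stopifnot(all(n >= 1))
  ifelse(n < 5, config$s_small, 1) * ifelse(n < 3, config$s_verysmall, 1)
}

#' Homogeneity assessment of every group
#'
#' Combines [baselineCV()], [homogeneityBaseScore()] and
#' [sampleSizeFactor()]; run once before and once after outlier filtering.
#'
#' @param study a [TumorStudy].
#' @param config a [homogeneityConfig()].
#' @param stage `"pre_filter"` or `"post_filter"`, recorded in the output.
#' @return [S4Vectors::DataFrame] with one row per group: `group`, `cv`,
#'   `n`, `base_score`, `factor`, `score`, `stage`.
#' @export
assessHomogeneity <- function(study, config = homogeneityConfig(),
                              stage = c("pre_filter", "post_filter")) {
  stage <- match.arg(stage)
  rows <- lapply(groupNames(study), function(g) {
    bc <- baselineCV(study, g)
    base <- homogeneityBaseScore(bc$cv, config)
    fac <- sampleSizeFactor(bc$n, config)
    data.frame(group = g, cv = bc$cv, n = bc$n, base_score = base,
               factor = fac, score = base * fac, stage = stage)
  })
  S4Vectors::DataFrame(do.call(rbind, rows))
}

#' Sample-size-adaptive outlier sensitivity
#'
#' Three tiers keyed on group size: ultra-conservative (n < 5; 4.0x IQR
#' fence, growth limit 5000 percent/day, decline limit 90 percent/day,
#' multiple indicators required for an exclusion recommendation),
#' conservative (5 <= n <= 10; 3.0x, 2500, 80) and moderate (n > 10; 2.0x,
#' 1000, 67).  Smaller groups get laxer limits to prevent excessive data
#' exclusion.  An alternative `"qc"` preset with cut points n < 8 / 8-12 /
#' > 12 is provided; the default `"detector"` preset is the one that carries
#' the IQR multipliers.
#'
#' @param n animals in the group.
#' @param preset `"detector"` (default) or `"qc"` tier boundaries.
#' @param level manual override: one of `"ultra_conservative"`,
#'   `"conservative"`, `"moderate"` (ignores `n`).
#' @return a list of class `sensitivity_profile` with fields `level`,
#'   `iqr_multiplier`, `growth_limit_pct_per_day`,
#'   `decline_limit_pct_per_day`, `require_multiple_indicators`.
#' @export
selectSensitivity <- function(n, preset = c("detector", "qc"), level = NULL) {
  preset <- match.arg(preset)
  if (is.null(level)) {
    level <- if (preset == "detector") {
      if (n < 5) "ultra_conservative" else if (n <= 10) "conservative"
      else "moderate"
    } else {
      if (n < 8) "ultra_conservative" else if (n <= 12) "conservative"
      else "moderate"
    }
  }
  level <- match.arg(level, c("ultra_conservative", "conservative",
                              "moderate"))
  p <- switch(level,
    ultra_conservative = list(iqr = 4.0, g = 5000, d = 90, multi = TRUE),
    conservative       = list(iqr = 3.0, g = 2500, d = 80, multi = FALSE),
    moderate           = list(iqr = 2.0, g = 1000, d = 67, multi = FALSE))
  structure(list(level = level, iqr_multiplier = p$iqr,
                 growth_limit_pct_per_day = p$g,
                 decline_limit_pct_per_day = p$d,
                 require_multiple_indicators = p$multi),
            class = "sensitivity_profile")
}

.SEVERITY <- c(IMPOSSIBLE_VALUE = "critical", EXTREME_GROWTH = "critical",
               EXTREME_DECLINE = "critical", INTRA_OUTLIER = "high",
               GROUP_OUTLIER = "medium", LAST_DAY_DROP = "medium")

.flagRow <- function(id, day, criterion, detail) {
  data.frame(animal_id = id, day = day, criterion = criterion,
             severity = unname(.SEVERITY[criterion]), detail = detail)
}

# Theil-Sen median slope/intercept on (t, y)
.theilSen <- function(t, y) {
  n <- length(t)
  sl <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (t[j] != t[i]) sl <- c(sl, (y[j] - y[i]) / (t[j] - t[i]))
  slope <- stats::median(sl)
  list(slope = slope, intercept = stats::median(y - slope * t))
}

#' Six-criteria outlier detection
#'
#' Screens every measurement and animal against six criteria, each with a
#' fixed severity:
#' \describe{
#'   \item{IMPOSSIBLE_VALUE (critical)}{recorded value <= 0.}
#'   \item{EXTREME_GROWTH (critical)}{per-day fold change
#'     \eqn{f = (N_{i+1}/N_i)^{1/\Delta t}} with `100*(f-1)` above the
#'     tier's growth limit.}
#'   \item{EXTREME_DECLINE (critical)}{`100*(1-f)` above the tier's decline
#'     limit.}
#'   \item{INTRA_OUTLIER (high)}{within one animal, residuals of `ln N` from
#'     the animal's Theil-Sen median-slope line outside
#'     median +/- multiplier * IQR.}
#'   \item{GROUP_OUTLIER (medium)}{at a shared day, an animal's `ln N`
#'     outside the group's median +/- multiplier * IQR for that day.}
#'   \item{LAST_DAY_DROP (medium)}{fractional decline over 50 percent/day on
#'     the final interval when no earlier interval declined.}
#' }
#' IQR fences use the linear-interpolation (type 7) quartile convention,
#' with a numerical floor of 1e-8 on the fence half-width so that
#' floating-point residue on noiseless data is never flagged.  Criteria with
#' insufficient data (fewer than 4 values for an IQR fence) are silently
#' skipped for that unit.
#'
#' @param study a [TumorStudy].
#' @param profiles optional named list of [selectSensitivity()] profiles per
#'   group; defaults to automatic selection from each group's size.
#' @param last_day_drop_limit threshold for LAST_DAY_DROP, percent/day
#'   (default 50).
#' @return [S4Vectors::DataFrame] of flags: `animal_id`, `day` (`NA` for a
#'   whole-animal flag), `criterion`, `severity`, `detail`.
#' @export
detectOutliers <- function(study, profiles = NULL, last_day_drop_limit = 50) {
  grp <- groupLabels(study)
  if (is.null(profiles)) {
    sizes <- table(grp)
    profiles <- lapply(as.list(sizes), selectSensitivity)
    names(profiles) <- names(sizes)
  }
  flags <- list()
  add <- function(f) flags[[length(flags) + 1L]] <<- f

  for (id in animalIds(study)) {
    prof <- profiles[[grp[[id]]]]
    s <- animalSeries(study, id)
    s <- s[!s$excluded, , drop = FALSE]
    if (!nrow(s)) next
    bad <- s$value <= 0
    for (k in which(bad))
      add(.flagRow(id, s$day[k], "IMPOSSIBLE_VALUE",
                   sprintf("value %g <= 0", s$value[k])))
    pos <- s[!bad, , drop = FALSE]
    if (nrow(pos) >= 2L) {
      f <- (pos$value[-1L] / pos$value[-nrow(pos)])^(1 / diff(pos$day))
      gpct <- 100 * (f - 1); dpct <- 100 * (1 - f)
      for (k in which(gpct > prof$growth_limit_pct_per_day))
        add(.flagRow(id, pos$day[k + 1L], "EXTREME_GROWTH",
                     sprintf("%.1f %%/day > %g", gpct[k],
                             prof$growth_limit_pct_per_day)))
      for (k in which(dpct > prof$decline_limit_pct_per_day))
        add(.flagRow(id, pos$day[k + 1L], "EXTREME_DECLINE",
                     sprintf("%.1f %%/day decline > %g", dpct[k],
                             prof$decline_limit_pct_per_day)))
      # abrupt final-day drop with no earlier decline
      last <- length(f)
      if (last >= 1L && dpct[last] > last_day_drop_limit &&
          (last == 1L || all(f[-last] >= 1)))
        add(.flagRow(id, pos$day[last + 1L], "LAST_DAY_DROP",
                     sprintf("final-interval decline %.1f %%/day",
                             dpct[last])))
      # within-animal IQR on residuals from the median-slope line
      if (nrow(pos) >= 4L) {
        y <- log(pos$value)
        ts <- .theilSen(pos$day, y)
        res <- y - (ts$intercept + ts$slope * pos$day)
        hw <- max(prof$iqr_multiplier * stats::IQR(res, type = 7), 1e-8)
        med <- stats::median(res)
        lo <- med - hw
        hi <- med + hw
        for (k in which(res < lo | res > hi))
          add(.flagRow(id, pos$day[k], "INTRA_OUTLIER",
                       sprintf("log-residual %.3f outside [%.3f, %.3f]",
                               res[k], lo, hi)))
      }
    }
  }

  # per-day group fences on ln N
  b <- burdenMatrix(study); e <- excludedMatrix(study)
  days <- studyDays(study)
  for (g in groupNames(study)) {
    prof <- profiles[[g]]
    ids <- animalIds(study)[grp == g]
    for (i in seq_along(days)) {
      v <- b[i, ids]; ex <- e[i, ids]
      ok <- !is.na(v) & !ex & v > 0
      if (sum(ok) < 4L) next
      y <- log(v[ok])
      hw <- max(prof$iqr_multiplier * stats::IQR(y, type = 7), 1e-8)
      med <- stats::median(y)
      lo <- med - hw
      hi <- med + hw
      out <- names(y)[y < lo | y > hi]
      for (id in out)
        add(.flagRow(id, days[i], "GROUP_OUTLIER",
                     sprintf("ln value %.3f outside group fence [%.3f, %.3f]",
                             log(v[[id]]), lo, hi)))
    }
  }

  if (!length(flags))
    return(S4Vectors::DataFrame(animal_id = character(), day = numeric(),
                                criterion = character(),
                                severity = character(), detail = character()))
  S4Vectors::DataFrame(do.call(rbind, flags))
}

#' Whole-animal exclusion recommendations
#'
#' An animal is recommended for exclusion when it carries at least one
#' critical flag, or — always sufficient — flags from two or more distinct
#' criteria.  Under profiles that do not require multiple indicators, any
#' flag is sufficient.
#'
#' @param flags a flag table from [detectOutliers()].
#' @param profiles named list of [selectSensitivity()] profiles per group.
#' @param groups named vector mapping animal id to group (from
#'   [groupLabels()]).
#' @return character vector of animal ids recommended for exclusion.
#' @export
recommendExclusions <- function(flags, profiles, groups) {
  flags <- as.data.frame(flags)
  if (!nrow(flags)) return(character())
  out <- character()
  for (id in unique(flags$animal_id)) {
    f <- flags[flags$animal_id == id, ]
    prof <- profiles[[groups[[id]]]]
    hit <- if (isTRUE(prof$require_multiple_indicators)) {
      length(unique(f$criterion)) >= 2L || any(f$severity == "critical")
    } else {
      TRUE
    }
    if (hit) out <- c(out, id)
  }
  out
}

#' Apply a filtering mode to a study
#'
#' Three complementary modes: `complete` returns the study untouched;
#' `animal_level` removes every animal carrying a flag of a selected
#' severity; `point_level` marks flagged measurements as excluded and keeps
#' an animal only while at least 3 valid (present, non-excluded) points
#' remain.  Filtering is non-destructive — points are marked excluded, the
#' loaded values are preserved.
#'
#' @param study a [TumorStudy].
#' @param flags a flag table from [detectOutliers()] on the same study.
#' @param mode `"complete"`, `"animal_level"` or `"point_level"`.
#' @param severities severities acted on (default all three).
#' @return the filtered [TumorStudy].
#' @export
applyFilter <- function(study, flags,
                        mode = c("complete", "animal_level", "point_level"),
                        severities = c("critical", "high", "medium")) {
  mode <- match.arg(mode)
  if (mode == "complete") return(study)
  flags <- as.data.frame(flags)
  flags <- flags[flags$severity %in% severities, , drop = FALSE]
  if (mode == "animal_level") {
    drop <- unique(flags$animal_id)
    keep <- setdiff(animalIds(study), drop)
    if (!length(keep)) stop("filtering removed every animal")
    out <- study[, keep]
    .warnEmptyGroups(study, out)
    return(out)
  }
  # point_level
  e <- excludedMatrix(study)
  days <- studyDays(study)
  for (k in seq_len(nrow(flags))) {
    id <- flags$animal_id[k]
    if (is.na(flags$day[k])) {
      e[, id] <- TRUE          # whole-animal flag excludes every point
    } else {
      e[match(flags$day[k], days), id] <- TRUE
    }
  }
  b <- burdenMatrix(study)
  nValid <- colSums(!is.na(b) & !e)
  keep <- animalIds(study)[nValid >= 3L]
  if (!length(keep)) stop("filtering removed every animal")
  SummarizedExperiment::assay(study, "excluded") <- e
  out <- study[, keep]
  .warnEmptyGroups(study, out)
  out
}

.warnEmptyGroups <- function(before, after) {
  gone <- setdiff(groupNames(before), groupNames(after))
  if (length(gone))
    warning("filtering emptied group(s): ", paste(gone, collapse = ", "))
  invisible(NULL)
}
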