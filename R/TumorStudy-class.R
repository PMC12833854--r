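#' TumorStudy: a longitudinal tumor-burden study
#'
#' `TumorStudy` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' one preclinical study: a `burden` assay (rows = time points, columns =
#' animals; `NA` = measurement absent) and a parallel logical `excluded`
#' assay recording quality-control exclusions.  Column metadata carries the
#' experimental group of each animal plus, when known, the terminal tumor
#' weight (g) and the euthanasia day.  Row metadata carries the study day of
#' each time point.  The measurement unit is declared once per study:
#' caliper volume (mm\eqn{^3}), bioluminescence (photons/s) or weight (g).
#'
#' Values \eqn{\le 0} are retained on load (they are data, later flagged as
#' impossible values by QC) but are never used in log-space computations.
#'
#' @param burden numeric matrix of measurements, time points in rows and
#'   animals in columns; `NA` marks an absent measurement.
#' @param days numeric vector of study days, one per row of `burden`,
#'   strictly increasing.
#' @param groups character vector of group labels, one per animal.
#' @param unit one of `"volume_mm3"`, `"bli_photons_per_s"`, `"weight_g"`.
#' @param animalIds character vector of unique animal identifiers; defaults
#'   to `colnames(burden)`.
#' @param terminalWeights optional numeric vector of terminal tumor weights
#'   (g), `NA` when unknown.
#' @param euthanasiaDays optional numeric vector of euthanasia days, `NA`
#'   when unknown.
#' @param excluded optional logical matrix parallel to `burden`; defaults to
#'   all `FALSE`.
#'
#' @return A `TumorStudy` object.
#'
#' @examples
#' m <- rbind(`0` = c(100, 120), `3` = c(180, 260), `7` = c(410, 700))
#' colnames(m) <- c("M1", "M2")
#' ts <- TumorStudy(m, days = c(0, 3, 7), groups = c("Control", "Treated"),
#'                  unit = "volume_mm3")
#' animalIds(ts)
#' studyDays(ts)
#'
#' @aliases TumorStudy animalIds studyDays studyUnit groupLabels groupNames
#'   burdenMatrix excludedMatrix terminalWeights euthanasiaDays
#' @name TumorStudy-class
#' @export
setClass("TumorStudy", contains = "SummarizedExperiment")

.STUDY_UNITS <- c("volume_mm3", "bli_photons_per_s", "weight_g")

setValidity("TumorStudy", function(object) {
  msg <- character()
  if (!all(c("burden", "excluded") %in% names(assays(object))))
    msg <- c(msg, "assays 'burden' and 'excluded' are required")
  if (ncol(object) < 1L)
    msg <- c(msg, "a study needs at least one animal")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "animal ids must be unique within a study")
  if (!"Group" %in% names(colData(object)))
    msg <- c(msg, "colData must carry a 'Group' column")
  d <- rowData(object)$Day
  if (is.null(d) || !is.numeric(d) || any(!is.finite(d)))
    msg <- c(msg, "rowData must carry finite numeric 'Day'")
  else if (any(diff(d) <= 0))
    msg <- c(msg, "study days must be strictly increasing")
  u <- metadata(object)$unit
  if (is.null(u) || !u %in% .STUDY_UNITS)
    msg <- c(msg, sprintf("unit must be one of: %s",
                          paste(.STUDY_UNITS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @rdname TumorStudy-class
#' @export
TumorStudy <- function(burden, days, groups, unit,
                       animalIds = colnames(burden),
                       terminalWeights = NULL, euthanasiaDays = NULL,
                       excluded = NULL) {
  burden <- as.matrix(burden)
  if (is.null(animalIds))
    animalIds <- paste0("A", seq_len(ncol(burden)))
  if (is.null(excluded))
    excluded <- matrix(FALSE, nrow(burden), ncol(burden))
  if (is.null(terminalWeights))
    terminalWeights <- rep(NA_real_, ncol(burden))
  if (is.null(euthanasiaDays))
    euthanasiaDays <- rep(NA_real_, ncol(burden))
  unit <- match.arg(unit, .STUDY_UNITS)
  dimnames(burden) <- list(as.character(days), animalIds)
  dimnames(excluded) <- dimnames(burden)
  se <- SummarizedExperiment(
    assays  = list(burden = burden, excluded = excluded),
    rowData = S4Vectors::DataFrame(Day = as.numeric(days)),
    colData = S4Vectors::DataFrame(
      Group = as.character(groups),
      TumorWeight = as.numeric(terminalWeights),
      EuthanasiaDay = as.numeric(euthanasiaDays),
      row.names = animalIds),
    metadata = list(unit = unit))
  new("TumorStudy", se)
}

#' @rdname TumorStudy-class
setMethod("animalIds", "TumorStudy", function(x) colnames(x))

#' @rdname TumorStudy-class
setMethod("studyDays", "TumorStudy", function(x) rowData(x)$Day)

#' @rdname TumorStudy-class
setMethod("studyUnit", "TumorStudy", function(x) metadata(x)$unit)

#' @rdname TumorStudy-class
setMethod("groupLabels", "TumorStudy", function(x) {
  setNames(colData(x)$Group, colnames(x))
})

#' @rdname TumorStudy-class
setMethod("groupNames", "TumorStudy", function(x) unique(colData(x)$Group))

#' @rdname TumorStudy-class
setMethod("burdenMatrix", "TumorStudy", function(x) assay(x, "burden"))

#' @rdname TumorStudy-class
setMethod("excludedMatrix", "TumorStudy", function(x) assay(x, "excluded"))

#' @rdname TumorStudy-class
setMethod("terminalWeights", "TumorStudy", function(x) {
  setNames(colData(x)$TumorWeight, colnames(x))
})

#' @rdname TumorStudy-class
setMethod("euthanasiaDays", "TumorStudy", function(x) {
  setNames(colData(x)$EuthanasiaDay, colnames(x))
})

setMethod("show", "TumorStudy", function(object) {
  cat(sprintf("TumorStudy: %d animals x %d time points [%s]\n",
              ncol(object), nrow(object), studyUnit(object)))
  grp <- table(colData(object)$Group)
  cat("  groups:",
      paste(sprintf("%s (n=%d)", names(grp), as.integer(grp)), collapse = ", "),
      "\n")
  cat("  days:", paste(studyDays(object), collapse = ", "), "\n")
  nexcl <- sum(excludedMatrix(object), na.rm = TRUE)
  if (nexcl > 0) cat("  excluded points:", nexcl, "\n")
  invisible(NULL)
})

#' Extract one animal's trajectory
#'
#' Returns the ordered (day, value) series for one animal as a data frame
#' with columns `day`, `value` and `excluded`.  Days where the measurement is
#' absent (`NA`) are dropped.
#'
#' @param study a [TumorStudy].
#' @param animalId an animal identifier present in `study`.
#' @return data frame with columns `day`, `value`, `excluded`.
#' @export
animalSeries <- function(study, animalId) {
  stopifnot(is(study, "TumorStudy"))
  if (!animalId %in% colnames(study))
    stop("unknown animal id: ", animalId)
  v <- burdenMatrix(study)[, animalId]
  e <- excludedMatrix(study)[, animalId]
  keep <- !is.na(v)
  data.frame(day = studyDays(study)[keep], value = unname(v[keep]),
             excluded = unname(e[keep]))
}

# points usable for log-space work: present, positive, not excluded
.usable <- function(study, animalId) {
  s <- animalSeries(study, animalId)
  s[!s$excluded & s$value > 0, c("day", "value")]
}
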