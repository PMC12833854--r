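#' Read a wide-format study CSV
#'
#' Expects a header with `Animal` and `Group` columns, one column per study
#' day and optionally `Tumor_Weight` (terminal weight, g) and
#' `Euthanasia_Day`.  Day columns may be bare numbers (`0`, `3`, `7`) or
#' prefixed (`Day_7`, `D7`).  Empty cells are absent measurements; a literal
#' `0` or negative number is kept as a recorded (impossible) value for QC to
#' flag.
#'
#' @param path path to a CSV file (UTF-8, comma separated, `.` decimal mark).
#' @param unit measurement unit of the study, one of `"volume_mm3"`,
#'   `"bli_photons_per_s"`, `"weight_g"`.
#' @return a [TumorStudy].
#' @export
readStudyCsv <- function(path, unit = c("volume_mm3", "bli_photons_per_s",
                                        "weight_g")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (required in c("Animal", "Group"))
    if (!required %in% names(df))
      stop("format error: required column '", required, "' is missing")
  day <- .parseDayHeader(names(df))
  dayCols <- which(!is.na(day))
  if (!length(dayCols))
    stop("format error: no parseable time-point column in header")
  ord <- dayCols[order(day[dayCols])]
  days <- day[ord]
  if (anyDuplicated(days))
    stop("format error: duplicate day columns: ",
         paste(unique(days[duplicated(days)]), collapse = ", "))
  ids <- as.character(df$Animal)
  if (anyDuplicated(ids))
    stop("validation error: duplicate animal id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  burden <- t(as.matrix(vapply(ord, function(j) as.numeric(df[[j]]),
                               numeric(nrow(df)))))
  if (nrow(df) == 1L) burden <- matrix(burden, ncol = 1L)
  tw <- if ("Tumor_Weight" %in% names(df)) as.numeric(df$Tumor_Weight)
  ed <- if ("Euthanasia_Day" %in% names(df)) as.numeric(df$Euthanasia_Day)
  TumorStudy(burden, days = days, groups = as.character(df$Group),
             unit = unit, animalIds = ids,
             terminalWeights = tw, euthanasiaDays = ed)
}

# header token -> day number, NA when not a day column
.parseDayHeader <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  pref <- grepl("^(Day[_ ]?|D)[0-9]", x, ignore.case = TRUE)
  out[pref] <- suppressWarnings(
    as.numeric(sub("^(Day[_ ]?|D)", "", x[pref], ignore.case = TRUE)))
  out
}

# full-precision decimal text that round-trips doubles; NA -> empty cell
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) == v) s else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write the enhanced per-animal results CSV
#'
#' One row per animal: the original measurement columns followed by the
#' fitted exponential parameters (initial burden `N0` with relative standard
#' error, growth rate `r` with relative standard error, doubling time
#' `ln(2)/r`, log-scale R-squared, validity flag), a summary of QC flags and,
#' when supplied, the standardized predicted tumor weight.  Animals without a
#' fit get empty derived cells and a warning is raised.
#'
#' @param study a [TumorStudy].
#' @param fits per-animal fit table from [fitGrowth()].
#' @param flags optional QC flag table from [detectOutliers()].
#' @param predictions optional named numeric vector of predicted weights (g)
#'   keyed by animal id, as from [predictWeights()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEnhancedCsv <- function(study, fits, flags = NULL, predictions = NULL,
                             path) {
  stopifnot(is(study, "TumorStudy"))
  days <- studyDays(study)
  b <- burdenMatrix(study)
  ids <- animalIds(study)
  fits <- as.data.frame(fits)
  rownames(fits) <- fits$animal_id

  flagSummary <- function(id) {
    if (is.null(flags) || !nrow(flags)) return("")
    f <- as.data.frame(flags)
    f <- f[f$animal_id == id, , drop = FALSE]
    if (!nrow(f)) return("")
    paste(sprintf("%s[%s]", f$criterion, f$severity), collapse = "; ")
  }

  derived <- c("N0", "RSE_N0_pct", "r", "RSE_r_pct", "Doubling_Time",
               "R_squared", "Valid", "N_Points")
  header <- c("Animal", "Group", .fmtNum(days), derived, "Outlier_Flags",
              "Predicted_Weight")
  lines <- vapply(ids, function(id) {
    row <- c(id, groupLabels(study)[[id]], .fmtNum(b[, id]))
    if (id %in% rownames(fits) && !is.na(fits[id, "r"])) {
      fr <- fits[id, ]
      row <- c(row, .fmtNum(c(fr$N0, fr$rse_N0, fr$r, fr$rse_r,
                              fr$doubling_time, fr$r_squared)),
               as.character(fr$valid), .fmtNum(fr$n_points))
    } else {
      warning("no valid fit for animal ", id,
              "; derived fields left empty", call. = FALSE)
      row <- c(row, rep("", length(derived)))
    }
    pw <- if (!is.null(predictions) && id %in% names(predictions))
      .fmtNum(predictions[[id]]) else ""
    paste(c(row, .csvQuote(flagSummary(id)), pw), collapse = ",")
  }, character(1))
  writeLines(c(paste(header, collapse = ","), lines), path, useBytes = TRUE)
  invisible(path)
}

.csvQuote <- function(x) {
  if (grepl("[,\"\n]", x)) paste0('"', gsub('"', '""', x), '"') else x
}

#' Write the TGR matrix CSV
#'
#' One row per animal with columns `Animal_ID`, `Experimental_Group` and one
#' column per ordered day pair `x < y`, named `r_<x>_to_<y>`.  Intervals an
#' animal does not possess are written empty.
#'
#' @param matrices named list of per-animal [TGRMatrix] objects sharing one
#'   day grid (as from [studyTGRMatrices()]).
#' @param study the [TumorStudy] the matrices came from (for group labels).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTgrCsv <- function(matrices, study, path) {
  stopifnot(length(matrices) > 0)
  grids <- lapply(matrices, tgrDays)
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) != 1L)
    stop("validation error: matrices do not share one day grid")
  days <- grids[[1L]]
  n <- length(days)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  cols <- sprintf("r_%s_to_%s", .fmtNum(days[pairs[, "row"]]),
                  .fmtNum(days[pairs[, "col"]]))
  grp <- groupLabels(study)
  lines <- vapply(names(matrices), function(id) {
    r <- tgrRates(matrices[[id]])
    vals <- .fmtNum(r[pairs])
    paste(c(id, grp[[id]], vals), collapse = ",")
  }, character(1))
  writeLines(c(paste(c("Animal_ID", "Experimental_Group", cols),
                     collapse = ","), lines), path, useBytes = TRUE)
  invisible(path)
}
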