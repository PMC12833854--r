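#' TGRMatrix: localized tumor growth rates over all time-point pairs
#'
#' An upper-triangular matrix of localized growth rates
#' \eqn{r_{x \to y} = \ln(N_y/N_x)/(t_y - t_x)} for every ordered pair of
#' study days \eqn{x < y}.  Entries are keyed by day value (dimnames carry
#' the days) so animals measured on a subset of days align.  A matrix is
#' either per-animal or a group aggregate (`aggregated = TRUE`).
#'
#' @slot days numeric, the strictly increasing shared day grid.
#' @slot rates numeric matrix (days x days); only the strict upper triangle
#'   may be non-`NA`.
#' @slot owner animal id or group label.
#' @slot aggregated logical.
#'
#' @aliases TGRMatrix tgrDays tgrRates tgrOwner isAggregated
#' @name TGRMatrix-class
#' @export
setClass("TGRMatrix",
         representation(days = "numeric", rates = "matrix",
                        owner = "character", aggregated = "logical"))

setValidity("TGRMatrix", function(object) {
  msg <- character()
  n <- length(object@days)
  if (any(diff(object@days) <= 0))
    msg <- c(msg, "days must be strictly increasing")
  if (!all(dim(object@rates) == c(n, n)))
    msg <- c(msg, "rates must be a square matrix over the day grid")
  else if (any(!is.na(object@rates[lower.tri(object@rates, diag = TRUE)])))
    msg <- c(msg, "rates defined only for x < y (strict upper triangle)")
  if (length(msg)) msg else TRUE
})

#' @rdname TGRMatrix-class
setMethod("tgrDays", "TGRMatrix", function(x) x@days)

#' @rdname TGRMatrix-class
setMethod("tgrRates", "TGRMatrix", function(x) x@rates)

#' @rdname TGRMatrix-class
setMethod("tgrOwner", "TGRMatrix", function(x) x@owner)

#' @rdname TGRMatrix-class
setMethod("isAggregated", "TGRMatrix", function(x) x@aggregated)

setMethod("show", "TGRMatrix", function(object) {
  n <- length(object@days)
  cat(sprintf("TGRMatrix [%s%s]: %d days, %d/%d intervals present\n",
              object@owner, if (object@aggregated) ", aggregated" else "",
              n, sum(!is.na(object@rates)), intervalCount(n)))
  invisible(NULL)
})

#' Look up one interval's rate
#'
#' @param x a [TGRMatrix].
#' @param x_day,y_day interval endpoints (day values, `x_day < y_day`).
#' @return the rate (day\eqn{^{-1}}) or `NA` when absent.
#' @export
tgrEntry <- function(x, x_day, y_day) {
  i <- match(x_day, x@days); j <- match(y_day, x@days)
  if (is.na(i) || is.na(j)) stop("day not on the matrix grid")
  if (i >= j) stop("interval requires x_day < y_day")
  x@rates[i, j]
}

#' Localized growth rate between two measurements
#'
#' \eqn{r_{x \to y} = \ln(N_y / N_x) / (t_y - t_x)}, the exponential rate
#' that carries burden \eqn{N_x} at day \eqn{t_x} to \eqn{N_y} at day
#' \eqn{t_y}.
#'
#' @param N_x,N_y burdens at the two days, positive.
#' @param t_x,t_y the two days, `t_y > t_x`.
#' @return rate in day\eqn{^{-1}}.
#' @examples
#' tgrRate(100, 200, 0, 2)  # ln(2)/2
#' @export
tgrRate <- function(N_x, N_y, t_x, t_y) {
  if (any(N_x <= 0 | N_y <= 0))
    stop("domain error: burdens must be positive")
  if (any(t_y <= t_x))
    stop("domain error: t_y must exceed t_x")
  log(N_y / N_x) / (t_y - t_x)
}

#' Build one animal's TGR matrix
#'
#' Computes \eqn{r_{x \to y}} for every ordered pair of days at which the
#' animal has a usable (present, positive, non-excluded) measurement; pairs
#' touching an unusable value are absent.  The matrix is laid out on the
#' study's full day grid.
#'
#' @param study a [TumorStudy].
#' @param animalId animal identifier.
#' @return a [TGRMatrix]; empty (all `NA`) with a warning when fewer than
#'   two usable points exist.
#' @export
animalTGRMatrix <- function(study, animalId) {
  days <- studyDays(study)
  n <- length(days)
  rates <- matrix(NA_real_, n, n, dimnames = list(days, days))
  u <- .usable(study, animalId)
  if (nrow(u) < 2L) {
    warning("animal ", animalId, ": fewer than 2 usable points; ",
            "empty TGR matrix")
  } else {
    idx <- match(u$day, days)
    for (a in seq_len(nrow(u) - 1L)) for (b in (a + 1L):nrow(u))
      rates[idx[a], idx[b]] <- tgrRate(u$value[a], u$value[b],
                                       u$day[a], u$day[b])
  }
  new("TGRMatrix", days = days, rates = rates, owner = animalId,
      aggregated = FALSE)
}

#' TGR matrices for every animal in a study
#'
#' @param study a [TumorStudy].
#' @return named list of [TGRMatrix] objects keyed by animal id.
#' @export
studyTGRMatrices <- function(study) {
  ids <- animalIds(study)
  setNames(lapply(ids, function(id) animalTGRMatrix(study, id)), ids)
}

#' Aggregate per-animal TGR matrices for display
#'
#' Entrywise mean (default, "group-averaged") or median over the animals
#' possessing each interval; an entry is absent when no animal has it.
#' Aggregates are for visualization — statistics always use per-animal
#' values.
#'
#' @param matrices list of per-animal [TGRMatrix] objects on one day grid.
#' @param method `"mean"` or `"median"`.
#' @param owner label for the aggregate (e.g. the group name).
#' @return a [TGRMatrix] with `aggregated = TRUE`.
#' @export
aggregateTGR <- function(matrices, method = c("mean", "median"),
                         owner = "group") {
  method <- match.arg(method)
  if (!length(matrices)) stop("no matrices to aggregate")
  grids <- lapply(matrices, tgrDays)
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) != 1L)
    stop("matrices do not share one day grid")
  arr <- simplify2array(lapply(matrices, tgrRates))
  f <- if (method == "mean") mean else stats::median
  agg <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE))
  dimnames(agg) <- dimnames(tgrRates(matrices[[1L]]))
  new("TGRMatrix", days = grids[[1L]], rates = agg, owner = owner,
      aggregated = TRUE)
}

.RATE_CLASSES <- c("high", "medium", "low", "very_low", "minimal")

#' Classify a growth rate into display bins
#'
#' Five bins: high (r > 0.25), medium (0.15 <= r <= 0.25), low
#' (0.10 <= r < 0.15), very low (0.05 <= r < 0.10) and minimal
#' (r < 0.05, including zero and negative rates).  Lower bounds are
#' inclusive; `high` is strictly above 0.25.
#'
#' @param r rate(s), day\eqn{^{-1}}, finite.
#' @return factor with levels `high`, `medium`, `low`, `very_low`,
#'   `minimal`.
#' @examples
#' classifyRate(c(0.30, 0.25, 0.12, -0.05))
#' @export
classifyRate <- function(r) {
  stopifnot(all(is.finite(r)))
  lab <- ifelse(r > 0.25, "high",
         ifelse(r >= 0.15, "medium",
         ifelse(r >= 0.10, "low",
         ifelse(r >= 0.05, "very_low", "minimal"))))
  factor(lab, levels = .RATE_CLASSES)
}

#' Number of pairwise intervals for n time points
#'
#' `n * (n - 1) / 2` ordered day pairs.
#'
#' @param n number of time points, non-negative.
#' @return interval count.
#' @examples
#' intervalCount(13)  # 78
#' @export
intervalCount <- function(n) {
  stopifnot(all(n >= 0))
  n * (n - 1) / 2
}
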