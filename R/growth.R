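#' Fitting configuration
#'
#' Settings for exponential growth fitting: the goodness-of-fit threshold
#' used to declare a fit valid, the minimum number of positive measurements
#' required before a fit is attempted, and the scale on which the coefficient
#' of determination is computed.
#'
#' @param r2_threshold R-squared above which a fit counts as valid;
#'   default 0.8, configurable in \[0, 1\].
#' @param min_points minimum positive, non-excluded measurements per animal;
#'   at least 3.
#' @param r2_scale `"log"` (default; the scale the regression is run on) or
#'   `"raw"` (R-squared of the back-transformed curve against raw values).
#' @return a list of class `fit_config`.
#' @export
fitConfig <- function(r2_threshold = 0.8, min_points = 3,
                      r2_scale = c("log", "raw")) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1, min_points >= 3)
  structure(list(r2_threshold = r2_threshold,
                 min_points = as.integer(min_points),
                 r2_scale = match.arg(r2_scale)),
            class = "fit_config")
}

#' Fit the exponential growth model to one trajectory
#'
#' Fits \eqn{N(t) = N_0 e^{rt}} by ordinary least squares on
#' \eqn{(t, \ln N)}: the slope is the growth rate `r` (day\eqn{^{-1}}), the
#' exponentiated intercept is the initial burden `N0`.  Only positive,
#' non-excluded measurements enter the regression.  Standard errors come from
#' the regression; relative standard errors are `100 * se/|estimate|` (for
#' `N0`, `100 * se(ln N0)`, the first-order relative error of a lognormal
#' intercept).  Doubling time is `ln(2)/r`, reported only for `r > 0`;
#' negative rates (regressing tumors) are retained with `doubling_time = NA`.
#'
#' @param day,value numeric vectors of study days and measurements.
#' @param excluded optional logical vector of QC exclusions.
#' @param config a [fitConfig()].
#' @return A one-row data frame with columns `n_points`, `N0`, `se_log_N0`,
#'   `rse_N0`, `r`, `se_r`, `rse_r`, `r_squared`, `doubling_time`, `valid` —
#'   or `NULL` when fewer than `min_points` positive measurements remain
#'   (absence, not an error).
#' @examples
#' fitExponential(c(0, 1, 2), c(100, 200, 400))$r  # ln 2
#' @export
fitExponential <- function(day, value, excluded = NULL,
                           config = fitConfig()) {
  if (is.null(excluded)) excluded <- rep(FALSE, length(value))
  keep <- !is.na(value) & !excluded & value > 0 & is.finite(day)
  t <- day[keep]; y <- log(value[keep])
  n <- length(t)
  if (n < config$min_points) return(NULL)
  if (length(unique(t)) == 1L)
    stop("degenerate design: all measurement days identical")
  fit <- stats::lm(y ~ t)
  # noiseless trajectories are legitimate input; silence lm's perfect-fit note
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- stats::coef(sm)
  r <- co["t", "Estimate"]
  se_r <- co["t", "Std. Error"]
  b0 <- co["(Intercept)", "Estimate"]
  se_b0 <- co["(Intercept)", "Std. Error"]
  r2 <- if (config$r2_scale == "log") {
    sm$r.squared
  } else {
    raw <- exp(y); pred <- exp(stats::fitted(fit))
    1 - sum((raw - pred)^2) / sum((raw - mean(raw))^2)
  }
  data.frame(
    n_points = n,
    N0 = exp(b0),
    se_log_N0 = se_b0,
    rse_N0 = 100 * se_b0,
    r = r,
    se_r = se_r,
    rse_r = if (r != 0) 100 * se_r / abs(r) else NA_real_,
    r_squared = r2,
    doubling_time = if (r > 0) log(2) / r else NA_real_,
    valid = r2 > config$r2_threshold)
}

#' Fit every animal in a study
#'
#' Applies [fitExponential()] per animal.  Animals with too few positive
#' points keep their row with `NA` parameters, `valid = FALSE` and status
#' `"insufficient data"`.
#'
#' @param study a [TumorStudy].
#' @param config a [fitConfig()].
#' @return A [S4Vectors::DataFrame] with one row per animal: `animal_id`,
#'   `group`, then the [fitExponential()] columns plus `status`.
#' @export
fitGrowth <- function(study, config = fitConfig()) {
  stopifnot(is(study, "TumorStudy"))
  grp <- groupLabels(study)
  rows <- lapply(animalIds(study), function(id) {
    s <- animalSeries(study, id)
    f <- fitExponential(s$day, s$value, s$excluded, config)
    if (is.null(f)) {
      f <- data.frame(n_points = sum(!s$excluded & s$value > 0),
                      N0 = NA_real_, se_log_N0 = NA_real_, rse_N0 = NA_real_,
                      r = NA_real_, se_r = NA_real_, rse_r = NA_real_,
                      r_squared = NA_real_, doubling_time = NA_real_,
                      valid = FALSE)
      f$status <- "insufficient data"
    } else {
      f$status <- if (f$valid) "ok" else "low R2"
    }
    cbind(data.frame(animal_id = id, group = grp[[id]]), f)
  })
  S4Vectors::DataFrame(do.call(rbind, rows))
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' \eqn{V = L W^2 / 2} with length `L` >= width `W` (mm); swapped with a
#' warning when given in the wrong order.
#'
#' @param length,width caliper length and width, mm, positive.
#' @return volume in mm\eqn{^3}.
#' @examples
#' ellipsoidVolume(12, 8)  # 384
#' @export
ellipsoidVolume <- function(length, width) {
  if (any(length <= 0 | width <= 0))
    stop("domain error: caliper dimensions must be positive")
  swap <- width > length
  if (any(swap)) {
    warning("length < width; dimensions swapped")
    tmp <- length[swap]; length[swap] <- width[swap]; width[swap] <- tmp
  }
  length * width^2 / 2
}

#' Propagate relative error of a predicted burden through time
#'
#' For \eqn{\ln N = \ln N_0 + r t}, the relative standard error of the
#' predicted burden is \eqn{\sqrt{RSE^2(N_0) + t^2 \cdot (100\,se_r)^2}}:
#' rate uncertainty grows quadratically with time while baseline uncertainty
#' contributes a constant term.
#'
#' @param rse_N0 relative standard error of the initial burden, percent.
#' @param se_r_pct `100 * se(r)`, percent per day.
#' @param t time from baseline, days.
#' @return relative standard error of \eqn{N(t)}, percent.
#' @examples
#' propagateRse(3, 4, 1)  # 5
#' @export
propagateRse <- function(rse_N0, se_r_pct, t) {
  stopifnot(all(rse_N0 >= 0), all(se_r_pct >= 0))
  sqrt(rse_N0^2 + t^2 * se_r_pct^2)
}

#' Predict tumor burden at a day from a fit
#'
#' @param fit a one-row fit (from [fitExponential()] or a [fitGrowth()] row)
#'   with fields `N0` and `r`.
#' @param t day at which to evaluate \eqn{N_0 e^{rt}}.
#' @return predicted burden in the study unit.
#' @export
predictSize <- function(fit, t) {
  if (is.null(fit) || is.na(fit$N0) || is.na(fit$r))
    stop("fit absent; cannot predict")
  fit$N0 * exp(fit$r * t)
}

#' Standardize a terminal tumor weight to a target day
#'
#' Projects a measured terminal weight forward or backward along the
#' animal's fitted exponential:
#' \eqn{w(t^\ast) = w \, e^{r (t^\ast - t_{euth})}}.  This puts animals
#' euthanized on different days (humane endpoints) on one common day so they
#' can enter a single endpoint comparison.
#'
#' @param terminal_weight measured tumor weight at euthanasia, g, positive.
#' @param euthanasia_day day the weight was measured.
#' @param r the animal's fitted growth rate, day\eqn{^{-1}}.
#' @param target_day day to standardize to.
#' @return predicted weight (g) at `target_day`.
#' @export
predictWeight <- function(terminal_weight, euthanasia_day, r, target_day) {
  if (is.na(terminal_weight) || is.na(r) || is.na(euthanasia_day))
    stop("not computable: missing weight, euthanasia day or fit")
  stopifnot(terminal_weight > 0)
  terminal_weight * exp(r * (target_day - euthanasia_day))
}

#' Absolute relative prediction error
#'
#' `100 * |experimental - predicted| / experimental`.
#'
#' @param experimental measured value, positive.
#' @param predicted model-predicted value.
#' @return percent error.
#' @export
predictionError <- function(experimental, predicted) {
  if (any(experimental <= 0))
    stop("domain error: experimental value must be positive")
  100 * abs(experimental - predicted) / experimental
}

#' Standardized weight predictions for a whole study
#'
#' For every animal with a terminal weight, a euthanasia day and a fitted
#' rate, computes the weight standardized to `target_day` via
#' [predictWeight()]; animals missing any ingredient are skipped.
#'
#' @param study a [TumorStudy].
#' @param fits the [fitGrowth()] table.
#' @param target_day common day to standardize to.
#' @param require_valid only use fits passing the R-squared filter
#'   (default `TRUE`).
#' @return named numeric vector of predicted weights (g) keyed by animal id.
#' @export
predictWeights <- function(study, fits, target_day, require_valid = TRUE) {
  fits <- as.data.frame(fits)
  rownames(fits) <- fits$animal_id
  tw <- terminalWeights(study)
  ed <- euthanasiaDays(study)
  out <- numeric(0)
  for (id in animalIds(study)) {
    if (is.na(tw[[id]]) || is.na(ed[[id]])) next
    if (!id %in% rownames(fits)) next
    fr <- fits[id, ]
    if (is.na(fr$r) || (require_valid && !isTRUE(fr$valid))) next
    out[[id]] <- predictWeight(tw[[id]], ed[[id]], fr$r, target_day)
  }
  out
}
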