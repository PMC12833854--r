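#' Mann-Whitney U test for two small samples
#'
#' Rank-sum comparison suited to the small, non-normal samples typical of
#' preclinical groups.  The default p-value uses the normal approximation
#' with tie correction and continuity correction; `exact = TRUE` switches to
#' the exact (tie-free) null distribution for verification.  The reported
#' `U` is the statistic for sample `a`, so `U_a + U_b = n_a * n_b`.
#'
#' @param a,b numeric samples, both nonempty.
#' @param exact use the exact null distribution instead of the normal
#'   approximation.
#' @return list with `U`, `p` (two-sided) and `method`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p  # 0.1
#' @export
mannWhitneyU <- function(a, b, exact = FALSE) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Cohen's d with 95% confidence interval
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with the
#' pooled SD weighted by `(n_a - 1, n_b - 1)`.  The CI uses the large-sample
#' variance `(n_a + n_b)/(n_a n_b) + d^2 / (2 (n_a + n_b - 2))`.  Magnitude
#' labels follow the usual conventions: small 0.2-0.5, medium 0.5-0.8,
#' large >= 0.8 (absolute value).
#'
#' @param a,b numeric samples, each of size >= 2.
#' @return list with `d`, `ci` (length-2), `magnitude`.
#' @export
cohensD <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  md <- mean(a) - mean(b)
  if (sp2 == 0) {
    if (md == 0) {
      d <- 0
    } else {
      warning("zero pooled SD with unequal means: infinite effect size")
      d <- sign(md) * Inf
    }
  } else {
    d <- md / sqrt(sp2)
  }
  se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb - 2)))
  mag <- if (!is.finite(d)) "large" else {
    ad <- abs(d)
    if (ad >= 0.8) "large" else if (ad >= 0.5) "medium"
    else if (ad >= 0.2) "small" else "negligible"
  }
  list(d = d, ci = c(d - 1.96 * se, d + 1.96 * se), magnitude = mag)
}

#' Percent reduction in growth rate
#'
#' `100 * (1 - r_treated / r_control)`: the fraction of the control growth
#' rate suppressed by treatment.
#'
#' @param r_treated,r_control group growth rates, day\eqn{^{-1}};
#'   `r_control` nonzero.
#' @return percent reduction.
#' @examples
#' percentReduction(0.175, 0.257)  # 31.9
#' @export
percentReduction <- function(r_treated, r_control) {
  if (any(r_control == 0)) stop("domain error: r_control must be nonzero")
  100 * (1 - r_treated / r_control)
}

#' Compare fitted growth rates between two groups
#'
#' Mann-Whitney test and Cohen's d (orientation `a - b`, conventionally
#' treated minus control) on the fitted rates of animals passing the
#' R-squared validity filter.  At least two valid animals per group are
#' required; otherwise an insufficient-data result is returned rather than
#' an error.
#'
#' @param fits a [fitGrowth()] table.
#' @param group_a,group_b the two group labels (a is reported first; use
#'   treated as `group_a` for treated-minus-control signs).
#' @param use_valid_only restrict to fits passing the R-squared filter
#'   (default `TRUE`).
#' @param exact passed to [mannWhitneyU()].
#' @return list with `status` (`"ok"` or `"insufficient_data"`), per-group
#'   `n`, `median` and `iqr`, and for `"ok"`: `U`, `p`, `d`, `d_ci`,
#'   `d_magnitude`, `percent_reduction` (treating `group_b` as control).
#' @export
compareGrowthRates <- function(fits, group_a, group_b,
                               use_valid_only = TRUE, exact = FALSE) {
  f <- as.data.frame(fits)
  pick <- function(g) {
    r <- f$r[f$group == g & !is.na(f$r) & (!use_valid_only | f$valid)]
    r
  }
  ra <- pick(group_a); rb <- pick(group_b)
  base <- list(group_a = group_a, group_b = group_b,
               n_a = length(ra), n_b = length(rb),
               median_a = stats::median(ra), median_b = stats::median(rb),
               iqr_a = if (length(ra)) stats::IQR(ra, type = 7) else NA_real_,
               iqr_b = if (length(rb)) stats::IQR(rb, type = 7) else NA_real_)
  if (length(ra) < 2L || length(rb) < 2L)
    return(c(base, list(status = "insufficient_data")))
  mw <- mannWhitneyU(ra, rb, exact = exact)
  cd <- cohensD(ra, rb)
  c(base, list(status = "ok", U = mw$U, p = mw$p, d = cd$d, d_ci = cd$ci,
               d_magnitude = cd$magnitude,
               percent_reduction = percentReduction(mean(ra), mean(rb))))
}

.isDiagonal <- function(days, x_day, y_day) {
  i <- match(x_day, days); j <- match(y_day, days)
  !is.na(i) && !is.na(j) && j == i + 1L
}

#' Compare one TGR interval between two groups
#'
#' Per-animal localized rates \eqn{r_{x \to y}} from the two groups'
#' matrices are compared with Mann-Whitney and Cohen's d; group medians and
#' IQRs are recorded.  Multiplicity corrections are only ever attached (by
#' [correctDiagonal()]) to diagonal intervals — consecutive-day entries,
#' the only data-disjoint ones.
#'
#' @param matrices_a,matrices_b lists of per-animal [TGRMatrix] objects
#'   (conventionally treated, control).
#' @param x_day,y_day the interval endpoints.
#' @param exact passed to [mannWhitneyU()].
#' @return one-row data frame with `x_day`, `y_day`, `diagonal`, per-group
#'   `n`/`median`/`iqr`, `U`, `p`, `d`, `d_lo`, `d_hi`, `status`,
#'   and `p_bonferroni`/`q_bh` initialized to `NA`.
#' @export
compareInterval <- function(matrices_a, matrices_b, x_day, y_day,
                            exact = FALSE) {
  va <- vapply(matrices_a, tgrEntry, numeric(1), x_day = x_day,
               y_day = y_day)
  vb <- vapply(matrices_b, tgrEntry, numeric(1), x_day = x_day,
               y_day = y_day)
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  days <- tgrDays(if (length(matrices_a)) matrices_a[[1L]]
                  else matrices_b[[1L]])
  out <- data.frame(
    x_day = x_day, y_day = y_day,
    diagonal = .isDiagonal(days, x_day, y_day),
    n_a = length(va), n_b = length(vb),
    median_a = if (length(va)) stats::median(va) else NA_real_,
    median_b = if (length(vb)) stats::median(vb) else NA_real_,
    iqr_a = if (length(va)) stats::IQR(va, type = 7) else NA_real_,
    iqr_b = if (length(vb)) stats::IQR(vb, type = 7) else NA_real_,
    U = NA_real_, p = NA_real_, d = NA_real_, d_lo = NA_real_,
    d_hi = NA_real_, p_bonferroni = NA_real_, q_bh = NA_real_,
    status = "insufficient_data", stringsAsFactors = FALSE)
  if (length(va) >= 2L && length(vb) >= 2L) {
    mw <- mannWhitneyU(va, vb, exact = exact)
    cd <- cohensD(va, vb)
    out$U <- mw$U; out$p <- mw$p
    out$d <- cd$d; out$d_lo <- cd$ci[1L]; out$d_hi <- cd$ci[2L]
    out$status <- "ok"
  }
  out
}

#' Compare every TGR interval between two groups
#'
#' Runs [compareInterval()] over all ordered day pairs of the shared grid
#' and attaches Bonferroni and Benjamini-Hochberg corrections to the
#' diagonal rows via [correctDiagonal()].
#'
#' @inheritParams compareInterval
#' @param correct attach diagonal-only corrections (default `TRUE`).
#' @return data frame with one row per interval.
#' @export
compareAllIntervals <- function(matrices_a, matrices_b, exact = FALSE,
                                correct = TRUE) {
  days <- tgrDays(matrices_a[[1L]])
  n <- length(days)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    rows[[length(rows) + 1L]] <-
      compareInterval(matrices_a, matrices_b, days[i], days[j],
                      exact = exact)
  out <- do.call(rbind, rows)
  if (correct) {
    diag <- out$diagonal & out$status == "ok"
    if (any(diag)) {
      corr <- correctDiagonal(out[diag, , drop = FALSE])
      out$p_bonferroni[diag] <- corr$p_bonferroni
      out$q_bh[diag] <- corr$q_bh
    }
  }
  out
}

#' Multiplicity correction for diagonal intervals
#'
#' Bonferroni (`p * m`, capped at 1) and Benjamini-Hochberg q-values,
#' applied exclusively to diagonal (consecutive-day) interval comparisons —
#' the only intervals that share no measurement and hence satisfy the
#' independence assumptions of these procedures.  Off-diagonal input is a
#' contract error.
#'
#' @param comparisons data frame of diagonal interval comparisons with a
#'   `p` column (and a `diagonal` column if present, all `TRUE`).
#' @return the input with `p_bonferroni` and `q_bh` filled in.
#' @export
correctDiagonal <- function(comparisons) {
  if (!is.null(comparisons$diagonal) && !all(comparisons$diagonal))
    stop("contract error: corrections apply to diagonal intervals only")
  p <- comparisons$p
  comparisons$p_bonferroni <- pmin(1, p * length(p))
  comparisons$q_bh <- stats::p.adjust(p, method = "BH")
  comparisons
}
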