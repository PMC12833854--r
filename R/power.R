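# run expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Resampling-based power assessment
#'
#' Estimates the statistical power of two analysis strategies at a given
#' pair of group sizes by repeated random subsetting of an available cohort.
#' For each of `n_subsets` subsets (drawn without replacement within group,
#' independently across subsets):
#' \describe{
#'   \item{conventional}{a Mann-Whitney test of raw burdens at every study
#'     day with at least two available animals per group; the subset's power
#'     contribution is the fraction of tested days with `p < alpha`.
#'     `power_conventional` is the mean of these fractions times 100.}
#'   \item{exponential}{exponential fits for the subset, filtered by the
#'     R-squared threshold; the subset is *valid* when both groups retain at
#'     least two valid fits, and *significant* when the Mann-Whitney test on
#'     the fitted rates has `p < alpha`.  `power_exponential` is
#'     `100 * significant / valid`; invalid subsets are excluded from the
#'     denominator.}
#' }
#'
#' @param study a [TumorStudy] with (at least) two groups.
#' @param n_a,n_b subset sizes drawn from `group_a` and `group_b`.
#' @param n_subsets number of random subsets (default 20).
#' @param seed integer seed; every random element derives from it.
#' @param config a [fitConfig()] (sets the R-squared threshold).
#' @param group_a,group_b group labels; default the study's first two.
#' @param alpha significance level (default 0.05).
#' @param exact passed to [mannWhitneyU()].
#' @return list of class `power_result`: `n_a`, `n_b`, `n_subsets`,
#'   `n_valid`, `power_conventional`, `power_exponential` (percent, `NA`
#'   when no subset was valid), `r2_threshold`, `alpha`, `seed`.
#' @export
assessPower <- function(study, n_a, n_b, n_subsets = 20, seed = 1,
                        config = fitConfig(), group_a = NULL, group_b = NULL,
                        alpha = 0.05, exact = FALSE) {
  if (n_subsets < 1L) stop("n_subsets must be at least 1")
  gl <- groupLabels(study)
  gn <- groupNames(study)
  if (is.null(group_a)) group_a <- gn[1L]
  if (is.null(group_b)) group_b <- gn[2L]
  idsA <- animalIds(study)[gl == group_a]
  idsB <- animalIds(study)[gl == group_b]
  if (n_a > length(idsA) || n_b > length(idsB))
    stop("requested subset sizes exceed available animals")
  b <- burdenMatrix(study); e <- excludedMatrix(study)
  avail <- !is.na(b) & !e

  dayFrac <- numeric(n_subsets)
  expOutcome <- rep(NA, n_subsets)   # NA = invalid subset

  .withSeed(seed, {
    for (s in seq_len(n_subsets)) {
      subA <- sample(idsA, n_a)
      subB <- sample(idsB, n_b)
      # conventional: day-by-day tests on available animals
      tested <- 0L; hits <- 0L
      for (i in seq_len(nrow(b))) {
        va <- b[i, subA][avail[i, subA]]
        vb <- b[i, subB][avail[i, subB]]
        if (length(va) < 2L || length(vb) < 2L) next
        tested <- tested + 1L
        p <- mannWhitneyU(va, vb, exact = exact)$p
        if (!is.na(p) && p < alpha) hits <- hits + 1L
      }
      dayFrac[s] <- if (tested) hits / tested else 0
      # exponential: rate comparison after quality filtering
      sub <- study[, c(subA, subB)]
      fits <- as.data.frame(fitGrowth(sub, config))
      ra <- fits$r[fits$group == group_a & fits$valid & !is.na(fits$r)]
      rb <- fits$r[fits$group == group_b & fits$valid & !is.na(fits$r)]
      if (length(ra) >= 2L && length(rb) >= 2L) {
        p <- mannWhitneyU(ra, rb, exact = exact)$p
        expOutcome[s] <- !is.na(p) && p < alpha
      }
    }
  })

  nValid <- sum(!is.na(expOutcome))
  structure(list(
    n_a = n_a, n_b = n_b, n_subsets = n_subsets, n_valid = nValid,
    power_conventional = 100 * mean(dayFrac),
    power_exponential = if (nValid) 100 * sum(expOutcome, na.rm = TRUE) /
      nValid else NA_real_,
    r2_threshold = config$r2_threshold, alpha = alpha, seed = seed),
    class = "power_result")
}

#' Power assessment over a grid of sample-size scenarios
#'
#' Runs [assessPower()] for each `(n_a, n_b)` scenario, deriving one
#' sub-seed per scenario from `seed`.
#'
#' @param study a [TumorStudy].
#' @param scenarios list of length-2 integer vectors `c(n_a, n_b)`.
#' @inheritParams assessPower
#' @return data frame with one row per scenario.
#' @export
powerScenarios <- function(study, scenarios, n_subsets = 20, seed = 1,
                           config = fitConfig(), group_a = NULL,
                           group_b = NULL, alpha = 0.05) {
  rows <- lapply(seq_along(scenarios), function(k) {
    sc <- scenarios[[k]]
    pr <- assessPower(study, sc[1L], sc[2L], n_subsets = n_subsets,
                      seed = (seed + 7919L * k) %% .Machine$integer.max,
                      config = config, group_a = group_a, group_b = group_b,
                      alpha = alpha)
    data.frame(n_a = pr$n_a, n_b = pr$n_b, n_subsets = pr$n_subsets,
               n_valid = pr$n_valid,
               power_conventional = pr$power_conventional,
               power_exponential = pr$power_exponential)
  })
  do.call(rbind, rows)
}
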