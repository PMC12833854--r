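# Build a small study from a days-by-animals matrix (or per-animal vectors).
makeStudy <- function(..., days, groups, unit = "volume_mm3",
                      terminalWeights = NULL, euthanasiaDays = NULL) {
  vals <- list(...)
  burden <- do.call(cbind, vals)
  ids <- names(vals)
  TumorStudy(burden, days = days, groups = groups, unit = unit,
             animalIds = ids, terminalWeights = terminalWeights,
             euthanasiaDays = euthanasiaDays)
}

# Noiseless exponential cohort with given per-animal rates.
makeCleanCohort <- function(rates, groups, days = c(0, 2, 4, 7, 9, 11),
                            N0 = 100) {
  burden <- vapply(rates, function(r) N0 * exp(r * days), numeric(length(days)))
  colnames(burden) <- sprintf("A%02d", seq_along(rates))
  TumorStudy(burden, days = days, groups = groups, unit = "volume_mm3")
}

# Textbook normal-equations simple linear regression on (x, y); the
# independent oracle for the log-linear fit.
olsOracle <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n; ybar <- sum(y) / n
  sxx <- sum((x - xbar)^2)
  slope <- sum((x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(s2 / sxx),
       se_intercept = sqrt(s2 * (1 / n + xbar^2 / sxx)),
       r_squared = 1 - sum(res^2) / sum((y - ybar)^2))
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (tie-free samples).
enumMannWhitneyP <- function(a, b) {
  na <- length(a); nb <- length(b)
  obs <- sum(rank(c(a, b))[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(na + nb, na)
  u <- apply(idx, 2, function(s) sum(s) - na * (na + 1) / 2)
  min(1, 2 * min(mean(u <= obs), mean(u >= obs)))
}

# Write a study back out as an input-format wide CSV.
writeInputCsv <- function(study, path) {
  b <- burdenMatrix(study)
  df <- data.frame(Animal = animalIds(study),
                   Group = unname(groupLabels(study)),
                   t(b), check.names = FALSE)
  names(df)[-(1:2)] <- studyDays(study)
  tw <- terminalWeights(study)
  if (any(!is.na(tw))) df$Tumor_Weight <- unname(tw)
  ed <- euthanasiaDays(study)
  if (any(!is.na(ed))) df$Euthanasia_Day <- unname(ed)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
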