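#' Specify a synthetic cohort
#'
#' Describes a cohort generated under the exponential model the framework
#' assumes: each animal draws a true rate `r ~ Normal(r_mean, r_sd)` and a
#' true initial burden `N0` from a lognormal with the given geometric mean
#' and geometric CV, and every measurement is the true trajectory times
#' multiplicative lognormal noise of a given CV.  Optional right-censoring
#' dropout (a humane-endpoint analogue) and planted outliers (spikes, drops,
#' nonpositive values) exercise the QC machinery.
#'
#' @param group_specs list of group descriptions, each a list with `label`,
#'   `n_animals`, `r_mean`, `r_sd` (day\eqn{^{-1}}), `N0_gmean`, `N0_gcv`
#'   (percent).
#' @param schedule strictly increasing numeric vector of study days.
#' @param noise_cv multiplicative measurement noise CV, percent (>= 0).
#' @param dropout optional list `list(prob=, day_range=c(lo, hi))`: with
#'   probability `prob` an animal is censored at a uniform random day in
#'   `day_range` (measurements after it become absent).
#' @param outlier_plan optional list of `list(kind=, count=)` with `kind`
#'   one of `"spike"` (x10), `"drop"` (x0.1), `"nonpositive"` (set to -1).
#' @param weight_scale optional g-per-unit factor; when set, each animal
#'   gets a terminal weight `weight_scale * N(t_euth)` (with the same
#'   measurement noise) at its euthanasia day.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a list of class `synthetic_spec`.
#' @export
syntheticSpec <- function(group_specs, schedule, noise_cv = 20,
                          dropout = NULL, outlier_plan = NULL,
                          weight_scale = NULL, seed = 1) {
  stopifnot(length(group_specs) >= 1, noise_cv >= 0,
            all(diff(schedule) > 0))
  for (g in group_specs)
    stopifnot(g$n_animals >= 1, g$r_sd >= 0, g$N0_gmean > 0, g$N0_gcv >= 0)
  structure(list(group_specs = group_specs, schedule = schedule,
                 noise_cv = noise_cv, dropout = dropout,
                 outlier_plan = outlier_plan, weight_scale = weight_scale,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# lognormal sdlog giving a target CV in percent
.sdlogFromCv <- function(cv) sqrt(log(1 + (cv / 100)^2))

#' Simulate a cohort from a specification
#'
#' Generates measurements `N0 * exp(r * t) * eps_t` with
#' `ln eps_t ~ Normal(0, sigma)`, `sigma = sqrt(ln(1 + (cv/100)^2))`, then
#' applies dropout and the outlier plan.  Returns both the study and the
#' ground truth so recovery can be checked.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `study` (a [TumorStudy]) and `truth`
#'   (a [S4Vectors::DataFrame]: `animal_id`, `group`, `r_true`, `N0_true`,
#'   `censor_day`).
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  days <- spec$schedule
  nd <- length(days)
  sdn <- .sdlogFromCv(spec$noise_cv)
  .withSeed(spec$seed, {
    cols <- list(); ids <- character(); grps <- character()
    rT <- numeric(); n0T <- numeric(); cens <- numeric()
    tw <- numeric(); ed <- numeric()
    a <- 0L
    for (g in spec$group_specs) {
      for (k in seq_len(g$n_animals)) {
        a <- a + 1L
        id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", g$label), k)
        r <- stats::rnorm(1, g$r_mean, g$r_sd)
        n0 <- stats::rlnorm(1, log(g$N0_gmean), .sdlogFromCv(g$N0_gcv))
        v <- n0 * exp(r * days) * stats::rlnorm(nd, 0, sdn)
        cday <- NA_real_
        if (!is.null(spec$dropout) &&
            stats::runif(1) < spec$dropout$prob) {
          cday <- stats::runif(1, spec$dropout$day_range[1L],
                               spec$dropout$day_range[2L])
          v[days > cday] <- NA_real_
        }
        euth <- if (is.na(cday)) days[nd] else max(days[days <= cday])
        ids <- c(ids, id); grps <- c(grps, g$label)
        rT <- c(rT, r); n0T <- c(n0T, n0); cens <- c(cens, cday)
        ed <- c(ed, euth)
        tw <- c(tw, if (is.null(spec$weight_scale)) NA_real_ else
          spec$weight_scale * n0 * exp(r * euth) * stats::rlnorm(1, 0, sdn))
        cols[[id]] <- v
      }
    }
    burden <- do.call(cbind, cols)
    # planted outliers on random present measurements
    if (!is.null(spec$outlier_plan)) {
      for (pl in spec$outlier_plan) {
        for (k in seq_len(pl$count)) {
          present <- which(!is.na(burden))
          cell <- present[sample.int(length(present), 1L)]
          burden[cell] <- switch(pl$kind,
            spike = burden[cell] * 10,
            drop = burden[cell] * 0.1,
            nonpositive = -1,
            stop("unknown outlier kind: ", pl$kind))
        }
      }
    }
    study <- TumorStudy(burden, days = days, groups = grps,
                        unit = "volume_mm3", animalIds = ids,
                        terminalWeights = tw, euthanasiaDays = ed)
    list(study = study,
         truth = S4Vectors::DataFrame(animal_id = ids, group = grps,
                                      r_true = rT, N0_true = n0T,
                                      censor_day = cens))
  })
}

#' Reference-style cohort specification
#'
#' A preset emulating the structure of the public glioma-xenograft
#' benchmark: 8 control and 10 treated animals measured on days 0, 3, 4, 5,
#' 6, 7, 10, 11, 12, 13, 14, 17 and 18 (13 time points, hence 78 TGR
#' intervals), control mean rate 0.257 day\eqn{^{-1}} versus treated 0.175
#' day\eqn{^{-1}} (a 31.9 percent reduction), 20 percent multiplicative
#' measurement noise.  Between-animal rate SDs are derived from the
#' benchmark's reported relative standard errors of the group means (11.3
#' and 6.9 percent) times \eqn{\sqrt{n}}; see the vignette.
#'
#' @param seed integer seed (default 1229).
#' @return a [syntheticSpec()].
#' @examples
#' sp <- daskalakisLikeSpec()
#' length(sp$schedule)  # 13
#' @export
daskalakisLikeSpec <- function(seed = 1229) {
  syntheticSpec(
    group_specs = list(
      list(label = "Control", n_animals = 8, r_mean = 0.257,
           r_sd = 0.257 * 0.113 * sqrt(8), N0_gmean = 100, N0_gcv = 40),
      list(label = "Treated", n_animals = 10, r_mean = 0.175,
           r_sd = 0.175 * 0.069 * sqrt(10), N0_gmean = 100, N0_gcv = 40)),
    schedule = c(0, 3, 4, 5, 6, 7, 10, 11, 12, 13, 14, 17, 18),
    noise_cv = 20, seed = seed)
}
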