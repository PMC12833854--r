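---
title: "Exponential tumor-growth modeling, TGR matrices and quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exponential tumor-growth modeling, TGR matrices and quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorkinetics)
```

## The problem

Preclinical tumor studies compare small groups of animals (often 4–10 per
arm) whose tumor burden — caliper volume in mm³, bioluminescence in
photons/s, or weight in g — is measured on a handful of study days.
Endpoint comparisons of raw burden waste most of the longitudinal signal
and are dominated by between-animal variability in starting burden.
`tumorkinetics` instead summarizes each animal by its exponential growth
rate and builds every downstream comparison on rates.

## The growth model

Early-stage tumor growth, while proliferation dominates and before
angiogenic and nutrient constraints reshape the kinetics, is well described
by

$$N(t) = N_0 e^{r t},$$

with $N(t)$ the tumor burden at day $t$, $N_0$ the initial burden and $r$
the growth rate (day⁻¹). Both caliper volume and bioluminescence are
approximately proportional to cell number, so either serves as $N$.
`fitExponential()` estimates $(N_0, r)$ by ordinary least squares on
$(t, \ln N)$: with multiplicative lognormal measurement noise the errors
are additive and Gaussian in log space, where least squares is the maximum
likelihood estimator. Only positive, non-excluded measurements enter the
regression, and at least 3 points are required (`fitConfig(min_points=)`),
matching the floor used by point-level filtering.

Reported per animal: $N_0$, $r$, their standard errors, relative standard
errors ($100\,\mathrm{SE}/|\hat\theta|$; for $N_0$ we report
$100\,\mathrm{SE}(\ln N_0)$, the first-order relative error of a lognormal
intercept), the doubling time $\ln 2 / r$ (undefined for $r \le 0$;
regressing tumors are retained, their doubling time is not reported), and
$R^2$.

**$R^2$ scale.** $R^2$ is computed on the log scale by default — the scale
the regression is performed on, and the internally consistent choice; a
raw-scale option exists (`fitConfig(r2_scale = "raw")`) for comparison with
tools that report raw-scale agreement. Fits with $R^2$ above the
configurable threshold (default 0.8, a standard operating point for
exponential fits to early-stage data) are marked valid; group statistics
use valid fits only. Threshold filtering is a selection step and can bias a
cohort if set aggressively — both the threshold and the validity flags are
surfaced in every export so the reader can see what was excluded.

**Why rates beat raw burden.** For a predicted burden,
$\mathrm{RSE}(N(t)) = \sqrt{\mathrm{RSE}^2(N_0) + t^2 (100\,se_r)^2}$
(`propagateRse()`): baseline uncertainty enters once while rate uncertainty
scales with $t$, so comparisons built on $r$ avoid the inflating baseline
term entirely. The second term uses the absolute SE of $r$ in percent
(dimensional analysis of $\ln N = \ln N_0 + r t$ forces $t^2
\mathrm{var}(r)$, not $t^2\,\mathrm{var}(r)/r^2$).

## TGR matrices

A single whole-study rate hides temporal structure — drug exposure
fluctuates, resistance emerges. The localized rate between any two
measurement days,

$$r_{x \to y} = \frac{\ln(N_y / N_x)}{t_y - t_x},$$

is computed for all $n(n-1)/2$ ordered day pairs (`animalTGRMatrix()`),
producing an upper-triangular matrix per animal; 13 measurement days give
78 intervals. Matrices are keyed by day value, so animals measured on a
subset of days align. Exact telescoping additivity,
$r_{x\to z}(t_z{-}t_x) = r_{x\to y}(t_y{-}t_x) + r_{y\to z}(t_z{-}t_y)$,
holds by construction and is asserted in the test suite to 1e-12.

Displayed matrices are group aggregates (`aggregateTGR()`, entrywise mean
by default — "group-averaged" — with a median option); statistics always
use per-animal values, never the aggregate. Heat-map rendering bins rates
into five classes: high ($r > 0.25$), medium ($0.15 \le r \le 0.25$), low
($[0.10, 0.15)$), very low ($[0.05, 0.10)$) and minimal/negative
($r < 0.05$). The high bin is strictly above 0.25; the remaining bounds are
lower-inclusive so the bins deterministically partition the line.

**Multiplicity.** Off-diagonal intervals share measurements and are
therefore correlated; each also asks a distinct temporal question. We
report uncorrected p-values with effect sizes as co-primary evidence, and
attach Bonferroni and Benjamini–Hochberg corrections *only* to the diagonal
intervals $r_{t \to t+1}$ — consecutive, data-disjoint, the only set that
approximately satisfies the independence assumptions
(`correctDiagonal()`, standard step-up BH via `p.adjust`).

## Quality control

**Homogeneity.** Each group's baseline coefficient of variation (first
recorded measurement per animal, animals with a nonpositive first value
excluded) is scored by the piecewise rule: 100 for CV ≤ ε (15%),
$95 - (CV - ε)$ for ε < CV ≤ π (30%), $\max(0, 100 - 2(CV - π))$ above π,
multiplied by small-sample factors (0.9 for $n<5$, a further 0.8 for
$n<3$). The piecewise form is applied exactly as defined, including its
discontinuity at CV = π (score 80 at CV = 30 but ≈100 just above) — we
document rather than silently repair it. Assessment runs before and after
filtering so the effect of exclusions is visible.

**Six-criteria outlier detector.** Sensitivity adapts to group size:
ultra-conservative ($n<5$: 4.0× IQR fences, growth limit 5000 %/day,
decline 90 %/day, multiple indicators required for a whole-animal
recommendation), conservative ($5 \le n \le 10$: 3.0×, 2500, 80) and
moderate ($n>10$: 2.0×, 1000, 67). Smaller groups get laxer limits to
prevent excessive exclusion. An alternative tier table keyed at
$n<8/8{-}12/{>}12$ is available as `selectSensitivity(preset = "qc")`;
the default table is the one that carries the fence multipliers. The six criteria: values ≤ 0
(critical); per-day fold-change growth/decline beyond the tier limit
(critical); within-animal log-residual IQR outliers about a Theil–Sen
median-slope line, chosen for robustness over an OLS trend (high); per-day
group-level log-value IQR outliers, computed within experimental group
(medium); and an abrupt final-interval drop — over 50 %/day with no earlier
declining interval, threshold configurable (medium). Quartiles use the
linear-interpolation (type 7) convention, which the fences inherit; fence
half-widths have a 1e-8 absolute floor in log space so floating-point
residue on noiseless data is never flagged. Re-estimating fences on
filtered data can flag additional borderline points (the usual masking
phenomenon of iterative robust detection); filtering is therefore a single
explicit pass, not a fixed-point iteration.

**Three filtering modes.** `complete` (everything retained),
`animal_level` (flagged animals removed entirely) and `point_level`
(flagged measurements excluded; an animal survives while ≥ 3 valid points
remain). Filtering is non-destructive — exclusions are marked, values
preserved — and every decision is logged.

## Group comparison and power

Rates are compared with Mann–Whitney U tests (small samples, no normality
assumption). The default p-value is the normal approximation with tie and
continuity corrections; an exact-enumeration mode exists for verification.
Enumeration shows the approximation stays within 0.035 absolute of the
exact two-sided p for group sizes 4–6, and within 10% relative where the
exact p ≥ 0.05; the deep tail is relatively (not absolutely) less accurate
— documented here because small-sample studies live near these sizes.
Cohen's d uses the pooled SD with $(n_a-1, n_b-1)$ weights and the
large-sample CI $d \pm 1.96\sqrt{(n_a+n_b)/(n_a n_b) + d^2/(2(n_a+n_b-2))}$;
signs are treated-minus-control throughout, and percent reduction is
$100(1 - r_T/r_C)$.

`assessPower()` estimates power by repeated random subsetting (default 20
subsets, seeded, drawn without replacement within group and independently
across subsets — repeated subsets are allowed, sampling the subset lattice
uniformly). Conventional power is the mean fraction of study days (those
with ≥ 2 available animals per group) significant at $\alpha$; exponential
power is the fraction of *valid* subsets (≥ 2 valid fits per group after
$R^2$ filtering — the minimum for a test) whose rate comparison is
significant. Because the rank test is discrete, its attained size at these
sizes sits below nominal (3.2% at $n=5,5$; 4.1% at $n=6,6$, the closest to
5% among small sizes) — the package's null-calibration test therefore
checks the type-I rate at $n=6,6$.

## Tumor-weight standardization

Humane endpoints scatter euthanasia across days, making terminal weights
incomparable. `predictWeight()` projects each measured weight along the
animal's fitted rate, $w(t^\ast) = w\,e^{r(t^\ast - t_{euth})}$, to a
common target day; `predictionError()` reports
$100\,|exp - pred|/exp$ where direct validation is possible. Animals
missing a weight, a euthanasia day or a valid fit are skipped, never
imputed.

## The synthetic-cohort generator

`simulateCohort()` draws per-animal $r \sim \mathcal N(\bar r, \sigma_r)$
and $N_0$ lognormal, then emits $N_0 e^{rt}\varepsilon_t$ with
$\ln\varepsilon_t \sim \mathcal N(0, \sigma)$,
$\sigma = \sqrt{\ln(1 + (cv/100)^2)}$ — multiplicative lognormal noise,
the noise model under which the log-linear fit is maximum likelihood.
Optional right-censoring dropout emulates humane endpoints, planted
spikes/drops/nonpositive values exercise the detector, and generation is
bit-reproducible given the seed without disturbing the caller's RNG
stream. `daskalakisLikeSpec()` presets the structure of the public
glioma-xenograft benchmark: 8 control + 10 treated animals, days
0,3,4,5,6,7,10,11,12,13,14,17,18, control mean rate 0.257 vs treated
0.175 day⁻¹, 20% measurement CV. The benchmark reports the group-mean
rates with relative errors of 11.3% and 6.9%; we read those as RSEs of
the group means and set the between-animal SDs to
$\bar r \cdot \mathrm{RSE} \cdot \sqrt{n}$ (0.082 and 0.038 day⁻¹). The
$N_0$ geometric mean (100) and geometric CV (40%) are generic choices at
the scale of early caliper volumes.

What the generator does *not* emulate: growth saturation (Gompertz/logistic
tails), serially correlated measurement error, day-level batch effects, or
informative dropout tied to burden. Tests passing on these cohorts
demonstrate correctness of the estimators and detectors under the model's
own assumptions, not robustness to every failure mode of real data.

## Numerical choices and problem sizes

Tolerances: noiseless recovery and oracle equivalence asserted at 1e-10;
TGR telescoping at 1e-12 absolute (log-increment scale); IQR fence floor
1e-8. Degenerate inputs: all-identical measurement days is an error; fewer
than `min_points` positive values yields an absent fit (reported
"insufficient data", not an error); empty CSV cells are missing data while
recorded nonpositive values are data that QC flags. Exports write full
decimal precision (shortest round-tripping representation); reports round
to 3 significant figures.

The validation suite uses cohorts of 8–20 animals per group over 5–13
time-point schedules, 200 independent null draws for the type-I
calibration, 60 cohorts per effect size for the power-monotonicity check
and 1,000 random instances for the least-squares oracle equivalence —
sizes chosen to keep Monte-Carlo error well inside the asserted bands
while the whole suite runs in minutes on one CPU.

## Worked example

```{r example}
sim <- simulateCohort(daskalakisLikeSpec())
study <- sim$study
study

fits <- fitGrowth(study)
head(as.data.frame(fits)[, c("animal_id", "group", "r", "rse_r",
                             "r_squared", "valid")], 4)

cmp <- compareGrowthRates(fits, "Treated", "Control")
c(p = cmp$p, d = cmp$d, reduction_pct = cmp$percent_reduction)
```

## Known limitations

The exponential model is only appropriate for proliferation-dominated
phases (typically the first 2–4 weeks); systematic residual patterns and
falling $R^2$ flag its breakdown, and no Gompertz/logistic fallback is
provided. $R^2$ filtering can select against genuine non-exponential
responders. Extremely small groups ($n \le 4$) limit what any method can
conclude; the power machinery quantifies, but cannot repair, that limit.
The Mann–Whitney approximation is conservative in the deep tail at these
sizes. Off-diagonal TGR intervals are exploratory by design: their
uncorrected p-values prioritize sensitivity, with effect sizes as the
companion evidence.
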