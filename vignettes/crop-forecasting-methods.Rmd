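---
title: "Methods: blending ensembles for crop production forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blending ensembles for crop production forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropcast)
```

## The problem and the data model

cropcast forecasts crop production (tons) for a (district, harvest year,
crop) unit from eight predictors: seven weather variables averaged over
the crop's growing window and the cultivated area in acres. Five crops
are modelled, each with a fixed month window — aus rice June–August, boro
rice March–May, potato February–March (kharif harvests), and aman rice
December–January and wheat November–March (rabi harvests, whose windows
wrap the calendar year). A wrapping window is attributed to the harvest
fiscal year of its later months: aman for harvest year $Y$ averages
December of $Y-1$ and January of $Y$. This attribution rule is a design
choice of the package — month lists alone do not determine a year — and
is applied consistently by `crop_window_months()`, the weather aggregator
and the simulator.

Production, not yield, is the regression target: area is a predictor, so
models are free to learn the (nearly proportional) area–production
relationship rather than having it imposed.

## Preprocessing

Cleaning proceeds in four stages, each exposed individually and chained
by `preprocess_pipeline()`:

1. **Coercion and plausibility filtering.** Character-typed numerics are
   parsed after stripping whitespace and thousands separators. Values
   outside per-column plausibility bounds (humidity outside $[0,100]$,
   negative areas, and so on; see `default_bounds()`) are set missing
   rather than dropped, as is a `temp_min`/`temp_max` pair in the wrong
   order — the pair is contradictory and neither value can be preferred.
2. **Imputation.** The default replaces a missing cell with the
   arithmetic mean of the column's *observed* values — the mean must be
   computed over observed values only, since any other reading is
   circular. This is idempotent and preserves column means. An
   alternative `"neighbor"` strategy interpolates within each (district,
   crop) series ordered by year — justified by the temporal continuity of
   agro-climate series — using the nearest observed values on either
   side and falling back to the column mean at series edges; it is
   opt-in, not the default.
3. **Reduction.** Exact duplicate rows are dropped (first kept), then
   rows with every predictor missing ("junk"), then any row repeating an
   earlier (district, year, crop) key, so the key is unique afterwards.
   Junk has no canonical definition in this setting; all-predictors
   missing plus exact duplication is the operationalization used here.
4. **Min–max normalization.** $x' = (x - \min)/(\max - \min)$ per
   column, with parameters stored for inversion and written to a JSON
   sidecar when a normalized dataset is saved. Constant columns map to 0
   with a warning. Parameters should be fitted on the training split and
   reused on the test split; test values may then fall outside $[0,1]$
   and are deliberately not clipped. Fitting on all data before the split
   leaks test information into the transform — mildly for min–max, but
   the leakage-free protocol is the defensible default, and
   `preprocess_pipeline(normalize = TRUE)` (whole-data fit) is provided
   for pipelines that want the simpler global behaviour.

## The blending ensemble

The forecaster blends three base learners chosen for complementary
inductive biases — k-nearest neighbours (local, nonparametric), a random
forest (axis-aligned nonlinearity, robust to outliers and scale), and
ridge regression (global linear structure, stable under collinearity).
`fit_krr()`:

1. splits the $n$ training rows uniformly at random (seeded) into a
   base-train set and a blend holdout of $\lceil f\,n\rceil$ rows
   (default $f = 0.15$, the top of the conventional 10–15% band for
   blending validation sets — the larger holdout stabilizes the
   meta-fit at moderate $n$);
2. fits each base on base-train only;
3. collects the base predictions $P \in \mathbb{R}^{m\times 3}$ on the
   holdout;
4. fits the meta-learner on $(P, y_{\text{holdout}})$.

The holdout is never shown to the base learners and the bases are not
refitted on the full training set afterwards: using a held-out slice
(rather than out-of-fold predictions) for the second layer is precisely
what distinguishes blending from stacking, and refitting would break the
correspondence between the meta-weights and the base functions they were
fitted to.

**The meta-learner.** The default solves least squares over the
probability simplex,
$$\hat w = \arg\min_{w \ge 0,\ \sum_i w_i = 1} \lVert Pw - y\rVert^2,$$
which makes "the best combination of the predictors" literal and yields a
machine-checkable guarantee: every vertex $e_i$ is feasible, so the
blend's holdout MSE never exceeds the best single base's. The solver
(`solve_simplex_ls()`) enumerates the faces of the simplex and solves
each face's equality-constrained problem through its KKT system — exact,
deterministic, and cheap for three bases; the test suite cross-checks it
against a brute-force grid search with 0.01 spacing. When several faces
tie (e.g. identical base predictions), the candidate touching the lowest
base indices wins, fixing the tie-break at KNN < RF < ridge for
determinism. An unconstrained least-squares meta with intercept
(`meta = "ols"`) is available where calibration matters more than the
dominance guarantee; which meta a practitioner should prefer is genuinely
open, so both are first-class. A holdout with constant targets cannot
identify weights at all; the fit then warns and falls back to uniform
weights $(1/3, 1/3, 1/3)$.

**Hyperparameters.** Inside the ensemble the defaults are KNN $k=5$, RF
10 trees (seed 42), ridge $\alpha = 0.01$. The standalone RF benchmark
uses 20 trees — the two settings serve different roles and are
deliberately not unified. $k$ for KNN has no canonical value in this
application; 5 is the field's common default and the ensemble's
guarantees do not depend on it.

## Benchmark regressors

Six benchmarks share one contract (`fit_regressor()`/`predict()`):
deterministic given the spec and seed, shape-checked, refusing missing
values. Standard backends are used — `caret::knnreg`, `randomForest`,
`e1071::svm` (linear kernel, $C = 100$, `scale = FALSE` so the contract
sees exactly the features it was given), `xgboost` (learning rate 0.05,
single-threaded for reproducibility). Ridge is a closed-form solve of
$(X_c^\top X_c + \alpha I)\,w = X_c^\top y_c$ on centred data with an
unpenalized intercept, because the installed ridge implementations either
standardize predictors or rescale the penalty, and the package's contract
fixes $\alpha$ as the plain L2 coefficient penalty.

Naive Bayes is a classifier; to obtain a regression baseline the target
is discretized into $B$ bins (default 20, quantile breaks), a Gaussian
naive-Bayes classifier with bin-frequency priors is fitted on the binned
labels, and the prediction is the posterior-mixed bin mean
$\sum_b P(b \mid x)\,\bar y_b$. Whether the original benchmark was run
this way or misapplied as a classifier cannot be determined from its
description; discretize-then-posterior-mean is the only reading that
yields a usable regressor, and it degrades gracefully (posterior
$\approx$ prior under uninformative features, so predictions revert to
the global mean). Within-bin zero variances are floored at $10^{-6}$
times the feature's spread to keep densities finite.

The gradient-boosted-trees family is a generic boosting baseline:
any gradient-boosted regression-tree backend at learning rate 0.05
qualifies; oblivious/symmetric tree structure is not required.

## Evaluation protocol

`run_experiment()` runs three phases — 80:20, 50:50 and 30:70 train:test
ratios (the last is read literally: 30% train, 70% test) — with ten
trials per phase by default. Trials differ only in the split seed (base
seed + trial index); model seeds stay fixed, isolating split variance.
Metrics are the standard MAE, MSE, RMSE and $R^2$, computed on the
normalized target scale; per-phase and pooled averages are reported.
Metrics can be computed on the original tonnage scale by inverting the
normalization (`minmax_invert()`) before scoring.

## The Diebold–Mariano test

For aligned error series $e_A, e_B$ and loss $L$ (squared by default),
the loss differential $d_t = L(e_{A,t}) - L(e_{B,t})$ has mean $\bar d$
and long-run variance $\hat\sigma^2 = \gamma_0 + 2\sum_{k=1}^{h-1}
\gamma_k$, with $\gamma_k$ the lag-$k$ autocovariance under $1/T$
normalization — the convention that keeps $\hat\sigma^2$ equal to
$\gamma_0$ at $h=1$ and positive semidefinite. The statistic
$DM = \bar d / \sqrt{\hat\sigma^2 / T}$ is referred to a standard normal
(an asymptotic z-test); the one-sided p-value $1 - \Phi(DM)$ tests the
alternative that model B — by convention the proposed ensemble — is more
accurate, and stars mark 1% (`*`), 5% (`**`) and 10% (`***`)
significance. The Harvey–Leybourne–Newbold small-sample correction
(scaling by $\sqrt{(T+1-2h+h(h-1)/T)/T}$ with a $t_{T-1}$ reference) is
available but off by default, matching the asymptotic-test convention. A
(near-)zero-variance loss differential — identical models, for instance —
raises an error rather than reporting $DM = 0$: a silent zero would
fabricate "no difference" evidence. The test suite verifies exact
antisymmetry and, by simulation (2,000 replicates at $T = 256$), that the
two-sided test's empirical size at the 5% level stays within
$[0.03, 0.07]$ under an i.i.d. normal null.

## The recommender

For a land unit and season, each candidate crop's production is predicted
from its model and current features and compared with an expert threshold
$\tau$ (an opaque institutional input, in tons). Qualifying crops
($\hat P \ge \tau$) are ranked by *relative* margin
$(\hat P - \tau)/\max(\tau, 10^{-9})$ — absolute margins would let
high-volume crops (rice, thousands of tons) trivially dominate low-volume
crops (wheat). Ties break alphabetically; candidates are restricted to
crops of the query season, since crops of different harvest periods do
not compete for the same planting decision. The filter compares
*production* against the threshold; predicted weather plays no role in
the comparison. The $\varepsilon$-guard handles $\tau = 0$ (any
non-negative prediction qualifies, margin finite).

## The synthetic data generator

No public archive matches the structure the pipeline targets, so the
package ships a generator whose defaults emulate it: 5 crops × 1,400
records (7,000 rows), 27 districts, harvest years 1969–2021, eight
predictors and the production target. For each record, weather is drawn
from a per-(crop, variable) normal climatology truncated at ±3σ (means
and sds in `default_weather_profile()`, sized so every draw is physically
valid — humidity within bounds, rain non-negative, `temp_min` strictly
below `temp_max`), and area from a per-crop lognormal. Log yield is

$$\log Y = \beta_0^{(c)} + \sum_v \beta_v z_v - \beta_q z_{tmax}^2
  + u_d + \delta\,(t - t_0) + \varepsilon,$$

with $z_v$ the weather z-scores, a quadratic heat penalty ($\beta_q =
0.04$) giving a concave yield response to extreme maximum temperature,
district effects $u_d \sim N(0, 0.1)$, a mild technology trend $\delta =
0.004$/year, and noise $\varepsilon \sim N(0, 0.1)$. Production is
$\text{area} \times e^{\log Y}$ — positive by construction,
area-proportional, and nonlinear in weather, so the tree/neighbour bases
and the linear base have complementary strengths and blending is
non-trivial.

Each crop's (district, year) keys are sampled *without replacement* from
the district-by-year grid, so a clean draw has unique keys and passes
validation outright. This is why the default is 27 districts: 1,400
records per crop over 53 years need at least $\lceil 1400/53 \rceil = 27$
districts for distinct keys. Corruption for pipeline testing is explicit
and seeded: `inject_missing()` blanks predictor cells independently at a
given rate, `inject_duplicates()` appends exact copies of uniformly
chosen rows.

**What the generator does and does not emulate.** It reproduces the
archive's shape, positivity, area-proportionality, per-crop climatology
differences and a plausible effect structure — enough to test the
pipeline's contracts, the ensemble's dominance guarantee and coefficient
recovery (an OLS fit on the generator's own scale recovers every nonzero
$\beta_v$ within ±10% at $n = 5000$, noise 0.01). It does *not* model
spatial correlation between districts, disaster-year shocks (a hook
exists in the design but is off by default), measurement idiosyncrasies
of real yearbooks, or any calibration to real national statistics.
Passing tests on synthetic data therefore demonstrate correctness of the
machinery, not forecasting skill on real archives.

## Numerical choices and degenerate inputs

* Simplex solver: faces whose KKT systems are numerically singular are
  skipped; a fully singular problem (all-zero predictions) falls back to
  uniform weights. Objective comparisons use a $10^{-12}$ slack so that
  earlier (lower-index) candidates win exact ties.
* `minmax_apply` maps constant columns to 0 with a warning instead of
  dividing by zero; inversion restores the stored constant.
* The DM long-run variance is floored at $\gamma_0 \times 10^{-12}$
  against negative truncated sums at $h > 1$.
* Metrics refuse empty and non-finite input; $R^2$ refuses constant $y$.
* CSV round-trips preserve at least 12 significant digits
  (`%.15g` formatting) and encode missing values as empty cells.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the evaluation protocol on
one crop's 1,400 records with three trials per phase, the dominance sweep
over 20 seeded blending fits on the full 7,000-row archive, the DM size
simulation with 2,000 replicates at $T = 256$, and coefficient recovery
at $n = 5000$ — sizes chosen so the whole battery completes in a few
minutes on a laptop while keeping every estimate's Monte-Carlo error well
inside the asserted bands.

## Known limitations

* Thresholds for the recommender are exogenous; the package neither
  estimates nor validates them.
* The evaluation protocol treats rows as exchangeable; there is no
  year-blocked or district-blocked splitting, which real forecasting
  deployments would want.
* The DM test here compares one split's error series; pooling errors
  across trials would violate the test's independence-across-$t$ framing
  and is not offered.
* Units for wind speed and cloud coverage are carried opaquely; no
  conversion is attempted.
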