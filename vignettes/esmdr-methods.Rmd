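---
title: "Martingale-residual MDR for age-of-onset interaction scans: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Martingale-residual MDR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmdr)
```

## The problem and the model

Multifactor dimensionality reduction (MDR) detects epistasis by collapsing
the $3^k$ genotype combinations of a $k$-SNP tuple into a one-dimensional
high/low-risk attribute and scoring the resulting two-group split.  For a
censored age-of-onset outcome the natural MDR score is a log-rank statistic
per candidate cell (survival MDR), but computing risk-set statistics for
every cell of every model of an exhaustive scan is expensive, and a
log-rank-only formulation offers no covariate adjustment.

`esmdr` instead replaces the survival outcome once, up front, with the
martingale residuals of a Cox proportional-hazards *null* model that
contains the adjustment covariates only (no genetic term):

$$M_i \;=\; \delta_i - \hat\Lambda_0(t_i)\, e^{\hat\beta' x_i},$$

the difference between subject $i$'s observed and model-expected event
count.  Residuals are bounded above by 1 and sum to zero on the fitting
data.  The key identity is that for any subject group $G$, with residuals
from the covariate-free null fit,

$$\sum_{i \in G} M_i \;=\; \sum_j \left(O_{1j} - E_{1j}\right),$$

the numerator of the two-group log-rank statistic — i.e. the log-rank
statistic with its variance set to 1.  Cell labels derived from
residual-sum signs therefore reproduce the survival-MDR cell partition
exactly (`test-equivalence.R` verifies the identity to $10^{-8}$ including
tied event times), while each model costs one pass of sums instead of a
risk-set traversal, and covariates enter through $\hat\beta$.

The per-cell rule is the one a quantitative-MDR scorer uses: a cell is
**high-risk** when its summed residuals are $\ge 0$ and **low-risk**
otherwise.  We extend the subject-level "$\ge 0$" convention to the cell
sum, so an exactly-zero sum is high-risk; the paperless alternative
(strictly positive) differs only on a measure-zero event for continuous
outcomes.

## Scoring, cross-validation and selection

All scans use $F$-fold cross-validation with a seeded uniform random
partition (no stratification); the default $F = 2$ keeps the training
halves disjoint, so every predicted label is evaluated on data that played
no part in its construction.  For each fold $f$:

* cells are labeled on the training portion (all other folds);
* the **training score** is the pooled two-sample $t$ statistic (high
  minus low) on the training subjects under those labels;
* the **fold test statistic** is the same statistic on the held-out
  fold-$f$ subjects under the trained labels.

A model's reported test score combines its fold statistics as
$\sum_f t_f / \sqrt{F}$, so independent $\mathcal N(0,1)$ fold statistics
combine to an $\mathcal N(0,1)$ reference.  Within each order $k$,
selection follows classic MDR mechanics: each fold's best model maximizes
that fold's training score; cross-validation consistency counts the folds
agreeing on one model; the chosen model has the highest consistency with
ties broken by mean training score and then by model index (deterministic).
The $k$-level *cross-validated prediction statistic* accumulates each fold
winner's own held-out statistic, again combined as $\sum_f/\sqrt F$;
because each term is selected only through data disjoint from its
evaluation fold, the statistic keeps its null reference even after an
exhaustive search.  Across orders, the overall best model is again chosen
by consistency first, with the prediction statistic breaking ties: a
higher-order superset of a true pair must win both folds to displace the
pair itself, not merely edge its statistic, which keeps the *stringent*
power accounting (exact-pair recovery) close to the *flexible* one.  The survival-MDR baseline
(`survmdrSearch`) runs the identical machinery with the squared log-rank
statistic of the pooled high/low grouping as its score (signed per-fold
statistics combined, then squared, for a $\chi^2_1$ reference); by the
identity above it partitions cells exactly as the residual method does.

**Held-out subjects in untrained cells.**  With $27$ cells and a few
hundred subjects, higher-order models routinely send test subjects into
cells that were empty during training.  Three fallbacks are implemented:
`"cell"` (default) classifies the untrained cell by the sign of its own
residual sum — the same cell rule applied to the data at hand; `"self"`
classifies each subject by its own residual sign; `"low"` assigns all of
them to the low-risk pool.  The default is deliberately *not* leakage-free:
an untrained cell classified from the scored data pushes the statistic
upward, which is visible only where untrained cells are common — the
three-way scan at small $n$.  This reproduces the characteristic behavior
of the method's null calibration: one- and two-way test scores are close to
$\mathcal N(0,1)$ (Kolmogorov–Smirnov distance below 0.05 at $m = 20$,
$n = 400$, 1000 replicates) and their type-I error at the 1.6449 threshold
sits near 5%, while the three-way error is anticonservative (roughly 9–11%
at $n = 200$) and decays toward 5% as cells fill in.  Users who prefer a
strictly conservative scan can set `emptyCells = "low"`, which holds all
orders at or below their nominal level.

**Significance thresholds.**  `nullThreshold` offers the standard-normal
95th quantile (1.6449) — justified by the near-normal null of the 1-/2-way
scores — or the empirical 95th percentile (type-7 interpolation) of a
supplied set of null scores, which is the safer choice for three-way
scans.  `permutationTest` gives model-level $p$-values by permuting the
residual vector with the fold split held fixed, using the add-one
estimator $p = (1 + \#\{s_\pi \ge s\})/(1 + B)$.

## Numerical choices

* Cox partial likelihood: Newton–Raphson from $\beta = 0$, convergence at
  $|\Delta\ell| < 10^{-9}$, at most 100 iterations (error with the
  iteration count otherwise), step-halving on overshoot; collinear or
  constant covariate columns are rejected up front.
* Ties: Breslow approximation throughout — likelihood, baseline
  (Breslow estimator; Nelson–Aalen when no covariates) and residuals stay
  mutually consistent, which is what makes the residual/log-rank identity
  exact under ties.
* $\hat\Lambda_0$ beyond the last event time is carried forward flat;
  before the first event it is 0.
* The exhaustive enumeration is chunked (`chunkSize`) with per-model
  computations independent, so results are identical under any chunking.
* A zero-variance pooled split with distinct means (the noiseless
  perfect-separation limit) saturates at $\pm 10^{12}$ rather than
  dividing by zero, so a perfect model outranks every finite competitor;
  a split with one empty pooled group scores 0 (uninformative).  The
  exported `tScore` op errors on zero pooled variance instead, to keep
  misuse visible.
* Pooled-variance $t$ is the default; Welch is available (`welch = TRUE`).

## Simulation designs

**Null study** (`simulateNull`, `estimateTypeIError`): $m$ SNPs with MAF
drawn from $U(0.1, 0.5)$, genotypes Binomial(2, MAF), outcomes i.i.d.
$\mathcal N(0,1)$ independent of the genotypes.  The outcome feeds the
scorer directly — no survival layer — and the type-I error of the scan is
the fraction of null datasets whose chosen $k$-way model clears the
threshold.

**Epistatic survival study** (`makePenetrance`, `simulateEpistatic`,
`estimatePower`): a two-locus penetrance table $f_{ij} = P(\text{high
risk}\mid g_1 = i, g_2 = j)$ is generated by constrained search
(GAMETES-style) with alternating projections: a random $3\times3$
deviation table is projected onto the subspace where both
Hardy–Weinberg-weighted marginals vanish (no main effects at either
locus), rescaled so the broad-sense heritability
$h^2 = \sum_{ij} p_i q_j (f_{ij} - K)^2 / (K(1-K))$ hits its target, and
clipped to the probability box, cycling until all constraints hold
simultaneously.  Feasibility is a real issue at the corners of the design
grid: at MAF 0.2 no prevalence supports $h^2$ much above 0.43, and a
balanced prevalence ($K = 0.5$) caps it near 0.3.  The generator
therefore searches a prevalence grid from 0.5 downward and records the
$K$ it used — 0.5 for 13 of the 14 (MAF, $h^2$) design cells and 0.40
for the tight MAF 0.2 / $h^2 = 0.4$ cell.  Because subjects are
rejection-resampled to exactly $n/2$ per risk class, downstream
quantities do not depend on $K$.  A fresh table is drawn per replicate,
so power averages over penetrance-model variability as well as sampling
noise.

Event times follow a Weibull baseline with shape 5 and scale 2 under
proportional hazards, $S(t \mid x) = \exp\{-(t/2)^5 e^{\beta x}\}$ with
$x$ the risk-class indicator; censoring times are uniform on $(0, 4)$,
independent of everything else.  The class effect defaults to
$\beta = 1.5$: under this design the expected censoring fraction is
$\tfrac12\!\left[\tfrac14\!\int_0^4 e^{-(c/2)^5}dc +
\tfrac14\!\int_0^4 e^{-e^{1.5}(c/2)^5}dc\right] = 0.3996$, i.e. the 40%
censoring the design targets — which is how $\beta$ was fixed, before any
power considerations; it is one global value, not tuned per heritability
cell.  ES-MDR consumes the martingale residuals of the covariate-free
null fit; the survival-MDR comparator consumes time/status directly with
the same genotypes and fold seed.  Power is the fraction of replicates in
which the overall best model contains both functional SNPs — exactly
(*stringent*) or with at most one extra SNP in a three-way model
(*flexible*) — **and** clears the 0.05-level threshold (1.6449 for the
$t$-scale score, $\chi^2_1$ 95th quantile for the squared log-rank).

**Problem sizes.**  The shipped validation uses $m = 20$ with 1000 null
replicates per sample size ($n = 200$ to $3200$), 100 power replicates per
(MAF, $h^2$) cell at $n = 1600$, and 20 end-to-end pipeline runs at
$m = 200$, $n = 2000$ — sizes chosen so the full suite re-runs from
scratch in minutes on a single core while keeping Monte-Carlo standard
errors below a percentage point for the null rates and about 3–5 points
for power cells.

## The prediction pipeline

`runPredictionPipeline` mirrors the applied analysis chain: greedy
windowed LD pruning at $r^2 > 0.1$ (map order, configurable window); a
seeded 2/3–1/3 split; covariate-adjusted residuals on the training set; an
exhaustive 1-/2-way scan; pooling of all SNPs in the top-ranked models
(ranked by test score, deduplicated); lasso-penalized Cox selection with
the penalty chosen by 10-fold cross-validated partial likelihood
(`glmnet`), adjustment covariates unpenalized; and held-out evaluation by
cumulative/dynamic time-dependent ROC/AUC (Kaplan–Meier form of the
Heagerty–Lumley–Pepe estimator, no smoothing) plus Kaplan–Meier risk
stratification with a covariate-adjusted hazard ratio.

One design choice deserves emphasis: the lasso design matrix carries, in
addition to the pooled SNP dosages, the trained high/low risk attribute of
the top two-way models (default 10, one binary column per model).  A
purely epistatic pair is marginally null by construction, so no additive
dosage selection could ever retain it; its risk attribute, in contrast, is
exactly the one-dimensional variable the MDR reduction was built to
expose.  Selecting a pair attribute reports both member SNPs.  At
prediction time, test subjects falling in cells untrained at the pipeline
stage are assigned low-risk: unlike the scan-internal fallback, prediction
must not consult the held-out outcomes.

The time-dependent ROC at horizon $t$ uses cumulative cases and dynamic
controls: $\mathrm{sens}(c,t) = \Pr\{f(X) > c \mid \text{event by } t\}$
and $\mathrm{spec}(c,t) = \Pr\{f(X) \le c \mid \text{event-free at } t\}$,
estimated by Bayes-combining Kaplan–Meier survival within the two score
strata with the marginal KM; the AUC is the trapezoid along the cutoff
sweep and is invariant to monotone transforms of the score.  In the
uncensored case the estimator reduces exactly to case/control pair
counting, which is the oracle the tests compare against.  Horizons before
the first event leave the ROC undefined; the function warns and returns
`NA`.

## What the simulations do and do not emulate

The generators reproduce the statistical skeleton of an age-of-onset
interaction study: independent common variants, Hardy–Weinberg genotypes,
pure epistasis at controlled heritability, proportional-hazards event
ages, uniform interview-age censoring, and (in the pipeline scenario)
small LD blocks, a binary smoking-type covariate, and planted main-effect
and interaction signals.  They do not emulate realistic genome-wide LD
structure, population stratification, genotyping error or missingness
patterns, rare variants, non-proportional hazards, informative censoring,
or case–control ascertainment — so green simulations certify the
machinery and its calibration under the stated model, not robustness to
those complications.  Known limitations inherited from the method itself:
residuals discard the variance information of the log-rank statistic
(weighting residuals by follow-up is a natural extension); the three-way
scan needs the empirical threshold at moderate $n$; and the per-model
subject exclusion under missing genotypes can make scores across models
refer to slightly different subject sets.

## A small worked run

```{r example, eval = FALSE}
pm <- makePenetrance(maf = 0.4, h2 = 0.3, seed = 1)
gse <- simulateEpistatic(pm, n = 400, seed = 2)
res <- esmdrSearch(gse, k = 1:2, seed = 3)
bestModel(res)            # the functional pair, with its CV statistic
estimatePower(maf = 0.4, h2 = 0.3, n = 400, reps = 50, seed = 4)
```
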