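---
title: "Partially synthetic pooling: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partially synthetic pooling: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`synthpool` implements a complete partial-synthesis workflow for pooling
two countries' harmonized health-survey tables when one table cannot be
shared: synthesize country A, assess its disclosure risk, pool m
synthetic replicates with country B's real data, run the regression
analysis on each pooled replicate, combine across replicates with
variance rules that account for synthesis noise, and validate the whole
chain against a federated least-squares fit of the two real tables. This
vignette explains each component's model, its tunable parameters, and the
design choices made where more than one reasonable construction exists.

## The sequential generative model

Variables are synthesized one at a time in a fixed order; each variable
is modelled conditional on all variables earlier in the sequence, and
sampling proceeds in the same order, so the joint distribution is built
up as a product of fitted conditionals. The first variable is stored as
its empirical marginal and resampled directly.

Each conditional is a gradient boosted decision tree (via `xgboost`,
single-threaded for reproducibility). Categorical targets are fitted as
(multi)classifiers with instance weights inversely proportional to class
frequency, so minority levels are not washed out; continuous targets are
fitted as regressors on their normal scores (below). Default
hyperparameters are `nrounds = 60`, `max_depth = 3`, `eta = 0.3`,
`min_child_weight = 5` — shallow, moderately boosted trees that fit
tabular survey conditionals well without memorizing rows.

**Hyperparameter search.** With `tune_trials > 0`, each conditional's
hyperparameters are chosen by sequential model-based optimization: a
Latin-hypercube initial design over (`nrounds`, `max_depth`, `eta`,
`min_child_weight`) — the last three on a log scale — each candidate
scored by 5-fold cross-validated log-loss (classifiers) or squared error
(regressors), then a random-forest surrogate proposes the next candidate
with the lowest predicted loss from a fresh candidate pool. The default
budget is 25 trials per variable; the pipeline default is
`tune_trials = 0` (the documented fixed parameters), which keeps a full
desk-scale study under a minute while leaving tuning one configuration
switch away. The search is deterministic given the seed.

**Probability calibration.** Boosted trees do not emit calibrated
probabilities, and minority-class weighting distorts them further, so
sampling categorical values from raw scores would bias every downstream
marginal. Each class's probability is therefore passed through a beta
calibration map $\mu(p) = \mathrm{logit}^{-1}(c + a\log p - b\log(1-p))$,
fitted by maximum-likelihood logistic regression of the observed outcome
on $(\log p, -\log(1-p))$. Three numerical details: probabilities are
clipped to $[10^{-6}, 1-10^{-6}]$ before taking logs; maps are fitted on
out-of-fold (cross-validated) predictions only, never on training-fold
predictions, which would give optimistic maps; and if the unconstrained
fit returns a negative $a$ or $b$ (a non-monotone map), the model is
refitted on the single feature $\log(p/(1-p))$, falling back to an
intercept-only map (the base rate) in the degenerate case. Multiclass
targets are calibrated one-vs-rest and renormalized to unit row sums —
the binary mechanics are standard, the multiclass extension is this
package's choice.

**Continuous variables.** Each continuous variable is mapped through its
empirical CDF and the standard-normal quantile function,
$\Phi^{-1}(F(x))$, modelled on that Gaussian scale, and back-transformed
after synthesis by $F^{-1}(\Phi(\hat x))$ with linear interpolation
between support points. The empirical CDF uses the $\mathrm{rank}/(n+1)$
convention so extreme observations map to finite scores; the inverse
clips to the observed training range. Boosting yields point predictions
only, so sampling noise is injected by adding a residual drawn with
replacement from the model's out-of-fold residual pool before
back-transforming — a choice made here, since nothing in the boosted
regression itself provides a noise model.

**Missing values.** Categorical missingness is synthesized as an explicit
extra level and restored to true missing cells on output; continuous
missingness via a synthesized yes/no indicator followed by a value model
trained on observed rows. Missingness therefore propagates into the
synthetic replicates at realistic rates and can itself depend on earlier
variables.

**Ordering.** The default order is schema order. An opt-in greedy
heuristic (`order = "auto"`) starts from the lowest-entropy variable and
repeatedly places the remaining variable most predictable from those
already placed (by CV loss); it is logged when used. The sequence
optimizer of the method this package follows is not publicly specified,
so the heuristic is deliberately separate from the default path.

**Determinism.** Every stage derives child seeds from the master seed via
a fixed integer recurrence (all below $2^{31}$); replicate $i$ is seeded
by $(\text{seed}, i)$, so replicates are mutually independent yet
individually reproducible, and `(data, order, config, seed)` fixes every
synthetic cell. A model saved with `save_synthesis_model()` (JSON
metadata plus base64 ensemble blobs, doubles at 17 significant digits)
reloads to bit-identical sampling.

## Combining rules

Partial synthesis — only country A's table is replaced — requires its own
variance rules. For a parameter estimated as $q_i$ with variance $v_i$ on
pooled replicate $i = 1\dots m$:

$$\bar q_m = \tfrac1m\sum_i q_i,\quad
  \bar v_m = \tfrac1m\sum_i v_i,\quad
  b_m = \tfrac{1}{m-1}\sum_i (q_i - \bar q_m)^2,\quad
  T_p = b_m/m + \bar v_m,$$

with 95% interval $\bar q_m \pm 1.96\sqrt{T_p}$ and a normal-reference
p-value. Inference is large-sample with the 1.96 multiplier and no
small-m degrees-of-freedom correction. `combine()` refuses $m = 1$
explicitly: with a single replicate there is no between-replicate
variance and the caller should use single-dataset inference. The default
study uses $m = 5$ at desk scale; $m = 10$ is conventional for synthetic
data analysis and is one configuration edit away.

## Membership disclosure

The privacy metric is an attack simulation: an adversary holding a
target's quasi-identifiers and the synthetic release predicts "member of
the training data" iff some synthetic record lies within distance $h$ of
the target. Distance is the mean per-variable distance over
quasi-identifiers (categorical: 0/1 mismatch; continuous: absolute
difference scaled by the synthetic range, capped at 1). The F1 of that
prediction is compared with the naive strategy of calling everyone a
member: `relative_f1 = f1 − naive_f1`. Near-zero relative F1 means the
synthetic data adds nothing to the adversary's prior; a memorizing
synthesizer scores `1 − naive_f1`.

The published description of this metric leaves the distance, threshold
and target mix to supplementary material, so the package exposes them as
configuration and defaults to the strictest, most reproducible choices:
quasi-identifiers = the seven demographic variables, $h = 0$ (exact
match), a 50/50 member/non-member target mix, and a plain Hamming-style
distance rather than weighted record linkage. With multiple replicates
the attack runs per replicate and reports the mean. At desk scale the
non-member pool is drawn from the simulator's population generator,
standing in for a fresh population sample.

## Federated least squares

The ground truth is the pooled OLS fit of the two real tables, computed
without moving rows: each node shares only $X'X$, $X'y$, $y'y$ and $n$
over complete cases, and the pooled solve
(`solve_federated()`) reproduces the row-concatenated fit exactly —
coefficients, variances and $R^2$ agree with a direct `lm()` to $10^{-8}$
relative, for any partition of the data. Rank-deficient pooled designs
fall back to a pseudo-inverse with an explicit aliasing warning.

Analysis codings are centralized in `code_analysis_data()`: sex
(ref male), marital-status dummies (ref single), immigrant (ref no),
country (ref CA), age as ordinal score 1–7, household size 1–5, education
1–4, and household income reverse-coded (high = 1 … low = 3) so its
coefficient reads "effect of lower income". Single-coefficient reporting
of age, education and household size implies ordinal scores rather than
dummies; that reading is adopted here and kept in one place so it can be
changed once. Models are complete-case per model. The interaction layer
crosses every predictor with country alongside all main effects.

## Utility surface

Balance uses the standardized mean difference with the conventional 0.1
imbalance threshold, computed per replicate against the real pooled table
and averaged. Continuous/ordinal variables use
$|m_a-m_b|/\sqrt{(s_a^2+s_b^2)/2}$; binary variables the same with
Bernoulli variances; multi-level categoricals a Mahalanobis-type distance
on the level-proportion vectors (one level omitted, pooled multinomial
covariance), giving one number per variable to mirror a one-row-per-
variable balance table. Reports are produced overall and within sex
strata; neither is asserted to be the only correct stratification.

Regression concordance is operationalized as three per-coefficient flags:
sign agreement (same side of zero, or both intervals covering zero),
significance agreement at uncorrected $p < 0.05$, and CI overlap. The
underlying comparison in the literature is narrative; fixing these flags
makes it testable.

## The survey simulator

Real microdata for this use case is restricted, so the package carries a
simulator that emulates its published structure: two countries with the
twelve harmonized variables, demographic marginals and per-sex
prevalences of the four cardiometabolic risk factors matching the
published baseline tables, and per-variable missing-completely-at-random
rates matching the published per-variable respondent counts. Risk factors
follow a logistic model in sex, age score, income score and education
score; the intercept and sex coefficient are calibrated by root-finding
so the implied per-sex prevalences hit the targets exactly given the
covariate slopes. The slopes themselves are documented package defaults
chosen once as epidemiologically plausible gradients (hypertension and
diabetes rising steeply with age; smoking falling with education and
income; normal BMI falling with age), since the true dependence structure
of the source surveys is unobservable: hypertension `age = 0.75`,
diabetes `age = 0.65`, smoking `education = −0.25, income = −0.20`, BMI
`age = −0.35, education = 0.15`, with the remaining slopes between −0.10
and 0.15. Age enters models as an ordinal score 1–7; BMI is simulated
directly as the binary "< 25" indicator used by the index, with an
optional continuous BMI column to exercise the continuous synthesis path;
"< 25" counts as ideal with no separate underweight handling.

What the simulator does *not* emulate: survey design weights,
stratification and clustering; informative (non-MCAR) missingness;
dependence among demographic variables (they are drawn independently);
and any within-household correlation. Passing end-to-end tests therefore
demonstrates that the pipeline preserves logistic dependence of outcomes
on demographics and recovers regression conclusions under these
conditions — not that it would survive arbitrarily complex real survey
structure.

## Problem sizes and numerical choices

The default study sizes are desk scale, chosen so a full run (simulate,
fit, generate, attack, analyze, compare) completes in well under a
minute: synthesize n = 20,000, pool with n = 5,000 real, m = 5
replicates, 1,000 attack targets. End-to-end validation uses ten seeded
runs at these sizes; sign agreement with the federated oracle is required
for every coefficient whose oracle magnitude is at least 0.1 on the
outcome scale (smaller effects are attenuated by synthesis noise and
their signs are not stable in any method at these n). Other fixed
numerical choices: probability clipping at $10^{-6}$; the
$\mathrm{rank}/(n+1)$ CDF convention with averaged ranks for ties;
normal-score inverse clipping to the training range; CV folds assigned by
seeded permutation; `xgboost` run with `nthread = 1` and explicit seeds.

## Known limitations

Only one synthesis engine (boosted trees) is provided; no
differential-privacy noise, no generative neural networks, and no
fully-synthetic combining rules (the partial-synthesis rules here assume
the partner table is real). The attack is a nearest-record
quasi-identifier attack only — attribute disclosure is out of scope. The
federated solver covers identity-link least squares, which is what the
cardiovascular-health analysis uses; generalized linear models would need
iterated interim exchanges and are not implemented.
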