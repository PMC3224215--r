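---
title: "Two-step L1/L2 regularized linear models for peptide QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step L1/L2 regularized linear models for peptide QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(twostepQSAR)
library(dplyr)
```

## The problem and the model

Binding-affinity regression for short peptides (for example 8–9-mer
epitopes binding MHC class I molecules) routinely lives in the
small-n/large-d regime: on the order of 100 peptides with measured pIC50
values, described by thousands of features once every residue is encoded
with every available amino-acid property. A dense linear model would have
far more parameters than observations; without aggressive feature
selection it memorizes the training set.

This package fits a linear scoring function

$$f(\vec{x}) = \vec{w}^{t} \vec{x} + b$$

by minimizing the regularized objective

$$L(\vec{w}, b) \;=\; \frac{1 - \lambda_1 - \lambda_2}{N}
  \sum_{i=1}^{N} \mu_i\, g\!\left(f(\vec{x}_i), m_i\right)
  \;+\; \lambda_1 \sum_j |w_j| \;+\; \lambda_2 \sum_j w_j^2 ,$$

where $m_i$ is the measured pIC50 of peptide $i$, $\mu_i$ optional
per-sample weights (default 1), and the loss is by default the robust
logarithmic ("soft") loss

$$g(f, m) = \log\!\left(1 + (f - m)^2\right),$$

which grows so slowly in the residual that single outliers cannot
dominate the fit ($g \le (f-m)^2$ everywhere). The bias $b$ is never
penalized.

Training is a two-step procedure:

1. **Stage 1 — selection.** Fit with an L1 penalty only
   ($\lambda_2 = 0$). The L1 term drives the weights of irrelevant and
   redundant features toward zero; every feature whose absolute weight
   ends below the threshold $10^{-8}$ is discarded.
2. **Stage 2 — model building.** Refit on the surviving features with a
   milder L2 penalty only ($\lambda_1 = 0$). This removes the downward
   bias the L1 penalty imposed on the weights that carry real signal.

Both strengths are chosen by $k$-times repeated $n$-fold cross
validation, by default $5 \times 10$-fold over the candidate grids
$\lambda_1 \in \{0.001, 0.005, 0.01, 0.05, 0.08, 0.1, 0.2, 0.3\}$ and
$\lambda_2 \in \{0.0001, 0.001, 0.01, 0.1, 0.2, \dots, 0.9, 0.93\}$.

## Feature encoding

Each peptide of fixed length $L$ is encoded by concatenating three
blocks, in this order:

* **physico-chemical**: each residue contributes the $P$ property values
  of its letter from a descriptor table ($P \cdot L$ features);
* **sparse**: one-hot sub-vectors of 24 components per residue — the 20
  standard amino acids in the order `ACDEFGHIKLMNPQRSTVWY`, then the
  placeholder codes `*`, `B`, `X`, `Z` ($24 \cdot L$ features);
* **BLOSUM62**: each residue contributes its 24-entry row of the NCBI
  BLOSUM62 substitution matrix, injecting pairwise chemical similarity
  ($24 \cdot L$ features).

The combined dimension is $d = (P + 48)\,L$: with the classic
643-property collections this gives 6219 features for 9-mers and 5528
for 8-mers.

```{r dimensions}
tab <- simulate_descriptor_table(n_properties = 643, seed = 1)
X <- build_feature_matrix(simulate_peptides(5, 9, seed = 1), tab)
dim(X)
```

Features are normalized with training-set statistics: columns whose
training standard deviation is below $10^{-12}$ (a tolerance absorbing
floating-point noise in constant columns) are dropped — this removes the
placeholder one-hot columns and the constant `X`/`*` BLOSUM columns —
and the rest are shifted and scaled to mean 0, standard deviation 1.
The standard deviation uses the population convention (denominator $n$);
the convention is recorded in saved models so results are reproducible.
Test data are always transformed with the training parameters, never
their own.

## The optimizer

The soft loss plus L1 penalty has no closed-form minimizer, and the L1
term's derivative is undefined at zero. Both issues are sidestepped by
resilient propagation (Rprop, here the iRprop⁻ variant with the standard
constants $\eta^+ = 1.2$, $\eta^- = 0.5$): each parameter keeps a private
step size that grows while its partial derivative keeps its sign and
shrinks when the sign flips (on a flip the stored derivative is zeroed,
so the parameter sits out one iteration), and parameters move by
$-\operatorname{sign}(\partial L) \cdot \text{step}$. Because only the
gradient's sign is used, the kink of the L1 term is harmless: the
subgradient convention $\operatorname{sign}(0) = 0$ lets a weight leave
zero only when the data gradient pushes it.

Numerical choices that matter:

* **Initialization**: $w = 0$, $b = \overline{m}$ — deterministic and on
  the scale of the data. Rprop contains no randomness, so a fit is a pure
  function of its inputs.
* **Steps**: initial 0.1, cap 50, floor $10^{-9}$ — one decade below the
  selection threshold, so that a weight oscillating around zero anneals
  into the $\pm 2\times10^{-9}$ band, safely below the $10^{-8}$ cut.
* **Stopping**: the fit stops when the objective changes by less than
  $10^{-10}$ over an iteration *and* the steps actually taken have
  annealed to the floor scale. The second condition is essential: an
  iteration in which every parameter sits out leaves the objective
  unchanged far from any minimum, and weights oscillating symmetrically
  about zero under a strong L1 penalty change the objective by almost
  nothing while their amplitude is still above the selection threshold.
* **Iteration budgets**: standalone fits default to a 30000-iteration
  cap. Converged fits stop far earlier (typically a few hundred
  iterations), but at the smallest grid value $\lambda_1 = 0.001$ the
  annealed solution needs tens of thousands of the cheap sign-step
  iterations; stopping a small-$\lambda_1$ fit at 2000 iterations leaves
  several times too many features above the threshold, which breaks the
  selection semantics. Inside the cross-validation loops a coarser
  2000-iteration budget (`run_config(cv_optimizer = )`) is used instead:
  there only the *ranking* of candidates matters, and the
  $k \cdot n \cdot |\text{grid}|$ fits dominate the total cost. Both
  budgets are exposed and recorded in saved models.
* **Best-seen iterate**: the returned model is the best-objective
  iterate encountered (the start included), guarding against terminal
  oscillation.
* The reported `final_objective` is exactly the R-level
  `objective_value()` at the returned model; the test suite asserts
  this, tying the compiled optimization path to the package's reference
  objective.

For the squared loss with an L2 penalty the minimizer is available in
closed form via Cholesky factorization of the centered normal equations
(`ridge_closed_form()`, bias unpenalized). It exists as the package's
primary correctness oracle: Rprop run on the same quadratic problem must
land on the same point, and the test suite checks agreement to
$10^{-4}$ across random problems. A singular system (collinear features
with $\lambda_2 = 0$) raises an error advising $\lambda_2 > 0$.

On the penalty form: the package uses $\sum_j |w_j|^p$ — the p-th
*power* of the p-norm — matching the standard Lasso/ridge forms and
keeping the L2 gradient linear. The literal-norm alternative
$(\sum |w_j|^p)^{1/p}$ remains available via
`penalty(w, p, form = "norm")` for comparison, but the optimizer runs on
the standard form.

## Cross validation

`cross_validate_lambda()` evaluates each candidate on every
(repeat, fold) cell: the normalizer is refit on the fold-training
portion (avoiding information leakage; a `"global"` flag reproduces the
leaky alternative for comparison), the model is trained at the candidate
strength, and the validation error is the mean training-loss function on
the held-out part — keeping selection consistent with the objective
being optimized (a $1 - q^2$ criterion is available behind
`validation = "q2"`). Ties go to the larger, more conservative lambda.
Fold shuffles derive from one master seed (stage-1 CV uses `seed`,
stage-2 CV `seed + 1`), so the entire pipeline is reproducible from
`(data, descriptors, config)`.

The stage-2 grid is applied to the submatrix of features selected on the
full training set, as the two-stage narrative prescribes. Note the
subtlety this inherits: the selection itself saw all training samples,
so stage-2 validation errors are mildly optimistic; an unbiased
performance estimate requires an external test set (which is how the
method is meant to be assessed).

## The synthetic-data generator

`simulate_regression_dataset()` emulates the regime the method targets:
random fixed-length peptides over the 20 standard letters, a synthetic
descriptor table with standard-normal property values (optionally with a
fraction of near-duplicate columns, correlation about 0.99, emulating the
strong redundancy of literature property collections), and targets

$$m_i = b_0 + \vec{w}_{\text{true}}^{\,t} \vec{x}_i + \varepsilon_i,
 \qquad \varepsilon_i \sim \mathcal{N}(0, \sigma^2),$$

with a sparse $\vec{w}_{\text{true}}$ planted on randomly chosen columns
of the *normalized* combined feature matrix (so effect sizes are
comparable across encoder blocks; real pIC50 targets are of course not
generated this way) and $b_0 = 6$, a typical pIC50 magnitude. A
train/test range-mismatch scenario adds a constant to the test targets
only, reproducing the situation where $q^2$ collapses below zero while
the rank correlation stays high because the training set is not a
representative sample of the prediction set.

The reference problem sizes used by the package's own checks are chosen
to be small but in-regime: $n = 100$ nona-peptides with an 8-property
table ($d = 504$), 5 planted coefficients of magnitude 1, noise standard
deviation 0.1 for recovery checks; $n = 80$ with a 50-property,
redundancy-0.5 table ($d = 882$) for the sparsity sweep; 20 (tests) or 5
(acceptance script) seeds for rate estimates.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: real amino-acid property values and their
block structure, binding motifs (position-specific preferences), and,
importantly, *diffuse* signal. In the generator the truth is exactly
sparse: every feature outside the planted support is pure noise by
construction. On such data the stage-1 L1 model is hard to beat — its
shrinkage of the not-quite-discarded noise features is exactly right —
and the package's checks find stage-2 refits performing on par with
stage 1 (differences of a few $10^{-3}$ in held-out $q^2$, with no
systematic sign at low noise, and in stage 1's favor at high noise). The
stage-2 improvement reported on real peptide data plausibly rests on
redundant, weakly informative features that all carry some signal —
a structure the planted-sparse generator deliberately lacks. The
two-step procedure is still the right default: stage 2 never costs much,
and on real data the refit removes the L1 bias from features that do
matter.

## Worked example

```{r example}
descriptors <- simulate_descriptor_table(n_properties = 8, seed = 2)
sim <- simulate_regression_dataset(
  n = 100, length = 9, descriptors = descriptors,
  support_size = 5, effect_size = 1, noise_sd = 0.1,
  seed = 2, n_test = 50
)
fit <- fit_two_step(sim$train, descriptors, run_config(seed = 2))
fit
glance(fit)

# did stage 1 find the planted features?
all(sim$truth$informative_features %in% fit$selected_features)

# held-out performance
pred <- predict(fit, sim$test)
evaluate_predictions(inner_join(sim$test, pred, by = "id"))
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(fit$cv1)
autoplot(fit)
```

## Known limitations

* Fixed-length peptides only; no alignment, no variable-length support.
* $\lambda_1$ and $\lambda_2$ are chosen sequentially, not on a joint
  2-D grid; the stage-2 grid never revisits the selection.
* Rprop approximates the L1 optimum; weights are thresholded at
  $10^{-8}$, not set exactly to zero. The test suite checks the
  resulting support against an exact coordinate-descent Lasso
  (glmnet) at matched penalty scaling on the squared-loss analogue.
* Cross-validation error estimates for stage 2 inherit the selection
  optimism described above; use an external test set for honest
  performance numbers.
* The redundancy of real descriptor collections makes the *identity* of
  the selected features unstable across $\lambda_1$ values even when
  predictive performance is stable; selected feature lists should be
  interpreted with that in mind.
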