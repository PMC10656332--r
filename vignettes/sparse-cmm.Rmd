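---
title: "Marginal models on sparse contingency tables: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal models on sparse contingency tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmmael)
```

## The model

A categorical marginal model (CMM) constrains marginal functions of a
multinomial contingency table without modelling the joint dependence of the
variables.  With `N` respondents on `J` categorical items (scores
`0..c_j - 1`), the cell counts **n** of the `J`-way table are assumed
multinomial with expected frequencies **m**, and the model is

$$\mathbf{g}(\mathbf{m}) = \mathbf{B}'\,\mathbf{f}(\mathbf{A}'\mathbf{m}) = \mathbf{0},$$

where $\mathbf{A}'\mathbf{m}$ collects marginal frequencies, $\mathbf{f}$ is
a smooth link with analytic Jacobian, and $\mathbf{B}'$ has full row rank
$D$.  The constrained maximum-likelihood fit $\hat{\mathbf{m}}$ maximizes
$\sum_i n_i \log m_i$ subject to $\mathbf{g}(\mathbf{m}) = \mathbf{0}$ and
$\sum_i m_i = N$; the deviance
$G^2 = 2\sum_i n_i \log (n_i/\hat m_i)$ is asymptotically
$\chi^2_D$ when the model holds.  When $\mathbf{B}$ has an orthogonal
complement $\mathbf{Z}$ (a design matrix of full column rank), the model
parameter $\beta = (\mathbf{Z}'\mathbf{Z})^{-1}\mathbf{Z}'\mathbf{f}(\mathbf{A}'\mathbf{m})$
is recoverable with delta-method standard errors.

Three model families are built in.

* **Mean** (`mean_model()`): equality of the $J$ item means, i.e. marginal
  homogeneity of the item margins for binary items.  Identity link on the
  mean numerators, successive-difference $\mathbf{B}'$, $D = J - 1$,
  $\mathbf{Z} = \mathbf{1}/\sqrt{J}$.  Two scalings of the parameter are
  reported deliberately: $\beta = \sum_j f_j/\sqrt{J}$ (the projection onto
  the normalized constant column) and the *overall mean item score*
  $\sum_j f_j/(JN)$; both appear in the fit object because either scaling
  is used in practice and neither is canonical.
* **Alpha** (`alpha_model()`): Cronbach's alpha equals a benchmark,
  $D = 1$.  Alpha is computed from first- and second-order marginal
  moments with divisor $N$ (the ML convention of the multinomial
  framework; users expecting the $N-1$ divisor will see slightly smaller
  item variances).  For binary items the margin set is reduced to
  $\{j{=}1\}$ and $\{j{=}1,k{=}1\}$; complements are recovered as
  $m^j_0 = N - m^j_1$.
* **H_j** (`hj_model()`): every Mokken item-scalability coefficient equals
  a lower bound, $D = J$ for dichotomous items.  $H_j$ is one minus the
  ratio of observed to expected-under-independence Guttman errors over the
  pairs involving item $j$; for an ordered pair $(i, j)$ the error cell is
  $\{i{=}0, j{=}1\}$.  By default items are taken **in the order given**:
  this reproduces sample values computed by applying the defining formula
  to the items as listed, which is also how the worked three-item example
  is usually quoted even though its items are not in ascending popularity.
  `item_order = "popularity"` re-sorts items by ascending sample
  popularity (the textbook assumption), and an explicit permutation gives
  full control.  For $J = 2$ the two constraints are one function; the
  duplicate is detected and collapsed to $D = 1$ with a warning.

Custom linear models are specified with `cmm_model()` (margin cells plus a
dense $\mathbf{B}'$), and serialize to YAML.

## Sparse support: ML, MEL, MAEL

The table is stored as its *support* — the list of patterns with positive
count — so the full $L = \prod_j c_j$ cells are never materialized
(`sparse_table()`).  ML estimation needs all $L$ cells and is guarded by a
materialization cap (default $10^7$ cells).  MEL restricts the likelihood
to the observed cells, treating zero cells as structural zeroes.  On sparse
tables MEL runs into two distinct failures:

* the **first-order (empty-set) problem** — no $\mathbf{m}$ on the
  restricted support satisfies the constraints.  For linear links this is
  decided exactly by linear-programming feasibility (via `boot::simplex`,
  with rank-pruning of dependent constraint rows); for nonlinear links a
  heuristic is used (constraints with identically vanishing Jacobian but
  nonzero value are certainly infeasible; otherwise a penalized feasibility
  search from random starts), so the status may be `"undetermined"`.
* the **second-order problem** — the multinomial covariance of the
  constraint statistics, $V = G\,(D_m - \mathbf{m}\mathbf{m}'/N)\,G'$
  evaluated at the uniform distribution over the support, is
  rank-deficient (smallest/largest eigenvalue below $10^{-10}$), so
  inference is impossible even when a fit exists.  The covariance is taken
  over the model constraints only: the total-count row is excluded because
  the multinomial covariance annihilates it identically.

MAEL augments the observed support with zero-count cells before fitting
(`augment_support()`).  Level `"first"` covers every cell of every marginal
distribution the model constrains — including the complement cells that the
reduced binary margin sets leave implicit; a support on which, say, one item
is constant would otherwise leave the constraints infeasible off the
boundary.  Level `"second"` (the default) additionally covers the bivariate
distributions of all pairs of constrained variables (the covariance
margins), then draws uniformly random zero cells until the rank test
passes, up to a cap of $50D + 100$ additions.  Every random draw flows
through one seed recorded in the plan, so augmentations replay exactly.

## The solver

Fitting is Fisher scoring on the Lagrangian (the classical treatment of
equality-constrained multinomial likelihoods): with $\tilde{\mathbf{g}}$
and $\tilde{G}$ the constraints and Jacobian extended by the total-count
row, each iteration solves
$(\tilde G D_m \tilde G')\lambda = \tilde{\mathbf{g}}(\mathbf{m}) + \tilde G(\mathbf{n} - \mathbf{m})$
and steps towards the candidate
$\mathbf{m}^+ = \mathbf{n} - D_m \tilde G'\lambda$, halving the step until
the iterate stays above the frequency floor ($10^{-12}N$) and an
$\ell_1$-penalized likelihood merit does not worsen.  Numerical choices
that matter:

* **Starting values** are uniform, $m_i = N/|\text{support}|$; the maximum
  iteration count defaults to 1000.
* **Convergence** requires $\max|\tilde{\mathbf{g}}| < 10^{-8}N$ together
  with either a settled iterate ($\max|\Delta m| < 10^{-8}N$) or a
  stationary log-likelihood over three successive iterations.  The second
  clause exists because cells with zero observed count decay geometrically
  towards the boundary: they never stop moving in absolute terms, yet they
  are likelihood-neutral and the constraints are already met.
* **Oscillation damping**: when the scoring direction reverses against the
  previous step, the initial step size is halved.  The full scoring map can
  fall into period-2 limit cycles on strongly-distorted fits (e.g. forcing
  a benchmark far from the sample value); damping collapses them.
* **Boundary handling**: cells are floored at $10^{-12}N$ for the weight
  matrix inversion; cells below $10^{-6}N$ are flagged as boundary cells
  (the geometric decay stalls above the hard floor, so the flag threshold
  must be looser than the floor).  If a *positive* count faces a boundary
  expected frequency, $G^2$ is reported as `Inf` and the value computed at
  the floored frequencies is kept separately as `G2_truncated`: any finite
  number printed for such a fit is an artifact of where a solver stops, and
  is deliberately not treated as reproducible.
* **Degrees of freedom** are always the number of constraints $D$,
  unreduced by structural zeroes or boundary cells.
* If the scoring equations are singular at the start, the fit signals a
  classed error — `cmm_first_order_error` when the empty-set check says the
  constraints are infeasible, otherwise `cmm_second_order_error` — so
  simulation harnesses can classify failures without string matching.

Standard errors use the constrained asymptotic covariance
$\mathrm{Cov}(\hat{\mathbf{m}}) = D_{\hat m} - D_{\hat m}\tilde G'(\tilde G D_{\hat m}\tilde G')^{-1}\tilde G D_{\hat m}$
(the total-count row included, which reduces to the multinomial covariance
$D_m - \mathbf{m}\mathbf{m}'/N$ for the saturated model), propagated
through the link Jacobian.  The Monte-Carlo agreement of these standard
errors with the replication SD of the estimate is itself a test in the
suite (15% relative tolerance).

## The synthetic-data generator

Null populations are built in three steps (`twopl_sample()`,
`build_population()`): draw a base table of 1000 response patterns from a
two-parameter logistic IRT model (standard-normal trait,
$P(X_j = 1\mid\theta) = \mathrm{logit}^{-1}(a_j(\theta - b_j))$), fit the
CMM of interest to it (ML for small tables, MAEL otherwise), and use
$\hat{\mathbf{m}}/N$ as the data-generating probabilities.  By
construction the population satisfies the model constraints to solver
tolerance — the suite checks $|\mathbf{g}| < 10^{-6}N$ — so Type I error
studies are genuine null experiments *regardless* of the 2PL parameters.
The defaults (discriminations 1.5, locations equally spaced on
$[-1.5, 1.5]$) were chosen once as a realistic difficulty spread for a
moderately discriminating scale; they shape the sparsity pattern and the
power of nothing, because the constraints are imposed exactly afterwards.
`thin_zeros()` randomly zeroes a fraction $U$ of the population cells and
rescales — such thinned populations need no longer satisfy the model and
are used only for convergence studies.

What the generator does *not* emulate: real test data have local
dependence, drifting item parameters, missingness and response styles.
Passing calibrations here show the estimator is correct under multinomial
sampling from a constrained population, not that any particular scale in
the field satisfies the constraints.

## Study sizes in the test suite

The packaged calibrations are scaled-down versions of full simulation
studies, sized so the whole suite runs comfortably on one CPU while the
Monte-Carlo error remains decisive for each assertion:

* Type I error of the MAEL deviance test, Mean model, $J = 4$, $N = 250$:
  1000 replications, asserted inside the binomial 95% band
  $[0.036, 0.064]$ around the nominal 0.05.
* The liberal inflation with many degrees of freedom (H_j model,
  $J = 40$, $N = 250$, about 6 observations per degree of freedom):
  200 replications, asserted above 0.064 — the true rate in this regime is
  several times the nominal level, so 200 replications are ample.
* $1/\sqrt{N}$ contraction of the mean-score estimate across
  $N \in \{250, 500, 1000\}$: 800 replications per size, ratio per
  doubling asserted in $[1.3, 1.55]$.
* Chi-square calibration of the deviance under a full-support null
  ($J = 3$, $N = 1000$): 400 replications, mean $G^2$ within three
  Monte-Carlo standard errors of $D = 2$.
* Convergence-rate comparison (ML / MEL / MAEL at zero-cell fractions
  $U \in \{0, 0.75\}$, $N = 50$): 40 replications per cell, asserting the
  qualitative pattern — plain likelihood and the augmented variant converge
  essentially always, empirical likelihood collapses at high sparsity.

## Known limitations

* $H_j$ coefficients are implemented for dichotomous items only; the
  polytomous generalization is out of scope.
* No generalized exp-log constraint calculus: only the identity/mean,
  alpha and H_j links plus custom *linear* models are supported (a custom
  nonlinear link can be supplied programmatically with its Jacobian).
* First-order detection for nonlinear links is heuristic and may return
  `"undetermined"`; no feasibility certificate is attempted.
* Boundary optima are reported with `G2 = Inf` and diagnostics rather than
  df-adjusted; inference at the boundary is outside the asymptotic theory
  the package relies on.
* Observation matrices are read into memory; there is no streaming input
  path (sample sizes in the intended applications are in the thousands).
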