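---
title: "Phase-type models for competing risks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-type models for competing risks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasecr)
```

## The model

A phase-type distribution is the law of the absorption time $T$ of a
finite-state continuous-time Markov chain. The chain moves among $m$
transient states according to an $m \times m$ sub-generator $\mathbf{Q}$
(nonnegative off-diagonal rates, strictly negative diagonal, all
eigenvalues with negative real part so absorption is certain), starting
from an initial law $\mathbf{p}$. The rate of leaving the transient set is
forced by conservation, $\boldsymbol\ell = -\mathbf{Q}\mathbf{1}$. The
standard functions follow from the matrix exponential:

$$S(t) = \mathbf{p}' e^{\mathbf{Q}t}\mathbf{1}, \qquad
  f(t) = \mathbf{p}' e^{\mathbf{Q}t}\boldsymbol\ell, \qquad
  \lambda(t) = f(t)/S(t).$$

For competing risks the chain has $K \ge 1$ absorbing states and the exit
rates form an $m \times K$ matrix $\mathbf{L}$ with
$\mathbf{L}\mathbf{1} = -\mathbf{Q}\mathbf{1}$. The observation is the
pair $(T, C)$: absorption time and the identity $C \in \{1,\dots,K\}$ of
the absorbing state (the failure cause). The cumulative incidence
functions, subdensities and cause-specific hazards are

$$F_j(t) = \mathbf{p}'\mathbf{Q}^{-1}(e^{\mathbf{Q}t}-\mathbf{I})\boldsymbol\ell_j,
 \qquad f_j(t) = \mathbf{p}' e^{\mathbf{Q}t} \boldsymbol\ell_j,
 \qquad \lambda_j(t) = f_j(t)/S(t),$$

with $\boldsymbol\ell_j$ the $j$-th column of $\mathbf{L}$. The triple
$(\mathbf{p}, \mathbf{Q}, \mathbf{L})$ has $(K+1)m-1$ free parameters.

## Identifiability and canonical forms

Markov representations are famously non-unique. Two nonredundant
same-dimension triples define the same joint law of $(T, C)$ exactly when
a nonsingular matrix $\mathbf{B}$ with unit row sums links them:
$\mathbf{p}_b' = \mathbf{p}_a'\mathbf{B}$,
$\mathbf{Q}_b = \mathbf{B}^{-1}\mathbf{Q}_a\mathbf{B}$,
$\mathbf{L}_b = \mathbf{B}^{-1}\mathbf{L}_a$. `find_similarity()`
constructs $\mathbf{B}$ from the Krylov (moment) matrices with rows
$\mathbf{p}'\mathbf{Q}^k$, $k = 0,\dots,m-1$: the similarity relations
force $M_b = M_a \mathbf{B}$, so $\mathbf{B} = M_a^{-1} M_b$ whenever a
similarity exists, and every relation is then verified explicitly so a
spurious solve cannot pass. Nonredundancy (degree of the reduced Laplace
transform equal to $m$) is checked first; a moment matrix with condition
number above $10^{10}$ is treated as numerically redundant.

For upper-triangular (acyclic) chains the package computes the unique
canonical mixture form: a single series chain with decreasing rates
$\lambda_1 \ge \dots \ge \lambda_m$, entered $i$ steps from absorption in
the cause-$j$ subchain with probability $p_{ij} \ge 0$,
$\sum_{i,j} p_{ij} = 1$. The cause-$j$ subdensity is then a plain mixture
of hypoexponential densities, $f_j(t) = \sum_i p_{ij}\, g_{(i)}(t)$ — no
matrix exponentials. The weights are obtained by matching numerator
coefficients of $\sum_i p_{ij}\, g^*_{(i)}(s)$ against the per-cause
rational Laplace transforms
$f_j^*(s) = \mathbf{p}'(s\mathbf{I}-\mathbf{Q})^{-1}\boldsymbol\ell_j$;
the system is triangular in the coefficient basis. A negative solved
weight proves that no canonical chain of that dimension exists, and the
solver reports the offending index — this happens for genuinely
degree-deficient mixtures, e.g. depth weights $(1/2, 0, 0, 1/2)$ on rates
$4 > 3 > 2 > 1$, whose transform drops to degree 3 yet admits no
three-state chain (the re-solve yields weights $(2/3, -1/3, 2/3)$).

The inverse map (`coxian_from_canonical()`) is explicit: with
$R_i = \sum_{i' \ge i, j} p_{i'j}$ the probability of reaching chain
position $i$, the link rates are
$\alpha_{i,i+1} = \lambda_i R_{i+1}/R_i$ and the exits
$L_{ij} = \lambda_i p_{ij}/R_i$, so each row conserves
$\alpha_{i,i+1} + \sum_j L_{ij} = \lambda_i$ and nonnegative weights give
a valid chain. The same solve run over all permutations of the diagonal
rates (`valid_orderings()`) decides which orderings admit valid Coxian
representations; the decreasing ordering always does.

### Numerical choices

* Polynomials are handled in double precision with ascending-power
  coefficient vectors; denominators come from the Faddeev–LeVerrier
  characteristic-polynomial recursion and numerators from interpolation of
  $\mathbf{p}'(s\mathbf{I}-\mathbf{Q})^{-1}v \cdot D(s)$ at small integer
  $s$ (all poles lie in the left half-plane, so these points are safe).
* Root cancellation in `reduce_transform()` pairs roots within a relative
  tolerance of $10^{-7}$ and cancels a denominator root only when *every*
  cause numerator shares it, which is exactly when the joint distribution
  is unchanged.
* Hypoexponential closed forms use partial fractions, whose coefficients
  blow up as rates coalesce; rates closer than $10^{-6}\max_i\lambda_i$
  are rejected with a pointer to the matrix-exponential route. Matrix
  exponentials are delegated to `Matrix::expm()`.
* Validation tolerances are absolute $10^{-8}$ on probability sums and
  rate balance — the scale of double-precision JSON round trips. The
  diagonal of $\mathbf{Q}$ must be strictly negative (every transient
  state is eventually left, and $\mathbf{Q}^{-1}$ is used throughout), and
  defective initial vectors ($\sum p_i < 1$, an atom at $t = 0$) are
  rejected rather than reinterpreted.
* Complex eigenvalues are rejected by the canonical solvers: the canonical
  theory covers real poles only. General (non-triangular) representations
  are still fully supported by the distribution, simulation and
  equivalence tools.

## Simulation

`sample_dataset()` draws (time, cause) pairs either by simulating the
chain path with competing exponential clocks, or — for canonical models —
by drawing the entry cell $(i, j)$ and summing $i$ exponential sojourns.
Right censoring is independent by construction: none, exponential, fixed
horizon, or administrative censoring at a model quantile. Each individual
derives its own RNG substream from the root seed, so identical seeds give
identical datasets and the first $k$ rows of an $n$-run equal a $k$-run —
scaled-down reruns of a large experiment stay exactly comparable. Ties
between event and censoring times (a probability-zero event) resolve in
favour of the event.

The simulator emulates i.i.d. right-censored competing-risks sampling and
nothing else: no covariates, no left truncation, no informative
censoring, no ties from discrete recording. Passing tests therefore
demonstrate correctness of the machinery under the model's own
assumptions, not robustness to the messiness of real registry data.

## EM fitting of the canonical model

The canonical mixture is the natural parameterization for likelihood
inference: the latent variable is the entry cell $(i, j)$, and with
$g_{(i)}$ and $S_{(i)}$ the hypoexponential density and survival of the
first $i$ stages,

* an event record $(t, j)$ contributes $\log \sum_i p_{ij} g_{(i)}(t)$,
* a censored record $t$ contributes $\log \sum_{i,j} p_{ij} S_{(i)}(t)$.

The E-step is Bayes' rule over the latent cell: responsibilities
proportional to $g_{(i)}(t) p_{ij}$ for an event of cause $j$ (the stage
index runs over $i$ — note that the subscript on $g$ is the entry depth,
not the cause), and to $S_{(i)}(t) p_{ij}$ over all cells for a censored
record. All of this is evaluated in the log domain with a signed
log-sum-exp, so very large observation times do not underflow. The M-step
updates $p_{ij}$ by averaging responsibilities (the closed-form
multinomial maximizer) and the rates numerically under the strict-order
constraint $\lambda_1 > \dots > \lambda_m$, enforced by the
reparameterization $\lambda_m = e^{\theta_m}$,
$\lambda_i = \lambda_{i+1} + e^{\theta_i}$. A short BFGS run per M-step is
used and any uphill step accepted (generalized EM); a failed update keeps
the previous rates and flags the fallback.

### The flat ridge, and why there is a polish step

The Coxian likelihood surface has a nearly flat ridge along which a
shrinking rate gap trades off against shifts in the mixing matrix: models
with clearly different $(\boldsymbol\lambda, P)$ can be separated by only
a few $10^{-5}$ nats of Kullback–Leibler divergence per observation. Two
practical consequences, both visible in this package's experiments:

1. Plain EM creeps along the ridge; the relative-log-likelihood stopping
   rule (default $10^{-8}$) can fire thousands of iterations before the
   maximizer is reached, at parameter values far from it.
2. The maximum-likelihood estimate itself is a long way from the
   generating parameters at moderate sample sizes. Fitting data simulated
   from the two-stage worked model ($\lambda = (5,4)$, mixing mass
   $(.40, .25, .20, .15)$), the exact MLE — confirmed by two independent
   likelihood implementations — typically sits near rate coalescence
   ($\hat\lambda_1 \approx \hat\lambda_2 \approx 4.3$) for $n = 5{,}000$
   and still at $n = 20{,}000$; separating that point from the truth would
   need on the order of $n \approx 2.6\times 10^5$ observations. Users
   should treat the fitted CIFs, not the raw $(\hat{\boldsymbol\lambda},
   \hat P)$, as the reliable output at such sample sizes.

Because of (1), `fit_em()` finishes with a quasi-Newton ascent of the
observed log-likelihood from the best EM solution (`polish = TRUE`),
accepted only when it improves the likelihood, so the monotone trace is
preserved. Restarts (default 3) jitter the moment-based start — rates
spaced geometrically around $m/\bar T$, uniform mixing — from a seeded
stream; the best run by final log-likelihood wins.

The identifiability theory motivates the strict decreasing-rate
constraint: among equally ordered Coxian models the parameterization is
unique, so the EM target is well defined. Covariate effects on the rates
(proportional factors $e^{\boldsymbol\beta' \mathbf{z}}$) are a
documented extension point, not implemented.

### Problem sizes used in the test suite

The simulation-consistency checks use 50,000 paths (empirical sub-CDFs
within four Monte-Carlo standard errors of the closed forms); the
parameter-recovery experiment uses $n = 5{,}000$ with five restarts and
$n = 20{,}000$ with two, capping EM at 150 iterations before the polish —
past that point EM's per-iteration gains are orders of magnitude below
the polish's final improvement. The end-to-end pipeline check mirrors a
hospital length-of-stay analysis: $n = 650$, $K = 2$ (alive discharge vs
in-hospital death), a three-stage chain with a slow final stage, and
roughly 1% independent censoring, validated by convergence, trace
monotonicity and agreement between fitted and Aalen–Johansen cumulative
incidence curves within nonparametric sampling error. These sizes are the
package's own choices and are stated here so the reported tolerances can
be read against them.

## Nonparametric comparator

`aalen_johansen()` wraps the multistate product-limit estimator
(`survival::survfit()` on a factor status) and returns step functions of
the cumulative incidence per cause; `fitted_cif_report()` tabulates the
fitted model's CIFs against them on a common grid — the standard
goodness-of-fit display for a parametric competing-risks model.

## Known limitations

* Canonical forms, ordering enumeration and the weight solver require
  real, pairwise-distinct eigenvalues; complex-pole distributions are out
  of scope (no canonical theory exists for them).
* Equivalence is decided for representations of equal dimension only;
  cross-dimension equivalence is not attempted beyond transform reduction.
* No standard errors or confidence intervals for the EM fit; given the
  ridge geometry described above, naive Wald intervals would be
  misleading anyway.
* Ordering enumeration is factorial in $m$ and capped at $m \le 8$.
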