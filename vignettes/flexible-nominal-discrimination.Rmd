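---
title: "Symmetric model-discrimination designs with flexible nominal sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symmetric model-discrimination designs with flexible nominal sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltadiscrim)
```

## The model and the criterion

We observe $y_i = \eta_k(\theta_k, x_i) + \varepsilon_i$ at design points
$x_1, \dots, x_n$ from a finite design space $X$, with
$\varepsilon_i \sim N(0, \sigma^2)$ i.i.d., and one of the two rival mean
functions $\eta_0$, $\eta_1$ (equal parameter dimension $m$) is true. After
the experiment the model is chosen by the likelihood ratio, which under
normal homoskedastic errors picks the model whose best least-squares fit is
closer to the data. The probability of a correct choice is bounded below by
$P[\chi^2_n \le d^2/(4\sigma^2)]$, where $d$ is the distance between the
two models' sets of possible mean vectors
(`correct_decision_lower_bound()`), so a good discrimination design makes
$d$ large. Computing $d$ exactly requires nonconvex optimization at every
candidate design, which is hopeless inside a discrete design search.

The package's criterion replaces each mean-value surface by its tangent
plane at a *nominal* parameter value $\tilde\theta_k$ (typically an
estimate from a previous experiment), restricted to a cuboid
*flexible nominal set*
$\tilde\Theta_k(r) = \prod_j [\tilde\theta_{kj} - r\tilde\sigma_{kj},
\tilde\theta_{kj} + r\tilde\sigma_{kj}]$
whose half-widths $\tilde\sigma_k$ are, in the intended use, the standard
errors of those estimates. The squared criterion

$$\delta_r^2(D) = \min_{\theta_k \in \tilde\Theta_k(r)}
  \bigl\lVert a_0(D) + F_0(D)\theta_0 - a_1(D) - F_1(D)\theta_1
  \bigr\rVert^2$$

is a convex quadratic in $(\theta_0, \theta_1)$: equivalently the residual
sum of squares of a box-constrained least-squares fit in the
*response-difference model* with regressors $[F_0, -F_1]$ and artificial
observations $a_1 - a_0$. Two evaluation paths exist and are tested against
each other: the norm expression above, and the quadratic form
$(\theta-\tilde\theta)^T M (\theta-\tilde\theta) +
2 b^T(\theta-\tilde\theta) + c$ with $M$ the information matrix of the
response-difference model (`delta_quad_form()`).

The flexible nominal sets are a tuning device, not parameter spaces: they
should cover the plausible parameter values, and the dilation $r$ sweeps
from local optimality at a point ($r = 0$) to the unconstrained linearized
problem ($r = \infty$). $\delta_r^2(D)$ is nonincreasing and convex in $r$,
positive homogeneous in replication, and concave over design measures —
each of these is verified as a property-style test.

## Numerical choices

* **Box-constrained least squares.** The inner minimization is solved by a
  compiled active-set routine (Stark–Parker-style) in `src/`: free-set
  least-squares solves with minimum-norm fallback under rank deficiency,
  feasibility step-backs, a KKT selection rule with an anti-cycling guard,
  and support for infinite boxes ($r = \infty$) and frozen coordinates
  (zero half-widths, with the convention $0 \cdot \infty = 0$). The
  returned minimizer is clipped to the cuboid (tolerance $10^{-10}$) and
  the value re-evaluated at the clipped point, so the reported value is
  always the squared norm at a feasible point. Rank-deficient unconstrained
  problems return the minimum-norm minimizer; the criterion value is
  unaffected by that choice. A zero criterion value has a nonunique
  minimizer and is flagged `solver_status = "degenerate"`.
* **Design search.** `kl_exchange()` runs best-improvement exchange: from
  each of `n_starts` (default 20) uniform random starts it scans all
  (occupied point, candidate) pairs in a randomized position order and
  applies the single best exchange if it improves $\delta^2$ by more than
  `tol` (default $10^{-12}$); ties go to the first candidate encountered in
  scan order, which makes runs bit-reproducible under a fixed seed. Full
  scans are affordable at the built-in problem sizes, so no candidate-list
  truncation is used. `exhaustive_search()` enumerates all
  $\binom{d+n-1}{n}$ multisets and is the oracle against which the
  heuristic is tested on small instances.
* **Exact-distance oracle.** `exact_distance()` minimizes the
  non-linearized distance over the same cuboids by multistart L-BFGS-B,
  started at the $\delta$ minimizer plus random cuboid draws. It validates
  the linearization empirically; no inequality between $\delta_r$ and the
  exact distance holds in general, so only the ratio is informative.

## Set upper bounds

Two distinct notions of "large enough $r$" are computed:

* **Iterative search** (`set_upper_bound_search()`): find $r^*$ with
  $o(r^*) = o(\infty)$, where $o(r)$ is the optimal criterion value. The
  method exploits convexity: the chord through the last two evaluated
  points $(r, o(r))$ crosses the level $o(\infty)$ at or below the true
  crossing, so chord extrapolation inflated by a small safety factor
  (default 1.05) approaches $r^*$ from below without overshooting wildly;
  the stopping rule is $o(r) \le q\,o(\infty)$ with $q$ slightly above 1
  (the study setting is $q = 1 + 10^{-6}$). Because the first probe that
  satisfies the stopping rule may exceed the crossing by up to the safety
  factor, a short bisection polish then narrows the bracket to 1%
  relative width and returns its upper end. On the toy problem this
  returns $r^* \approx 0.68$ in about eight design searches. The returned
  bound is validated by re-running the design search at $2 r^*$ and
  checking that the optimal value stays at $o(\infty)$.
* **LP certificate** (`lp_set_upper_bound()`): the smallest $r$ making the
  two linearized mean-value sets intersect over the design with one trial
  at *every* design-space point. Past this $r^*$, every design of every
  size has $\delta_r = 0$ — discrimination by this criterion is
  impossible. The $d$ equality constraints (one per grid point) involve
  only $2m$ unknowns, so the implementation first solves the equality
  system by least squares (inconsistency means the LP is infeasible, i.e.
  no such $r^*$ exists), parametrizes its affine solution set, and solves
  the remaining tiny LP over the subspace coordinates with
  `pracma::linprog`; when the solution is unique — as for the enzyme
  problem, whose equality system pins both leading coefficients to zero —
  the optimum has the closed form
  $\max_j |\theta_j - \tilde\theta_j| / \tilde\sigma_j$. The certificate
  is always re-verified against the original constraints at $10^{-8}$.
  `conditionally_linear_feasible_point()` provides the companion
  construction for models that are linear once part of their parameters is
  fixed: zeroing the linear coefficients annihilates the linearized
  responses, giving a feasible point and hence an upper bound on the LP
  optimum ($7.298/0.114 \approx 64.02$ for the enzyme pair, which the LP
  confirms is optimal).

## The built-in study problems

* `make_example1_problem()`: $\eta_0 = \theta x$ vs
  $\eta_1 = e^{\theta x}$ on the grid $\{1.00, 1.01, \dots, 2.00\}$,
  nominals $e$ and $1$ (so the nominal responses coincide at $x = 1$), unit
  cuboids $[e-1, e+1]$ and $[0, 2]$. All constants of this problem are the
  study settings themselves.
* `make_enzyme_problem()`: competitive vs noncompetitive inhibition with
  nominals/half-widths from the initial experiment's estimates and
  standard errors. The design rectangle $[0,30] \times [0,40]$ is
  continuous in the source study; since the methods here operate on a
  finite design space, the default discretization is a $61 \times 41$ grid
  (steps 0.5 in substrate, 1 in inhibitor) — fine enough to represent the
  edge and mid-range support points that optimal inhibition designs use,
  and cheap for the exchange search. The grid is a constructor argument,
  and the LP bound moves by less than 1% under a twofold refinement in
  each axis (a tested invariant). Parameter boxes
  ($\theta_1 > 0$, $\theta_2 \in (0, 60]$, $\theta_3 \in (0, 30]$) are
  enforced in Monte-Carlo fitting but not in criterion evaluation: at the
  dilations studied, the flexible nominal sets lie well inside them.

## The Monte-Carlo study

`hit_rate_study()` measures realized discrimination performance: for each
design and each assumption about the true model, N replicates of
*perturb → simulate → fit both → decide*. Its generator settings are the
study conditions:

* **Error scale.** The base value `enzyme_sigma_hat()` = 0.1526 is the
  residual standard-deviation estimate from the encompassing-model fit of
  the initial experiment. At that noise level all designs discriminate
  almost perfectly, so the confirmatory study uses $2\hat\sigma = 0.3052$
  (and the large-sample log-normal variant uses $5\hat\sigma$); both enter
  as configuration values, not hard-wired constants. Under additive normal
  errors, inflation much beyond $2\hat\sigma$ produces frequent negative
  velocities and invalid likelihood fits, which motivates the alternative
  error model below. Negative observations that do occur are retained.
* **Perturbation.** Each replicate draws the data-generating parameters
  uniformly from the nominal $\pm\, c \times$ half-width cuboid, fresh per
  replicate (`perturb_params()`); $c = 0$ reproduces the nominals exactly.
* **Log-normal variant.** `simulate_lognormal_rescaled()` uses
  multiplicative log-normal errors rescaled to the original means. The
  construction here is per-point variance-matched and mean-exact:
  $y_i = \eta_i \exp(\varepsilon_i - s_i^2/2)$ with
  $s_i^2 = \log\{1 + (\sigma/\eta_i)^2\}$, so $E[y_i] = \eta_i$ and
  $SD[y_i] = \sigma$ hold exactly and observations are always positive.
  An alternative reading — common log-scale variance with post-hoc mean
  rescaling — would change only the higher moments; the tests pin the
  implemented choice through its first two moments.
* **Fitting.** Both models are fitted by Levenberg–Marquardt least squares
  (`minpack.lm::nls.lm`) with analytic Jacobians, from the nominal value
  plus four uniform draws from the unit ($r = 1$) cuboid, under box
  constraints formed by intersecting the model's parameter box with a wide
  ($\pm 50$ half-widths) cuboid around the nominal to keep the optimizer
  from diverging. Replicates where every start of a model fails are
  counted (`n_failed`) and cannot score as correct; in practice none fail
  at the study settings.
* **Common random numbers.** Within a replicate the two true-model arms
  share the perturbation uniforms, the error draws, and the fit-start
  draws. This makes the study exactly symmetric under relabeling of the
  two models (a tested invariant) and reduces the variance of
  between-design comparisons; replicates remain independent.
* **Decision.** `lr_decide()` picks the model with the smaller residual
  sum of squares, which is the likelihood-ratio rule for equal parameter
  counts; exact ties (a probability-zero event under continuous noise) go
  to model 0. No small-sample correction for unequal parameter counts is
  implemented — the package requires $m_0 = m_1$.

What the generators do *not* emulate: model error (data from neither rival
model), heteroskedastic or dependent errors, and design-space constraints
beyond a rectangle. Passing tests therefore demonstrate internal
correctness and reproduction of the reference study conditions, not
robustness to those violations.

## Problem sizes and reproducibility

The test suite runs the full study computations at reduced Monte-Carlo
sizes (e.g. N = 2000 hit-rate replicates, with tolerances widened
accordingly to about 1.5 percentage points); `scripts/acceptance.R`
recomputes the headline quantities at the full N = 10000. All stochastic
functions accept a seed and record it in their outputs; the exchange
search, the Monte-Carlo study, and the CLI runs are bit-reproducible for a
fixed seed. The `q` stopping factor of the bound search is exposed on the
command line as $q - 1$ to avoid floating-point noise in config files, and
$r = \infty$ is spelled `"inf"`.

## Known limitations

* The criterion is a linearization; for strongly curved models at wide
  nominal sets, $\delta_r$ may misrank designs relative to the exact
  distance. `exact_distance()` quantifies the gap for any given design but
  is too slow to drive the search.
* The exchange heuristic carries no global-optimality guarantee; it
  matches enumeration on all tested small instances, and multiple restarts
  are cheap, but a pathological design space could defeat it.
* Cuboid nominal sets only; functional relations among parameters
  (noncuboid sets) would forfeit the fast box-constrained solver.
* Approximate-design theory (continuous measures, equivalence theorems) is
  out of scope: the package optimizes exact designs on finite spaces.

## A compact session

```{r example, eval = FALSE}
prob <- make_example1_problem()
search <- kl_exchange(prob, n = 6, r = Inf, n_starts = 20, seed = 1)
glance(search)                        # delta^2 ~ 0.02614
autoplot(search)                      # 3-point support
bound <- set_upper_bound_search(prob, n = 6, r_ini = 0.3, q = 1 + 1e-6,
                                seed = 1)
autoplot(bound)                       # o(r) trace with r* ~ 0.68

enz <- make_enzyme_problem()
lp_set_upper_bound(enz)$r_star        # 64.02
d5 <- kl_exchange(enz, n = 6, r = 5, n_starts = 20, seed = 1)$best_design
cfg <- mc_config(n_reps = 10000, c = 0, sigma = 2 * enzyme_sigma_hat(),
                 seed = 4)
hit_rate_study(enz, list(delta2 = d5), cfg)   # ~98% / ~97% hit rates
```
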