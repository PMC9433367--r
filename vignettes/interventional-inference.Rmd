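---
title: "Interventional distributions and delta-method inference for linear ADMG models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interventional distributions and delta-method inference for linear ADMG models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosem)
```

## The model

`dosem` works with linear Gaussian causal models on acyclic directed
mixed graphs (ADMGs).  An ADMG over observed variables
$V = (V_1, \dots, V_n)^\top$ has directed edges for direct causal
effects and bidirected edges for correlated errors due to unobserved
confounding.  The structural equations are

$$ V = C V + \varepsilon, \qquad \varepsilon \sim N_n(0, \Psi), $$

where $C$ collects the path coefficients ($c_{ji} \neq 0$ iff
$V_i \to V_j$) and $\Psi$ is the error covariance matrix
($\psi_{ij} \neq 0$ iff $V_i \leftrightarrow V_j$, with the diagonal
holding error variances).  All variables are mean deviations; there is
no mean structure anywhere in the package, and data are centered at
load time.  Only recursive systems are supported: the directed part
must be acyclic, so some ordering makes $C$ strictly lower triangular
and the reduced form $V = (I - C)^{-1}\varepsilon$ exists, with
model-implied covariance matrix
$\Sigma(\theta) = (I-C)^{-1}\Psi(I-C)^{-\top}$.

The free parameters are collected as
$\theta = (\theta_F, \theta_P)$: structural labels first (in order of
first appearance in the directed edge list), then covariance labels.
Equality constraints are expressed purely by sharing a label across
edges — e.g. a cross-lagged panel model with time-constant effects —
and labels can instead be held at fixed values.  No other functional
constraints are supported, which keeps every free parameter distinct
and functionally unrelated.

The package's assumptions, then, are the usual ones for this model
class: known causal ordering, modularity of interventions, no
interference between units, effects constant across units and across
value combinations (linearity), and Gaussian errors.  Everything
downstream — closed-form interventional distributions, normal-theory
likelihood, delta-method intervals — leans on them.

## Interventions in matrix form

An intervention $do(x)$ fixes the variables with index set
$\mathcal I$ ($K_x = |\mathcal I|$) to constants $x$ and deletes their
structural equations, leaving all others intact (modularity).  With
the selection matrices $1_{\mathcal I}$, $1_{\mathcal N}$ and the
diagonal indicator $I_{\mathcal N}$ of the untouched set
$\mathcal N$, the mutilated system is

$$ V = I_{\mathcal N} C V + I_{\mathcal N}\varepsilon + 1_{\mathcal I} x, $$

whose reduced form yields the interventional distribution in closed
form:

$$ V \mid do(x) \sim N^{\,n-K_x}_n\!\big(a_1 x,\; T_1 \Psi T_1^\top\big),
\qquad T_1 = (I - I_{\mathcal N} C)^{-1} I_{\mathcal N},
\quad a_1 = (I - I_{\mathcal N} C)^{-1} 1_{\mathcal I}. $$

The covariance is singular of rank $n - K_x$: intervened variables
carry no randomness.  `interventional_moments()` stores the full
$n \times n$ covariance with *exact* zeros in the intervened rows and
columns (they are zeroed analytically, not left to floating-point
residue), and densities are defined only for subsets of $\mathcal N$ —
queries on an intervened variable error out.  The interventional mean
is linear in $x$ while the covariance does not depend on $x$ at all; a
test asserts the latter bitwise.  Indexing is 1-based everywhere in
the user interface; any translation happens inside the accessors.

Three conveniences sit on top: marginalization to outcome subsets,
interval (rectangle) probabilities, and the average treatment effect
$\imath_j^\top a_1 (x - x')$.  For contrast with "seeing",
`conditional_distribution()` does ordinary Gaussian conditioning on
the joint covariance (Schur complement); nothing causal about it, but
the seeing-vs-doing comparison is the central didactic point of the
worked example below.

## Causal effect functions and their Jacobians

A causal quantity $\gamma$ is any feature of the interventional
distribution; a causal effect function $g$ maps the parameters of the
*observational* joint distribution onto it.  Four are built in:

* $g_1(\theta; x) = a_1 x$ — the interventional mean (depends only on
  $\theta_F$; its Jacobian has exact zero columns for every
  covariance parameter, which is asserted in tests);
* $g_2(\theta) = \mathrm{vech}(T_1 \Psi T_1^\top)$ — the
  half-vectorized interventional covariance;
* $g_3(\theta; x, v_{\mathcal N})$ — the interventional density at a
  point;
* $g_4(\theta; x, y^{low}, y^{up})$ — the interval probability
  ("treatment success" when the interval is a clinically acceptable
  range).

Their Jacobians in $\theta$ are closed-form chains through the
constant 0/1 patterns $\partial\,\mathrm{vec}\,C/\partial\theta^\top$
and $\partial\,\mathrm{vec}\,\Psi/\partial\theta^\top$ (one column per
label, one unit entry per tagged position, symmetric pairs for
off-diagonal covariances).  All vec/vech plumbing follows the
Magnus–Neudecker column-major convention — `vech` stacks the lower
triangle including the diagonal — because the duplication,
elimination and commutation matrices $D_n, L_n, K_n$ appear together
in the covariance Jacobian and must agree on conventions.  The
Jacobians are computed for the full $\theta$ and the structurally
zero columns are kept (a mask is trivial to derive); that keeps
shapes predictable for users at the cost of a few zero columns.

The probability Jacobian is implemented for a single outcome
variable; asking for several outcomes raises a clear "unsupported"
error rather than falling back to numerics silently.  Every closed
form is validated against a central-finite-difference oracle (a small
test helper, not a production path) on dozens of randomized recursive
models at relative tolerance $10^{-5}$.

Delta-method inference then propagates the asymptotic covariance of
$\sqrt N\,\hat\theta$ through a Jacobian:
$\mathrm{AV}(\sqrt N \hat\gamma) = J\,\mathrm{AV}(\sqrt N\hat\theta)\,J^\top$,
with $\mathrm{ASE} = \sqrt{\mathrm{diag}/N}$, z-values, and normal
intervals using the exact quantile $1.959964$ (values printed with
$1.96$ elsewhere still match at two decimals).

## Estimation

`ml_fit()` minimizes the covariance-structure ML discrepancy

$$ F_{ML}(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}\,(S\,\Sigma(\theta)^{-1})
   - \log|S| - n $$

with the analytic gradient
$\Delta^\top \mathrm{vec}\big(\Sigma^{-1}(\Sigma - S)\Sigma^{-1}\big)$,
where $\Delta = \partial\,\mathrm{vech}\,\Sigma/\partial\theta^\top$.
The sample covariance uses denominator $N$ (the ML convention; an
`"N-1"` option exists).  The optimizer runs Fisher scoring — damped
Newton steps on the expected curvature
$\Delta^\top D_n^\top(\Sigma^{-1}\otimes\Sigma^{-1})D_n\Delta$ — from
a default start (path coefficients 0, error variances at the sample
variances, error covariances 0), falling back to BFGS when scoring
stalls away from a stationary point, and declares convergence only
when the gradient max-norm drops below $10^{-8}$.  Five jittered
starts under a fixed internal seed guard against local minima.
Scoring was chosen as the primary loop because it is both much faster
and more reliable at driving the gradient to tolerance than BFGS
alone; fitting the exact model-implied covariance is a fixed point
recovered to $10^{-6}$ in the parameters with $F_{ML} = 0$.

The asymptotic covariance uses the expected-information form
$\mathrm{AV}(\sqrt N\hat\theta) =
2\big(\Delta^\top D_n^\top(\Sigma^{-1}\otimes\Sigma^{-1})D_n\Delta\big)^{-1}$,
the standard normal-theory result (it reduces to $2\psi^2$ for a
single normal variance, and matches the Monte-Carlo covariance of
$\sqrt N\hat\theta$ within 10% in Frobenius norm at $N = 2000$ over
1000 replications in the test suite).  An observed-information
variant (curvature at the actual $S$) is available behind a flag; the
two coincide at a perfectly fitting sample.

Identification is checked *locally and numerically*: $\theta$ is
locally identified from the covariance structure iff
$\mathrm{rank}\,\Delta = q + p$.  The rank is evaluated at five
random parameter draws (plus the point of interest) with a
singular-value threshold of
$\max(\mathrm{dim}) \cdot \varepsilon \cdot \sigma_{\max} \cdot 10^3$,
and identification is declared only when every draw agrees; deficient
models get the offending labels reported from the null space.  This
is a deliberate reduction — global/symbolic identification arguments
are outside the package's scope, and users of heavily constrained
models should be aware that a local rank check cannot distinguish
finitely many observationally equivalent points.

## The synthetic-data generator

`simulate_observational()` draws
$\varepsilon$ row-wise via the (fixed, upper-triangular `chol`)
factor of $\Psi$ and applies the reduced form;
`simulate_interventional()` pushes the *same* error draws through the
mutilated system, so with equal seeds an intervention on a sink
variable leaves every other column untouched — a property the tests
exploit.  Seeds pin tables byte-for-byte and the caller's RNG stream
is restored afterwards.

The packaged `illustration_fixture()` is a six-variable cross-lagged
panel of blood insulin ($X_1, X_2, X_3$, mcIU/ml) and blood glucose
($Y_1, Y_2, Y_3$, mg/dl) at three occasions six minutes apart:
time-constant autoregressive and cross-lagged coefficients
($c_{xx} = 0.05$, $c_{xy} = 0.4$, $c_{yx} = -0.6$, $c_{yy} = 1.2$),
contemporaneous confounding of insulin and glucose, and serial error
covariances — fourteen free parameters ($q = 4$, $p = 10$).  These
population values are the data-generating conditions for every
simulation-based test; they are fixed, not tuning knobs.  What the
generator emulates is exactly the model's assumptions — Gaussian
errors, linear time-constant effects, no measurement error.  Real
panel data violate at least some of these (excess kurtosis, effect
heterogeneity, measurement error), so passing tests demonstrate
correctness of the machinery *under the model*, not robustness beyond
it.

## Numerical choices

* Positive definiteness of $\Psi$ is checked by attempted Cholesky
  factorization with tolerance $10^{-10}$ on the smallest squared
  pivot.
* Rectangle probabilities for $K_y > 1$ use the deterministic Miwa
  quadrature (512 grid steps) from `mvtnorm`, accurate to about
  $10^{-6}$; determinism without any seed bookkeeping was preferred
  over randomized quasi-Monte-Carlo.  Univariate probabilities are
  differences of `pnorm` values.
* `optimal_intervention_level()` searches the dose by
  `stats::optimize` (golden-section/parabolic) at tolerance
  $10^{-8}$, then cross-checks the closed form: because the mean is
  linear in the dose and the variance dose-free, the optimum puts the
  mean at the interval midpoint whenever the slope is nonzero.  A
  zero slope means a flat objective; the function flags this rather
  than returning an arbitrary dose.
* Degenerate inputs: empty interventions reproduce the observational
  distribution; $C = 0$ collapses every transformation to its
  selection pattern; infinite interval bounds are handled exactly.

## Problem sizes used in the test suite

Deterministic checks run on the six-variable panel model and on
randomized recursive models with $n \le 8$.  The simulation-based
properties use $10^5$–$10^6$ draws for moment checks, 1000
replications at $N = 500$ for the 93–97% coverage band of the
delta-method intervals, 1000 replications at $N = 2000$ for the
asymptotic-covariance check, and 60 replications per sample size for
the $\sqrt N$-consistency (RMSE-halving) property — sizes chosen so
Monte-Carlo error is comfortably below the asserted tolerances while
the whole suite stays fast on one CPU.

## Known limitations

Non-recursive (cyclic) systems, latent variables/measurement models,
mean structures, conditional or dynamic interventions, GLS/ADF/robust
estimators, and identification from graph structure alone
(back-door/do-calculus search) are out of scope.  The probability
Jacobian covers one outcome at a time.  Published finite-sample
estimate tables from any particular unseeded simulation cannot be
reproduced bit-for-bit; the package's own seeded generator plus the
consistency, rate and coverage properties take their place.
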