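---
title: "Estimating time-varying metabolic rates from concentration data"
author: "dmfa package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating time-varying metabolic rates from concentration data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmfa)
```

## The estimation problem

Macroscopic models of fermentation processes describe the medium through
a handful of *macro-reactions* — net conversions of glucose, glutamine,
lactate, ammonium, product and biomass — whose stoichiometry comes from
the elementary modes (EMs) of a small metabolic network.  Building such
a model requires estimates of the time-varying reaction rates of those
modes, and the classical route (differentiate each noisy concentration
series, then regress the resulting cell-specific fluxes onto the mode
stoichiometry) amplifies measurement error in its very first step.

This package takes the dynamic metabolic flux analysis (DMFA) route
instead: the *volumetric* flux profiles are parameterized as piecewise
linear in time between inflection nodes $T_1 < \dots < T_{n_T}$, the
concentrations implied by integrating those fluxes are compared with the
data directly, and the node values are estimated by weighted least
squares.  No numerical differentiation of data ever occurs.

With external stoichiometric matrix $P$, internal matrix $N$, viable
cell density $X_v(t)$ and cell-specific fluxes $\nu(t)$, concentrations
evolve as $\dot c = P\,\nu(t)\,X_v(t)$.  Writing $V(t) = \nu X_v$ for
the volumetric fluxes, the steady-state assumption $N V = 0$ lets us
express $V = K U$ with $K$ a null-space basis of $N$ and $U$ the free
fluxes.  Because $U(t)$ is piecewise linear, each fitted concentration
$\hat c_i(t)$ is a *linear* function of the node values $U_k(T_j)$ and
of the initial concentrations, and piecewise quadratic in $t$.  The fit
minimizes the standardized residual sum
$$\mathrm{SSR} = \sum_i \sum_j
  \left(\frac{c^m_i(t_j) - \hat c_i(t_j)}{\sigma_i(t_j)}\right)^2 .$$

Four variants share this machinery:

* **unbounded** — plain weighted least squares on $U_k(T_j)$;
* **bounded** — adds $K_{\mathrm{irr}} U(T_j) \ge 0$ at every node so
  that irreversible reactions never run backwards.  Since $V(t)$ is
  piecewise linear, node-wise feasibility implies feasibility at all
  times.  Its SSR is the best fit attainable from the network at all,
  and therefore the reference against which mode subsets are judged;
* **em** — replaces $PK$ by the L2-normalized macro-reaction matrix $E$
  and estimates non-negative mode rates $R_k(T_j) \ge 0$.  With the
  complete mode set its optimal SSR equals the bounded SSR, because both
  feasible sets describe the same cone of volumetric fluxes;
* **em_regularized** — adds the ridge penalty
  $\alpha \sum_{k,j} (R_k(T_j)/X_v(T_j))^2$ on *cell-specific* rates.
  Penalizing specific rather than volumetric rates suppresses the
  unrealistically large per-cell rates that otherwise appear where few
  cells are present.

## Numerical formulation and solver

All four problems are convex: (inequality-constrained) linear least
squares.  We solve them through the classical reduction of
least-squares-with-inequalities to least-distance programming and
finally to a single non-negative least squares problem (Lawson–Hanson),
with the NNLS subproblem handled by `pracma::lsqnonneg`.  Constraint
rows are normalized before the reduction so the solver is scale
invariant under the very large weights that near-noise-free data
produce.  Every constrained solution is certified post hoc: stationarity
and complementarity residuals below $10^{-8}$ (relative), constraint
violation above $-10^{-9}$.

Two numerical choices deserve mention:

* **Null-space convention.**  $K$ is non-unique; we fix it to the
  orthonormal SVD basis (singular values below
  $10^{-10}\sigma_{\max}$ counted as zero) with each column's
  largest-magnitude entry made positive.  All reported quantities
  ($\hat c$, SSR, $V = KU$) are basis invariant, and the test suite
  verifies this by re-solving under permuted reaction orders.
* **Collinear mode sets.**  When more modes than independent external
  directions are supplied — the situation the regularization exists
  for — the $\alpha = 0$ problem has a unique SSR but non-unique $R$.
  The solver then adds a conditioning ridge of $10^{-12}$ of the data
  scale, selecting the minimum-norm representative while leaving the
  SSR unchanged to solver precision.

Initial concentrations are estimated jointly with the node values by
default (`estimate_c0 = TRUE`); pinning them to the first measurement is
available but biases the first segment by a single noisy sample.  The
default inflection grid is five equally spaced nodes over the data span;
any strictly increasing user grid is accepted.  `n_T = 2` degenerates to
globally linear volumetric rates.  Masked measurements are dropped from
the SSR, never imputed.

## Choosing the regularization weight

`cross_validate_alpha()` shuffles the measurement *time points* into
folds (round-robin after a seeded permutation), refits on the training
folds for each candidate $\alpha$ and scores the held-out standardized
residuals.  Ties are broken toward the larger $\alpha$, i.e. toward the
smoother model.  Holding out whole time points (rather than individual
values) is what makes the procedure sensitive to the overfitting that
collinear mode sets produce.

## Bootstrap confidence bounds

Analytic (Fisher-information) intervals are unreliable here: parameters
can be near-unobservable where $X_v$ is small, and the non-negativity
constraints have no place in them.  `dmfa_bootstrap()` instead resamples
each measurement from a Gaussian centered at the observed value with the
affine noise model
$$\sigma_i(t_j) = a_i + b_i\, c_i(t_j),$$
re-randomizes the interior inflection nodes (uniform jitter within
half the local node spacing; endpoints fixed, ordering preserved by
construction), re-solves, and summarizes median, 68% and 95% empirical
percentile bands per quantity and time.  During bootstrap the
regularization must be zero (the default) or tiny, otherwise the bands
inherit the regularization bias.  Per-sample seeded substreams make
ensembles bitwise reproducible regardless of execution order.  The
common benchmark convention "the 95% confidence interval equals $p$% of
the magnitude" maps to $a = 0$, $b = p/(100 \cdot 1.96)$; the 1.96
quantile is fixed, not configurable.

A percentile (not BCa) band was chosen deliberately: it matches the
"bounds of all estimations" reading of ensemble summaries and it is
exact under the constraint-free Gaussian linear model.  With 50-sample
ensembles the 2.5%/97.5% quantiles sit between the extreme order
statistics, so mild undercoverage at small ensemble sizes is expected
and visible in the validation study (≈90% empirical coverage of the
95% band); production analyses should use the 500-sample default.

## Selecting a minimal mode set

Large networks generate thousands of modes, most redundant.  Two
reduction stages are provided:

1. **Geometrical reduction** (`geometric_reduction()`): columns of $E$
   are grouped by single-linkage at a decreasing cosine-similarity
   threshold (schedule from $1-10^{-10}$ down to 0.70), each group is
   replaced by its medoid, and the reduction stops before the summed
   elementary-mode SSR over all experiments exceeds the full-set SSR by
   more than a tolerance (1% by default).  The published description of
   this step leaves the threshold schedule and the representative rule
   open; the implemented variant (medoid representative, fixed
   schedule, SSR re-verified by a fresh solve after every step) is our
   interpretation, chosen to be deterministic.
2. **Multiobjective selection** (`nsga2_select()`): NSGA-II over binary
   inclusion chromosomes minimizing (summed SSR, subset size), with
   uniform crossover (probability 0.9), per-bit mutation ($1/n_{EM}$),
   binary tournament on rank and crowding distance, and a repair step
   enforcing at least one active mode and any always-include mask
   (e.g. a biomass death mode).  Population 100 and 200 generations by
   default — standard practice for binary encodings; the published
   study names the algorithm but not its settings.  Chromosome
   evaluations are cached, as the inner solve dominates runtime.
   Multi-experiment objectives are plain unweighted SSR sums.

`knee_report()` then flags the smallest cardinality whose SSR stays
within a tolerance of the bounded-DMFA lower bound.

## The synthetic validation scenario

Because the experimental data behind the published application are
confidential, every claim in this package is validated against
synthetic data with known truth.  The bundled generator is a
constructed stand-in, not a published organism model; it was designed
once, before any estimator was run, to exhibit the qualitative features
of a mammalian fed-batch culture:

* four modes over Glc, Gln, Lac, Amm, Glu, mAb and $X_v$: growth,
  lactate overflow, lactate re-utilization and product formation
  (`demo_em_matrix()`);
* saturating (Monod-type) kinetics in every consumed species, with
  glucose inhibition of lactate reuse, so true concentrations stay
  non-negative and the culture shows the classical overflow-then-reuse
  phase structure;
* a feed ramping in from 24 h carrying concentrated glucose and
  glutamine, with dilution terms in every balance, over a 120 h
  horizon sampled every 8 h;
* measurement noise per the affine model at the "95% CI = 5% of
  magnitude" convention, with a detection-limit floor of $10^{-3}$ of
  each species' trajectory maximum on the *recorded* sigma (species
  crossing zero would otherwise carry zero weight); the floor never
  affects the generated noise itself.

Trajectories are integrated by `deSolve::lsoda` at relative tolerance
$10^{-8}$; the run aborts if any true concentration goes negative.
What the generator does **not** emulate — sampling-time irregularities,
systematic (non-Gaussian) analyzer bias, pH/temperature coupling,
gas-phase dynamics beyond user-supplied transfer rates — bounds what
green tests can say about real data.

A second, smaller network ships as a plain-text file
(`inst/extdata/toy_network.txt`): one balanced pyruvate pool feeding
lactate overflow, oxidative growth and product synthesis, plus a
balanced glutaminolysis chain.  Its four elementary modes have linearly
independent external signatures (a simplicial flux cone), which is
exactly the property needed to demonstrate both halves of the mode-set
theory: the complete-set SSR equals the bounded SSR, and removing *any*
active mode strictly worsens the attainable fit.  Networks whose cone
is not simplicial (more modes than independent external directions)
admit positively dependent mode combinations, and there the removal of
an individual mode may be compensated — which is why the demonstration
network was chosen simplicial on purpose.

The rate-based baselines used in the benchmark are per-time-point
non-negative least squares of estimated specific fluxes onto $E$
(Poolman-style), with the fluxes obtained from interpolating splines,
GCV smoothing splines, or a centered moving-average filter (window 5,
shrinking symmetrically at the edges so linear trends pass unchanged)
followed by spline differentiation.  A windowed variant that stacks
several consecutive time points into one joint NNLS approximates the
collocation spirit of the cited alternative; it is labeled an
approximation.  The pseudo-batch correction
$$c^{\mathrm{batch}}_i(t) = \frac{c_i(t)V(t) - \int_0^t F c_{i,\mathrm{feed}}
  - \int_0^t q_{i,\mathrm{gas}} V}{V_{\mathrm{ref}}}$$
reconstructs $V(t)$ from the feed profile and compensates feed,
dilution and gas transfer; the published appendix describing the
original procedure was unavailable, so this form is stated here as the
package's own definition, verified by a simulator round trip (fed-batch
shifted data vs. an independently integrated batch equivalent, to
$10^{-4}$ relative — the agreement is limited by the dense-output
interpolation of the oracle, not by the correction itself).

## Validation problem sizes

The test suite and the acceptance script work at deliberately small
scale, chosen as the smallest sizes at which every property is
informative: 4–10 candidate modes, 3–5 inflection nodes, 9–17 sampling
times, 20 benchmark replicates per noise level, 200 outer replications
of 50-sample bootstraps for the coverage study, and exhaustive
enumeration of all 1023 subsets of a 10-mode instance as the oracle for
the genetic algorithm.  Production-scale settings (500 bootstrap
samples, population 100 × 200 generations) remain the documented
defaults.

## Units

Times are hours; concentrations mM (mmol/l); viable cells
$10^6\,$cells/ml.  Volumetric rates $R_k$ are mM/h.  `specific_rates()`
converts to mmol/($10^6$ cells)/h via the single ml↔l factor
`scale = 1e-3`; `scale = 1` returns the bare ratio $R_k/X_v$, which is
what the simulator's kinetics are defined in.

## Known limitations

* EM enumeration is exact double description with support-minimality
  filtering — fine up to a few dozen reactions, not competitive with
  dedicated enumerators; import externally computed matrices with
  `read_em_matrix()` beyond that.
* The piecewise-linear flux class smooths aggressively: under strongly
  exponential growth with few nodes the fit carries visible bias (this
  is also why the zero-noise benchmark can favor derivative-based
  estimators, while any realistic noise reverses the ordering).
* $X_v$ enters the regularization and the specific-rate conversion as a
  linear interpolant of its *measured* series, keeping the objective
  quadratic; a fitted $\hat X_v$ would couple the problem nonlinearly.
* Isotope-resolved MFA, thermodynamic constraints and B-spline flux
  classes are out of scope.
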