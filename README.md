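# dmfa — dynamic metabolic flux analysis with elementary-mode selection

`dmfa` estimates time-varying metabolic reaction rates of fermentation
processes **directly from noisy concentration measurements**, and
selects minimal sets of elementary modes (EMs) for macroscopic process
models. It is aimed at bioprocess modelers who have time courses of
medium components and viable cell density from (fed-)batch cultures —
for example CHO platform processes — and want macro-reaction rates with
honest uncertainty bounds, without ever differentiating noisy data.

## The method in brief

Concentrations evolve as `dc/dt = P ν(t) Xv(t)` with external
stoichiometry `P`, cell-specific fluxes `ν` and viable cell density
`Xv`. At pseudo steady state of the internal metabolites (`N V = 0`,
`V = ν Xv` the volumetric fluxes), `V = K U` with `K = null(N)`.
Dynamic metabolic flux analysis (DMFA) assumes the free fluxes `U(t)`
are **piecewise linear between inflection points** `T_j`, which makes
every fitted concentration a linear function of the node values, and
minimizes the standardized residual sum

    SSR = Σ_i Σ_j ( (c_i(t_j) − ĉ_i(t_j)) / σ_i(t_j) )²

Four estimators share that machinery:

| mode             | constraint                      | use                                |
|------------------|---------------------------------|------------------------------------|
| `unbounded`      | none                            | quick diagnostic                   |
| `bounded`        | `K_irr U(T_j) ≥ 0`              | best attainable fit of the network |
| `em`             | `V = E R`, `R_k(T_j) ≥ 0`       | rates of elementary modes          |
| `em_regularized` | `em` + `α Σ (R_k(T_j)/Xv(T_j))²`| large, collinear mode sets         |

With the complete mode set the `em` optimum equals the `bounded`
optimum (both feasible sets are the same flux cone); removing essential
modes strictly increases the SSR — this gap is what drives mode
selection. The regularization weight `α` is chosen by time-point
cross-validation; confidence bounds come from bootstrap resampling of
the measurements with randomized inflection points; minimal mode
subsets are found by an NSGA-II genetic algorithm over binary
inclusion chromosomes, with the exact Pareto trade-off between subset
size and SSR.

The package also contains a fed-batch simulator (known EM set, Monod
kinetics, feed dilution, affine measurement noise), a pseudo-batch
("shifting") correction for fed-batch data, elementary-mode
enumeration for small networks, geometrical reduction of large EM sets
by cosine similarity, and the classical derivative-then-NNLS rate
estimators as baselines.

## Worked example

Simulate the bundled fed-batch scenario, fit the elementary-mode
estimator with cross-validated regularization, and bootstrap the
specific rates:

```r
library(dmfa)

sc   <- simulation_scenario()          # 4 EMs, 6 medium species + Xv, 120 h
sim  <- simulate_scenario(sc)
d    <- sample_measurements(sim, rng = 42)   # 5%-CI Gaussian noise
print(d)
#> Measurement set: 7 species, 16 time points, 112 observations

grid <- inflection_grid(d, n_nodes = 5)
xv   <- xv_interpolant(d)
cv   <- cross_validate_alpha(d, sc$E, grid, alphas = 10^seq(-4, 2),
                             folds = 4, seed = 1, xv = xv)
fit  <- solve_em(d, sc$E, grid, alpha = cv$alpha, xv = xv)
print(fit)
#> DMFA fit (em_regularized): 4 flux directions, 5 inflection nodes,
#> SSR = 11549.64, alpha = 100

ens <- dmfa_bootstrap(d, sc$noise, grid, E = sc$E, mode = "em",
                      n_samples = 200, seed = 7, xv = xv, scale = 1,
                      eval_times = c(24, 60, 96))
subset(ens$bands$specific, time == 60)
#>  quantity time median   lo68   hi68   lo95   hi95
#>       EM1   60 0.0892 0.0817 0.0973 0.0745 0.1045
#>       EM2   60 0.0371 0.0341 0.0419 0.0306 0.0442
#>       EM3   60 0.0000 0.0000 0.0000 0.0000 0.0000
#>       EM4   60 0.0325 0.0296 0.0360 0.0276 0.0386
```

The bands are cell-specific rates (here as the bare ratio `R/Xv`;
`scale = 1e-3` converts to mmol/10⁶ cells/h). The true rates at 60 h
are (0.0762, 0.0498, 0.0020, 0.0285): the estimates carry the
smoothing bias of the piecewise-linear flux class under exponential
growth — see the methods vignette — while the band widths quantify the
measurement-noise uncertainty.

Where DMFA pays off is robustness. Reconstruction error
`mean |r̂ − r_true|` against the derivative-based baselines:

```r
run_benchmark(sc, noise_levels = c(0, 0.05), n_replicates = 10,
              seed = 3)$table
#>                     method    noise_0 noise_0.05
#>                   dmfa_reg 0.02072926 0.01228256
#>          poolman_ma_filter 0.02665650 0.03709815
#>  poolman_smoothing_splines 0.02806524 0.04183532
#>            poolman_splines 0.02813194 0.06178991
#>              soons_splines 0.02236384 0.04411638
```

At realistic noise (95% CI = 5% of magnitude) the regularized DMFA
error is five times smaller than spline-differentiated rates; without
noise the more flexible derivative methods close the gap.

Mode selection on a network file:

```r
net  <- read_network(system.file("extdata", "toy_network.txt", package = "dmfa"))
ems  <- enumerate_ems(net)             # 4 modes, unit-norm macro-reactions
front <- nsga2_select(datasets, ems$E, grid, seed = 1)
knee_report(front, ssr_bound = solve_bounded(datasets, net, grid)$SSR)
```

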