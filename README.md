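# hetassoc

Quantifying cell-to-cell heterogeneity in nano-engineered particle–cell
association kinetics from routine flow cytometry time courses.

## The problem

Incubate fluorescently labelled particles with cells; measure tens of
thousands of single-cell fluorescence values at a handful of time points by
flow cytometry; ask how fast particles associate with cells and how many a
cell can carry. The conventional pipeline collapses each time point to its
median fluorescence, fits a homogeneous two-parameter uptake model, and
reports one association rate `r` and one carrying capacity `K` for the whole
population. Real populations are heterogeneous, and the controls routinely
acquired alongside the experiment (cell-only autofluorescence, single-particle
fluorescence) are themselves noisy and right-skewed — information the median
pipeline discards and biases it ignores.

`hetassoc` models the population hierarchically and fits it to the *full*
fluorescence distributions:

* per-cell traits `r_j ~ LogNormal(mean m_r, SD s_r)`,
  `K_j ~ LogNormal(mean m_K, SD s_K)`, independent across and within cells;
* per-cell kinetics
  `P_j(t) = K_j (1 − exp(−(C S r_j / K_j) ∫₀ᵗ ū))`,
  the fast decoupled form of the coupled cell–media depletion ODE system
  (`du/dt = −(C S r / V)(1 − P/K) u`, `P = V(u0 − u)`), with the full
  `N + 1`-dimensional coupled system available as a verification oracle;
* a generative fluorescence model that resamples the empirical controls:
  one autofluorescence draw plus `⌊P⌋` single-particle draws plus a
  fractional draw per cell and time point;
* ABC-SMC inference of `(m_r, s_r, m_K, s_K)` under uniform priors, with
  the summed two-sample Anderson–Darling distance (Cramér–von Mises and
  Kolmogorov–Smirnov variants included) between observed and simulated
  fluorescence distributions at each time point;
* posterior predictions: particles-per-cell bands, fluorescence histogram
  bands, inferred `r`/`K` distributions, and the percentage of cells within a
  fraction β of their own capacity;
* the conventional median-transform + least-squares pipeline and the
  per-cell transform, as baselines;
* exhaustive Bayesian design search over measurement time points (all
  `choose(14, 6) = 3003` six-point designs on the standard candidate grid),
  scored by the mean inverse determinant of the rejection-ABC posterior
  covariance over pre-simulated scenario datasets.

## Worked example

Simulate a synthetic experiment with known heterogeneity, fit it, and
summarise the posterior:

```r
library(hetassoc)

consts   <- default_constants()                      # C, S, V, u0
controls <- generate_control_fixtures(seed = 101)    # Dcells, Dparticles
truth    <- c(m_r = 2.96e-7, s_r = 2.92e-6,          # generating values
              m_K = 51.2,    s_K = 53.3)
obs <- simulate_dataset(truth, consts, times = c(1, 2, 4, 8, 16, 24),
                        controls, n_cells = 2000, seed = 202)

fit <- abc_smc(obs, controls = controls, consts = consts,
               n_particles = 200, n_cells = 2000,
               min_acceptance = 0.01, max_generations = 25, seed = 303)
summary(fit)
```

```
Posterior summary (95% HPD):
  parameter    median hpd_lower hpd_upper hpd_frac_prior
1       m_r 3.652e-07 2.181e-07 6.667e-07       0.004486
2       s_r 3.822e-06 1.448e-06 1.079e-05       0.093423
3       m_K 8.723e+01 3.897e+01 1.294e+02       0.181211
4       s_K 2.642e+02 4.024e+01 4.550e+02       0.829733
```

Each generating value lies inside its 95% highest-posterior-density
interval, and the posterior median of the rate mean `m_r` sits within ~23%
of the truth. `hpd_frac_prior` is the width of the HPD interval as a
fraction of the prior width — the package's practical-identifiability
diagnostic (values near 1 mean the parameter is returned at its prior).
Here the rate hyperparameters and `m_K` are well informed, while `s_K` is
only weakly identified at this scaled-down sample size: the posterior rides
the `m_K`–`s_K` ridge along which the implied capacity distributions have
the same bulk quantiles, so its `m_K` median sits above the generating
value even though the truth is well inside the HPD. At the full experimental
scale (20,000 cells per time point, 1000 SMC particles) the ridge narrows
and the capacity hyperparameters tighten substantially.

Downstream of a fit:

```r
predict(fit, "pband")                     # P(t) median, 50% and 95% bands
predict(fit, "distribution", trait = "K") # inferred capacity distribution
predict(fit, "fraction", beta = 0.5)      # % of cells above half capacity
plot(fit)                                 # posterior marginals

po <- median_transform(obs, controls)     # conventional baseline
least_squares_fit(po, consts)             # homogeneous point estimate
```

Design search (scaled-down settings):

```r
res <- design_search(design_scenarios()$low, controls = generate_control_fixtures(seed = 1),
                     n_pre = 2000, j_reps = 5, n_cells = 1000, seed = 1)
head(res[order(res$rank), ])              # best six-time-point designs
```

A thin command-line interface over the same functions ships at
`inst/cli/hetassoc.R` (subcommands `simulate`, `fit`, `predict`, `baseline`,
`design`; every run writes its seed and resolved configuration to
`run.json`).

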