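---
title: "Methods: heterogeneous particle-cell association kinetics from flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous particle-cell association kinetics from flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Incubating nano-engineered particles with cultured cells and measuring
per-cell fluorescence by flow cytometry is the routine way to characterise
how strongly a particle formulation associates with a cell type. Each time
point yields tens of thousands of single-cell fluorescence values, yet the
conventional analysis reduces every time point to one number (the median
fluorescence intensity), fits a homogeneous two-parameter uptake model and
reports a single association rate and carrying capacity. That discards the
cell-to-cell heterogeneity which the raw data resolve, and it conflates
biological variability with the optical variability already present in the
routine control measurements.

`hetassoc` implements a hierarchical alternative: every cell carries its own
association rate and capacity drawn from lognormal laws, simulated
fluorescence inherits the empirical noise of the control data, and the four
hyperparameters of the heterogeneity laws are inferred from the full
fluorescence distributions by likelihood-free (ABC) methods.

## Mechanistic models

### Homogeneous population

With fractional available surface coverage $C$ (dimensionless), cell surface
area $S$ (m$^2$), media volume per cell $V$ (m$^3$) and initial particle
concentration $u_0$ (particles cell$^{-1}$ m$^{-3}$), a homogeneous
population with association rate $r$ (m s$^{-1}$) and carrying capacity $K$
(particles cell$^{-1}$) depletes the well-mixed media according to

$$\frac{du}{dt} = -\frac{C S r}{V}\Big(1 - \frac{P}{K}\Big)u, \qquad
  P(t) = V\,(u_0 - u(t)),$$

whose closed form (`homogeneous_solution()`) is

$$P(t) = V u_0 \left(1 -
  \frac{V u_0 - K}{V u_0 - K\,e^{-r C S (V u_0 - K)\,t/(K V)}}\right),$$

with the separate limit $P(t) = r C S K u_0 t / (K + r C S u_0 t)$ when
$K = V u_0$. The implementation switches to the limiting branch when
$|V u_0 - K|/(V u_0) < 10^{-9}$; at that scale the generic branch loses
all significant digits to cancellation while the two expressions agree to
within the switching tolerance, so the solution is continuous across the
switch. $K$ is phenomenological: particles may associate and dissociate
rapidly, and $K$ simply captures the observed saturation.

Times are accepted in hours at every user-facing interface and converted to
seconds internally, so that $r$ in m s$^{-1}$ is dimensionally consistent
with $S$ in m$^2$ and $V$ in m$^3$.

### Heterogeneous population

Cell-to-cell variability is modelled by giving cell $j$ its own pair
$(r_j, K_j)$, drawn independently from lognormal distributions parameterised
directly by their natural-scale means and standard deviations
$(m_r, s_r, m_K, s_K)$ (`lognormal_natural_params()` maps these to the
log-scale location and scale). Independence of $r$ and $K$ within a cell is
an assumption, not an inference.

The exact heterogeneous model couples $N$ cells through the shared media:

$$\frac{dP_j}{dt} = C S r_j \Big(1 - \frac{P_j}{K_j}\Big) u, \qquad
  \frac{du}{dt} = -\frac{C S}{N V} \sum_j r_j \Big(1 - \frac{P_j}{K_j}\Big) u,$$

which conserves $N V u + \sum_j P_j$ and captures competition: fast cells
deplete the media available to slow cells. `heterogeneous_solution_full()`
integrates this $N{+}1$-dimensional system (via `deSolve`) and serves as the
verification oracle, but it is far too slow for inference, where the model
must be simulated tens of thousands of times.

The workhorse is the decoupled approximation
(`heterogeneous_solution_approx()`): the shared concentration is replaced by
a deterministic mean trajectory $\bar u(t)$, and each cell then solves
independently to

$$P_j(t) = K_j\Big(1 - \exp\big(-\tfrac{C S r_j}{K_j}
  \int_0^t \bar u(\hat t)\, d\hat t\big)\Big).$$

$\bar u(t) = u_0 - \overline{P_{\mathrm{hom}}}(t)/V$ is estimated by
averaging $M = 100$ evaluations of the homogeneous solution at traits drawn
from the heterogeneity law (`media_concentration_approx()`), on a uniform
grid of 1001 points, with the cumulative integral accumulated by the
trapezoid rule and interpolated linearly at measurement times. $\bar u$ is
smooth, monotone and varies by at most $m_K/(V u_0)$ in relative terms, so
the quadrature error is orders of magnitude below the Monte Carlo error of
the $M$-sample average; $M = 100$ follows the usual accuracy/cost trade-off
for this estimator. The approximation is accurate exactly when uptake is
small relative to supply ($P \ll V u_0$), which is the typical experimental
regime; the package's tests verify <1% per-cell error against the full
coupled system in that regime and that the error shrinks monotonically as
$u_0$ grows. When all cells are identical the approximate form reduces
exactly to the homogeneous solution (the integral form of the same ODE), so
the degenerate limit $s_r = s_K = 0$ is exact up to quadrature error.

## Generative flow cytometry model

Calibrated control data enter the likelihood-free machinery as empirical
noise distributions, never as fitted parametric forms. A simulated reading
for a cell carrying $p$ particles (`simulate_fluorescence()`) is

* one autofluorescence draw from the cell-only control, plus
* $\lfloor p \rfloor$ independent draws from the particle-only control, plus
* the fractional remainder $p - \lfloor p \rfloor$ times one further
  particle draw.

All control resampling is uniform with replacement and independent across
cells, particles and time points. Because the data are snapshots (no cell is
measured twice), each (cell, time) pair receives fresh noise draws, while the
cell's latent trajectory $P_j(t)$ is retained across time points.
`median_fluorescence()` is the deterministic counterpart built on control
medians, used by the baseline transforms.

The bundled fixture generator (`generate_control_fixtures()`) emits
right-skewed, strictly positive samples (lognormal on the log scale) with
default sizes 11,605 (cell-only) and 500,000 (particle-only), matching
typical acquisition counts. The default log-scales (cell median 200 AU,
`sdlog` 0.7; particle median 30 AU, `sdlog` 0.5) emulate a fluorescently
labelled particle assay: a single particle's fluorescence sits well below
the spread of cell autofluorescence — so individual particles cannot be
resolved and distribution-level inference is needed — while a
capacity-scale load of tens of particles dominates the weak autofluorescence
background, which is what makes the assay informative at all. (A background
that drowned the particle signal would render the hyperparameters
unidentifiable at any realistic sample size.) What the generator
does *not* emulate: instrument-specific calibration artefacts, negative
calibrated values, debris/doublet gating, or day effects between replicates.
Passing tests on these fixtures therefore demonstrate correctness of the
inferential machinery under the model's own assumptions, not robustness to
real-data misspecification.

Experimental constants default to $C = 0.3$, $S = 4.5 \times 10^{-10}$ m$^2$
(a cell of roughly 6 µm radius), $V = 10^{-10}$ m$^3$ and
$u_0 = 10^{13}$ particles cell$^{-1}$ m$^{-3}$, i.e. a dose of
$V u_0 = 1000$ particles available per cell — supply well above typical
capacities, as in the motivating experiments. These are placeholders for a
concrete setup and are configurable everywhere; no operation hard-codes them.

## ABC-SMC inference

`abc_smc()` infers $(m_r, s_r, m_K, s_K)$ under independent uniform priors
(defaults: $m_r, s_r \in [10^{-9}, 10^{-4}]$ m s$^{-1}$,
$m_K \in [1, 500]$, $s_K \in [0.1, 500]$ particles cell$^{-1}$). The
discrepancy between an observed and a simulated time course is the sum over
time points of a two-sample statistic; the default is the tie-adjusted,
non-standardized two-sample Anderson-Darling statistic of the $k$-sample
family, with Cramér-von Mises and Kolmogorov-Smirnov variants available
through the same registry. AD weights the distribution tails more strongly
than CvM/KS, which matters here because the informative cells (those far
from the bulk) sit in the tails; comparing fits across distances is the
recommended robustness check.

The sampler is the standard adaptive SMC scheme: generation 1 is a
prior-predictive sample; each subsequent generation resamples ancestors by
weight, perturbs with a multivariate Gaussian kernel **on the log scale**
(the hyperparameters are positive and span several orders of magnitude, so
a natural-scale kernel wastes nearly every mid-run proposal) with covariance
twice the weighted empirical covariance of the log-parameters, discards
proposals outside the prior before simulating, accepts simulated datasets
within the current threshold, and corrects weights by the kernel mixture
density including the log-transform Jacobian (computed stably in log space;
with uniform priors the prior density cancels). The threshold sequence is
the median of the previous generation's accepted distances.

**Termination.** When a target threshold is supplied (as when matching a
previous analysis), the run stops on reaching it. Otherwise the run stops
at the simulator's *noise floor*: each generation, replicate datasets are
re-simulated at the best-supported particles and their distances to the
observation measured; once the next threshold would dip to or below the
smallest mean replicate distance, tightening further can only fit the
sampling noise of the particular observed dataset — which measurably biases
the posterior along weakly identified directions — so the run stops there.
An acceptance-rate floor (`min_acceptance`, default 2%) acts as a cost
backstop. A fixed target at a low quantile (e.g. the 1st percentile) of the
prior-predictive distances is *not* a good default for these models: it sits
roughly an order of magnitude above the noise floor, terminating the sampler
long before the posterior concentrates.

Posterior summaries use weighted quantiles and highest-posterior-density
intervals computed by a shortest-window scan over the weighted cumulative
mass on sorted samples — deterministic, with no resampling noise in the
endpoints. `summary()` reports each HPD width as a fraction of the prior
width: the package's practical-identifiability diagnostic (fractions near 1
mean the parameter is returned at its prior).

### Posterior prediction

All predictions propagate weighted posterior draws through the generative
model: fluorescence histogram bands (per-bin quantiles of bar heights on
bins shared with the observed data, count scale), particles-per-cell bands
(cells pooled across posterior draws; the 50% band is the pooled IQR),
inferred lognormal densities for $r$ and $K$ (pointwise weighted quantiles),
and the percentage of cells above a fraction $\beta$ of their own capacity
(default $\beta = 0.5$). Pooling cells across draws mixes parameter
uncertainty with biological variability — the relevant view for "how many
particles do cells carry"; per-draw nesting can be recovered from
`simulate()` if needed.

## Baselines

`median_transform()` and `least_squares_fit()` reproduce the conventional
pipeline: medians of the observed fluorescence mapped through the control
medians to point estimates $P_o(t_i)$ (with $P_o(0) = 0$), then an
unweighted least-squares fit of the homogeneous solution on
$(\log r, \log K)$ with bounded quasi-Newton iterations from ten
log-uniform starts (rates span orders of magnitude, so a single start on the
natural scale is unreliable). The objective includes $t = 0$, where both
sides vanish; no Gaussian error model is attached because nothing suggests
those assumptions hold for these data — the fit reports its SSE and nothing
more. The known structural non-identifiability of $C S r$ (only the product
is constrained) is documented and deliberately not resolved.

`per_cell_transform()` applies the same map to every single-cell value.
When the signal is close to background, roughly half the transformed values
are negative; they are preserved, and the negative fraction is always
reported, because discarding them biases the remaining sample upward.

The methodological point reproduced by the package's tests: with
right-skewed controls the median-transform pipeline systematically
overestimates the true median of $P(t)$ (the sum of $p$ skewed particle
draws concentrates near $p$ times the *mean*, which exceeds $p$ times the
*median* used by the transform), while the ABC pipeline's prediction bands
cover the truth.

## Optimal design of measurement times

A design is a set of six distinct times from the candidate grid 0.5 h, 1 h,
2 h, 4 h, ..., 24 h (14 candidates, hence 3003 designs, enumerated
exhaustively). Designs are scored by a pre-simulation (reference table)
strategy: `n_pre` prior draws are each simulated once over the *full*
candidate grid; per-time-point noise is keyed on the time label, so
restricting a table row to a design's columns is exactly the dataset that
would have been simulated at those times under the same seed. For each of
`j_reps` scenario datasets (hyperparameters drawn from positive-truncated
Gaussians with CV 0.1 about the scenario means), a design's rejection-ABC
posterior is the `n_accept = 200` prior draws with the smallest summed
distance over the design's time points — a fixed-count acceptance, which
keeps posterior size exactly comparable across designs, rather than a global
threshold that merely bounds it below. The utility is the mean over scenario
datasets of $1/\det(\mathrm{Cov}(\theta))$ on the accepted set, capped at
$10^{12}$ per set so that a degenerate acceptance set cannot dominate the
ranking. Per-scenario utilities are normalised to a maximum of one; an
overall design for unknown rate minimises the average rank across scenarios.

The table is shared across all designs and scenario datasets (the standard
efficiency device for rejection-based design search); desk-scale defaults
are `n_pre = 2000`, `n_cells = 1000`, `j_reps = 5`, with production-scale
values available through the same configuration.

## Numerical and design choices

* **Branch tolerance** $10^{-9}$ on $|Vu_0 - K|/(Vu_0)$ for the analytic
  solution, as above.
* **Media grid** 1001 uniform points on $[0, t_{\max}]$; linear
  interpolation of the cumulative integral; error negligible against the
  $M = 100$ Monte Carlo error.
* **RNG discipline**: every stochastic operation takes an explicit seed and
  restores the caller's RNG state; inside composite algorithms the
  sequential stream keeps runs bit-reproducible from the single run seed.
  Per-time-point sub-seeds are derived from the master seed and the time
  label (small-integer arithmetic, safely below $2^{31}$).
* **Ties** in the distance statistics are handled by the midrank form of
  the AD statistic and multiplicity-weighted ECDF sums for CvM; continuous
  fluorescence data rarely tie, but transformed or rounded data may.
* **Degenerate inputs**: $s = 0$ heterogeneity is accepted and exact
  (degenerate lognormal); identical samples give distance 0 (KS/CvM and
  tie-adjusted AD); HPD of constant samples is a point; singular design
  covariances hit the utility cap rather than propagating `Inf`.
* **Problem sizes in the test-suite**: the bundled end-to-end checks run
  scaled-down configurations chosen for a single CPU — recovery at 200 SMC
  particles and 2000 cells per time point; identifiability-regime runs at
  100 particles and 500 cells; design search at `n_pre = 2000`,
  `j_reps = 5`, 1000 cells. These sizes are the package's own choices for
  routine verification; production analyses should scale all of them up
  (the motivating analyses used 1000 particles, 20,000 cells,
  `n_pre = 200000`, `j_reps = 20`).
* **Compiled hot paths**: the control-resampling noise model and the three
  two-sample statistics are implemented in C++ (Rcpp), drawing from R's RNG
  stream so that seed-reproducibility is preserved; the observed samples are
  pre-sorted once per fit so the statistics only sort the simulated sample.

## Known limitations

* The decoupled approximation assumes weak media depletion; with doses
  comparable to total capacity ($V u_0 \lesssim N$-average $K$), use the
  full coupled solver or expect biased late-time predictions.
* Lognormal heterogeneity and $r \perp K$ within cells are modelling
  choices; misspecification shows up as prediction intervals that miss the
  data (the histogram-band check), not as estimation failure.
* Identifiability is regime-dependent: with slow rates the capacity
  hyperparameters return their prior (no saturation observed); with fast
  rates the rate hyperparameters do (no transient observed). The
  `hpd_frac_prior` diagnostic makes this visible; predictions of $P(t)$
  remain accurate in all regimes because the ABC fit matches the observed
  distributions by construction.
* At reduced sample sizes (thousands rather than tens of thousands of cells
  per time point) and under strongly heterogeneous rates, the capacity law
  is identified mainly through its bulk quantiles: a cell only reveals its
  $K_j$ if it saturates, which requires a large $r_j$, so the upper $K$ tail
  stays invisible. The posterior then pins the median of $K$ tightly while
  $(m_K, s_K)$ trade off along a ridge of equal bulk quantiles, and with a
  wide uniform prior most ridge mass sits at large $s_K$ — so the posterior
  *median* of the mean-parameterised $m_K$ can sit well above the generating
  value even though the generating values remain inside all HPD intervals.
  Scaling the experiment up tightens the ridge (the distance statistics gain
  resolution linearly in sample size); so does a more informative prior on
  $s_K$ when one is defensible.
* Proliferation, media exchange, particle degradation and spatial transport
  are out of scope.
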