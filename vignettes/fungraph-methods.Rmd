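---
title: "From functional mapping to genetic interaction networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From functional mapping to genetic interaction networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`fungraph` maps quantitative trait loci (QTLs) for longitudinal growth
traits and then reconstructs, from the per-marker fits, a multilayer,
bidirectional, signed and weighted genetic interaction network.  The
pipeline has four stages:

1. **Functional mapping.**  Each marker is tested by a likelihood-ratio
   (LR) scan in which genotype classes carry their own logistic growth
   curves and residuals follow a first-order structured antedependence
   (SAD(1)) covariance.  Genome-wide significance comes from permutation.
2. **Effect curves.**  Each fitted marker is summarised by its age-varying
   genetic standard deviation, a curve over the common age grid.
3. **Functional clustering.**  Effect curves are clustered into modules
   (and submodules, recursively) by an EM mixture with BIC model selection,
   producing the layers of the network.
4. **Effect dynamics.**  Within each layer, every node's effect curve is
   modelled by a Lotka-Volterra ordinary differential equation whose
   right-hand side splits into an *independent* component (the node's own
   state) and sparse *dependent* components (regulation by selected other
   nodes).  The fitted dependent components become signed, weighted,
   directed edges, and each reciprocal pair is classified into one of seven
   epistasis types.

# Functional mapping

## Model

For individual $i$ with measurements $y_i(t_{i1}),\dots,y_i(t_{iT_i})$ and
genotype class $j$ at the scanned marker, the model is multivariate normal
with mean vector
$$\mu_j(t) = \frac{a_j}{1 + b_j e^{-r_j t}}$$
($a_j$ asymptotic size, $b_j$ initial-condition parameter, $r_j$ relative
growth rate) and a covariance shared by all classes.  The SAD(1) residual
process is $e_t = \phi\, e_{t-1} + \epsilon_t$ with
$\epsilon_t \sim N(0, \nu^2)$ and $e_0 = 0$ at the first measurement; the
lag index is the *position* in the individual's grid, so irregular spacing
is handled ordinally and no stationarity is assumed.  The factorisation
$\Sigma = L D L^\top$ (with $L$ unit lower triangular and $D = \nu^2 I$)
gives $\log|\Sigma| = T\log\nu^2$ and a tridiagonal inverse, so each
likelihood evaluation costs $O(T)$ per individual.

The null model (H0) forces one growth curve for everyone; the LR statistic
is $2(\ell_1 - \ell_0)$, clipped at zero.  An advisory p-value uses a
chi-square with $3(J-1)$ degrees of freedom (the constrained growth
parameters); the primary genome-wide device is the permutation threshold:
individuals are re-paired with genotypes (trajectories kept intact), the
scan maximum is recorded for each of $B$ permutations, and the threshold is
the empirical $1-\alpha$ quantile of the maxima.

## Numerics

Maximisation is Nelder-Mead simplex over log-transformed growth parameters
(positivity by construction), with $(\phi, \nu^2)$ profiled out in closed
form at every objective evaluation — the profile maximiser for SAD(1) is
exact, which both shrinks the search space and removes the need for
covariance bounds ($\phi$ is clamped to $[-2, 2]$ for numerical safety;
values of $|\phi| \ge 1$ are legitimate and give variance growing with
age).  H1 fits start from the pooled (H0) fit replicated across classes,
plus jittered restarts; because the H0 optimum is a vertex of the initial
H1 simplex, the LR is non-negative by construction.  Permutation scans use
a single start seeded from the pooled fit — under permutation the null is
the truth, so the pooled start is already near the optimum; this was
checked against multi-start, high-precision settings (threshold differences
within quantile noise).  The likelihood kernel and simplex run in compiled
code; a permutation study with $m = 50$ markers and $B = 200$ runs in a few
seconds.

Genotype classes with fewer than 3 members are dropped at that marker (the
marker is flagged, $J$ reduces); individuals missing a genotype are dropped
for that marker only.

## Effect curves and plasticity

The genetic effect curve of marker $s$ is the age-varying genetic standard
deviation
$$z_s(\tau) = \sqrt{\tfrac1n \sum_j n_j\, (\mu_j(\tau) - \bar\mu_s(\tau))^2},
\qquad \bar\mu_s(\tau) = \sum_j \tfrac{n_j}{n}\mu_j(\tau),$$
computed with *observed* class frequencies.  For two-condition designs the
mapped trait can be phenotypic plasticity, defined per individual as
control minus stress (larger values = stronger growth suppression by the
stress); misaligned age grids are linearly interpolated onto the shared
overlap.

# Functional clustering

Effect curves are clustered by an EM mixture of multivariate normals whose
component means are Legendre-polynomial (LOP) expansions of order $Q$
(default 4) over the common grid — effect curves are differences of
logistics and need not be logistic themselves — and whose component
covariance is SAD(1)-structured, shared across components.  Inside each
M-step the mean coefficients are updated by generalised least squares and
$(\phi,\nu^2)$ by their closed-form conditional maximisers; this is a
generalised EM, so the log-likelihood is non-decreasing (asserted at every
iteration).  Initialisation is k-means on raw curves with restarts.

Model selection uses $\mathrm{BIC} = -2\log L + p \log N$ with
$p = K(Q{+}1) + (K{-}1) + 2$ and $N$ = the number of curves (curves, not
curve-by-age points, are the exchangeable units).  The module tree applies
`select_K` recursively until every leaf has at most $M$ members (default
30, a size tractable for the ODE stage), K = 1 is selected, or a depth cap
of 6 is reached.

# Effect dynamics and the network

## The decomposition model

Within a layer, node $s$'s curve obeys
$$\frac{dz_s}{dt} = Q_s(z_s;\Phi_s) +
  \sum_{s' \in R_s} Q_{ss'}(z_{s'};\Phi_{ss'}),$$
where $Q_s$ (the independent component) and each $Q_{ss'}$ (dependent
components) are Legendre expansions of their argument affinely mapped to
$[-1,1]$ over the node's padded observed range (defaults: order 3 for both;
arguments outside the range are clamped).  The regulator set $R_s$ is
sparse ($|R_s| \le d_{\max}$, default 5).

## Regulator selection

Selection works on the *integral form* of the equation: integrating from
the first age,
$$z_s(t_k) - z_s(t_1) = \int_{t_1}^{t_k} Q_s +
  \sum_{s'} \int_{t_1}^{t_k} Q_{ss'} + \text{noise}.$$
The response is the vector of raw observed increments — whose errors are
the original measurement errors — and each candidate block is the running
time-integral of the LOP expansion of a smoothed state curve.  An intercept
absorbs the $-\epsilon(t_1)$ term shared by all increments.  This is
deliberate: the more obvious derivative-matching regression (smoothed
$dz/d\tau$ on state expansions) was implemented first and found
unrecoverable — differentiating a smoother yields *smooth, correlated*
errors which competing smooth curve blocks fit better than white noise,
so the selection criterion cannot separate true regulators from mimics at
any noise level.

The self block is never penalised or dropped, so the independent component
cannot be selected away.  Regulator blocks use a parsimonious
order-1 expansion at the selection stage (`K_sel`); the subsequent ODE fit
uses the full order.  Support is chosen by best-subset search — exhaustive
to three regulators, greedy with swap refinement up to $d_{\max}$ — under
the extended BIC
$$T\log(\mathrm{RSS}/T) + p\log T + 2\gamma\log\binom{m-1}{k},$$
with $\gamma = 2$ by default: candidate blocks are few-sample, highly
collinear curves, and the plain BIC systematically over-selects.  When a
layer has many nodes, candidates are first screened to 24 by the union of
LASSO path entry order (blocks that matter jointly) and marginal
residualised fit (which protects blocks whose signal is partly collinear
with the self block and therefore enters the LASSO path late).

## ODE fitting and decomposition

Given the selected regulators, coefficients are estimated by nonlinear
least squares: the reduced ODE is solved by classic fourth-order
Runge-Kutta (RK4) from the first observed value, with regulator curves
treated as known forcing functions (cubic interpolants of their smoothed
curves, evaluated once at all RK4 stage times), and the squared deviation
from the observed curve is minimised by Nelder-Mead started from a
gradient-matching regression.  Because the forcing terms do not depend on
the state, each objective evaluation is one matrix-vector product plus a
scalar RK4 sweep in compiled code.

The decomposition integrates $Q_s$ along the fitted trajectory with the
same RK4 stages and each $Q_{ss'}$ with the matching Simpson rule, so
$$I_s(\tau) + \sum_{s'} D_{ss'}(\tau) = \hat z_s(\tau)$$
holds to rounding error by construction (the conservation identity).

**Constant attribution.**  In an additive model only one constant is
identifiable, yet the sign of an edge is read off the time-integrated
dependent effect.  The package therefore anchors each dependent function at
zero raw argument — a regulator whose effect curve is zero exerts no
regulation, a natural convention when the state is a genetic standard
deviation — and lets the independent component absorb the complementary
constants.  Without an anchoring convention the split of constants, and
hence edge signs, would be arbitrary.

## Edges and epistasis types

The weight of edge $s' \to s$ is the time-averaged dependent effect
$W_{s\leftarrow s'} = D_{ss'}(\tau_T) / (\tau_T - \tau_1)$.  Reciprocal
pairs are classified into seven qualitative types (symmetric, asymmetric
and directional epistasis, each positive or negative, plus
altruistic/repressive for opposite signs).  The qualitative definitions
need two thresholds, chosen here as $\varepsilon$ = 5% of the layer's
largest $|W|$ (zero threshold) and $\delta = 0.2$ (relative tolerance for
"the same extent"); both are recorded in the export metadata.  The
classification is exhaustive and mutually exclusive over
$(u,v)\in\mathbb R^2$ and maps positive to negative labels under
$(u,v)\mapsto(-u,-v)$.

# The synthetic-data generator

`simulate_population()` emulates the mapping design: biallelic genotypes
drawn binomially at given allele frequencies (two or three classes,
heterozygote midway — no dominance), phenotypes as genotype-class logistic
means plus SAD(1) noise, optional paired stress/control conditions sharing
individuals.  It does *not* emulate linkage disequilibrium, population
structure or kinship, so passing tests say nothing about confounding in
structured populations.

`simulate_effect_system()` plants interaction systems of exactly the form
the inference fits (relaxation-plus-coupling dynamics, linear edge
functions $\beta z_{s'}$, RK4 integration, observation noise proportional
to each curve's range).  The default benchmark topology deserves comment.
Slowly relaxing trajectories — the "obvious" fixture — are provably
uninformative: all curves are near-collinear mixtures of a few decaying
modes, and even exhaustive best-subset selection with noise-free data picks
mimicking regulator sets.  Support recovery from a single trajectory
requires persistent excitation, so the benchmark plants antisymmetrically
coupled node pairs whose coupling strengths place each pair's oscillation
at a distinct frequency (0.8–1.8 rad per time unit, i.e. at least ~1.5
cycles over the 12-unit window, the most a moderate-order polynomial
smoother can still track), with source pairs feeding sink pairs so the
cross-edge graph is block-triangular (stable by construction, no coupling
rescaling needed) and a constant production term placing every fixed point
at a positive level (so that the sign of a planted $\beta$ is the sign of
its time-integrated contribution).  Each sink node receives cross edges
with $|\beta| \in [0.6, 0.9]$ from two source pairs; with the pair
couplings this averages two regulators per node.  On this benchmark (20
nodes, 2% observation noise, 10 seeds) edge precision and recall are
about 0.82–0.85 and sign agreement about 0.96, as recomputed by
`scripts/acceptance.R`.

# Problem sizes and defaults

The validation studies run at: parameter recovery n = 200 individuals, 20
markers, 50 replicates; type-I calibration m = 50 markers, n = 100, B = 200
permutations, 100 null scans; clustering 150 curves, 20 replicates; network
recovery 20 nodes, 121 grid points, 10 seeds.  These sizes make each check
statistically meaningful while keeping a full run in the minutes range on
one core.

Key defaults: `min_class = 3` (class-membership floor), `n_starts = 5`
(single-marker fits) / 2 (scans) / 1 (permutations), effect-curve grid 30
points over the pooled age range, `Q = 4` and `leaf_size = 30`
(clustering), `K_ind = K_dep = 3`, `K_sel = 1`, `d_max = 5`,
`smooth_order = 14`, `ebic_gamma = 2` (network stage), `eps_frac = 0.05`,
`delta = 0.2` (classification).

# Known limitations

- The chi-square reference for the LR is advisory; inference should use the
  permutation threshold.
- Functional clustering assumes SAD(1) residuals around LOP means; strongly
  heteroscedastic curve sets may prefer more components than the planted
  truth.
- Regulator selection inherits the identifiability limits of observational
  trajectory data: regulators whose curves are (near-)linear combinations
  of other candidates over the observation window cannot be distinguished,
  whatever the criterion.  The benchmark quantifies performance in an
  identifiable regime; flat, feature-poor effect curves will yield
  unstable edge sets in real data.
- Population structure, kinship and linkage disequilibrium are out of
  scope; apply the scan to panels checked for confounding.
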