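---
title: "Information flow of Ising dynamics on brain-like networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information flow of Ising dynamics on brain-like networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingflow)
```

## The model

`isingflow` studies how a simple spin dynamics redistributes information over
a weighted network. Spins $s_i \in \{-1,+1\}$ sit on the nodes of a
symmetric, non-negative weight matrix $A$ (a structural connectome or a
synthetic stand-in), with energy

$$E(s) = -\sum_{i<j} A_{ij}\, s_i s_j,$$

and are sampled from the Boltzmann distribution $\propto e^{-\beta E}$ at
inverse temperature $\beta$. The couplings are $\beta A_{ij}$: a single
global parameter scales the fixed anatomical weights, so sweeping $\beta$
moves the system from the disordered (paramagnetic) to the ordered
(ferromagnetic) phase. On a finite network there is no true transition; we
call the location of the susceptibility peak the *pseudo-critical* point.

Four updating schemes share this stationary distribution. One sweep is $N$
single-site update attempts at uniformly random sites for the local rules —
Glauber (flip probability $1/(1+e^{\beta\Delta E})$), Metropolis
($\min(1, e^{-\beta\Delta E})$) and heat bath (resample the site from its
conditional law; identical in law to Glauber but a separately seeded code
path, since the two are conventionally reported as distinct dynamics) — or
one cluster flip for Wolff (bond activation $1-e^{-2\beta A_{ij}}$ between
aligned linked spins). $\Delta E = 2 s_i h_i$ with local field
$h_i = \sum_j A_{ij} s_j$. One configuration is recorded per sweep; the
initial state is uniform random spins and a transient is discarded.
Per-sweep sampling is a genuine choice: the sampling interval fixes the time
unit of every lagged quantity below, and one sweep (one expected update
attempt per site) makes the four dynamics comparable.

## Information flow

For every ordered pair of spins joined by a structural link we estimate the
bivariate transfer entropy

$$\mathrm{TE}_{j \to i} = \sum p\!\left(s_i^+, S_i, S_j\right)
  \log_2 \frac{p\!\left(s_i^+ \mid S_i, S_j\right)}
              {p\!\left(s_i^+ \mid S_i\right)},$$

where $s_i^+$ is the target's next recorded state and $S_i$, $S_j$ are the
$m$-step past blocks. Probabilities are plug-in frequencies with no
smoothing — unobserved states contribute zero — and the result is clamped at
zero (the plug-in value is a KL divergence and can dip below zero only by
floating-point rounding). Logarithms are base 2 throughout, so flows are in
bits. The default embedding is $m=1$; the joint state space grows as
$2^{2m+1}$, and at the run lengths used here larger $m$ mostly adds
estimation bias. Pairs not joined by a structural link are not estimated
(set to zero): with $\beta A_{ij} = 0$ the true bivariate TE vanishes, and
restricting to the coupling support is what makes the flow network
comparable to the substrate.

The linear Granger index treats the $\pm 1$ series as real values:
$\delta_{j\to i} = \log_2\!\big(\varepsilon(s_i^+\mid S_i) /
\varepsilon(s_i^+\mid S_i, S_j)\big)$, a ratio of least-squares residual
variances with intercept (floored at $10^{-12}$). Under the Gaussian
approximation of the spin statistics $\mathrm{TE} \approx \delta/2$; the
package verifies this relation empirically (correlation above 0.9 across
linked pairs near criticality, and pairwise agreement within 20% on small
chains). No standardisation of the design matrix is needed — the variance
ratio is scale invariant.

Two independent verification routes exist for the estimator. For systems of
at most four spins, `exact_te_oracle()` builds the exact
$2^N \times 2^N$ single-update transition matrix of random-site Glauber
dynamics, takes its $N$-th power for one sweep, solves for the stationary
law and marginalises to the exact TE. The test suite holds the plug-in
estimate to within three block-bootstrap standard errors of this oracle, and
holds the oracle itself to a second, independently coded enumeration.

## Flow topology

From the flow matrix (flow $j \to i$ stored at $[i,j]$) the package derives:

* **Per-node ratio** $r_i = \mathrm{out}_i / \mathrm{in}_i$. With symmetric
  couplings the expected flow network is symmetric ($r = 1$); nodes driven
  toward their input capacity show $r > 1$ — bottleneck candidates under the
  law of diminishing marginal returns. Nodes with incoming flow below
  $10^{-12}$ get an `NA` sentinel and are excluded (and counted) in
  correlations.
* **Global ratio** $R = \sigma(\mathrm{out}) / \sigma(\mathrm{in})$
  (population standard deviations; `NA` sentinel when $\sigma(\mathrm{in})$
  degenerates). $R > 1$ is the global saturation signature.
* **Segregation** $S$: intra-module flow over inter-module flow, `Inf`
  sentinel when no inter-module flow exists.
* **Rich club** $\Phi(k)$ on the binarized flow graph: an undirected edge
  exists iff $\max(F_{ij}, F_{ji})$ exceeds a quantile (default the median)
  of the nonzero flows; $\Phi(k) = 2E_k / (N_k(N_k-1))$ over nodes of degree
  $\ge k$, `NA` when fewer than two qualify. The max rule makes the result
  transpose-invariant, i.e. identical whether one binarizes incoming or
  outgoing flows. The threshold quantile is exposed because the scale of
  plug-in TE values varies strongly with $\beta$; a relative (quantile)
  threshold keeps the edge density comparable across the sweep.
* **Flip times** $\tau_i$: mean recorded-sweeps between sign changes;
  spins with fewer than two changes get `Inf`. $\tau \approx 1$ is
  paramagnetic-like, large $\tau$ quasi-frozen.
* **Classical metrics** via igraph with edge length $1/A_{ij}$: strength,
  local efficiency (mean inverse distance between neighbours inside the
  neighbour-induced subgraph), and betweenness normalised to the fraction of
  source–target pairs. The $1/w$ length convention follows standard
  connectivity toolboxes and is stated explicitly because efficiency and
  betweenness depend on it.

Thermodynamic observables use the finite-size estimators
$\chi = \beta N (\langle m^2\rangle - \langle|m|\rangle^2)$ and
$C = \beta^2 \mathrm{var}(E)/N$. The $|m|$-based susceptibility is the
standard choice for pseudo-transitions: on a finite graph the magnetisation
flips globally, and $\langle m\rangle$-based estimators conflate that
symmetry restoration with fluctuation strength.

## Substrates and the synthetic connectome

Three generators cover the study's substrates. The $L \times L$ torus is the
exactly solvable control: its pseudo-critical coupling must bracket the
Onsager value $\ln(1+\sqrt2)/2 \approx 0.4407$. The deterministic scale-free
graph is the three-copy hierarchical construction (generation $g$ is three
copies of $g-1$ with the middle root joined to the outer copies' leaf
levels), giving $3^g$ nodes — 81 at generation 4 — with hub degrees
$\sum_{k\le g} 2^k$.

The measured connectomes this analysis emulates are not publicly archived,
so the surrogate generator is a first-class, synthetic stand-in, not a data
loader. It produces two equal modules (hemispheres) with dense intra- and
sparse inter-module Erdős–Rényi wiring and log-normal edge weights. Defaults
— 66 nodes, intra density 0.30, inter density 0.05, weights with median 0.3
and $\mathrm{sdlog} = 1$ — were fixed once as the study conditions: the
densities give a mean degree near 11 with a clear two-module structure, the
log-normal weights give the heterogeneous, right-skewed strength
distribution that weight-shuffled controls lack, and the weight scale places
the surrogate's pseudo-critical point mid-way into the default sweep grid
($\beta$ from 0.02 to 1.0 in 25 steps), which a sweep must bracket for any
peak-location statement to be meaningful. When `inter_density = 0` the
modules are deliberately decoupled and connectivity is enforced per module
rather than globally.

What the surrogate does *not* emulate matters for interpreting results: real
connectomes have fat-tailed degree (not just weight) distributions,
distance-dependent wiring, and much weaker callosal (inter-hemispheric)
weights. Consequences observed in this package's own runs: the rich-club
structure of the flow network is weak (ER-block modules have no strong
structural hubs), the segregation ratio $S(\beta)$ is not monotone over the
full grid (it dips in the ordered phase, where global alignment couples the
hemispheres, and is noise-floor dominated at both ends), and the $R$-peak
sits within one grid step of the susceptibility peak rather than clearly on
the high-temperature side. Passing tests on the surrogate therefore validate
the estimators and the qualitative critical phenomenology, not every
connectome-specific effect.

The degree-preserving null rewires the binary backbone by double-edge swaps
(10 per edge attempted) and then permutes the original weight multiset onto
the rewired edges; graphs admitting no valid swap (e.g. a triangle) are
returned unchanged with a warning.

## Numerical choices and degenerate inputs

* RNG: everything flows from R's own stream; each simulation seeds
  `set.seed()` and the compiled core draws via `unif_rand()`, so identical
  arguments give identical trajectories and the caller's RNG state is
  restored afterwards.
* Run lengths: transient and sample default to $10^4$ sweeps each.
  Estimator-validation runs use $T = 10^5$ on 2–3 spin systems. Sweeps use
  10 replicate seeds; peak locations are read off the seed-mean curve with
  argmax, ties broken toward lower $\beta$ and flagged, boundary argmaxes
  flagged inconclusive.
* TE uncertainty: moving-block bootstrap (blocks of 100 recorded steps) on
  the stream of transition tuples.
* Undefined values are typed sentinels (`NA` for undefined ratios, `Inf`
  for never-flipping spins and zero inter-module flow), never silently
  propagated NaNs; `correlate()` excludes non-finite pairs and reports the
  count used.
* Text I/O prints weights with 17 significant digits so dense-matrix and
  edge-list round trips are exact; asymmetric dense input, self-loops and
  negative weights are rejected with the offending line identified.

## Known limitations

Bivariate (not conditional) TE only: multivariate conditioning is
exponential in $N$ and out of scope, so common-drive effects are not removed
from individual flows. The plug-in estimator carries an $O(\text{states}/T)$
positive bias; at $\beta = 0$ this bias *is* the flow matrix, which is why
node-level ratios at independence scatter widely around 1 (the noise scale
cancels between numerator and denominator, independent of $T$) while the
flow matrix itself is symmetric to well under $10^{-3}$ bits. Peak
comparisons are grid-resolution limited: on the 16×16 torus the total-TE and
susceptibility peaks coincide at the 0.05 grid step used. The problem sizes
throughout (66–256 nodes, $10^4$ sweeps, 10 replicates) are desk-scale
choices; the 998-node preset reproduces the pipeline at the mesoscale and is
excluded from routine runs.
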