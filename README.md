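# isingflow

Ising spin dynamics on weighted, brain-like networks, and the directed
information flow it generates.

## The problem

How does a network's structure shape the flow of information through the
dynamics living on it — and what is special about the critical point? This
package reimplements, end to end, an analysis built around that question:
spins $s_i \in \{-1,+1\}$ coupled through a weighted symmetric adjacency
matrix $A$ (energy $E = -\sum_{i<j} A_{ij} s_i s_j$, couplings scaled by an
inverse temperature $\beta$) are simulated with Glauber, Metropolis,
heat-bath or Wolff updates; the directed flow between every pair of linked
spins is estimated by the plug-in bivariate transfer entropy

$$\mathrm{TE}_{j\to i} = \sum p(s_i^+, S_i, S_j)\,
  \log_2 \frac{p(s_i^+ \mid S_i, S_j)}{p(s_i^+ \mid S_i)} \quad [\text{bits}],$$

or its linear Granger approximation $\delta \approx 2\,\mathrm{TE}$; and the
resulting flow network is scanned across $\beta$ for the signatures of the
law of diminishing marginal returns: the global ratio
$R = \sigma(\mathrm{out})/\sigma(\mathrm{in})$, the per-node bottleneck
ratio $r_i = \mathrm{out}_i/\mathrm{in}_i$, hemispheric segregation $S$,
spin flip times $\tau_i$, and the rich-club coefficient $\Phi(k)$ of the
flow network.

It is written for computational neuroscientists and statistical physicists
who want a compact, fully tested R implementation of this pipeline —
including an exact small-system transfer-entropy oracle for estimator
validation and a synthetic two-hemisphere connectome generator (the measured
connectomes the original analysis used are not publicly archived).

## Worked example

```r
library(isingflow)

net <- make_surrogate_connectome(66, seed = 101)   # two-hemisphere surrogate
cfg <- sweep_config(net, betas = default_beta_grid(), dynamics = "glauber",
                    n_sweeps = 1e4, n_transient = 1e4, seeds = 1:10)
sw  <- temperature_sweep(cfg)
print(sw)
#> <sweep_result> 25 betas x 10 seeds on 66 nodes (glauber, te)
#>   peak chi            beta* = 0.265
#>   peak heat_capacity  beta* = 0.3058
#>   peak total_flow     beta* = 0.3058
#>   peak R              beta* = 0.265
```

The susceptibility peak at $\beta^* = 0.265$ is the pseudo-critical point of
this surrogate; the total transferred information (15.2 ± 0.1 bits summed
over linked pairs) peaks one grid step away, and $R \approx 1.55 > 1$ there:
the distribution of incoming flows is sharper than that of outgoing flows,
the saturation signature of diminishing marginal returns. Node-level
structure at $\beta^*$:

```r
traj <- simulate_ising(net, 0.265, "glauber", 1e4, 1e4, seed = 1)
fl   <- flow_matrix(traj, net, "te")
ns   <- node_flow_stats(fl, net, traj)
correlate(ns$r, ns$strength)
#> $r
#> [1] 0.8679745
#> $n
#> [1] 66
```

Nodes with high bottleneck ratio $r$ are the strongly connected ones (here
Pearson 0.87 with strength, 0.96 with the mean inter-flip time $\tau$, but
only 0.12 with local efficiency): being a bottleneck of information is an
intrinsic, strength-driven property, not generic "hubness".

The numbered scripts under `analysis/` run the full study: substrate
construction, the exactly solvable 16×16-torus control, the connectome
sweep, the four-dynamics comparison, and the bottleneck/rich-club analysis
with a degree-preserving null. Each writes its tables under `results/`.

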