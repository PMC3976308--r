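#' Monte-Carlo simulation of the Ising model on a weighted network
#'
#' Simulates spins `s_i ∈ {-1, +1}` coupled by `beta * A_ij`, where `A` is the
#' network weight matrix and `beta` the inverse temperature, with energy
#' `E(s) = -sum_{i<j} A_ij s_i s_j` and stationary distribution
#' `∝ exp(-beta E)`. One sweep is `N` single-site update attempts at
#' uniformly random sites (`glauber`, `metropolis`, `heat_bath`) or one
#' cluster flip (`wolff`, bond-activation probability
#' `1 - exp(-2 beta A_ij)` between aligned linked spins). One configuration
#' is recorded per sweep after the transient.
#'
#' Update rules: Glauber flips with probability `1 / (1 + exp(beta dE))`;
#' Metropolis with `min(1, exp(-beta dE))`; heat bath resamples the site from
#' its conditional distribution given its neighbours (identical in law to
#' Glauber, kept as a separately seeded code path). `dE = 2 s_i h_i` with the
#' local field `h_i = sum_j A_ij s_j`.
#'
#' @param net a [weighted_network()].
#' @param beta inverse temperature, `>= 0`.
#' @param dynamics one of `"glauber"`, `"metropolis"`, `"heat_bath"`,
#'   `"wolff"`.
#' @param n_sweeps number of recorded sweeps, `>= 2`.
#' @param n_transient number of discarded equilibration sweeps.
#' @param seed integer RNG seed; identical arguments give an identical
#'   trajectory.
#' @return A `spin_trajectory`: list with `spins` (`n_sweeps x n_nodes`
#'   matrix of ±1), `beta`, `dynamics`, `n_transient`, `seed`.
#' @export
simulate_ising <- function(net, beta, dynamics = "glauber",
                           n_sweeps = 10000L, n_transient = 10000L,
                           seed = 1L) {
  stopifnot(inherits(net, "weighted_network"))
  if (beta < 0) stop("beta must be >= 0")
  if (n_sweeps < 2) stop("n_sweeps must be >= 2")
  dyn_code <- match(dynamics, c("glauber", "metropolis", "heat_bath", "wolff"))
  if (is.na(dyn_code))
    stop("unknown dynamics '", dynamics,
         "'; use glauber, metropolis, heat_bath or wolff")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  init <- sample(c(-1L, 1L), net$n_nodes, replace = TRUE)
  spins <- cpp_ising_simulate(net$weights, beta, dyn_code - 1L,
                              as.integer(n_sweeps), as.integer(n_transient),
                              init)
  structure(
    list(spins = spins, beta = beta, dynamics = dynamics,
         n_transient = as.integer(n_transient), seed = as.integer(seed)),
    class = "spin_trajectory")
}

#' @export
print.spin_trajectory <- function(x, ...) {
  cat("<spin_trajectory> ", nrow(x$spins), " sweeps x ", ncol(x$spins),
      " spins, beta = ", x$beta, ", ", x$dynamics,
      " dynamics, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Per-configuration energies
#'
#' `E(s) = -sum_{i<j} A_ij s_i s_j`, evaluated for every recorded sweep.
#'
#' @param traj a `spin_trajectory`.
#' @param net the [weighted_network()] it was simulated on.
#' @return Numeric vector of length `n_sweeps`.
#' @export
trajectory_energy <- function(traj, net) {
  S <- traj$spins
  if (ncol(S) != net$n_nodes)
    stop("trajectory and network dimensions differ")
  -0.5 * rowSums((S %*% net$weights) * S)
}

#' Thermodynamic observables of a trajectory
#'
#' Finite-size estimators: susceptibility
#' `chi = beta * N * (<m^2> - <|m|>^2)` with magnetisation per spin
#' `m = mean(s)`, and heat capacity `C = beta^2 * var(E) / N` (per spin,
#' population variance). The `|m|`-based susceptibility is the standard
#' choice for pseudo-transitions on finite graphs, where the symmetry is
#' restored by rare global flips.
#'
#' @param traj a `spin_trajectory`.
#' @param net the [weighted_network()] it was simulated on.
#' @return List with `chi`, `heat_capacity`, `mean_abs_magnetization`,
#'   `mean_energy_per_spin`.
#' @export
thermo <- function(traj, net) {
  S <- traj$spins
  if (ncol(S) != net$n_nodes)
    stop("trajectory and network dimensions differ")
  n <- net$n_nodes
  m <- rowMeans(S)
  E <- trajectory_energy(traj, net)
  chi <- traj$beta * n * (mean(m^2) - mean(abs(m))^2)
  heat <- traj$beta^2 * (mean(E^2) - mean(E)^2) / n
  list(chi = max(chi, 0), heat_capacity = max(heat, 0),
       mean_abs_magnetization = mean(abs(m)),
       mean_energy_per_spin = mean(E) / n)
}

#' Mean inter-flip times
#'
#' For each spin, the mean number of recorded sweeps between successive sign
#' changes. `tau` close to 1 marks paramagnetic-like dynamics (the spin
#' flips almost every sweep), large `tau` marks frozen, ferromagnetic-like
#' dynamics. Spins with fewer than two sign changes in the record get the
#' `+Inf` sentinel.
#'
#' @param traj a `spin_trajectory` with at least 2 recorded sweeps.
#' @return Numeric vector `tau` of length `n_nodes` (sweeps; may be `Inf`).
#' @export
flip_times <- function(traj) {
  S <- traj$spins
  T_ <- nrow(S)
  if (T_ < 2) stop("need at least 2 recorded sweeps")
  vapply(seq_len(ncol(S)), function(i) {
    ch <- which(S[-1, i] != S[-T_, i])
    if (length(ch) < 2) return(Inf)
    mean(diff(ch))
  }, numeric(1))
}
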