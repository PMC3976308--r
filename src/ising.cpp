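#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbour lists built once per simulation; couplings are beta * A_ij with
// A fixed, so beta premultiplies nothing here -- it enters the flip rules.
struct AdjList {
  std::vector<std::vector<int>> nbr;
  std::vector<std::vector<double>> w;
};

static AdjList build_adj(const NumericMatrix& W) {
  int n = W.nrow();
  AdjList a;
  a.nbr.resize(n);
  a.w.resize(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && W(i, j) > 0.0) {
        a.nbr[i].push_back(j);
        a.w[i].push_back(W(i, j));
      }
  return a;
}

static inline double local_field(const AdjList& a, const std::vector<int>& s, int i) {
  double h = 0.0;
  const std::vector<int>& nb = a.nbr[i];
  const std::vector<double>& wi = a.w[i];
  for (size_t k = 0; k < nb.size(); ++k) h += wi[k] * s[nb[k]];
  return h;
}

// One sweep = N single-site update attempts at uniformly random sites.
// dynamics: 0 glauber, 1 metropolis, 2 heat_bath (site-resampling), 3 wolff
// (one cluster flip per sweep, bond probability 1 - exp(-2 beta A_ij)).
static void do_sweep(const AdjList& a, std::vector<int>& s, double beta, int dynamics) {
  int n = (int)s.size();
  if (dynamics == 3) {  // Wolff single-cluster update
    int seed_site = (int)(unif_rand() * n);
    if (seed_site == n) seed_site = n - 1;
    std::vector<char> in_cluster(n, 0);
    std::vector<int> stack;
    stack.push_back(seed_site);
    in_cluster[seed_site] = 1;
    int s0 = s[seed_site];
    while (!stack.empty()) {
      int i = stack.back();
      stack.pop_back();
      const std::vector<int>& nb = a.nbr[i];
      const std::vector<double>& wi = a.w[i];
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        if (!in_cluster[j] && s[j] == s0) {
          double p = 1.0 - std::exp(-2.0 * beta * wi[k]);
          if (unif_rand() < p) {
            in_cluster[j] = 1;
            stack.push_back(j);
          }
        }
      }
    }
    for (int i = 0; i < n; ++i)
      if (in_cluster[i]) s[i] = -s[i];
    return;
  }
  for (int t = 0; t < n; ++t) {
    int i = (int)(unif_rand() * n);
    if (i == n) i = n - 1;
    double h = local_field(a, s, i);
    if (dynamics == 0) {            // Glauber: flip with 1/(1+exp(beta dE))
      double dE = 2.0 * s[i] * h;
      if (unif_rand() < 1.0 / (1.0 + std::exp(beta * dE))) s[i] = -s[i];
    } else if (dynamics == 1) {     // Metropolis: min(1, exp(-beta dE))
      double dE = 2.0 * s[i] * h;
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) s[i] = -s[i];
    } else {                        // heat bath: resample from conditional
      double p_up = 1.0 / (1.0 + std::exp(-2.0 * beta * h));
      s[i] = (unif_rand() < p_up) ? 1 : -1;
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_ising_simulate(NumericMatrix W, double beta, int dynamics,
                                 int n_sweeps, int n_transient, IntegerVector init) {
  int n = W.nrow();
  AdjList a = build_adj(W);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = init[i];
  RNGScope scope;
  for (int t = 0; t < n_transient; ++t) do_sweep(a, s, beta, dynamics);
  IntegerMatrix out(n_sweeps, n);
  for (int t = 0; t < n_sweeps; ++t) {
    do_sweep(a, s, beta, dynamics);
    for (int i = 0; i < n; ++i) out(t, i) = s[i];
  }
  return out;
}

// Joint transition counts for one ordered pair at embedding m: index
// a + 2*b + 2^{m+1}*c where a = next target bit, b = target past block,
// c = source past block (most recent step = lowest bit).
static void te_count_pair(const int* si, const int* sj, int T, int m,
                          std::vector<double>& counts) {
  int pm = 1 << m;
  std::fill(counts.begin(), counts.end(), 0.0);
  for (int t = m; t < T; ++t) {
    int b = 0, c = 0;
    for (int k = 0; k < m; ++k) {
      b |= (si[t - 1 - k] > 0 ? 1 : 0) << k;
      c |= (sj[t - 1 - k] > 0 ? 1 : 0) << k;
    }
    int a = si[t] > 0 ? 1 : 0;
    counts[a + 2 * b + 2 * pm * c] += 1.0;
  }
}

static double te_from_counts(const std::vector<double>& counts, int m) {
  int pm = 1 << m;
  double total = 0.0;
  for (double x : counts) total += x;
  if (total <= 0) return 0.0;
  // marginals: n_ab over c, n_bc over a, n_b over a and c
  std::vector<double> n_ab(2 * pm, 0.0), n_bc(pm * pm, 0.0), n_b(pm, 0.0);
  for (int c = 0; c < pm; ++c)
    for (int b = 0; b < pm; ++b)
      for (int a = 0; a < 2; ++a) {
        double x = counts[a + 2 * b + 2 * pm * c];
        n_ab[a + 2 * b] += x;
        n_bc[b + pm * c] += x;
        n_b[b] += x;
      }
  double te = 0.0;
  for (int c = 0; c < pm; ++c)
    for (int b = 0; b < pm; ++b)
      for (int a = 0; a < 2; ++a) {
        double x = counts[a + 2 * b + 2 * pm * c];
        if (x > 0.0)
          te += (x / total) *
                std::log2((x * n_b[b]) / (n_ab[a + 2 * b] * n_bc[b + pm * c]));
      }
  return te > 0.0 ? te : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_flow_te(IntegerMatrix spins, IntegerMatrix pairs, int m) {
  int T = spins.nrow();
  int np = pairs.nrow();
  NumericVector out(np);
  std::vector<double> counts((size_t)(2 << (2 * m)));
  // column-major copies so each series is contiguous
  int N = spins.ncol();
  std::vector<std::vector<int>> cols(N, std::vector<int>(T));
  for (int j = 0; j < N; ++j)
    for (int t = 0; t < T; ++t) cols[j][t] = spins(t, j);
  for (int p = 0; p < np; ++p) {
    int src = pairs(p, 0), tgt = pairs(p, 1);  // 0-based
    te_count_pair(cols[tgt].data(), cols[src].data(), T, m, counts);
    out[p] = te_from_counts(counts, m);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_te_counts(IntegerVector target, IntegerVector source, int m) {
  int T = target.size();
  std::vector<double> counts((size_t)(2 << (2 * m)));
  te_count_pair(&target[0], &source[0], T, m, counts);
  return NumericVector(counts.begin(), counts.end());
}

// [[Rcpp::export]]
double cpp_te_from_counts(NumericVector counts, int m) {
  std::vector<double> c(counts.begin(), counts.end());
  return te_from_counts(c, m);
}
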