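#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Flat lower-triangle index for 1 <= a <= n.
static inline std::size_t tri_idx(int n, int a) {
  return (std::size_t)n * (n - 1) / 2 + (a - 1);
}

static inline double log_add(double x, double y) {
  if (x == R_NegInf) return y;
  if (y == R_NegInf) return x;
  double mx = std::max(x, y);
  return mx + std::log1p(std::exp(std::min(x, y) - mx));
}

// Log-scale unsigned Stirling numbers of the first kind, s(n, a), built by
// the recurrence s(n, a) = (n-1) s(n-1, a) + s(n-1, a-1).
static std::vector<double> stirling_triangle(int n_max) {
  std::vector<double> ls((std::size_t)n_max * (n_max + 1) / 2);
  ls[tri_idx(1, 1)] = 0.0;
  for (int n = 2; n <= n_max; ++n) {
    ls[tri_idx(n, 1)] = std::log((double)(n - 1)) + ls[tri_idx(n - 1, 1)];
    for (int a = 2; a < n; ++a) {
      double x = std::log((double)(n - 1)) + ls[tri_idx(n - 1, a)];
      ls[tri_idx(n, a)] = log_add(x, ls[tri_idx(n - 1, a - 1)]);
    }
    ls[tri_idx(n, n)] = 0.0;
    if (n % 512 == 0) checkUserInterrupt();
  }
  return ls;
}

// [[Rcpp::export]]
NumericVector log_stirling_triangle_cpp(int n_max) {
  if (n_max < 1) stop("n_max must be >= 1");
  std::vector<double> ls = stirling_triangle(n_max);
  return NumericVector(ls.begin(), ls.end());
}

// log K(D, A) for A = S..J, where
//   K(D, A) = sum over {a_i : sum a_i = A} of
//             prod_i s(n_i, a_i) s(a_i, 1) / s(n_i, 1).
// Computed by sequentially convolving per-species log-weight vectors
//   w_i(a) = log s(n_i, a) + lgamma(a) - lgamma(n_i),  a = 1..n_i,
// with element-wise log-sum-exp.  Species with n_i = 1 have the single
// weight w(1) = 0 and only shift A; they are skipped.
// [[Rcpp::export]]
NumericVector logK_DA_cpp(IntegerVector abund) {
  int S = abund.size();
  if (S < 1) stop("need at least one species");
  int n_max = 1;
  std::vector<int> big;
  for (int i = 0; i < S; ++i) {
    if (abund[i] < 1) stop("abundances must be positive integers");
    if (abund[i] > n_max) n_max = abund[i];
    if (abund[i] > 1) big.push_back(abund[i]);
  }
  // ascending order keeps the running vector short for longer
  std::sort(big.begin(), big.end());

  std::vector<double> v(1, 0.0);  // v[k] = log K restricted; A = S + k
  if (!big.empty()) {
    std::vector<double> ls = stirling_triangle(n_max);
    std::vector<double> w, nv;
    for (std::size_t s = 0; s < big.size(); ++s) {
      int n = big[s];
      w.resize(n);
      for (int a = 1; a <= n; ++a)
        w[a - 1] = ls[tri_idx(n, a)] + std::lgamma((double)a) -
                   std::lgamma((double)n);
      int lenv = (int)v.size();
      int newlen = lenv + n - 1;
      nv.assign(newlen, R_NegInf);
      for (int k = 0; k < newlen; ++k) {
        int alo = std::max(1, k - lenv + 2);
        int ahi = std::min(n, k + 1);
        double mx = R_NegInf;
        for (int a = alo; a <= ahi; ++a) {
          double t = v[k - a + 1] + w[a - 1];
          if (t > mx) mx = t;
        }
        double sum = 0.0;
        for (int a = alo; a <= ahi; ++a) {
          double t = v[k - a + 1] + w[a - 1] - mx;
          if (t > -745.0) sum += std::exp(t);
        }
        nv[k] = mx + std::log(sum);
      }
      v.swap(nv);
      checkUserInterrupt();
    }
  }
  // singleton species contribute weight 1 at a_i = 1: pure shift, no-op here
  return NumericVector(v.begin(), v.end());
}

// Sequential-construction urn for the dispersal-limited neutral model.
// Individual j is a new immigrant ancestor with probability I/(I + j - 1),
// else copies a uniformly chosen earlier individual.  Ancestor a founds a
// new species with probability theta/(theta + a - 1), else copies a
// uniformly chosen earlier ancestor's species.  Uses R's RNG.
// [[Rcpp::export]]
IntegerVector sim_etienne_cpp(double theta, double I, int J) {
  if (!(theta > 0) || !(I > 0) || J < 1)
    stop("theta > 0, I > 0 and J >= 1 are required");
  std::vector<int> anc_species;  // species of each ancestor
  std::vector<int> ind_species(J);
  std::vector<int> counts;
  for (int j = 1; j <= J; ++j) {
    if (unif_rand() < I / (I + j - 1.0)) {
      int A = (int)anc_species.size();  // ancestor index a = A + 1
      int sp;
      if (unif_rand() < theta / (theta + A)) {
        sp = (int)counts.size();
        counts.push_back(0);
      } else {
        int pick = (int)(unif_rand() * A);
        if (pick >= A) pick = A - 1;
        sp = anc_species[pick];
      }
      anc_species.push_back(sp);
      ind_species[j - 1] = sp;
    } else {
      int pick = (int)(unif_rand() * (j - 1));
      if (pick >= j - 1) pick = j - 2;
      ind_species[j - 1] = ind_species[pick];
    }
    counts[ind_species[j - 1]] += 1;
  }
  std::sort(counts.begin(), counts.end(), std::greater<int>());
  return IntegerVector(counts.begin(), counts.end());
}

// Chinese-restaurant / Ewens sampler: the same urn without dispersal
// limitation, used to draw a metacommunity of J_meta individuals.
// [[Rcpp::export]]
IntegerVector sim_crp_cpp(double theta, int J) {
  if (!(theta > 0) || J < 1) stop("theta > 0 and J >= 1 are required");
  std::vector<int> ind_species(J);
  std::vector<int> counts;
  for (int j = 1; j <= J; ++j) {
    if (unif_rand() < theta / (theta + j - 1.0)) {
      ind_species[j - 1] = (int)counts.size();
      counts.push_back(0);
    } else {
      int pick = (int)(unif_rand() * (j - 1));
      if (pick >= j - 1) pick = j - 2;
      ind_species[j - 1] = ind_species[pick];
    }
    counts[ind_species[j - 1]] += 1;
  }
  std::sort(counts.begin(), counts.end(), std::greater<int>());
  return IntegerVector(counts.begin(), counts.end());
}

// One-death-per-step birth/death/immigration chain for a focal species.
// P(up)   = ((NT-N)/NT) [ m p + (1-m) N/(NT-1) ]
// P(down) = (N/NT)      [ m (1-p) + (1-m) (NT-N)/(NT-1) ]
// P(stay) = 1 - P(up) - P(down).  Uses R's RNG.
// [[Rcpp::export]]
IntegerVector sim_sloan_chain_cpp(int N0, int NT, double m, double p,
                                  int n_steps) {
  if (NT < 2 || N0 < 0 || N0 > NT || m < 0 || m > 1 || p < 0 || p > 1 ||
      n_steps < 1)
    stop("invalid chain parameters");
  IntegerVector traj(n_steps);
  int N = N0;
  for (int t = 0; t < n_steps; ++t) {
    double Ni = (double)N;
    double pup = ((NT - Ni) / NT) * (m * p + (1 - m) * Ni / (NT - 1.0));
    double pdn = (Ni / NT) * (m * (1 - p) + (1 - m) * (NT - Ni) / (NT - 1.0));
    double u = unif_rand();
    if (u < pup) ++N;
    else if (u < pup + pdn) --N;
    traj[t] = N;
    if (t % (1 << 20) == 0) checkUserInterrupt();
  }
  return traj;
}
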