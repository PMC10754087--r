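#include <Rcpp.h>
#include <map>
#include <cmath>
using namespace Rcpp;

// Count ordered photon pairs (i from `ta`, j from `tb`) whose lag
// tb[j] - ta[i] falls into the half-open bins [edges[k], edges[k+1]).
// Both time vectors must be sorted ascending; `edges` strictly increasing
// and may start at negative lags. Every ordered pair is counted once.
// [[Rcpp::export]]
NumericVector pair_count(NumericVector ta, NumericVector tb,
                         NumericVector edges) {
  const int na = ta.size(), nb = tb.size();
  const int nk = edges.size() - 1;
  NumericVector counts(nk);
  if (na == 0 || nb == 0 || nk < 1) return counts;
  const double lo = edges[0], hi = edges[nk];
  int jlo = 0;
  for (int i = 0; i < na; ++i) {
    const double t0 = ta[i];
    while (jlo < nb && tb[jlo] - t0 < lo) ++jlo;
    for (int j = jlo; j < nb; ++j) {
      const double lag = tb[j] - t0;
      if (lag >= hi) break;
      int l = 0, r = nk; // invariant: edges[l] <= lag < edges[r]
      while (r - l > 1) {
        const int m = (l + r) / 2;
        if (lag >= edges[m]) l = m; else r = m;
      }
      counts[l] += 1.0;
    }
  }
  return counts;
}

// Stationary Ornstein-Uhlenbeck process sampled at sorted irregular times:
// standard-normal marginal, correlation exp(-dt/tau). `z` supplies iid
// standard normal deviates drawn in R.
// [[Rcpp::export]]
NumericVector ou_at(NumericVector t, double tau, NumericVector z) {
  const int n = t.size();
  NumericVector x(n);
  if (n == 0) return x;
  x[0] = z[0];
  for (int i = 1; i < n; ++i) {
    const double phi = std::exp(-(t[i] - t[i - 1]) / tau);
    x[i] = phi * x[i - 1] + std::sqrt(1.0 - phi * phi) * z[i];
  }
  return x;
}

// Renewal antibunching filter: photon i (sorted times t, emitter id `mol`)
// survives with probability 1 - exp(-(t_i - t_prev)/tau), where t_prev is the
// previous *kept* photon of the same emitter. `u` supplies uniform deviates
// (drawn in R so the generator state stays under set.seed control).
// [[Rcpp::export]]
LogicalVector antibunch_keep(NumericVector t, IntegerVector mol,
                             double tau, NumericVector u) {
  const int n = t.size();
  LogicalVector keep(n);
  std::map<int, double> last;
  for (int i = 0; i < n; ++i) {
    double p = 1.0;
    std::map<int, double>::iterator it = last.find(mol[i]);
    if (it != last.end())
      p = 1.0 - std::exp(-(t[i] - it->second) / tau);
    if (u[i] < p) {
      keep[i] = true;
      last[mol[i]] = t[i];
    }
  }
  return keep;
}
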