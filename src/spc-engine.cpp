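// Swendsen-Wang cluster Monte Carlo for the q-state Potts model on a
// sparse graph with per-edge ferromagnetic couplings. Uses R's RNG so
// set.seed() in R makes runs reproducible.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int findRoot(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static inline void unite(std::vector<int>& parent, std::vector<int>& rank_,
                         int a, int b) {
  a = findRoot(parent, a);
  b = findRoot(parent, b);
  if (a == b) return;
  if (rank_[a] < rank_[b]) std::swap(a, b);
  parent[b] = a;
  if (rank_[a] == rank_[b]) rank_[a]++;
}

static inline int drawSpin(int q) {
  int s = (int)(unif_rand() * q);
  return s >= q ? q - 1 : s;
}

// One Swendsen-Wang sweep in place: freeze aligned bonds with probability
// 1 - exp(-J/T), then give every frozen component a fresh uniform spin.
static void swSweep(std::vector<int>& spin, const IntegerVector& ef,
                    const IntegerVector& et, const std::vector<double>& pf,
                    int q, std::vector<int>& parent, std::vector<int>& rank_,
                    std::vector<int>& rootSpin) {
  const int n = spin.size(), nE = ef.size();
  for (int i = 0; i < n; ++i) { parent[i] = i; rank_[i] = 0; }
  for (int e = 0; e < nE; ++e) {
    if (spin[ef[e]] == spin[et[e]] && unif_rand() < pf[e])
      unite(parent, rank_, ef[e], et[e]);
  }
  std::fill(rootSpin.begin(), rootSpin.end(), -1);
  for (int i = 0; i < n; ++i) {
    int r = findRoot(parent, i);
    if (rootSpin[r] < 0) rootSpin[r] = drawSpin(q);
    spin[i] = rootSpin[r];
  }
}

// [[Rcpp::export(name = ".spcEngine")]]
List spcEngine(int n, IntegerVector edgeFrom, IntegerVector edgeTo,
               NumericVector J, NumericVector temps, int q,
               int burnin, int sweeps) {
  const int nE = edgeFrom.size(), nT = temps.size();
  NumericMatrix deltaFreq(nT, nE);
  NumericVector mMean(nT), m2Mean(nT);
  std::vector<int> spin(n), parent(n), rank_(n), rootSpin(n), count(q);
  std::vector<double> pf(nE);

  for (int t = 0; t < nT; ++t) {
    const double T = temps[t];
    for (int e = 0; e < nE; ++e) pf[e] = 1.0 - std::exp(-J[e] / T);
    for (int i = 0; i < n; ++i) spin[i] = drawSpin(q);
    double sumM = 0.0, sumM2 = 0.0;
    for (int s = 0; s < burnin + sweeps; ++s) {
      swSweep(spin, edgeFrom, edgeTo, pf, q, parent, rank_, rootSpin);
      if (s >= burnin) {
        for (int e = 0; e < nE; ++e)
          if (spin[edgeFrom[e]] == spin[edgeTo[e]]) deltaFreq(t, e) += 1.0;
        std::fill(count.begin(), count.end(), 0);
        for (int i = 0; i < n; ++i) count[spin[i]]++;
        int nMax = 0;
        for (int c = 0; c < q; ++c) if (count[c] > nMax) nMax = count[c];
        const double m = (q * (double)nMax / n - 1.0) / (q - 1.0);
        sumM += m;
        sumM2 += m * m;
      }
    }
    for (int e = 0; e < nE; ++e) deltaFreq(t, e) /= sweeps;
    mMean[t] = sumM / sweeps;
    m2Mean[t] = sumM2 / sweeps;
  }
  return List::create(_["deltaFreq"] = deltaFreq, _["mMean"] = mMean,
                      _["m2Mean"] = m2Mean);
}

// [[Rcpp::export(name = ".swSweepOnce")]]
IntegerVector swSweepOnce(IntegerVector spins, IntegerVector edgeFrom,
                          IntegerVector edgeTo, NumericVector J,
                          double temperature, int q) {
  const int n = spins.size(), nE = edgeFrom.size();
  std::vector<int> spin(spins.begin(), spins.end());
  std::vector<int> parent(n), rank_(n), rootSpin(n);
  std::vector<double> pf(nE);
  for (int e = 0; e < nE; ++e) pf[e] = 1.0 - std::exp(-J[e] / temperature);
  swSweep(spin, edgeFrom, edgeTo, pf, q, parent, rank_, rootSpin);
  return IntegerVector(spin.begin(), spin.end());
}
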