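#include <Rcpp.h>
using namespace Rcpp;

// Boolean spin engine. Convention: J(i, j) is the influence of node j on
// node i, entries in {-1, 0, +1}. Spins s_i = +/-1. One unit time equals N
// single-node update attempts (random sequential update). All randomness
// comes from R's RNG so set.seed() at the R level governs everything.

// Sparse incoming-edge view of the interaction matrix (CSR by target node).
struct SpinNet {
  int N;
  std::vector<int> eptr, esrc, esgn;

  explicit SpinNet(const IntegerMatrix& J) {
    N = J.nrow();
    std::vector<int> cnt(N, 0);
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        if (J(i, j) != 0) cnt[i]++;
    eptr.assign(N + 1, 0);
    for (int i = 0; i < N; ++i) eptr[i + 1] = eptr[i] + cnt[i];
    esrc.resize(eptr[N]); esgn.resize(eptr[N]);
    std::vector<int> pos(eptr.begin(), eptr.end() - 1);
    for (int j = 0; j < N; ++j)
      for (int i = 0; i < N; ++i)
        if (J(i, j) != 0) {
          int p = pos[i]++;
          esrc[p] = j;
          esgn[p] = J(i, j);
        }
  }

  inline int field(const int* s, int i) const {
    int f = 0;
    for (int p = eptr[i]; p < eptr[i + 1]; ++p) f += esgn[p] * s[esrc[p]];
    return f;
  }

  inline int frustration(const int* s) const {
    int f = 0;
    for (int i = 0; i < N; ++i)
      for (int p = eptr[i]; p < eptr[i + 1]; ++p)
        if (s[i] * esgn[p] * s[esrc[p]] < 0) ++f;
    return f;
  }
};

// Number of unsatisfied directed links: sum over nonzero J(i,j) of
// theta(-s_i J_ij s_j), each directed link counted once.
// [[Rcpp::export]]
int cpp_frustration(const IntegerMatrix& J, const IntegerVector& s) {
  if (J.nrow() != s.size() || J.ncol() != s.size())
    stop("dimension mismatch between J and state");
  SpinNet net(J);
  std::vector<int> sv(s.begin(), s.end());
  return net.frustration(sv.data());
}

static void run_chain(const SpinNet& net, std::vector<int>& s, double T,
                      long long nAttempts, const std::vector<char>& clamped,
                      int deltaESign, bool recordFlips,
                      std::vector<int>* flipAttempt, std::vector<int>* flipNode,
                      std::vector<int>* flipValue) {
  const int N = net.N;
  for (long long a = 0; a < nAttempts; ++a) {
    int i = (int) std::floor(unif_rand() * N);
    if (i >= N) i = N - 1;
    if (clamped[i]) continue;
    double dE = deltaESign * 2.0 * s[i] * net.field(s.data(), i);
    bool accept;
    if (T > 0.0) {
      double p = dE <= 0.0 ? 1.0 : std::exp(-dE / T);
      accept = unif_rand() < p;
    } else {
      accept = dE <= 0.0;
    }
    if (accept) {
      s[i] = -s[i];
      if (recordFlips) {
        flipAttempt->push_back((int) (a + 1));
        flipNode->push_back(i + 1);
        flipValue->push_back(s[i]);
      }
    }
  }
}

// Run nAttempts Metropolis single-node updates at pseudo-temperature T.
// clampMask[i] freezes node i at its current value. deltaESign = +1 uses
// dE = +2 s_i sum_j J_ij s_j; -1 flips the sign. T == 0 is the greedy limit
// (accept iff dE <= 0; dE == 0 ties accepted, min(1, e^0) = 1). Optionally
// records accepted flips as (attempt index, node index, new spin).
// [[Rcpp::export]]
List cpp_metropolis_run(const IntegerMatrix& J, const IntegerVector& s0,
                        double T, double nAttempts,
                        const LogicalVector& clampMask, int deltaESign,
                        bool recordFlips = false) {
  const int N = s0.size();
  if (J.nrow() != N || J.ncol() != N) stop("dimension mismatch between J and state");
  SpinNet net(J);
  std::vector<int> s(s0.begin(), s0.end());
  std::vector<char> clamped(clampMask.begin(), clampMask.end());
  std::vector<int> fa, fn, fv;
  run_chain(net, s, T, (long long) nAttempts, clamped, deltaESign,
            recordFlips, &fa, &fn, &fv);
  List out = List::create(_["state"] = IntegerVector(s.begin(), s.end()));
  if (recordFlips)
    out["flips"] = DataFrame::create(_["attempt"] = fa, _["node"] = fn,
                                     _["spin"] = fv);
  return out;
}

// One search attempt for a low-frustration state: start from a fresh random
// spin configuration and anneal at temperature T, checking the frustration
// after every unit time (N attempts). Returns as soon as f <= fMax.
// [[Rcpp::export]]
List cpp_low_frustration_search(const IntegerMatrix& J, double T, int fMax,
                                int maxUnits, int deltaESign) {
  const int N = J.nrow();
  SpinNet net(J);
  std::vector<int> s(N);
  for (int i = 0; i < N; ++i) s[i] = unif_rand() < 0.5 ? -1 : 1;
  std::vector<char> clamped(N, 0);
  int best = net.frustration(s.data());
  bool found = best <= fMax;
  for (int u = 0; u < maxUnits && !found; ++u) {
    run_chain(net, s, T, N, clamped, deltaESign, false, nullptr, nullptr,
              nullptr);
    int f = net.frustration(s.data());
    if (f < best) best = f;
    if (f <= fMax) found = true;
  }
  return List::create(_["state"] = IntegerVector(s.begin(), s.end()),
                      _["frustration"] = best, _["found"] = found);
}
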