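// Event-level Moran birth-death simulator with mutation kernels.
//
// One event: a parent is drawn proportional to x_s * exp(beta * pi_s); the
// offspring's type is drawn from the parent's kernel row (mutation at the
// moment of copying); a uniformly chosen individual is removed (the parent
// may die); the offspring is added. Population size stays exactly N.
//
// Payoff engines: (0) matrix games with self-interaction excluded,
// (1) optional public goods with punishment, where the game share term is an
// exact hypergeometric expectation over group compositions and punishment
// terms are exact pairwise expectations. Payoffs are recomputed only when the
// composition actually changed since the last event (in the rare-mutation
// regime most events copy and remove the same type).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>
#include <memory>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  Rng(uint64_t root, uint64_t run) {
    std::seed_seq seq{static_cast<uint64_t>(0x9e3779b97f4a7c15ULL), root, run};
    gen.seed(seq);
  }
  double unif() {  // in [0, 1), 53-bit, implementation-independent
    return (gen() >> 11) * (1.0 / 9007199254740992.0);
  }
  int below(int n) { return std::min(n - 1, static_cast<int>(unif() * n)); }
};

class PayoffEngine {
 public:
  virtual ~PayoffEngine() {}
  virtual void payoffs(const std::vector<int>& x, int N,
                       std::vector<double>& pi) = 0;
};

class MatrixEngine : public PayoffEngine {
  NumericMatrix A;
 public:
  explicit MatrixEngine(NumericMatrix A_) : A(A_) {}
  void payoffs(const std::vector<int>& x, int N,
               std::vector<double>& pi) override {
    int m = A.nrow();
    for (int s = 0; s < m; ++s) {
      if (x[s] == 0) { pi[s] = 0.0; continue; }
      double tot = 0.0;
      for (int j = 0; j < m; ++j) tot += A(s, j) * x[j];
      pi[s] = (tot - A(s, s)) / (N - 1);
    }
  }
};

class PggEngine : public PayoffEngine {
  std::vector<int> base;          // 0 = C, 1 = D, 2 = L
  std::vector<int> pun;           // m x 3 flags, pun[3*s + target_base]
  int n_group;
  double c_invest, r_mult, sigma, fine, fine_cost;
  std::vector<double> lg;         // lgamma(k + 1) table

  double lch(int n, int k) const {
    if (k < 0 || k > n) return -INFINITY;
    return lg[n] - lg[k] - lg[n - k];
  }

 public:
  PggEngine(IntegerVector base_, IntegerMatrix pun_, int n_group_,
            double c_, double r_, double sigma_, double fine_, double cost_,
            int N)
      : base(base_.begin(), base_.end()), n_group(n_group_), c_invest(c_),
        r_mult(r_), sigma(sigma_), fine(fine_), fine_cost(cost_) {
    int m = pun_.nrow();
    pun.resize(3 * m);
    for (int s = 0; s < m; ++s)
      for (int t = 0; t < 3; ++t) pun[3 * s + t] = pun_(s, t);
    lg.resize(N + 2);
    for (int k = 0; k <= N + 1; ++k) lg[k] = std::lgamma(k + 1.0);
  }

  void payoffs(const std::vector<int>& x, int N,
               std::vector<double>& pi) override {
    int m = static_cast<int>(base.size());
    int b[3] = {0, 0, 0};       // population counts per base
    int pc[3] = {0, 0, 0};      // punishers targeting each base
    for (int s = 0; s < m; ++s) {
      if (!x[s]) continue;
      b[base[s]] += x[s];
      for (int t = 0; t < 3; ++t)
        if (pun[3 * s + t]) pc[t] += x[s];
    }
    int nm1 = n_group - 1;
    double pair_w = static_cast<double>(nm1) / (N - 1);
    double denom = lch(N - 1, nm1);
    for (int s = 0; s < m; ++s) {
      if (!x[s]) { pi[s] = 0.0; continue; }
      int bs = base[s];
      double game;
      if (bs == 2) {
        game = sigma;
      } else {
        int oC = b[0] - (bs == 0);
        int oD = b[1] - (bs == 1);
        int oL = b[2];
        game = 0.0;
        for (int kC = 0; kC <= std::min(nm1, oC); ++kC) {
          double lC = lch(oC, kC);
          for (int kD = 0; kD <= std::min(nm1 - kC, oD); ++kD) {
            int kL = nm1 - kC - kD;
            if (kL > oL) continue;
            double lw = lC + lch(oD, kD) + lch(oL, kL) - denom;
            int part = kC + kD + 1;
            int contrib = kC + (bs == 0);
            double val = (part >= 2)
                ? r_mult * c_invest * contrib / part - (bs == 0) * c_invest
                : sigma;
            game += std::exp(lw) * val;
          }
        }
      }
      double received = fine * pair_w * (pc[bs] - pun[3 * s + bs]);
      double paid = 0.0;
      for (int t = 0; t < 3; ++t)
        if (pun[3 * s + t]) paid += b[t] - (bs == t);
      paid *= fine_cost * pair_w;
      pi[s] = game - received - paid;
    }
  }
};

// Uniform random integer composition of N into m parts (stars and bars).
void random_composition(Rng& rng, int N, int m, std::vector<int>& x) {
  int top = N + m - 1;
  std::vector<int> bars;
  bars.reserve(m - 1);
  while (static_cast<int>(bars.size()) < m - 1) {
    int v = 1 + rng.below(top);
    if (std::find(bars.begin(), bars.end(), v) == bars.end()) bars.push_back(v);
  }
  std::sort(bars.begin(), bars.end());
  int prev = 0;
  for (int j = 0; j < m - 1; ++j) {
    x[j] = bars[j] - prev - 1;
    prev = bars[j];
  }
  x[m - 1] = top - prev;
}

}  // namespace

// [[Rcpp::export(name = ".moran_sim_cpp")]]
NumericMatrix moran_sim_cpp(int mode, NumericMatrix payA, IntegerVector base,
                            IntegerMatrix pun, int n_group, double c_invest,
                            double r_mult, double sigma, double fine,
                            double fine_cost, NumericMatrix kernel, int N,
                            double beta, int runs, double generations,
                            double window_fraction, double seed,
                            IntegerVector init_counts) {
  int m = kernel.nrow();
  std::unique_ptr<PayoffEngine> engine;
  if (mode == 0) {
    engine.reset(new MatrixEngine(payA));
  } else {
    engine.reset(new PggEngine(base, pun, n_group, c_invest, r_mult, sigma,
                               fine, fine_cost, N));
  }
  long long total = std::llround(generations * N);
  long long wlen = std::max(1LL, std::llround(window_fraction * total));
  long long wfirst = total - wlen + 1;  // first counted sample, 1-based

  NumericMatrix out(runs, m);
  std::vector<int> x(m);
  std::vector<double> pi(m), fit(m);

  for (int run = 0; run < runs; ++run) {
    Rng rng(static_cast<uint64_t>(seed), static_cast<uint64_t>(run));
    if (init_counts.size() == m) {
      for (int j = 0; j < m; ++j) x[j] = init_counts[j];
    } else {
      random_composition(rng, N, m, x);
    }
    std::vector<double> acc(m, 0.0);
    long long seg_start = 1;  // first sample index of current constant segment
    bool dirty = true;
    for (long long ev = 1; ev <= total; ++ev) {
      if (dirty) {
        engine->payoffs(x, N, pi);
        double mx = -INFINITY;
        for (int s = 0; s < m; ++s)
          if (x[s] && pi[s] > mx) mx = pi[s];
        for (int s = 0; s < m; ++s)
          fit[s] = x[s] ? x[s] * std::exp(beta * (pi[s] - mx)) : 0.0;
        dirty = false;
      }
      double W = 0.0;
      for (int s = 0; s < m; ++s) W += fit[s];
      double u = rng.unif() * W;
      int parent = m - 1;
      for (int s = 0; s < m; ++s) {
        u -= fit[s];
        if (u <= 0) { parent = s; break; }
      }
      double v = rng.unif();
      int off = m - 1;
      for (int s = 0; s < m; ++s) {
        v -= kernel(parent, s);
        if (v <= 0) { off = s; break; }
      }
      int ridx = rng.below(N);
      int rem = m - 1;
      for (int s = 0; s < m; ++s) {
        ridx -= x[s];
        if (ridx < 0) { rem = s; break; }
      }
      if (off != rem) {
        // flush samples [seg_start, ev - 1] of the old composition
        long long lo = std::max(seg_start, wfirst);
        long long hi = ev - 1;
        if (hi >= lo)
          for (int s = 0; s < m; ++s) acc[s] += static_cast<double>(x[s]) * (hi - lo + 1);
        x[rem] -= 1;
        x[off] += 1;
        seg_start = ev;
        dirty = true;
      }
      if ((ev & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    long long lo = std::max(seg_start, wfirst);
    if (total >= lo)
      for (int s = 0; s < m; ++s) acc[s] += static_cast<double>(x[s]) * (total - lo + 1);
    for (int s = 0; s < m; ++s) out(run, s) = acc[s] / (static_cast<double>(wlen) * N);
  }
  return out;
}
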