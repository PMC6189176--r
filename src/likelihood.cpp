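#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double HALF_LOG_2PI = 0.918938533204672741780329736406;

// Event model shared by all routines: N z-score events over I biomarkers,
// K-point midpoint quadrature per stage, T = K*(N+1) grid points on [0,1].
struct EventModel {
  int N, I, K, T;
  std::vector<int> bio;      // 0-based biomarker of each event
  std::vector<double> z;     // z-score threshold of each event
  std::vector<double> zmax;  // per-biomarker terminal z-score
  std::vector<double> lc, q; // per-biomarker log norm-const and 0.5/sigma^2
};

static EventModel make_model(const IntegerVector& ev_bio, const NumericVector& ev_z,
                             const NumericVector& zmax, const NumericVector& sigma,
                             int K) {
  EventModel m;
  m.N = ev_bio.size();
  m.I = zmax.size();
  m.K = K;
  m.T = K * (m.N + 1);
  m.bio.resize(m.N);
  m.z.resize(m.N);
  for (int e = 0; e < m.N; ++e) { m.bio[e] = ev_bio[e] - 1; m.z[e] = ev_z[e]; }
  m.zmax.assign(zmax.begin(), zmax.end());
  m.lc.resize(m.I);
  m.q.resize(m.I);
  for (int b = 0; b < m.I; ++b) {
    m.lc[b] = -std::log(sigma[b]) - HALF_LOG_2PI;
    m.q[b] = 0.5 / (sigma[b] * sigma[b]);
  }
  return m;
}

// Piecewise-linear trajectories g_i(t) evaluated at the T quadrature
// midpoints; knots are (0,0), (p/(N+1), z) for the event at 1-based
// position p, and (1, zmax_i). Column-major layout G[b*T + t].
static void traj_grid(const EventModel& m, const int* seq, std::vector<double>& G) {
  int N = m.N, I = m.I, T = m.T;
  std::vector<std::vector<double> > kt(I), kz(I);
  for (int b = 0; b < I; ++b) {
    kt[b].reserve(N + 2); kz[b].reserve(N + 2);
    kt[b].push_back(0.0); kz[b].push_back(0.0);
  }
  for (int p = 0; p < N; ++p) {
    int e = seq[p], b = m.bio[e];
    kt[b].push_back((p + 1.0) / (N + 1.0));
    kz[b].push_back(m.z[e]);
  }
  for (int b = 0; b < I; ++b) { kt[b].push_back(1.0); kz[b].push_back(m.zmax[b]); }
  G.resize((size_t)T * I);
  for (int b = 0; b < I; ++b) {
    const std::vector<double>& t_ = kt[b];
    const std::vector<double>& z_ = kz[b];
    size_t s = 1;
    double* g = &G[(size_t)b * T];
    for (int tt = 0; tt < T; ++tt) {
      double t = (tt + 0.5) / (double)T;
      while (s + 1 < t_.size() && t > t_[s]) ++s;
      g[tt] = z_[s - 1] + (z_[s] - z_[s - 1]) * (t - t_[s - 1]) / (t_[s] - t_[s - 1]);
    }
  }
}

// Per-subject log P(x_j | S) (and optionally the J x (N+1) per-stage log
// integrals). Missing values (NA) contribute a factor of 1. All sums in
// log space; exp() skipped below a -40 cutoff (relative mass < 1e-17).
static void seq_loglik(const EventModel& m, const NumericMatrix& X, const int* seq,
                       double* Lj, NumericMatrix* stage) {
  int J = X.nrow(), I = m.I, T = m.T, K = m.K, S = m.N + 1;
  std::vector<double> G;
  traj_grid(m, seq, G);
  double logw = -std::log((double)T);
  std::vector<double> st(T);
  for (int j = 0; j < J; ++j) {
    std::fill(st.begin(), st.end(), 0.0);
    for (int b = 0; b < I; ++b) {
      double x = X(j, b);
      if (ISNAN(x)) continue;
      const double* g = &G[(size_t)b * T];
      double c = m.lc[b], q = m.q[b];
      for (int tt = 0; tt < T; ++tt) { double d = x - g[tt]; st[tt] += c - q * d * d; }
    }
    double mx = st[0];
    for (int tt = 1; tt < T; ++tt) if (st[tt] > mx) mx = st[tt];
    double acc = 0.0;
    for (int tt = 0; tt < T; ++tt) { double d = st[tt] - mx; if (d > -40.0) acc += std::exp(d); }
    Lj[j] = mx + std::log(acc) + logw;
    if (stage) {
      for (int k = 0; k < S; ++k) {
        const double* sk = &st[(size_t)k * K];
        double mk = sk[0];
        for (int u = 1; u < K; ++u) if (sk[u] > mk) mk = sk[u];
        double ak = 0.0;
        for (int u = 0; u < K; ++u) { double d = sk[u] - mk; if (d > -40.0) ak += std::exp(d); }
        (*stage)(j, k) = mk + std::log(ak) + logw;
      }
    }
  }
}

// Total mixture objective sum_j log( exp(log_other_j) + f * P(x_j|S) );
// log_other_j = -Inf reduces to the single-sequence log likelihood.
static double mixture_obj(const std::vector<double>& Lj, const NumericVector& log_other,
                          double log_f) {
  double tot = 0.0;
  int J = Lj.size();
  for (int j = 0; j < J; ++j) {
    double a = log_other[j], b = log_f + Lj[j];
    if (a == NEG_INF) { tot += b; continue; }
    double mx = a > b ? a : b;
    tot += mx + std::log(std::exp(a - mx) + std::exp(b - mx));
  }
  return tot;
}

// Admissible insertion range for event e into the order `rem` (length N-1):
// final 0-based positions q in [lo+1, hi], where lo is the last index of a
// same-biomarker lower-z event and hi the first index of a higher-z one.
static void slot_range(const EventModel& m, const std::vector<int>& rem, int e,
                       int& lo, int& hi) {
  int N = m.N;
  lo = -1; hi = N - 1;
  for (int p = 0; p < N - 1; ++p) {
    if (m.bio[rem[p]] != m.bio[e]) continue;
    if (m.z[rem[p]] < m.z[e]) { if (p > lo) lo = p; }
    else if (p < hi) hi = p;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_stage_loglik(NumericMatrix X, IntegerVector seq, IntegerVector ev_bio,
                               NumericVector ev_z, NumericVector zmax,
                               NumericVector sigma, int K) {
  EventModel m = make_model(ev_bio, ev_z, zmax, sigma, K);
  std::vector<int> s(m.N);
  for (int p = 0; p < m.N; ++p) s[p] = seq[p] - 1;
  NumericMatrix stage(X.nrow(), m.N + 1);
  std::vector<double> Lj(X.nrow());
  seq_loglik(m, X, s.data(), Lj.data(), &stage);
  stage.attr("subject_loglik") = NumericVector(Lj.begin(), Lj.end());
  return stage;
}

// [[Rcpp::export]]
NumericVector cpp_subject_loglik(NumericMatrix X, IntegerVector seq, IntegerVector ev_bio,
                                 NumericVector ev_z, NumericVector zmax,
                                 NumericVector sigma, int K) {
  EventModel m = make_model(ev_bio, ev_z, zmax, sigma, K);
  std::vector<int> s(m.N);
  for (int p = 0; p < m.N; ++p) s[p] = seq[p] - 1;
  NumericVector Lj(X.nrow());
  seq_loglik(m, X, s.data(), REAL(Lj), nullptr);
  return Lj;
}

// Greedy coordinate ascent over event positions: each event in turn is
// moved to its best admissible position with the rest of the order fixed,
// repeated until a full pass changes nothing. Strict improvement required,
// so ties keep the incumbent position and the ascent terminates.
// [[Rcpp::export]]
List cpp_optimise_sequence(NumericMatrix X, IntegerVector seq0, IntegerVector ev_bio,
                           NumericVector ev_z, NumericVector zmax, NumericVector sigma,
                           int K, NumericVector log_other, double log_f, int max_passes) {
  EventModel m = make_model(ev_bio, ev_z, zmax, sigma, K);
  int N = m.N, J = X.nrow();
  std::vector<int> seq(N);
  for (int p = 0; p < N; ++p) seq[p] = seq0[p] - 1;
  std::vector<double> Lj(J);
  seq_loglik(m, X, seq.data(), Lj.data(), nullptr);
  double best = mixture_obj(Lj, log_other, log_f);
  std::vector<double> trace;
  trace.push_back(best);
  std::vector<int> rem(N > 1 ? N - 1 : 0), cand(N);
  int passes = 0;
  for (int pass = 0; pass < max_passes; ++pass) {
    bool changed = false;
    for (int e = 0; e < N; ++e) {
      int pcur = -1;
      for (int p = 0; p < N; ++p) if (seq[p] == e) { pcur = p; break; }
      int idx = 0;
      for (int p = 0; p < N; ++p) if (p != pcur) rem[idx++] = seq[p];
      int lo, hi;
      slot_range(m, rem, e, lo, hi);
      for (int q = lo + 1; q <= hi; ++q) {
        if (q == pcur) continue;
        for (int p = 0; p < q; ++p) cand[p] = rem[p];
        cand[q] = e;
        for (int p = q; p < N - 1; ++p) cand[p + 1] = rem[p];
        seq_loglik(m, X, cand.data(), Lj.data(), nullptr);
        double val = mixture_obj(Lj, log_other, log_f);
        if (val > best) {
          best = val;
          std::copy(cand.begin(), cand.end(), seq.begin());
          pcur = q;
          changed = true;
        }
      }
      Rcpp::checkUserInterrupt();
    }
    ++passes;
    trace.push_back(best);
    if (!changed) break;
  }
  IntegerVector out(N);
  for (int p = 0; p < N; ++p) out[p] = seq[p] + 1;
  return List::create(_["sequence"] = out, _["log_likelihood"] = best,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_passes"] = passes);
}

// Metropolis-Hastings over admissible orderings (and optionally mixture
// fractions). One step relocates one random event of one random subtype to
// a uniformly random admissible slot (symmetric proposal: the slot count
// depends only on the order of the other events); fractions get a clipped
// and renormalised Gaussian perturbation accepted jointly. Uses R's RNG so
// set.seed() gives identical chains.
// [[Rcpp::export]]
List cpp_mcmc(NumericMatrix X, IntegerMatrix seqs0, NumericVector f0,
              IntegerVector ev_bio, NumericVector ev_z, NumericVector zmax,
              NumericVector sigma, int K, int n_samples, int thin,
              bool sample_f, double f_sd) {
  EventModel m = make_model(ev_bio, ev_z, zmax, sigma, K);
  int C = seqs0.nrow(), N = m.N, J = X.nrow();
  std::vector<std::vector<int> > seqs(C, std::vector<int>(N));
  for (int c = 0; c < C; ++c)
    for (int p = 0; p < N; ++p) seqs[c][p] = seqs0(c, p) - 1;
  std::vector<double> f(f0.begin(), f0.end());
  std::vector<std::vector<double> > L(C, std::vector<double>(J));
  for (int c = 0; c < C; ++c) seq_loglik(m, X, seqs[c].data(), L[c].data(), nullptr);

  std::vector<double> lf(C), fnew(C), Lnew(J);
  auto total_with = [&](int crep, const std::vector<double>& Lrep,
                        const std::vector<double>& fr) -> double {
    for (int c = 0; c < C; ++c) lf[c] = fr[c] > 0 ? std::log(fr[c]) : NEG_INF;
    double tot = 0.0;
    for (int j = 0; j < J; ++j) {
      double mx = NEG_INF;
      for (int c = 0; c < C; ++c) {
        double v = lf[c] + ((c == crep) ? Lrep[j] : L[c][j]);
        if (v > mx) mx = v;
      }
      double acc = 0.0;
      for (int c = 0; c < C; ++c) {
        double v = lf[c] + ((c == crep) ? Lrep[j] : L[c][j]) - mx;
        if (v > -40.0) acc += std::exp(v);
      }
      tot += mx + std::log(acc);
    }
    return tot;
  };
  double cur = total_with(-1, Lnew, f);

  int n_store = n_samples / thin;
  IntegerMatrix S_out(n_store, C * N);
  NumericMatrix F_out(n_store, C);
  NumericVector LL_out(n_store);
  long accepted = 0;
  std::vector<int> rem(N > 1 ? N - 1 : 0), cand(N);
  RNGScope scope;
  int si = 0;
  for (int it = 0; it < n_samples; ++it) {
    int c = std::min((int)(unif_rand() * C), C - 1);
    int e = std::min((int)(unif_rand() * N), N - 1);
    const std::vector<int>& sc = seqs[c];
    int pcur = -1;
    for (int p = 0; p < N; ++p) if (sc[p] == e) { pcur = p; break; }
    int idx = 0;
    for (int p = 0; p < N; ++p) if (p != pcur) rem[idx++] = sc[p];
    int lo, hi;
    slot_range(m, rem, e, lo, hi);
    int nslots = hi - lo;
    int q = lo + 1 + std::min((int)(unif_rand() * nslots), nslots - 1);
    for (int p = 0; p < q; ++p) cand[p] = rem[p];
    cand[q] = e;
    for (int p = q; p < N - 1; ++p) cand[p + 1] = rem[p];
    bool fok = true;
    if (sample_f && C > 1) {
      double s = 0.0;
      for (int cc = 0; cc < C; ++cc) {
        fnew[cc] = f[cc] + f_sd * norm_rand();
        if (fnew[cc] < 0) fnew[cc] = 0;
        s += fnew[cc];
      }
      if (s <= 0) fok = false;
      else for (int cc = 0; cc < C; ++cc) fnew[cc] /= s;
    } else {
      std::copy(f.begin(), f.end(), fnew.begin());
    }
    if (fok) {
      seq_loglik(m, X, cand.data(), Lnew.data(), nullptr);
      double prop = total_with(c, Lnew, fnew);
      if (prop >= cur || std::log(unif_rand()) < prop - cur) {
        seqs[c].assign(cand.begin(), cand.end());
        L[c].swap(Lnew);
        std::copy(fnew.begin(), fnew.end(), f.begin());
        cur = prop;
        ++accepted;
      }
    }
    if ((it + 1) % thin == 0) {
      for (int cc = 0; cc < C; ++cc) {
        for (int p = 0; p < N; ++p) S_out(si, cc * N + p) = seqs[cc][p] + 1;
        F_out(si, cc) = f[cc];
      }
      LL_out[si] = cur;
      ++si;
    }
    if ((it & 2047) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sequences"] = S_out, _["fractions"] = F_out,
                      _["log_likelihoods"] = LL_out,
                      _["acceptance_rate"] = (double)accepted / n_samples);
}
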