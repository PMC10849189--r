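// Hartigan's dip statistic: the minimum over unimodal CDFs G of
// sup_x |F_n(x) - G(x)|.
//
// Computed by bisection on d with an exact feasibility test for "some
// unimodal CDF lies in the band [F_n - d, F_n + d]".  A unimodal CDF is
// convex left of the mode and concave right of it, with an atom allowed at
// the mode.  For fixed d the test reduces to hull conditions per side plus
// a junction condition: the minimal value the convex piece can take at the
// split must not exceed the maximal value the concave piece can take.
// Those extremal junction values are suprema of chord extrapolations
// (lower bound at t, upper bound at s < t, extrapolated to the split),
// maintained as an upper envelope of lines (Li Chao tree) with tangent
// queries against the incrementally built convex hull of the upper band.
//
// Validated exhaustively against an LP formulation of the same
// minimization during development.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

const double NEG_INF = -1e300;

struct LiChao {
  int n = 0;
  std::vector<double> xs, A, B;
  std::vector<char> has;
  void init(const std::vector<double>& x) {
    n = (int)x.size();
    xs = x;
    A.assign(4 * n + 4, 0.0);
    B.assign(4 * n + 4, 0.0);
    has.assign(4 * n + 4, 0);
  }
  void reset() { std::fill(has.begin(), has.end(), 0); }
  void insert(double a, double b) {
    int node = 1, lo = 0, hi = n - 1;
    while (true) {
      if (!has[node]) { A[node] = a; B[node] = b; has[node] = 1; return; }
      int mid = (lo + hi) / 2;
      bool leftBetter = a * xs[lo] + b > A[node] * xs[lo] + B[node];
      bool midBetter = a * xs[mid] + b > A[node] * xs[mid] + B[node];
      if (midBetter) { std::swap(a, A[node]); std::swap(b, B[node]); }
      if (lo == hi) return;
      if (leftBetter != midBetter) { node = 2 * node; hi = mid; }
      else { node = 2 * node + 1; lo = mid + 1; }
    }
  }
  double query(int i) const {
    double res = NEG_INF;
    int node = 1, lo = 0, hi = n - 1;
    while (true) {
      if (has[node]) res = std::max(res, A[node] * xs[i] + B[node]);
      if (lo == hi) break;
      int mid = (lo + hi) / 2;
      if (i <= mid) { node = 2 * node; hi = mid; } else { node = 2 * node + 1; lo = mid + 1; }
    }
    return res;
  }
};

// One orientation of the feasibility machinery: convex piece growing
// left-to-right over points (v, u upper, l lower).  The mirrored (concave)
// side is obtained by running this on reflected data.
struct SideEngine {
  const std::vector<double>&v, &u, &l;
  int Q;
  std::vector<double> hx, hy;  // scratch hull

  SideEngine(const std::vector<double>& v_, const std::vector<double>& u_,
             const std::vector<double>& l_)
      : v(v_), u(u_), l(l_), Q((int)v_.size()) {
    hx.resize(Q); hy.resize(Q);
  }

  // convex band feasibility: lower hull of (v, u)[1..q] >= l on 1..lim
  bool feas(int q, int lim) {
    if (lim < 1) return true;
    int m = 0;
    for (int t = 0; t < q; ++t) {
      while (m >= 2 && (hy[m - 1] - hy[m - 2]) * (v[t] - hx[m - 1]) >=
                           (u[t] - hy[m - 1]) * (hx[m - 1] - hx[m - 2]))
        --m;
      hx[m] = v[t]; hy[m] = u[t]; ++m;
    }
    int s = 0;
    for (int t = 0; t < lim; ++t) {
      while (s < m - 1 && hx[s + 1] <= v[t]) ++s;
      double hv = (s == m - 1 || hx[s] == v[t])
                      ? hy[s]
                      : hy[s] + (hy[s + 1] - hy[s]) * (v[t] - hx[s]) / (hx[s + 1] - hx[s]);
      if (l[t] > hv + 1e-13) return false;
    }
    return true;
  }

  // largest q in [0, Q] with feas(q, q - half) (monotone in q)
  int max_feasible(bool half) {
    int lo = 0, hi = Q;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (feas(mid, half ? mid - 1 : mid)) lo = mid; else hi = mid - 1;
    }
    return lo;
  }

  // Lgap[m] (m = 1..Q): minimal convex-piece value at v[m] using points 1..m
  // Lhalf[t]: minimal left-limit at v[t] using points 1..t-1
  // empty_floor: lower bound on G with no points yet (0 forward; -1 when the
  // engine runs on reflected data, where it encodes G <= 1)
  void junction_values(LiChao& env, double empty_floor,
                       std::vector<double>& Lgap, std::vector<double>& Lhalf) {
    Lgap.assign(Q + 1, empty_floor);  // 1-based; Lgap[0] unused
    Lhalf.assign(Q + 1, empty_floor);
    env.reset();
    int m = 0;  // hull of (v, u) over processed points
    for (int t = 0; t < Q; ++t) {
      double q0 = env.query(t);
      Lhalf[t + 1] = (q0 > NEG_INF / 2) ? q0 : empty_floor;
      // steepest chord from (v[t], l[t]) back through an upper point
      double slope = 0.0;
      if (m > 0) {
        int lo = 0, hi = m - 1;  // peak of slope((v[t],l[t]) -> hull[i])
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          // g(mid) < g(mid+1)?
          double lhs = (l[t] - hy[mid]) * (v[t] - hx[mid + 1]);
          double rhs = (l[t] - hy[mid + 1]) * (v[t] - hx[mid]);
          if (lhs < rhs) lo = mid + 1; else hi = mid;
        }
        slope = std::max(0.0, (l[t] - hy[lo]) / (v[t] - hx[lo]));
      }
      env.insert(slope, l[t] - slope * v[t]);
      Lgap[t + 1] = env.query(t);
      while (m >= 2 && (hy[m - 1] - hy[m - 2]) * (v[t] - hx[m - 1]) >=
                           (u[t] - hy[m - 1]) * (hx[m - 1] - hx[m - 2]))
        --m;
      hx[m] = v[t]; hy[m] = u[t]; ++m;
    }
  }
};

struct DipProblem {
  std::vector<double> v, up, lo;  // unique values, F_n below / at each
  int n = 0, Q = 0;
  LiChao envF, envR;
  std::vector<double> vr;  // reflected x grid

  void init(const double* x, int n_) {  // x sorted ascending
    n = n_;
    v.clear(); up.clear(); lo.clear();
    int i = 0;
    while (i < n) {
      int j = i;
      while (j + 1 < n && x[j + 1] == x[i]) ++j;
      v.push_back(x[i]);
      up.push_back((double)i / n);
      lo.push_back((double)(j + 1) / n);
      i = j + 1;
    }
    Q = (int)v.size();
    envF.init(v);
    vr.assign(Q, 0.0);
    for (int t = 0; t < Q; ++t) vr[t] = -v[Q - 1 - t];
    envR.init(vr);
  }

  bool feasible(double d) {
    std::vector<double> u(Q), l(Q), ur(Q), lr(Q), vv(Q);
    for (int t = 0; t < Q; ++t) {
      u[t] = std::min(up[t] + d, 1.0);
      l[t] = std::max(lo[t] - d, 0.0);
    }
    for (int t = 0; t < Q; ++t) {  // reflect: (x, y) -> (-x, -y)
      ur[t] = -l[Q - 1 - t];
      lr[t] = -u[Q - 1 - t];
    }
    SideEngine L(v, u, l), R(vr, ur, lr);
    int TconvF = L.max_feasible(false), TconvH = L.max_feasible(true);
    int TrF = R.max_feasible(false), TrH = R.max_feasible(true);
    // concave suffix s..Q feasible  <=>  reflected prefix of size Q+1-s
    int TconcF = Q + 1 - TrF;  // min feasible suffix start (full)
    int TconcH = Q + 1 - TrH;  // min t with concave side of a jump feasible

    std::vector<double> LgapF, LhalfF, LgapR, LhalfR;
    L.junction_values(envF, 0.0, LgapF, LhalfF);
    R.junction_values(envR, -1.0, LgapR, LhalfR);
    const double eps = 1e-13;

    // gap configurations: prefix 1..m convex, suffix m+1..Q concave
    int mlo = std::max(0, TconcF - 1), mhi = std::min(Q, TconvF);
    for (int m = mlo; m <= mhi; ++m) {
      if (m == 0 || m == Q) return true;
      double rmax = -LgapR[Q - m];  // concave value at v[m+1] using m+1..Q
      if (LgapF[m] <= rmax + eps) return true;
    }
    // jump configurations: atom at v[t]
    int tlo = std::max(1, TconcH), thi = std::min(Q, TconvH);
    for (int t = tlo; t <= thi; ++t) {
      double lm = LhalfF[t];                      // min left limit at v[t]
      double rc = (t == Q) ? 1.0 : -LhalfR[Q + 1 - t];  // max G(v[t]) from right
      if (lm <= std::min(u[t - 1], rc) + eps) return true;
    }
    return false;
  }

  double solve() {
    if (Q == 1) return 0.0;
    double a = 0.0, b = 0.5;
    for (int it = 0; it < 48 && b - a > 1e-10; ++it) {
      double mid = 0.5 * (a + b);
      if (feasible(mid)) b = mid; else a = mid;
    }
    return b;
  }
};

double dip_one(std::vector<double>& x) {
  std::sort(x.begin(), x.end());
  DipProblem P;
  P.init(x.data(), (int)x.size());
  return P.solve();
}

}  // namespace

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector x) {
  std::vector<double> xs(x.begin(), x.end());
  if (xs.size() < 2) return 0.0;
  return dip_one(xs);
}

// [[Rcpp::export(name = ".dip_null_cpp")]]
NumericVector dip_null_cpp(int n, int n_null) {
  NumericVector out(n_null);
  std::vector<double> xs(n);
  for (int r = 0; r < n_null; ++r) {
    for (int i = 0; i < n; ++i) xs[i] = R::unif_rand();
    out[r] = dip_one(xs);
  }
  return out;
}
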