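#include <Rcpp.h>
#include <array>
#include <map>
#include <set>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Incremental Bowyer-Watson Delaunay triangulation in 2 or 3 dimensions.
// Each simplex caches its circumcentre and squared circumradius, so the
// in-circumsphere test reduces to a distance comparison.  A simplex whose
// circumsphere cannot be computed (degenerate vertex set) is given an
// infinite radius so that it is removed by the next insertion.

struct Simplex {
  std::array<int, 4> v;      // vertex indices (v[3] = -1 in 2D)
  std::array<double, 3> cc;  // circumcentre
  double r2;                 // squared circumradius
  bool alive;
};

static bool circumsphere(const std::vector<std::array<double, 3> > &P,
                         const std::array<int, 4> &v, int d,
                         std::array<double, 3> &cc, double &r2) {
  // Solve 2 (v_i - v_0) . x = |v_i|^2 - |v_0|^2 for i = 1..d.
  long double A[3][3], b[3];
  const std::array<double, 3> &p0 = P[v[0]];
  long double n0 = 0;
  for (int k = 0; k < d; ++k) n0 += (long double)p0[k] * p0[k];
  for (int i = 0; i < d; ++i) {
    const std::array<double, 3> &pi = P[v[i + 1]];
    long double ni = 0;
    for (int k = 0; k < d; ++k) {
      A[i][k] = 2.0L * ((long double)pi[k] - p0[k]);
      ni += (long double)pi[k] * pi[k];
    }
    b[i] = ni - n0;
  }
  // Gaussian elimination with partial pivoting.
  for (int c = 0; c < d; ++c) {
    int piv = c;
    for (int r = c + 1; r < d; ++r)
      if (fabsl(A[r][c]) > fabsl(A[piv][c])) piv = r;
    if (fabsl(A[piv][c]) < 1e-300L) return false;
    if (piv != c) {
      for (int k = 0; k < d; ++k) std::swap(A[piv][k], A[c][k]);
      std::swap(b[piv], b[c]);
    }
    for (int r = c + 1; r < d; ++r) {
      long double f = A[r][c] / A[c][c];
      for (int k = c; k < d; ++k) A[r][k] -= f * A[c][k];
      b[r] -= f * b[c];
    }
  }
  long double x[3] = {0, 0, 0};
  for (int r = d - 1; r >= 0; --r) {
    long double s = b[r];
    for (int k = r + 1; k < d; ++k) s -= A[r][k] * x[k];
    x[r] = s / A[r][r];
  }
  long double rr = 0;
  for (int k = 0; k < d; ++k) {
    cc[k] = (double)x[k];
    long double dk = x[k] - (long double)p0[k];
    rr += dk * dk;
  }
  if (d == 2) cc[2] = 0.0;
  r2 = (double)rr;
  return std::isfinite(r2);
}

static inline bool in_circumsphere(const Simplex &s,
                                   const std::array<double, 3> &p, int d) {
  if (!std::isfinite(s.r2)) return true;
  double dist2 = 0;
  for (int k = 0; k < d; ++k) {
    double dk = p[k] - s.cc[k];
    dist2 += dk * dk;
  }
  return dist2 <= s.r2 * (1.0 + 1e-12);
}

// [[Rcpp::export]]
IntegerMatrix delaunay_edges_cpp(NumericMatrix pts, int d) {
  const int n = pts.nrow();
  if (d != 2 && d != 3) stop("dimension must be 2 or 3");
  if (n < 2) return IntegerMatrix(0, 2);

  std::vector<std::array<double, 3> > P(n + d + 1);
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < d; ++k) {
      double v = pts(i, k);
      if (!std::isfinite(v)) stop("coordinates must be finite");
      P[i][k] = v;
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
    if (d == 2) P[i][2] = 0.0;
  }
  double ctr[3] = {0, 0, 0}, span = 0;
  for (int k = 0; k < d; ++k) {
    ctr[k] = 0.5 * (lo[k] + hi[k]);
    span = std::max(span, hi[k] - lo[k]);
  }
  if (span <= 0) span = 1.0;
  // Far enough that circumspheres of boundary simplices behave as half-space
  // tests; the long-double circumcentre solve keeps this numerically safe.
  const double M = 65536.0 * span;

  // Super-simplex enclosing all points.
  std::vector<Simplex> S;
  {
    Simplex s0;
    s0.alive = true;
    if (d == 2) {
      P[n]     = { ctr[0],         ctr[1] + 3 * M, 0 };
      P[n + 1] = { ctr[0] - 3 * M, ctr[1] - 2 * M, 0 };
      P[n + 2] = { ctr[0] + 3 * M, ctr[1] - 2 * M, 0 };
      s0.v = { n, n + 1, n + 2, -1 };
    } else {
      P[n]     = { ctr[0],         ctr[1],         ctr[2] + 4 * M };
      P[n + 1] = { ctr[0] - 3 * M, ctr[1] - 2 * M, ctr[2] - 2 * M };
      P[n + 2] = { ctr[0] + 3 * M, ctr[1] - 2 * M, ctr[2] - 2 * M };
      P[n + 3] = { ctr[0],         ctr[1] + 3 * M, ctr[2] - 2 * M };
      s0.v = { n, n + 1, n + 2, n + 3 };
    }
    if (!circumsphere(P, s0.v, d, s0.cc, s0.r2))
      s0.r2 = std::numeric_limits<double>::infinity();
    S.push_back(s0);
  }

  typedef std::array<int, 3> Facet;  // sorted vertex ids (third = -1 in 2D)
  for (int ip = 0; ip < n; ++ip) {
    std::map<Facet, int> facets;
    for (size_t is = 0; is < S.size(); ++is) {
      if (!S[is].alive) continue;
      if (!in_circumsphere(S[is], P[ip], d)) continue;
      S[is].alive = false;
      // facets: omit one vertex at a time
      for (int omit = 0; omit <= d; ++omit) {
        Facet f = { -1, -1, -1 };
        int m = 0;
        for (int j = 0; j <= d; ++j)
          if (j != omit) f[m++] = S[is].v[j];
        std::sort(f.begin(), f.begin() + d);
        facets[f] += 1;
      }
    }
    for (std::map<Facet, int>::const_iterator it = facets.begin();
         it != facets.end(); ++it) {
      if (it->second != 1) continue;  // interior facet of the cavity
      Simplex ns;
      ns.alive = true;
      ns.v = { it->first[0], it->first[1], d == 3 ? it->first[2] : ip,
               d == 3 ? ip : -1 };
      if (!circumsphere(P, ns.v, d, ns.cc, ns.r2))
        ns.r2 = std::numeric_limits<double>::infinity();
      S.push_back(ns);
    }
    // periodic compaction keeps the scan linear in live simplices
    if (S.size() > 4096) {
      std::vector<Simplex> keep;
      keep.reserve(S.size() / 2);
      for (size_t is = 0; is < S.size(); ++is)
        if (S[is].alive) keep.push_back(S[is]);
      S.swap(keep);
    }
  }

  std::set<std::pair<int, int> > edges;
  for (size_t is = 0; is < S.size(); ++is) {
    if (!S[is].alive) continue;
    for (int a = 0; a <= d; ++a)
      for (int b = a + 1; b <= d; ++b) {
        int va = S[is].v[a], vb = S[is].v[b];
        if (va >= n || vb >= n || va < 0 || vb < 0) continue;
        edges.insert(std::make_pair(std::min(va, vb), std::max(va, vb)));
      }
  }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first + 1;  // 1-based for R
    out(r, 1) = it->second + 1;
  }
  return out;
}
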