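#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// E-step of rigid Coherent Point Drift.
//
// X  : N x D fixed (data) points
// TY : M x D transformed moving points (current GMM centroids)
// sigma2 : shared isotropic Gaussian variance (mm^2)
// w  : uniform outlier weight in [0, 1)
//
// Returns the standard CPD sufficient statistics P1 (row sums of the
// posterior matrix P, length M), Pt1 (column sums, length N), PX = P %*% X
// (M x D), and L, the negative log-likelihood of the mixture
//   p(x) = w/N + (1-w)/M * sum_m N(x; TY_m, sigma2 I).
// Posteriors are computed with a per-point log-sum-exp shift so the E-step
// stays finite as sigma2 collapses on clean data.
// [[Rcpp::export]]
List cpd_estep_cpp(NumericMatrix X, NumericMatrix TY, double sigma2, double w) {
  const int N = X.nrow(), M = TY.nrow(), D = X.ncol();
  NumericVector P1(M), Pt1(N);
  NumericMatrix PX(M, D);
  double L = 0.0;
  const double g = std::log((1.0 - w) / (double)M)
    - 0.5 * D * std::log(2.0 * M_PI * sigma2);
  const double logc = (w > 0.0) ? std::log(w / (double)N) : R_NegInf;
  std::vector<double> a(M);
  for (int n = 0; n < N; ++n) {
    double amax = R_NegInf;
    for (int m = 0; m < M; ++m) {
      double d2 = 0.0;
      for (int d = 0; d < D; ++d) {
        const double diff = X(n, d) - TY(m, d);
        d2 += diff * diff;
      }
      a[m] = -d2 / (2.0 * sigma2);
      if (a[m] > amax) amax = a[m];
    }
    double ssum = 0.0;
    for (int m = 0; m < M; ++m) ssum += std::exp(a[m] - amax);
    const double lse = amax + std::log(ssum);
    const double term1 = g + lse;
    double logZ;
    if (w > 0.0) {
      const double mx = (term1 > logc) ? term1 : logc;
      logZ = mx + std::log(std::exp(term1 - mx) + std::exp(logc - mx));
    } else {
      logZ = term1;
    }
    L -= logZ;
    const double base = g - logZ;
    for (int m = 0; m < M; ++m) {
      const double p = std::exp(base + a[m]);
      if (p > 0.0) {
        P1[m] += p;
        Pt1[n] += p;
        for (int d = 0; d < D; ++d) PX(m, d) += p * X(n, d);
      }
    }
  }
  return List::create(_["P1"] = P1, _["Pt1"] = Pt1, _["PX"] = PX, _["L"] = L);
}

// Exhaustive nearest-vertex query: for each row of Q find the closest row of
// V. Returns 1-based indices and Euclidean distances.
// [[Rcpp::export]]
List nn_vertex_cpp(NumericMatrix Q, NumericMatrix V) {
  const int n = Q.nrow(), m = V.nrow(), D = Q.ncol();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bestj = 0;
    for (int j = 0; j < m; ++j) {
      double d2 = 0.0;
      for (int d = 0; d < D; ++d) {
        const double diff = Q(i, d) - V(j, d);
        d2 += diff * diff;
      }
      if (d2 < best) { best = d2; bestj = j; }
    }
    idx[i] = bestj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Closest point on triangle (a, b, c) to p (Ericson, Real-Time Collision
// Detection, ch. 5). Writes result into out.
static void closest_pt_triangle(const double *p, const double *a,
                                const double *b, const double *c,
                                double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  const double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }
  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  const double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }
  const double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    const double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }
  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  const double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }
  const double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    const double wv = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + wv * ac[i];
    return;
  }
  const double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    const double wv = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + wv * (c[i] - b[i]);
    return;
  }
  const double denom = 1.0 / (va + vb + vc);
  const double v = vb * denom, wv = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i] + wv * ac[i];
}

// Exhaustive nearest point on a triangle mesh surface. F0 holds 0-based
// vertex indices, one triangle per row. Returns for each query row the
// closest surface point, its distance and the 1-based face index.
// [[Rcpp::export]]
List nn_surface_cpp(NumericMatrix Q, NumericMatrix V, IntegerMatrix F0) {
  const int n = Q.nrow(), nf = F0.nrow();
  NumericMatrix closest(n, 3);
  NumericVector dist(n);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    const double p[3] = { Q(i, 0), Q(i, 1), Q(i, 2) };
    double best = R_PosInf;
    double bestpt[3] = { 0.0, 0.0, 0.0 };
    int bestf = 0;
    double out[3];
    for (int f = 0; f < nf; ++f) {
      const int ia = F0(f, 0), ib = F0(f, 1), ic = F0(f, 2);
      const double a[3] = { V(ia, 0), V(ia, 1), V(ia, 2) };
      const double b[3] = { V(ib, 0), V(ib, 1), V(ib, 2) };
      const double c[3] = { V(ic, 0), V(ic, 1), V(ic, 2) };
      closest_pt_triangle(p, a, b, c, out);
      double d2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        const double diff = p[d] - out[d];
        d2 += diff * diff;
      }
      if (d2 < best) {
        best = d2;
        bestf = f;
        for (int d = 0; d < 3; ++d) bestpt[d] = out[d];
      }
    }
    for (int d = 0; d < 3; ++d) closest(i, d) = bestpt[d];
    dist[i] = std::sqrt(best);
    face[i] = bestf + 1;
  }
  return List::create(_["point"] = closest, _["distance"] = dist,
                      _["face"] = face);
}
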