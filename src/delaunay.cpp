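#include <Rcpp.h>
using namespace Rcpp;

// Brute-force Delaunay complexes by the empty-circumsphere property.
// Point counts per snapshot are small (a few dozen C-alpha atoms), so the
// O(n^4) / O(n^5) enumeration is exact and fast enough; no incremental
// triangulation is needed.

static inline double det3(double a11, double a12, double a13,
                          double a21, double a22, double a23,
                          double a31, double a32, double a33) {
  return a11 * (a22 * a33 - a23 * a32)
       - a12 * (a21 * a33 - a23 * a31)
       + a13 * (a21 * a32 - a22 * a31);
}

// Circumsphere of 4 points: solve 2 (p_k - p_i) . c = |p_k|^2 - |p_i|^2.
// Returns false when the tetrahedron is (numerically) flat.
static bool circumsphere3(const double *p0, const double *p1,
                          const double *p2, const double *p3,
                          double *centre, double *r2) {
  double a[3][3], b[3];
  const double *q[3] = {p1, p2, p3};
  double n0 = p0[0] * p0[0] + p0[1] * p0[1] + p0[2] * p0[2];
  double scale = 0.0;
  for (int k = 0; k < 3; ++k) {
    double rowlen = 0.0;
    for (int d = 0; d < 3; ++d) {
      a[k][d] = 2.0 * (q[k][d] - p0[d]);
      rowlen += a[k][d] * a[k][d];
    }
    scale = std::max(scale, rowlen);
    b[k] = q[k][0] * q[k][0] + q[k][1] * q[k][1] + q[k][2] * q[k][2] - n0;
  }
  double det = det3(a[0][0], a[0][1], a[0][2],
                    a[1][0], a[1][1], a[1][2],
                    a[2][0], a[2][1], a[2][2]);
  // relative flatness threshold: det scales like (edge length)^3
  double lim = 1e-12 * std::pow(std::sqrt(scale), 3.0);
  if (std::fabs(det) <= lim) return false;
  centre[0] = det3(b[0], a[0][1], a[0][2], b[1], a[1][1], a[1][2],
                   b[2], a[2][1], a[2][2]) / det;
  centre[1] = det3(a[0][0], b[0], a[0][2], a[1][0], b[1], a[1][2],
                   a[2][0], b[2], a[2][2]) / det;
  centre[2] = det3(a[0][0], a[0][1], b[0], a[1][0], a[1][1], b[1],
                   a[2][0], a[2][1], b[2]) / det;
  double dx = p0[0] - centre[0], dy = p0[1] - centre[1], dz = p0[2] - centre[2];
  *r2 = dx * dx + dy * dy + dz * dz;
  return true;
}

// [[Rcpp::export]]
List cpp_delaunay3(NumericMatrix X) {
  int n = X.nrow();
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = X(i, 0); py[i] = X(i, 1); pz[i] = X(i, 2);
  }
  std::vector<int> tets;
  std::vector<double> radii2;
  double c[3], r2;
  for (int i = 0; i < n - 3; ++i) {
    double pi[3] = {px[i], py[i], pz[i]};
    for (int j = i + 1; j < n - 2; ++j) {
      double pj[3] = {px[j], py[j], pz[j]};
      for (int k = j + 1; k < n - 1; ++k) {
        double pk[3] = {px[k], py[k], pz[k]};
        for (int l = k + 1; l < n; ++l) {
          double pl[3] = {px[l], py[l], pz[l]};
          if (!circumsphere3(pi, pj, pk, pl, c, &r2)) continue;
          bool empty = true;
          // strict emptiness; cospherical ties are broken upstream by a
          // seeded symbolic jitter, not by a tolerance here
          double lim = r2;
          for (int m = 0; m < n; ++m) {
            if (m == i || m == j || m == k || m == l) continue;
            double dx = px[m] - c[0], dy = py[m] - c[1], dz = pz[m] - c[2];
            if (dx * dx + dy * dy + dz * dz < lim) { empty = false; break; }
          }
          if (empty) {
            tets.push_back(i + 1); tets.push_back(j + 1);
            tets.push_back(k + 1); tets.push_back(l + 1);
            radii2.push_back(r2);
          }
        }
      }
    }
  }
  int nt = (int)radii2.size();
  IntegerMatrix T(nt, 4);
  NumericVector R2(nt);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = tets[4 * t]; T(t, 1) = tets[4 * t + 1];
    T(t, 2) = tets[4 * t + 2]; T(t, 3) = tets[4 * t + 3];
    R2[t] = radii2[t];
  }
  return List::create(_["simplices"] = T, _["r2"] = R2);
}

// Circumcircle of 3 points in the plane; false when (numerically) collinear.
static bool circumcircle2(const double *p0, const double *p1, const double *p2,
                          double *centre, double *r2) {
  double ax = 2.0 * (p1[0] - p0[0]), ay = 2.0 * (p1[1] - p0[1]);
  double bx = 2.0 * (p2[0] - p0[0]), by = 2.0 * (p2[1] - p0[1]);
  double det = ax * by - ay * bx;
  double scale = std::max(ax * ax + ay * ay, bx * bx + by * by);
  if (std::fabs(det) <= 1e-12 * scale) return false;
  double n0 = p0[0] * p0[0] + p0[1] * p0[1];
  double ca = p1[0] * p1[0] + p1[1] * p1[1] - n0;
  double cb = p2[0] * p2[0] + p2[1] * p2[1] - n0;
  centre[0] = (ca * by - cb * ay) / det;
  centre[1] = (ax * cb - bx * ca) / det;
  double dx = p0[0] - centre[0], dy = p0[1] - centre[1];
  *r2 = dx * dx + dy * dy;
  return true;
}

// [[Rcpp::export]]
List cpp_delaunay2(NumericMatrix X) {
  int n = X.nrow();
  std::vector<double> px(n), py(n);
  for (int i = 0; i < n; ++i) { px[i] = X(i, 0); py[i] = X(i, 1); }
  std::vector<int> tris;
  std::vector<double> radii2;
  double c[2], r2;
  for (int i = 0; i < n - 2; ++i) {
    double pi[2] = {px[i], py[i]};
    for (int j = i + 1; j < n - 1; ++j) {
      double pj[2] = {px[j], py[j]};
      for (int k = j + 1; k < n; ++k) {
        double pk[2] = {px[k], py[k]};
        if (!circumcircle2(pi, pj, pk, c, &r2)) continue;
        bool empty = true;
        double lim = r2;
        for (int m = 0; m < n; ++m) {
          if (m == i || m == j || m == k) continue;
          double dx = px[m] - c[0], dy = py[m] - c[1];
          if (dx * dx + dy * dy < lim) { empty = false; break; }
        }
        if (empty) {
          tris.push_back(i + 1); tris.push_back(j + 1); tris.push_back(k + 1);
          radii2.push_back(r2);
        }
      }
    }
  }
  int nt = (int)radii2.size();
  IntegerMatrix T(nt, 3);
  NumericVector R2(nt);
  for (int t = 0; t < nt; ++t) {
    T(t, 0) = tris[3 * t]; T(t, 1) = tris[3 * t + 1]; T(t, 2) = tris[3 * t + 2];
    R2[t] = radii2[t];
  }
  return List::create(_["simplices"] = T, _["r2"] = R2);
}

// Column reduction of a Z2 boundary matrix (columns in filtration order,
// entries = 1-based row positions, sorted ascending). Returns each column's
// pivot (0 when the column reduces to zero), the reduced columns, and the
// accumulated column combinations V (R = D V), used to warm-start the
// volume-optimal cycle search.
static std::vector<int> xor_merge(const std::vector<int> &a,
                                  const std::vector<int> &b) {
  std::vector<int> out;
  out.reserve(a.size() + b.size());
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) out.push_back(a[i++]);
    else if (b[j] < a[i]) out.push_back(b[j++]);
    else { ++i; ++j; }
  }
  while (i < a.size()) out.push_back(a[i++]);
  while (j < b.size()) out.push_back(b[j++]);
  return out;
}

// [[Rcpp::export]]
List cpp_reduce_z2(List cols, int nrows) {
  int nc = cols.size();
  std::vector< std::vector<int> > R(nc), V(nc);
  std::vector<int> owner(nrows + 1, -1);
  IntegerVector pivots(nc);
  for (int j = 0; j < nc; ++j) {
    IntegerVector cj = cols[j];
    std::vector<int> col(cj.begin(), cj.end());
    std::sort(col.begin(), col.end());
    std::vector<int> v(1, j + 1);
    while (!col.empty()) {
      int p = col.back();
      int o = owner[p];
      if (o < 0) break;
      col = xor_merge(col, R[o]);
      v = xor_merge(v, V[o]);
    }
    R[j] = col;
    V[j] = v;
    if (!col.empty()) {
      pivots[j] = col.back();
      owner[col.back()] = j;
    }
  }
  List Rl(nc), Vl(nc);
  for (int j = 0; j < nc; ++j) {
    Rl[j] = IntegerVector(R[j].begin(), R[j].end());
    Vl[j] = IntegerVector(V[j].begin(), V[j].end());
  }
  return List::create(_["pivots"] = pivots, _["reduced"] = Rl, _["v"] = Vl);
}
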