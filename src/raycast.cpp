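#include <Rcpp.h>
using namespace Rcpp;

// Ray/triangle intersection test (Moller-Trumbore). Counts crossings of a ray
// from each query point against a closed triangulated surface; odd parity
// means inside. Several ray directions are voted on by the caller's contract
// so that rays grazing triangle edges on imperfect surfaces cannot flip the
// answer.

static inline bool ray_hits_tri(const double *o, const double *d,
                                const double *v0, const double *v1,
                                const double *v2) {
  const double eps = 1e-12;
  double e1[3], e2[3], p[3], t[3], q[3];
  for (int i = 0; i < 3; ++i) {
    e1[i] = v1[i] - v0[i];
    e2[i] = v2[i] - v0[i];
  }
  p[0] = d[1] * e2[2] - d[2] * e2[1];
  p[1] = d[2] * e2[0] - d[0] * e2[2];
  p[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = e1[0] * p[0] + e1[1] * p[1] + e1[2] * p[2];
  if (std::fabs(det) < eps) return false;
  double inv = 1.0 / det;
  for (int i = 0; i < 3; ++i) t[i] = o[i] - v0[i];
  double u = (t[0] * p[0] + t[1] * p[1] + t[2] * p[2]) * inv;
  if (u < 0.0 || u > 1.0) return false;
  q[0] = t[1] * e1[2] - t[2] * e1[1];
  q[1] = t[2] * e1[0] - t[0] * e1[2];
  q[2] = t[0] * e1[1] - t[1] * e1[0];
  double v = (d[0] * q[0] + d[1] * q[1] + d[2] * q[2]) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  double s = (e2[0] * q[0] + e2[1] * q[1] + e2[2] * q[2]) * inv;
  return s > eps;
}

// [[Rcpp::export(name = ".raycast_inside")]]
LogicalVector raycast_inside(NumericMatrix points, NumericMatrix verts,
                             IntegerMatrix tris, NumericMatrix rays) {
  const int np = points.nrow(), nt = tris.nrow(), nr = rays.nrow();
  // column-major copies into flat row-major arrays for cache locality
  std::vector<double> P(3 * np), V(3 * verts.nrow()), R(3 * nr);
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < 3; ++j) P[3 * i + j] = points(i, j);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3 * i + j] = verts(i, j);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < 3; ++j) R[3 * i + j] = rays(i, j);
  std::vector<int> T(3 * nt);
  for (int i = 0; i < nt; ++i)
    for (int j = 0; j < 3; ++j) T[3 * i + j] = tris(i, j) - 1;

  // surface bounding box prefilter
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
  for (int i = 0; i < verts.nrow(); ++i)
    for (int j = 0; j < 3; ++j) {
      if (V[3 * i + j] < lo[j]) lo[j] = V[3 * i + j];
      if (V[3 * i + j] > hi[j]) hi[j] = V[3 * i + j];
    }

  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    const double *o = &P[3 * i];
    bool in_box = true;
    for (int j = 0; j < 3; ++j)
      if (o[j] < lo[j] || o[j] > hi[j]) { in_box = false; break; }
    if (!in_box) { out[i] = false; continue; }
    int votes = 0;
    for (int r = 0; r < nr; ++r) {
      const double *d = &R[3 * r];
      int crossings = 0;
      for (int k = 0; k < nt; ++k) {
        const int *tr = &T[3 * k];
        if (ray_hits_tri(o, d, &V[3 * tr[0]], &V[3 * tr[1]], &V[3 * tr[2]]))
          ++crossings;
      }
      if (crossings % 2 == 1) ++votes;
    }
    out[i] = votes * 2 > nr;
  }
  return out;
}
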