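// d-dimensional convex hull by randomized incremental insertion
// (beneath-beyond). Sized for community-ecology problems: tens to a few
// hundred points in 2-6 dimensions, called many times inside null models,
// so facets live in flat reusable buffers and ridge matching uses packed
// integer keys. Near-degenerate inputs are detected and signalled; the R
// wrapper retries with a seeded joggle.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <unordered_map>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

namespace {

struct HullBuilder {
  int n, d;
  std::vector<double> pts;     // n x d, row-major
  double span;
  // facets, flat (slot k of facet f at index f*d + k)
  std::vector<double> fnorm;   // unit outward normals
  std::vector<double> foff;    // offsets: normal . x <= offset inside
  std::vector<int> fverts;
  std::vector<int> fneigh;     // neighbour across ridge omitting fverts[f*d+k]
  std::vector<char> alive;
  std::vector<double> c0;      // fixed interior point
  // workspace
  std::vector<double> A;       // (d-1) x d Gauss-Jordan tableau
  std::vector<int> pivcol;
  std::vector<char> ispiv, vis;
  bool failed;

  HullBuilder(const NumericMatrix &points)
      : n(points.nrow()), d(points.ncol()), failed(false) {
    pts.resize((size_t)n * d);
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < d; ++c) pts[(size_t)i * d + c] = points(i, c);
    span = 0.0;
    for (int c = 0; c < d; ++c) {
      double lo = pts[c], hi = pts[c];
      for (int i = 1; i < n; ++i) {
        const double v = pts[(size_t)i * d + c];
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      span = std::max(span, hi - lo);
    }
    if (!(span > 0.0)) span = 1.0;
    A.resize((size_t)(d - 1) * d);
    pivcol.resize(d - 1);
    ispiv.resize(d);
    c0.assign(d, 0.0);
  }

  inline const double *pt(int i) const { return &pts[(size_t)i * d]; }
  inline double fdist(int f, const double *p) const {
    const double *nr = &fnorm[(size_t)f * d];
    double s = 0.0;
    for (int c = 0; c < d; ++c) s += nr[c] * p[c];
    return s - foff[f];
  }
  inline int nfacets() const { return (int)foff.size(); }

  // normal of the hyperplane through verts[0..d-1]: null vector of the
  // (d-1) x d edge matrix, Gauss-Jordan with partial pivoting
  bool facet_normal(const int *verts, double *nrm) {
    const int m = d - 1;
    const double *w0 = pt(verts[0]);
    for (int r = 0; r < m; ++r) {
      const double *w = pt(verts[r + 1]);
      for (int c = 0; c < d; ++c) A[(size_t)r * d + c] = w[c] - w0[c];
    }
    const double tol = 1e-12 * span;
    int row = 0;
    for (int col = 0; col < d && row < m; ++col) {
      int best = -1;
      double bv = tol;
      for (int r = row; r < m; ++r) {
        const double a = std::fabs(A[(size_t)r * d + col]);
        if (a > bv) { bv = a; best = r; }
      }
      if (best < 0) continue;
      if (best != row)
        for (int c = 0; c < d; ++c)
          std::swap(A[(size_t)best * d + c], A[(size_t)row * d + c]);
      const double piv = A[(size_t)row * d + col];
      for (int r = 0; r < m; ++r) {
        if (r == row) continue;
        const double f = A[(size_t)r * d + col] / piv;
        if (f == 0.0) continue;
        for (int c = col; c < d; ++c)
          A[(size_t)r * d + c] -= f * A[(size_t)row * d + c];
      }
      pivcol[row] = col;
      ++row;
    }
    if (row < m) return false; // rank < d-1
    std::fill(ispiv.begin(), ispiv.end(), 0);
    for (int r = 0; r < m; ++r) ispiv[pivcol[r]] = 1;
    int freec = -1;
    for (int c = 0; c < d; ++c) if (!ispiv[c]) { freec = c; break; }
    for (int c = 0; c < d; ++c) nrm[c] = 0.0;
    nrm[freec] = 1.0;
    for (int r = 0; r < m; ++r)
      nrm[pivcol[r]] = -A[(size_t)r * d + freec] / A[(size_t)r * d + pivcol[r]];
    double nn = 0.0;
    for (int c = 0; c < d; ++c) nn += nrm[c] * nrm[c];
    nn = std::sqrt(nn);
    if (!(nn > 0.0)) return false;
    for (int c = 0; c < d; ++c) nrm[c] /= nn;
    return true;
  }

  // append a facet (orienting the normal away from c0); returns its id
  int add_facet(const int *verts) {
    const int fid = nfacets();
    fverts.insert(fverts.end(), verts, verts + d);
    fneigh.insert(fneigh.end(), d, -1);
    fnorm.resize(fnorm.size() + d);
    double *nrm = &fnorm[(size_t)fid * d];
    if (!facet_normal(verts, nrm)) { failed = true; foff.push_back(0); alive.push_back(0); return fid; }
    double off = 0.0;
    const double *w0 = pt(verts[0]);
    for (int c = 0; c < d; ++c) off += nrm[c] * w0[c];
    double side = -off;
    for (int c = 0; c < d; ++c) side += nrm[c] * c0[c];
    if (std::fabs(side) < 1e-13 * span) { failed = true; }
    if (side > 0) {
      for (int c = 0; c < d; ++c) nrm[c] = -nrm[c];
      off = -off;
    }
    foff.push_back(off);
    alive.push_back(1);
    return fid;
  }

  bool build() {
    if (n < d + 1) return false; // degenerate by count

    // initial simplex: greedy farthest-point Gram-Schmidt
    std::vector<int> sv;
    {
      int v0 = 0;
      for (int i = 1; i < n; ++i)
        if (pts[(size_t)i * d] < pts[(size_t)v0 * d]) v0 = i;
      sv.push_back(v0);
      std::vector<double> basis; // orthonormal rows, flat
      std::vector<double> r(d), bestres(d);
      const double rtol = 1e-9 * span;
      for (int k = 0; k < d; ++k) {
        int best = -1;
        double bestr = rtol;
        for (int i = 0; i < n; ++i) {
          const double *p = pt(i);
          const double *o = pt(v0);
          for (int c = 0; c < d; ++c) r[c] = p[c] - o[c];
          for (size_t bq = 0; bq * d < basis.size(); ++bq) {
            double pr = 0.0;
            for (int c = 0; c < d; ++c) pr += basis[bq * d + c] * r[c];
            for (int c = 0; c < d; ++c) r[c] -= pr * basis[bq * d + c];
          }
          double rn = 0.0;
          for (int c = 0; c < d; ++c) rn += r[c] * r[c];
          rn = std::sqrt(rn);
          if (rn > bestr) { bestr = rn; best = i; bestres = r; }
        }
        if (best < 0) return false; // affine rank < d: degenerate
        for (int c = 0; c < d; ++c) bestres[c] /= bestr;
        basis.insert(basis.end(), bestres.begin(), bestres.end());
        sv.push_back(best);
      }
    }
    for (size_t k = 0; k < sv.size(); ++k)
      for (int c = 0; c < d; ++c) c0[c] += pt(sv[k])[c] / (d + 1.0);

    // d+1 simplex facets; facet i omits sv[i]
    std::vector<int> fv(d);
    for (int i = 0; i <= d; ++i) {
      int t = 0;
      for (int j = 0; j <= d; ++j) if (j != i) fv[t++] = sv[j];
      const int fid = add_facet(&fv[0]);
      if (failed) return true; // failed flag set
      // neighbour across ridge omitting fv[k] is the facet omitting fv[k]
      for (int k = 0; k < d; ++k)
        for (int j = 0; j <= d; ++j)
          if (sv[j] == fverts[(size_t)fid * d + k]) {
            fneigh[(size_t)fid * d + k] = j;
            break;
          }
    }

    std::vector<char> insimp(n, 0);
    for (size_t k = 0; k < sv.size(); ++k) insimp[sv[k]] = 1;
    const double epsV = 1e-9 * span;
    const bool packable = (d <= 5) && (n < (1 << 20));
    std::vector<int> horizon_rv, horizon_base; // flat (d-1 verts per ridge)
    std::vector<int> newfacets;
    std::unordered_map<long long, int> open_packed; // key -> fid*d + slot
    std::map<std::vector<int>, int> open_generic;
    std::vector<int> key(d > 2 ? d - 2 : 1);

    for (int p = 0; p < n; ++p) {
      if (insimp[p]) continue;
      const double *pp = pt(p);
      const int nf = nfacets();
      vis.assign(nf, 0);
      bool any = false;
      for (int f = 0; f < nf; ++f) {
        if (!alive[f]) continue;
        if (fdist(f, pp) > epsV) { vis[f] = 1; any = true; }
      }
      if (!any) continue;

      horizon_rv.clear();
      horizon_base.clear();
      for (int f = 0; f < nf; ++f) {
        if (!vis[f]) continue;
        for (int k = 0; k < d; ++k) {
          const int g = fneigh[(size_t)f * d + k];
          if (g < 0) { failed = true; break; }
          if (vis[g]) continue;
          horizon_base.push_back(g);
          for (int j = 0; j < d; ++j)
            if (j != k) horizon_rv.push_back(fverts[(size_t)f * d + j]);
        }
        alive[f] = 0;
        if (failed) break;
      }
      if (failed || horizon_base.empty()) { failed = true; return true; }

      open_packed.clear();
      open_generic.clear();
      newfacets.clear();
      for (size_t h = 0; h < horizon_base.size() && !failed; ++h) {
        const int *rv = &horizon_rv[h * (d - 1)];
        for (int j = 0; j < d - 1; ++j) fv[j] = rv[j];
        fv[d - 1] = p;
        const int fid = add_facet(&fv[0]);
        if (failed) return true;
        newfacets.push_back(fid);

        // link across the horizon ridge (slot of p, position d-1)
        const int base = horizon_base[h];
        fneigh[(size_t)fid * d + (d - 1)] = base;
        int slot = -1;
        for (int k = 0; k < d; ++k) {
          const int w = fverts[(size_t)base * d + k];
          bool inridge = false;
          for (int j = 0; j < d - 1; ++j)
            if (rv[j] == w) { inridge = true; break; }
          if (!inridge) { slot = k; break; }
        }
        if (slot < 0) { failed = true; return true; }
        fneigh[(size_t)base * d + slot] = fid;

        // link among new facets via the subridge omitting rv[j] (plus p)
        for (int j = 0; j < d - 1; ++j) {
          int t = 0;
          for (int q = 0; q < d - 1; ++q)
            if (q != j) key[t++] = rv[q];
          std::sort(key.begin(), key.begin() + (d - 2));
          if (packable) {
            long long kk = 1;
            for (int q = 0; q < d - 2; ++q) kk = (kk << 20) | key[q];
            std::unordered_map<long long, int>::iterator it =
                open_packed.find(kk);
            if (it == open_packed.end()) {
              open_packed[kk] = fid * d + j;
            } else {
              const int of = it->second / d, os = it->second % d;
              fneigh[(size_t)fid * d + j] = of;
              fneigh[(size_t)of * d + os] = fid;
              open_packed.erase(it);
            }
          } else {
            std::vector<int> kv(key.begin(), key.begin() + (d - 2));
            std::map<std::vector<int>, int>::iterator it =
                open_generic.find(kv);
            if (it == open_generic.end()) {
              open_generic[kv] = fid * d + j;
            } else {
              const int of = it->second / d, os = it->second % d;
              fneigh[(size_t)fid * d + j] = of;
              fneigh[(size_t)of * d + os] = fid;
              open_generic.erase(it);
            }
          }
        }
      }
      if (!open_packed.empty() || !open_generic.empty()) {
        failed = true; // non-manifold horizon (coplanarity)
        return true;
      }
    }

    // containment check: every input point inside every facet
    const double ctol = 50.0 * epsV;
    for (int f = 0; f < nfacets(); ++f) {
      if (!alive[f]) continue;
      for (int i = 0; i < n; ++i)
        if (fdist(f, pt(i)) > ctol) { failed = true; return true; }
    }
    return true; // full-dimensional, not failed
  }

  // (d-1)-volume of facet f via the Gram determinant of its edges
  double facet_area(int f) {
    const int m = d - 1;
    const int *verts = &fverts[(size_t)f * d];
    const double *w0 = pt(verts[0]);
    // reuse A as the edge matrix, then form Gram in-place
    for (int r = 0; r < m; ++r) {
      const double *w = pt(verts[r + 1]);
      for (int c = 0; c < d; ++c) A[(size_t)r * d + c] = w[c] - w0[c];
    }
    std::vector<double> G((size_t)m * m);
    for (int i = 0; i < m; ++i)
      for (int j = i; j < m; ++j) {
        double s = 0.0;
        for (int c = 0; c < d; ++c)
          s += A[(size_t)i * d + c] * A[(size_t)j * d + c];
        G[(size_t)i * m + j] = G[(size_t)j * m + i] = s;
      }
    double det = 1.0;
    for (int k = 0; k < m; ++k) {
      int best = k;
      for (int r = k + 1; r < m; ++r)
        if (std::fabs(G[(size_t)r * m + k]) > std::fabs(G[(size_t)best * m + k]))
          best = r;
      if (best != k) {
        for (int c = 0; c < m; ++c)
          std::swap(G[(size_t)best * m + c], G[(size_t)k * m + c]);
        det = -det;
      }
      const double piv = G[(size_t)k * m + k];
      if (piv == 0.0) return 0.0;
      det *= piv;
      for (int r = k + 1; r < m; ++r) {
        const double fct = G[(size_t)r * m + k] / piv;
        for (int c = k; c < m; ++c)
          G[(size_t)r * m + c] -= fct * G[(size_t)k * m + c];
      }
    }
    if (det < 0.0) det = 0.0;
    double fact = 1.0;
    for (int k = 2; k <= m; ++k) fact *= k;
    return std::sqrt(det) / fact;
  }

  double volume() {
    double vol = 0.0;
    for (int f = 0; f < nfacets(); ++f) {
      if (!alive[f]) continue;
      double h = foff[f];
      const double *nr = &fnorm[(size_t)f * d];
      for (int c = 0; c < d; ++c) h -= nr[c] * c0[c];
      vol += facet_area(f) * h / d;
    }
    return vol;
  }
};

} // namespace

// [[Rcpp::export(name = ".chull_cpp")]]
List chull_cpp(NumericMatrix points, bool want_facets) {
  if (points.ncol() < 2) stop("need at least 2 dimensions");
  HullBuilder hb(points);
  const bool fulldim = hb.build();
  if (hb.failed)
    return List::create(_["volume"] = 0.0, _["degenerate"] = false,
                        _["ok"] = false, _["vertices"] = IntegerVector(0));
  if (!fulldim)
    return List::create(_["volume"] = 0.0, _["degenerate"] = true,
                        _["ok"] = true, _["vertices"] = IntegerVector(0));

  List out = List::create(_["volume"] = hb.volume(),
                          _["degenerate"] = false, _["ok"] = true);
  std::vector<char> onhull(hb.n, 0);
  int nalive = 0;
  for (int f = 0; f < hb.nfacets(); ++f) {
    if (!hb.alive[f]) continue;
    ++nalive;
    for (int k = 0; k < hb.d; ++k) onhull[hb.fverts[(size_t)f * hb.d + k]] = 1;
  }
  IntegerVector vertices;
  for (int i = 0; i < hb.n; ++i) if (onhull[i]) vertices.push_back(i + 1);
  out["vertices"] = vertices;
  if (want_facets) {
    NumericMatrix normals(nalive, hb.d);
    NumericVector offsets(nalive);
    int r = 0;
    for (int f = 0; f < hb.nfacets(); ++f) {
      if (!hb.alive[f]) continue;
      for (int c = 0; c < hb.d; ++c)
        normals(r, c) = hb.fnorm[(size_t)f * hb.d + c];
      offsets[r] = hb.foff[f];
      ++r;
    }
    out["normals"] = normals;
    out["offsets"] = offsets;
  }
  return out;
}

// volumes of hulls of row subsets (1-based index columns), for null models
// [[Rcpp::export(name = ".subset_hull_volumes_cpp")]]
NumericVector subset_hull_volumes_cpp(NumericMatrix points,
                                      IntegerMatrix subsets) {
  const int d = points.ncol(), m = subsets.ncol(), nsim = subsets.nrow();
  NumericVector out(nsim);
  NumericMatrix sub(m, d);
  for (int s = 0; s < nsim; ++s) {
    for (int i = 0; i < m; ++i)
      for (int c = 0; c < d; ++c) sub(i, c) = points(subsets(s, i) - 1, c);
    HullBuilder hb(sub);
    const bool fulldim = hb.build();
    out[s] = (hb.failed) ? NA_REAL : (fulldim ? hb.volume() : 0.0);
  }
  return out;
}

// [[Rcpp::export(name = ".points_in_hull_cpp")]]
LogicalVector points_in_hull_cpp(NumericMatrix points, NumericMatrix normals,
                                 NumericVector offsets, double tol) {
  const int n = points.nrow(), d = points.ncol(), m = normals.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    bool inside = true;
    for (int f = 0; f < m && inside; ++f) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) s += normals(f, c) * points(i, c);
      if (s > offsets[f] + tol) inside = false;
    }
    out[i] = inside;
  }
  return out;
}
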