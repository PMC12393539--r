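#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Volumes are indexed (z, y, x) with dim = c(nz, ny, nx); linear index
// i = z + nz*(y + ny*x), 0-based, matching R's column-major layout.

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// [[Rcpp::export(name = ".cc_label_26")]]
IntegerVector cc_label_26(IntegerVector mask, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int n = nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (mask[i] == 0 || lab[i] != 0) continue;
    ++cur;
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v % nz, rest = v / nz;
      int y = rest % ny, x = rest / ny;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dz && !dy && !dx) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            int w = lin(zz, yy, xx, nz, ny);
            if (mask[w] != 0 && lab[w] == 0) {
              lab[w] = cur;
              stack.push_back(w);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("n_components") = cur;
  return lab;
}

// Fill interior cavities: background voxels not 6-connected to the volume
// border become foreground. Input mask must be 0/1. Voxels set in
// `blocker` (e.g. other segmentation labels walling off a lumen) cannot
// be traversed by the outside flood and are never added to the fill.
// [[Rcpp::export(name = ".fill_holes_6")]]
IntegerVector fill_holes_6(IntegerVector mask, IntegerVector dims,
                           Nullable<IntegerVector> blocker = R_NilValue) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int n = nz * ny * nx;
  std::vector<char> blocked(n, 0);
  if (blocker.isNotNull()) {
    IntegerVector b(blocker);
    for (int i = 0; i < n; ++i) blocked[i] = (b[i] != 0);
  }
  std::vector<char> outside(n, 0);
  std::vector<int> stack;
  // seed from all border voxels that are traversable background
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        if (z > 0 && z < nz - 1 && y > 0 && y < ny - 1 && x > 0 && x < nx - 1)
          continue;
        int i = lin(z, y, x, nz, ny);
        if (mask[i] == 0 && !blocked[i] && !outside[i]) {
          outside[i] = 1;
          stack.push_back(i);
        }
      }
  const int dzs[6] = {1, -1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, 1, -1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int z = v % nz, rest = v / nz;
    int y = rest % ny, x = rest / ny;
    for (int k = 0; k < 6; ++k) {
      int zz = z + dzs[k], yy = y + dys[k], xx = x + dxs[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int w = lin(zz, yy, xx, nz, ny);
      if (mask[w] == 0 && !blocked[w] && !outside[w]) {
        outside[w] = 1;
        stack.push_back(w);
      }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (mask[i] != 0 || (!outside[i] && !blocked[i])) ? 1 : 0;
  out.attr("dim") = dims;
  return out;
}

// One or more passes of a 3x3x3 box mean over a numeric volume; voxels
// outside the array are treated as 0 (callers pad the crop accordingly).
// [[Rcpp::export(name = ".smooth_box3")]]
NumericVector smooth_box3(NumericVector vals, IntegerVector dims, int iterations) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int n = nz * ny * nx;
  std::vector<double> a(vals.begin(), vals.end()), b(n);
  for (int it = 0; it < iterations; ++it) {
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          double s = 0.0;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int zz = z + dz, yy = y + dy, xx = x + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                    xx < 0 || xx >= nx) continue;
                s += a[lin(zz, yy, xx, nz, ny)];
              }
          b[lin(z, y, x, nz, ny)] = s / 27.0;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---- marching tetrahedra ---------------------------------------------------
// Kuhn decomposition of each grid cube into 6 tetrahedra sharing the main
// diagonal; isosurface vertices interpolated along tetrahedron edges.
// Vertices are deduplicated by grid-edge key so the mesh is watertight.

struct MTState {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int edge_point(MTState &st, int ga, int gb,
                      const double *px, const double *py, const double *pz,
                      const double *val, double iso) {
  if (ga > gb) std::swap(ga, gb);
  uint64_t key = (uint64_t)ga * 0x100000000ULL + (uint64_t)gb;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double va = val[ga], vb = val[gb];
  double t = (iso - va) / (vb - va);
  if (t < 0) t = 0; if (t > 1) t = 1;
  st.vx.push_back(px[ga] + t * (px[gb] - px[ga]));
  st.vy.push_back(py[ga] + t * (py[gb] - py[ga]));
  st.vz.push_back(pz[ga] + t * (pz[gb] - pz[ga]));
  int id = (int)st.vx.size() - 1;
  st.edge_vertex[key] = id;
  return id;
}

// [[Rcpp::export(name = ".marching_tetra")]]
List marching_tetra(NumericVector vals, IntegerVector dims, double iso) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int nnode = nz * ny * nx;
  // node positions in index units (x, y, z)
  std::vector<double> px(nnode), py(nnode), pz(nnode);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        px[i] = x; py[i] = y; pz[i] = z;
      }
  const double *val = vals.begin();
  // cube corner c: bits (x = c&1, y = (c>>1)&1, z = (c>>2)&1)
  const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  MTState st;
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        int g[8];
        for (int c = 0; c < 8; ++c)
          g[c] = lin(z + ((c >> 2) & 1), y + ((c >> 1) & 1), x + (c & 1),
                     nz, ny);
        // skip uniform cubes quickly
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c)
          (val[g[c]] > iso ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int a = g[tets[t][0]], b = g[tets[t][1]],
              c = g[tets[t][2]], d = g[tets[t][3]];
          int node[4] = {a, b, c, d};
          bool in[4];
          int nin = 0;
          for (int k = 0; k < 4; ++k) {
            in[k] = val[node[k]] > iso;
            if (in[k]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          if (nin == 1 || nin == 3) {
            bool want = (nin == 1);
            int apex = -1, others[3], no = 0;
            for (int k = 0; k < 4; ++k) {
              if (in[k] == want) apex = node[k];
              else others[no++] = node[k];
            }
            int p0 = edge_point(st, apex, others[0], px.data(), py.data(), pz.data(), val, iso);
            int p1 = edge_point(st, apex, others[1], px.data(), py.data(), pz.data(), val, iso);
            int p2 = edge_point(st, apex, others[2], px.data(), py.data(), pz.data(), val, iso);
            st.f0.push_back(p0); st.f1.push_back(p1); st.f2.push_back(p2);
          } else {
            int ins[2], outs[2], ni = 0, no = 0;
            for (int k = 0; k < 4; ++k) {
              if (in[k]) ins[ni++] = node[k];
              else outs[no++] = node[k];
            }
            int p0 = edge_point(st, ins[0], outs[0], px.data(), py.data(), pz.data(), val, iso);
            int p1 = edge_point(st, ins[0], outs[1], px.data(), py.data(), pz.data(), val, iso);
            int p2 = edge_point(st, ins[1], outs[1], px.data(), py.data(), pz.data(), val, iso);
            int p3 = edge_point(st, ins[1], outs[0], px.data(), py.data(), pz.data(), val, iso);
            st.f0.push_back(p0); st.f1.push_back(p1); st.f2.push_back(p2);
            st.f0.push_back(p0); st.f1.push_back(p2); st.f2.push_back(p3);
          }
        }
      }
  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = st.vx[i]; V(i, 1) = st.vy[i]; V(i, 2) = st.vz[i];
  }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = st.f0[i] + 1; F(i, 1) = st.f1[i] + 1; F(i, 2) = st.f2[i] + 1;
  }
  return List::create(Named("vertices") = V, Named("faces") = F);
}

// ---- exact point-to-triangle distance (Ericson, Real-Time Collision
// Detection, 5.1.5) --------------------------------------------------------

static inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double dist2_to(const double *p, double qx, double qy, double qz) {
  double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
  return dx * dx + dy * dy + dz * dz;
}

static double pt_tri_dist2(const double *p, const double *a,
                           const double *b, const double *c) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) return dist2_to(p, a[0], a[1], a[2]);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) return dist2_to(p, b[0], b[1], b[2]);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return dist2_to(p, a[0] + v * ab[0], a[1] + v * ab[1], a[2] + v * ab[2]);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) return dist2_to(p, c[0], c[1], c[2]);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return dist2_to(p, a[0] + w * ac[0], a[1] + w * ac[1], a[2] + w * ac[2]);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2_to(p, b[0] + w * (c[0] - b[0]), b[1] + w * (c[1] - b[1]),
                    b[2] + w * (c[2] - b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return dist2_to(p, a[0] + ab[0] * v + ac[0] * w,
                  a[1] + ab[1] * v + ac[1] * w,
                  a[2] + ab[2] * v + ac[2] * w);
}

// Minimal Euclidean distance from each query point to a triangle mesh.
// [[Rcpp::export(name = ".point_mesh_min_dist")]]
NumericVector point_mesh_min_dist(NumericMatrix points, NumericMatrix vertices,
                                  IntegerMatrix faces) {
  int np = points.nrow(), nf = faces.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      int ia = faces(f, 0) - 1, ib = faces(f, 1) - 1, ic = faces(f, 2) - 1;
      double a[3] = {vertices(ia, 0), vertices(ia, 1), vertices(ia, 2)};
      double b[3] = {vertices(ib, 0), vertices(ib, 1), vertices(ib, 2)};
      double c[3] = {vertices(ic, 0), vertices(ic, 1), vertices(ic, 2)};
      double d2 = pt_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
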