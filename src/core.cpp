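#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <unordered_map>
#include <vector>
#include "mc_tables.h"

using namespace Rcpp;

// ---- marching cubes -------------------------------------------------------

// corner offsets, conventional numbering: 0=(0,0,0) 1=(1,0,0) 2=(1,1,0)
// 3=(0,1,0) 4=(0,0,1) 5=(1,0,1) 6=(1,1,1) 7=(0,1,1)
static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
// edge -> (cornerA, cornerB)
static const int EDGE[12][2] = {
  {0,1},{1,2},{2,3},{3,0},{4,5},{5,6},{6,7},{7,4},{0,4},{1,5},{2,6},{3,7}
};

// Unique key for an edge of the global grid: base corner index * 3 + axis.
static inline int64_t edge_key(int x, int y, int z, int axis,
                               int nx, int ny) {
  int64_t lin = (int64_t)z * ny * (int64_t)nx + (int64_t)y * nx + x;
  return lin * 3 + axis;
}

// [[Rcpp::export(name = ".mc_extract")]]
List mc_extract(NumericVector field, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = REAL(field);
  auto at = [&](int x, int y, int z) {
    return f[(int64_t)z * ny * nx + (int64_t)y * nx + x];
  };

  std::unordered_map<int64_t, int> vindex;
  std::vector<double> verts;   // x,y,z triples in voxel-index units
  std::vector<int> faces;      // 0-based

  double val[8];
  int gx[8], gy[8], gz[8];

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int ci = 0;
        for (int c = 0; c < 8; ++c) {
          gx[c] = x + CORNER[c][0];
          gy[c] = y + CORNER[c][1];
          gz[c] = z + CORNER[c][2];
          val[c] = at(gx[c], gy[c], gz[c]);
          // bit set for corners above the isovalue (interior side; fixes the
          // ambiguous-saddle resolution deterministically)
          if (val[c] > iso) ci |= (1 << c);
        }
        if (ci == 0 || ci == 255) continue;
        const signed char *tri = MC_TRI_TABLE[ci];
        for (int t = 0; tri[t] != -1; t += 3) {
          int fidx[3];
          for (int e = 0; e < 3; ++e) {
            int ed = tri[t + e];
            int a = EDGE[ed][0], b = EDGE[ed][1];
            int axis = (gx[a] != gx[b]) ? 0 : (gy[a] != gy[b]) ? 1 : 2;
            int bx = std::min(gx[a], gx[b]);
            int by = std::min(gy[a], gy[b]);
            int bz = std::min(gz[a], gz[b]);
            int64_t key = edge_key(bx, by, bz, axis, nx, ny);
            auto it = vindex.find(key);
            int vi;
            if (it == vindex.end()) {
              double va = val[a], vb = val[b];
              double mu = (vb == va) ? 0.5 : (iso - va) / (vb - va);
              if (mu < 0) mu = 0;
              if (mu > 1) mu = 1;
              double px = gx[a] + mu * (gx[b] - gx[a]);
              double py = gy[a] + mu * (gy[b] - gy[a]);
              double pz = gz[a] + mu * (gz[b] - gz[a]);
              vi = (int)(verts.size() / 3);
              verts.push_back(px); verts.push_back(py); verts.push_back(pz);
              vindex.emplace(key, vi);
            } else vi = it->second;
            fidx[e] = vi;
          }
          // skip degenerate triangles (shared interpolated vertices)
          if (fidx[0] == fidx[1] || fidx[1] == fidx[2] || fidx[0] == fidx[2])
            continue;
          faces.push_back(fidx[0]);
          faces.push_back(fidx[1]);
          faces.push_back(fidx[2]);
        }
      }

  int nv = (int)(verts.size() / 3), nf = (int)(faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = verts[3 * i]; V(i, 1) = verts[3 * i + 1]; V(i, 2) = verts[3 * i + 2];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = faces[3 * i] + 1; F(i, 1) = faces[3 * i + 1] + 1;
    F(i, 2) = faces[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---- 3D connected components ---------------------------------------------

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims,
                         int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int64_t n = (int64_t)nx * ny * nz;
  IntegerVector out(n, 0);
  const int *m = LOGICAL(mask);

  std::vector<int> noff;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        noff.push_back(dx); noff.push_back(dy); noff.push_back(dz);
      }

  int label = 0;
  std::vector<int64_t> stack;
  for (int64_t s = 0; s < n; ++s) {
    if (m[s] != TRUE || out[s] != 0) continue;
    ++label;
    stack.clear();
    stack.push_back(s);
    out[s] = label;
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      int cz = (int)(cur / ((int64_t)nx * ny));
      int rem = (int)(cur % ((int64_t)nx * ny));
      int cy = rem / nx, cx = rem % nx;
      for (size_t q = 0; q < noff.size(); q += 3) {
        int px = cx + noff[q], py = cy + noff[q + 1], pz = cz + noff[q + 2];
        if (px < 0 || py < 0 || pz < 0 || px >= nx || py >= ny || pz >= nz)
          continue;
        int64_t pi = (int64_t)pz * ny * nx + (int64_t)py * nx + px;
        if (m[pi] == TRUE && out[pi] == 0) {
          out[pi] = label;
          stack.push_back(pi);
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

// Standard lower-envelope-of-parabolas pass; sample positions are i*s.
// BIG stands in for +infinity (sources absent); it survives the algebra
// because all coordinates here are << 1e6 mm.
static const double DT_BIG = 1e20;

static void dt1d(const std::vector<double> &fin, std::vector<double> &fout,
                 double s) {
  const int n = (int)fin.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_BIG; z[1] = DT_BIG;
  for (int q = 1; q < n; ++q) {
    double sq = (double)q * s;
    double inter;
    while (true) {
      double sv = (double)v[k] * s;
      inter = ((fin[q] + sq * sq) - (fin[v[k]] + sv * sv)) / (2 * sq - 2 * sv);
      if (inter <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = inter;
    z[k + 1] = DT_BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (z[k + 1] < sq) ++k;
    double sv = (double)v[k] * s;
    fout[q] = (sq - sv) * (sq - sv) + fin[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every pixel to the nearest TRUE
// pixel; values >= DT_BIG signal an empty mask.
// [[Rcpp::export(name = ".edt2d_sq")]]
NumericMatrix edt2d_sq(LogicalMatrix mask, double sx, double sy) {
  const int nx = mask.nrow(), ny = mask.ncol();
  NumericMatrix d(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      d(i, j) = mask(i, j) ? 0.0 : DT_BIG;

  std::vector<double> fin, fout;
  // pass along rows (first index, spacing sx)
  fin.resize(nx); fout.resize(nx);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) fin[i] = d(i, j);
    dt1d(fin, fout, sx);
    for (int i = 0; i < nx; ++i) d(i, j) = fout[i];
  }
  // pass along columns (second index, spacing sy)
  fin.resize(ny); fout.resize(ny);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) fin[j] = d(i, j);
    dt1d(fin, fout, sy);
    for (int j = 0; j < ny; ++j) d(i, j) = fout[j];
  }
  return d;
}

// ---- distances ------------------------------------------------------------

// max over rows of A of min distance to rows of B (coordinates in mm)
// [[Rcpp::export(name = ".directed_hausdorff")]]
double directed_hausdorff(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  if (na == 0) return 0.0;
  if (nb == 0) return R_PosInf;
  double hmax = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (best <= hmax) break;  // cannot raise the running maximum
      }
    }
    if (best > hmax) hmax = best;
  }
  return std::sqrt(hmax);
}

// largest pairwise Euclidean distance between rows (mm)
// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericMatrix P) {
  const int n = P.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = P(i, 0) - P(j, 0);
      double dy = P(i, 1) - P(j, 1);
      double dz = P(i, 2) - P(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
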