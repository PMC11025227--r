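#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on a scalar field.
// Each grid cell is split into 6 tetrahedra around the main diagonal; every
// tetrahedron contributes 0, 1 or 2 triangles whose vertices sit on tet edges
// at the linear-interpolation crossing of the iso level. Vertices are merged
// by the (sorted) pair of grid-node indices of the edge they lie on, so the
// result is a closed, watertight surface for fields that are background at
// the boundary. Triangles are oriented with normals pointing away from the
// high-field (interior) side.

static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
static const int CUBE_OFF[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};

struct MeshAcc {
  std::unordered_map<uint64_t, int> edgeVert;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;

  int edgePoint(int64_t ia, int64_t ib, const double *px, const double *py,
                const double *pz, double va, double vb, double iso) {
    uint64_t a = (uint64_t)ia, b = (uint64_t)ib;
    if (a > b) { std::swap(a, b); std::swap(va, vb); std::swap(ia, ib); }
    uint64_t key = (a << 32) | b;
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    double t = (iso - va) / (vb - va);
    int id = (int)vx.size();
    vx.push_back(px[ia] + t * (px[ib] - px[ia]));
    vy.push_back(py[ia] + t * (py[ib] - py[ia]));
    vz.push_back(pz[ia] + t * (pz[ib] - pz[ia]));
    edgeVert[key] = id;
    return id;
  }

  void addTri(int a, int b, int c, double cx, double cy, double cz) {
    // orient so the normal points from the interior centroid (cx,cy,cz)
    // outward through the triangle
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
    double tx = (vx[a] + vx[b] + vx[c]) / 3.0 - cx;
    double ty = (vy[a] + vy[b] + vy[c]) / 3.0 - cy;
    double tz = (vz[a] + vz[b] + vz[c]) / 3.0 - cz;
    if (nx * tx + ny * ty + nz * tz < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  }
};

// [[Rcpp::export(name = ".cpp_marching_tets")]]
List cpp_marching_tets(NumericVector field, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = field.begin();
  // precomputed node coordinates are just the 0-based indices
  std::vector<double> px((size_t)nx * ny * nz), py(px.size()), pz(px.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t l = (size_t)i + nx * ((size_t)j + (size_t)ny * k);
        px[l] = i; py[l] = j; pz[l] = k;
      }
  MeshAcc acc;
  int64_t corn[8];
  double val[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool anyIn = false, anyOut = false;
        for (int c = 0; c < 8; ++c) {
          corn[c] = (int64_t)(i + CUBE_OFF[c][0]) +
                    (int64_t)nx * ((j + CUBE_OFF[c][1]) +
                    (int64_t)ny * (k + CUBE_OFF[c][2]));
          val[c] = f[corn[c]];
          (val[c] > iso ? anyIn : anyOut) = true;
        }
        if (!anyIn || !anyOut) continue;
        for (int t = 0; t < 6; ++t) {
          int64_t tc[4]; double tv[4]; int in[4], out[4]; int nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            tc[c] = corn[TETS[t][c]]; tv[c] = val[TETS[t][c]];
            if (tv[c] > iso) in[nin++] = c; else out[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          // centroid of interior corners, used for orientation
          double cx = 0, cy = 0, cz = 0;
          for (int c = 0; c < nin; ++c) {
            cx += px[tc[in[c]]]; cy += py[tc[in[c]]]; cz += pz[tc[in[c]]];
          }
          cx /= nin; cy /= nin; cz /= nin;
          if (nin == 1) {
            int a = in[0];
            int p0 = acc.edgePoint(tc[a], tc[out[0]], px.data(), py.data(), pz.data(), tv[a], tv[out[0]], iso);
            int p1 = acc.edgePoint(tc[a], tc[out[1]], px.data(), py.data(), pz.data(), tv[a], tv[out[1]], iso);
            int p2 = acc.edgePoint(tc[a], tc[out[2]], px.data(), py.data(), pz.data(), tv[a], tv[out[2]], iso);
            acc.addTri(p0, p1, p2, cx, cy, cz);
          } else if (nin == 3) {
            int a = out[0];
            int p0 = acc.edgePoint(tc[in[0]], tc[a], px.data(), py.data(), pz.data(), tv[in[0]], tv[a], iso);
            int p1 = acc.edgePoint(tc[in[1]], tc[a], px.data(), py.data(), pz.data(), tv[in[1]], tv[a], iso);
            int p2 = acc.edgePoint(tc[in[2]], tc[a], px.data(), py.data(), pz.data(), tv[in[2]], tv[a], iso);
            acc.addTri(p0, p1, p2, cx, cy, cz);
          } else { // 2 in, 2 out -> quad split into two triangles
            int a = in[0], b = in[1], c = out[0], d = out[1];
            int pac = acc.edgePoint(tc[a], tc[c], px.data(), py.data(), pz.data(), tv[a], tv[c], iso);
            int pad = acc.edgePoint(tc[a], tc[d], px.data(), py.data(), pz.data(), tv[a], tv[d], iso);
            int pbc = acc.edgePoint(tc[b], tc[c], px.data(), py.data(), pz.data(), tv[b], tv[c], iso);
            int pbd = acc.edgePoint(tc[b], tc[d], px.data(), py.data(), pz.data(), tv[b], tv[d], iso);
            acc.addTri(pac, pad, pbd, cx, cy, cz);
            acc.addTri(pac, pbd, pbc, cx, cy, cz);
          }
        }
      }
  int nv = (int)acc.vx.size(), nf = (int)acc.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = acc.vx[v]; V(v, 1) = acc.vy[v]; V(v, 2) = acc.vz[v]; }
  IntegerMatrix F(nf, 3);
  for (int t = 0; t < nf; ++t) {
    F(t, 0) = acc.tri[3 * t] + 1; F(t, 1) = acc.tri[3 * t + 1] + 1; F(t, 2) = acc.tri[3 * t + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Coverage rasterization: pixel (row iy, col ix) with centre
// (ix - 0.5, iy - 0.5) in pixel units is foreground iff it lies inside any
// projected triangle (inclusive edges).
// [[Rcpp::export(name = ".cpp_rasterize_triangles")]]
LogicalMatrix cpp_rasterize_triangles(NumericMatrix vxy, IntegerMatrix faces,
                                      int ny, int nx) {
  LogicalMatrix img(ny, nx);
  const double eps = 1e-12;
  for (int t = 0; t < faces.nrow(); ++t) {
    int a = faces(t, 0) - 1, b = faces(t, 1) - 1, c = faces(t, 2) - 1;
    double x0 = vxy(a, 0), y0 = vxy(a, 1);
    double x1 = vxy(b, 0), y1 = vxy(b, 1);
    double x2 = vxy(c, 0), y2 = vxy(c, 1);
    double det = (x1 - x0) * (y2 - y0) - (x2 - x0) * (y1 - y0);
    if (std::fabs(det) < eps) continue; // degenerate in projection
    double xmin = std::min(x0, std::min(x1, x2)), xmax = std::max(x0, std::max(x1, x2));
    double ymin = std::min(y0, std::min(y1, y2)), ymax = std::max(y0, std::max(y1, y2));
    int ix0 = std::max(0, (int)std::floor(xmin + 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil(xmax - 0.5));
    int iy0 = std::max(0, (int)std::floor(ymin + 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil(ymax - 0.5));
    for (int iy = iy0; iy <= iy1; ++iy) {
      double py = iy + 0.5;
      for (int ix = ix0; ix <= ix1; ++ix) {
        if (img(iy, ix)) continue;
        double px = ix + 0.5;
        double l0 = ((x1 - px) * (y2 - py) - (x2 - px) * (y1 - py)) / det;
        double l1 = ((x2 - px) * (y0 - py) - (x0 - px) * (y2 - py)) / det;
        double l2 = 1.0 - l0 - l1;
        if (l0 >= -1e-9 && l1 >= -1e-9 && l2 >= -1e-9) img(iy, ix) = true;
      }
    }
  }
  return img;
}

// Exact nearest neighbour from each query point to the reference cloud,
// accelerated by a uniform grid over the reference bounding box. Cells are
// visited in expanding rings; the search stops once the ring's lower-bound
// distance exceeds the best match, so the result equals brute force exactly.
// Returns 1-based indices and Euclidean distances.
// [[Rcpp::export(name = ".cpp_nearest_neighbour")]]
List cpp_nearest_neighbour(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  std::vector<double> rx(nr), ry(nr), rz(nr);
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
    lo[0] = std::min(lo[0], rx[j]); hi[0] = std::max(hi[0], rx[j]);
    lo[1] = std::min(lo[1], ry[j]); hi[1] = std::max(hi[1], ry[j]);
    lo[2] = std::min(lo[2], rz[j]); hi[2] = std::max(hi[2], rz[j]);
  }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  // target a few points per occupied cell
  double h = std::max(ext / 256.0, std::cbrt(ext * ext * ext / std::max(nr, 1)) * 0.5);
  int ncx = std::max(1, (int)std::floor((hi[0] - lo[0]) / h) + 1);
  int ncy = std::max(1, (int)std::floor((hi[1] - lo[1]) / h) + 1);
  int ncz = std::max(1, (int)std::floor((hi[2] - lo[2]) / h) + 1);
  size_t ncell = (size_t)ncx * ncy * ncz;
  std::vector<int> cellStart(ncell + 1, 0), cellOf(nr), order(nr);
  auto cellIdx = [&](double x, double y, double z) {
    int cx = std::min(ncx - 1, std::max(0, (int)((x - lo[0]) / h)));
    int cy = std::min(ncy - 1, std::max(0, (int)((y - lo[1]) / h)));
    int cz = std::min(ncz - 1, std::max(0, (int)((z - lo[2]) / h)));
    return (size_t)cx + (size_t)ncx * (cy + (size_t)ncy * cz);
  };
  for (int j = 0; j < nr; ++j) { cellOf[j] = (int)cellIdx(rx[j], ry[j], rz[j]); cellStart[cellOf[j] + 1]++; }
  for (size_t c = 0; c < ncell; ++c) cellStart[c + 1] += cellStart[c];
  { std::vector<int> fill(cellStart.begin(), cellStart.end() - 1);
    for (int j = 0; j < nr; ++j) order[fill[cellOf[j]]++] = j; }
  for (int i = 0; i < nq; ++i) {
    double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int cx = std::min(ncx - 1, std::max(0, (int)((qx - lo[0]) / h)));
    int cy = std::min(ncy - 1, std::max(0, (int)((qy - lo[1]) / h)));
    int cz = std::min(ncz - 1, std::max(0, (int)((qz - lo[2]) / h)));
    double best = R_PosInf; int bj = 0;
    int maxRing = std::max({ncx, ncy, ncz});
    for (int ring = 0; ring <= maxRing; ++ring) {
      if (best < R_PosInf) {
        double lb = (ring - 1) * h; // closest possible point in this ring
        if (lb > 0 && lb * lb > best) break;
      }
      int x0 = cx - ring, x1 = cx + ring;
      int y0 = cy - ring, y1 = cy + ring;
      int z0 = cz - ring, z1 = cz + ring;
      for (int zz = z0; zz <= z1; ++zz) {
        if (zz < 0 || zz >= ncz) continue;
        for (int yy = y0; yy <= y1; ++yy) {
          if (yy < 0 || yy >= ncy) continue;
          for (int xx = x0; xx <= x1; ++xx) {
            if (xx < 0 || xx >= ncx) continue;
            // only the shell of the ring
            if (ring > 0 && std::abs(xx - cx) != ring && std::abs(yy - cy) != ring &&
                std::abs(zz - cz) != ring) continue;
            size_t c = (size_t)xx + (size_t)ncx * (yy + (size_t)ncy * zz);
            for (int s = cellStart[c]; s < cellStart[c + 1]; ++s) {
              int j = order[s];
              double dx = rx[j] - qx, dy = ry[j] - qy, dz = rz[j] - qz;
              double d = dx * dx + dy * dy + dz * dz;
              if (d < best) { best = d; bj = j; }
            }
          }
        }
      }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
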