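#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 3D index helpers: volumes are passed as flat integer vectors in R's
// column-major layout with explicit dims (nx, ny, nz).
static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// [[Rcpp::export(name = ".cpp_binary_dilate")]]
IntegerVector cpp_binary_dilate(IntegerVector mask, IntegerVector dims,
                                bool full26) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (mask[i]) { out[i] = 1; continue; }
        int hit = 0;
        for (int dz = -1; dz <= 1 && !hit; ++dz)
          for (int dy = -1; dy <= 1 && !hit; ++dy)
            for (int dx = -1; dx <= 1 && !hit; ++dx) {
              int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
              if (ad == 0) continue;
              if (!full26 && ad != 1) continue;  // 6-connected cross
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              if (mask[idx3(xx, yy, zz, nx, ny)]) hit = 1;
            }
        out[i] = hit;
      }
  return out;
}

// [[Rcpp::export(name = ".cpp_binary_erode")]]
IntegerVector cpp_binary_erode(IntegerVector mask, IntegerVector dims,
                               bool full26) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = idx3(x, y, z, nx, ny);
        if (!mask[i]) { out[i] = 0; continue; }
        int keep = 1;
        for (int dz = -1; dz <= 1 && keep; ++dz)
          for (int dy = -1; dy <= 1 && keep; ++dy)
            for (int dx = -1; dx <= 1 && keep; ++dx) {
              int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
              if (ad == 0) continue;
              if (!full26 && ad != 1) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              // outside the grid counts as background: erosion removes
              // voxels touching the boundary, matching dilation's clamp
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) {
                keep = 0; continue;
              }
              if (!mask[idx3(xx, yy, zz, nx, ny)]) keep = 0;
            }
        out[i] = keep;
      }
  return out;
}

// Majority filter over the full 3x3x3 window; voxels outside the grid count
// as background, so the denominator is always 27.
// [[Rcpp::export(name = ".cpp_median3")]]
IntegerVector cpp_median3(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int s = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                continue;
              s += mask[idx3(xx, yy, zz, nx, ny)] ? 1 : 0;
            }
        out[idx3(x, y, z, nx, ny)] = (s >= 14) ? 1 : 0;
      }
  return out;
}

// 26-connected component labelling by flood fill; returns integer labels
// (0 = background), components numbered in scan order.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size());
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int x = c % nx, y = (c / nx) % ny, z = c / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            R_xlen_t j = idx3(xx, yy, zz, nx, ny);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  return lab;
}

// Iso-surface extraction at level 0.5 from a binary volume.
//
// The per-case triangulation is supplied from R (derived there at load time):
// for each of the 256 corner-sign cases, a set of closed polygonal loops whose
// vertices are cube-edge midpoints. Loops longer than three edges are fanned
// from their centroid. Edge-midpoint vertices are welded between neighbouring
// cells via an exact half-integer coordinate key, so a single-component mask
// yields a watertight mesh; centroid vertices are interior to one cell.
//
// Arguments:
//   mask, dims      binary volume (values sampled at voxel centres)
//   loop_edges      concatenated edge indices (0..11) of all loops, all cases
//   loop_start      0-based start of each loop within loop_edges
//   loop_case       case id (0..255) owning each loop
//   edge_mid        12 x 3 matrix of edge midpoint offsets in voxel units
// Returns list(vertices = N x 3 (voxel units, 0-based), faces = M x 3, 1-based).
// [[Rcpp::export(name = ".cpp_marching_cubes")]]
List cpp_marching_cubes(IntegerVector mask, IntegerVector dims,
                        IntegerVector loop_edges, IntegerVector loop_start,
                        IntegerVector loop_case, NumericMatrix edge_mid) {
  int nx = dims[0], ny = dims[1], nz = dims[2];

  // index loops by case
  std::vector<std::vector<int>> case_loops(256);
  for (int l = 0; l < loop_case.size(); ++l)
    case_loops[loop_case[l]].push_back(l);

  std::unordered_map<uint64_t, int> weld;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  std::vector<int> loop_vtx;  // scratch

  auto add_weld = [&](double px, double py, double pz) -> int {
    // all welded vertices have coordinates that are multiples of 0.5
    uint64_t kx = (uint64_t)llround(px * 2.0);
    uint64_t ky = (uint64_t)llround(py * 2.0);
    uint64_t kz = (uint64_t)llround(pz * 2.0);
    uint64_t key = (kx << 42) | (ky << 21) | kz;
    auto it = weld.find(key);
    if (it != weld.end()) return it->second;
    int id = (int)vx.size();
    vx.push_back(px); vy.push_back(py); vz.push_back(pz);
    weld[key] = id;
    return id;
  };

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        int cs = 0;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          if (mask[idx3(cx, cy, cz, nx, ny)]) cs |= (1 << c);
        }
        if (cs == 0 || cs == 255) continue;
        for (int l : case_loops[cs]) {
          int s = loop_start[l];
          int e = (l + 1 < loop_start.size()) ? loop_start[l + 1]
                                              : (int)loop_edges.size();
          int n = e - s;
          loop_vtx.clear();
          double cxm = 0, cym = 0, czm = 0;
          for (int t = 0; t < n; ++t) {
            int ed = loop_edges[s + t];
            double px = x + edge_mid(ed, 0);
            double py = y + edge_mid(ed, 1);
            double pz = z + edge_mid(ed, 2);
            loop_vtx.push_back(add_weld(px, py, pz));
            cxm += px; cym += py; czm += pz;
          }
          if (n == 3) {
            f0.push_back(loop_vtx[0]); f1.push_back(loop_vtx[1]);
            f2.push_back(loop_vtx[2]);
          } else {
            int cid = (int)vx.size();
            vx.push_back(cxm / n); vy.push_back(cym / n); vz.push_back(czm / n);
            for (int t = 0; t < n; ++t) {
              f0.push_back(cid);
              f1.push_back(loop_vtx[t]);
              f2.push_back(loop_vtx[(t + 1) % n]);
            }
          }
        }
      }

  int nv = (int)vx.size(), nf = (int)f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = vx[i]; V(i, 1) = vy[i]; V(i, 2) = vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i, 0) = f0[i] + 1; F(i, 1) = f1[i] + 1; F(i, 2) = f2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
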