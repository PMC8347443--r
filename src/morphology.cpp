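// 3-D binary morphology and connected-component labelling on voxel grids.
// Arrays use R's column-major layout with dim = (nz, ny, nx); the linear
// index of voxel (z, y, x) is z + nz*(y + ny*x).  Connectivity is 6
// (faces) or 26 (faces + edges + corners).

#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int64_t lin(int z, int y, int x, int nz, int ny) {
  return (int64_t)z + (int64_t)nz * ((int64_t)y + (int64_t)ny * x);
}

// Offsets for the requested connectivity as (dz, dy, dx) triples.
static std::vector<std::array<int, 3>> conn_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims,
                         int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int64_t n = (int64_t)nz * ny * nx;
  if ((int64_t)mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 26)
    stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> off = conn_offsets(connectivity);
  std::vector<int64_t> queue;
  queue.reserve(1024);
  int current = 0;

  for (int64_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || labels[seed] != 0) continue;
    ++current;
    labels[seed] = current;
    queue.clear();
    queue.push_back(seed);
    size_t head = 0;
    while (head < queue.size()) {
      int64_t idx = queue[head++];
      int z = (int)(idx % nz);
      int64_t rest = idx / nz;
      int y = (int)(rest % ny);
      int x = (int)(rest / ny);
      for (const auto &o : off) {
        int zz = z + o[0], yy = y + o[1], xx = x + o[2];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int64_t nb = lin(zz, yy, xx, nz, ny);
        if (mask[nb] && labels[nb] == 0) {
          labels[nb] = current;
          queue.push_back(nb);
        }
      }
    }
  }
  labels.attr("dim") = dims;
  labels.attr("n_components") = current;
  return labels;
}

// Dilation by an arbitrary structuring element given as an m x 3 matrix of
// (dz, dy, dx) offsets.  Only set voxels are visited, so cost scales with
// the foreground, not the grid.
// [[Rcpp::export(name = ".binary_dilate3d")]]
LogicalVector binary_dilate3d(LogicalVector mask, IntegerVector dims,
                              IntegerMatrix offsets) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int64_t n = (int64_t)nz * ny * nx;
  if ((int64_t)mask.size() != n) stop("mask length does not match dims");
  LogicalVector out(n, 0);
  const int *src = LOGICAL(mask);
  int *dst = LOGICAL(out);
  const int m = offsets.nrow();
  std::vector<int64_t> linoff(m);
  int rz = 0, ry = 0, rx = 0;
  for (int k = 0; k < m; ++k) {
    linoff[k] = lin(offsets(k, 0), offsets(k, 1), offsets(k, 2), nz, ny);
    rz = std::max(rz, std::abs(offsets(k, 0)));
    ry = std::max(ry, std::abs(offsets(k, 1)));
    rx = std::max(rx, std::abs(offsets(k, 2)));
  }
  for (int64_t idx = 0; idx < n; ++idx) {
    if (!src[idx]) continue;
    int z = (int)(idx % nz);
    int64_t rest = idx / nz;
    int y = (int)(rest % ny);
    int x = (int)(rest / ny);
    if (z >= rz && z < nz - rz && y >= ry && y < ny - ry && x >= rx &&
        x < nx - rx) {
      for (int k = 0; k < m; ++k) dst[idx + linoff[k]] = 1;
    } else {
      for (int k = 0; k < m; ++k) {
        int zz = z + offsets(k, 0), yy = y + offsets(k, 1),
            xx = x + offsets(k, 2);
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        dst[lin(zz, yy, xx, nz, ny)] = 1;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Erosion: a voxel survives iff every offset neighbour is set.  Voxels whose
// structuring element leaves the grid are eroded (outside counts as FALSE).
// [[Rcpp::export(name = ".binary_erode3d")]]
LogicalVector binary_erode3d(LogicalVector mask, IntegerVector dims,
                             IntegerMatrix offsets) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int64_t n = (int64_t)nz * ny * nx;
  if ((int64_t)mask.size() != n) stop("mask length does not match dims");
  LogicalVector out(n, 0);
  const int *src = LOGICAL(mask);
  int *dst = LOGICAL(out);
  const int m = offsets.nrow();
  std::vector<int64_t> linoff(m);
  int rz = 0, ry = 0, rx = 0;
  for (int k = 0; k < m; ++k) {
    linoff[k] = lin(offsets(k, 0), offsets(k, 1), offsets(k, 2), nz, ny);
    rz = std::max(rz, std::abs(offsets(k, 0)));
    ry = std::max(ry, std::abs(offsets(k, 1)));
    rx = std::max(rx, std::abs(offsets(k, 2)));
  }
  for (int64_t idx = 0; idx < n; ++idx) {
    if (!src[idx]) continue;
    int z = (int)(idx % nz);
    int64_t rest = idx / nz;
    int y = (int)(rest % ny);
    int x = (int)(rest / ny);
    bool keep = true;
    if (z >= rz && z < nz - rz && y >= ry && y < ny - ry && x >= rx &&
        x < nx - rx) {
      for (int k = 0; k < m; ++k) {
        if (!src[idx + linoff[k]]) { keep = false; break; }
      }
    } else {
      for (int k = 0; k < m && keep; ++k) {
        int zz = z + offsets(k, 0), yy = y + offsets(k, 1),
            xx = x + offsets(k, 2);
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
          keep = false;
        } else if (!src[lin(zz, yy, xx, nz, ny)]) {
          keep = false;
        }
      }
    }
    if (keep) dst[idx] = 1;
  }
  out.attr("dim") = dims;
  return out;
}

// Fill cavities: background (6-connected complement) reachable from the grid
// boundary stays background, every other complement voxel becomes foreground.
// [[Rcpp::export(name = ".fill_holes3d")]]
LogicalVector fill_holes3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int64_t n = (int64_t)nz * ny * nx;
  if ((int64_t)mask.size() != n) stop("mask length does not match dims");
  std::vector<uint8_t> outside(n, 0);
  std::vector<int64_t> queue;
  queue.reserve(4096);

  auto push_if_bg = [&](int z, int y, int x) {
    int64_t idx = lin(z, y, x, nz, ny);
    if (!mask[idx] && !outside[idx]) {
      outside[idx] = 1;
      queue.push_back(idx);
    }
  };
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      push_if_bg(0, y, x);
      push_if_bg(nz - 1, y, x);
    }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      push_if_bg(z, 0, x);
      push_if_bg(z, ny - 1, x);
    }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      push_if_bg(z, y, 0);
      push_if_bg(z, y, nx - 1);
    }

  static const int d6[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                               {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  size_t head = 0;
  while (head < queue.size()) {
    int64_t idx = queue[head++];
    int z = (int)(idx % nz);
    int64_t rest = idx / nz;
    int y = (int)(rest % ny);
    int x = (int)(rest / ny);
    for (auto &o : d6) {
      int zz = z + o[0], yy = y + o[1], xx = x + o[2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int64_t nb = lin(zz, yy, xx, nz, ny);
      if (!mask[nb] && !outside[nb]) {
        outside[nb] = 1;
        queue.push_back(nb);
      }
    }
  }

  LogicalVector out(n);
  for (int64_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dims;
  return out;
}

// Component sizes and centroids in one pass; rows follow label order 1..K.
// [[Rcpp::export(name = ".component_stats3d")]]
NumericMatrix component_stats3d(IntegerVector labels, IntegerVector dims,
                                int n_components) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int64_t n = (int64_t)nz * ny * nx;
  NumericMatrix out(n_components, 4);  // count, cz, cy, cx
  for (int64_t idx = 0; idx < n; ++idx) {
    int lab = labels[idx];
    if (lab <= 0) continue;
    int z = (int)(idx % nz);
    int64_t rest = idx / nz;
    int y = (int)(rest % ny);
    int x = (int)(rest / ny);
    out(lab - 1, 0) += 1;
    out(lab - 1, 1) += z;
    out(lab - 1, 2) += y;
    out(lab - 1, 3) += x;
  }
  for (int k = 0; k < n_components; ++k) {
    double c = out(k, 0);
    if (c > 0) {
      out(k, 1) /= c;
      out(k, 2) /= c;
      out(k, 3) /= c;
    }
  }
  return out;
}
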