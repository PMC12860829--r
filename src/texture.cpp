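// Gray-level texture matrix counting over a discretized ROI.
// `levels` is an integer grid in R array order (x fastest); 0 marks voxels
// outside the ROI, ROI voxels carry levels 1..ng. Directions follow the 13
// unique 3D offsets (distance 1, 26-connectivity halved by symmetry).

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static const int DIR13[13][3] = {
    {1, 0, 0},  {0, 1, 0},  {0, 0, 1},  {1, 1, 0},  {1, -1, 0},
    {1, 0, 1},  {1, 0, -1}, {0, 1, 1},  {0, 1, -1}, {1, 1, 1},
    {1, 1, -1}, {1, -1, 1}, {1, -1, -1}};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Symmetric GLCM counts summed over the 13 directions (each pair counted in
// both orders), ng x ng.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix P(ng, ng);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int l1 = levels[idx3(x, y, z, nx, ny)];
        if (l1 == 0) continue;
        for (int d = 0; d < 13; ++d) {
          const int xs = x + DIR13[d][0], ys = y + DIR13[d][1],
                    zs = z + DIR13[d][2];
          if (xs < 0 || xs >= nx || ys < 0 || ys >= ny || zs < 0 || zs >= nz)
            continue;
          const int l2 = levels[idx3(xs, ys, zs, nx, ny)];
          if (l2 == 0) continue;
          P(l1 - 1, l2 - 1) += 1.0;
          P(l2 - 1, l1 - 1) += 1.0;
        }
      }
  return P;
}

// Run counts summed over the 13 directions: ng x max run length.
// A run is a maximal collinear segment of equal-level ROI voxels.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector levels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int maxd = std::max(nx, std::max(ny, nz));
  NumericMatrix R(ng, maxd);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int l = levels[idx3(x, y, z, nx, ny)];
          if (l == 0) continue;
          // run starts here iff predecessor is out of bounds / other level
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[idx3(xp, yp, zp, nx, ny)] == l)
            continue;
          int len = 1, xs = x + dx, ys = y + dy, zs = z + dz;
          while (xs >= 0 && xs < nx && ys >= 0 && ys < ny && zs >= 0 &&
                 zs < nz && levels[idx3(xs, ys, zs, nx, ny)] == l) {
            ++len;
            xs += dx; ys += dy; zs += dz;
          }
          R(l - 1, len - 1) += 1.0;
        }
  }
  return R;
}

// 26-connected equal-level zones; returns a 2-column matrix (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> seen(levels.size(), 0);
  std::vector<int> zl, zs;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int i0 = idx3(x, y, z, nx, ny);
        const int l = levels[i0];
        if (l == 0 || seen[i0]) continue;
        int size = 0;
        std::queue<std::array<int, 3>> q;
        q.push({x, y, z});
        seen[i0] = 1;
        while (!q.empty()) {
          auto v = q.front();
          q.pop();
          ++size;
          for (int dz2 = -1; dz2 <= 1; ++dz2)
            for (int dy2 = -1; dy2 <= 1; ++dy2)
              for (int dx2 = -1; dx2 <= 1; ++dx2) {
                if (!dx2 && !dy2 && !dz2) continue;
                const int xs = v[0] + dx2, ys = v[1] + dy2, zs2 = v[2] + dz2;
                if (xs < 0 || xs >= nx || ys < 0 || ys >= ny || zs2 < 0 ||
                    zs2 >= nz)
                  continue;
                const int j = idx3(xs, ys, zs2, nx, ny);
                if (!seen[j] && levels[j] == l) {
                  seen[j] = 1;
                  q.push({xs, ys, zs2});
                }
              }
        }
        zl.push_back(l);
        zs.push_back(size);
      }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) {
    out(k, 0) = zl[k];
    out(k, 1) = zs[k];
  }
  return out;
}

// Neighbourhood gray-tone difference accumulators: per level, the count of
// contributing voxels n_i and the summed |level - neighbourhood mean| s_i.
// Only ROI voxels with at least one in-ROI 26-neighbour contribute.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int l = levels[idx3(x, y, z, nx, ny)];
        if (l == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz2 = -1; dz2 <= 1; ++dz2)
          for (int dy2 = -1; dy2 <= 1; ++dy2)
            for (int dx2 = -1; dx2 <= 1; ++dx2) {
              if (!dx2 && !dy2 && !dz2) continue;
              const int xs = x + dx2, ys = y + dy2, zs = z + dz2;
              if (xs < 0 || xs >= nx || ys < 0 || ys >= ny || zs < 0 ||
                  zs >= nz)
                continue;
              const int ln = levels[idx3(xs, ys, zs, nx, ny)];
              if (ln > 0) {
                sum += ln;
                ++cnt;
              }
            }
        if (cnt > 0) {
          out(l - 1, 0) += 1.0;
          out(l - 1, 1) += std::fabs((double)l - sum / cnt);
        }
      }
  return out;
}

// Gray-level dependence counts: dependence of a voxel is 1 + the number of
// in-ROI 26-neighbours whose level differs by at most alpha (the centre
// itself guarantees dependence >= 1). Returns ng x 27.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector levels, IntegerVector dims, int ng,
                       double alpha) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix D(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int l = levels[idx3(x, y, z, nx, ny)];
        if (l == 0) continue;
        int dep = 1;
        for (int dz2 = -1; dz2 <= 1; ++dz2)
          for (int dy2 = -1; dy2 <= 1; ++dy2)
            for (int dx2 = -1; dx2 <= 1; ++dx2) {
              if (!dx2 && !dy2 && !dz2) continue;
              const int xs = x + dx2, ys = y + dy2, zs = z + dz2;
              if (xs < 0 || xs >= nx || ys < 0 || ys >= ny || zs < 0 ||
                  zs >= nz)
                continue;
              const int ln = levels[idx3(xs, ys, zs, nx, ny)];
              if (ln > 0 && std::fabs((double)(ln - l)) <= alpha) ++dep;
            }
        D(l - 1, dep - 1) += 1.0;
      }
  return D;
}
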