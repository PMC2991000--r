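#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Marching tetrahedra over the Kuhn (6-simplex) decomposition of each grid
// cell, extracting the `iso` level set of a scalar field sampled at voxel
// centers. The Kuhn decomposition is translation-invariant, so shared cell
// faces are split identically in neighbouring cells and the extracted surface
// is watertight by construction. Level-set vertices lie on segments between
// grid points and are deduplicated by their (grid point, grid point) key, so
// every edge of the triangulation is shared exactly between adjacent faces.
//
// Triangles are oriented so their normals point away from the >= iso side.
// Vertex coordinates are 0-based voxel-index coordinates.

namespace {

// Kuhn tetrahedra as corner indices (x+2y+4z)
static const int TET[6][4] = {
  {0, 1, 3, 7},  // x >= y >= z
  {0, 2, 3, 7},  // y >= x >= z
  {0, 2, 6, 7},  // y >= z >= x
  {0, 4, 6, 7},  // z >= y >= x
  {0, 4, 5, 7},  // z >= x >= y
  {0, 1, 5, 7}   // x >= z >= y
};

struct MeshAccum {
  std::unordered_map<uint64_t, int> vid;   // edge key -> vertex id (0-based)
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;             // 0-based vertex ids
};

inline void cornerXYZ(int c, int &x, int &y, int &z) {
  x = c & 1; y = (c >> 1) & 1; z = (c >> 2) & 1;
}

inline int edgeVertex(MeshAccum &M, double iso,
                      R_xlen_t ga, R_xlen_t gb, double va, double vb,
                      double ax, double ay, double az,
                      double bx, double by, double bz) {
  uint64_t lo = (uint64_t)std::min(ga, gb), hi = (uint64_t)std::max(ga, gb);
  uint64_t key = (lo << 32) | hi;
  auto it = M.vid.find(key);
  if (it != M.vid.end()) return it->second;
  // interpolate consistently in the (lo, hi) direction so shared edges agree
  double vlo = (ga <= gb) ? va : vb, vhi = (ga <= gb) ? vb : va;
  double lx = (ga <= gb) ? ax : bx, ly = (ga <= gb) ? ay : by, lz = (ga <= gb) ? az : bz;
  double hx = (ga <= gb) ? bx : ax, hy = (ga <= gb) ? by : ay, hz = (ga <= gb) ? bz : az;
  double t = (iso - vlo) / (vhi - vlo);
  int id = (int)M.vx.size();
  M.vid.emplace(key, id);
  M.vx.push_back(lx + t * (hx - lx));
  M.vy.push_back(ly + t * (hy - ly));
  M.vz.push_back(lz + t * (hz - lz));
  return id;
}

inline void addTri(MeshAccum &M, int a, int b, int c,
                   double icx, double icy, double icz) {
  // orient: normal away from the inside (>= iso) centroid (icx, icy, icz)
  double ax = M.vx[a], ay = M.vy[a], az = M.vz[a];
  double ux = M.vx[b] - ax, uy = M.vy[b] - ay, uz = M.vz[b] - az;
  double wx = M.vx[c] - ax, wy = M.vy[c] - ay, wz = M.vz[c] - az;
  double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz, nz = ux * wy - uy * wx;
  double gx = (ax + M.vx[b] + M.vx[c]) / 3.0;
  double gy = (ay + M.vy[b] + M.vy[c]) / 3.0;
  double gz = (az + M.vz[b] + M.vz[c]) / 3.0;
  double d = nx * (icx - gx) + ny * (icy - gy) + nz * (icz - gz);
  if (d > 0) { int t = b; b = c; c = t; }
  M.f0.push_back(a); M.f1.push_back(b); M.f2.push_back(c);
}

} // namespace

// [[Rcpp::export(name = ".marchingTets")]]
List marching_tets(NumericVector field, IntegerVector dim, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  if (field.size() != nxy * nz) stop("field length does not match dim");
  MeshAccum M;
  double cv[8];        // corner values
  R_xlen_t gidx[8];    // corner global linear indices
  double cx[8], cy[8], cz[8];
  for (int z = 0; z < nz - 1; ++z) {
    for (int y = 0; y < ny - 1; ++y) {
      for (int x = 0; x < nx - 1; ++x) {
        int nin = 0;
        for (int c = 0; c < 8; ++c) {
          int ox, oy, oz; cornerXYZ(c, ox, oy, oz);
          int xx = x + ox, yy = y + oy, zz = z + oz;
          R_xlen_t g = (R_xlen_t)zz * nxy + (R_xlen_t)yy * nx + xx;
          gidx[c] = g;
          cv[c] = field[g];
          cx[c] = xx; cy[c] = yy; cz[c] = zz;
          if (cv[c] >= iso) ++nin;
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TET[t];
          int in[4], ni = 0, no = 0, out[4];
          for (int k = 0; k < 4; ++k) {
            if (cv[T[k]] >= iso) in[ni++] = T[k]; else out[no++] = T[k];
          }
          if (ni == 0 || ni == 4) continue;
          // centroid of inside corners (for orientation)
          double icx = 0, icy = 0, icz = 0;
          for (int k = 0; k < ni; ++k) { icx += cx[in[k]]; icy += cy[in[k]]; icz += cz[in[k]]; }
          icx /= ni; icy /= ni; icz /= ni;
          if (ni == 1) {
            int a = in[0];
            int p0 = edgeVertex(M, iso, gidx[a], gidx[out[0]], cv[a], cv[out[0]],
                                cx[a], cy[a], cz[a], cx[out[0]], cy[out[0]], cz[out[0]]);
            int p1 = edgeVertex(M, iso, gidx[a], gidx[out[1]], cv[a], cv[out[1]],
                                cx[a], cy[a], cz[a], cx[out[1]], cy[out[1]], cz[out[1]]);
            int p2 = edgeVertex(M, iso, gidx[a], gidx[out[2]], cv[a], cv[out[2]],
                                cx[a], cy[a], cz[a], cx[out[2]], cy[out[2]], cz[out[2]]);
            addTri(M, p0, p1, p2, icx, icy, icz);
          } else if (ni == 3) {
            int d = out[0];
            int p0 = edgeVertex(M, iso, gidx[in[0]], gidx[d], cv[in[0]], cv[d],
                                cx[in[0]], cy[in[0]], cz[in[0]], cx[d], cy[d], cz[d]);
            int p1 = edgeVertex(M, iso, gidx[in[1]], gidx[d], cv[in[1]], cv[d],
                                cx[in[1]], cy[in[1]], cz[in[1]], cx[d], cy[d], cz[d]);
            int p2 = edgeVertex(M, iso, gidx[in[2]], gidx[d], cv[in[2]], cv[d],
                                cx[in[2]], cy[in[2]], cz[in[2]], cx[d], cy[d], cz[d]);
            addTri(M, p0, p1, p2, icx, icy, icz);
          } else { // ni == 2: quad split into two triangles
            int a = in[0], b = in[1], c = out[0], d = out[1];
            int pac = edgeVertex(M, iso, gidx[a], gidx[c], cv[a], cv[c],
                                 cx[a], cy[a], cz[a], cx[c], cy[c], cz[c]);
            int pad = edgeVertex(M, iso, gidx[a], gidx[d], cv[a], cv[d],
                                 cx[a], cy[a], cz[a], cx[d], cy[d], cz[d]);
            int pbd = edgeVertex(M, iso, gidx[b], gidx[d], cv[b], cv[d],
                                 cx[b], cy[b], cz[b], cx[d], cy[d], cz[d]);
            int pbc = edgeVertex(M, iso, gidx[b], gidx[c], cv[b], cv[c],
                                 cx[b], cy[b], cz[b], cx[c], cy[c], cz[c]);
            addTri(M, pac, pad, pbd, icx, icy, icz);
            addTri(M, pac, pbd, pbc, icx, icy, icz);
          }
        }
      }
    }
  }
  int nv = (int)M.vx.size(), nf = (int)M.f0.size();
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) { V(i, 0) = M.vx[i]; V(i, 1) = M.vy[i]; V(i, 2) = M.vz[i]; }
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nf; ++i) { F(i, 0) = M.f0[i] + 1; F(i, 1) = M.f1[i] + 1; F(i, 2) = M.f2[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Fraction of each listed voxel lying on the >= iso side of the *same*
// piecewise-linear (per Kuhn tetrahedron) field whose level set the mesher
// extracts, estimated on a fixed nsub^3 sub-voxel lattice. Using the identical
// interpolant makes the sampled region exactly the mesh interior.
// vox: N x 3 matrix of 0-based voxel indices.
// [[Rcpp::export(name = ".insideFractions")]]
NumericVector inside_fractions(NumericVector field, IntegerVector dim, double iso,
                               IntegerMatrix vox, int nsub) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  if (field.size() != nxy * nz) stop("field length does not match dim");
  const int N = vox.nrow();
  NumericVector out(N);
  const int ns3 = nsub * nsub * nsub;
  std::vector<double> off(nsub);
  for (int s = 0; s < nsub; ++s) off[s] = (s + 0.5) / nsub - 0.5;
  for (int i = 0; i < N; ++i) {
    int cnt = 0;
    for (int sz = 0; sz < nsub; ++sz)
      for (int sy = 0; sy < nsub; ++sy)
        for (int sx = 0; sx < nsub; ++sx) {
          double px = vox(i, 0) + off[sx];
          double py = vox(i, 1) + off[sy];
          double pz = vox(i, 2) + off[sz];
          int cxi = (int)std::floor(px), cyi = (int)std::floor(py), czi = (int)std::floor(pz);
          if (cxi < 0) cxi = 0; if (cxi > nx - 2) cxi = nx - 2;
          if (cyi < 0) cyi = 0; if (cyi > ny - 2) cyi = ny - 2;
          if (czi < 0) czi = 0; if (czi > nz - 2) czi = nz - 2;
          double fx = px - cxi, fy = py - cyi, fz = pz - czi;
          if (fx < 0) fx = 0; if (fx > 1) fx = 1;
          if (fy < 0) fy = 0; if (fy > 1) fy = 1;
          if (fz < 0) fz = 0; if (fz > 1) fz = 1;
          // sort (fx, fy, fz) descending to find the Kuhn simplex; walk the
          // corner path c0 -> +e_a1 -> +e_a2 -> +e_a3
          double u[3] = {fx, fy, fz};
          int ax[3] = {0, 1, 2};
          for (int a = 0; a < 2; ++a)
            for (int b = a + 1; b < 3; ++b)
              if (u[b] > u[a] || (u[b] == u[a] && ax[b] < ax[a])) {
                double tu = u[a]; u[a] = u[b]; u[b] = tu;
                int ta = ax[a]; ax[a] = ax[b]; ax[b] = ta;
              }
          int gx = cxi, gy = cyi, gz = czi;
          R_xlen_t g0 = (R_xlen_t)gz * nxy + (R_xlen_t)gy * nx + gx;
          double val = field[g0] * (1.0 - u[0]);
          double w[3] = {u[0] - u[1], u[1] - u[2], u[2]};
          for (int k = 0; k < 3; ++k) {
            if (ax[k] == 0) ++gx; else if (ax[k] == 1) ++gy; else ++gz;
            R_xlen_t g = (R_xlen_t)gz * nxy + (R_xlen_t)gy * nx + gx;
            val += field[g] * w[k];
          }
          if (val >= iso) ++cnt;
        }
    out[i] = (double)cnt / ns3;
  }
  return out;
}
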