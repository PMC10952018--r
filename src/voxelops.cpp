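#include <Rcpp.h>
#include <array>
#include <queue>
#include <vector>
#include <map>
#include <unordered_map>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Neighbourhood offsets for 6/18/26-connectivity (city-block distance 1/2/3).
static void build_offsets(int connectivity, std::vector<std::array<int, 3>> &offs) {
  offs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Flood-fill connected-component labelling of a binary mask.
// Labels are assigned in ascending order of the first-encountered voxel in
// array (column-major) scan order, so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> offs;
  build_offsets(connectivity, offs);

  int next = 0;
  std::queue<int> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    q.push((int)i);
    while (!q.empty()) {
      int cur = q.front();
      q.pop();
      int x = cur % nx, rest = cur / nx;
      int y = rest % ny, z = rest / ny;
      for (const auto &o : offs) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int j = lin(xx, yy, zz, nx, ny);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          q.push(j);
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Fill enclosed background cavities in a labelled mask.
// Background voxels unreachable from the grid boundary through background
// (6-connectivity) are assigned the label owning the majority of the
// cavity-adjacent labelled voxels (ties -> lower label).
// Returns the filled labels plus a per-cavity report.
// [[Rcpp::export]]
List fill_holes_cpp(IntegerVector labels, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out = clone(labels);

  // background components, 6-connectivity
  std::vector<int> bgcomp(n, 0);
  std::vector<std::array<int, 3>> offs6;
  build_offsets(6, offs6);

  int ncomp = 0;
  std::vector<char> touches;
  std::queue<int> q;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (labels[i] != 0 || bgcomp[i] != 0) continue;
    ++ncomp;
    touches.push_back(0);
    bgcomp[i] = ncomp;
    q.push((int)i);
    while (!q.empty()) {
      int cur = q.front();
      q.pop();
      int x = cur % nx, rest = cur / nx;
      int y = rest % ny, z = rest / ny;
      if (x == 0 || y == 0 || z == 0 || x == nx - 1 || y == ny - 1 || z == nz - 1)
        touches[ncomp - 1] = 1;
      for (const auto &o : offs6) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int j = lin(xx, yy, zz, nx, ny);
        if (labels[j] == 0 && bgcomp[j] == 0) {
          bgcomp[j] = ncomp;
          q.push(j);
        }
      }
    }
  }

  // vote on the enclosing label per cavity
  std::vector<std::map<int, int>> votes(ncomp);
  std::vector<int> csize(ncomp, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = bgcomp[i];
    if (c == 0 || touches[c - 1]) continue;
    csize[c - 1]++;
    int x = (int)(i % nx), rest = (int)(i / nx);
    int y = rest % ny, z = rest / ny;
    for (const auto &o : offs6) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
      int l = labels[lin(xx, yy, zz, nx, ny)];
      if (l > 0) votes[c - 1][l]++;
    }
  }

  std::vector<int> cav_id, cav_size, cav_label, cav_nlabels;
  std::vector<int> assigned(ncomp, 0);
  for (int c = 0; c < ncomp; ++c) {
    if (touches[c] || csize[c] == 0) continue;
    int best = 0, bestv = -1;
    for (const auto &kv : votes[c]) {
      if (kv.second > bestv || (kv.second == bestv && kv.first < best)) {
        best = kv.first;
        bestv = kv.second;
      }
    }
    assigned[c] = best;
    cav_id.push_back(c + 1);
    cav_size.push_back(csize[c]);
    cav_label.push_back(best);
    cav_nlabels.push_back((int)votes[c].size());
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    int c = bgcomp[i];
    if (c != 0 && !touches[c - 1] && assigned[c - 1] > 0) out[i] = assigned[c - 1];
  }

  return List::create(
      _["labels"] = out,
      _["cavities"] = DataFrame::create(
          _["cavity"] = cav_id, _["n_voxels"] = cav_size,
          _["assigned_label"] = cav_label, _["n_adjacent_labels"] = cav_nlabels));
}

// ---------------------------------------------------------------------------
// Marching tetrahedra over the 0/1 indicator field at iso-level 0.5.
// Each cube is split into 6 tetrahedra sharing the main diagonal c0-c6; the
// decomposition is translation-consistent across neighbouring cubes, so the
// extracted surface is watertight by construction. Surface vertices are edge
// midpoints of the binary field. Coordinates are voxel indices (0-based);
// scaling to world mm is done in R.
// ---------------------------------------------------------------------------

static const int corner_off[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                                     {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
static const int tets6[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};

struct MeshAcc {
  // key: doubled integer coordinates of a midpoint, packed into 64 bits
  std::unordered_map<uint64_t, int> vid;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  int64_t K;

  int vertex(const int a[3], const int b[3]) {
    int gx = a[0] + b[0], gy = a[1] + b[1], gz = a[2] + b[2];  // 2 * midpoint
    uint64_t key = ((uint64_t)(gx + 4) * (uint64_t)K + (uint64_t)(gy + 4)) * (uint64_t)K +
                   (uint64_t)(gz + 4);
    auto it = vid.find(key);
    if (it != vid.end()) return it->second;
    int id = (int)vx.size();
    vid.emplace(key, id);
    vx.push_back(gx / 2.0);
    vy.push_back(gy / 2.0);
    vz.push_back(gz / 2.0);
    return id;
  }

  // append triangle, flipping so the normal has positive dot with ref
  void tri(int i0, int i1, int i2, const double ref[3]) {
    double ax = vx[i1] - vx[i0], ay = vy[i1] - vy[i0], az = vz[i1] - vz[i0];
    double bx = vx[i2] - vx[i0], by = vy[i2] - vy[i0], bz = vz[i2] - vz[i0];
    double nx = ay * bz - az * by, ny = az * bx - ax * bz, nz = ax * by - ay * bx;
    double d = nx * ref[0] + ny * ref[1] + nz * ref[2];
    if (d >= 0) {
      f0.push_back(i0); f1.push_back(i1); f2.push_back(i2);
    } else {
      f0.push_back(i0); f1.push_back(i2); f2.push_back(i1);
    }
  }
};

// [[Rcpp::export]]
List march_tets_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  MeshAcc acc;
  acc.K = 2 * (int64_t)std::max(nx, std::max(ny, nz)) + 16;

  auto inside = [&](int x, int y, int z) -> bool {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return mask[lin(x, y, z, nx, ny)];
  };

  int c[8][3];
  bool b[8];
  for (int z = -1; z < nz; ++z)
    for (int y = -1; y < ny; ++y)
      for (int x = -1; x < nx; ++x) {
        int nin = 0;
        for (int k = 0; k < 8; ++k) {
          c[k][0] = x + corner_off[k][0];
          c[k][1] = y + corner_off[k][1];
          c[k][2] = z + corner_off[k][2];
          b[k] = inside(c[k][0], c[k][1], c[k][2]);
          nin += b[k];
        }
        if (nin == 0 || nin == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets6[t][0], tets6[t][1], tets6[t][2], tets6[t][3]};
          int tin = b[id[0]] + b[id[1]] + b[id[2]] + b[id[3]];
          if (tin == 0 || tin == 4) continue;
          if (tin == 1 || tin == 3) {
            bool want = (tin == 1);  // the lone corner
            int lone = -1, oth[3], no = 0;
            for (int k = 0; k < 4; ++k) {
              if (b[id[k]] == want) lone = id[k]; else oth[no++] = id[k];
            }
            int m0 = acc.vertex(c[lone], c[oth[0]]);
            int m1 = acc.vertex(c[lone], c[oth[1]]);
            int m2 = acc.vertex(c[lone], c[oth[2]]);
            double cx = (acc.vx[m0] + acc.vx[m1] + acc.vx[m2]) / 3.0;
            double cy = (acc.vy[m0] + acc.vy[m1] + acc.vy[m2]) / 3.0;
            double cz = (acc.vz[m0] + acc.vz[m1] + acc.vz[m2]) / 3.0;
            double ref[3];
            if (tin == 1) {  // outward = away from the inside corner
              ref[0] = cx - c[lone][0]; ref[1] = cy - c[lone][1]; ref[2] = cz - c[lone][2];
            } else {         // outward = towards the outside corner
              ref[0] = c[lone][0] - cx; ref[1] = c[lone][1] - cy; ref[2] = c[lone][2] - cz;
            }
            acc.tri(m0, m1, m2, ref);
          } else {  // 2 in / 2 out -> planar quad of midpoints
            int in[2], outv[2], ni = 0, nu = 0;
            for (int k = 0; k < 4; ++k) {
              if (b[id[k]]) in[ni++] = id[k]; else outv[nu++] = id[k];
            }
            int mac = acc.vertex(c[in[0]], c[outv[0]]);
            int mad = acc.vertex(c[in[0]], c[outv[1]]);
            int mbd = acc.vertex(c[in[1]], c[outv[1]]);
            int mbc = acc.vertex(c[in[1]], c[outv[0]]);
            double ref[3] = {
                (c[outv[0]][0] + c[outv[1]][0] - c[in[0]][0] - c[in[1]][0]) / 2.0,
                (c[outv[0]][1] + c[outv[1]][1] - c[in[0]][1] - c[in[1]][1]) / 2.0,
                (c[outv[0]][2] + c[outv[1]][2] - c[in[0]][2] - c[in[1]][2]) / 2.0};
            acc.tri(mac, mad, mbd, ref);
            acc.tri(mac, mbd, mbc, ref);
          }
        }
      }

  int nv = (int)acc.vx.size(), nf = (int)acc.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = acc.vx[i]; V(i, 1) = acc.vy[i]; V(i, 2) = acc.vz[i];
  }
  for (int i = 0; i < nf; ++i) {
    F(i, 0) = acc.f0[i] + 1; F(i, 1) = acc.f1[i] + 1; F(i, 2) = acc.f2[i] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Edge incidence audit for watertightness: every undirected edge must belong
// to exactly two faces, and with consistent orientation each directed edge
// must appear exactly once. faces are 1-based.
// [[Rcpp::export]]
List edge_incidence_cpp(IntegerMatrix faces, int n_vertices) {
  std::unordered_map<uint64_t, int> undirected;
  std::unordered_map<uint64_t, int> directed;
  const uint64_t K = (uint64_t)n_vertices + 2;
  int nf = faces.nrow();
  for (int i = 0; i < nf; ++i) {
    int v[3] = {faces(i, 0), faces(i, 1), faces(i, 2)};
    for (int e = 0; e < 3; ++e) {
      int a = v[e], bb = v[(e + 1) % 3];
      uint64_t dkey = (uint64_t)a * K + (uint64_t)bb;
      uint64_t ukey = a < bb ? (uint64_t)a * K + bb : (uint64_t)bb * K + a;
      undirected[ukey]++;
      directed[dkey]++;
    }
  }
  int bad_undirected = 0, bad_directed = 0;
  for (const auto &kv : undirected)
    if (kv.second != 2) ++bad_undirected;
  for (const auto &kv : directed)
    if (kv.second != 1) ++bad_directed;
  return List::create(_["n_edges"] = (int)undirected.size(),
                      _["n_edges_not_two_faces"] = bad_undirected,
                      _["n_directed_edges_repeated"] = bad_directed);
}

// Exact maximum pairwise Euclidean distance (3D caliper / Feret diameter).
// [[Rcpp::export]]
double max_pair_dist_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  }
  return std::sqrt(best);
}
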