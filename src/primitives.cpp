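// Low-level n-D image kernels shared across the pipeline.
// Volumes are passed as numeric vectors with dims (nz, ny, nx), first index
// fastest (R array layout); linear index = z + nz*(y + ny*x).
// 2D images are handled by passing nz = 1.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int lin(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + (long)ny * x);
}

// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector vol, IntegerVector dims, int axis,
                            NumericVector kernel) {
  // 1-D convolution along `axis` (0=z,1=y,2=x) with reflected boundary.
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int n = nz * ny * nx;
  int klen = kernel.size(), kh = klen / 2;
  int alen = (axis == 0) ? nz : (axis == 1) ? ny : nx;
  int stride = (axis == 0) ? 1 : (axis == 1) ? nz : nz * ny;
  NumericVector out(n);
  // iterate over all lines along `axis`
  int nlines = n / alen;
  std::vector<double> line(alen);
  for (int l = 0; l < nlines; ++l) {
    // base index of this line
    int base;
    if (axis == 0) {
      base = l * nz;                      // l enumerates (y,x)
    } else if (axis == 1) {
      int z = l % nz, x = l / nz;
      base = lin(z, 0, x, nz, ny);
    } else {
      base = l;                           // l enumerates (z,y)
    }
    for (int i = 0; i < alen; ++i) line[i] = vol[base + i * stride];
    for (int i = 0; i < alen; ++i) {
      double acc = 0.0;
      for (int k = 0; k < klen; ++k) {
        int j = i + k - kh;
        if (j < 0) j = -j - 1;            // reflect
        if (j >= alen) j = 2 * alen - j - 1;
        if (j < 0) j = 0;                 // degenerate short axes
        if (j >= alen) j = alen - 1;
        acc += line[j] * kernel[k];
      }
      out[base + i * stride] = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix local_maxima3d_cpp(NumericVector vol, IntegerVector dims,
                                 double min_value) {
  // Strict local maxima in the 3x3x3 neighborhood; plateau ties keep only the
  // lexicographically smallest (z,y,x). Border voxels excluded. Returns
  // 0-based (z,y,x) rows.
  int nz = dims[0], ny = dims[1], nx = dims[2];
  std::vector<int> zz, yy, xx;
  int z0 = (nz > 1) ? 1 : 0, z1 = (nz > 1) ? nz - 1 : 1;
  for (int x = 1; x + 1 < nx; ++x)
    for (int y = 1; y + 1 < ny; ++y)
      for (int z = z0; z < z1; ++z) {
        double v = vol[lin(z, y, x, nz, ny)];
        if (v < min_value) continue;
        bool keep = true;
        for (int dx = -1; dx <= 1 && keep; ++dx)
          for (int dy = -1; dy <= 1 && keep; ++dy)
            for (int dz = -1; dz <= 1 && keep; ++dz) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int zq = z + dz, yq = y + dy, xq = x + dx;
              if (zq < 0 || zq >= nz) continue;
              double q = vol[lin(zq, yq, xq, nz, ny)];
              if (q > v) keep = false;
              else if (q == v) {
                // lexicographic (z,y,x): neighbor smaller => drop this voxel
                if (zq < z || (zq == z && (yq < y || (yq == y && xq < x))))
                  keep = false;
              }
            }
        if (keep) { zz.push_back(z); yy.push_back(y); xx.push_back(x); }
      }
  IntegerMatrix out(zz.size(), 3);
  for (size_t i = 0; i < zz.size(); ++i) {
    out(i, 0) = zz[i]; out(i, 1) = yy[i]; out(i, 2) = xx[i];
  }
  return out;
}

struct QItem {
  double prio; long order; int idx;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // min-heap on priority
    return a.order > b.order;                       // FIFO tie-break
  }
};

// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector priority, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dims,
                            bool lines) {
  // Meyer's marker-seeded flooding on `priority` (low floods first),
  // restricted to `mask`. Face connectivity. If `lines`, voxels claimed by
  // two or more basins become watershed lines (label 0) and do not
  // propagate.
  int nz = dims[0], ny = dims[1], nx = dims[2];
  int n = nz * ny * nx;
  const int WSLINE = -1;
  IntegerVector lab(n);
  for (int i = 0; i < n; ++i) lab[i] = (mask[i] ? seeds[i] : 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long counter = 0;
  int noff = (nz > 1) ? 6 : 4;
  int offs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  int start = (nz > 1) ? 0 : 2;  // skip z offsets for single-plane images
  // push unlabeled mask neighbors of seeds
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = lin(z, y, x, nz, ny);
        if (lab[i] <= 0) continue;
        for (int o = start; o < start + noff && o < 6; ++o) {
          int zq = z + offs[o][0], yq = y + offs[o][1], xq = x + offs[o][2];
          if (zq < 0 || zq >= nz || yq < 0 || yq >= ny || xq < 0 || xq >= nx)
            continue;
          int q = lin(zq, yq, xq, nz, ny);
          if (mask[q] && lab[q] == 0)
            pq.push({priority[q], counter++, q});
        }
      }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int i = it.idx;
    if (lab[i] != 0) continue;
    int z = i % nz, y = (i / nz) % ny, x = i / (nz * ny);
    int found = 0; bool conflict = false;
    for (int o = start; o < start + noff && o < 6; ++o) {
      int zq = z + offs[o][0], yq = y + offs[o][1], xq = x + offs[o][2];
      if (zq < 0 || zq >= nz || yq < 0 || yq >= ny || xq < 0 || xq >= nx)
        continue;
      int l = lab[lin(zq, yq, xq, nz, ny)];
      if (l > 0) {
        if (found == 0) found = l;
        else if (l != found) conflict = true;
      }
    }
    if (found == 0) continue;             // orphan: will be re-pushed by others
    if (conflict && lines) {
      lab[i] = WSLINE;
      continue;
    }
    lab[i] = found;
    for (int o = start; o < start + noff && o < 6; ++o) {
      int zq = z + offs[o][0], yq = y + offs[o][1], xq = x + offs[o][2];
      if (zq < 0 || zq >= nz || yq < 0 || yq >= ny || xq < 0 || xq >= nx)
        continue;
      int q = lin(zq, yq, xq, nz, ny);
      if (mask[q] && lab[q] == 0)
        pq.push({priority[q], counter++, q});
    }
  }
  for (int i = 0; i < n; ++i) if (lab[i] == WSLINE) lab[i] = 0;
  return lab;
}

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   bool full_connectivity) {
  // Connected-component labeling (BFS); labels assigned in linear-scan order
  // of each component's first voxel, so the result is deterministic.
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long n = (long)nz * ny * nx;
  IntegerVector lab(n);
  std::vector<long> stack;
  int next = 0;
  for (long i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      long p = stack.back(); stack.pop_back();
      int z = p % nz, y = (p / nz) % ny, x = p / ((long)nz * ny);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            if (!full_connectivity && (std::abs(dz) + std::abs(dy) + std::abs(dx)) != 1)
              continue;
            int zq = z + dz, yq = y + dy, xq = x + dx;
            if (zq < 0 || zq >= nz || yq < 0 || yq >= ny || xq < 0 || xq >= nx)
              continue;
            long q = lin(zq, yq, xq, nz, ny);
            if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  return lab;
}

// [[Rcpp::export]]
NumericVector reconstruct_dilation_cpp(NumericVector marker, NumericVector mask,
                                       IntegerVector dims) {
  // Grayscale reconstruction by dilation (marker <= mask), hybrid
  // raster/anti-raster + queue algorithm, face connectivity.
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long n = (long)nz * ny * nx;
  NumericVector J(n);
  for (long i = 0; i < n; ++i) J[i] = std::min(marker[i], mask[i]);
  int noff = (nz > 1) ? 3 : 2;
  // "preceding" face offsets in linear order: z-1, y-1, x-1
  int poffs[3][3] = {{-1,0,0},{0,-1,0},{0,0,-1}};
  int pstart = (nz > 1) ? 0 : 1;
  // raster
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        long i = lin(z, y, x, nz, ny);
        double m = J[i];
        for (int o = pstart; o < pstart + noff && o < 3; ++o) {
          int zq = z + poffs[o][0], yq = y + poffs[o][1], xq = x + poffs[o][2];
          if (zq < 0 || yq < 0 || xq < 0) continue;
          double v = J[lin(zq, yq, xq, nz, ny)];
          if (v > m) m = v;
        }
        J[i] = std::min(m, mask[i]);
      }
  // anti-raster + queue seeding
  std::queue<long> fifo;
  for (int x = nx - 1; x >= 0; --x)
    for (int y = ny - 1; y >= 0; --y)
      for (int z = nz - 1; z >= 0; --z) {
        long i = lin(z, y, x, nz, ny);
        double m = J[i];
        for (int o = pstart; o < pstart + noff && o < 3; ++o) {
          int zq = z - poffs[o][0], yq = y - poffs[o][1], xq = x - poffs[o][2];
          if (zq >= nz || yq >= ny || xq >= nx) continue;
          double v = J[lin(zq, yq, xq, nz, ny)];
          if (v > m) m = v;
        }
        J[i] = std::min(m, mask[i]);
        for (int o = pstart; o < pstart + noff && o < 3; ++o) {
          int zq = z - poffs[o][0], yq = y - poffs[o][1], xq = x - poffs[o][2];
          if (zq >= nz || yq >= ny || xq >= nx) continue;
          long q = lin(zq, yq, xq, nz, ny);
          if (J[q] < J[i] && J[q] < mask[q]) { fifo.push(i); break; }
        }
      }
  int offs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  int start = (nz > 1) ? 0 : 2;
  int nall = (nz > 1) ? 6 : 4;
  while (!fifo.empty()) {
    long i = fifo.front(); fifo.pop();
    int z = i % nz, y = (i / nz) % ny, x = i / ((long)nz * ny);
    for (int o = start; o < start + nall && o < 6; ++o) {
      int zq = z + offs[o][0], yq = y + offs[o][1], xq = x + offs[o][2];
      if (zq < 0 || zq >= nz || yq < 0 || yq >= ny || xq < 0 || xq >= nx)
        continue;
      long q = lin(zq, yq, xq, nz, ny);
      if (J[q] < J[i] && mask[q] != J[q]) {
        J[q] = std::min(J[i], mask[q]);
        fifo.push(q);
      }
    }
  }
  return J;
}

// [[Rcpp::export]]
NumericVector minmax_filter_cpp(NumericVector vol, IntegerVector dims,
                                IntegerMatrix offsets, bool take_max) {
  // Erosion (take_max = false) / dilation (true) over an arbitrary offset
  // set; out-of-bounds offsets are ignored (+inf / -inf padding), which
  // preserves the opening <= image adjunction at borders.
  int nz = dims[0], ny = dims[1], nx = dims[2];
  long n = (long)nz * ny * nx;
  int m = offsets.nrow();
  NumericVector out(n);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        double best = take_max ? -INFINITY : INFINITY;
        for (int k = 0; k < m; ++k) {
          int zq = z + offsets(k, 0), yq = y + offsets(k, 1), xq = x + offsets(k, 2);
          if (zq < 0 || zq >= nz || yq < 0 || yq >= ny || xq < 0 || xq >= nx)
            continue;
          double v = vol[lin(zq, yq, xq, nz, ny)];
          if (take_max ? (v > best) : (v < best)) best = v;
        }
        out[lin(z, y, x, nz, ny)] = best;
      }
  return out;
}

// [[Rcpp::export]]
List nearest_point_label_cpp(NumericMatrix query_um, NumericMatrix ref_um,
                             IntegerVector ref_label) {
  // For each query point, the minimal Euclidean distance to the reference
  // points and the label achieving it; ties go to the lower label.
  int nq = query_um.nrow(), nr = ref_um.nrow();
  NumericVector dist(nq);
  IntegerVector lab(nq);
  for (int i = 0; i < nq; ++i) {
    double best = INFINITY; int bl = 0;
    for (int j = 0; j < nr; ++j) {
      double dz = query_um(i,0) - ref_um(j,0);
      double dy = query_um(i,1) - ref_um(j,1);
      double dx = query_um(i,2) - ref_um(j,2);
      double d2 = dz*dz + dy*dy + dx*dx;
      if (d2 < best - 1e-12 || (std::abs(d2 - best) <= 1e-12 && ref_label[j] < bl)) {
        best = d2; bl = ref_label[j];
      }
    }
    dist[i] = std::sqrt(best);
    lab[i] = bl;
  }
  return List::create(_["distance"] = dist, _["label"] = lab);
}
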