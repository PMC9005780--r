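#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline long long cell_key(long long i, long long j, long long k) {
  // pack three 21-bit signed cell indices into one 64-bit key
  const long long B = 1 << 20;
  return ((i + B) << 42) | ((j + B) << 21) | (k + B);
}

// Mean distance to the k nearest neighbours of every vertex, via a uniform
// cell list sized so that a few shells of cells contain >= k points.
// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix v, int k) {
  int n = v.nrow();
  if (n <= k) stop("need more vertices than neighbours");
  // cell edge: scale so average occupancy ~ k points per cell
  double xmin = v(0, 0), xmax = v(0, 0), ymin = v(0, 1), ymax = v(0, 1),
         zmin = v(0, 2), zmax = v(0, 2);
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, v(i, 0)); xmax = std::max(xmax, v(i, 0));
    ymin = std::min(ymin, v(i, 1)); ymax = std::max(ymax, v(i, 1));
    zmin = std::min(zmin, v(i, 2)); zmax = std::max(zmax, v(i, 2));
  }
  double vol = std::max(xmax - xmin, 1e-9) * std::max(ymax - ymin, 1e-9) *
               std::max(zmax - zmin, 1e-9);
  double h = std::cbrt(vol * k / n);
  if (!(h > 0)) h = 1.0;
  std::unordered_map<long long, std::vector<int> > cells;
  cells.reserve(n);
  for (int i = 0; i < n; ++i)
    cells[cell_key((long long)std::floor(v(i, 0) / h),
                   (long long)std::floor(v(i, 1) / h),
                   (long long)std::floor(v(i, 2) / h))].push_back(i);
  NumericVector out(n);
  std::vector<double> d2;
  for (int i = 0; i < n; ++i) {
    long long ci = (long long)std::floor(v(i, 0) / h);
    long long cj = (long long)std::floor(v(i, 1) / h);
    long long ck = (long long)std::floor(v(i, 2) / h);
    int shell = 1;
    for (;;) {
      d2.clear();
      for (long long a = ci - shell; a <= ci + shell; ++a)
        for (long long b = cj - shell; b <= cj + shell; ++b)
          for (long long c = ck - shell; c <= ck + shell; ++c) {
            std::unordered_map<long long, std::vector<int> >::iterator it =
              cells.find(cell_key(a, b, c));
            if (it == cells.end()) continue;
            for (size_t q = 0; q < it->second.size(); ++q) {
              int j = it->second[q];
              if (j == i) continue;
              double dx = v(i, 0) - v(j, 0), dy = v(i, 1) - v(j, 1),
                     dz = v(i, 2) - v(j, 2);
              d2.push_back(dx * dx + dy * dy + dz * dz);
            }
          }
      // accept only neighbours certain to be within the searched radius
      double rmax = shell * h;
      int within = 0;
      for (size_t q = 0; q < d2.size(); ++q)
        if (d2[q] <= rmax * rmax) ++within;
      if (within >= k || shell > 64) break;
      ++shell;
    }
    std::partial_sort(d2.begin(), d2.begin() + std::min((size_t)k, d2.size()),
                      d2.end());
    double s = 0.0;
    int kk = std::min((size_t)k, d2.size());
    for (int q = 0; q < kk; ++q) s += std::sqrt(d2[q]);
    out[i] = kk > 0 ? s / kk : R_PosInf;
  }
  return out;
}

// 26-connected component labels for a set of occupied integer voxels
// (n x 3 matrix). Returns 1-based labels, largest component is label 1.
// [[Rcpp::export]]
IntegerVector cpp_voxel_components(IntegerMatrix vox) {
  int n = vox.nrow();
  std::unordered_map<long long, int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; ++i)
    idx[cell_key(vox(i, 0), vox(i, 1), vox(i, 2))] = i;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> sizes;
  for (int s = 0; s < n; ++s) {
    if (lab[s]) continue;
    ++next;
    sizes.push_back(0);
    std::queue<int> q;
    q.push(s);
    lab[s] = next;
    while (!q.empty()) {
      int i = q.front(); q.pop();
      ++sizes[next - 1];
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            if (!a && !b && !c) continue;
            std::unordered_map<long long, int>::iterator it =
              idx.find(cell_key(vox(i, 0) + a, vox(i, 1) + b, vox(i, 2) + c));
            if (it != idx.end() && !lab[it->second]) {
              lab[it->second] = lab[i];
              q.push(it->second);
            }
          }
    }
  }
  // relabel so component 1 is the largest
  std::vector<int> order(next);
  for (int i = 0; i < next; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return sizes[a] > sizes[b]; });
  std::vector<int> rank(next);
  for (int r = 0; r < next; ++r) rank[order[r]] = r + 1;
  for (int i = 0; i < n; ++i) lab[i] = rank[lab[i] - 1];
  return lab;
}

// Exhaustive 1-degree rotational alignment of curve a to curve b (both
// centred): returns (best angle in degrees, rmsd) minimizing the
// symmetrized mean point-to-nearest-point squared distance.
// [[Rcpp::export]]
NumericVector cpp_align_curves(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow(), m = b.nrow();
  double best_ang = 0.0, best_rmsd = R_PosInf;
  std::vector<double> rx(n), ry(n);
  for (int ang = 0; ang < 360; ++ang) {
    double ca = std::cos(ang * M_PI / 180.0), sa = std::sin(ang * M_PI / 180.0);
    for (int i = 0; i < n; ++i) {
      rx[i] = ca * a(i, 0) - sa * a(i, 1);
      ry[i] = sa * a(i, 0) + ca * a(i, 1);
    }
    double sab = 0.0;
    for (int i = 0; i < n; ++i) {
      double dmin = R_PosInf;
      for (int j = 0; j < m; ++j) {
        double dx = rx[i] - b(j, 0), dy = ry[i] - b(j, 1);
        double d2 = dx * dx + dy * dy;
        if (d2 < dmin) dmin = d2;
      }
      sab += dmin;
    }
    double sba = 0.0;
    for (int j = 0; j < m; ++j) {
      double dmin = R_PosInf;
      for (int i = 0; i < n; ++i) {
        double dx = rx[i] - b(j, 0), dy = ry[i] - b(j, 1);
        double d2 = dx * dx + dy * dy;
        if (d2 < dmin) dmin = d2;
      }
      sba += dmin;
    }
    double rmsd = std::sqrt((sab / n + sba / m) / 2.0);
    if (rmsd < best_rmsd - 1e-12) {
      best_rmsd = rmsd;
      best_ang = ang;
    }
  }
  return NumericVector::create(best_ang, best_rmsd);
}

// For each point of a, the distance to the nearest point of b (uniform cell
// list over b, expanding shell search).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix a, NumericMatrix b, double cell) {
  int n = a.nrow(), m = b.nrow();
  std::unordered_map<long long, std::vector<int> > cells;
  cells.reserve(m);
  for (int j = 0; j < m; ++j)
    cells[cell_key((long long)std::floor(b(j, 0) / cell),
                   (long long)std::floor(b(j, 1) / cell),
                   (long long)std::floor(b(j, 2) / cell))].push_back(j);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    long long ci = (long long)std::floor(a(i, 0) / cell);
    long long cj = (long long)std::floor(a(i, 1) / cell);
    long long ck = (long long)std::floor(a(i, 2) / cell);
    double best = R_PosInf;
    for (int shell = 1; shell <= 64; ++shell) {
      for (long long p = ci - shell; p <= ci + shell; ++p)
        for (long long q = cj - shell; q <= cj + shell; ++q)
          for (long long s = ck - shell; s <= ck + shell; ++s) {
            std::unordered_map<long long, std::vector<int> >::iterator it =
              cells.find(cell_key(p, q, s));
            if (it == cells.end()) continue;
            for (size_t t = 0; t < it->second.size(); ++t) {
              int j = it->second[t];
              double dx = a(i, 0) - b(j, 0), dy = a(i, 1) - b(j, 1),
                     dz = a(i, 2) - b(j, 2);
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) best = d2;
            }
          }
      if (best <= (double)(shell - 0) * cell * (shell - 0) * cell || shell == 64)
        break;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
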