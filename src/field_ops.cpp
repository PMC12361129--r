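// Skeleton-to-voxel geometry kernels: spherical region expansion around
// skeleton points, nearest-point assignment, perpendicular-distance Gaussian
// decay fields, instance labeling, point-set matching, neighbor graphs and
// tube rendering for the phantom generator.
//
// Coordinates are zero-based SWC-order (x, y, z); volumes are R arrays with
// dim (d1, d2, d3) = (nz, ny, nx), so voxel (x, y, z) lives at linear index
// z + d1*y + d1*d2*x.

#include <RcppArmadillo.h>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword vidx(int z, int y, int x, int d1, int d2) {
  return (arma::uword)z + (arma::uword)d1 * (y + (arma::uword)d2 * x);
}

// Minimum squared distance to any skeleton point (Inf where no point is
// within `radius`) and the 1-based row of the nearest point (ties -> first
// row in input order, i.e. lowest (tree, node) when rows are so ordered).
// [[Rcpp::export]]
List nearest_field(NumericMatrix pts, IntegerVector dims, double radius, bool strict) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  arma::uword N = (arma::uword)d1 * d2 * d3;
  NumericVector bd2((R_xlen_t)N, R_PosInf);
  IntegerVector near((R_xlen_t)N, 0);
  double r2 = radius * radius;
  for (int p = 0; p < pts.nrow(); p++) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    int x0 = std::max(0, (int)std::floor(px - radius));
    int x1 = std::min(d3 - 1, (int)std::ceil(px + radius));
    int y0 = std::max(0, (int)std::floor(py - radius));
    int y1 = std::min(d2 - 1, (int)std::ceil(py + radius));
    int z0 = std::max(0, (int)std::floor(pz - radius));
    int z1 = std::min(d1 - 1, (int)std::ceil(pz + radius));
    for (int x = x0; x <= x1; x++) {
      double dx = x - px;
      for (int y = y0; y <= y1; y++) {
        double dy = y - py;
        double dxy = dx * dx + dy * dy;
        if (dxy > r2) continue;
        for (int z = z0; z <= z1; z++) {
          double dz = z - pz;
          double d2v = dxy + dz * dz;
          bool in = strict ? (d2v < r2) : (d2v <= r2);
          if (!in) continue;
          arma::uword ii = vidx(z, y, x, d1, d2);
          if (d2v < bd2[ii]) { bd2[ii] = d2v; near[ii] = p + 1; }
        }
      }
    }
  }
  bd2.attr("dim") = dims;
  near.attr("dim") = dims;
  return List::create(_["dist2"] = bd2, _["nearest"] = near);
}

// Gaussian-decay distance field: per tree, assign each in-region voxel its
// nearest skeleton point, take the perpendicular distance to the local
// centerline direction (Euclidean fallback where the direction is NaN), map
// through exp(-d / (2 sigma^2)) (or d^2 with `squared`), and max-combine
// fields across trees.
// [[Rcpp::export]]
NumericVector decay_field(NumericMatrix pts, NumericMatrix dirs, IntegerVector tree,
                          IntegerVector dims, double radius, double sigma,
                          bool strict, bool squared) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  arma::uword N = (arma::uword)d1 * d2 * d3;
  NumericVector out((R_xlen_t)N, 0.0);
  out.attr("dim") = dims;
  std::vector<double> bd2(N);
  std::vector<int> near(N), stamp(N, -1);
  std::vector<arma::uword> touched;
  double r2 = radius * radius;
  double denom = 2.0 * sigma * sigma;
  int n = pts.nrow();
  int p = 0;
  int marker = 0;
  while (p < n) {
    int t = tree[p];
    touched.clear();
    for (; p < n && tree[p] == t; p++) {
      double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
      int x0 = std::max(0, (int)std::floor(px - radius));
      int x1 = std::min(d3 - 1, (int)std::ceil(px + radius));
      int y0 = std::max(0, (int)std::floor(py - radius));
      int y1 = std::min(d2 - 1, (int)std::ceil(py + radius));
      int z0 = std::max(0, (int)std::floor(pz - radius));
      int z1 = std::min(d1 - 1, (int)std::ceil(pz + radius));
      for (int x = x0; x <= x1; x++) {
        double dx = x - px;
        for (int y = y0; y <= y1; y++) {
          double dy = y - py;
          double dxy = dx * dx + dy * dy;
          if (dxy > r2) continue;
          for (int z = z0; z <= z1; z++) {
            double dz = z - pz;
            double d2v = dxy + dz * dz;
            bool in = strict ? (d2v < r2) : (d2v <= r2);
            if (!in) continue;
            arma::uword ii = vidx(z, y, x, d1, d2);
            if (stamp[ii] != marker) {
              stamp[ii] = marker;
              bd2[ii] = d2v;
              near[ii] = p;
              touched.push_back(ii);
            } else if (d2v < bd2[ii]) {
              bd2[ii] = d2v;
              near[ii] = p;
            }
          }
        }
      }
    }
    for (arma::uword ii : touched) {
      int q = near[ii];
      arma::uword x = ii / ((arma::uword)d1 * d2);
      arma::uword rem = ii % ((arma::uword)d1 * d2);
      arma::uword y = rem / d1;
      arma::uword z = rem % d1;
      double wx = (double)x - pts(q, 0);
      double wy = (double)y - pts(q, 1);
      double wz = (double)z - pts(q, 2);
      double w2 = wx * wx + wy * wy + wz * wz;
      double dist;
      double ux = dirs(q, 0);
      if (ISNAN(ux)) {
        dist = std::sqrt(w2);
      } else {
        double proj = wx * ux + wy * dirs(q, 1) + wz * dirs(q, 2);
        double perp2 = w2 - proj * proj;
        dist = perp2 > 0 ? std::sqrt(perp2) : 0.0;
      }
      double val = std::exp(-(squared ? dist * dist : dist) / denom);
      if (val > out[ii]) out[ii] = val;
    }
    marker++;
  }
  return out;
}

// Instance labels: in-region voxels carry the tree id of their globally
// nearest skeleton point (ties -> first row, rows ordered by (tree, node)).
// [[Rcpp::export]]
IntegerVector label_nearest(NumericMatrix pts, IntegerVector tree, IntegerVector dims,
                            double radius, bool strict) {
  List nf = nearest_field(pts, dims, radius, strict);
  IntegerVector near = nf["nearest"];
  IntegerVector lab(near.size(), 0);
  for (R_xlen_t i = 0; i < near.size(); i++)
    if (near[i] > 0) lab[i] = tree[near[i] - 1];
  lab.attr("dim") = dims;
  return lab;
}

// flag[i] = 1 iff min_j ||A_i - B_j|| < thre (Euclidean; with `squared`,
// the squared distance is compared against thre as printed in the prose
// reading of the matching function).
// [[Rcpp::export]]
IntegerVector match_flags(NumericMatrix A, NumericMatrix B, double thre, bool squared) {
  int n = A.nrow(), m = B.nrow();
  double cut = squared ? thre : thre * thre;
  IntegerVector flag(n, 0);
  for (int i = 0; i < n; i++) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < m; j++) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < cut) { flag[i] = 1; break; }
    }
  }
  return flag;
}

// All point pairs within `cutoff` (cell-list search), as a 1-based edge list
// with Euclidean lengths.
// [[Rcpp::export]]
List neighbor_edges(NumericMatrix P, double cutoff) {
  int n = P.nrow();
  double c2 = cutoff * cutoff;
  std::unordered_map<long long, std::vector<int>> cells;
  auto key = [&](long long cx, long long cy, long long cz) {
    return ((cx + 1048576) << 42) | ((cy + 1048576) << 21) | (cz + 1048576);
  };
  std::vector<long long> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; i++) {
    cx[i] = (long long)std::floor(P(i, 0) / cutoff);
    cy[i] = (long long)std::floor(P(i, 1) / cutoff);
    cz[i] = (long long)std::floor(P(i, 2) / cutoff);
    cells[key(cx[i], cy[i], cz[i])].push_back(i);
  }
  std::vector<int> from, to;
  std::vector<double> w;
  for (int i = 0; i < n; i++) {
    for (long long ox = -1; ox <= 1; ox++)
      for (long long oy = -1; oy <= 1; oy++)
        for (long long oz = -1; oz <= 1; oz++) {
          auto it = cells.find(key(cx[i] + ox, cy[i] + oy, cz[i] + oz));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            if (j <= i) continue;
            double dx = P(i, 0) - P(j, 0);
            double dy = P(i, 1) - P(j, 1);
            double dz = P(i, 2) - P(j, 2);
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 <= c2) {
              from.push_back(i + 1);
              to.push_back(j + 1);
              w.push_back(std::sqrt(d2));
            }
          }
        }
  }
  return List::create(_["from"] = wrap(from), _["to"] = wrap(to), _["w"] = wrap(w));
}

// Stamp tubes with a Gaussian radial intensity profile; overlapping stamps
// combine by maximum so intensity does not accumulate along a path.
// [[Rcpp::export]]
NumericVector render_tubes(NumericVector vol, IntegerVector dims, NumericMatrix pts,
                           NumericVector intens, NumericVector radius) {
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericVector out = clone(vol);
  for (int p = 0; p < pts.nrow(); p++) {
    double r = radius[p];
    double cut = 2.5 * r;
    double cut2 = cut * cut;
    double inv = 1.0 / (2.0 * r * r);
    double I = intens[p];
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    int x0 = std::max(0, (int)std::floor(px - cut));
    int x1 = std::min(d3 - 1, (int)std::ceil(px + cut));
    int y0 = std::max(0, (int)std::floor(py - cut));
    int y1 = std::min(d2 - 1, (int)std::ceil(py + cut));
    int z0 = std::max(0, (int)std::floor(pz - cut));
    int z1 = std::min(d1 - 1, (int)std::ceil(pz + cut));
    for (int x = x0; x <= x1; x++) {
      double dx = x - px;
      for (int y = y0; y <= y1; y++) {
        double dy = y - py;
        double dxy = dx * dx + dy * dy;
        if (dxy > cut2) continue;
        for (int z = z0; z <= z1; z++) {
          double dz = z - pz;
          double d2v = dxy + dz * dz;
          if (d2v > cut2) continue;
          double v = I * std::exp(-d2v * inv);
          arma::uword ii = vidx(z, y, x, d1, d2);
          if (v > out[ii]) out[ii] = v;
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
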