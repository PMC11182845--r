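#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e20;

// 1-D squared distance transform (lower envelope of parabolas) on samples
// spaced t apart.  f holds squared distances on input, d on output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double t) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * t;
    double s;
    while (true) {
      double xv = v[k] * t;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * t;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * t;
    d[q] = dx * dx + f[v[k]];
  }
}

// Anisotropy-aware Euclidean distance (um) from every voxel centre to the
// nearest mask voxel centre; 0 on mask voxels.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : BIG;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> d(f.size());

  // along x (stride 1)
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // along y (stride nx)
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // along z (stride nx*ny)
  R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * sz];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * sz] = d[z];
    }
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(g[i]);
  return out;
}

// Connected-component labels (1..k) of true voxels; connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dim,
                          int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx);
        offy.push_back(dy);
        offz.push_back(dz);
      }
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
      for (size_t k = 0; k < offx.size(); ++k) {
        int xx = x + offx[k], yy = y + offy[k], zz = z + offz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[q] && lab[q] == 0) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Geodesic (within-mask) distance in um from a set of source voxels
// (1-based linear indices) over the 26-neighbourhood graph with Euclidean
// step weights.  Background / unreachable voxels get +Inf.
// [[Rcpp::export]]
NumericVector geodesic_cpp(LogicalVector mask, IntegerVector dim,
                           NumericVector spacing, IntegerVector sources) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector dist(n, R_PosInf);
  std::vector<int> offx, offy, offz;
  std::vector<double> w;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        offx.push_back(dx);
        offy.push_back(dy);
        offz.push_back(dz);
        double a = dx * spacing[0], b = dy * spacing[1], c = dz * spacing[2];
        w.push_back(std::sqrt(a * a + b * b + c * c));
      }
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int i = 0; i < sources.size(); ++i) {
    R_xlen_t s = (R_xlen_t)sources[i] - 1;
    if (s < 0 || s >= n || !mask[s]) stop("source voxel outside mask");
    dist[s] = 0.0;
    pq.push(Node(0.0, s));
  }
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    if (top.first > dist[top.second]) continue;
    R_xlen_t p = top.second;
    int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
    for (size_t k = 0; k < offx.size(); ++k) {
      int xx = x + offx[k], yy = y + offy[k], zz = z + offz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      R_xlen_t q = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
      if (!mask[q]) continue;
      double nd = top.first + w[k];
      if (nd < dist[q]) {
        dist[q] = nd;
        pq.push(Node(nd, q));
      }
    }
  }
  return dist;
}

// For each row of pts, the 1-based row index of the nearest row of verts
// (Euclidean, coordinates already in um).  Ties go to the smaller index.
// [[Rcpp::export]]
List nearest_vertex_cpp(NumericMatrix pts, NumericMatrix verts) {
  int n = pts.nrow(), m = verts.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = px - verts(j, 0), dy = py - verts(j, 1),
             dz = pz - verts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        bj = j;
      }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(Named("index") = idx, Named("dist") = dist);
}

// True where the voxel centre (0-based index * spacing) lies within radius
// of the polyline given by path (rows of x,y,z in um).
// [[Rcpp::export]]
LogicalVector tube_mask_cpp(NumericMatrix path, IntegerVector dim,
                            NumericVector spacing, double radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  double r2 = radius * radius;
  int nseg = path.nrow() - 1;
  for (int s = 0; s < std::max(nseg, 1); ++s) {
    double ax = path(s, 0), ay = path(s, 1), az = path(s, 2);
    double bx = ax, by = ay, bz = az;
    if (nseg >= 1) {
      bx = path(s + 1, 0);
      by = path(s + 1, 1);
      bz = path(s + 1, 2);
    }
    double lox = std::min(ax, bx) - radius, hix = std::max(ax, bx) + radius;
    double loy = std::min(ay, by) - radius, hiy = std::max(ay, by) + radius;
    double loz = std::min(az, bz) - radius, hiz = std::max(az, bz) + radius;
    int x0 = std::max(0, (int)std::ceil(lox / spacing[0]));
    int x1 = std::min(nx - 1, (int)std::floor(hix / spacing[0]));
    int y0 = std::max(0, (int)std::ceil(loy / spacing[1]));
    int y1 = std::min(ny - 1, (int)std::floor(hiy / spacing[1]));
    int z0 = std::max(0, (int)std::ceil(loz / spacing[2]));
    int z1 = std::min(nz - 1, (int)std::floor(hiz / spacing[2]));
    double vx = bx - ax, vy = by - ay, vz = bz - az;
    double vv = vx * vx + vy * vy + vz * vz;
    for (int z = z0; z <= z1; ++z)
      for (int y = y0; y <= y1; ++y)
        for (int x = x0; x <= x1; ++x) {
          double px = x * spacing[0], py = y * spacing[1], pz = z * spacing[2];
          double t = 0.0;
          if (vv > 0) {
            t = ((px - ax) * vx + (py - ay) * vy + (pz - az) * vz) / vv;
            t = std::min(1.0, std::max(0.0, t));
          }
          double dx = px - (ax + t * vx), dy = py - (ay + t * vy),
                 dz = pz - (az + t * vz);
          if (dx * dx + dy * dy + dz * dz <= r2)
            out[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = true;
        }
  }
  return out;
}
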