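// Low-level numerical kernels: separable convolution, Hessian line filter,
// grid Dijkstra (vesselness-weighted paths and intensity-geodesic label
// propagation), polyline distance, subdivision upsampling, isosurfacing
// (marching tetrahedra on the Kuhn 6-tetrahedra cube split) and connected
// components. All linear indices are 0-based, column-major (i fastest),
// matching R's array layout.

#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>

using namespace Rcpp;

static inline R_xlen_t lin3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Separable convolution along one axis, nearest-neighbour boundary extension.
// kernel must have odd length; axis is 0 (i), 1 (j) or 2 (k).
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector x, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int rad = (klen - 1) / 2;
  NumericVector out(x.size());
  const int nax[3] = {nx, ny, nz};
  const int n = nax[axis];
  const R_xlen_t stride = (axis == 0) ? 1 :
    (axis == 1) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int idx3[3] = {i, j, k};
        const int pos = idx3[axis];
        const R_xlen_t base = lin3(i, j, k, nx, ny) - (R_xlen_t)pos * stride;
        double acc = 0.0;
        for (int t = -rad; t <= rad; ++t) {
          int p = pos + t;
          if (p < 0) p = 0;
          if (p >= n) p = n - 1;
          acc += kernel[t + rad] * x[base + (R_xlen_t)p * stride];
        }
        out[lin3(i, j, k, nx, ny)] = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Eigenvalues of a symmetric 3x3 matrix, closed form (Smith's method).
static inline void sym3_eig(double xx, double yy, double zz,
                            double xy, double xz, double yz,
                            double ev[3]) {
  const double p1 = xy * xy + xz * xz + yz * yz;
  if (p1 < 1e-300) {
    ev[0] = xx; ev[1] = yy; ev[2] = zz;
  } else {
    const double q = (xx + yy + zz) / 3.0;
    const double p2 = (xx - q) * (xx - q) + (yy - q) * (yy - q) +
                      (zz - q) * (zz - q) + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    const double bxx = (xx - q) / p, byy = (yy - q) / p, bzz = (zz - q) / p;
    const double bxy = xy / p, bxz = xz / p, byz = yz / p;
    double detB = bxx * (byy * bzz - byz * byz)
                - bxy * (bxy * bzz - byz * bxz)
                + bxz * (bxy * byz - byy * bxz);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0;
    if (r > 1.0) r = 1.0;
    const double phi = std::acos(r) / 3.0;
    const double e1 = q + 2.0 * p * std::cos(phi);
    const double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[0] = e1; ev[1] = 3.0 * q - e1 - e3; ev[2] = e3;
  }
  // sort ascending by |eigenvalue|
  for (int a = 0; a < 2; ++a)
    for (int b = 0; b < 2 - a; ++b)
      if (std::fabs(ev[b]) > std::fabs(ev[b + 1])) {
        double t = ev[b]; ev[b] = ev[b + 1]; ev[b + 1] = t;
      }
}

// Hessian line filter (vesselness) from the six Hessian component images.
// gamma <= 0 requests the automatic rule: half the maximum Hessian
// Frobenius norm over the image. dark = true selects dark tubes on a
// bright background (lambda2, lambda3 > 0).
// [[Rcpp::export]]
NumericVector cpp_line_filter(NumericVector hxx, NumericVector hyy,
                              NumericVector hzz, NumericVector hxy,
                              NumericVector hxz, NumericVector hyz,
                              double alpha, double beta, double gamma,
                              bool dark) {
  const R_xlen_t n = hxx.size();
  std::vector<double> l1(n), l2(n), l3(n);
  double smax = 0.0;
  for (R_xlen_t v = 0; v < n; ++v) {
    double ev[3];
    sym3_eig(hxx[v], hyy[v], hzz[v], hxy[v], hxz[v], hyz[v], ev);
    l1[v] = ev[0]; l2[v] = ev[1]; l3[v] = ev[2];
    const double s = std::sqrt(ev[0] * ev[0] + ev[1] * ev[1] + ev[2] * ev[2]);
    if (s > smax) smax = s;
  }
  if (gamma <= 0.0) gamma = 0.5 * smax;
  NumericVector out(n);
  if (smax == 0.0) return out;  // constant image: zero response
  const double ia2 = 1.0 / (2.0 * alpha * alpha);
  const double ib2 = 1.0 / (2.0 * beta * beta);
  const double ig2 = (gamma > 0.0) ? 1.0 / (2.0 * gamma * gamma) : 0.0;
  for (R_xlen_t v = 0; v < n; ++v) {
    const double a2 = l2[v], a3 = l3[v];
    const bool sign_ok = dark ? (a2 > 0.0 && a3 > 0.0)
                              : (a2 < 0.0 && a3 < 0.0);
    if (!sign_ok) { out[v] = 0.0; continue; }
    const double ra = std::fabs(a2) / std::fabs(a3);
    const double rb = std::fabs(l1[v]) / std::sqrt(std::fabs(a2 * a3));
    const double s2 = l1[v] * l1[v] + a2 * a2 + a3 * a3;
    out[v] = (1.0 - std::exp(-ra * ra * ia2)) *
             std::exp(-rb * rb * ib2) *
             (1.0 - std::exp(-s2 * ig2));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Neighbourhood offset table for 6- or 26-connectivity.
static void build_offsets(int conn, std::vector<int>& di, std::vector<int>& dj,
                          std::vector<int>& dk) {
  di.clear(); dj.clear(); dk.clear();
  if (conn == 6) {
    const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int t = 0; t < 6; ++t) { di.push_back(d[t][0]); dj.push_back(d[t][1]); dk.push_back(d[t][2]); }
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          di.push_back(a); dj.push_back(b); dk.push_back(c);
        }
  }
}

typedef std::pair<double, R_xlen_t> QNode;  // (dist, index); ties pop lowest index

// Point-to-point Dijkstra on the voxel grid with vesselness-derived edge
// weights w(p,q) = max(floor, 1 - (V(p)+V(q))/2) * ||x_p - x_q|| (physical mm).
// Returns the optimal voxel path (0-based linear indices, source first) and
// its accumulated cost.
// [[Rcpp::export]]
List cpp_dijkstra_path(NumericVector V, IntegerVector dims,
                       NumericVector spacing, int src, int dst,
                       int conn, double wfloor) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> di, dj, dk;
  build_offsets(conn, di, dj, dk);
  const int m = (int)di.size();
  std::vector<double> elen(m);
  for (int t = 0; t < m; ++t)
    elen[t] = std::sqrt(di[t] * di[t] * spacing[0] * spacing[0] +
                        dj[t] * dj[t] * spacing[1] * spacing[1] +
                        dk[t] * dk[t] * spacing[2] * spacing[2]);

  std::vector<double> dist(n, R_PosInf);
  std::vector<R_xlen_t> pred(n, -1);
  std::vector<char> done(n, 0);
  std::priority_queue<QNode, std::vector<QNode>, std::greater<QNode> > pq;
  dist[src] = 0.0;
  pq.push(QNode(0.0, src));
  while (!pq.empty()) {
    const QNode top = pq.top(); pq.pop();
    const R_xlen_t u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    if (u == dst) break;
    const int ui = (int)(u % nx);
    const int uj = (int)((u / nx) % ny);
    const int uk = (int)(u / ((R_xlen_t)nx * ny));
    for (int t = 0; t < m; ++t) {
      const int vi = ui + di[t], vj = uj + dj[t], vk = uk + dk[t];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
      const R_xlen_t v = lin3(vi, vj, vk, nx, ny);
      if (done[v]) continue;
      double w = 1.0 - 0.5 * (V[u] + V[v]);
      if (w < wfloor) w = wfloor;
      const double nd = dist[u] + w * elen[t];
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        pq.push(QNode(nd, v));
      }
    }
  }
  if (!R_FINITE(dist[dst])) stop("voxel graph unexpectedly disconnected");
  std::vector<R_xlen_t> rev;
  for (R_xlen_t v = dst; v != -1; v = pred[v]) rev.push_back(v);
  IntegerVector path(rev.size());
  for (size_t t = 0; t < rev.size(); ++t) path[t] = (int)rev[rev.size() - 1 - t];
  return List::create(_["path"] = path, _["cost"] = dist[dst]);
}

// Multi-source intensity-geodesic distance: every source voxel starts at 0
// and the cost of a step p -> q is |I(q) - I(p)| (no spatial length factor).
// active (if non-empty) restricts the graph to the flagged voxels; sources
// must be active. Unreached/inactive voxels stay +Inf.
// [[Rcpp::export]]
NumericVector cpp_geodesic_dist(NumericVector I, IntegerVector dims,
                                IntegerVector sources, int conn,
                                LogicalVector active) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const bool restrict_graph = active.size() > 0;
  std::vector<int> di, dj, dk;
  build_offsets(conn, di, dj, dk);
  const int m = (int)di.size();

  NumericVector dist(n, R_PosInf);
  std::vector<char> done(n, 0);
  std::priority_queue<QNode, std::vector<QNode>, std::greater<QNode> > pq;
  for (R_xlen_t t = 0; t < sources.size(); ++t) {
    const R_xlen_t s = sources[t];
    dist[s] = 0.0;
    pq.push(QNode(0.0, s));
  }
  while (!pq.empty()) {
    const QNode top = pq.top(); pq.pop();
    const R_xlen_t u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    const int ui = (int)(u % nx);
    const int uj = (int)((u / nx) % ny);
    const int uk = (int)(u / ((R_xlen_t)nx * ny));
    for (int t = 0; t < m; ++t) {
      const int vi = ui + di[t], vj = uj + dj[t], vk = uk + dk[t];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
      const R_xlen_t v = lin3(vi, vj, vk, nx, ny);
      if (done[v]) continue;
      if (restrict_graph && !active[v]) continue;
      const double nd = dist[u] + std::fabs(I[u] - I[v]);
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(QNode(nd, v));
      }
    }
  }
  return dist;
}

// ---------------------------------------------------------------------------
// Minimum Euclidean distance from each query point to a polyline (mm).
// [[Rcpp::export]]
NumericVector cpp_dist_to_polyline(NumericMatrix pts, NumericMatrix verts) {
  const R_xlen_t np = pts.nrow();
  const R_xlen_t nv = verts.nrow();
  NumericVector out(np);
  if (nv == 1) {
    for (R_xlen_t p = 0; p < np; ++p) {
      const double dx = pts(p,0)-verts(0,0), dy = pts(p,1)-verts(0,1), dz = pts(p,2)-verts(0,2);
      out[p] = std::sqrt(dx*dx + dy*dy + dz*dz);
    }
    return out;
  }
  const R_xlen_t ns = nv - 1;
  std::vector<double> ax(ns), ay(ns), az(ns), bx(ns), by(ns), bz(ns), len2(ns);
  for (R_xlen_t s = 0; s < ns; ++s) {
    ax[s] = verts(s,0); ay[s] = verts(s,1); az[s] = verts(s,2);
    bx[s] = verts(s+1,0)-ax[s]; by[s] = verts(s+1,1)-ay[s]; bz[s] = verts(s+1,2)-az[s];
    len2[s] = bx[s]*bx[s] + by[s]*by[s] + bz[s]*bz[s];
  }
  for (R_xlen_t p = 0; p < np; ++p) {
    const double px = pts(p,0), py = pts(p,1), pz = pts(p,2);
    double best = R_PosInf;
    for (R_xlen_t s = 0; s < ns; ++s) {
      double t = 0.0;
      if (len2[s] > 0.0) {
        t = ((px-ax[s])*bx[s] + (py-ay[s])*by[s] + (pz-az[s])*bz[s]) / len2[s];
        if (t < 0.0) t = 0.0;
        if (t > 1.0) t = 1.0;
      }
      const double dx = px - (ax[s] + t*bx[s]);
      const double dy = py - (ay[s] + t*by[s]);
      const double dz = pz - (az[s] + t*bz[s]);
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// Distance from every voxel centre of a regular grid to a polyline, without
// materialising the point matrix. Point(i,j,k) = origin + spacing * (i,j,k)
// in a local orthonormal frame (distances are rotation invariant).
// [[Rcpp::export]]
NumericVector cpp_grid_dist_to_polyline(IntegerVector dims, NumericVector spacing,
                                        NumericVector origin, NumericMatrix verts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nv = verts.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  const R_xlen_t ns = (nv > 1) ? nv - 1 : 0;
  std::vector<double> ax(nv), ay(nv), az(nv), bx(ns), by(ns), bz(ns), len2(ns);
  for (R_xlen_t s = 0; s < nv; ++s) { ax[s] = verts(s,0); ay[s] = verts(s,1); az[s] = verts(s,2); }
  for (R_xlen_t s = 0; s < ns; ++s) {
    bx[s] = ax[s+1]-ax[s]; by[s] = ay[s+1]-ay[s]; bz[s] = az[s+1]-az[s];
    len2[s] = bx[s]*bx[s] + by[s]*by[s] + bz[s]*bz[s];
  }
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k) {
    const double pz = origin[2] + spacing[2] * k;
    for (int j = 0; j < ny; ++j) {
      const double py = origin[1] + spacing[1] * j;
      for (int i = 0; i < nx; ++i, ++idx) {
        const double px = origin[0] + spacing[0] * i;
        double best = R_PosInf;
        if (ns == 0) {
          const double dx = px-ax[0], dy = py-ay[0], dz = pz-az[0];
          best = dx*dx + dy*dy + dz*dz;
        } else {
          for (R_xlen_t s = 0; s < ns; ++s) {
            double t = 0.0;
            if (len2[s] > 0.0) {
              t = ((px-ax[s])*bx[s] + (py-ay[s])*by[s] + (pz-az[s])*bz[s]) / len2[s];
              if (t < 0.0) t = 0.0;
              if (t > 1.0) t = 1.0;
            }
            const double dx = px - (ax[s] + t*bx[s]);
            const double dy = py - (ay[s] + t*by[s]);
            const double dz = pz - (az[s] + t*bz[s]);
            const double d2 = dx*dx + dy*dy + dz*dz;
            if (d2 < best) best = d2;
          }
        }
        out[idx] = std::sqrt(best);
      }
    }
  }
  return out;
}

// Exterior-seed shell: label-2 voxels with at least one Moore neighbour
// whose label is not 2 (the only exterior seeds optimal propagation paths
// can enter the undetermined region through).
// [[Rcpp::export]]
LogicalVector cpp_seed_ring(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<int> di, dj, dk;
  build_offsets(26, di, dj, dk);
  for (R_xlen_t u = 0; u < n; ++u) {
    if (labels[u] != 2) continue;
    const int ui = (int)(u % nx);
    const int uj = (int)((u / nx) % ny);
    const int uk = (int)(u / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 26; ++t) {
      const int vi = ui + di[t], vj = uj + dj[t], vk = uk + dk[t];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
      if (labels[lin3(vi, vj, vk, nx, ny)] != 2) { out[u] = true; break; }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Subdivision upsampling by an odd factor c: each voxel becomes c^3
// subvoxels; values by trilinear interpolation between original voxel
// centres with clamped (nearest) extension beyond the outermost centres.
// [[Rcpp::export]]
NumericVector cpp_upsample(NumericVector x, IntegerVector dims, int c) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = nx * c, oy = ny * c, oz = nz * c;
  NumericVector out((R_xlen_t)ox * oy * oz);

  // per-axis base index and interpolation weight for each output position
  std::vector<int> bi(ox), bj(oy), bk(oz);
  std::vector<double> fi(ox), fj(oy), fk(oz);
  const int nax[3] = {nx, ny, nz};
  const int oax[3] = {ox, oy, oz};
  // position in input index space: u = (t + 0.5)/c - 0.5, decomposed as
  // base + frac with |frac| < 0.5 so that subvoxels at original voxel
  // centres (frac == 0) reproduce the original value bit-exactly
  for (int a = 0; a < 3; ++a) {
    const int n = nax[a];
    for (int t = 0; t < oax[a]; ++t) {
      const int base = t / c;
      const int rem = t % c;
      double frac = (rem + 0.5) / c - 0.5;   // exactly 0 at the centre
      int b = base;
      if (frac < 0.0) { b = base - 1; frac += 1.0; }
      if (b < 0) { b = 0; frac = 0.0; }                  // clamped extension
      if (b > n - 1) { b = n - 1; frac = 0.0; }
      if (a == 0) { bi[t] = b; fi[t] = frac; }
      else if (a == 1) { bj[t] = b; fj[t] = frac; }
      else { bk[t] = b; fk[t] = frac; }
    }
  }
  for (int k = 0; k < oz; ++k) {
    const int k0 = bk[k]; const double wk = fk[k];
    const int k1 = (k0 + 1 <= nz - 1) ? k0 + 1 : nz - 1;
    for (int j = 0; j < oy; ++j) {
      const int j0 = bj[j]; const double wj = fj[j];
      const int j1 = (j0 + 1 <= ny - 1) ? j0 + 1 : ny - 1;
      for (int i = 0; i < ox; ++i) {
        const int i0 = bi[i]; const double wi = fi[i];
        const int i1 = (i0 + 1 <= nx - 1) ? i0 + 1 : nx - 1;
        const double c000 = x[lin3(i0,j0,k0,nx,ny)], c100 = x[lin3(i1,j0,k0,nx,ny)];
        const double c010 = x[lin3(i0,j1,k0,nx,ny)], c110 = x[lin3(i1,j1,k0,nx,ny)];
        const double c001 = x[lin3(i0,j0,k1,nx,ny)], c101 = x[lin3(i1,j0,k1,nx,ny)];
        const double c011 = x[lin3(i0,j1,k1,nx,ny)], c111 = x[lin3(i1,j1,k1,nx,ny)];
        const double c00 = c000 + wi * (c100 - c000);
        const double c10 = c010 + wi * (c110 - c010);
        const double c01 = c001 + wi * (c101 - c001);
        const double c11 = c011 + wi * (c111 - c011);
        const double c0 = c00 + wj * (c10 - c00);
        const double c1 = c01 + wj * (c11 - c01);
        out[lin3(i, j, k, ox, oy)] = c0 + wk * (c1 - c0);
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra on the Kuhn split (6 tetrahedra per cube, consistent
// across the lattice, hence watertight). Scalar field sampled at voxel
// centres; isosurface at `level`; a vertex with f exactly == level is
// treated as outside. Triangles are oriented with normals pointing from the
// inside (f > level) toward the outside. Vertex coordinates are continuous
// 0-based voxel-index coordinates.
// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector f, IntegerVector dims, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // axis permutations defining the 6 Kuhn tetrahedra
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}
  };
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f1, f2, f3;

  // corner coordinate/value scratch
  int cx[4], cy[4], cz[4];
  R_xlen_t cid[4];
  double cv[4];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // quick reject: all 8 cube corners on one side
        bool any_in = false, any_out = false;
        for (int dz = 0; dz < 2 && !(any_in && any_out); ++dz)
          for (int dy = 0; dy < 2 && !(any_in && any_out); ++dy)
            for (int dx = 0; dx < 2; ++dx) {
              const double val = f[lin3(i+dx, j+dy, k+dz, nx, ny)];
              if (val > level) any_in = true; else any_out = true;
              if (any_in && any_out) break;
            }
        if (!(any_in && any_out)) continue;

        for (int t = 0; t < 6; ++t) {
          // tet corners in cube-offset coordinates
          int off[4][3] = {{0,0,0},{0,0,0},{0,0,0},{1,1,1}};
          off[1][perms[t][0]] = 1;
          off[2][perms[t][0]] = 1;
          off[2][perms[t][1]] = 1;
          int n_in = 0;
          int in_idx[4], out_idx[4];
          int n_out = 0;
          for (int v = 0; v < 4; ++v) {
            cx[v] = i + off[v][0]; cy[v] = j + off[v][1]; cz[v] = k + off[v][2];
            cid[v] = lin3(cx[v], cy[v], cz[v], nx, ny);
            cv[v] = f[cid[v]];
            if (cv[v] > level) in_idx[n_in++] = v; else out_idx[n_out++] = v;
          }
          if (n_in == 0 || n_in == 4) continue;

          // interpolated vertex on edge (a inside, b outside), cached by edge id
          auto edge_point = [&](int a, int b) -> int {
            R_xlen_t ga = cid[a], gb = cid[b];
            if (ga > gb) { R_xlen_t tmp = ga; ga = gb; gb = tmp; }
            const uint64_t key = (uint64_t)ga * (uint64_t)((R_xlen_t)nx*ny*nz) + (uint64_t)gb;
            std::unordered_map<uint64_t,int>::iterator it = edge_vertex.find(key);
            if (it != edge_vertex.end()) return it->second;
            const double denom = cv[b] - cv[a];
            double tt = (denom != 0.0) ? (level - cv[a]) / denom : 0.5;
            if (tt < 0.0) tt = 0.0;
            if (tt > 1.0) tt = 1.0;
            vx.push_back(cx[a] + tt * (cx[b] - cx[a]));
            vy.push_back(cy[a] + tt * (cy[b] - cy[a]));
            vz.push_back(cz[a] + tt * (cz[b] - cz[a]));
            const int id = (int)vx.size() - 1;
            edge_vertex[key] = id;
            return id;
          };

          // emit one triangle, oriented so its normal points inside -> outside
          auto emit = [&](int p, int q, int r) {
            const double ux = vx[q]-vx[p], uy = vy[q]-vy[p], uz = vz[q]-vz[p];
            const double wx = vx[r]-vx[p], wy = vy[r]-vy[p], wz = vz[r]-vz[p];
            const double nxv = uy*wz - uz*wy;
            const double nyv = uz*wx - ux*wz;
            const double nzv = ux*wy - uy*wx;
            double ox = 0, oy2 = 0, oz2 = 0;
            for (int a = 0; a < n_out; ++a) { ox += cx[out_idx[a]]; oy2 += cy[out_idx[a]]; oz2 += cz[out_idx[a]]; }
            ox /= n_out; oy2 /= n_out; oz2 /= n_out;
            double ix = 0, iy = 0, iz = 0;
            for (int a = 0; a < n_in; ++a) { ix += cx[in_idx[a]]; iy += cy[in_idx[a]]; iz += cz[in_idx[a]]; }
            ix /= n_in; iy /= n_in; iz /= n_in;
            const double dot = nxv*(ox-ix) + nyv*(oy2-iy) + nzv*(oz2-iz);
            if (dot >= 0) { f1.push_back(p+1); f2.push_back(q+1); f3.push_back(r+1); }
            else          { f1.push_back(p+1); f2.push_back(r+1); f3.push_back(q+1); }
          };

          if (n_in == 1) {
            const int a = in_idx[0];
            emit(edge_point(a, out_idx[0]), edge_point(a, out_idx[1]), edge_point(a, out_idx[2]));
          } else if (n_in == 3) {
            const int b = out_idx[0];
            emit(edge_point(in_idx[0], b), edge_point(in_idx[1], b), edge_point(in_idx[2], b));
          } else {  // 2 in, 2 out -> quad split into two triangles
            const int a0 = in_idx[0], a1 = in_idx[1], b0 = out_idx[0], b1 = out_idx[1];
            const int p00 = edge_point(a0, b0), p01 = edge_point(a0, b1);
            const int p11 = edge_point(a1, b1), p10 = edge_point(a1, b0);
            emit(p00, p01, p11);
            emit(p00, p11, p10);
          }
        }
      }

  const int nvtx = (int)vx.size();
  NumericMatrix vertices(nvtx, 3);
  for (int v = 0; v < nvtx; ++v) {
    vertices(v, 0) = vx[v]; vertices(v, 1) = vy[v]; vertices(v, 2) = vz[v];
  }
  const int nf = (int)f1.size();
  IntegerMatrix faces(nf, 3);
  for (int t = 0; t < nf; ++t) {
    faces(t, 0) = f1[t]; faces(t, 1) = f2[t]; faces(t, 2) = f3[t];
  }
  return List::create(_["vertices"] = vertices, _["faces"] = faces);
}

// Connected components of mesh vertices under face adjacency (union-find).
// Returns a 1-based component id per vertex (0 for vertices in no face).
// [[Rcpp::export]]
IntegerVector cpp_vertex_components(IntegerMatrix faces, int nv) {
  std::vector<int> parent(nv + 1);
  for (int i = 0; i <= nv; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int t = 0; t < faces.nrow(); ++t) {
    const int a = find(faces(t, 0)), b = find(faces(t, 1)), c = find(faces(t, 2));
    parent[b] = a;
    parent[find(c)] = find(a);
  }
  IntegerVector out(nv);
  std::vector<int> used(nv + 1, 0);
  for (int t = 0; t < faces.nrow(); ++t)
    for (int s = 0; s < 3; ++s) used[faces(t, s)] = 1;
  for (int i = 1; i <= nv; ++i)
    out[i - 1] = used[i] ? find(i) : 0;
  return out;
}

// Flood fill of the complement of a mask from the grid boundary
// (6-connectivity, the dual of 26-connected foreground). Returns TRUE for
// complement voxels reachable from the boundary; complement voxels left
// FALSE are enclosed cavities.
// [[Rcpp::export]]
LogicalVector cpp_outside_fill(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> di, dj, dk;
  build_offsets(6, di, dj, dk);
  LogicalVector out(n);
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 &&
            k != 0 && k != nz - 1) continue;
        const R_xlen_t s = lin3(i, j, k, nx, ny);
        if (!mask[s] && !out[s]) { out[s] = true; stack.push_back(s); }
      }
  while (!stack.empty()) {
    const R_xlen_t u = stack.back(); stack.pop_back();
    const int ui = (int)(u % nx);
    const int uj = (int)((u / nx) % ny);
    const int uk = (int)(u / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 6; ++t) {
      const int vi = ui + di[t], vj = uj + dj[t], vk = uk + dk[t];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
      const R_xlen_t v = lin3(vi, vj, vk, nx, ny);
      if (!mask[v] && !out[v]) { out[v] = true; stack.push_back(v); }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Largest connected component of a binary mask (6- or 26-connectivity).
// [[Rcpp::export]]
LogicalVector cpp_largest_cc(LogicalVector mask, IntegerVector dims, int conn) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<int> di, dj, dk;
  build_offsets(conn, di, dj, dk);
  const int m = (int)di.size();
  std::vector<int> comp(n, -1);
  std::vector<R_xlen_t> stack;
  int ncomp = 0;
  std::vector<R_xlen_t> comp_size;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || comp[s] >= 0) continue;
    R_xlen_t sz = 0;
    comp[s] = ncomp;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t u = stack.back(); stack.pop_back();
      ++sz;
      const int ui = (int)(u % nx);
      const int uj = (int)((u / nx) % ny);
      const int uk = (int)(u / ((R_xlen_t)nx * ny));
      for (int t = 0; t < m; ++t) {
        const int vi = ui + di[t], vj = uj + dj[t], vk = uk + dk[t];
        if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz) continue;
        const R_xlen_t v = lin3(vi, vj, vk, nx, ny);
        if (mask[v] && comp[v] < 0) { comp[v] = ncomp; stack.push_back(v); }
      }
    }
    comp_size.push_back(sz);
    ++ncomp;
  }
  LogicalVector out(n);
  if (ncomp == 0) return out;
  int best = 0;
  for (int c = 1; c < ncomp; ++c) if (comp_size[c] > comp_size[best]) best = c;
  for (R_xlen_t v = 0; v < n; ++v) out[v] = (comp[v] == best);
  return out;
}
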