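#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Linear index for column-major (nx, ny, nz) arrays.
static inline R_xlen_t vox(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k);
}

// Separable 3-wide box average (edge-renormalized), used to anti-alias
// binary label indicators before sub-voxel boundary localization.
// [[Rcpp::export]]
NumericVector box3_smooth_cpp(NumericVector x, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector a = clone(x), b(x.size());
  for (int ax = 0; ax < 3; ++ax) {
    int n[3] = {nx, ny, nz};
    for (int k = 0; k < nz; ++k) for (int j = 0; j < ny; ++j) for (int i = 0; i < nx; ++i) {
      int c[3] = {i, j, k};
      double s = 0.0; int m = 0;
      for (int d = -1; d <= 1; ++d) {
        int cc = c[ax] + d;
        if (cc < 0 || cc >= n[ax]) continue;
        int p[3] = {i, j, k}; p[ax] = cc;
        s += a[vox(p[0], p[1], p[2], nx, ny)]; ++m;
      }
      b[vox(i, j, k, nx, ny)] = s / m;
    }
    std::swap(a, b);
  }
  return a;
}

// Shortley-Weller SOR solver for the Laplace equation on the WM domain.
// is_wm/is_low/is_high: 0/1 integer volumes. lev_low/lev_high: level-set
// fields positive inside WM, negative beyond the respective boundary; the
// per-arm Dirichlet offset theta is the linear-interpolation root of the
// level along the arm. Neumann (zero-flux) walls elsewhere.
// [[Rcpp::export]]
List solve_laplace_cpp(IntegerVector dims, IntegerVector is_wm,
                       IntegerVector is_low, IntegerVector is_high,
                       NumericVector lev_low, NumericVector lev_high,
                       NumericVector voxsize, double tol, int max_iter,
                       double omega, double theta_min) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  std::vector<R_xlen_t> freeIdx;
  freeIdx.reserve(nvox / 8);
  for (R_xlen_t p = 0; p < nvox; ++p) if (is_wm[p]) freeIdx.push_back(p);
  R_xlen_t N = freeIdx.size();
  if (N == 0) stop("empty white-matter domain");

  std::vector<R_xlen_t> rank(nvox, -1);
  for (R_xlen_t q = 0; q < N; ++q) rank[freeIdx[q]] = q;

  // Per free voxel, 6 arms: weight, neighbor rank (-1 if Dirichlet/Neumann),
  // Dirichlet contribution bc*weight (0 for Neumann).
  std::vector<double> W(N * 6, 0.0), B(N * 6, 0.0);
  std::vector<R_xlen_t> NB(N * 6, -1);
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (R_xlen_t q = 0; q < N; ++q) {
    R_xlen_t p = freeIdx[q];
    int i = (int)(p % nx), j = (int)((p / nx) % ny), k = (int)(p / ((R_xlen_t)nx * ny));
    double th[6]; double bc[6]; int kind[6]; // 0 free, 1 dirichlet, 2 neumann
    for (int a = 0; a < 6; ++a) {
      int ii = i + off[a][0], jj = j + off[a][1], kk = k + off[a][2];
      th[a] = 1.0; bc[a] = 0.0; kind[a] = 2;
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t pn = vox(ii, jj, kk, nx, ny);
      if (is_wm[pn]) { kind[a] = 0; NB[q * 6 + a] = rank[pn]; }
      else if (is_low[pn] || is_high[pn]) {
        kind[a] = 1;
        bc[a] = is_high[pn] ? 1.0 : 0.0;
        double li = is_high[pn] ? lev_high[p] : lev_low[p];
        double lj = is_high[pn] ? lev_high[pn] : lev_low[pn];
        double t = 0.5;
        if (R_finite(li) && R_finite(lj) && (li - lj) > 1e-12) t = li / (li - lj);
        if (!R_finite(t)) t = 0.5;
        if (t < theta_min) t = theta_min;
        if (t > 1.0) t = 1.0;
        th[a] = t;
      }
    }
    for (int ax = 0; ax < 3; ++ax) {
      int ap = 2 * ax, am = 2 * ax + 1;
      double h2 = voxsize[ax] * voxsize[ax];
      double tp = th[ap], tm = th[am];
      double denom = tp + tm;
      for (int s = 0; s < 2; ++s) {
        int a = s == 0 ? ap : am;
        double t = s == 0 ? tp : tm;
        if (kind[a] == 2) continue; // Neumann: mirrored ghost, zero weight
        double w = 2.0 / (t * denom * h2);
        W[q * 6 + a] = w;
        if (kind[a] == 1) B[q * 6 + a] = w * bc[a];
      }
    }
  }

  std::vector<double> u(N, 0.5);
  double maxupd = R_PosInf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    maxupd = 0.0;
    for (R_xlen_t q = 0; q < N; ++q) {
      double num = 0.0, den = 0.0;
      for (int a = 0; a < 6; ++a) {
        double w = W[q * 6 + a];
        if (w == 0.0) continue;
        den += w;
        R_xlen_t nb = NB[q * 6 + a];
        num += nb >= 0 ? w * u[nb] : B[q * 6 + a];
      }
      if (den <= 0.0) continue; // isolated voxel: leave as-is
      double unew = num / den;
      double upd = omega * (unew - u[q]);
      u[q] += upd;
      if (u[q] < 0.0) u[q] = 0.0;
      if (u[q] > 1.0) u[q] = 1.0;
      double au = std::fabs(upd);
      if (au > maxupd) maxupd = au;
    }
    if (maxupd < tol) { ++it; break; }
  }

  NumericVector U(nvox, NA_REAL);
  for (R_xlen_t q = 0; q < N; ++q) U[freeIdx[q]] = u[q];
  return List::create(_["u"] = U, _["residual"] = maxupd,
                      _["iterations"] = it, _["converged"] = maxupd < tol);
}

// Trilinear interpolation of a volume at points given in 0-based voxel
// coordinates. Outside the grid -> NA; NA corners propagate.
// [[Rcpp::export]]
NumericVector trilinear_sample_cpp(NumericVector vol, IntegerVector dims,
                                   NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = pts.nrow();
  NumericVector out(n, NA_REAL);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
    if (!R_finite(x) || !R_finite(y) || !R_finite(z)) continue;
    if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 || z < 0 || z > nz - 1) continue;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) --i0;
    if (j0 == ny - 1) --j0;
    if (k0 == nz - 1) --k0;
    if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double acc = 0.0; bool ok = true;
    for (int di = 0; di < 2 && ok; ++di) for (int dj = 0; dj < 2 && ok; ++dj)
      for (int dk = 0; dk < 2 && ok; ++dk) {
        int ii = std::min(i0 + di, nx - 1), jj = std::min(j0 + dj, ny - 1),
            kk = std::min(k0 + dk, nz - 1);
        double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
        double v = vol[vox(ii, jj, kk, nx, ny)];
        if (!R_finite(v)) { if (w > 1e-12) ok = false; continue; }
        acc += w * v;
      }
    if (ok) out[p] = acc;
  }
  return out;
}

// Interpolate a 3-component vector field (world-mm components, stored per
// voxel, NA outside domain) at a voxel-coordinate point with NA-weight
// renormalization. Returns weight coverage in w.
static bool interp_vec(const NumericVector &gx, const NumericVector &gy,
                       const NumericVector &gz, int nx, int ny, int nz,
                       double x, double y, double z, double out[3], double &wtot) {
  wtot = 0.0; out[0] = out[1] = out[2] = 0.0;
  if (x < 0 || x > nx - 1 || y < 0 || y > ny - 1 || z < 0 || z > nz - 1) return false;
  int i0 = std::min((int)std::floor(x), nx - 2 >= 0 ? nx - 2 : 0);
  int j0 = std::min((int)std::floor(y), ny - 2 >= 0 ? ny - 2 : 0);
  int k0 = std::min((int)std::floor(z), nz - 2 >= 0 ? nz - 2 : 0);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  for (int di = 0; di < 2; ++di) for (int dj = 0; dj < 2; ++dj) for (int dk = 0; dk < 2; ++dk) {
    int ii = std::min(i0 + di, nx - 1), jj = std::min(j0 + dj, ny - 1),
        kk = std::min(k0 + dk, nz - 1);
    double w = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) * (dk ? fz : 1 - fz);
    R_xlen_t p = vox(ii, jj, kk, nx, ny);
    if (!R_finite(gx[p])) continue;
    wtot += w;
    out[0] += w * gx[p]; out[1] += w * gy[p]; out[2] += w * gz[p];
  }
  if (wtot < 0.25) return false;
  out[0] /= wtot; out[1] /= wtot; out[2] /= wtot;
  return true;
}

// Advect seed vertices along a unit vector field, emitting positions each
// time accumulated arc length crosses a target depth. starts: V x 3 world
// mm; ainv: 3 x 4 world->voxel affine; field components in world mm.
// Returns V x 3 x D positions and V x D validity flags.
// [[Rcpp::export]]
List trace_streamlines_cpp(NumericVector gx, NumericVector gy, NumericVector gz,
                           IntegerVector dims, NumericMatrix ainv,
                           NumericMatrix starts, NumericVector depths,
                           double step, int max_steps) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int V = starts.nrow(), D = depths.size();
  NumericVector pos(Dimension(V, 3, D));
  LogicalMatrix valid(V, D);
  std::fill(pos.begin(), pos.end(), NA_REAL);
  for (int v = 0; v < V; ++v) {
    double p[3] = {starts(v, 0), starts(v, 1), starts(v, 2)};
    double s = 0.0;
    int nextd = 0;
    bool alive = true;
    double last[3] = {p[0], p[1], p[2]};
    for (int st = 0; st < max_steps && nextd < D && alive; ++st) {
      double vxc[3];
      for (int r = 0; r < 3; ++r)
        vxc[r] = ainv(r, 0) * p[0] + ainv(r, 1) * p[1] + ainv(r, 2) * p[2] + ainv(r, 3);
      double dir[3], wtot;
      bool ok = interp_vec(gx, gy, gz, nx, ny, nz, vxc[0], vxc[1], vxc[2], dir, wtot);
      if (!ok && st == 0) {
        // seed on/outside the domain boundary: snap the sampling position to
        // the nearest in-domain voxel center within one voxel (the vertex
        // itself is not moved; arc length still starts at the seed)
        double best = 3.0; int bi = -1, bj = -1, bk = -1;
        int ci = (int)std::lround(vxc[0]), cj = (int)std::lround(vxc[1]),
            ck = (int)std::lround(vxc[2]);
        for (int di = -1; di <= 1; ++di) for (int dj = -1; dj <= 1; ++dj)
          for (int dk = -1; dk <= 1; ++dk) {
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
            if (!R_finite(gx[vox(ii, jj, kk, nx, ny)])) continue;
            double d2 = (vxc[0]-ii)*(vxc[0]-ii) + (vxc[1]-jj)*(vxc[1]-jj) +
                        (vxc[2]-kk)*(vxc[2]-kk);
            if (d2 < best) { best = d2; bi = ii; bj = jj; bk = kk; }
          }
        if (bi >= 0 && best <= 1.0) {
          vxc[0] = bi; vxc[1] = bj; vxc[2] = bk;
          ok = interp_vec(gx, gy, gz, nx, ny, nz, vxc[0], vxc[1], vxc[2], dir, wtot);
        }
      }
      if (!ok) { alive = false; break; }
      double nrm = std::sqrt(dir[0]*dir[0] + dir[1]*dir[1] + dir[2]*dir[2]);
      if (nrm < 1e-8) { alive = false; break; }
      double pn[3];
      for (int r = 0; r < 3; ++r) pn[r] = p[r] + step * dir[r] / nrm;
      double snew = s + step;
      while (nextd < D && snew >= depths[nextd]) {
        double f = (depths[nextd] - s) / step;
        for (int r = 0; r < 3; ++r) pos[v + (R_xlen_t)V * (r + 3 * nextd)] = p[r] + f * (pn[r] - p[r]);
        valid(v, nextd) = true;
        ++nextd;
      }
      for (int r = 0; r < 3; ++r) { last[r] = pn[r]; p[r] = pn[r]; }
      s = snew;
    }
    // clamp unreached depths at last valid position, invalid
    for (int d = nextd; d < D; ++d) {
      for (int r = 0; r < 3; ++r) pos[v + (R_xlen_t)V * (r + 3 * d)] = last[r];
      valid(v, d) = false;
    }
  }
  return List::create(_["positions"] = pos, _["valid"] = valid);
}
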