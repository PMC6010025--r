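// Compute kernels: 3x3x3 median, separable smoothing, connected-component
// labelling and region growth on voxel lattices; staggered-grid FDTD
// solvers (1D/2D/3D, 6th-order in space, split-field PML); axisymmetric
// Rayleigh quadrature for the spherical-cap source.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <algorithm>
#if defined(__SSE2__)
#include <xmmintrin.h>
#endif
using namespace Rcpp;

// Subnormal pressures in the decaying wavefront tail cripple FDTD
// throughput on x86; flush them to zero inside the solvers (restored on
// scope exit).
struct FlushDenormals {
#if defined(__SSE2__)
  unsigned int saved;
  FlushDenormals() : saved(_mm_getcsr()) { _mm_setcsr(saved | 0x8040); }
  ~FlushDenormals() { _mm_setcsr(saved); }
#else
  FlushDenormals() {}
#endif
};

// 6th-order staggered-grid first-derivative coefficients (sum of odd
// multiples equals 1: 75/64 - 3*25/384 + 5*3/640 = 1).
static const double C1 = 75.0 / 64.0;
static const double C2 = -25.0 / 384.0;
static const double C3 = 3.0 / 640.0;

static inline size_t idx3(int i, int j, int k, int nx, int ny) {
  return (size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * (size_t)k);
}

// [[Rcpp::export]]
NumericVector median3_cpp(NumericVector vol, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(vol.size());
  std::vector<double> buf(27);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int n = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          const int kk = std::min(std::max(k + dk, 0), nz - 1);
          for (int dj = -1; dj <= 1; ++dj) {
            const int jj = std::min(std::max(j + dj, 0), ny - 1);
            for (int di = -1; di <= 1; ++di) {
              const int ii = std::min(std::max(i + di, 0), nx - 1);
              buf[n++] = vol[idx3(ii, jj, kk, nx, ny)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + 13, buf.end());
        out[idx3(i, j, k, nx, ny)] = buf[13];
      }
    }
  }
  return out;
}

// Separable convolution along each axis with edge replication.
// kernels: list of 3 odd-length numeric vectors (pass length-1 c(1) to skip).
// [[Rcpp::export]]
NumericVector sep_conv3_cpp(NumericVector vol, IntegerVector dim, List kernels) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(vol.begin(), vol.end());
  std::vector<double> b(a.size());
  const int strides[3] = {1, nx, nx * ny};
  const int sizes[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    NumericVector ker = kernels[ax];
    const int kl = ker.size();
    if (kl == 1 && ker[0] == 1.0) continue;
    const int half = (kl - 1) / 2;
    const int n = sizes[ax], st = strides[ax];
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int pos[3] = {i, j, k};
          size_t base = idx3(i, j, k, nx, ny);
          double s = 0.0;
          for (int m = -half; m <= half; ++m) {
            int q = std::min(std::max(pos[ax] + m, 0), n - 1);
            s += ker[m + half] * a[base + (size_t)(q - pos[ax]) * st];
          }
          b[base] = s;
        }
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// 26-connected component labels (0 = background).
// [[Rcpp::export]]
IntegerVector label26_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  int cur = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < (size_t)mask.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      int i = v % nx, j = (v / nx) % ny, k = v / ((size_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        int kk = k + dk; if (kk < 0 || kk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = j + dj; if (jj < 0 || jj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int ii = i + di; if (ii < 0 || ii >= nx) continue;
            size_t w = idx3(ii, jj, kk, nx, ny);
            if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
          }
        }
      }
    }
  }
  return lab;
}

// Grow a 26-connected region of n_target voxels from the score maximum,
// always adding the highest-score frontier voxel (connected superlevel set).
// [[Rcpp::export]]
LogicalVector grow_connected_cpp(NumericVector score, LogicalVector mask,
                                 IntegerVector dim, int n_target) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(score.size(), false);
  if (n_target <= 0) return out;
  std::vector<char> seen(score.size(), 0);
  size_t best = 0; double bestv = -1e300; bool found = false;
  for (size_t s = 0; s < (size_t)score.size(); ++s)
    if (mask[s] && score[s] > bestv) { bestv = score[s]; best = s; found = true; }
  if (!found) return out;
  typedef std::pair<double, size_t> Node;
  std::priority_queue<Node> pq;
  pq.push(Node(bestv, best)); seen[best] = 1;
  int taken = 0;
  while (!pq.empty() && taken < n_target) {
    Node nd = pq.top(); pq.pop();
    size_t v = nd.second;
    out[v] = true; ++taken;
    int i = v % nx, j = (v / nx) % ny, k = v / ((size_t)nx * ny);
    for (int dk = -1; dk <= 1; ++dk) {
      int kk = k + dk; if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj; if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di; if (ii < 0 || ii >= nx) continue;
          size_t w = idx3(ii, jj, kk, nx, ny);
          if (mask[w] && !seen[w]) { seen[w] = 1; pq.push(Node(score[w], w)); }
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// FDTD helpers
// ---------------------------------------------------------------------------

static std::vector<double> pml_profile(int n, int pml_n, double dx,
                                       double cmax, double R0, double offset) {
  // cubic-graded absorption sigma(d) = smax*(d/L)^3, d measured into the layer
  std::vector<double> sig(n, 0.0);
  if (pml_n <= 0) return sig;
  const double L = pml_n * dx;
  const double smax = 4.0 * cmax * std::log(1.0 / R0) / (2.0 * L);
  for (int i = 0; i < n; ++i) {
    double x = i + offset;
    double d = 0.0;
    if (x < pml_n) d = pml_n - x;
    else if (x > n - 1 - pml_n) d = x - (n - 1 - pml_n);
    if (d > 0) {
      double r = d / pml_n; if (r > 1.0) r = 1.0;
      sig[i] = smax * r * r * r;
    }
  }
  return sig;
}

static inline double ramp_val(double t, double Tr) {
  if (Tr <= 0.0 || t >= Tr) return 1.0;
  return 0.5 * (1.0 - std::cos(M_PI * t / Tr));
}

// ---------------------------------------------------------------------------
// 1D FDTD: pressure/velocity leapfrog, 6th order in space, PML both ends.
// [[Rcpp::export]]
List fdtd1d_cpp(NumericVector rho, NumericVector cc, NumericVector alpha,
                double dx, double dt, int nsteps, double f0,
                IntegerVector src_idx, NumericVector src_amp, NumericVector src_phase,
                double amp0, double ramp_cycles,
                IntegerVector rec_idx, int avg_start, int pml_n, double pml_R0) {
  FlushDenormals ftz;
  const int n = rho.size();
  std::vector<double> kap(n), binv(n, 0.0), gam(n);
  double cmax = 0.0;
  for (int i = 0; i < n; ++i) {
    kap[i] = rho[i] * cc[i] * cc[i];
    gam[i] = 2.0 * alpha[i] * cc[i];
    if (cc[i] > cmax) cmax = cc[i];
  }
  for (int i = 0; i < n - 1; ++i) binv[i] = 0.5 * (1.0 / rho[i] + 1.0 / rho[i + 1]);
  std::vector<double> sigp = pml_profile(n, pml_n, dx, cmax, pml_R0, 0.0);
  std::vector<double> sigv = pml_profile(n, pml_n, dx, cmax, pml_R0, 0.5);
  std::vector<double> p(n, 0.0), v(n, 0.0);
  const int nrec = rec_idx.size();
  NumericMatrix rec(nsteps, std::max(nrec, 1));
  NumericVector psq(n, 0.0), pmax(n, 0.0);
  const double w0 = 2.0 * M_PI * f0, Tr = ramp_cycles / f0, inv_dx = 1.0 / dx;
  int navg = 0;
  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;
    for (int i = 2; i <= n - 4; ++i) {
      const double dp = (C1 * (p[i + 1] - p[i]) + C2 * (p[i + 2] - p[i - 1]) +
                         C3 * (p[i + 3] - p[i - 2])) * inv_dx;
      const double a = 0.5 * dt * sigv[i];
      v[i] = ((1.0 - a) * v[i] - dt * binv[i] * dp) / (1.0 + a);
    }
    for (int i = 3; i <= n - 4; ++i) {
      const double dv = (C1 * (v[i] - v[i - 1]) + C2 * (v[i + 1] - v[i - 2]) +
                         C3 * (v[i + 2] - v[i - 3])) * inv_dx;
      const double a = 0.5 * dt * (sigp[i] + gam[i]);
      p[i] = ((1.0 - a) * p[i] - dt * kap[i] * dv) / (1.0 + a);
    }
    const double rmp = ramp_val(t, Tr);
    for (int q = 0; q < src_idx.size(); ++q)
      p[src_idx[q]] += amp0 * src_amp[q] * rmp * std::sin(w0 * t + src_phase[q]);
    for (int q = 0; q < nrec; ++q) rec(s, q) = p[rec_idx[q]];
    if (s >= avg_start) {
      ++navg;
      for (int i = 0; i < n; ++i) {
        psq[i] += p[i] * p[i];
        if (std::fabs(p[i]) > pmax[i]) pmax[i] = std::fabs(p[i]);
      }
    }
    if (s % 200 == 0 && !R_finite(p[n / 2]))
      stop("FDTD diverged (non-finite pressure) at step %d", s);
  }
  if (navg > 0) for (int i = 0; i < n; ++i) psq[i] /= navg;
  return List::create(_["psq"] = psq, _["pmax"] = pmax, _["rec"] = rec,
                      _["navg"] = navg);
}

// ---------------------------------------------------------------------------
// 2D FDTD with split-field PML, optional quadratic (B/A) nonlinearity,
// per-element receiver averaging and interior energy trace.
// [[Rcpp::export]]
List fdtd2d_cpp(NumericMatrix rho, NumericMatrix cc, NumericMatrix alpha,
                double dx, double dt, int nsteps, double f0,
                IntegerVector src_idx, NumericVector src_amp, NumericVector src_phase,
                double amp0, double ramp_cycles,
                IntegerVector rec_idx, IntegerVector rec_elem, NumericVector rec_w,
                int n_elem,
                int avg_start, int pml_n, double pml_R0,
                bool nonlinear, NumericMatrix beta_nl, int energy_every,
                int src_stop_step) {
  FlushDenormals ftz;
  const int nx = rho.nrow(), nz = rho.ncol();
  const size_t N = (size_t)nx * nz;
  std::vector<double> kap(N), gam(N), binvx(N, 0.0), binvz(N, 0.0), cf(N, 0.0);
  double cmax = 0.0;
  for (size_t s = 0; s < N; ++s) {
    const double r = rho[s], c = cc[s];
    kap[s] = r * c * c;
    gam[s] = 2.0 * alpha[s] * c;
    if (nonlinear) cf[s] = beta_nl[s] / (r * c * c);
    if (c > cmax) cmax = c;
  }
  for (int j = 0; j < nz; ++j)
    for (int i = 0; i < nx - 1; ++i) {
      size_t s = i + (size_t)nx * j;
      binvx[s] = 0.5 * (1.0 / rho[s] + 1.0 / rho[s + 1]);
    }
  for (int j = 0; j < nz - 1; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t s = i + (size_t)nx * j;
      binvz[s] = 0.5 * (1.0 / rho[s] + 1.0 / rho[s + nx]);
    }
  std::vector<double> sigxp = pml_profile(nx, pml_n, dx, cmax, pml_R0, 0.0);
  std::vector<double> sigxv = pml_profile(nx, pml_n, dx, cmax, pml_R0, 0.5);
  std::vector<double> sigzp = pml_profile(nz, pml_n, dx, cmax, pml_R0, 0.0);
  std::vector<double> sigzv = pml_profile(nz, pml_n, dx, cmax, pml_R0, 0.5);
  std::vector<double> vx(N, 0.0), vz(N, 0.0), px(N, 0.0), pz(N, 0.0), pt(N, 0.0);

  const int nrec = rec_idx.size();
  std::vector<double> elem_wsum(std::max(n_elem, 1), 0.0);
  for (int q = 0; q < nrec; ++q) elem_wsum[rec_elem[q]] += rec_w[q];
  NumericMatrix rec(n_elem > 0 ? nsteps : 0, n_elem);
  std::vector<double> esum(std::max(n_elem, 1));

  NumericVector psq(N, 0.0), pmax(N, 0.0);
  std::vector<double> energy;
  const double w0 = 2.0 * M_PI * f0, Tr = ramp_cycles / f0, inv_dx = 1.0 / dx;
  const int em = pml_n + 6;  // energy bookkeeping region excludes the PML
  int navg = 0;

  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;
    // velocity update (t + dt/2)
    for (int j = 0; j < nz; ++j) {
      const size_t off = (size_t)nx * j;
      for (int i = 2; i <= nx - 4; ++i) {
        const size_t q = off + i;
        const double dp = (C1 * (pt[q + 1] - pt[q]) + C2 * (pt[q + 2] - pt[q - 1]) +
                           C3 * (pt[q + 3] - pt[q - 2])) * inv_dx;
        const double a = 0.5 * dt * sigxv[i];
        vx[q] = ((1.0 - a) * vx[q] - dt * binvx[q] * dp) / (1.0 + a);
      }
    }
    for (int j = 2; j <= nz - 4; ++j) {
      const size_t off = (size_t)nx * j;
      const double a = 0.5 * dt * sigzv[j];
      for (int i = 0; i < nx; ++i) {
        const size_t q = off + i;
        const double dp = (C1 * (pt[q + nx] - pt[q]) + C2 * (pt[q + 2 * (size_t)nx] - pt[q - nx]) +
                           C3 * (pt[q + 3 * (size_t)nx] - pt[q - 2 * (size_t)nx])) * inv_dx;
        vz[q] = ((1.0 - a) * vz[q] - dt * binvz[q] * dp) / (1.0 + a);
      }
    }
    // pressure update (t + dt)
    for (int j = 3; j <= nz - 4; ++j) {
      const size_t off = (size_t)nx * j;
      const double sz = sigzp[j];
      for (int i = 3; i <= nx - 4; ++i) {
        const size_t q = off + i;
        const double dvx = (C1 * (vx[q] - vx[q - 1]) + C2 * (vx[q + 1] - vx[q - 2]) +
                            C3 * (vx[q + 2] - vx[q - 3])) * inv_dx;
        const double dvz = (C1 * (vz[q] - vz[q - nx]) + C2 * (vz[q + nx] - vz[q - 2 * (size_t)nx]) +
                            C3 * (vz[q + 2 * (size_t)nx] - vz[q - 3 * (size_t)nx])) * inv_dx;
        double k = kap[q];
        if (nonlinear) k *= 1.0 + cf[q] * pt[q];
        // each split component carries the full loss rate so p = px + pz
        // decays at gamma = 2*alpha*c (plane-wave decay alpha at f0)
        const double ax = 0.5 * dt * (sigxp[i] + gam[q]);
        const double az = 0.5 * dt * (sz + gam[q]);
        px[q] = ((1.0 - ax) * px[q] - dt * k * dvx) / (1.0 + ax);
        pz[q] = ((1.0 - az) * pz[q] - dt * k * dvz) / (1.0 + az);
        pt[q] = px[q] + pz[q];
      }
    }
    if (src_stop_step <= 0 || s < src_stop_step) {
      const double rmp = ramp_val(t, Tr);
      for (int q = 0; q < src_idx.size(); ++q) {
        const double val = amp0 * src_amp[q] * rmp * std::sin(w0 * t + src_phase[q]);
        const size_t ix = src_idx[q];
        px[ix] += 0.5 * val; pz[ix] += 0.5 * val; pt[ix] = px[ix] + pz[ix];
      }
    }
    if (n_elem > 0) {
      std::fill(esum.begin(), esum.end(), 0.0);
      for (int q = 0; q < nrec; ++q) esum[rec_elem[q]] += rec_w[q] * pt[rec_idx[q]];
      for (int e = 0; e < n_elem; ++e)
        rec(s, e) = elem_wsum[e] > 0 ? esum[e] / elem_wsum[e] : 0.0;
    }
    if (s >= avg_start) {
      ++navg;
      for (size_t q = 0; q < N; ++q) {
        psq[q] += pt[q] * pt[q];
        if (std::fabs(pt[q]) > pmax[q]) pmax[q] = std::fabs(pt[q]);
      }
    }
    if (energy_every > 0 && s % energy_every == 0) {
      double E = 0.0;
      for (int j = em; j < nz - em; ++j)
        for (int i = em; i < nx - em; ++i) {
          const size_t q = i + (size_t)nx * j;
          E += pt[q] * pt[q] / (2.0 * kap[q]) +
               0.5 * rho[q] * (vx[q] * vx[q] + vz[q] * vz[q]);
        }
      energy.push_back(E * dx * dx);
    }
    if (s % 200 == 0 && !R_finite(pt[N / 2]))
      stop("FDTD diverged (non-finite pressure) at step %d", s);
  }
  if (navg > 0) for (size_t q = 0; q < N; ++q) psq[q] /= navg;
  psq.attr("dim") = IntegerVector::create(nx, nz);
  pmax.attr("dim") = IntegerVector::create(nx, nz);
  return List::create(_["psq"] = psq, _["pmax"] = pmax, _["rec"] = rec,
                      _["energy"] = NumericVector(energy.begin(), energy.end()),
                      _["navg"] = navg);
}

// ---------------------------------------------------------------------------
// 3D FDTD (linear or quadratic-nonlinear), split-field PML.
// [[Rcpp::export]]
List fdtd3d_cpp(NumericVector rho, NumericVector cc, NumericVector alpha,
                IntegerVector dim, double dx, double dt, int nsteps, double f0,
                IntegerVector src_idx, NumericVector src_amp, NumericVector src_phase,
                double amp0, double ramp_cycles,
                IntegerVector rec_idx, IntegerVector rec_elem, NumericVector rec_w,
                int n_elem,
                int avg_start, int pml_n, double pml_R0,
                bool nonlinear, NumericVector beta_nl) {
  FlushDenormals ftz;
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t N = (size_t)nx * ny * nz, sy = nx, sz = (size_t)nx * ny;
  std::vector<double> kap(N), gam(N), binvx(N, 0.0), binvy(N, 0.0), binvz(N, 0.0), cf(N, 0.0);
  double cmax = 0.0;
  for (size_t s = 0; s < N; ++s) {
    const double r = rho[s], c = cc[s];
    kap[s] = r * c * c;
    gam[s] = 2.0 * alpha[s] * c;
    if (nonlinear) cf[s] = beta_nl[s] / (r * c * c);
    if (c > cmax) cmax = c;
  }
  for (size_t s = 0; s < N; ++s) {
    int i = s % nx, j = (s / nx) % ny, k = s / sz;
    if (i < nx - 1) binvx[s] = 0.5 * (1.0 / rho[s] + 1.0 / rho[s + 1]);
    if (j < ny - 1) binvy[s] = 0.5 * (1.0 / rho[s] + 1.0 / rho[s + sy]);
    if (k < nz - 1) binvz[s] = 0.5 * (1.0 / rho[s] + 1.0 / rho[s + sz]);
  }
  std::vector<double> sxp = pml_profile(nx, pml_n, dx, cmax, pml_R0, 0.0);
  std::vector<double> sxv = pml_profile(nx, pml_n, dx, cmax, pml_R0, 0.5);
  std::vector<double> syp = pml_profile(ny, pml_n, dx, cmax, pml_R0, 0.0);
  std::vector<double> syv = pml_profile(ny, pml_n, dx, cmax, pml_R0, 0.5);
  std::vector<double> szp = pml_profile(nz, pml_n, dx, cmax, pml_R0, 0.0);
  std::vector<double> szv = pml_profile(nz, pml_n, dx, cmax, pml_R0, 0.5);
  std::vector<double> vx(N, 0.0), vy(N, 0.0), vz(N, 0.0),
      p1(N, 0.0), p2(N, 0.0), p3(N, 0.0), pt(N, 0.0);
  const int nrec = rec_idx.size();
  std::vector<double> elem_wsum(std::max(n_elem, 1), 0.0);
  for (int q = 0; q < nrec; ++q) elem_wsum[rec_elem[q]] += rec_w[q];
  NumericMatrix rec(n_elem > 0 ? nsteps : 0, n_elem);
  std::vector<double> esum(std::max(n_elem, 1));
  NumericVector psq(N, 0.0), pmax(N, 0.0);
  const double w0 = 2.0 * M_PI * f0, Tr = ramp_cycles / f0, inv_dx = 1.0 / dx;
  int navg = 0;
  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const size_t off = (size_t)nx * j + sz * k;
        for (int i = 2; i <= nx - 4; ++i) {
          const size_t q = off + i;
          const double dp = (C1 * (pt[q + 1] - pt[q]) + C2 * (pt[q + 2] - pt[q - 1]) +
                             C3 * (pt[q + 3] - pt[q - 2])) * inv_dx;
          const double a = 0.5 * dt * sxv[i];
          vx[q] = ((1.0 - a) * vx[q] - dt * binvx[q] * dp) / (1.0 + a);
        }
      }
    for (int k = 0; k < nz; ++k)
      for (int j = 2; j <= ny - 4; ++j) {
        const size_t off = (size_t)nx * j + sz * k;
        const double a = 0.5 * dt * syv[j];
        for (int i = 0; i < nx; ++i) {
          const size_t q = off + i;
          const double dp = (C1 * (pt[q + sy] - pt[q]) + C2 * (pt[q + 2 * sy] - pt[q - sy]) +
                             C3 * (pt[q + 3 * sy] - pt[q - 2 * sy])) * inv_dx;
          vy[q] = ((1.0 - a) * vy[q] - dt * binvy[q] * dp) / (1.0 + a);
        }
      }
    for (int k = 2; k <= nz - 4; ++k)
      for (int j = 0; j < ny; ++j) {
        const size_t off = (size_t)nx * j + sz * k;
        const double a = 0.5 * dt * szv[k];
        for (int i = 0; i < nx; ++i) {
          const size_t q = off + i;
          const double dp = (C1 * (pt[q + sz] - pt[q]) + C2 * (pt[q + 2 * sz] - pt[q - sz]) +
                             C3 * (pt[q + 3 * sz] - pt[q - 2 * sz])) * inv_dx;
          vz[q] = ((1.0 - a) * vz[q] - dt * binvz[q] * dp) / (1.0 + a);
        }
      }
    for (int k = 3; k <= nz - 4; ++k)
      for (int j = 3; j <= ny - 4; ++j) {
        const size_t off = (size_t)nx * j + sz * k;
        for (int i = 3; i <= nx - 4; ++i) {
          const size_t q = off + i;
          const double dvx = (C1 * (vx[q] - vx[q - 1]) + C2 * (vx[q + 1] - vx[q - 2]) +
                              C3 * (vx[q + 2] - vx[q - 3])) * inv_dx;
          const double dvy = (C1 * (vy[q] - vy[q - sy]) + C2 * (vy[q + sy] - vy[q - 2 * sy]) +
                              C3 * (vy[q + 2 * sy] - vy[q - 3 * sy])) * inv_dx;
          const double dvz = (C1 * (vz[q] - vz[q - sz]) + C2 * (vz[q + sz] - vz[q - 2 * sz]) +
                              C3 * (vz[q + 2 * sz] - vz[q - 3 * sz])) * inv_dx;
          double kp = kap[q];
          if (nonlinear) kp *= 1.0 + cf[q] * pt[q];
          const double a1 = 0.5 * dt * (sxp[i] + gam[q]);
          const double a2 = 0.5 * dt * (syp[j] + gam[q]);
          const double a3 = 0.5 * dt * (szp[k] + gam[q]);
          p1[q] = ((1.0 - a1) * p1[q] - dt * kp * dvx) / (1.0 + a1);
          p2[q] = ((1.0 - a2) * p2[q] - dt * kp * dvy) / (1.0 + a2);
          p3[q] = ((1.0 - a3) * p3[q] - dt * kp * dvz) / (1.0 + a3);
          pt[q] = p1[q] + p2[q] + p3[q];
        }
      }
    const double rmp = ramp_val(t, Tr);
    for (int q = 0; q < src_idx.size(); ++q) {
      const double val = amp0 * src_amp[q] * rmp * std::sin(w0 * t + src_phase[q]);
      const size_t ix = src_idx[q];
      p1[ix] += val / 3.0; p2[ix] += val / 3.0; p3[ix] += val / 3.0;
      pt[ix] = p1[ix] + p2[ix] + p3[ix];
    }
    if (n_elem > 0) {
      std::fill(esum.begin(), esum.end(), 0.0);
      for (int q = 0; q < nrec; ++q) esum[rec_elem[q]] += rec_w[q] * pt[rec_idx[q]];
      for (int e = 0; e < n_elem; ++e)
        rec(s, e) = elem_wsum[e] > 0 ? esum[e] / elem_wsum[e] : 0.0;
    }
    if (s >= avg_start) {
      ++navg;
      for (size_t q = 0; q < N; ++q) {
        psq[q] += pt[q] * pt[q];
        if (std::fabs(pt[q]) > pmax[q]) pmax[q] = std::fabs(pt[q]);
      }
    }
    if (s % 100 == 0 && !R_finite(pt[N / 2]))
      stop("FDTD diverged (non-finite pressure) at step %d", s);
  }
  if (navg > 0) for (size_t q = 0; q < N; ++q) psq[q] /= navg;
  psq.attr("dim") = dim;
  pmax.attr("dim") = dim;
  return List::create(_["psq"] = psq, _["pmax"] = pmax, _["rec"] = rec,
                      _["navg"] = navg);
}

// ---------------------------------------------------------------------------
// Axisymmetric Rayleigh quadrature over a spherical-cap band.
// Focus at the origin; surface points at distance R (polar angle theta from
// the beam axis, the cap behind the focus at z = -R*cos(theta)). Observation
// points (robs, zobs) in the focal half-plane. Returns sum of
// exp(i k d)/d dS (constant prefactors dropped; the field is used in ratios
// or normalized comparisons).
// [[Rcpp::export]]
ComplexVector rayleigh_cap_cpp(NumericVector robs, NumericVector zobs,
                               double R, double th0, double th1,
                               int ntheta, int npsi, double k) {
  const int nobs = robs.size();
  ComplexVector out(nobs);
  std::vector<double> sth(ntheta), cth(ntheta), wth(ntheta);
  const double dth = (th1 - th0) / ntheta;
  for (int m = 0; m < ntheta; ++m) {
    const double th = th0 + (m + 0.5) * dth;
    sth[m] = std::sin(th); cth[m] = std::cos(th);
    wth[m] = R * R * sth[m] * dth;  // dS / dpsi
  }
  std::vector<double> cpsi(npsi);
  const double dpsi = 2.0 * M_PI / npsi;
  for (int q = 0; q < npsi; ++q) cpsi[q] = std::cos((q + 0.5) * dpsi);
  for (int o = 0; o < nobs; ++o) {
    const double r = robs[o], z = zobs[o];
    double sre = 0.0, sim = 0.0;
    for (int m = 0; m < ntheta; ++m) {
      const double A = r * r + z * z + R * R + 2.0 * z * R * cth[m];
      const double B = 2.0 * r * R * sth[m];
      const double w = wth[m] * dpsi;
      if (B == 0.0) {
        const double d = std::sqrt(A);
        sre += npsi * w * std::cos(k * d) / d;
        sim += npsi * w * std::sin(k * d) / d;
      } else {
        for (int q = 0; q < npsi; ++q) {
          const double d = std::sqrt(A - B * cpsi[q]);
          sre += w * std::cos(k * d) / d;
          sim += w * std::sin(k * d) / d;
        }
      }
    }
    out[o].r = sre; out[o].i = sim;
  }
  return out;
}
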