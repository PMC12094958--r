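#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cmath>
#include <algorithm>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Tensors are R arrays in column-major order with dim (nx, ny, nz, C):
// linear index x + nx*(y + ny*(z + nz*c)). Each channel is a contiguous
// nx*ny*nz block, so convolutions are implemented as shift-and-accumulate
// passes over contiguous x-runs.

// ---------------------------------------------------------------------------
// Dense 3D convolution, odd kernel k, stride 1, zero ("same") padding.
// w has dim (k, k, k, cin, cout); b has length cout. Implemented as
// z-slab-blocked im2col + BLAS dgemm so the arithmetic runs at GEMM speed
// and the scratch stays bounded.

// fill the im2col block for output slices [z0, z1): rows are output voxels
// (x fastest), columns are (kx, ky, kz, ci) in the weight-flattening order
static void im2col_block(const double* px, int nx, int ny, int nz, int cin,
                         int k, int z0, int z1, std::vector<double>& col) {
  const int r = k / 2;
  const size_t plane = (size_t)nx * ny;
  const size_t vol = plane * nz;
  const int bz = z1 - z0;
  const size_t m = plane * bz;
  col.assign(m * (size_t)k * k * k * cin, 0.0);
  size_t j = 0;
  for (int ci = 0; ci < cin; ++ci) {
    const double* ichan = px + vol * ci;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx, ++j) {
          // note: weight index (kx,ky,kz,ci) is kx + k*(ky + k*(kz + k*ci)),
          // so j must advance kx fastest — reorder the loop accordingly
          const int dx = kx - r, dy = ky - r, dz = kz - r;
          double* cj = col.data() + m * ((size_t)kx + k * ((size_t)ky +
                        k * ((size_t)kz + (size_t)k * ci)));
          const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          const int len = x1 - x0;
          if (len <= 0) continue;
          for (int z = z0; z < z1; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= ny) continue;
              double* dst = cj + x0 + (size_t)nx * (y + (size_t)ny * (z - z0));
              const double* src = ichan + (x0 + dx) +
                (size_t)nx * (sy + (size_t)ny * sz);
              std::copy(src, src + len, dst);
            }
          }
        }
  }
}

static int slab_height(int nx, int ny, int k, int cin) {
  // keep the im2col scratch around <= 32 MB
  const double rowBytes = 8.0 * nx * ny * k * k * k * cin;
  int bz = (int)(32.0e6 / rowBytes);
  return std::max(1, bz);
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector dims,
                             NumericVector w, NumericVector b, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int cout = b.size();
  const int K = k * k * k * cin;
  const size_t plane = (size_t)nx * ny;
  const size_t vol = plane * nz;
  NumericVector out(vol * cout);
  double* po = REAL(out);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  for (int co = 0; co < cout; ++co)
    std::fill(po + vol * co, po + vol * (co + 1), (double)b[co]);
  const int bzmax = slab_height(nx, ny, k, cin);
  std::vector<double> col;
  std::vector<double> obuf;
  const double one = 1.0;
  for (int z0 = 0; z0 < nz; z0 += bzmax) {
    const int z1 = std::min(nz, z0 + bzmax);
    im2col_block(px, nx, ny, nz, cin, k, z0, z1, col);
    const int m = (int)(plane * (z1 - z0));
    obuf.assign((size_t)m * cout, 0.0);
    F77_CALL(dgemm)("N", "N", &m, &cout, &K, &one, col.data(), &m,
                    pw, &K, &one, obuf.data(), &m FCONE FCONE);
    for (int co = 0; co < cout; ++co) {
      double* dst = po + vol * co + plane * z0;
      const double* src = obuf.data() + (size_t)m * co;
      for (int i = 0; i < m; ++i) dst[i] += src[i];
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector dims,
                    NumericVector w, NumericVector gout, int k, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int r = k / 2;
  const int K = k * k * k * cin;
  const size_t plane = (size_t)nx * ny;
  const size_t vol = plane * nz;
  NumericVector gx(vol * cin), gw((size_t)K * cout), gb(cout);
  double* pgx = REAL(gx);
  double* pgw = REAL(gw);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  const double* pgo = REAL(gout);
  for (int co = 0; co < cout; ++co) {
    const double* g = pgo + vol * co;
    double acc = 0.0;
    for (size_t i = 0; i < vol; ++i) acc += g[i];
    gb[co] = acc;
  }
  const int bzmax = slab_height(nx, ny, k, cin);
  std::vector<double> col, gbuf, gcol;
  const double one = 1.0, zero = 0.0;
  for (int z0 = 0; z0 < nz; z0 += bzmax) {
    const int z1 = std::min(nz, z0 + bzmax);
    const int bz = z1 - z0;
    const int m = (int)(plane * bz);
    im2col_block(px, nx, ny, nz, cin, k, z0, z1, col);
    // gather this slab's output gradient into an (m x cout) block
    gbuf.resize((size_t)m * cout);
    for (int co = 0; co < cout; ++co)
      std::copy(pgo + vol * co + plane * z0,
                pgo + vol * co + plane * z0 + m,
                gbuf.data() + (size_t)m * co);
    // gw += col^T %*% gout_slab
    F77_CALL(dgemm)("T", "N", &K, &cout, &m, &one, col.data(), &m,
                    gbuf.data(), &m, &one, pgw, &K FCONE FCONE);
    // gcol = gout_slab %*% w^T, then scatter (col2im) into gx
    gcol.assign((size_t)m * K, 0.0);
    F77_CALL(dgemm)("N", "T", &m, &K, &cout, &one, gbuf.data(), &m,
                    pw, &K, &zero, gcol.data(), &m FCONE FCONE);
    size_t j = 0;
    for (int ci = 0; ci < cin; ++ci) {
      double* gchan = pgx + vol * ci;
      for (int kz = 0; kz < k; ++kz)
        for (int ky = 0; ky < k; ++ky)
          for (int kx = 0; kx < k; ++kx, ++j) {
            const int dx = kx - r, dy = ky - r, dz = kz - r;
            const double* cj = gcol.data() + (size_t)m *
              ((size_t)kx + k * ((size_t)ky + k * ((size_t)kz +
                (size_t)k * ci)));
            const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
            const int len = x1 - x0;
            if (len <= 0) continue;
            for (int z = z0; z < z1; ++z) {
              const int sz = z + dz;
              if (sz < 0 || sz >= nz) continue;
              for (int y = 0; y < ny; ++y) {
                const int sy = y + dy;
                if (sy < 0 || sy >= ny) continue;
                const double* src = cj + x0 +
                  (size_t)nx * (y + (size_t)ny * (z - z0));
                double* dst = gchan + (x0 + dx) +
                  (size_t)nx * (sy + (size_t)ny * sz);
                for (int i = 0; i < len; ++i) dst[i] += src[i];
              }
            }
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Depthwise 3D convolution, odd kernel k, stride 1, "same" padding.
// w has dim (k, k, k, C); b has length C.

// [[Rcpp::export]]
NumericVector dwconv3d_fwd_cpp(NumericVector x, IntegerVector dims,
                               NumericVector w, NumericVector b, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int r = k / 2;
  const size_t vol = (size_t)nx * ny * nz;
  NumericVector out(vol * nc);
  double* po = REAL(out);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  for (int c = 0; c < nc; ++c) {
    double* ochan = po + vol * c;
    const double bc = b[c];
    for (size_t i = 0; i < vol; ++i) ochan[i] = bc;
    const double* ichan = px + vol * c;
    const double* wbase = pw + (size_t)k * k * k * c;
    for (int dz = -r; dz <= r; ++dz)
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx) {
          const double wv = wbase[(dx + r) + k * ((dy + r) + k * (dz + r))];
          const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
          const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
          const int len = x1 - x0;
          if (len <= 0) continue;
          for (int z = z0; z < z1; ++z)
            for (int y = y0; y < y1; ++y) {
              double* o = ochan + x0 + (size_t)nx * (y + (size_t)ny * z);
              const double* in = ichan + (x0 + dx) +
                (size_t)nx * ((y + dy) + (size_t)ny * (z + dz));
              for (int i = 0; i < len; ++i) o[i] += wv * in[i];
            }
        }
  }
  return out;
}

// [[Rcpp::export]]
List dwconv3d_bwd_cpp(NumericVector x, IntegerVector dims,
                      NumericVector w, NumericVector gout, int k) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int r = k / 2;
  const size_t vol = (size_t)nx * ny * nz;
  NumericVector gx(vol * nc), gw((size_t)k * k * k * nc), gb(nc);
  double* pgx = REAL(gx);
  double* pgw = REAL(gw);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  const double* pgo = REAL(gout);
  for (int c = 0; c < nc; ++c) {
    const double* gchan = pgo + vol * c;
    const double* ichan = px + vol * c;
    double* gxchan = pgx + vol * c;
    double bacc = 0.0;
    for (size_t i = 0; i < vol; ++i) bacc += gchan[i];
    gb[c] = bacc;
    const size_t wb = (size_t)k * k * k * c;
    for (int dz = -r; dz <= r; ++dz)
      for (int dy = -r; dy <= r; ++dy)
        for (int dx = -r; dx <= r; ++dx) {
          const size_t wi = wb + (dx + r) + k * ((dy + r) + k * (dz + r));
          const double wv = pw[wi];
          const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
          const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
          const int len = x1 - x0;
          if (len <= 0) continue;
          double wacc = 0.0;
          for (int z = z0; z < z1; ++z)
            for (int y = y0; y < y1; ++y) {
              const double* g = gchan + x0 + (size_t)nx * (y + (size_t)ny * z);
              const size_t off = (x0 + dx) +
                (size_t)nx * ((y + dy) + (size_t)ny * (z + dz));
              const double* in = ichan + off;
              double* gxp = gxchan + off;
              for (int i = 0; i < len; ++i) {
                gxp[i] += wv * g[i];
                wacc += in[i] * g[i];
              }
            }
          pgw[wi] += wacc;
        }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Strided downsampling convolution: kernel 2, stride 2, no padding.
// Input dims must be even. w has dim (2, 2, 2, cin, cout).

// [[Rcpp::export]]
NumericVector downconv3d_fwd_cpp(NumericVector x, IntegerVector dims,
                                 NumericVector w, NumericVector b) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int cout = b.size();
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const size_t vin = (size_t)nx * ny * nz, vout = (size_t)ox * oy * oz;
  NumericVector out(vout * cout);
  double* po = REAL(out);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  for (int co = 0; co < cout; ++co) {
    double* o = po + vout * co;
    const double bc = b[co];
    for (size_t i = 0; i < vout; ++i) o[i] = bc;
  }
  for (int co = 0; co < cout; ++co) {
    double* ochan = po + vout * co;
    for (int ci = 0; ci < cin; ++ci) {
      const double* ichan = px + vin * ci;
      const double* wbase = pw + 8 * ((size_t)ci + (size_t)cin * co);
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const double wv = wbase[dx + 2 * (dy + 2 * dz)];
            for (int z = 0; z < oz; ++z)
              for (int y = 0; y < oy; ++y) {
                double* o = ochan + (size_t)ox * (y + (size_t)oy * z);
                const double* in = ichan + dx +
                  (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz));
                for (int i = 0; i < ox; ++i) o[i] += wv * in[2 * i];
              }
          }
    }
  }
  return out;
}

// [[Rcpp::export]]
List downconv3d_bwd_cpp(NumericVector x, IntegerVector dims,
                        NumericVector w, NumericVector gout, int cout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], cin = dims[3];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const size_t vin = (size_t)nx * ny * nz, vout = (size_t)ox * oy * oz;
  NumericVector gx(vin * cin), gw(8 * (size_t)cin * cout), gb(cout);
  double* pgx = REAL(gx);
  double* pgw = REAL(gw);
  const double* px = REAL(x);
  const double* pw = REAL(w);
  const double* pgo = REAL(gout);
  for (int co = 0; co < cout; ++co) {
    const double* g = pgo + vout * co;
    double acc = 0.0;
    for (size_t i = 0; i < vout; ++i) acc += g[i];
    gb[co] = acc;
  }
  for (int co = 0; co < cout; ++co) {
    const double* gchan = pgo + vout * co;
    for (int ci = 0; ci < cin; ++ci) {
      const double* ichan = px + vin * ci;
      double* gxchan = pgx + vin * ci;
      const size_t wb = 8 * ((size_t)ci + (size_t)cin * co);
      for (int dz = 0; dz < 2; ++dz)
        for (int dy = 0; dy < 2; ++dy)
          for (int dx = 0; dx < 2; ++dx) {
            const size_t wi = wb + dx + 2 * (dy + 2 * dz);
            const double wv = pw[wi];
            double wacc = 0.0;
            for (int z = 0; z < oz; ++z)
              for (int y = 0; y < oy; ++y) {
                const double* g = gchan + (size_t)ox * (y + (size_t)oy * z);
                const size_t off = dx +
                  (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz));
                const double* in = ichan + off;
                double* gxp = gxchan + off;
                for (int i = 0; i < ox; ++i) {
                  gxp[2 * i] += wv * g[i];
                  wacc += in[2 * i] * g[i];
                }
              }
            pgw[wi] += wacc;
          }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Nearest-neighbour 2x upsampling.

// [[Rcpp::export]]
NumericVector upsample2_fwd_cpp(NumericVector x, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const size_t vin = (size_t)nx * ny * nz, vout = (size_t)ox * oy * oz;
  NumericVector out(vout * nc);
  double* po = REAL(out);
  const double* px = REAL(x);
  for (int c = 0; c < nc; ++c) {
    const double* ichan = px + vin * c;
    double* ochan = po + vout * c;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y) {
        const double* in = ichan + (size_t)nx * ((y / 2) + (size_t)ny * (z / 2));
        double* o = ochan + (size_t)ox * (y + (size_t)oy * z);
        for (int i = 0; i < ox; ++i) o[i] = in[i / 2];
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd_cpp(NumericVector gout, IntegerVector dims) {
  // dims are the *input* (coarse) dims of the forward pass
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const size_t vin = (size_t)nx * ny * nz, vout = (size_t)ox * oy * oz;
  NumericVector gx(vin * nc);
  double* pgx = REAL(gx);
  const double* pgo = REAL(gout);
  for (int c = 0; c < nc; ++c) {
    double* gchan = pgx + vin * c;
    const double* ochan = pgo + vout * c;
    for (int z = 0; z < oz; ++z)
      for (int y = 0; y < oy; ++y) {
        double* g = gchan + (size_t)nx * ((y / 2) + (size_t)ny * (z / 2));
        const double* o = ochan + (size_t)ox * (y + (size_t)oy * z);
        for (int i = 0; i < ox; ++i) g[i / 2] += o[i];
      }
  }
  return gx;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary 3D mask (6- or 26-connectivity).
// Returns integer labels 1..n in first-encounter order (deterministic).

// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t vol = (size_t)nx * ny * nz;
  IntegerVector lab(vol);
  std::vector<int> offs_x, offs_y, offs_z;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs_x.push_back(dx); offs_y.push_back(dy); offs_z.push_back(dz);
      }
  const int nn = offs_x.size();
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < vol; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t cur = stack.back();
      stack.pop_back();
      const int cx = cur % nx;
      const int cy = (cur / nx) % ny;
      const int cz = cur / ((size_t)nx * ny);
      for (int j = 0; j < nn; ++j) {
        const int px = cx + offs_x[j], py = cy + offs_y[j], pz = cz + offs_z[j];
        if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
          continue;
        const size_t q = px + (size_t)nx * (py + (size_t)ny * pz);
        if (mask[q] != 0 && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// For each point (row) in a, the minimum Euclidean distance to any row of b.
// Coordinates are already in physical units.

// [[Rcpp::export]]
NumericVector min_distances_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
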