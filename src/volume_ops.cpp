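#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <queue>
#include <vector>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx); linear index z + nz*(y + ny*x).

static inline int reflect(int i, int n) {
    // symmetric (edge-inclusive) reflection: -1 -> 0, -2 -> 1, n -> n-1
    while (i < 0 || i >= n) {
        if (i < 0) i = -i - 1;
        if (i >= n) i = 2 * n - 1 - i;
    }
    return i;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(const NumericVector& vol, const IntegerVector& dim,
                           int window) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const int r = window / 2;
    const int wn = window * window * window;
    NumericVector out(vol.size());
    std::vector<double> buf(wn);
    for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
            for (int z = 0; z < nz; ++z) {
                int k = 0;
                for (int dx = -r; dx <= r; ++dx) {
                    const int xx = reflect(x + dx, nx);
                    for (int dy = -r; dy <= r; ++dy) {
                        const int yy = reflect(y + dy, ny);
                        const long base = (long)nz * (yy + (long)ny * xx);
                        for (int dz = -r; dz <= r; ++dz)
                            buf[k++] = vol[reflect(z + dz, nz) + base];
                    }
                }
                std::nth_element(buf.begin(), buf.begin() + wn / 2,
                                 buf.begin() + wn);
                out[z + (long)nz * (y + (long)ny * x)] = buf[wn / 2];
            }
    return out;
}

static void conv_axis(const std::vector<double>& in, std::vector<double>& out,
                      int nz, int ny, int nx, int axis,
                      const std::vector<double>& kern) {
    const int r = (int)kern.size() / 2;
    const int n[3] = {nz, ny, nx};
    for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
            for (int z = 0; z < nz; ++z) {
                double acc = 0.0;
                for (int d = -r; d <= r; ++d) {
                    int zz = z, yy = y, xx = x;
                    if (axis == 0) zz = reflect(z + d, n[0]);
                    else if (axis == 1) yy = reflect(y + d, n[1]);
                    else xx = reflect(x + d, n[2]);
                    acc += kern[d + r] * in[zz + (long)nz * (yy + (long)ny * xx)];
                }
                out[z + (long)nz * (y + (long)ny * x)] = acc;
            }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(const NumericVector& vol, const IntegerVector& dim,
                          const NumericVector& kernel) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    std::vector<double> a(vol.begin(), vol.end()), b(vol.size());
    std::vector<double> k(kernel.begin(), kernel.end());
    conv_axis(a, b, nz, ny, nx, 0, k);
    conv_axis(b, a, nz, ny, nx, 1, k);
    conv_axis(a, b, nz, ny, nx, 2, k);
    return NumericVector(b.begin(), b.end());
}

// Flat erosion; out-of-bounds neighbors are ignored (treated as +Inf).
// offsets: n x 3 integer matrix of (dz, dy, dx). Interior voxels take a
// precomputed-linear-offset fast path; the border falls back to checks.
// [[Rcpp::export]]
NumericVector cpp_erode3d(const NumericVector& vol, const IntegerVector& dim,
                          const IntegerMatrix& offsets) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    const int no = offsets.nrow();
    NumericVector out(vol.size());
    int rz = 0, ry = 0, rx = 0;
    std::vector<long> loff(no);
    std::vector<int> dz(no), dy(no), dx(no);
    for (int o = 0; o < no; ++o) {
        dz[o] = offsets(o, 0); dy[o] = offsets(o, 1); dx[o] = offsets(o, 2);
        rz = std::max(rz, std::abs(dz[o]));
        ry = std::max(ry, std::abs(dy[o]));
        rx = std::max(rx, std::abs(dx[o]));
        loff[o] = dz[o] + (long)nz * (dy[o] + (long)ny * dx[o]);
    }
    const double* v = &vol[0];
    for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y) {
            const bool yx_inner = (x >= rx && x < nx - rx &&
                                   y >= ry && y < ny - ry);
            const long row = (long)nz * (y + (long)ny * x);
            for (int z = 0; z < nz; ++z) {
                double m = R_PosInf;
                const long i = z + row;
                if (yx_inner && z >= rz && z < nz - rz) {
                    for (int o = 0; o < no; ++o) {
                        const double w = v[i + loff[o]];
                        if (w < m) m = w;
                    }
                } else {
                    for (int o = 0; o < no; ++o) {
                        const int zz = z + dz[o], yy = y + dy[o],
                                  xx = x + dx[o];
                        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                            xx < 0 || xx >= nx) continue;
                        const double w = v[zz + (long)nz * (yy + (long)ny * xx)];
                        if (w < m) m = w;
                    }
                }
                out[i] = m;
            }
        }
    return out;
}

static std::vector<std::array<int, 3>> neigh_offsets(int connectivity) {
    std::vector<std::array<int, 3>> off;
    for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
                const int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (s == 0) continue;
                if (connectivity == 6 && s > 1) continue;
                if (connectivity == 18 && s > 2) continue;
                off.push_back({dz, dy, dx});
            }
    return off;
}

// Grayscale reconstruction by dilation (Vincent's hybrid algorithm): one
// forward and one backward raster scan of the conditional dilation
// marker <- min(mask, dilate(marker)), then FIFO propagation from the
// pixels still able to flood a neighbor. Equivalent to iterating the
// conditional dilation to its fixed point.
// [[Rcpp::export]]
NumericVector cpp_reconstruct3d(const NumericVector& marker,
                                const NumericVector& mask,
                                const IntegerVector& dim, int connectivity) {
    const int nz = dim[0], ny = dim[1], nx = dim[2];
    std::vector<double> m(marker.begin(), marker.end());
    const auto all = neigh_offsets(connectivity);
    std::vector<std::array<int, 3>> before, after;
    for (const auto& o : all) {
        // scan order: x slowest, then y, then z (matches linear index order)
        const bool prec = (o[2] < 0) || (o[2] == 0 && o[1] < 0) ||
                          (o[2] == 0 && o[1] == 0 && o[0] < 0);
        (prec ? before : after).push_back(o);
    }
    // forward pass
    for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
            for (int z = 0; z < nz; ++z) {
                const long i = z + (long)nz * (y + (long)ny * x);
                double v = m[i];
                for (const auto& o : before) {
                    const int zz = z + o[0], yy = y + o[1], xx = x + o[2];
                    if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                        xx < 0 || xx >= nx) continue;
                    const double nv = m[zz + (long)nz * (yy + (long)ny * xx)];
                    if (nv > v) v = nv;
                }
                if (v > mask[i]) v = mask[i];
                m[i] = v;
            }
    // backward pass + seed the queue
    std::queue<long> fifo;
    for (int x = nx - 1; x >= 0; --x)
        for (int y = ny - 1; y >= 0; --y)
            for (int z = nz - 1; z >= 0; --z) {
                const long i = z + (long)nz * (y + (long)ny * x);
                double v = m[i];
                for (const auto& o : after) {
                    const int zz = z + o[0], yy = y + o[1], xx = x + o[2];
                    if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                        xx < 0 || xx >= nx) continue;
                    const double nv = m[zz + (long)nz * (yy + (long)ny * xx)];
                    if (nv > v) v = nv;
                }
                if (v > mask[i]) v = mask[i];
                m[i] = v;
                for (const auto& o : after) {
                    const int zz = z + o[0], yy = y + o[1], xx = x + o[2];
                    if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                        xx < 0 || xx >= nx) continue;
                    const long q = zz + (long)nz * (yy + (long)ny * xx);
                    if (m[q] < m[i] && m[q] < mask[q]) { fifo.push(i); break; }
                }
            }
    // FIFO propagation
    while (!fifo.empty()) {
        const long i = fifo.front();
        fifo.pop();
        const int z = (int)(i % nz);
        const int y = (int)((i / nz) % ny);
        const int x = (int)(i / ((long)nz * ny));
        for (const auto& o : all) {
            const int zz = z + o[0], yy = y + o[1], xx = x + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                xx < 0 || xx >= nx) continue;
            const long q = zz + (long)nz * (yy + (long)ny * xx);
            if (m[q] < m[i] && mask[q] != m[q]) {
                m[q] = std::min(m[i], mask[q]);
                fifo.push(q);
            }
        }
    }
    return NumericVector(m.begin(), m.end());
}
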