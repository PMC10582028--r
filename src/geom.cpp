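// Trilinear resampling primitives shared by the simulator, reconstruction
// and averaging paths.  Volumes are column-major (x fastest), 0-based, with
// the rotation center at voxel floor(dim/2) on each axis (documented package
// convention).  Samples outside the source grid are zero.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

#include "interp.h"

static inline double bi_sample(const double* img, int nx, int ny,
                               double x, double y) {
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    if (x0 < -1 || y0 < -1 || x0 > nx - 1 || y0 > ny - 1) return 0.0;
    double fx = x - x0, fy = y - y0, acc = 0.0;
    for (int dy = 0; dy < 2; ++dy) {
        int yy = y0 + dy;
        if (yy < 0 || yy >= ny) continue;
        double wy = dy ? fy : 1.0 - fy;
        for (int dx = 0; dx < 2; ++dx) {
            int xx = x0 + dx;
            if (xx < 0 || xx >= nx) continue;
            double wx = dx ? fx : 1.0 - fx;
            acc += wx * wy * img[(size_t)yy * nx + xx];
        }
    }
    return acc;
}

// Active rotation by R plus translation: out(v) = in(R^T (v - c - t) + c).
// Periodic sampling (wrap) makes multiples of 90 degrees exact grid
// permutations; pass wrap = false for zero-outside semantics.
// [[Rcpp::export(name = "cpp_rotate3")]]
NumericVector cpp_rotate3(NumericVector vol, IntegerVector dims,
                          NumericMatrix R, NumericVector shift,
                          bool wrap = true) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    double cx = nx / 2, cy = ny / 2, cz = nz / 2;
    NumericVector out((size_t)nx * ny * nz);
    const double* in = vol.begin();
    double r00 = R(0,0), r01 = R(0,1), r02 = R(0,2);
    double r10 = R(1,0), r11 = R(1,1), r12 = R(1,2);
    double r20 = R(2,0), r21 = R(2,1), r22 = R(2,2);
    double tx = shift[0], ty = shift[1], tz = shift[2];
    size_t idx = 0;
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x, ++idx) {
                double dx = x - cx - tx, dy = y - cy - ty, dz = z - cz - tz;
                // R^T * d
                double sx = r00 * dx + r10 * dy + r20 * dz + cx;
                double sy = r01 * dx + r11 * dy + r21 * dz + cy;
                double sz = r02 * dx + r12 * dy + r22 * dz + cz;
                out[idx] = wrap ? tri_sample_w(in, nx, ny, nz, sx, sy, sz, true)
                                : tri_sample(in, nx, ny, nz, sx, sy, sz);
            }
    out.attr("dim") = dims;
    return out;
}

// Parallel-beam projections of a specimen tilted about the y axis.
// For tilt theta the specimen is actively rotated by R_y(theta) and summed
// along lab z; returns an nx*ny x n_tilt matrix of images.
// [[Rcpp::export(name = "cpp_project_tilts")]]
NumericMatrix cpp_project_tilts(NumericVector vol, IntegerVector dims,
                                NumericVector angles_deg) {
    int nx = dims[0], ny = dims[1], nz = dims[2], nt = angles_deg.size();
    double cx = nx / 2, cy = ny / 2, cz = nz / 2;
    NumericMatrix out((size_t)nx * ny, nt);
    const double* in = vol.begin();
    // ray length: long enough to cross the volume at any tilt
    int tmin = -(int)std::ceil(std::hypot(cx, cz)) - 1;
    int tmax = (int)std::ceil(std::hypot((double)nx - cx, (double)nz - cz)) + 1;
    for (int i = 0; i < nt; ++i) {
        double th = angles_deg[i] * M_PI / 180.0;
        double c = std::cos(th), s = std::sin(th);
        // sample point of lab (x,y,t): R^T [x-cx, ., t-cz] + c
        // R_y = [[c,0,s],[0,1,0],[-s,0,c]]; R^T = R_y(-theta)
        double* img = &out(0, 0) + (size_t)i * nx * ny;
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                double acc = 0.0, dx = x - cx;
                for (int t = tmin; t <= tmax; ++t) {
                    double sx = c * dx - s * t + cx;
                    double sz = s * dx + c * t + cz;
                    acc += tri_sample(in, nx, ny, nz, sx, (double)y, sz);
                }
                img[(size_t)y * nx + x] = acc;
            }
    }
    return out;
}

// Voxel-driven back-projection.  images: nx*ny x n_tilt (already filtered);
// out volume nx x ny x thickness; offsets: 2 x n_tilt sub-pixel image offsets;
// origin: 3-vector world offset of the output volume center from the
// specimen/tomogram center (voxels), used for particle reconstruction.
// [[Rcpp::export(name = "cpp_backproject")]]
NumericVector cpp_backproject(NumericMatrix images, IntegerVector imdims,
                              NumericVector angles_deg, int thickness,
                              NumericMatrix offsets, NumericVector origin,
                              IntegerVector outxy) {
    int inx = imdims[0], iny = imdims[1], nt = angles_deg.size();
    int onx = outxy[0], ony = outxy[1], onz = thickness;
    double cox = onx / 2, coy = ony / 2, coz = onz / 2;
    double cix = inx / 2, ciy = iny / 2;
    NumericVector out((size_t)onx * ony * onz);
    for (int i = 0; i < nt; ++i) {
        double th = angles_deg[i] * M_PI / 180.0;
        double c = std::cos(th), s = std::sin(th);
        const double* img = &images(0, 0) + (size_t)i * inx * iny;
        double offx = offsets(0, i), offy = offsets(1, i);
        size_t idx = 0;
        for (int z = 0; z < onz; ++z)
            for (int y = 0; y < ony; ++y)
                for (int x = 0; x < onx; ++x, ++idx) {
                    double ux = x - cox + origin[0];
                    double uy = y - coy + origin[1];
                    double uz = z - coz + origin[2];
                    // image position of world point u under tilt i
                    double px = c * ux + s * uz + cix + offx;
                    double py = uy + ciy + offy;
                    out[idx] += bi_sample(img, inx, iny, px, py);
                }
    }
    out.attr("dim") = IntegerVector::create(onx, ony, onz);
    return out;
}
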