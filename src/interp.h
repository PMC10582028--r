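#ifndef TOMOSTA_INTERP_H
#define TOMOSTA_INTERP_H
#include <cmath>
#include <cstddef>

// wrap = true samples periodically (rotations become exact grid
// permutations for multiples of 90 degrees); wrap = false is zero outside.
inline double tri_sample_w(const double* v, int nx, int ny, int nz,
                           double x, double y, double z, bool wrap) {
    if (wrap) {
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
        double fx = x - x0, fy = y - y0, fz = z - z0;
        int x1 = ((x0 % nx) + nx) % nx, x2 = (x1 + 1) % nx;
        int y1 = ((y0 % ny) + ny) % ny, y2 = (y1 + 1) % ny;
        int z1 = ((z0 % nz) + nz) % nz, z2 = (z1 + 1) % nz;
        const double* p = v;
        double c00 = p[(size_t)z1 * nx * ny + (size_t)y1 * nx + x1] * (1 - fx)
                   + p[(size_t)z1 * nx * ny + (size_t)y1 * nx + x2] * fx;
        double c10 = p[(size_t)z1 * nx * ny + (size_t)y2 * nx + x1] * (1 - fx)
                   + p[(size_t)z1 * nx * ny + (size_t)y2 * nx + x2] * fx;
        double c01 = p[(size_t)z2 * nx * ny + (size_t)y1 * nx + x1] * (1 - fx)
                   + p[(size_t)z2 * nx * ny + (size_t)y1 * nx + x2] * fx;
        double c11 = p[(size_t)z2 * nx * ny + (size_t)y2 * nx + x1] * (1 - fx)
                   + p[(size_t)z2 * nx * ny + (size_t)y2 * nx + x2] * fx;
        return (c00 * (1 - fy) + c10 * fy) * (1 - fz)
             + (c01 * (1 - fy) + c11 * fy) * fz;
    }
    return 0.0; // unreachable; zero-outside path below
}

inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z) {
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 < -1 || y0 < -1 || z0 < -1 || x0 > nx - 1 || y0 > ny - 1 || z0 > nz - 1)
        return 0.0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz) {
        int zz = z0 + dz;
        if (zz < 0 || zz >= nz) continue;
        double wz = dz ? fz : 1.0 - fz;
        for (int dy = 0; dy < 2; ++dy) {
            int yy = y0 + dy;
            if (yy < 0 || yy >= ny) continue;
            double wy = dy ? fy : 1.0 - fy;
            double wyz = wy * wz;
            for (int dx = 0; dx < 2; ++dx) {
                int xx = x0 + dx;
                if (xx < 0 || xx >= nx) continue;
                double wx = dx ? fx : 1.0 - fx;
                acc += wx * wyz * v[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
            }
        }
    }
    return acc;
}

#endif
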