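#ifndef TOMOSTA_FFTCORE_H
#define TOMOSTA_FFTCORE_H
// Lane-batched single-precision mixed-radix Stockham FFT.  Split re/im
// arrays (SoA), G sequences transformed at once so inner loops vectorize.
// Sizes must be 2,3,5,7,11,13-smooth.  Unnormalized in both directions.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

namespace tfft {

static const int G = 16; // lanes per tile

struct Plan {
    int n;
    std::vector<int> radices;
    // per stage: twiddle tables tw[stage][(q*m + p)] for q=0..r-1, p=0..m-1
    std::vector< std::vector<float> > twre, twim;
    int sign; // -1 forward, +1 inverse
};

inline bool factorize(int n, std::vector<int>& out) {
    static const int rs[] = {4, 2, 3, 5, 7, 11, 13};
    for (int k = 0; k < 7; ++k) {
        while (n % rs[k] == 0) { out.push_back(rs[k]); n /= rs[k]; }
    }
    return n == 1;
}

inline void make_plan(Plan& pl, int n, int sign) {
    pl.n = n; pl.sign = sign;
    pl.radices.clear(); pl.twre.clear(); pl.twim.clear();
    if (!factorize(n, pl.radices))
        Rcpp::stop("FFT size %d has a prime factor > 13", n);
    int m = 1;
    for (size_t s = 0; s < pl.radices.size(); ++s) {
        int r = pl.radices[s];
        std::vector<float> wre((size_t)r * m), wim((size_t)r * m);
        double base = sign * 2.0 * M_PI / ((double)m * r);
        for (int q = 0; q < r; ++q)
            for (int p = 0; p < m; ++p) {
                double a = base * (double)q * (double)p;
                wre[(size_t)q * m + p] = (float)std::cos(a);
                wim[(size_t)q * m + p] = (float)std::sin(a);
            }
        pl.twre.push_back(std::move(wre));
        pl.twim.push_back(std::move(wim));
        m *= r;
    }
}

// One Stockham stage.  Input A viewed as blocks j=0..l*r-1 of completed
// DFT_m sub-transforms; output B as blocks j'=0..l-1 of DFT_{m*r}.
// A[(j' + q*l)*m + p] -> B[j'*m*r + u*m + p].  Lane-major innermost.
static void stage(const float* __restrict Are, const float* __restrict Aim, float* __restrict Bre, float* __restrict Bim,
                  int l, int r, int m, const float* wre, const float* wim,
                  int sign) {
    const size_t mG = (size_t)m * G;
    float ar[13][G], ai[13][G];
    for (int j = 0; j < l; ++j) {
        for (int p = 0; p < m; ++p) {
            // gather + twiddle
            for (int q = 0; q < r; ++q) {
                const float* xr = Are + ((size_t)(j + (size_t)q * l) * m + p) * G;
                const float* xi = Aim + ((size_t)(j + (size_t)q * l) * m + p) * G;
                const float wr = wre[(size_t)q * m + p], wi = wim[(size_t)q * m + p];
                for (int g = 0; g < G; ++g) {
                    ar[q][g] = xr[g] * wr - xi[g] * wi;
                    ai[q][g] = xr[g] * wi + xi[g] * wr;
                }
            }
            float* br = Bre + ((size_t)j * r * m + p) * G;
            float* bi = Bim + ((size_t)j * r * m + p) * G;
            // radix butterfly across q -> u, scatter stride mG
            if (r == 2) {
                for (int g = 0; g < G; ++g) {
                    br[g]      = ar[0][g] + ar[1][g];
                    bi[g]      = ai[0][g] + ai[1][g];
                    br[mG + g] = ar[0][g] - ar[1][g];
                    bi[mG + g] = ai[0][g] - ai[1][g];
                }
            } else if (r == 4) {
                const float s = (float)sign;
                for (int g = 0; g < G; ++g) {
                    float t0r = ar[0][g] + ar[2][g], t0i = ai[0][g] + ai[2][g];
                    float t1r = ar[0][g] - ar[2][g], t1i = ai[0][g] - ai[2][g];
                    float t2r = ar[1][g] + ar[3][g], t2i = ai[1][g] + ai[3][g];
                    // s * i * (a1 - a3)
                    float t3r = -s * (ai[1][g] - ai[3][g]);
                    float t3i =  s * (ar[1][g] - ar[3][g]);
                    br[g]          = t0r + t2r; bi[g]          = t0i + t2i;
                    br[mG + g]     = t1r + t3r; bi[mG + g]     = t1i + t3i;
                    br[2 * mG + g] = t0r - t2r; bi[2 * mG + g] = t0i - t2i;
                    br[3 * mG + g] = t1r - t3r; bi[3 * mG + g] = t1i - t3i;
                }
            } else if (r == 3) {
                const float c1 = -0.5f;
                const float s1 = (float)sign * 0.8660254037844386f;
                for (int g = 0; g < G; ++g) {
                    float spr = ar[1][g] + ar[2][g], spi = ai[1][g] + ai[2][g];
                    float smr = ar[1][g] - ar[2][g], smi = ai[1][g] - ai[2][g];
                    br[g] = ar[0][g] + spr; bi[g] = ai[0][g] + spi;
                    float mr = ar[0][g] + c1 * spr, mi = ai[0][g] + c1 * spi;
                    br[mG + g]     = mr - s1 * smi; bi[mG + g]     = mi + s1 * smr;
                    br[2 * mG + g] = mr + s1 * smi; bi[2 * mG + g] = mi - s1 * smr;
                }
            } else {
                // generic O(r^2) DFT across q (r in {5,7,11,13})
                static float cr[13][13], ci[13][13];
                static int last_r = -1, last_sign = 0;
                if (r != last_r || sign != last_sign) {
                    for (int u = 0; u < r; ++u)
                        for (int q = 0; q < r; ++q) {
                            double a = sign * 2.0 * M_PI * u * q / r;
                            cr[u][q] = (float)std::cos(a);
                            ci[u][q] = (float)std::sin(a);
                        }
                    last_r = r; last_sign = sign;
                }
                for (int u = 0; u < r; ++u) {
                    float* our = br + (size_t)u * mG;
                    float* oui = bi + (size_t)u * mG;
                    for (int g = 0; g < G; ++g) { our[g] = 0.f; oui[g] = 0.f; }
                    for (int q = 0; q < r; ++q) {
                        const float wr2 = cr[u][q], wi2 = ci[u][q];
                        for (int g = 0; g < G; ++g) {
                            our[g] += ar[q][g] * wr2 - ai[q][g] * wi2;
                            oui[g] += ar[q][g] * wi2 + ai[q][g] * wr2;
                        }
                    }
                }
            }
        }
    }
}

// Transform G lanes held in SoA buffers bre/bim (layout [n][G]); uses
// scratch of same size.  Result left in bre/bim.
inline void fft1d_lanes(const Plan& pl, float* bre, float* bim,
                        float* sre, float* sim) {
    int n = pl.n;
    float *Ar = bre, *Ai = bim, *Br = sre, *Bi = sim;
    int m = 1;
    for (size_t s = 0; s < pl.radices.size(); ++s) {
        int r = pl.radices[s];
        int l = n / (m * r);
        stage(Ar, Ai, Br, Bi, l, r, m, pl.twre[s].data(), pl.twim[s].data(),
              pl.sign);
        std::swap(Ar, Br); std::swap(Ai, Bi);
        m *= r;
    }
    if (Ar != bre) {
        std::memcpy(bre, Ar, (size_t)n * G * sizeof(float));
        std::memcpy(bim, Ai, (size_t)n * G * sizeof(float));
    }
}

// 3D FFT, volume in SoA float arrays, column-major (x fastest), in place.
// No normalization on either direction (caller divides by N after inverse).
struct Plan3 {
    Plan px, py, pz;
    int nx, ny, nz;
    std::vector<float> bre, bim, sre, sim;
    void init(int nx_, int ny_, int nz_, int sign) {
        nx = nx_; ny = ny_; nz = nz_;
        make_plan(px, nx, sign);
        make_plan(py, ny, sign);
        make_plan(pz, nz, sign);
        int nmax = std::max(nx, std::max(ny, nz));
        bre.resize((size_t)nmax * G); bim.resize((size_t)nmax * G);
        sre.resize((size_t)nmax * G); sim.resize((size_t)nmax * G);
    }
};

inline void fft3d(Plan3& pl, float* re, float* im) {
    const int nx = pl.nx, ny = pl.ny, nz = pl.nz;
    float* bre = pl.bre.data(); float* bim = pl.bim.data();
    float* sre = pl.sre.data(); float* sim = pl.sim.data();
    // along x: lanes are G consecutive (y,z) columns
    {
        size_t ncol = (size_t)ny * nz;
        for (size_t c0 = 0; c0 < ncol; c0 += G) {
            int gmax = (int)std::min((size_t)G, ncol - c0);
            for (int i = 0; i < nx; ++i)
                for (int g = 0; g < G; ++g) {
                    size_t src = (size_t)(c0 + (g < gmax ? g : 0)) * nx + i;
                    bre[(size_t)i * G + g] = re[src];
                    bim[(size_t)i * G + g] = im[src];
                }
            fft1d_lanes(pl.px, bre, bim, sre, sim);
            for (int i = 0; i < nx; ++i)
                for (int g = 0; g < gmax; ++g) {
                    size_t dst = (size_t)(c0 + g) * nx + i;
                    re[dst] = bre[(size_t)i * G + g];
                    im[dst] = bim[(size_t)i * G + g];
                }
        }
    }
    // along y: lanes are G consecutive x's, for each z-plane
    for (int z = 0; z < nz; ++z) {
        size_t zoff = (size_t)z * nx * ny;
        for (int x0 = 0; x0 < nx; x0 += G) {
            int gmax = std::min(G, nx - x0);
            for (int j = 0; j < ny; ++j) {
                size_t src = zoff + (size_t)j * nx + x0;
                for (int g = 0; g < G; ++g) {
                    bre[(size_t)j * G + g] = re[src + (g < gmax ? g : 0)];
                    bim[(size_t)j * G + g] = im[src + (g < gmax ? g : 0)];
                }
            }
            fft1d_lanes(pl.py, bre, bim, sre, sim);
            for (int j = 0; j < ny; ++j) {
                size_t dst = zoff + (size_t)j * nx + x0;
                for (int g = 0; g < gmax; ++g) {
                    re[dst + g] = bre[(size_t)j * G + g];
                    im[dst + g] = bim[(size_t)j * G + g];
                }
            }
        }
    }
    // along z: lanes are G consecutive x's, for each y-row
    for (int y = 0; y < ny; ++y) {
        for (int x0 = 0; x0 < nx; x0 += G) {
            int gmax = std::min(G, nx - x0);
            for (int k = 0; k < nz; ++k) {
                size_t src = ((size_t)k * ny + y) * nx + x0;
                for (int g = 0; g < G; ++g) {
                    bre[(size_t)k * G + g] = re[src + (g < gmax ? g : 0)];
                    bim[(size_t)k * G + g] = im[src + (g < gmax ? g : 0)];
                }
            }
            fft1d_lanes(pl.pz, bre, bim, sre, sim);
            for (int k = 0; k < nz; ++k) {
                size_t dst = ((size_t)k * ny + y) * nx + x0;
                for (int g = 0; g < gmax; ++g) {
                    re[dst + g] = bre[(size_t)k * G + g];
                    im[dst + g] = bim[(size_t)k * G + g];
                }
            }
        }
    }
}

} // namespace tfft
#endif
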