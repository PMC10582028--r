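// Chunked missing-wedge-aware local-normalized cross-correlation engine.
// For every orientation the cubic template is rotated (trilinear), filtered
// with the tomogram-frame wedge mask in Fourier space, normalized to zero
// mean / unit energy under the (spherical, rotation-invariant) mask and
// correlated against the chunk by FFT.  Correlations for two orientations
// are packed into the real and imaginary parts of a single complex
// transform, so the cost is one full-size FFT per orientation.  Local
// normalization follows the fast local-statistics approach: mask-windowed
// sums of the data and its square come from two convolutions computed once.
#include "fftcore.h"
#include "interp.h"
using namespace Rcpp;

// Wrap-pad a box volume into the big buffer so that the box center lands on
// voxel 0 (circular correlation then indexes cc by template-center position).
static void wrap_pad(const std::vector<float>& box, int b,
                     float* big, int nx, int ny, int nz) {
    int c = b / 2;
    for (int z = 0; z < b; ++z) {
        int zz = (z - c + nz) % nz;
        for (int y = 0; y < b; ++y) {
            int yy = (y - c + ny) % ny;
            size_t brow = ((size_t)zz * ny + yy) * nx;
            size_t srow = ((size_t)z * b + y) * b;
            for (int x = 0; x < b; ++x) {
                int xx = (x - c + nx) % nx;
                big[brow + xx] = box[srow + x];
            }
        }
    }
}

// [[Rcpp::export(name = "cpp_match_chunk")]]
List cpp_match_chunk(NumericVector tomo, IntegerVector tdims,
                     NumericVector tmpl, NumericVector mask, int b,
                     NumericMatrix rotmats, NumericVector wedge,
                     bool use_wedge, double eps_rel) {
    const int nx = tdims[0], ny = tdims[1], nz = tdims[2];
    const size_t N = (size_t)nx * ny * nz;
    const size_t Nb = (size_t)b * b * b;
    const int nori = rotmats.ncol();
    if ((size_t)tmpl.size() != Nb || (size_t)mask.size() != Nb)
        stop("template/mask must be cubic with side %d", b);
    if (b > nx || b > ny || b > nz)
        stop("chunk smaller than template box");

    tfft::Plan3 fwd, inv, bfwd, binv;
    fwd.init(nx, ny, nz, -1); inv.init(nx, ny, nz, 1);
    bfwd.init(b, b, b, -1);   binv.init(b, b, b, 1);

    std::vector<float> wre(N), wim(N);          // work buffers
    std::vector<float> ftr(N), fti(N);          // tomogram spectrum
    std::vector<float> invden(N);
    // --- setup: tomogram spectrum and local statistics under the mask ---
    double Nm = 0.0, gsum = 0.0, gsum2 = 0.0;
    for (size_t i = 0; i < Nb; ++i) Nm += mask[i];
    for (size_t i = 0; i < N; ++i) {
        double v = tomo[i];
        gsum += v; gsum2 += v * v;
        wre[i] = (float)v; wim[i] = (float)(v * v);
    }
    double gvar = gsum2 / N - (gsum / N) * (gsum / N);
    tfft::fft3d(fwd, wre.data(), wim.data());   // packed: F(tomo) + i F(tomo^2)
    // unpack via Hermitian symmetry and store F(tomo); multiply packed
    // spectrum by conj(F(maskpad)) to get local sums in one inverse FFT.
    std::vector<float> pre = wre, pim = wim;    // packed spectrum copy
    for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
            for (int x = 0; x < nx; ++x) {
                size_t k = ((size_t)z * ny + y) * nx + x;
                size_t kc = ((size_t)((nz - z) % nz) * ny + (ny - y) % ny) * nx
                            + (nx - x) % nx;
                ftr[k] = 0.5f * (pre[k] + pre[kc]);
                fti[k] = 0.5f * (pim[k] - pim[kc]);
            }
    {   // mask spectrum
        std::vector<float> mre(N, 0.f), mim(N, 0.f);
        std::vector<float> boxf(Nb);
        for (size_t i = 0; i < Nb; ++i) boxf[i] = (float)mask[i];
        wrap_pad(boxf, b, mre.data(), nx, ny, nz);
        tfft::fft3d(fwd, mre.data(), mim.data());
        // packed * conj(Fmask) -> IFFT gives S1 + i S2
        for (size_t k = 0; k < N; ++k) {
            float ar = pre[k], ai = pim[k], br = mre[k], bi = -mim[k];
            wre[k] = ar * br - ai * bi;
            wim[k] = ar * bi + ai * br;
        }
    }
    tfft::fft3d(inv, wre.data(), wim.data());
    const double eps = std::max(eps_rel * gvar * Nm, 1e-30);
    for (size_t k = 0; k < N; ++k) {
        double S1 = wre[k] / (double)N, S2 = wim[k] / (double)N;
        double varsum = S2 - S1 * S1 / Nm;
        invden[k] = varsum > eps ? (float)(1.0 / std::sqrt(varsum)) : 0.f;
    }

    // --- orientation loop, two orientations per complex FFT ---
    std::vector<float> ccbest(N, -2.f);
    std::vector<int> oribest(N, 1);
    std::vector<double> rot(Nb);
    std::vector<float> bre(Nb), bim(Nb), A1(Nb), A2(Nb);
    const double* tin = tmpl.begin();

    auto prep = [&](int o, std::vector<float>& A) {
        // rotate template: out(v) = tmpl(R^T (v - c) + c)
        const double* R = &rotmats(0, o); // column-major 3x3
        double c = b / 2;
        size_t idx = 0;
        for (int z = 0; z < b; ++z)
            for (int y = 0; y < b; ++y)
                for (int x = 0; x < b; ++x, ++idx) {
                    double dx = x - c, dy = y - c, dz = z - c;
                    double sx = R[0] * dx + R[1] * dy + R[2] * dz + c;
                    double sy = R[3] * dx + R[4] * dy + R[5] * dz + c;
                    double sz = R[6] * dx + R[7] * dy + R[8] * dz + c;
                    rot[idx] = tri_sample(tin, b, b, b, sx, sy, sz);
                }
        if (use_wedge) {
            for (size_t i = 0; i < Nb; ++i) { bre[i] = (float)rot[i]; bim[i] = 0.f; }
            tfft::fft3d(bfwd, bre.data(), bim.data());
            for (size_t i = 0; i < Nb; ++i) {
                float w = (float)wedge[i];
                bre[i] *= w; bim[i] *= w;
            }
            tfft::fft3d(binv, bre.data(), bim.data());
            for (size_t i = 0; i < Nb; ++i) rot[i] = bre[i] / (double)Nb;
        }
        double tm = 0.0;
        for (size_t i = 0; i < Nb; ++i) tm += mask[i] * rot[i];
        tm /= Nm;
        double s2 = 0.0;
        for (size_t i = 0; i < Nb; ++i) {
            double a = mask[i] * (rot[i] - tm);
            s2 += (rot[i] - tm) * a;
        }
        double sc = s2 > 1e-20 ? 1.0 / std::sqrt(s2) : 0.0;
        for (size_t i = 0; i < Nb; ++i)
            A[i] = (float)(mask[i] * (rot[i] - tm) * sc);
    };

    for (int o = 0; o < nori; o += 2) {
        bool pair = (o + 1) < nori;
        prep(o, A1);
        if (pair) prep(o + 1, A2); else std::fill(A2.begin(), A2.end(), 0.f);
        std::fill(wre.begin(), wre.end(), 0.f);
        std::fill(wim.begin(), wim.end(), 0.f);
        wrap_pad(A1, b, wre.data(), nx, ny, nz);
        wrap_pad(A2, b, wim.data(), nx, ny, nz);
        tfft::fft3d(fwd, wre.data(), wim.data());
        // conj(P) * Ftomo; IFFT -> c1 - i c2
        for (size_t k = 0; k < N; ++k) {
            float pr = wre[k], pi = -wim[k];
            float fr = ftr[k], fi = fti[k];
            wre[k] = pr * fr - pi * fi;
            wim[k] = pr * fi + pi * fr;
        }
        tfft::fft3d(inv, wre.data(), wim.data());
        const float scale = 1.f / (float)N;
        for (size_t k = 0; k < N; ++k) {
            float cc = wre[k] * scale * invden[k];
            if (cc > ccbest[k]) { ccbest[k] = cc; oribest[k] = o + 1; }
        }
        if (pair) {
            for (size_t k = 0; k < N; ++k) {
                float cc = -wim[k] * scale * invden[k];
                if (cc > ccbest[k]) { ccbest[k] = cc; oribest[k] = o + 2; }
            }
        }
        Rcpp::checkUserInterrupt();
    }

    NumericVector cc(N);
    IntegerVector ori(N);
    for (size_t k = 0; k < N; ++k) {
        double v = ccbest[k];
        cc[k] = v < -1.0 ? -1.0 : (v > 1.0 ? 1.0 : v);
        ori[k] = oribest[k];
    }
    cc.attr("dim") = tdims;
    ori.attr("dim") = tdims;
    return List::create(Named("cc") = cc, Named("ori") = ori);
}
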