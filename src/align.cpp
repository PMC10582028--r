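// Constrained single-particle alignment kernel: for each candidate rotation
// the reference is rotated, wedge-filtered, weighted by the squared soft
// mask and correlated with the particle by FFT.  The correlation is
// normalized per shift by the particle energy under the shifted mask
// window, so an exact displaced copy of the reference scores exactly 1 at
// its true shift (no mask-clipping bias).  The translation search is
// restricted to a +/- shift_limit window around zero.
#include "fftcore.h"
#include "interp.h"
using namespace Rcpp;

// [[Rcpp::export(name = "cpp_align")]]
List cpp_align(NumericVector particle, NumericVector mask, int b,
               NumericVector reference, NumericMatrix rotmats,
               NumericVector wedge, bool use_wedge, int shift_limit) {
    const size_t Nb = (size_t)b * b * b;
    const int nori = rotmats.ncol();
    tfft::Plan3 fwd, inv;
    fwd.init(b, b, b, -1); inv.init(b, b, b, 1);

    // spectrum of the raw particle, and the per-shift particle energy
    // under the squared mask: den(s) = sum_u M(u)^2 p(u+s)^2, packed as the
    // imaginary lane of one FFT pair with the mask spectrum as the real lane
    std::vector<float> pr(Nb), pi(Nb), w2(Nb);
    for (size_t i = 0; i < Nb; ++i) {
        double m = mask[i];
        w2[i] = (float)(m * m);
        pr[i] = (float)particle[i]; pi[i] = 0.f;
    }
    tfft::fft3d(fwd, pr.data(), pi.data());
    std::vector<float> den(Nb);
    {
        std::vector<float> ar(Nb), ai(Nb), br(Nb), bi(Nb);
        for (size_t i = 0; i < Nb; ++i) {
            ar[i] = w2[i]; ai[i] = 0.f;
            double p = particle[i];
            br[i] = (float)(p * p); bi[i] = 0.f;
        }
        tfft::fft3d(fwd, ar.data(), ai.data());
        tfft::fft3d(fwd, br.data(), bi.data());
        for (size_t i = 0; i < Nb; ++i) {
            float cr = ar[i] * br[i] + ai[i] * bi[i];   // conj(FW2) * Fp2
            float ci = ar[i] * bi[i] - ai[i] * br[i];
            br[i] = cr; bi[i] = ci;
        }
        tfft::fft3d(inv, br.data(), bi.data());
        double dmax = 0.0;
        for (size_t i = 0; i < Nb; ++i) {
            double v = br[i] / (double)Nb;
            den[i] = (float)(v > 0 ? v : 0);
            if (v > dmax) dmax = v;
        }
        if (dmax <= 0) stop("particle is identically zero under the mask");
        float floorv = (float)(1e-6 * dmax);
        for (size_t i = 0; i < Nb; ++i)
            den[i] = den[i] > floorv ? std::sqrt(den[i]) : 0.f;
    }

    const int L = shift_limit;
    const int W = 2 * L + 1;
    std::vector<double> rot(Nb), best_win((size_t)W * W * W, 0.0);
    std::vector<float> rre(Nb), rim(Nb);
    double best_cc = -2.0;
    int best_ori = 1;
    const double* tin = reference.begin();

    for (int o = 0; o < nori; ++o) {
        const double* R = &rotmats(0, o);
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
            for (size_t i = 0; i < Nb; ++i) { rre[i] = (float)rot[i]; rim[i] = 0.f; }
            tfft::fft3d(fwd, rre.data(), rim.data());
            for (size_t i = 0; i < Nb; ++i) {
                float w = (float)wedge[i];
                rre[i] *= w; rim[i] *= w;
            }
            tfft::fft3d(inv, rre.data(), rim.data());
            for (size_t i = 0; i < Nb; ++i) rot[i] = rre[i] / (double)Nb;
        }
        double rnorm2 = 0.0;
        for (size_t i = 0; i < Nb; ++i) {
            double v = rot[i];
            rnorm2 += w2[i] * v * v;          // ||M * ref||^2
            rre[i] = (float)(w2[i] * v); rim[i] = 0.f;
        }
        if (rnorm2 <= 0.0) continue;
        tfft::fft3d(fwd, rre.data(), rim.data());
        // conj(Fref) * Fparticle
        for (size_t i = 0; i < Nb; ++i) {
            float ar = rre[i], ai = -rim[i];
            float brv = pr[i], biv = pi[i];
            rre[i] = ar * brv - ai * biv;
            rim[i] = ar * biv + ai * brv;
        }
        tfft::fft3d(inv, rre.data(), rim.data());
        const double scale = 1.0 / ((double)Nb * std::sqrt(rnorm2));
        // windowed max over shifts in [-L, L]^3 (wrap-around indexing)
        double omax = -2.0;
        for (int sz = -L; sz <= L; ++sz)
            for (int sy = -L; sy <= L; ++sy)
                for (int sx = -L; sx <= L; ++sx) {
                    size_t k = ((size_t)((sz + b) % b) * b + (sy + b) % b) * b
                               + (sx + b) % b;
                    double v = den[k] > 0 ? rre[k] * scale / den[k] : 0.0;
                    if (v > omax) omax = v;
                }
        if (omax > best_cc) {
            best_cc = omax;
            best_ori = o + 1;
            size_t w = 0;
            for (int sz = -L; sz <= L; ++sz)
                for (int sy = -L; sy <= L; ++sy)
                    for (int sx = -L; sx <= L; ++sx, ++w) {
                        size_t k = ((size_t)((sz + b) % b) * b + (sy + b) % b) * b
                                   + (sx + b) % b;
                        best_win[w] = den[k] > 0 ? rre[k] * scale / den[k] : 0.0;
                    }
        }
    }
    NumericVector win((size_t)W * W * W);
    for (size_t i = 0; i < win.size(); ++i) win[i] = best_win[i];
    win.attr("dim") = IntegerVector::create(W, W, W);
    return List::create(Named("ori") = best_ori, Named("cc") = best_cc,
                        Named("window") = win);
}
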