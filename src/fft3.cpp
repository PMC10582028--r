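#include "fftcore.h"

// [[Rcpp::export(name = "cpp_fft3")]]
Rcpp::List cpp_fft3(Rcpp::NumericVector re, Rcpp::NumericVector im,
                    Rcpp::IntegerVector dims, int sign) {
    int nx = dims[0], ny = dims.size() > 1 ? dims[1] : 1,
        nz = dims.size() > 2 ? dims[2] : 1;
    size_t n = (size_t)nx * ny * nz;
    if ((size_t)re.size() != n || (size_t)im.size() != n)
        Rcpp::stop("length mismatch with dims");
    std::vector<float> fre(n), fim(n);
    for (size_t i = 0; i < n; ++i) { fre[i] = (float)re[i]; fim[i] = (float)im[i]; }
    tfft::Plan3 pl;
    pl.init(nx, ny, nz, sign < 0 ? -1 : 1);
    tfft::fft3d(pl, fre.data(), fim.data());
    Rcpp::NumericVector ore(n), oim(n);
    for (size_t i = 0; i < n; ++i) { ore[i] = fre[i]; oim[i] = fim[i]; }
    return Rcpp::List::create(Rcpp::Named("re") = ore, Rcpp::Named("im") = oim);
}
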