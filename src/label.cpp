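// Connected-component labeling (6-connectivity in 3D, 4-connectivity in 2D)
// by breadth-first search over a logical mask.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = "cpp_label")]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dims) {
    int nx = dims[0], ny = dims.size() > 1 ? dims[1] : 1,
        nz = dims.size() > 2 ? dims[2] : 1;
    size_t N = (size_t)nx * ny * nz;
    IntegerVector lab(N, 0);
    std::vector<size_t> queue;
    int next = 0;
    for (size_t s = 0; s < N; ++s) {
        if (!mask[s] || lab[s]) continue;
        ++next;
        lab[s] = next;
        queue.clear();
        queue.push_back(s);
        while (!queue.empty()) {
            size_t v = queue.back(); queue.pop_back();
            int x = (int)(v % nx), y = (int)((v / nx) % ny), z = (int)(v / ((size_t)nx * ny));
            const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
            for (int k = 0; k < 6; ++k) {
                int xx = x + d[k][0], yy = y + d[k][1], zz = z + d[k][2];
                if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
                    continue;
                size_t u = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
                if (mask[u] && !lab[u]) { lab[u] = next; queue.push_back(u); }
            }
        }
    }
    lab.attr("dim") = dims;
    return lab;
}
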