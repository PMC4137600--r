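#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Disjoint-set with path compression (halving) and union by rank.
static inline int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

static inline void uf_union(std::vector<int> &parent, std::vector<int> &rank_,
                            int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra == rb) return;
    if (rank_[ra] < rank_[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    if (rank_[ra] == rank_[rb]) rank_[ra]++;
}

// Connected-component labeling of a 3D logical array via union-find.
//
// connectivity: 1 = face (6-neighborhood), 2 = face+edge (18),
//               3 = face+edge+corner (26).
// per_slice: restrict connectivity to dz == 0 (independent 2D labeling of
//            each z-slice, 4/8-neighborhood depending on connectivity).
//
// Labels are consecutive 1..K, assigned in ascending order of each
// component's first voxel in x-fastest (column-major linear) scan order,
// so results are deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_uf(LogicalVector mask, IntegerVector dims,
                          int connectivity, bool per_slice) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");

    // Neighbor offsets with negative linear offset (already-scanned voxels).
    std::vector<int> odx, ody, odz;
    for (int dz = -1; dz <= 0; ++dz) {
        if (per_slice && dz != 0) continue;
        for (int dy = -1; dy <= 1; ++dy) {
            for (int dx = -1; dx <= 1; ++dx) {
                long lin = (long)dz * nx * ny + (long)dy * nx + dx;
                if (lin >= 0) continue;
                int order = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (order > connectivity) continue;
                odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
            }
        }
    }

    std::vector<int> parent(n), rank_(n, 0);
    for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

    R_xlen_t idx = 0;
    for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x, ++idx) {
                if (!mask[idx]) continue;
                for (size_t k = 0; k < odx.size(); ++k) {
                    int xx = x + odx[k], yy = y + ody[k], zz = z + odz[k];
                    if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0)
                        continue;
                    R_xlen_t j = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
                    if (mask[j]) uf_union(parent, rank_, (int)idx, (int)j);
                }
            }
        }
    }

    // Second pass: relabel roots by first occurrence in scan order.
    IntegerVector out(n, 0);
    std::vector<int> root_label(n, 0);
    int next = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i]) continue;
        int r = uf_find(parent, (int)i);
        if (root_label[r] == 0) root_label[r] = ++next;
        out[i] = root_label[r];
    }
    out.attr("dim") = dims;
    return out;
}

// Per-label voxel counts, centroid accumulators and index bounding boxes in
// one pass; returns a list consumed by region_statistics().
// [[Rcpp::export]]
List cc_region_stats(IntegerVector labels, IntegerVector dims, int nlab) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    NumericVector cnt(nlab), sx(nlab), sy(nlab), sz(nlab);
    IntegerVector x0(nlab, nx), x1(nlab, -1), y0(nlab, ny), y1(nlab, -1),
        z0(nlab, nz), z1(nlab, -1);
    R_xlen_t idx = 0;
    for (int z = 0; z < nz; ++z) {
        for (int y = 0; y < ny; ++y) {
            for (int x = 0; x < nx; ++x, ++idx) {
                int lab = labels[idx];
                if (lab == 0) continue;
                int k = lab - 1;
                cnt[k] += 1; sx[k] += x; sy[k] += y; sz[k] += z;
                if (x < x0[k]) x0[k] = x;
                if (x > x1[k]) x1[k] = x;
                if (y < y0[k]) y0[k] = y;
                if (y > y1[k]) y1[k] = y;
                if (z < z0[k]) z0[k] = z;
                if (z > z1[k]) z1[k] = z;
            }
        }
    }
    return List::create(_["count"] = cnt, _["sx"] = sx, _["sy"] = sy,
                        _["sz"] = sz, _["x0"] = x0, _["x1"] = x1,
                        _["y0"] = y0, _["y1"] = y1, _["z0"] = z0,
                        _["z1"] = z1);
}
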