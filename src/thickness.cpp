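#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Local thickness of a voxelized solid: for every foreground voxel, the
// diameter of the largest sphere that is fully contained in the solid and
// covers the voxel centre.  The solid is the union of the closed unit cubes
// of the foreground voxels; sphere centres live on the half-voxel grid and a
// sphere's radius is the exact Euclidean distance from its centre to the
// complement.  All comparisons are done in integer arithmetic on the refined
// (half-voxel) lattice, so the result is exact for this discretization.
//
// outside_bg = true : everything beyond the grid is background (spheres are
//                     clipped at the domain hull).
// outside_bg = false: the volume is treated as a crop of a larger solid; the
//                     domain hull does not limit spheres ("solid" boundary).

// Coordinates: voxel v (0-based int) sits at refined coordinate 2v + koff,
// where koff = 1 when the refined lattice starts at -0.5 (outside_bg) and 0
// when it starts at 0 (solid boundary).  Refined lattice spacing = 0.5 voxel.

static inline int isqrt_floor(long long x) {
    int s = (int)std::floor(std::sqrt((double)x));
    while ((long long)(s + 1) * (s + 1) <= x) ++s;
    while ((long long)s * s > x) --s;
    return s;
}

struct RefGrid {
    int n1, n2, n3;      // voxel dims (first index fastest, as in R arrays)
    int m1, m2, m3;      // refined dims
    int koff;            // refined coord of voxel 0
    bool outside_bg;
};

static inline size_t ridx(const RefGrid& g, int r1, int r2, int r3) {
    return (size_t)r1 + (size_t)g.m1 * ((size_t)r2 + (size_t)g.m2 * (size_t)r3);
}
static inline size_t vidx(const RefGrid& g, int v1, int v2, int v3) {
    return (size_t)v1 + (size_t)g.n1 * ((size_t)v2 + (size_t)g.n2 * (size_t)v3);
}

// voxel candidates along one axis for a refined coordinate r: voxels whose
// closed cube contains that coordinate.  Returns count (1 or 2), fills q[2].
static inline int axis_candidates(int r, int koff, int n, int q[2]) {
    int t = r - koff;                 // 2 * voxel coordinate
    if (t % 2 == 0) { q[0] = t / 2; return 1; }
    // on a shared face between voxels (t-1)/2 and (t+1)/2
    q[0] = (t - 1) / 2; q[1] = (t + 1) / 2;
    (void)n;
    return 2;
}

// Is refined point (r1,r2,r3) inside the closed background region?
static bool is_seed(const RefGrid& g, const int* mask, int r1, int r2, int r3) {
    int qa[2], qb[2], qc[2];
    int na = axis_candidates(r1, g.koff, g.n1, qa);
    int nb = axis_candidates(r2, g.koff, g.n2, qb);
    int nc = axis_candidates(r3, g.koff, g.n3, qc);
    for (int a = 0; a < na; ++a)
        for (int b = 0; b < nb; ++b)
            for (int c = 0; c < nc; ++c) {
                int v1 = qa[a], v2 = qb[b], v3 = qc[c];
                bool inside = v1 >= 0 && v1 < g.n1 && v2 >= 0 && v2 < g.n2 &&
                              v3 >= 0 && v3 < g.n3;
                if (!inside) {
                    if (g.outside_bg) return true;  // out-of-domain cube is background
                    continue;
                }
                if (!mask[vidx(g, v1, v2, v3)]) return true;
            }
    return false;
}

static const int INF_I = INT32_MAX / 4;

// Felzenszwalb-Huttenlocher 1D squared-distance lower envelope.  Inputs are
// integers; parabola intersections are rationals with denominator <= 2n, so
// double arithmetic resolves every envelope comparison exactly (ties between
// parabolas produce equal values and are harmless either way).
static void fh_line(const int* f, int* d, int n, int* v, double* z) {
    int k = -1;
    for (int q = 0; q < n; ++q) {
        if (f[q] >= INF_I) continue;
        double s;
        while (true) {
            if (k < 0) { s = -1e300; break; }
            int p = v[k];
            s = ((double)f[q] + (double)q * q - (double)f[p] - (double)p * p) /
                (2.0 * (q - p));
            if (s > z[k]) break;
            --k;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = 1e300;
    }
    if (k < 0) { for (int x = 0; x < n; ++x) d[x] = INF_I; return; }
    int j = 0;
    for (int x = 0; x < n; ++x) {
        while (z[j + 1] < (double)x) ++j;
        long long dx = (long long)(x - v[j]);
        long long val = (long long)f[v[j]] + dx * dx;
        d[x] = (val >= INF_I) ? INF_I : (int)val;
    }
}

// Exact squared EDT over the refined grid given seed mask (d2 = 0 at seeds).
static void edt3(const RefGrid& g, std::vector<int>& D) {
    int m1 = g.m1, m2 = g.m2, m3 = g.m3;
    int mmax = std::max(m1, std::max(m2, m3));
    std::vector<int> f(mmax), d(mmax), v(mmax);
    std::vector<double> z(mmax + 1);

    // pass 1: along axis 1, simple two-sweep (1D distance then square)
    for (int r3 = 0; r3 < m3; ++r3)
        for (int r2 = 0; r2 < m2; ++r2) {
            size_t base = ridx(g, 0, r2, r3);
            int dist = INF_I;
            for (int r1 = 0; r1 < m1; ++r1) {
                if (D[base + r1] == 0) dist = 0; else if (dist < INF_I) ++dist;
                D[base + r1] = dist;
            }
            dist = INF_I;
            for (int r1 = m1 - 1; r1 >= 0; --r1) {
                if (D[base + r1] == 0) dist = 0; else if (dist < INF_I) ++dist;
                if (dist < D[base + r1]) D[base + r1] = dist;
            }
            for (int r1 = 0; r1 < m1; ++r1) {
                long long val = (long long)D[base + r1];
                D[base + r1] = (val >= INF_I || val * val >= INF_I) ? INF_I : (int)(val * val);
            }
        }
    // pass 2: along axis 2
    for (int r3 = 0; r3 < m3; ++r3)
        for (int r1 = 0; r1 < m1; ++r1) {
            for (int r2 = 0; r2 < m2; ++r2) f[r2] = D[ridx(g, r1, r2, r3)];
            fh_line(f.data(), d.data(), m2, v.data(), z.data());
            for (int r2 = 0; r2 < m2; ++r2) D[ridx(g, r1, r2, r3)] = d[r2];
        }
    // pass 3: along axis 3
    for (int r2 = 0; r2 < m2; ++r2)
        for (int r1 = 0; r1 < m1; ++r1) {
            for (int r3 = 0; r3 < m3; ++r3) f[r3] = D[ridx(g, r1, r2, r3)];
            fh_line(f.data(), d.data(), m3, v.data(), z.data());
            for (int r3 = 0; r3 < m3; ++r3) D[ridx(g, r1, r2, r3)] = d[r3];
        }
}

// sphere(c, dc) is contained in sphere(nb, dnb) iff dnb >= dc + |c-nb|.
// Exact integer certificate: L = d2nb - d2c - delta2 >= 0 and L^2 >= 4*delta2*d2c.
static inline bool contained(long long d2c, long long d2nb, long long delta2) {
    long long L = d2nb - d2c - delta2;
    if (L < 0) return false;
    return L * L >= 4LL * delta2 * d2c;
}

static void mark_sphere(const RefGrid& g, std::vector<int>& T2,
                        int r1, int r2, int r3, int d2) {
    int s = isqrt_floor(d2);
    // voxel v covered iff sum (2v+koff - r)^2 <= d2
    int lo1 = (r1 - g.koff - s), hi1 = (r1 - g.koff + s);
    int lo2 = (r2 - g.koff - s), hi2 = (r2 - g.koff + s);
    int lo3 = (r3 - g.koff - s), hi3 = (r3 - g.koff + s);
    // convert twice-voxel bounds to voxel index bounds
    int a1 = std::max(0, (int)std::ceil(lo1 / 2.0));
    int b1 = std::min(g.n1 - 1, (int)std::floor(hi1 / 2.0));
    int a2 = std::max(0, (int)std::ceil(lo2 / 2.0));
    int b2 = std::min(g.n2 - 1, (int)std::floor(hi2 / 2.0));
    int a3 = std::max(0, (int)std::ceil(lo3 / 2.0));
    int b3 = std::min(g.n3 - 1, (int)std::floor(hi3 / 2.0));
    for (int v3 = a3; v3 <= b3; ++v3) {
        long long e3 = 2LL * v3 + g.koff - r3; e3 *= e3;
        if (e3 > d2) continue;
        for (int v2 = a2; v2 <= b2; ++v2) {
            long long e2 = 2LL * v2 + g.koff - r2; e2 *= e2;
            long long e23 = e2 + e3;
            if (e23 > d2) continue;
            size_t base = vidx(g, 0, v2, v3);
            for (int v1 = a1; v1 <= b1; ++v1) {
                if (T2[base + v1] >= d2) continue;
                long long e1 = 2LL * v1 + g.koff - r1; e1 *= e1;
                if (e1 + e23 <= d2) T2[base + v1] = d2;
            }
        }
    }
}

// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dims,
                                  bool outside_bg) {
    RefGrid g;
    g.n1 = dims[0]; g.n2 = dims[1]; g.n3 = dims[2];
    g.outside_bg = outside_bg;
    g.koff = outside_bg ? 1 : 0;
    g.m1 = outside_bg ? 2 * g.n1 + 1 : 2 * g.n1 - 1;
    g.m2 = outside_bg ? 2 * g.n2 + 1 : 2 * g.n2 - 1;
    g.m3 = outside_bg ? 2 * g.n3 + 1 : 2 * g.n3 - 1;

    size_t nvox = (size_t)g.n1 * g.n2 * g.n3;
    std::vector<int> mk(nvox);
    bool any_fg = false, any_bg = false;
    for (size_t i = 0; i < nvox; ++i) {
        mk[i] = mask[i] ? 1 : 0;
        if (mk[i]) any_fg = true; else any_bg = true;
    }
    if (!any_fg) stop("empty mask: no foreground voxels");
    if (!outside_bg && !any_bg)
        stop("mask fills the whole grid and the boundary is 'solid': thickness is unbounded");

    size_t nref = (size_t)g.m1 * g.m2 * g.m3;
    std::vector<int> D(nref);
    for (int r3 = 0; r3 < g.m3; ++r3)
        for (int r2 = 0; r2 < g.m2; ++r2)
            for (int r1 = 0; r1 < g.m1; ++r1)
                D[ridx(g, r1, r2, r3)] =
                    is_seed(g, mk.data(), r1, r2, r3) ? 0 : INF_I;

    edt3(g, D);

    // collect sphere centres (refined points with d2 > 0), prune those whose
    // sphere is certified to lie inside a 26-neighbour's sphere (distance ridge)
    struct C { int d2; int r1, r2, r3; };
    std::vector<C> centres;
    static const int off[26][3] = {
        {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},
        {-1,1,-1},{0,1,-1},{1,1,-1},{-1,-1,0},{0,-1,0},{1,-1,0},
        {-1,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},{-1,-1,1},
        {0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}};
    for (int r3 = 0; r3 < g.m3; ++r3)
        for (int r2 = 0; r2 < g.m2; ++r2)
            for (int r1 = 0; r1 < g.m1; ++r1) {
                int d2 = D[ridx(g, r1, r2, r3)];
                if (d2 <= 0) continue;
                bool redundant = false;
                for (int o = 0; o < 26 && !redundant; ++o) {
                    int s1 = r1 + off[o][0], s2 = r2 + off[o][1], s3 = r3 + off[o][2];
                    if (s1 < 0 || s1 >= g.m1 || s2 < 0 || s2 >= g.m2 ||
                        s3 < 0 || s3 >= g.m3) continue;
                    int d2n = D[ridx(g, s1, s2, s3)];
                    if (d2n <= d2) continue;
                    long long delta2 = (long long)off[o][0] * off[o][0] +
                                       (long long)off[o][1] * off[o][1] +
                                       (long long)off[o][2] * off[o][2];
                    if (contained(d2, d2n, delta2)) redundant = true;
                }
                if (!redundant) centres.push_back({d2, r1, r2, r3});
            }
    std::sort(centres.begin(), centres.end(),
              [](const C& a, const C& b) { return a.d2 > b.d2; });

    std::vector<int> T2(nvox, 0);
    for (const C& c : centres) mark_sphere(g, T2, c.r1, c.r2, c.r3, c.d2);

    NumericVector out(nvox);
    for (size_t i = 0; i < nvox; ++i)
        out[i] = mk[i] ? std::sqrt((double)T2[i]) : NA_REAL;
    // sqrt(d2) (refined units = half-voxels) equals the sphere diameter in voxels
    return out;
}

// Brute-force oracle: same geometric definition, computed by exhaustive
// search — direct minimization over background cubes for every candidate
// centre and unpruned covering.  No distance transform, no ridge.
// [[Rcpp::export]]
NumericVector cpp_brute_thickness(LogicalVector mask, IntegerVector dims,
                                  bool outside_bg) {
    RefGrid g;
    g.n1 = dims[0]; g.n2 = dims[1]; g.n3 = dims[2];
    g.outside_bg = outside_bg;
    g.koff = outside_bg ? 1 : 0;
    g.m1 = outside_bg ? 2 * g.n1 + 1 : 2 * g.n1 - 1;
    g.m2 = outside_bg ? 2 * g.n2 + 1 : 2 * g.n2 - 1;
    g.m3 = outside_bg ? 2 * g.n3 + 1 : 2 * g.n3 - 1;

    size_t nvox = (size_t)g.n1 * g.n2 * g.n3;
    std::vector<int> mk(nvox);
    bool any_fg = false, any_bg = false;
    for (size_t i = 0; i < nvox; ++i) {
        mk[i] = mask[i] ? 1 : 0;
        if (mk[i]) any_fg = true; else any_bg = true;
    }
    if (!any_fg) stop("empty mask: no foreground voxels");
    if (!outside_bg && !any_bg)
        stop("mask fills the whole grid and the boundary is 'solid': thickness is unbounded");

    // list background voxel cube centres (in twice-voxel units)
    std::vector<int> bg1, bg2, bg3;
    for (int v3 = 0; v3 < g.n3; ++v3)
        for (int v2 = 0; v2 < g.n2; ++v2)
            for (int v1 = 0; v1 < g.n1; ++v1)
                if (!mk[vidx(g, v1, v2, v3)]) {
                    bg1.push_back(2 * v1 + g.koff);
                    bg2.push_back(2 * v2 + g.koff);
                    bg3.push_back(2 * v3 + g.koff);
                }

    std::vector<int> T2(nvox, 0);
    for (int r3 = 0; r3 < g.m3; ++r3)
        for (int r2 = 0; r2 < g.m2; ++r2)
            for (int r1 = 0; r1 < g.m1; ++r1) {
                // exact squared distance from this refined point to the
                // background region (cubes have half-width 1 refined unit)
                long long d2 = INT64_MAX / 4;
                if (outside_bg) {
                    long long h = std::min(std::min((long long)r1, (long long)(g.m1 - 1 - r1)),
                               std::min(std::min((long long)r2, (long long)(g.m2 - 1 - r2)),
                                        std::min((long long)r3, (long long)(g.m3 - 1 - r3))));
                    d2 = h * h;  // distance to the domain hull
                }
                for (size_t b = 0; b < bg1.size(); ++b) {
                    long long a1 = std::llabs((long long)r1 - bg1[b]); a1 = a1 > 1 ? a1 - 1 : 0;
                    long long a2 = std::llabs((long long)r2 - bg2[b]); a2 = a2 > 1 ? a2 - 1 : 0;
                    long long a3 = std::llabs((long long)r3 - bg3[b]); a3 = a3 > 1 ? a3 - 1 : 0;
                    long long dd = a1 * a1 + a2 * a2 + a3 * a3;
                    if (dd < d2) d2 = dd;
                }
                if (d2 <= 0) continue;
                int s = isqrt_floor(d2);
                int a1v = std::max(0, (int)std::ceil((r1 - g.koff - s) / 2.0));
                int b1v = std::min(g.n1 - 1, (int)std::floor((r1 - g.koff + s) / 2.0));
                int a2v = std::max(0, (int)std::ceil((r2 - g.koff - s) / 2.0));
                int b2v = std::min(g.n2 - 1, (int)std::floor((r2 - g.koff + s) / 2.0));
                int a3v = std::max(0, (int)std::ceil((r3 - g.koff - s) / 2.0));
                int b3v = std::min(g.n3 - 1, (int)std::floor((r3 - g.koff + s) / 2.0));
                for (int v3 = a3v; v3 <= b3v; ++v3)
                    for (int v2 = a2v; v2 <= b2v; ++v2)
                        for (int v1 = a1v; v1 <= b1v; ++v1) {
                            long long e1 = 2LL * v1 + g.koff - r1;
                            long long e2 = 2LL * v2 + g.koff - r2;
                            long long e3 = 2LL * v3 + g.koff - r3;
                            long long dd = e1 * e1 + e2 * e2 + e3 * e3;
                            size_t iv = vidx(g, v1, v2, v3);
                            if (dd <= d2 && T2[iv] < d2) T2[iv] = (int)d2;
                        }
            }

    NumericVector out(nvox);
    for (size_t i = 0; i < nvox; ++i)
        out[i] = mk[i] ? std::sqrt((double)T2[i]) : NA_REAL;
    return out;
}

// Connected component labelling of a 3D binary array (26- or 6-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 26) {
    if (connectivity != 26 && connectivity != 6)
        stop("connectivity must be 6 or 26");
    int n1 = dims[0], n2 = dims[1], n3 = dims[2];
    size_t nvox = (size_t)n1 * n2 * n3;
    IntegerVector lab(nvox, 0);
    std::vector<size_t> stack;
    int cur = 0;
    for (size_t start = 0; start < nvox; ++start) {
        if (!mask[start] || lab[start] != 0) continue;
        ++cur;
        stack.clear();
        stack.push_back(start);
        lab[start] = cur;
        while (!stack.empty()) {
            size_t p = stack.back(); stack.pop_back();
            int v1 = (int)(p % n1);
            int v2 = (int)((p / n1) % n2);
            int v3 = (int)(p / ((size_t)n1 * n2));
            for (int d3 = -1; d3 <= 1; ++d3)
                for (int d2 = -1; d2 <= 1; ++d2)
                    for (int d1 = -1; d1 <= 1; ++d1) {
                        if (!d1 && !d2 && !d3) continue;
                        if (connectivity == 6 &&
                            std::abs(d1) + std::abs(d2) + std::abs(d3) != 1)
                            continue;
                        int w1 = v1 + d1, w2 = v2 + d2, w3 = v3 + d3;
                        if (w1 < 0 || w1 >= n1 || w2 < 0 || w2 >= n2 ||
                            w3 < 0 || w3 >= n3) continue;
                        size_t q = (size_t)w1 + (size_t)n1 * ((size_t)w2 + (size_t)n2 * w3);
                        if (mask[q] && lab[q] == 0) {
                            lab[q] = cur;
                            stack.push_back(q);
                        }
                    }
        }
    }
    return lab;
}
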