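#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Prominence-based local maxima detection on a 2-D integer image.
//
// Semantics (fixed here so that the R-level brute-force oracle and this
// implementation agree by construction):
//   (i)   candidates are connected plateaus of equal intensity with no
//         strictly higher neighbour under the requested connectivity;
//         a plateau spanning the whole image (flat image) is no maximum;
//   (ii)  a candidate at value v is rejected iff the connected component of
//         {pixels >= v - prominence} containing it holds a strictly higher
//         pixel (drop to the saddle towards higher ground <= prominence);
//   (iii) equal-valued accepted candidates connected within the same
//         tolerance region merge: only the plateau whose top-left (row-major
//         first) pixel comes first survives;
//   (iv)  the reported coordinate is the plateau centroid rounded to the
//         nearest pixel, half-ties rounding down (towards the image origin).
//
// Coordinates in the returned data frame are 0-based, x = column, y = row.

struct Plateau {
    int value;
    long long sumx, sumy;
    int size;
    int min_rowmajor;    // y * W + x of the first pixel in row-major order
    bool has_higher;     // any strictly higher neighbour
    bool touches_edge;
    std::vector<int> pixels; // linear indices y * W + x
};

// [[Rcpp::export]]
DataFrame cpp_find_maxima(IntegerMatrix img, double prominence,
                          int connectivity, bool exclude_edge) {
    const int H = img.nrow(), W = img.ncol();
    const long N = (long)H * (long)W;

    // neighbour offsets (dy, dx)
    static const int dy8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    static const int dx8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    static const int dy4[4] = {-1, 0, 0, 1};
    static const int dx4[4] = {0, -1, 1, 0};
    const int *DY = (connectivity == 4) ? dy4 : dy8;
    const int *DX = (connectivity == 4) ? dx4 : dx8;
    const int NB = (connectivity == 4) ? 4 : 8;

    // flatten for speed; linear index = y * W + x (row-major)
    std::vector<int> val(N);
    for (int y = 0; y < H; ++y)
        for (int x = 0; x < W; ++x)
            val[(long)y * W + x] = img(y, x);

    // --- 1. plateau labelling -------------------------------------------
    std::vector<int> label(N, -1);
    std::vector<Plateau> plateaus;
    std::vector<int> stack;
    for (long s = 0; s < N; ++s) {
        if (label[s] != -1) continue;
        int id = (int)plateaus.size();
        Plateau pl;
        pl.value = val[s];
        pl.sumx = pl.sumy = 0;
        pl.size = 0;
        pl.min_rowmajor = (int)s;
        pl.has_higher = false;
        pl.touches_edge = false;
        label[s] = id;
        stack.clear();
        stack.push_back((int)s);
        while (!stack.empty()) {
            int p = stack.back(); stack.pop_back();
            int py = p / W, px = p % W;
            pl.pixels.push_back(p);
            pl.sumx += px; pl.sumy += py; pl.size += 1;
            if (p < pl.min_rowmajor) pl.min_rowmajor = p;
            if (py == 0 || py == H - 1 || px == 0 || px == W - 1)
                pl.touches_edge = true;
            for (int k = 0; k < NB; ++k) {
                int ny = py + DY[k], nx = px + DX[k];
                if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
                int q = ny * W + nx;
                if (val[q] > pl.value) pl.has_higher = true;
                else if (val[q] == pl.value && label[q] == -1) {
                    label[q] = id;
                    stack.push_back(q);
                }
            }
        }
        plateaus.push_back(std::move(pl));
    }

    // --- 2. candidates, ordered by value desc then top-left pixel -------
    std::vector<int> cand;
    for (int i = 0; i < (int)plateaus.size(); ++i)
        if (!plateaus[i].has_higher && plateaus[i].size < N)
            cand.push_back(i);
    std::sort(cand.begin(), cand.end(), [&](int a, int b) {
        if (plateaus[a].value != plateaus[b].value)
            return plateaus[a].value > plateaus[b].value;
        return plateaus[a].min_rowmajor < plateaus[b].min_rowmajor;
    });
    std::vector<bool> is_cand(plateaus.size(), false);
    for (int id : cand) is_cand[id] = true;

    // --- 3. per-candidate tolerance flood -------------------------------
    std::vector<int> stamp(N, -1);
    std::vector<bool> killed(plateaus.size(), false);
    std::vector<int> accepted;
    std::vector<int> merged; // equal-valued candidate plateaus met in flood

    for (size_t ci = 0; ci < cand.size(); ++ci) {
        int id = cand[ci];
        if (killed[id]) continue;
        const Plateau &pl = plateaus[id];
        const double lo = (double)pl.value - prominence;
        bool rejected = false;
        merged.clear();
        stack.clear();
        for (int p : pl.pixels) { stamp[p] = id; stack.push_back(p); }
        while (!stack.empty() && !rejected) {
            int p = stack.back(); stack.pop_back();
            int py = p / W, px = p % W;
            for (int k = 0; k < NB; ++k) {
                int ny = py + DY[k], nx = px + DX[k];
                if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
                int q = ny * W + nx;
                if (stamp[q] == id) continue;
                if (val[q] > pl.value) { rejected = true; break; }
                if ((double)val[q] >= lo) {
                    stamp[q] = id;
                    stack.push_back(q);
                    int lq = label[q];
                    if (lq != id && is_cand[lq] && !killed[lq] &&
                        plateaus[lq].value == pl.value)
                        merged.push_back(lq);
                }
            }
        }
        if (!rejected) {
            accepted.push_back(id);
            for (int m : merged) killed[m] = true;
        }
    }

    // --- 4. coordinates, edge filter, output order ----------------------
    std::vector<int> ox, oy, ov;
    for (int id : accepted) {
        const Plateau &pl = plateaus[id];
        if (exclude_edge && pl.touches_edge) continue;
        double mx = (double)pl.sumx / pl.size;
        double my = (double)pl.sumy / pl.size;
        // nearest pixel, half-ties towards the origin
        int cx = (int)std::ceil(mx - 0.5);
        int cy = (int)std::ceil(my - 0.5);
        ox.push_back(cx); oy.push_back(cy); ov.push_back(pl.value);
    }
    std::vector<int> ord(ox.size());
    for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        if (ov[a] != ov[b]) return ov[a] > ov[b];
        if (oy[a] != oy[b]) return oy[a] < oy[b];
        return ox[a] < ox[b];
    });
    IntegerVector rx(ord.size()), ry(ord.size()), rv(ord.size());
    for (size_t i = 0; i < ord.size(); ++i) {
        rx[i] = ox[ord[i]]; ry[i] = oy[ord[i]]; rv[i] = ov[ord[i]];
    }
    return DataFrame::create(_["x"] = rx, _["y"] = ry, _["value"] = rv);
}
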