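#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Smith-Waterman-Gotoh local alignment with affine gaps.
// Gap cost convention: a gap of length L costs gap_open + L * gap_ext
// (both penalties passed as positive numbers).
//
// Tie-breaking is fixed so alignments are fully deterministic:
//  * the best-scoring cell is the first maximum in row-major scan order
//    (earliest read position, then earliest reference position);
//  * traceback prefers diagonal over deletion (gap in read) over insertion
//    (gap in reference);
//  * after traceback, single gaps are left-shifted within homopolymer runs
//    (score-neutral), so e.g. the c.261delG gap always sits at the leftmost
//    position of its run.

static const int NEG_INF = -1000000000;

// left-align gaps within homopolymers on the aligned (gapped) strings;
// a shift is applied only when it is score-neutral, i.e. the base entering
// the gap equals the base leaving it.
static void left_align_gaps(std::string &a_read, std::string &a_ref) {
    const size_t n = a_read.size();
    bool moved = true;
    while (moved) {
        moved = false;
        for (size_t i = 1; i < n; ++i) {
            // deletion column: gap in read over a reference base; the gap
            // shifts left through the read only — the reference stays fixed
            if (a_read[i] == '-' && a_read[i - 1] != '-' && a_ref[i - 1] != '-') {
                // find end of this gap run
                size_t j = i;
                while (j + 1 < n && a_read[j + 1] == '-') ++j;
                if (a_ref[i - 1] == a_ref[j]) {
                    char rb = a_read[i - 1];
                    for (size_t k = i; k <= j; ++k) a_read[k - 1] = a_read[k];
                    a_read[j] = rb;
                    moved = true;
                }
            }
            // insertion column: gap in reference under a read base; the gap
            // shifts left through the reference only
            if (a_ref[i] == '-' && a_ref[i - 1] != '-' && a_read[i - 1] != '-') {
                size_t j = i;
                while (j + 1 < n && a_ref[j + 1] == '-') ++j;
                if (a_read[i - 1] == a_read[j]) {
                    char fb = a_ref[i - 1];
                    for (size_t k = i; k <= j; ++k) a_ref[k - 1] = a_ref[k];
                    a_ref[j] = fb;
                    moved = true;
                }
            }
        }
    }
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string read, std::string ref,
                  int match = 2, int mismatch = -4,
                  int gap_open = 4, int gap_ext = 2) {
    const int m = (int) read.size();
    const int n = (int) ref.size();
    if (m == 0 || n == 0)
        return List::create(_["score"] = 0);

    // H: best score ending at (i,j); D: gap in read (ref consumed);
    // I: gap in ref (read consumed). Row-major (m+1) x (n+1).
    std::vector<int> H((size_t)(m + 1) * (n + 1), 0);
    std::vector<int> D((size_t)(m + 1) * (n + 1), NEG_INF);
    std::vector<int> I((size_t)(m + 1) * (n + 1), NEG_INF);
    const int W = n + 1;

    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
        const char rc = read[(size_t)i - 1];
        for (int j = 1; j <= n; ++j) {
            const int idx = i * W + j;
            int d1 = H[idx - 1] - gap_open - gap_ext;
            int d2 = D[idx - 1] - gap_ext;
            D[idx] = d1 >= d2 ? d1 : d2;
            int i1 = H[idx - W] - gap_open - gap_ext;
            int i2 = I[idx - W] - gap_ext;
            I[idx] = i1 >= i2 ? i1 : i2;
            const int s = (rc == ref[(size_t)j - 1]) ? match : mismatch;
            int h = H[idx - W - 1] + s;
            if (D[idx] > h) h = D[idx];
            if (I[idx] > h) h = I[idx];
            if (h < 0) h = 0;
            H[idx] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }

    if (best <= 0)
        return List::create(_["score"] = 0);

    // traceback
    std::string a_read, a_ref;
    int i = bi, j = bj;
    int state = 0;  // 0 = H, 1 = D, 2 = I
    while (i > 0 || j > 0) {
        const int idx = i * W + j;
        if (state == 0) {
            if (H[idx] == 0) break;
            const int s = (read[(size_t)i - 1] == ref[(size_t)j - 1]) ? match : mismatch;
            if (i > 0 && j > 0 && H[idx] == H[idx - W - 1] + s) {
                a_read.push_back(read[(size_t)i - 1]);
                a_ref.push_back(ref[(size_t)j - 1]);
                --i; --j;
            } else if (H[idx] == D[idx]) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) {
            a_read.push_back('-');
            a_ref.push_back(ref[(size_t)j - 1]);
            const int idx2 = i * W + j;
            if (D[idx2] == D[idx2 - 1] - gap_ext) {
                --j;  // stay in D
            } else {
                --j;
                state = 0;
            }
        } else {
            a_read.push_back(read[(size_t)i - 1]);
            a_ref.push_back('-');
            const int idx2 = i * W + j;
            if (I[idx2] == I[idx2 - W] - gap_ext) {
                --i;
            } else {
                --i;
                state = 0;
            }
        }
    }
    std::reverse(a_read.begin(), a_read.end());
    std::reverse(a_ref.begin(), a_ref.end());

    left_align_gaps(a_read, a_ref);

    // 1-based coordinates of the aligned region
    int read_start = i + 1, ref_start = j + 1;
    int read_end = bi, ref_end = bj;
    int matches = 0;
    for (size_t k = 0; k < a_read.size(); ++k)
        if (a_read[k] == a_ref[k]) ++matches;

    return List::create(
        _["score"] = best,
        _["read_start"] = read_start, _["read_end"] = read_end,
        _["ref_start"] = ref_start, _["ref_end"] = ref_end,
        _["aligned_read"] = a_read, _["aligned_ref"] = a_ref,
        _["matches"] = matches,
        _["columns"] = (int) a_read.size());
}
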