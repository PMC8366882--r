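#include <Rcpp.h>
using namespace Rcpp;

// Semi-global pairwise alignment with affine gap costs.
//
// Scoring: +match for identical characters, +mismatch otherwise (no
// ambiguity-aware scoring: IUPAC codes score as plain characters; they are
// excluded later when identity and distances are counted). A gap run of
// length L costs gap_open + L * gap_extend, the convention used by the
// common pairwise aligners this one is cross-checked against.
//
// free_end_a: terminal columns where sequence a holds the gap are free
//             (i.e. b may overhang a at no cost); free_end_b likewise.
// With both flags set this is the classic ends-free "overlap" alignment.
//
// States: M = a[i] paired with b[j]; X = a[i] against a gap in b's row;
//         Y = b[j] against a gap in a's row.
//
// Scores roll over two rows; the traceback is one packed byte per cell
// (2 bits per state), keeping the working set small.

static const double NEG_INF = -1e30; // large but additive-safe

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    bool free_end_a, bool free_end_b) {
    const int n = (int) a.size();
    const int m = (int) b.size();
    if (n < 1 || m < 1) stop("sequences must be nonempty");

    const size_t W = (size_t)(m + 1);
    std::vector<double> M0(W), X0(W), Y0(W), M1(W), X1(W), Y1(W);
    // packed predecessors: bits 0-1 for M, 2-3 for X, 4-5 for Y
    // (0=M, 1=X, 2=Y, 3=origin/terminal)
    std::vector<unsigned char> tb((size_t)(n + 1) * W, 0x3F);

    M0[0] = 0.0; X0[0] = Y0[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        M0[j] = X0[j] = NEG_INF;
        Y0[j] = free_end_a ? 0.0 : -(gap_open + j * gap_extend);
        tb[j] = (unsigned char)(0x0F | ((j == 1 ? 3 : 2) << 4));
    }

    // row-final scores kept for the ends-free end-cell scan
    std::vector<double> lastColM(n + 1), lastColX(n + 1), lastColY(n + 1);
    lastColM[0] = M0[m]; lastColX[0] = X0[m]; lastColY[0] = Y0[m];

    const double go_e = gap_open + gap_extend;
    for (int i = 1; i <= n; ++i) {
        const char ai = a[i - 1];
        unsigned char *trow = &tb[(size_t) i * W];
        M1[0] = Y1[0] = NEG_INF;
        X1[0] = free_end_b ? 0.0 : -(gap_open + i * gap_extend);
        trow[0] = (unsigned char)(0x03 | (((i == 1) ? 3 : 1) << 2) | 0x30);
        for (int j = 1; j <= m; ++j) {
            const double s = (ai == b[j - 1]) ? match : mismatch;
            // M state from (i-1, j-1)
            double best = M0[j - 1]; unsigned pm = 0;
            if (X0[j - 1] > best) { best = X0[j - 1]; pm = 1; }
            if (Y0[j - 1] > best) { best = Y0[j - 1]; pm = 2; }
            const double Mij = best + s;
            // X state from (i-1, j)
            best = X0[j] - gap_extend; unsigned px = 1;
            if (M0[j] - go_e > best) { best = M0[j] - go_e; px = 0; }
            if (Y0[j] - go_e > best) { best = Y0[j] - go_e; px = 2; }
            const double Xij = best;
            // Y state from (i, j-1)
            best = Y1[j - 1] - gap_extend; unsigned py = 2;
            if (M1[j - 1] - go_e > best) { best = M1[j - 1] - go_e; py = 0; }
            if (X1[j - 1] - go_e > best) { best = X1[j - 1] - go_e; py = 1; }
            M1[j] = Mij; X1[j] = Xij; Y1[j] = best;
            trow[j] = (unsigned char)(pm | (px << 2) | (py << 4));
        }
        lastColM[i] = M1[m]; lastColX[i] = X1[m]; lastColY[i] = Y1[m];
        std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
    }
    // after the loop, row n lives in the "0" arrays
    // choose end cell: (n, m) always; (n, j<m) if trailing a-row gaps
    // free; (i<n, m) if trailing b-row gaps free. Ties prefer larger i,
    // then larger j, then state order M, X, Y.
    int bi = n, bj = m, bs = 0;
    double bscore = NEG_INF * 2;
    {
        const double v[3] = { M0[m], X0[m], Y0[m] };
        for (int s = 0; s < 3; ++s)
            if (v[s] > bscore) { bscore = v[s]; bs = s; }
    }
    if (free_end_a) {
        for (int j = m - 1; j >= 0; --j) {
            const double v[3] = { M0[j], X0[j], Y0[j] };
            for (int s = 0; s < 3; ++s)
                if (v[s] > bscore) { bscore = v[s]; bi = n; bj = j; bs = s; }
        }
    }
    if (free_end_b) {
        for (int i = n - 1; i >= 0; --i) {
            const double v[3] = { lastColM[i], lastColX[i], lastColY[i] };
            for (int s = 0; s < 3; ++s)
                if (v[s] > bscore) { bscore = v[s]; bi = i; bj = m; bs = s; }
        }
    }
    if (bscore <= NEG_INF / 2) stop("alignment failed (no finite score)");

    // traceback from (bi, bj, bs), then pad the free overhangs
    std::string ra, rb;
    ra.reserve(n + m); rb.reserve(n + m);
    for (int j = m; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
    for (int i = n; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
    int i = bi, j = bj, s = bs;
    while (i > 0 || j > 0) {
        const unsigned char t = tb[(size_t) i * W + j];
        unsigned prev;
        if (s == 0) {
            if (i == 0 || j == 0) break; // origin
            prev = t & 0x3;
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
        } else if (s == 1) {
            prev = (t >> 2) & 0x3;
            ra.push_back(a[i - 1]); rb.push_back('-'); --i;
        } else {
            prev = (t >> 4) & 0x3;
            ra.push_back('-'); rb.push_back(b[j - 1]); --j;
        }
        if (prev == 3) break;
        s = (int) prev;
    }
    while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
    while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());

    return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                        _["score"] = bscore);
}

// Tally alignment columns: compared (both rows an unambiguous base),
// matches, transitions (A<->G, C<->T) and transversions among them.
// [[Rcpp::export(name = ".count_columns_cpp")]]
IntegerVector count_columns_cpp(std::string a, std::string b) {
    if (a.size() != b.size()) stop("aligned strings differ in length");
    auto code = [](char c) -> int {
        switch (c) {
        case 'A': return 0; case 'G': return 1; // purines
        case 'C': return 2; case 'T': return 3; // pyrimidines
        default: return -1;
        }
    };
    int compared = 0, matches = 0, ts = 0, tv = 0;
    for (size_t k = 0; k < a.size(); ++k) {
        const int ca = code(a[k]), cb = code(b[k]);
        if (ca < 0 || cb < 0) continue;
        ++compared;
        if (ca == cb) ++matches;
        else if ((ca >> 1) == (cb >> 1)) ++ts;
        else ++tv;
    }
    return IntegerVector::create(_["n_columns"] = (int) a.size(),
                                 _["n_compared"] = compared,
                                 _["n_matches"] = matches,
                                 _["n_transitions"] = ts,
                                 _["n_transversions"] = tv);
}
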