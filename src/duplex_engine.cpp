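#include <Rcpp.h>
#include <array>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Base coding used throughout: A=0, C=1, G=2, T/U=3, other=-1.
// Pair classes: 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch.

static inline int pair_class(int m, int g) {
    if (m < 0 || g < 0) return 2;
    if ((m == 0 && g == 3) || (m == 3 && g == 0) ||
        (m == 2 && g == 1) || (m == 1 && g == 2)) return 0;
    if ((m == 2 && g == 3) || (m == 3 && g == 2)) return 1;
    return 2;
}

// Enumerate all maximal ungapped antiparallel duplexes between an mRNA
// (5'->3') and a gRNA (5'->3') that satisfy the threshold set.  mRNA
// position i pairs gRNA position j with i + j constant along a duplex
// (antiparallel geometry).  Windows are maximal per diagonal: no passing
// window properly contained in another passing window is reported.
// Returns a list of integer vectors:
//   mrna_start, mrna_end (0-based half-open), grna_start, grna_end,
//   score, n_wc, n_gu, n_mm, and a character vector of pair strings
//   ('|' WC, ':' GU, '#' MM; 5'->3' along the mRNA).
// [[Rcpp::export(name = ".duplex_scan_cpp")]]
List duplex_scan_cpp(IntegerVector m, IntegerVector g,
                     int seed_score, int seed_len, int min_len,
                     int min_score, int max_gu, int max_mm, int min_anchor,
                     int s_wc, int s_gu, int s_mm) {
    const int M = m.size(), G = g.size();
    std::vector<int> r_ms, r_me, r_gs, r_ge, r_sc, r_wc, r_gu, r_mm;
    std::vector<std::string> r_ps;
    if (M == 0 || G == 0 || M < min_len || G < min_len)
        goto done;

    {
        std::vector<signed char> mv(M), gv(G);
        for (int i = 0; i < M; ++i) mv[i] = (signed char)m[i];
        for (int j = 0; j < G; ++j) gv[j] = (signed char)g[j];
        // pair-class lookup over codes -1..3 (shifted by 1)
        signed char lut[5][5];
        for (int a = -1; a <= 3; ++a)
            for (int b = -1; b <= 3; ++b)
                lut[a + 1][b + 1] = (signed char)pair_class(a, b);
        std::vector<int> cls, csum_sc, csum_mm, csum_gu;
        cls.reserve(std::min(M, G));
        for (int d = 0; d <= M + G - 2; ++d) {
            int i0 = std::max(0, d - (G - 1));
            int i1 = std::min(M - 1, d);
            int n = i1 - i0 + 1;
            if (n < min_len) continue;
            cls.assign(n, 2);
            {
                // single pass: classify and track the longest stretch with
                // <= max_mm mismatches; most diagonals are rejected here
                int lo = 0, mm_in = 0, best = 0;
                const signed char *mp = mv.data() + i0;
                const signed char *gp = gv.data() + d - i0;
                for (int t = 0; t < n; ++t) {
                    int c = lut[mp[t] + 1][*(gp - t) + 1];
                    cls[t] = c;
                    if (c == 2) ++mm_in;
                    while (mm_in > max_mm) {
                        if (cls[lo] == 2) --mm_in;
                        ++lo;
                    }
                    if (t - lo + 1 > best) best = t - lo + 1;
                }
                if (best < std::max(min_len, seed_len)) continue;
            }
            // prefix sums over the diagonal
            csum_sc.assign(n + 1, 0);
            csum_mm.assign(n + 1, 0);
            csum_gu.assign(n + 1, 0);
            for (int t = 0; t < n; ++t) {
                int sc = cls[t] == 0 ? s_wc : (cls[t] == 1 ? s_gu : s_mm);
                csum_sc[t + 1] = csum_sc[t] + sc;
                csum_mm[t + 1] = csum_mm[t] + (cls[t] == 2);
                csum_gu[t + 1] = csum_gu[t] + (cls[t] == 1);
            }
            // wcrun[t]: length of WC run ending at t (anchor check)
            std::vector<int> wcrun(n, 0);
            for (int t = 0; t < n; ++t)
                wcrun[t] = (cls[t] == 0) ? (t ? wcrun[t - 1] + 1 : 1) : 0;
            // rolling seed-window scores (window starts at t)
            int nseed = n - seed_len + 1;
            if (nseed < 1) continue;
            std::vector<int> seedsc(nseed);
            for (int t = 0; t < nseed; ++t)
                seedsc[t] = csum_sc[t + seed_len] - csum_sc[t];

            std::vector<std::array<int, 2>> pass; // [a, b] inclusive
            int bmax = -1; // two-pointer upper end with mm <= max_mm
            for (int a = 0; a < n; ++a) {
                if (bmax < a - 1) bmax = a - 1;
                while (bmax + 1 < n &&
                       csum_mm[bmax + 2] - csum_mm[a] <= max_mm) ++bmax;
                int b0 = a + std::max(min_len, seed_len) - 1;
                if (b0 > bmax) continue;
                int runmax = INT_MIN; // max seed score over starts in [a, b-seed_len+1]
                // pre-roll the running max up to the first b
                for (int t = a; t <= b0 - seed_len + 1; ++t)
                    runmax = std::max(runmax, seedsc[t]);
                for (int b = b0; b <= bmax; ++b) {
                    if (b > b0) {
                        int t = b - seed_len + 1;
                        if (t >= a && t < nseed)
                            runmax = std::max(runmax, seedsc[t]);
                    }
                    if (csum_gu[b + 1] - csum_gu[a] > max_gu) continue;
                    if (csum_sc[b + 1] - csum_sc[a] < min_score) continue;
                    if (min_anchor > 0 && wcrun[b] < min_anchor) continue;
                    if (runmax < seed_score) continue;
                    pass.push_back({a, b});
                }
            }
            // group overlapping windows on this diagonal and keep the
            // best-scoring one per group (ties: longer, then leftmost);
            // `pass` is sorted by a (then b) by construction
            std::vector<std::array<int, 2>> kept;
            size_t u0 = 0;
            while (u0 < pass.size()) {
                size_t u1 = u0;
                int reach = pass[u0][1];
                int besti = (int)u0;
                int bests = csum_sc[pass[u0][1] + 1] - csum_sc[pass[u0][0]];
                while (u1 + 1 < pass.size() && pass[u1 + 1][0] <= reach) {
                    ++u1;
                    reach = std::max(reach, pass[u1][1]);
                    int sc = csum_sc[pass[u1][1] + 1] - csum_sc[pass[u1][0]];
                    int blen = pass[besti][1] - pass[besti][0];
                    int ulen = pass[u1][1] - pass[u1][0];
                    if (sc > bests || (sc == bests && ulen > blen))
                        { bests = sc; besti = (int)u1; }
                }
                kept.push_back(pass[besti]);
                u0 = u1 + 1;
            }
            for (size_t u = 0; u < kept.size(); ++u) {
                int a = kept[u][0], b = kept[u][1];
                int ia = i0 + a, ib = i0 + b;      // mRNA index range
                int ja = d - ib, jb = d - ia;      // gRNA index range
                r_ms.push_back(ia); r_me.push_back(ib + 1);
                r_gs.push_back(ja); r_ge.push_back(jb + 1);
                r_sc.push_back(csum_sc[b + 1] - csum_sc[a]);
                r_mm.push_back(csum_mm[b + 1] - csum_mm[a]);
                r_gu.push_back(csum_gu[b + 1] - csum_gu[a]);
                r_wc.push_back((b - a + 1) -
                               (csum_mm[b + 1] - csum_mm[a]) -
                               (csum_gu[b + 1] - csum_gu[a]));
                std::string ps(b - a + 1, '#');
                for (int t = a; t <= b; ++t)
                    ps[t - a] = cls[t] == 0 ? '|' : (cls[t] == 1 ? ':' : '#');
                r_ps.push_back(ps);
            }
        }
    }
done:
    return List::create(
        _["mrna_start"] = wrap(r_ms), _["mrna_end"] = wrap(r_me),
        _["grna_start"] = wrap(r_gs), _["grna_end"] = wrap(r_ge),
        _["score"] = wrap(r_sc), _["n_wc"] = wrap(r_wc),
        _["n_gu"] = wrap(r_gu), _["n_mm"] = wrap(r_mm),
        _["pair_string"] = wrap(r_ps));
}

// Smith-Waterman of a sequence against its own reverse complement with
// linear gap penalties, restricted to end cells with non-overlapping arms
// (einverted-style inverted-repeat search).  Iteratively extracts the best
// local alignment, masks its arm positions and repeats.
// seq: base codes; returns list of hits with 0-based half-open arm
// coordinates on the forward strand, score, mismatches, gaps, and the two
// aligned arm strings (arm2 given 5'->3' on the forward strand is implied;
// the alignment pairs arm1 with the reverse complement of arm2).
// [[Rcpp::export(name = ".inverted_repeat_cpp")]]
List inverted_repeat_cpp(IntegerVector seq, int match, int mismatch,
                         int gap, int threshold, int max_hits) {
    const int L = seq.size();
    std::vector<int> s(seq.begin(), seq.end());
    std::vector<bool> masked(L, false);
    std::vector<int> h_a1s, h_a1e, h_a2s, h_a2e, h_sc, h_mm, h_gap;

    for (int hit = 0; hit < max_hits; ++hit) {
        // rc[j] (1-based j) = complement of s[L-j] (0-based)
        // H is (L+1) x (L+1); traceback codes 0 stop, 1 diag, 2 up(i), 3 left(j)
        std::vector<int> H((L + 1) * (L + 1), 0);
        std::vector<unsigned char> TB((L + 1) * (L + 1), 0);
        int best = 0, bi = 0, bj = 0;
        for (int i = 1; i <= L; ++i) {
            int base_i = masked[i - 1] ? -2 : s[i - 1];
            for (int j = 1; j <= L; ++j) {
                int p = L - j;           // 0-based original pos of rc[j]
                int base_j = masked[p] ? -3 : (s[p] >= 0 ? 3 - s[p] : -3);
                int sub = (base_i >= 0 && base_i == base_j) ? match : mismatch;
                int diag = H[(i - 1) * (L + 1) + (j - 1)] + sub;
                int up   = H[(i - 1) * (L + 1) + j] + gap;
                int left = H[i * (L + 1) + (j - 1)] + gap;
                int v = 0; unsigned char tb = 0;
                if (diag > v) { v = diag; tb = 1; }
                if (up > v)   { v = up;   tb = 2; }
                if (left > v) { v = left; tb = 3; }
                H[i * (L + 1) + j] = v;
                TB[i * (L + 1) + j] = tb;
                // valid end cell: arms disjoint (i + j <= L);
                // deterministic tie-break: first (i, then j) encountered wins
                if (i + j <= L && v > best) { best = v; bi = i; bj = j; }
            }
        }
        if (best < threshold) break;
        // traceback
        int i = bi, j = bj, mm = 0, ng = 0;
        int i_end = bi, j_end = bj;
        while (i > 0 && j > 0 && TB[i * (L + 1) + j] != 0) {
            unsigned char tb = TB[i * (L + 1) + j];
            if (tb == 1) {
                int base_j = s[L - j] >= 0 ? 3 - s[L - j] : -3;
                if (!(s[i - 1] >= 0 && s[i - 1] == base_j)) ++mm;
                --i; --j;
            } else if (tb == 2) { ++ng; --i; }
            else { ++ng; --j; }
        }
        int a1s = i, a1e = i_end;                  // 0-based half-open on fwd
        int a2s = L - j_end, a2e = L - j;          // 0-based half-open on fwd
        h_a1s.push_back(a1s); h_a1e.push_back(a1e);
        h_a2s.push_back(a2s); h_a2e.push_back(a2e);
        h_sc.push_back(best); h_mm.push_back(mm); h_gap.push_back(ng);
        for (int k = a1s; k < a1e; ++k) masked[k] = true;
        for (int k = a2s; k < a2e; ++k) masked[k] = true;
    }
    return List::create(
        _["arm1_start"] = wrap(h_a1s), _["arm1_end"] = wrap(h_a1e),
        _["arm2_start"] = wrap(h_a2s), _["arm2_end"] = wrap(h_a2e),
        _["score"] = wrap(h_sc), _["mismatches"] = wrap(h_mm),
        _["gaps"] = wrap(h_gap));
}

// Hamming-distance occurrence scan: positions (0-based) in `hay` where
// `needle` matches with at most max_mm substitutions, plus the distance.
// [[Rcpp::export(name = ".hamming_scan_cpp")]]
List hamming_scan_cpp(IntegerVector hay, IntegerVector needle, int max_mm) {
    const int H = hay.size(), N = needle.size();
    std::vector<int> pos, dist;
    for (int o = 0; o + N <= H; ++o) {
        int d = 0;
        for (int k = 0; k < N && d <= max_mm; ++k)
            if (hay[o + k] != needle[k]) ++d;
        if (d <= max_mm) { pos.push_back(o); dist.push_back(d); }
    }
    return List::create(_["pos"] = wrap(pos), _["dist"] = wrap(dist));
}
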