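#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
static inline int iupac_bits(char c) {
    switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1 | 4;
    case 'Y': return 2 | 8;
    case 'S': return 2 | 4;
    case 'W': return 1 | 8;
    case 'K': return 4 | 8;
    case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8;
    case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8;
    case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default:  return 0;
    }
}

// Concrete read base as a single-bit mask; 0 for anything ambiguous.
static inline int base2bits_mask(char c) {
    switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': case 'U': return 8;
    default: return 0;
    }
}

// Hamming distance between equal-length string pairs (elementwise over two
// vectors; the shorter vector is recycled only if length 1). NA when lengths
// differ within a pair.
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
    R_xlen_t n = std::max(a.size(), b.size());
    if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
        stop("a and b must have equal length (or one of length 1)");
    IntegerVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        const char *sa = CHAR(STRING_ELT(a, a.size() == 1 ? 0 : k));
        const char *sb = CHAR(STRING_ELT(b, b.size() == 1 ? 0 : k));
        size_t la = std::strlen(sa), lb = std::strlen(sb);
        if (la != lb) { out[k] = NA_INTEGER; continue; }
        int d = 0;
        for (size_t i = 0; i < la; ++i) if (sa[i] != sb[i]) ++d;
        out[k] = d;
    }
    return out;
}

// Mismatches of an IUPAC pattern against each sequence, anchored at 0-based
// offset `at`. A pattern position matches when the read base is a concrete
// A/C/G/T within the pattern's IUPAC set; ambiguous read bases (N etc.)
// never match. Sequences too short get NA.
// [[Rcpp::export]]
IntegerVector cpp_iupac_mismatch(CharacterVector seqs, std::string pattern, int at) {
    size_t lp = pattern.size();
    std::vector<int> pbits(lp);
    for (size_t i = 0; i < lp; ++i) pbits[i] = iupac_bits(pattern[i]);
    R_xlen_t n = seqs.size();
    IntegerVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        const char *s = CHAR(STRING_ELT(seqs, k));
        size_t ls = std::strlen(s);
        if (ls < static_cast<size_t>(at) + lp) { out[k] = NA_INTEGER; continue; }
        int m = 0;
        for (size_t i = 0; i < lp; ++i) {
            int b = base2bits_mask(s[at + i]);
            if (b == 0 || (b & pbits[i]) == 0) ++m;
        }
        out[k] = m;
    }
    return out;
}

// Barcode assignment: index (1-based) of the unique barcode within
// max_mismatch of the read prefix; 0 = none within tolerance; -1 = ambiguous
// (two or more barcodes within tolerance).
// [[Rcpp::export]]
IntegerVector cpp_assign_barcode(CharacterVector seqs, CharacterVector barcodes,
                                 int max_mismatch) {
    R_xlen_t n = seqs.size(), nb = barcodes.size();
    std::vector<std::string> bcs(nb);
    for (R_xlen_t j = 0; j < nb; ++j) bcs[j] = as<std::string>(barcodes[j]);
    IntegerVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        const char *s = CHAR(STRING_ELT(seqs, k));
        size_t ls = std::strlen(s);
        int hit = 0, nhits = 0;
        for (R_xlen_t j = 0; j < nb; ++j) {
            size_t lb = bcs[j].size();
            if (ls < lb) continue;
            int d = 0;
            for (size_t i = 0; i < lb && d <= max_mismatch; ++i)
                if (s[i] != bcs[j][i]) ++d;
            if (d <= max_mismatch) { ++nhits; hit = static_cast<int>(j) + 1; }
        }
        out[k] = (nhits == 1) ? hit : (nhits == 0 ? 0 : -1);
    }
    return out;
}

// FLASH-style ungapped merge of oriented pairs. `rev` must already be
// reverse-complemented and its qualities reversed. Scans overlap lengths v
// from the largest feasible down to min_overlap, keeps the v with the lowest
// mismatch fraction (ties -> larger v); rejects if the best fraction exceeds
// max_mismatch_frac. Overlap consensus: disagreeing bases take the
// higher-quality call (tie -> forward base); merged quality is the positional
// maximum over the whole overlap.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector fqual,
                     CharacterVector rev, CharacterVector rqual,
                     int min_overlap, double max_mismatch_frac) {
    R_xlen_t n = fwd.size();
    if (fqual.size() != n || rev.size() != n || rqual.size() != n)
        stop("all four vectors must have equal length");
    CharacterVector mseq(n), mqual(n);
    IntegerVector status(n);  // 0 = merged, 1 = no acceptable overlap
    for (R_xlen_t k = 0; k < n; ++k) {
        const char *f  = CHAR(STRING_ELT(fwd, k));
        const char *fq = CHAR(STRING_ELT(fqual, k));
        const char *r  = CHAR(STRING_ELT(rev, k));
        const char *rq = CHAR(STRING_ELT(rqual, k));
        int L1 = static_cast<int>(std::strlen(f));
        int L2 = static_cast<int>(std::strlen(r));
        int vmax = std::min(L1, L2);
        int best_v = -1, best_m = 0;
        double best_ratio = 2.0;
        for (int v = vmax; v >= min_overlap; --v) {
            int m = 0;
            const char *fo = f + (L1 - v);
            for (int i = 0; i < v; ++i) if (fo[i] != r[i]) ++m;
            double ratio = static_cast<double>(m) / v;
            if (ratio < best_ratio) { best_ratio = ratio; best_v = v; best_m = m; }
            if (best_m == 0) break;  // cannot be beaten; ties prefer larger v
        }
        if (best_v < 0 || best_ratio > max_mismatch_frac) {
            mseq[k] = NA_STRING; mqual[k] = NA_STRING; status[k] = 1;
            continue;
        }
        int v = best_v, L = L1 + L2 - v;
        std::string s(L, 'N'), q(L, '!');
        for (int i = 0; i < L1 - v; ++i) { s[i] = f[i]; q[i] = fq[i]; }
        for (int i = 0; i < v; ++i) {
            char cf = f[L1 - v + i], cr = r[i];
            char qf = fq[L1 - v + i], qr = rq[i];
            int pos = L1 - v + i;
            if (cf == cr) s[pos] = cf;
            else s[pos] = (qr > qf) ? cr : cf;
            q[pos] = std::max(qf, qr);
        }
        for (int i = v; i < L2; ++i) { s[L1 + i - v] = r[i]; q[L1 + i - v] = rq[i]; }
        mseq[k] = s; mqual[k] = q; status[k] = 0;
    }
    return List::create(_["seq"] = mseq, _["qual"] = mqual, _["status"] = status);
}

// Btrim-style sliding-window truncation point. Returns, per read, the number
// of leading bases kept: the read is cut immediately before the first window
// (size `window`, step 1, 5'->3') whose mean quality is <= q_threshold.
// Reads shorter than the window are returned whole.
// [[Rcpp::export]]
IntegerVector cpp_window_keep_len(CharacterVector quals, double q_threshold,
                                  int window) {
    R_xlen_t n = quals.size();
    IntegerVector out(n);
    double thr_sum = q_threshold * window;
    for (R_xlen_t k = 0; k < n; ++k) {
        const char *q = CHAR(STRING_ELT(quals, k));
        int L = static_cast<int>(std::strlen(q));
        if (L < window) { out[k] = L; continue; }
        int sum = 0;
        for (int i = 0; i < window; ++i) sum += q[i] - 33;
        int keep = L;
        if (sum <= thr_sum) keep = 0;
        else {
            for (int i = 1; i + window <= L; ++i) {
                sum += (q[i + window - 1] - 33) - (q[i - 1] - 33);
                if (sum <= thr_sum) { keep = i; break; }
            }
        }
        out[k] = keep;
    }
    return out;
}

// Banded global (Needleman-Wunsch) alignment identity: match +1,
// mismatch -1, linear gap -2, end gaps penalized. Identity = matches /
// alignment columns of the optimal-score alignment. W < 0 runs the full
// (exact) dynamic program.
static double banded_identity(const char *a, int la, const char *b, int lb,
                              int W) {
    int delta = lb - la;
    int w1, w2;  // j in [i - w1, i + w2]
    if (W < 0) { w1 = la; w2 = lb; }
    else {
        w1 = W + (delta < 0 ? -delta : 0);
        w2 = W + (delta > 0 ? delta : 0);
    }
    const int BW = w1 + w2 + 1;
    const int NEG = -1000000000;
    std::vector<int> prev(BW, NEG), cur(BW, NEG);
    std::vector<unsigned char> dir(static_cast<size_t>(la + 1) * BW, 0);
    // band column index for (i, j): j - i + w1
    for (int j = 0; j <= std::min(lb, w2); ++j) {
        prev[j + w1] = -2 * j;
        dir[j + w1] = (j > 0) ? 2 : 0;  // 2 = left (gap in a)
    }
    for (int i = 1; i <= la; ++i) {
        int jlo = std::max(0, i - w1), jhi = std::min(lb, i + w2);
        std::fill(cur.begin(), cur.end(), NEG);
        for (int j = jlo; j <= jhi; ++j) {
            int bi = j - i + w1;
            int best = NEG; unsigned char d = 0;
            if (j == 0) { best = -2 * i; d = 1; }
            else {
                int diag = prev[bi];  // (i-1, j-1) -> same band column
                if (diag > NEG) {
                    int sc = diag + ((a[i - 1] == b[j - 1]) ? 1 : -1);
                    if (sc > best) { best = sc; d = 3; }  // 3 = diagonal
                }
            }
            if (bi + 1 < BW && prev[bi + 1] > NEG) {  // up: (i-1, j), gap in b
                int sc = prev[bi + 1] - 2;
                if (sc > best) { best = sc; d = 1; }
            }
            if (bi - 1 >= 0 && cur[bi - 1] > NEG) {   // left: (i, j-1)
                int sc = cur[bi - 1] - 2;
                if (sc > best) { best = sc; d = 2; }
            }
            cur[bi] = best;
            dir[static_cast<size_t>(i) * BW + bi] = d;
        }
        std::swap(prev, cur);
    }
    // traceback from (la, lb)
    int i = la, j = lb, matches = 0, cols = 0;
    if (prev[lb - la + w1] <= NEG) return 0.0;  // endpoint out of band
    while (i > 0 || j > 0) {
        unsigned char d = dir[static_cast<size_t>(i) * BW + (j - i + w1)];
        if (d == 3) { if (a[i - 1] == b[j - 1]) ++matches; --i; --j; }
        else if (d == 1) --i;
        else if (d == 2) --j;
        else break;
        ++cols;
    }
    return cols > 0 ? static_cast<double>(matches) / cols : 0.0;
}

// Exact pairwise identity under the clustering convention (full dynamic
// program; quadratic, for tests and annotation).
// [[Rcpp::export]]
NumericVector cpp_seq_identity(CharacterVector a, CharacterVector b) {
    R_xlen_t n = std::max(a.size(), b.size());
    if (a.size() != b.size() && a.size() != 1 && b.size() != 1)
        stop("a and b must have equal length (or one of length 1)");
    NumericVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        const char *sa = CHAR(STRING_ELT(a, a.size() == 1 ? 0 : k));
        const char *sb = CHAR(STRING_ELT(b, b.size() == 1 ? 0 : k));
        out[k] = banded_identity(sa, std::strlen(sa), sb, std::strlen(sb), -1);
    }
    return out;
}

static inline int base2bits(char c) {
    switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
    }
}

// First centroid (1-based, scan order) whose identity with the query reaches
// the threshold; 0 if none. Equal-length pairs take the gapless (Hamming)
// identity; unequal-length pairs a banded global alignment (band
// |length difference| + 16). Two sound prefilters skip hopeless candidates:
// a length-ratio cap (identity <= min/max length) and a shared-8-mer count
// bound (an alignment at >= thr identity over L columns has at most
// ~(1 - thr) L edit columns, each destroying at most 8 of the reference's
// 8-mers).
// [[Rcpp::export]]
int cpp_first_match(std::string query, CharacterVector refs, double thr) {
    const char *q = query.c_str();
    int lq = static_cast<int>(query.size());
    double eps = 1e-12;
    // query 8-mer presence table
    std::vector<unsigned char> kmer(1 << 16, 0);
    if (lq >= 8) {
        int code = 0, valid = 0;
        for (int i = 0; i < lq; ++i) {
            int b = base2bits(q[i]);
            if (b < 0) { valid = 0; code = 0; continue; }
            code = ((code << 2) | b) & 0xFFFF;
            if (++valid >= 8) kmer[code] = 1;
        }
    }
    for (R_xlen_t j = 0; j < refs.size(); ++j) {
        const char *r = CHAR(STRING_ELT(refs, j));
        int lr = static_cast<int>(std::strlen(r));
        int lmin = std::min(lq, lr), lmax = std::max(lq, lr);
        if (static_cast<double>(lmin) / lmax < thr - eps) continue;
        if (lq >= 8 && lr >= 8) {
            int shared = 0, code = 0, valid = 0;
            for (int i = 0; i < lr; ++i) {
                int b = base2bits(r[i]);
                if (b < 0) { valid = 0; code = 0; continue; }
                code = ((code << 2) | b) & 0xFFFF;
                if (++valid >= 8 && kmer[code]) ++shared;
            }
            int max_edits = static_cast<int>((1.0 - thr) * lmax) + 1;
            if (shared < lmin - 7 - 8 * max_edits - 8) continue;
        }
        if (lq == lr) {
            int d = 0;
            for (int i = 0; i < lq; ++i) if (q[i] != r[i]) ++d;
            if (1.0 - static_cast<double>(d) / lq >= thr - eps)
                return static_cast<int>(j) + 1;
        } else {
            int W = (lmax - lmin) + 16;
            if (banded_identity(q, lq, r, lr, W) >= thr - eps)
                return static_cast<int>(j) + 1;
        }
    }
    return 0;
}

// Two-parent single-breakpoint chimera screen over abundance-sorted uniques.
// A sequence is flagged iff some split point s yields a left segment
// (length >= min_seg) >= `ident` identical to the PREFIX of one kept sequence
// with abundance >= skew x its own, and a right segment (length >= min_seg)
// >= `ident` identical to the SUFFIX of a DIFFERENT such kept sequence.
// Flagged sequences are excluded from the kept (potential-parent) set.
// [[Rcpp::export]]
LogicalVector cpp_chimera_flags(CharacterVector seqs, NumericVector abund,
                                double skew, double ident, int min_seg) {
    R_xlen_t n = seqs.size();
    if (abund.size() != n) stop("seqs and abund must have equal length");
    LogicalVector flagged(n);
    std::vector<const char *> s(n);
    std::vector<int> len(n);
    int Lmax = 0;
    for (R_xlen_t k = 0; k < n; ++k) {
        s[k] = CHAR(STRING_ELT(seqs, k));
        len[k] = static_cast<int>(std::strlen(s[k]));
        Lmax = std::max(Lmax, len[k]);
    }
    // abundance is non-increasing, so the eligible-parent set (abundance >=
    // skew * own) is a growing prefix as the scan descends
    R_xlen_t cut = 0;
    std::vector<int> leftP1(Lmax + 1), leftP2(Lmax + 1),
                     rightP1(Lmax + 1), rightP2(Lmax + 1);
    for (R_xlen_t k = 0; k < n; ++k) {
        int L = len[k];
        while (cut < n && abund[cut] >= skew * abund[k]) ++cut;
        if (L < 2 * min_seg) continue;
        std::vector<int> parents;
        for (R_xlen_t j = 0; j < std::min(cut, k); ++j)
            if (!flagged[j]) parents.push_back(static_cast<int>(j));
        if (parents.size() < 2) continue;
        // single-parent guard: a candidate explained end-to-end at >= ident
        // by ONE parent is a sequence variant, not a chimera
        bool explained = false;
        for (size_t pi = 0; pi < parents.size() && !explained; ++pi) {
            const char *p = s[parents[pi]];
            int Lp = len[parents[pi]];
            int m = std::min(L, Lp);
            if (static_cast<double>(m) < ident * L) continue;
            int mm_pre = 0, mm_suf = 0;
            for (int i = 0; i < m; ++i) {
                if (s[k][i] != p[i]) ++mm_pre;
                if (s[k][L - 1 - i] != p[Lp - 1 - i]) ++mm_suf;
            }
            double best = static_cast<double>(m - std::min(mm_pre, mm_suf)) / L;
            if (best >= ident) explained = true;
        }
        if (explained) continue;
        // first/second distinct parent with a valid prefix (suffix) match at
        // each split point
        std::fill(leftP1.begin(), leftP1.begin() + L + 1, -1);
        std::fill(leftP2.begin(), leftP2.begin() + L + 1, -1);
        std::fill(rightP1.begin(), rightP1.begin() + L + 1, -1);
        std::fill(rightP2.begin(), rightP2.begin() + L + 1, -1);
        for (size_t pi = 0; pi < parents.size(); ++pi) {
            int pj = parents[pi];
            const char *p = s[pj];
            int Lp = len[pj];
            int smax = std::min(L, Lp);
            int mm = 0;
            for (int i = 0; i < smax; ++i) {
                if (s[k][i] != p[i]) ++mm;
                int seg = i + 1;
                if (seg >= min_seg && mm <= (1.0 - ident) * seg + 1e-9) {
                    if (leftP1[seg] < 0) leftP1[seg] = pj;
                    else if (leftP2[seg] < 0 && leftP1[seg] != pj)
                        leftP2[seg] = pj;
                }
            }
            mm = 0;
            for (int i = 0; i < smax; ++i) {
                if (s[k][L - 1 - i] != p[Lp - 1 - i]) ++mm;
                int seg = i + 1;  // right segment length; split at s = L - seg
                if (seg >= min_seg && mm <= (1.0 - ident) * seg + 1e-9) {
                    int sp = L - seg;
                    if (rightP1[sp] < 0) rightP1[sp] = pj;
                    else if (rightP2[sp] < 0 && rightP1[sp] != pj)
                        rightP2[sp] = pj;
                }
            }
        }
        bool flag = false;
        for (int sp = min_seg; sp <= L - min_seg && !flag; ++sp) {
            int l1 = leftP1[sp], l2 = leftP2[sp];
            int r1 = rightP1[sp], r2 = rightP2[sp];
            if (l1 < 0 || r1 < 0) continue;
            if (l1 != r1 || l2 >= 0 || r2 >= 0) flag = true;
        }
        flagged[k] = flag;
    }
    return flagged;
}

// Substitution-error injection: every base mutates with probability `rate`
// to one of the three other bases, using R's RNG (so set.seed applies).
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector seqs, double rate) {
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    RNGScope scope;
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    for (R_xlen_t k = 0; k < n; ++k) {
        std::string s = as<std::string>(seqs[k]);
        for (size_t i = 0; i < s.size(); ++i) {
            if (unif_rand() < rate) {
                char cur = s[i];
                char repl;
                do {
                    repl = bases[static_cast<int>(unif_rand() * 4) & 3];
                } while (repl == cur);
                s[i] = repl;
            }
        }
        out[k] = s;
    }
    return out;
}
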