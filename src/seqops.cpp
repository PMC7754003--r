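#include <Rcpp.h>
using namespace Rcpp;

// Hamming distance of one string against a table of equal-length strings.
// Entries of differing length get NA.
// [[Rcpp::export]]
IntegerVector hamming_to_table(std::string x, CharacterVector table) {
    const size_t n = table.size();
    IntegerVector out(n);
    const size_t lx = x.size();
    for (size_t i = 0; i < n; ++i) {
        const char *t = CHAR(STRING_ELT(table, i));
        size_t lt = std::strlen(t);
        if (lt != lx) { out[i] = NA_INTEGER; continue; }
        int d = 0;
        for (size_t j = 0; j < lx; ++j) if (x[j] != t[j]) ++d;
        out[i] = d;
    }
    return out;
}

// All unordered pairs (i, j), 1-based, of equal-length strings at Hamming
// distance exactly 1. Used by RSEC to build the UMI neighbour graph.
// [[Rcpp::export]]
IntegerMatrix hamming1_pairs(CharacterVector x) {
    const int n = x.size();
    std::vector<int> ii, jj;
    std::vector<const char *> p(n);
    std::vector<size_t> len(n);
    for (int i = 0; i < n; ++i) {
        p[i] = CHAR(STRING_ELT(x, i));
        len[i] = std::strlen(p[i]);
    }
    for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j) {
            if (len[i] != len[j]) continue;
            int d = 0;
            for (size_t k = 0; k < len[i] && d < 2; ++k)
                if (p[i][k] != p[j][k]) ++d;
            if (d == 1) { ii.push_back(i + 1); jj.push_back(j + 1); }
        }
    }
    IntegerMatrix out(ii.size(), 2);
    for (size_t r = 0; r < ii.size(); ++r) { out(r, 0) = ii[r]; out(r, 1) = jj[r]; }
    return out;
}

// Ungapped extension of read vs reference along a fixed diagonal.
// diag = ref_offset - read_offset (0-based). The full overlap is scanned,
// then leading/trailing mismatch runs are trimmed (soft-clip analogue) so
// that read_start reports where the retained alignment actually begins.
// Returns a matrix with columns: read_start (0-based), aln_len
// (match+mismatch columns after trimming), mismatches (within the trimmed
// span). aln_len = 0 when the overlap is empty or all-mismatch.
// [[Rcpp::export]]
IntegerMatrix extend_ungapped(CharacterVector reads, CharacterVector refs,
                              IntegerVector diag) {
    const int n = reads.size();
    IntegerMatrix out(n, 3);
    colnames(out) = CharacterVector::create("read_start", "aln_len", "mismatches");
    for (int r = 0; r < n; ++r) {
        const char *rd = CHAR(STRING_ELT(reads, r));
        const char *rf = CHAR(STRING_ELT(refs, r));
        const long lr = (long) std::strlen(rd);
        const long lf = (long) std::strlen(rf);
        const long d = diag[r];
        long i0 = d < 0 ? -d : 0;          // first read pos in overlap
        long i1 = std::min(lr, lf - d);    // one past last read pos
        if (i1 <= i0) { out(r, 0) = 0; out(r, 1) = 0; out(r, 2) = 0; continue; }
        // trim leading/trailing mismatch runs
        long a = i0, b = i1 - 1;
        while (a <= b && rd[a] != rf[a + d]) ++a;
        while (b >= a && rd[b] != rf[b + d]) --b;
        if (a > b) { out(r, 0) = 0; out(r, 1) = 0; out(r, 2) = 0; continue; }
        int mism = 0;
        for (long i = a; i <= b; ++i) if (rd[i] != rf[i + d]) ++mism;
        out(r, 0) = (int) a;
        out(r, 1) = (int) (b - a + 1);
        out(r, 2) = mism;
    }
    return out;
}
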