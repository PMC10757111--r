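#include <Rcpp.h>
#include <cstdint>
#include <string>
using namespace Rcpp;

// FNV-1a over "peptide|allele|seed". Pure integer arithmetic on uint64 so the
// stream is bit-identical across platforms; top 53 bits map to [0, 100).
static double fnv_rank(const std::string& key) {
    uint64_t h = 1469598103934665603ULL;
    for (size_t i = 0; i < key.size(); ++i) {
        h ^= static_cast<uint64_t>(static_cast<unsigned char>(key[i]));
        h *= 1099511628211ULL;
    }
    return 100.0 * ((h >> 11) * (1.0 / 9007199254740992.0)); /* 2^53 */
}

// [[Rcpp::export]]
NumericVector surrogate_rank_cpp(CharacterVector peptide, CharacterVector allele, int seed) {
    R_xlen_t n = peptide.size();
    if (allele.size() != n) stop("peptide and allele must have equal length");
    NumericVector out(n);
    std::string s = std::to_string(seed);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string key = std::string(peptide[i]) + "|" + std::string(allele[i]) + "|" + s;
        out[i] = fnv_rank(key);
    }
    return out;
}

// Best gapless local alignment score of `a` vs each reference: the maximum,
// over all diagonals, of the maximum-sum contiguous run of substitution
// scores (Kadane). Substitution matrix passed as a flat vector with dimnames.
// [[Rcpp::export]]
NumericVector gapless_local_scores_cpp(std::string a, CharacterVector refs,
                                       NumericMatrix sub, CharacterVector alphabet) {
    int idx[256];
    for (int i = 0; i < 256; ++i) idx[i] = -1;
    for (int i = 0; i < alphabet.size(); ++i)
        idx[static_cast<unsigned char>(std::string(alphabet[i])[0])] = i;

    R_xlen_t nref = refs.size();
    NumericVector out(nref);
    int la = a.size();
    for (R_xlen_t r = 0; r < nref; ++r) {
        std::string b = std::string(refs[r]);
        int lb = b.size();
        double best = 0.0;
        for (int off = -(lb - 1); off <= la - 1; ++off) {
            double run = 0.0;
            for (int i = std::max(0, off); i < std::min(la, lb + off); ++i) {
                int ia = idx[static_cast<unsigned char>(a[i])];
                int ib = idx[static_cast<unsigned char>(b[i - off])];
                if (ia < 0 || ib < 0) { run = 0.0; continue; }
                double s = sub(ia, ib);
                run = std::max(0.0, run + s);
                if (run > best) best = run;
            }
        }
        out[r] = best;
    }
    return out;
}
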