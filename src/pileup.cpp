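#include <Rcpp.h>
#include <cctype>
#include <cstring>
using namespace Rcpp;

// Decode samtools mpileup base columns. For each line the base string is
// resolved against the reference base and paired positionally with the
// Phred+33 quality string:
//   '.' ','            -> reference base (consumes one quality char)
//   A/C/G/T/N any case -> that base, uppercased (consumes one quality char)
//   '*' '#'            -> deletion placeholder, discarded with its quality
//   '>' '<'            -> reference skip, discarded with its quality
//   '^'                -> read start; the following mapping-quality char is
//                         consumed too; no quality char
//   '$'                -> read end marker; no quality char
//   '+n<seq>' '-n<seq>'-> indel attached to the previous call; the length
//                         digits and n inserted/deleted bases are consumed
//                         and discarded; no quality char
// Retained calls and retained qualities must end up equal in length;
// anything else is a malformed line and raises an error naming it.

// [[Rcpp::export]]
List decode_pileup_cpp(CharacterVector bases, CharacterVector quals,
                       CharacterVector ref) {
    R_xlen_t n = bases.size();
    if (quals.size() != n || ref.size() != n)
        stop("bases, quals and ref must have equal length");
    CharacterVector out_calls(n), out_quals(n);
    std::string calls, kept;
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *b = CHAR(STRING_ELT(bases, i));
        const char *q = CHAR(STRING_ELT(quals, i));
        const char *r = CHAR(STRING_ELT(ref, i));
        char refbase = std::toupper(r[0] ? r[0] : 'N');
        size_t nq = std::strlen(q);
        size_t qi = 0;
        calls.clear();
        kept.clear();
        for (size_t j = 0; b[j] != '\0'; ++j) {
            char c = b[j];
            switch (c) {
            case '^':
                if (b[j + 1] != '\0') ++j;  // mapping-quality char
                break;
            case '$':
                break;
            case '+':
            case '-': {
                size_t len = 0;
                while (std::isdigit((unsigned char)b[j + 1])) {
                    len = len * 10 + (b[j + 1] - '0');
                    ++j;
                }
                for (size_t k = 0; k < len && b[j + 1] != '\0'; ++k) ++j;
                break;
            }
            case '*':
            case '#':
            case '>':
            case '<':
                if (qi >= nq)
                    stop("pileup line %d: quality string exhausted before base string",
                         (int)(i + 1));
                ++qi;  // placeholder consumes a quality, both dropped
                break;
            case '.':
            case ',':
                if (qi >= nq)
                    stop("pileup line %d: quality string exhausted before base string",
                         (int)(i + 1));
                calls.push_back(refbase);
                kept.push_back(q[qi++]);
                break;
            default: {
                char up = std::toupper((unsigned char)c);
                if (up == 'A' || up == 'C' || up == 'G' || up == 'T' ||
                    up == 'N') {
                    if (qi >= nq)
                        stop("pileup line %d: quality string exhausted before base string",
                             (int)(i + 1));
                    calls.push_back(up);
                    kept.push_back(q[qi++]);
                } else {
                    stop("pileup line %d: unexpected symbol '%c' in base string",
                         (int)(i + 1), c);
                }
            }
            }
        }
        if (qi != nq)
            stop("pileup line %d: %d base calls but %d quality characters",
                 (int)(i + 1), (int)qi, (int)nq);
        out_calls[i] = calls;
        out_quals[i] = kept;
    }
    return List::create(_["calls"] = out_calls, _["quals"] = out_quals);
}

// Per-site A/C/G/T counts over decoded calls, keeping only calls whose
// Phred quality (char - 33) is >= min_qual. N calls are never counted.

// [[Rcpp::export]]
IntegerMatrix count_alleles_cpp(CharacterVector calls, CharacterVector quals,
                                int min_qual) {
    R_xlen_t n = calls.size();
    if (quals.size() != n) stop("calls and quals must have equal length");
    IntegerMatrix counts(n, 4);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char *c = CHAR(STRING_ELT(calls, i));
        const char *q = CHAR(STRING_ELT(quals, i));
        for (size_t j = 0; c[j] != '\0'; ++j) {
            if (q[j] == '\0')
                stop("row %d: fewer qualities than calls", (int)(i + 1));
            if ((int)q[j] - 33 < min_qual) continue;
            switch (c[j]) {
            case 'A': counts(i, 0)++; break;
            case 'C': counts(i, 1)++; break;
            case 'G': counts(i, 2)++; break;
            case 'T': counts(i, 3)++; break;
            default: break;  // N
            }
        }
    }
    colnames(counts) = CharacterVector::create("A", "C", "G", "T");
    return counts;
}
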