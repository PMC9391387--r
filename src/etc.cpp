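#include <Rcpp.h>
#include <map>
#include <vector>

using namespace Rcpp;

// Non-Sequential Recursive Pair Substitution (NSRPS) primitives.
//
// Pair occurrences are counted non-overlapping, greedily left-to-right
// ("aaa" contains ONE (a,a) pair).  The most frequent pair wins; ties go
// to the pair whose first counted occurrence appears earliest in the
// sequence.  The positional tie-break makes the step count exactly
// invariant under any bijective relabeling of the alphabet (a lexicographic
// rule is not), which the causality measures rely on: the joint pair
// coding must collapse to a relabeling for identical inputs.  Replacement
// uses the same greedy left-to-right scan.  Fresh symbols extend the
// alphabet and are never reused.

static bool is_constant(const std::vector<int>& s) {
    for (size_t i = 1; i < s.size(); ++i)
        if (s[i] != s[0]) return false;
    return true;
}

// One substitution pass.  `alphabet` is the current alphabet size; the
// fresh symbol is `alphabet` itself.  Returns false if irreducible.
static bool nsrps_pass(std::vector<int>& s, long long& alphabet,
                       bool stop_on_constant) {
    const size_t n = s.size();
    if (n < 2 || (stop_on_constant && is_constant(s))) return false;

    const long long K = alphabet;
    std::map<long long, int> count;
    std::map<long long, size_t> first_pos;  // first counted occurrence
    std::map<long long, size_t> last_end;   // 2nd element of last counted occurrence

    for (size_t i = 0; i + 1 < n; ++i) {
        long long key = (long long)s[i] * K + s[i + 1];
        std::map<long long, size_t>::iterator it = last_end.find(key);
        if (it != last_end.end() && i <= it->second) continue;  // overlaps previous count
        if (count.find(key) == count.end()) first_pos[key] = i;
        ++count[key];
        last_end[key] = i + 1;
    }

    // most frequent pair; ties resolved by earliest first occurrence
    // (positions are unique across pairs, so the winner is unique)
    long long best_key = -1;
    int best_count = -1;
    size_t best_pos = n;
    for (std::map<long long, int>::const_iterator it = count.begin();
         it != count.end(); ++it) {
        const size_t pos = first_pos[it->first];
        if (it->second > best_count ||
            (it->second == best_count && pos < best_pos)) {
            best_count = it->second;
            best_key = it->first;
            best_pos = pos;
        }
    }

    const int a = (int)(best_key / K);
    const int b = (int)(best_key % K);
    const int fresh = (int)alphabet;

    std::vector<int> out;
    out.reserve(n);
    for (size_t i = 0; i < n; ) {
        if (i + 1 < n && s[i] == a && s[i + 1] == b) {
            out.push_back(fresh);
            i += 2;
        } else {
            out.push_back(s[i]);
            ++i;
        }
    }
    s.swap(out);
    ++alphabet;
    return true;
}

static int etc_core(std::vector<int> s, long long alphabet) {
    int steps = 0;
    while (nsrps_pass(s, alphabet, true)) ++steps;
    return steps;
}

static long long max_plus_one(const IntegerVector& x) {
    long long m = 0;
    for (R_xlen_t i = 0; i < x.size(); ++i)
        if ((long long)x[i] + 1 > m) m = (long long)x[i] + 1;
    return m;
}

// [[Rcpp::export]]
int cpp_etc_steps(IntegerVector seq, int alphabet) {
    std::vector<int> s(seq.begin(), seq.end());
    long long a = alphabet > 0 ? alphabet : max_plus_one(seq);
    return etc_core(s, a);
}

// [[Rcpp::export]]
List cpp_nsrps_step(IntegerVector seq, int alphabet) {
    std::vector<int> s(seq.begin(), seq.end());
    long long a = alphabet > 0 ? alphabet : max_plus_one(seq);
    // A single pass substitutes any length >= 2 sequence (a constant run
    // still contains its repeated pair); only length 1 is irreducible.
    bool done = nsrps_pass(s, a, false);
    if (!done) stop("already irreducible: sequence has length 1");
    return List::create(_["seq"] = IntegerVector(s.begin(), s.end()),
                        _["alphabet_size"] = (int)a);
}

// Product-alphabet coding of two equal-length sequences: observed pairs are
// mapped to fresh integers in first-appearance order, then ETC is applied.
// [[Rcpp::export]]
int cpp_joint_etc_steps(IntegerVector a, IntegerVector b) {
    if (a.size() != b.size()) stop("sequences must have equal length");
    const R_xlen_t n = a.size();
    const long long Kb = max_plus_one(b);
    std::map<long long, int> code;
    std::vector<int> s((size_t)n);
    int next = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        long long key = (long long)a[i] * Kb + b[i];
        std::map<long long, int>::iterator it = code.find(key);
        if (it == code.end()) {
            code[key] = next;
            s[(size_t)i] = next++;
        } else {
            s[(size_t)i] = it->second;
        }
    }
    return etc_core(s, next);
}
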