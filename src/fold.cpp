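#include <Rcpp.h>
#include <vector>
#include <stack>
#include <string>

using namespace Rcpp;

// Base-pair weights of the default folding backend: GC=3, AU=2, GU=1.
static inline int pairWeight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
    return 0;
}

// Weighted base-pair maximization (Nussinov-style dynamic programming) with
// a minimum hairpin loop size and no pseudoknots. Returns the dot-bracket
// structure, the total pair weight, and the 1-based pair table (0 =
// unpaired). O(n^3) time, O(n^2) memory.
// [[Rcpp::export(name = ".nussinovFold")]]
List nussinovFold(std::string seq, int min_loop) {
    const int n = seq.size();
    if (n == 0) stop("empty sequence");
    // M[i][j]: best weight on the closed interval [i, j], 0-based.
    std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = M[i + 1][j];  // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                int w = pairWeight(seq[i], seq[k]);
                if (w == 0) continue;
                int inner = (k - i - 1 >= 1) ? M[i + 1][k - 1] : 0;
                int rest = (k + 1 <= j) ? M[k + 1][j] : 0;
                int cand = w + inner + rest;
                if (cand > best) best = cand;
            }
            M[i][j] = best;
        }
    }
    // Traceback (iterative; deterministic: first optimal branch wins, i.e.
    // leaving i unpaired is preferred only when no pairing attains the
    // optimum, and the smallest optimal partner k is chosen).
    std::vector<int> pairTable(n, 0);
    std::string db(n, '.');
    std::stack<std::pair<int, int> > todo;
    todo.push(std::make_pair(0, n - 1));
    while (!todo.empty()) {
        int i = todo.top().first, j = todo.top().second;
        todo.pop();
        if (i >= j || j - i < min_loop + 1) continue;
        bool done = false;
        for (int k = i + min_loop + 1; k <= j && !done; ++k) {
            int w = pairWeight(seq[i], seq[k]);
            if (w == 0) continue;
            int inner = (k - i - 1 >= 1) ? M[i + 1][k - 1] : 0;
            int rest = (k + 1 <= j) ? M[k + 1][j] : 0;
            if (w + inner + rest == M[i][j]) {
                pairTable[i] = k + 1;
                pairTable[k] = i + 1;
                db[i] = '(';
                db[k] = ')';
                if (k - i - 1 >= 1) todo.push(std::make_pair(i + 1, k - 1));
                if (k + 1 <= j) todo.push(std::make_pair(k + 1, j));
                done = true;
            }
        }
        if (!done) todo.push(std::make_pair(i + 1, j));
    }
    return List::create(_["structure"] = db,
                        _["weight"] = M[0][n - 1],
                        _["pairs"] = IntegerVector(pairTable.begin(),
                                                   pairTable.end()));
}
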