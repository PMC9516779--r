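#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment of each read against one
// reference, affine gap costs (gap of length L costs gapOpen + L * gapExt),
// N scores 0 against anything. Traceback preference is fixed
// (diagonal > deletion > insertion), so edit scripts are deterministic;
// the R layer additionally left-normalizes indels to their leftmost
// equivalent placement.
//
// Returns, per read, a list with parallel vectors:
//   op    character: "I" (insertion in read), "D" (deletion from reference),
//         "X" (substitution)
//   pos0  0-based reference coordinate (for "I": the junction index =
//         number of reference bases 5' of the insertion point)
//   len   operation length
//   bases inserted bases ("I"), read base ("X"), "" for "D"

static inline double subScore(char a, char b, double match, double mismatch) {
    if (a == 'N' || b == 'N') return 0.0;
    return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".nwAlignOps")]]
List nwAlignOps(CharacterVector reads, std::string ref,
                double match, double mismatch,
                double gapOpen, double gapExt) {
    const int n = (int) ref.size();
    const double NEG = -1e18;
    List out(reads.size());

    // reusable DP rows are simplest as full matrices; amplicons are short
    for (int r = 0; r < reads.size(); ++r) {
        std::string rd = as<std::string>(reads[r]);
        const int m = (int) rd.size();
        // M: read i aligned ending in match/mismatch at ref j
        // Dg: ends in gap in read (deletion of ref chars)
        // Ig: ends in gap in ref (insertion of read chars)
        std::vector<std::vector<double>> M(m + 1, std::vector<double>(n + 1, NEG)),
            Dg(m + 1, std::vector<double>(n + 1, NEG)),
            Ig(m + 1, std::vector<double>(n + 1, NEG));
        M[0][0] = 0.0;
        for (int j = 1; j <= n; ++j)
            Dg[0][j] = -gapOpen - gapExt * j;
        for (int i = 1; i <= m; ++i)
            Ig[i][0] = -gapOpen - gapExt * i;
        for (int i = 1; i <= m; ++i) {
            for (int j = 1; j <= n; ++j) {
                double s = subScore(rd[i - 1], ref[j - 1], match, mismatch);
                double best = std::max(M[i - 1][j - 1],
                                       std::max(Dg[i - 1][j - 1], Ig[i - 1][j - 1]));
                M[i][j] = best + s;
                double openD = std::max(M[i][j - 1], Ig[i][j - 1]) - gapOpen - gapExt;
                double extD = Dg[i][j - 1] - gapExt;
                Dg[i][j] = std::max(openD, extD);
                double openI = std::max(M[i - 1][j], Dg[i - 1][j]) - gapOpen - gapExt;
                double extI = Ig[i - 1][j] - gapExt;
                Ig[i][j] = std::max(openI, extI);
            }
        }
        // traceback from the best terminal state; prefer M > Dg > Ig on ties
        std::vector<int> posv, lenv;
        std::vector<std::string> basv;
        int i = m, j = n;
        int state; // 0 = M, 1 = Dg, 2 = Ig
        double sc = std::max(M[m][n], std::max(Dg[m][n], Ig[m][n]));
        state = (M[m][n] == sc) ? 0 : (Dg[m][n] == sc ? 1 : 2);
        // collect raw single-column ops, merge afterwards
        std::vector<std::pair<char, std::pair<int, char>>> steps; // op, refpos(0b), readchar
        while (i > 0 || j > 0) {
            if (state == 0) {
                double s = subScore(rd[i - 1], ref[j - 1], match, mismatch);
                double prev = M[i][j] - s;
                if (rd[i - 1] != ref[j - 1] && rd[i - 1] != 'N' && ref[j - 1] != 'N')
                    steps.push_back({'X', {j - 1, rd[i - 1]}});
                if (M[i - 1][j - 1] == prev) state = 0;
                else if (Dg[i - 1][j - 1] == prev) state = 1;
                else state = 2;
                --i; --j;
            } else if (state == 1) { // deletion: consumes ref char j-1
                steps.push_back({'D', {j - 1, '-'}});
                double v = Dg[i][j];
                if (M[i][j - 1] - gapOpen - gapExt == v) state = 0;
                else if (Ig[i][j - 1] - gapOpen - gapExt == v) state = 2;
                else state = 1; // extend
                --j;
            } else { // insertion: consumes read char i-1
                steps.push_back({'I', {j, rd[i - 1]}});
                double v = Ig[i][j];
                if (M[i - 1][j] - gapOpen - gapExt == v) state = 0;
                else if (Dg[i - 1][j] - gapOpen - gapExt == v) state = 1;
                else state = 2; // extend
                --i;
            }
        }
        // steps are in reverse order; merge runs of D and I
        std::reverse(steps.begin(), steps.end());
        std::vector<std::string> opsv;
        size_t k = 0;
        while (k < steps.size()) {
            char op = steps[k].first;
            if (op == 'X') {
                opsv.push_back("X");
                posv.push_back(steps[k].second.first);
                lenv.push_back(1);
                basv.push_back(std::string(1, steps[k].second.second));
                ++k;
            } else if (op == 'D') {
                int start = steps[k].second.first;
                size_t k2 = k;
                while (k2 + 1 < steps.size() && steps[k2 + 1].first == 'D' &&
                       steps[k2 + 1].second.first == steps[k2].second.first + 1)
                    ++k2;
                opsv.push_back("D");
                posv.push_back(start);
                lenv.push_back((int)(k2 - k + 1));
                basv.push_back("");
                k = k2 + 1;
            } else { // I: same junction for a run
                int pos = steps[k].second.first;
                std::string ins(1, steps[k].second.second);
                size_t k2 = k;
                while (k2 + 1 < steps.size() && steps[k2 + 1].first == 'I' &&
                       steps[k2 + 1].second.first == pos) {
                    ++k2;
                    ins.push_back(steps[k2].second.second);
                }
                opsv.push_back("I");
                posv.push_back(pos);
                lenv.push_back((int) ins.size());
                basv.push_back(ins);
                k = k2 + 1;
            }
        }
        out[r] = List::create(
            _["op"] = wrap(opsv),
            _["pos0"] = IntegerVector(posv.begin(), posv.end()),
            _["len"] = IntegerVector(lenv.begin(), lenv.end()),
            _["bases"] = CharacterVector(basv.begin(), basv.end()),
            _["score"] = sc);
    }
    return out;
}
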