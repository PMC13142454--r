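#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Local alignment of a position-specific score matrix against one encoded
// target sequence (affine gaps), with iterated optimal-subalignment
// extraction: after each reported alignment its target envelope is masked
// and the DP is rerun, until the score drops below min_score or max_hits
// is reached.
//
// S:       L x 21 match scores (bits); column 21 (index 20) is X.
// target:  1-based residue codes (1..21).
// gap_open:   cost of a length-1 gap (bits, positive).
// gap_extend: cost per additional gap position (bits, positive).
//
// Returns a list of hits; each hit is a list(score, t_start, t_end,
// p_start, p_end, aligned) where aligned[i] is the target residue code
// matched to profile column i (0 = column not covered by the alignment).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".pssm_scan_seq")]]
List pssm_scan_seq(NumericMatrix S, IntegerVector target,
                   double gap_open, double gap_extend,
                   int max_hits, double min_score) {
  const int L = S.nrow();
  const int n = target.size();
  std::vector<bool> masked(n + 1, false);

  // DP matrices, (L+1) x (n+1)
  std::vector<double> M((L + 1) * (n + 1)), Ix((L + 1) * (n + 1)),
      Iy((L + 1) * (n + 1));
  // traceback: 0 = start, 1 = from M, 2 = from Ix, 3 = from Iy
  std::vector<signed char> tM((L + 1) * (n + 1)), tIx((L + 1) * (n + 1)),
      tIy((L + 1) * (n + 1));
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  List hits;
  for (int hit = 0; hit < max_hits; ++hit) {
    double best = 0.0;
    int bi = -1, bj = -1;
    for (int j = 0; j <= n; ++j) {
      M[at(0, j)] = Ix[at(0, j)] = Iy[at(0, j)] = NEG_INF;
    }
    for (int i = 1; i <= L; ++i) {
      M[at(i, 0)] = Ix[at(i, 0)] = Iy[at(i, 0)] = NEG_INF;
      for (int j = 1; j <= n; ++j) {
        if (masked[j]) {
          M[at(i, j)] = Ix[at(i, j)] = Iy[at(i, j)] = NEG_INF;
          continue;
        }
        // match state
        double sc = S(i - 1, target[j - 1] - 1);
        double dM = M[at(i - 1, j - 1)], dIx = Ix[at(i - 1, j - 1)],
               dIy = Iy[at(i - 1, j - 1)];
        double m0 = 0.0; signed char tb = 0;
        if (dM > m0) { m0 = dM; tb = 1; }
        if (dIx > m0) { m0 = dIx; tb = 2; }
        if (dIy > m0) { m0 = dIy; tb = 3; }
        M[at(i, j)] = sc + m0;
        tM[at(i, j)] = tb;
        // Ix: target residue j consumed, no profile column (insertion)
        double oIx = M[at(i, j - 1)] - gap_open;
        double eIx = Ix[at(i, j - 1)] - gap_extend;
        if (oIx >= eIx) { Ix[at(i, j)] = oIx; tIx[at(i, j)] = 1; }
        else            { Ix[at(i, j)] = eIx; tIx[at(i, j)] = 2; }
        // Iy: profile column i consumed, no target residue (deletion)
        double oIy = M[at(i - 1, j)] - gap_open;
        double eIy = Iy[at(i - 1, j)] - gap_extend;
        if (oIy >= eIy) { Iy[at(i, j)] = oIy; tIy[at(i, j)] = 1; }
        else            { Iy[at(i, j)] = eIy; tIy[at(i, j)] = 3; }
        if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
      }
    }
    if (bi < 0 || best < min_score) break;
    // traceback from (bi, bj) in state M
    IntegerVector aligned(L, 0);
    int i = bi, j = bj, state = 1;
    int t_end = bj, p_end = bi, t_start = bj, p_start = bi;
    while (true) {
      if (state == 1) {
        aligned[i - 1] = target[j - 1];
        t_start = j; p_start = i;
        signed char tb = tM[at(i, j)];
        --i; --j;
        if (tb == 0) break;
        state = tb;
      } else if (state == 2) { // Ix: consumed target j
        signed char tb = tIx[at(i, j)];
        --j;
        state = tb;
      } else {                 // Iy: consumed profile i
        signed char tb = tIy[at(i, j)];
        --i;
        state = tb;
      }
    }
    hits.push_back(List::create(
        _["score"] = best, _["t_start"] = t_start, _["t_end"] = t_end,
        _["p_start"] = p_start, _["p_end"] = p_end, _["aligned"] = aligned));
    for (int k = t_start; k <= t_end; ++k) masked[k] = true;
  }
  return hits;
}

// Optimal local score only, for a batch of targets (used by E-value
// calibration; no traceback, single best alignment per target).
// [[Rcpp::export(name = ".pssm_best_scores")]]
NumericVector pssm_best_scores(NumericMatrix S, List targets,
                               double gap_open, double gap_extend) {
  const int L = S.nrow();
  NumericVector out(targets.size());
  for (int t = 0; t < targets.size(); ++t) {
    IntegerVector target = targets[t];
    const int n = target.size();
    std::vector<double> Mprev(n + 1, NEG_INF), Mcur(n + 1, NEG_INF);
    std::vector<double> Ixprev(n + 1, NEG_INF), Ixcur(n + 1, NEG_INF);
    std::vector<double> Iyprev(n + 1, NEG_INF), Iycur(n + 1, NEG_INF);
    double best = 0.0;
    for (int i = 1; i <= L; ++i) {
      Mcur[0] = Ixcur[0] = Iycur[0] = NEG_INF;
      for (int j = 1; j <= n; ++j) {
        double sc = S(i - 1, target[j - 1] - 1);
        double m0 = 0.0;
        if (Mprev[j - 1] > m0) m0 = Mprev[j - 1];
        if (Ixprev[j - 1] > m0) m0 = Ixprev[j - 1];
        if (Iyprev[j - 1] > m0) m0 = Iyprev[j - 1];
        Mcur[j] = sc + m0;
        double oIx = Mcur[j - 1] - gap_open, eIx = Ixcur[j - 1] - gap_extend;
        Ixcur[j] = oIx >= eIx ? oIx : eIx;
        double oIy = Mprev[j] - gap_open, eIy = Iyprev[j] - gap_extend;
        Iycur[j] = oIy >= eIy ? oIy : eIy;
        if (Mcur[j] > best) best = Mcur[j];
      }
      std::swap(Mprev, Mcur);
      std::swap(Ixprev, Ixcur);
      std::swap(Iyprev, Iycur);
    }
    out[t] = best;
  }
  return out;
}
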