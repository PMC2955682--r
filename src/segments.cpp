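#include <Rcpp.h>
using namespace Rcpp;

// All maximal scoring subsequences (Ruzzo-Tompa) of a real-valued score
// sequence. Returns 0-based half-open [start, end) spans with their scores,
// left to right. Only segments with score strictly above `cutoff` are kept.
//
// The running list of disjoint candidate subsequences is kept as parallel
// stacks of (start, end, L, R) where L is the cumulative sum just before the
// segment and R the cumulative sum at its end. Tie conventions (strict
// L_j < L_s to find the merge partner, R_j >= R_s to stop merging) yield the
// leftmost-start / shortest-extent segment for tied scores.
// [[Rcpp::export]]
DataFrame rt_segments_cpp(NumericVector scores, double cutoff) {
  const int n = scores.size();
  std::vector<int> sIdx, eIdx;
  std::vector<long double> Lval, Rval;
  sIdx.reserve(64); eIdx.reserve(64); Lval.reserve(64); Rval.reserve(64);

  long double cum = 0.0L;
  for (int i = 0; i < n; ++i) {
    const long double x = scores[i];
    if (!(x > 0.0)) { cum += x; continue; }
    long double Ls = cum, Rs = cum + x;
    int st = i;
    cum = Rs;
    for (;;) {
      // rightmost j with L_j < L_s
      int j = (int)Lval.size() - 1;
      while (j >= 0 && Lval[j] >= Ls) --j;
      if (j < 0 || Rval[j] >= Rs) {
        sIdx.push_back(st); eIdx.push_back(i + 1);
        Lval.push_back(Ls); Rval.push_back(Rs);
        break;
      }
      // merge: absorb subsequences j..top into the current one
      Ls = Lval[j];
      st = sIdx[j];
      sIdx.resize(j); eIdx.resize(j);
      Lval.resize(j); Rval.resize(j);
    }
  }

  std::vector<int> outS, outE;
  std::vector<double> outScore;
  for (size_t m = 0; m < sIdx.size(); ++m) {
    const double sc = (double)(Rval[m] - Lval[m]);
    if (sc > cutoff) {
      outS.push_back(sIdx[m]);
      outE.push_back(eIdx[m]);
      outScore.push_back(sc);
    }
  }
  return DataFrame::create(_["start"] = outS, _["end"] = outE,
                           _["score"] = outScore);
}

// Maximum-scoring contiguous subarray with deterministic tie-breaking:
// highest score, then leftmost start, then shortest extent. Returns
// (start, end, score) with start = -1 when no positive-score segment exists.
// [[Rcpp::export]]
NumericVector best_subarray_cpp(NumericVector scores) {
  const int n = scores.size();
  long double cum = 0.0L, minv = 0.0L;
  int minIdx = 0;
  long double best = 0.0L;
  int bs = -1, be = -1;
  for (int i = 0; i < n; ++i) {
    cum += scores[i];
    const long double cand = cum - minv;
    if (cand > best || (cand == best && bs >= 0 && minIdx < bs)) {
      best = cand; bs = minIdx; be = i + 1;
    }
    if (cum < minv) { minv = cum; minIdx = i + 1; }
  }
  if (bs < 0 || !(best > 0.0))
    return NumericVector::create(-1.0, -1.0, 0.0);
  return NumericVector::create((double)bs, (double)be, (double)best);
}
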