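#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps (Gotoh) over a
// precomputed column-vs-column score matrix M (rows = positions of A,
// cols = positions of B).  A gap of length L costs open + L * ext, the
// same convention Biostrings::pairwiseAlignment uses.  Ties prefer
// diagonal, then gap-in-B (consume A), so tracebacks are deterministic.
// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix M, double open, double ext) {
  const int n = M.nrow(), m = M.ncol();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // E: gap in A (consume B), F: gap in B (consume A)
  H(0, 0) = 0.0; E(0, 0) = F(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    E(0, j) = -(open + j * ext);
    H(0, j) = E(0, j);
    F(0, j) = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    F(i, 0) = -(open + i * ext);
    H(i, 0) = F(i, 0);
    E(i, 0) = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H(i, j - 1) - (open + ext), E(i, j - 1) - ext);
      double f = std::max(H(i - 1, j) - (open + ext), F(i - 1, j) - ext);
      double d = H(i - 1, j - 1) + M(i - 1, j - 1);
      E(i, j) = e; F(i, j) = f;
      H(i, j) = std::max(d, std::max(e, f));
    }
  }
  // traceback
  std::vector<int> pa, pb; pa.reserve(n + m); pb.reserve(n + m);
  int i = n, j = m;
  int state = 0;  // 0 = H, 1 = E (gap in A), 2 = F (gap in B)
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0) { state = 1; continue; }
      if (j == 0) { state = 2; continue; }
      double d = H(i - 1, j - 1) + M(i - 1, j - 1);
      if (H(i, j) == d) { pa.push_back(i); pb.push_back(j); --i; --j; }
      else if (H(i, j) == F(i, j)) state = 2;
      else state = 1;
    } else if (state == 1) {
      pa.push_back(0); pb.push_back(j);
      bool fromH = (E(i, j) == H(i, j - 1) - (open + ext));
      --j;
      if (fromH) state = 0;
    } else {
      pa.push_back(i); pb.push_back(0);
      bool fromH = (F(i, j) == H(i - 1, j) - (open + ext));
      --i;
      if (fromH) state = 0;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = H(n, m),
                      _["path_a"] = wrap(pa),
                      _["path_b"] = wrap(pb));
}

// Sliding log-odds scan of an integer-encoded protein (1-based residue
// codes) against a width-W score matrix (W rows, K columns).  Returns the
// score of every window start, plus the per-window fraction of positions
// matching the consensus code vector.
// [[Rcpp::export]]
List scan_windows_cpp(IntegerVector seq, NumericMatrix score,
                      IntegerVector consensus_code) {
  const int L = seq.size(), W = score.nrow();
  const int nw = L - W + 1;
  if (nw <= 0) {
    return List::create(_["logodds"] = NumericVector(0),
                        _["identity"] = NumericVector(0));
  }
  NumericVector lo(nw, 0.0), id(nw, 0.0);
  for (int j = 0; j < W; ++j) {
    for (int s = 0; s < nw; ++s) {
      int code = seq[s + j];
      lo[s] += score(j, code - 1);
      if (code == consensus_code[j]) id[s] += 1.0;
    }
  }
  for (int s = 0; s < nw; ++s) id[s] /= W;
  return List::create(_["logodds"] = lo, _["identity"] = id);
}
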