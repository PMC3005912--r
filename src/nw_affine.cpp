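#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gap costs over a
// precomputed column-pair score matrix S (n x m).  A gap run of length k
// costs gapOpen + (k - 1) * gapExtend; terminal gaps are penalised.
//
// Three-state DP (M = match/substitution, X = gap in the second profile,
// i.e. consume a row / move "up"; Y = gap in the first profile, move
// "left").  Ties are broken M > X > Y everywhere so the traceback is the
// spec'd deterministic diagonal > up > left order.
//
// Returns the optimal score and the traceback as a vector of moves
// (1 = diagonal, 2 = up, 3 = left) from the start of the alignment.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nwAffineCpp")]]
List nwAffineCpp(NumericMatrix S, double gapOpen, double gapExtend) {
  const int n = S.nrow(), m = S.ncol();

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // backpointers: which state we came from (0 = M, 1 = X, 2 = Y)
  std::vector<unsigned char> bM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> bX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> bY((n + 1) * (m + 1), 0);

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = gapOpen + (i - 1) * gapExtend;
    bX[idx(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = gapOpen + (j - 1) * gapExtend;
    bY[idx(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume one column from each profile
      {
        double vm = M[idx(i - 1, j - 1)], vx = X[idx(i - 1, j - 1)],
               vy = Y[idx(i - 1, j - 1)];
        double best = vm; unsigned char arg = 0;
        if (vx > best) { best = vx; arg = 1; }
        if (vy > best) { best = vy; arg = 2; }
        M[idx(i, j)] = best + S(i - 1, j - 1);
        bM[idx(i, j)] = arg;
      }
      // X: consume row i against a gap
      {
        double vm = M[idx(i - 1, j)] + gapOpen;
        double vx = X[idx(i - 1, j)] + gapExtend;
        double vy = Y[idx(i - 1, j)] + gapOpen;
        double best = vm; unsigned char arg = 0;
        if (vx > best) { best = vx; arg = 1; }
        if (vy > best) { best = vy; arg = 2; }
        X[idx(i, j)] = best;
        bX[idx(i, j)] = arg;
      }
      // Y: consume column j against a gap
      {
        double vm = M[idx(i, j - 1)] + gapOpen;
        double vx = X[idx(i, j - 1)] + gapOpen;
        double vy = Y[idx(i, j - 1)] + gapExtend;
        double best = vm; unsigned char arg = 0;
        if (vx > best) { best = vx; arg = 1; }
        if (vy > best) { best = vy; arg = 2; }
        Y[idx(i, j)] = best;
        bY[idx(i, j)] = arg;
      }
    }
  }

  double vm = M[idx(n, m)], vx = X[idx(n, m)], vy = Y[idx(n, m)];
  double score = vm; int state = 0;
  if (vx > score) { score = vx; state = 1; }
  if (vy > score) { score = vy; state = 2; }

  std::vector<int> moves;
  moves.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = bM[idx(i, j)];
      moves.push_back(1);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = bX[idx(i, j)];
      moves.push_back(2);
      --i;
      state = prev;
    } else {
      int prev = bY[idx(i, j)];
      moves.push_back(3);
      --j;
      state = prev;
    }
  }
  std::reverse(moves.begin(), moves.end());

  return List::create(_["score"] = score,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}
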