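#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular duplex minimum-free-energy dynamic programming.
//
// Both strands are given 5'->3' as integer codes 0=A, 1=C, 2=G, 3=U.
// Hybridization is antiparallel: pairs (i, j) sorted by increasing i have
// strictly decreasing j.  Structures are chains of canonical pairs joined
// by stacks, bulges or interior loops (total unpaired span <= max_span);
// energy = duplex initiation + sum of stack/loop terms + terminal AU/GU
// penalties at the two outermost pairs.

static const double NEG_INF_GUARD = 1e9;

// pair type indices into the 6x6 stack table: CG GC GU UG AU UA (1-based,
// 0 = not a canonical pair)
static inline int pair_type(int x, int y) {
  if (x == 1 && y == 2) return 1; // C-G
  if (x == 2 && y == 1) return 2; // G-C
  if (x == 2 && y == 3) return 3; // G-U
  if (x == 3 && y == 2) return 4; // U-G
  if (x == 0 && y == 3) return 5; // A-U
  if (x == 3 && y == 0) return 6; // U-A
  return 0;
}

struct Params {
  NumericMatrix stack;   // 6x6, kcal/mol
  NumericVector bulge;   // sizes 1..max_span
  NumericVector interior;// sizes 1..max_span (sizes < 2 unused)
  double init_penalty;
  double terminal_au_gu;
  double ninio_per_nt;
  double ninio_max;
  int max_span;
};

static inline double terminal_pen(int type, const Params &P) {
  return (type >= 3) ? P.terminal_au_gu : 0.0; // GU, UG, AU, UA
}

// energy of joining pair (i,j) to the next pair (k,l); a,b = unpaired
// counts on strand1 / strand2 between them
static inline double join_cost(const IntegerVector &s1, const IntegerVector &s2,
                               int i, int j, int k, int l, const Params &P) {
  int a = k - i - 1, b = j - l - 1;
  int t = a + b;
  if (t > P.max_span) return NEG_INF_GUARD;
  if (t == 0) { // stack: 5'-s1[i] s1[k]-3' over 3'-s2[j] s2[l]-5'
    int t1 = pair_type(s1[i], s2[j]);
    int t2 = pair_type(s2[l], s1[k]);
    return P.stack(t1 - 1, t2 - 1);
  }
  if (a == 0 || b == 0) { // bulge
    double e = P.bulge[t - 1];
    if (t == 1) { // single-nt bulge keeps the flanking stack
      int t1 = pair_type(s1[i], s2[j]);
      int t2 = pair_type(s2[l], s1[k]);
      e += P.stack(t1 - 1, t2 - 1);
    }
    return e;
  }
  double asym = P.ninio_per_nt * std::abs(a - b);
  if (asym > P.ninio_max) asym = P.ninio_max;
  return P.interior[t - 1] + asym;
}

// [[Rcpp::export(name = ".duplex_fold_cpp")]]
List duplex_fold_cpp(IntegerVector s1, IntegerVector s2,
                     NumericMatrix stack, NumericVector bulge,
                     NumericVector interior, double init_penalty,
                     double terminal_au_gu, double ninio_per_nt,
                     double ninio_max, int max_span) {
  Params P{stack, bulge, interior, init_penalty, terminal_au_gu,
           ninio_per_nt, ninio_max, max_span};
  int n = s1.size(), m = s2.size();

  // R[i][j]: minimal energy of the duplex part from pair (i,j) rightwards
  // (terminal penalty at the right end included; init and left terminal
  // penalty are not).
  std::vector<std::vector<double> > R(n, std::vector<double>(m, NEG_INF_GUARD));
  std::vector<std::vector<int> > ptype(n, std::vector<int>(m, 0));
  bool any_pair = false;

  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      ptype[i][j] = pair_type(s1[i], s2[j]);

  for (int i = n - 1; i >= 0; --i) {
    for (int j = 0; j < m; ++j) {
      if (!ptype[i][j]) continue;
      any_pair = true;
      double best = terminal_pen(ptype[i][j], P); // duplex ends here
      int kmax = std::min(n - 1, i + P.max_span + 1);
      int lmin = std::max(0, j - P.max_span - 1);
      for (int k = i + 1; k <= kmax; ++k) {
        for (int l = j - 1; l >= lmin; --l) {
          if (!ptype[k][l]) continue;
          double c = join_cost(s1, s2, i, j, k, l, P);
          if (c >= NEG_INF_GUARD) continue;
          double v = c + R[k][l];
          if (v < best) best = v;
        }
      }
      R[i][j] = best;
    }
  }

  if (!any_pair) {
    return List::create(_["dg"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2),
                        _["n_pairs"] = 0, _["n_gu_pairs"] = 0);
  }

  double mfe = NEG_INF_GUARD;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (ptype[i][j]) {
        double v = P.init_penalty + terminal_pen(ptype[i][j], P) + R[i][j];
        if (v < mfe) mfe = v;
      }

  // traceback: lexicographically smallest co-optimal pair list
  const double tol = 1e-9;
  int ci = -1, cj = -1;
  for (int i = 0; i < n && ci < 0; ++i)
    for (int j = 0; j < m; ++j)
      if (ptype[i][j] &&
          std::fabs(P.init_penalty + terminal_pen(ptype[i][j], P) + R[i][j] - mfe) < tol) {
        ci = i; cj = j; break;
      }

  std::vector<int> pi, pj;
  while (ci >= 0) {
    pi.push_back(ci + 1); pj.push_back(cj + 1);
    double target = R[ci][cj];
    if (std::fabs(target - terminal_pen(ptype[ci][cj], P)) < tol) break; // prefer stopping
    int ni = -1, nj = -1;
    int kmax = std::min(n - 1, ci + P.max_span + 1);
    int lmin = std::max(0, cj - P.max_span - 1);
    for (int k = ci + 1; k <= kmax && ni < 0; ++k) {
      for (int l = lmin; l <= cj - 1; ++l) {
        if (!ptype[k][l]) continue;
        double c = join_cost(s1, s2, ci, cj, k, l, P);
        if (c >= NEG_INF_GUARD) continue;
        if (std::fabs(c + R[k][l] - target) < tol) { ni = k; nj = l; break; }
      }
    }
    if (ni < 0) break; // numerically unreachable; stop rather than loop
    ci = ni; cj = nj;
  }

  int np = pi.size(), ngu = 0;
  IntegerMatrix pairs(np, 2);
  for (int q = 0; q < np; ++q) {
    pairs(q, 0) = pi[q];
    pairs(q, 1) = pj[q];
    int t = pair_type(s1[pi[q] - 1], s2[pj[q] - 1]);
    if (t == 3 || t == 4) ++ngu;
  }

  return List::create(_["dg"] = mfe, _["pairs"] = pairs,
                      _["n_pairs"] = np, _["n_gu_pairs"] = ngu);
}
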