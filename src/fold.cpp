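// Minimum-free-energy folding of a single RNA strand under a minimal
// nearest-neighbour model: Watson-Crick and G:U wobble pairs, stacking
// energies, size-dependent hairpin/bulge/internal-loop penalties, an
// affine multibranch term, hairpin loops >= 3 nt, no pseudoknots, no
// dangling ends.  Zuker-style O(n^3) dynamic programme with interior
// loops capped at 30 unpaired nucleotides.
//
// The same parameter tables are exposed to R through fold_params() (see
// R/fold.R); the two copies must stay in sync.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-7;
static const int MAXLOOP = 30;

// multibranch affine parameters: closing init, per-branch, per-unpaired
static const double MULTI_A = 3.4;
static const double MULTI_B = 0.4;
static const double MULTI_C = 0.0;

// pair codes: 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG; -1 not pairable
static int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': case 'U': return 3;
  default: return -1;
  }
}

static int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 0;  // A-U
  if (a == 3 && b == 0) return 1;  // U-A
  if (a == 1 && b == 2) return 2;  // C-G
  if (a == 2 && b == 1) return 3;  // G-C
  if (a == 2 && b == 3) return 4;  // G-U
  if (a == 3 && b == 2) return 5;  // U-G
  return -1;
}

// stack[p][q]: pair p at (i,j) stacked on pair q at (i+1,j-1), kcal/mol.
// Watson-Crick entries are the ten Turner unique stacks completed by the
// symmetry stack(p,q) = stack(rev q, rev p); G:U-containing entries use a
// coarse three-level scheme (see fold_params()).
static double STACK[6][6];

static void init_stack() {
  for (int p = 0; p < 6; ++p)
    for (int q = 0; q < 6; ++q)
      STACK[p][q] = 0.0;
  STACK[0][0] = -0.93; STACK[0][1] = -1.10; STACK[1][0] = -1.33;
  STACK[2][1] = -2.08; STACK[2][0] = -2.11; STACK[3][1] = -2.24;
  STACK[3][0] = -2.35; STACK[2][3] = -2.36; STACK[3][3] = -3.26;
  STACK[3][2] = -3.42;
  // symmetry-derived WC entries
  STACK[1][1] = -0.93; STACK[0][3] = -2.08; STACK[0][2] = -2.24;
  STACK[1][3] = -2.11; STACK[1][2] = -2.35; STACK[2][2] = -3.26;
  // G:U-containing stacks: coarse published-magnitude values
  for (int p = 0; p < 6; ++p) {
    for (int q = 0; q < 6; ++q) {
      bool pu = (p >= 4), qu = (q >= 4);
      if (!pu && !qu) continue;
      if (pu && qu) STACK[p][q] = -0.50;
      else {
        int wc = pu ? q : p;
        STACK[p][q] = (wc == 2 || wc == 3) ? -1.50 : -0.80;
      }
    }
  }
  STACK[4][4] = 0.47;  // 5'GG/3'UU, the destabilising tandem wobble
  STACK[5][5] = 0.47;
}

static double hairpin_energy(int n) {
  static const double H[] = {5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4}; // n = 3..9
  if (n < 3) return INF;
  if (n <= 9) return H[n - 3];
  return 6.4 + 1.08 * std::log((double)n / 9.0);
}

static double bulge_energy(int n) {
  static const double B[] = {3.8, 2.8, 3.2, 3.6, 4.0, 4.4}; // n = 1..6
  if (n <= 6) return B[n - 1];
  return 4.4 + 1.08 * std::log((double)n / 6.0);
}

static double internal_energy(int n) {
  static const double I[] = {1.5, 2.2, 2.7, 3.0, 3.2}; // n = 2..6
  if (n <= 6) return I[n - 2];
  return 3.2 + 1.08 * std::log((double)n / 6.0);
}

// energy of the loop closed by an outer pair with n1/n2 unpaired on the
// 5'/3' sides and exactly one inner pair (n1 + n2 >= 1)
static double interior_loop_energy(int n1, int n2) {
  int n = n1 + n2;
  if (n1 == 0 || n2 == 0) return bulge_energy(n);
  double asym = 0.6 * std::abs(n1 - n2);
  if (asym > 3.0) asym = 3.0;
  return internal_energy(n) + asym;
}

struct Fold {
  int n;
  std::vector<int> s;
  std::vector<double> V, M, M2;
  std::vector<double> W;
  std::vector<int> partner;

  double &v(int i, int j) { return V[(size_t)i * n + j]; }
  double &m(int i, int j) { return M[(size_t)i * n + j]; }
  double &m2(int i, int j) { return M2[(size_t)i * n + j]; }

  int pc(int i, int j) { return pair_code(s[i], s[j]); }

  double hairpin_term(int i, int j) { return hairpin_energy(j - i - 1); }

  void fill() {
    V.assign((size_t)n * n, INF);
    M.assign((size_t)n * n, INF);
    M2.assign((size_t)n * n, INF);
    for (int d = 1; d < n; ++d) {
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        // V(i,j)
        if (pc(i, j) >= 0 && d >= 4) {
          double best = hairpin_term(i, j);
          if (pc(i + 1, j - 1) >= 0 && v(i + 1, j - 1) < INF / 2) {
            double e = STACK[pc(i, j)][pc(i + 1, j - 1)] + v(i + 1, j - 1);
            if (e < best) best = e;
          }
          for (int k = i + 1; k <= std::min(i + 1 + MAXLOOP, j - 2); ++k) {
            int n1 = k - i - 1;
            for (int l = j - 1; l > k; --l) {
              int n2 = j - l - 1;
              if (n1 + n2 < 1) continue;        // (i+1,j-1) is the stack case
              if (n1 + n2 > MAXLOOP) break;
              if (v(k, l) >= INF / 2) continue;
              double e = interior_loop_energy(n1, n2) + v(k, l);
              if (e < best) best = e;
            }
          }
          if (d >= 6 && m2(i + 1, j - 1) < INF / 2) {
            double e = MULTI_A + MULTI_B + m2(i + 1, j - 1);
            if (e < best) best = e;
          }
          v(i, j) = best;
        }
        // M(i,j): >= 1 branch inside a multiloop
        {
          double best = INF;
          if (m(i + 1, j) < INF / 2) best = std::min(best, m(i + 1, j) + MULTI_C);
          if (j - 1 >= i && m(i, j - 1) < INF / 2) best = std::min(best, m(i, j - 1) + MULTI_C);
          if (v(i, j) < INF / 2) best = std::min(best, v(i, j) + MULTI_B);
          for (int k = i + 1; k <= j; ++k) {
            if (m(i, k - 1) < INF / 2 && m(k, j) < INF / 2)
              best = std::min(best, m(i, k - 1) + m(k, j));
          }
          m(i, j) = best;
        }
        // M2(i,j): >= 2 branches
        {
          double best = INF;
          for (int k = i + 1; k <= j; ++k) {
            if (m(i, k - 1) < INF / 2 && m(k, j) < INF / 2)
              best = std::min(best, m(i, k - 1) + m(k, j));
          }
          m2(i, j) = best;
        }
      }
    }
    W.assign(n + 1, 0.0);
    for (int j = 1; j <= n; ++j) {
      double best = W[j - 1];
      for (int i = 1; i <= j; ++i) {
        if (v(i - 1, j - 1) < INF / 2)
          best = std::min(best, W[i - 1] + v(i - 1, j - 1));
      }
      W[j] = best;
    }
  }

  void trace_V(int i, int j);

  void trace_M(int i, int j) {
    double t = m(i, j);
    if (m(i + 1, j) < INF / 2 && std::fabs(m(i + 1, j) + MULTI_C - t) < EPS) {
      trace_M(i + 1, j); return;
    }
    if (j - 1 >= i && m(i, j - 1) < INF / 2 &&
        std::fabs(m(i, j - 1) + MULTI_C - t) < EPS) {
      trace_M(i, j - 1); return;
    }
    if (v(i, j) < INF / 2 && std::fabs(v(i, j) + MULTI_B - t) < EPS) {
      trace_V(i, j); return;
    }
    for (int k = i + 1; k <= j; ++k) {
      if (m(i, k - 1) < INF / 2 && m(k, j) < INF / 2 &&
          std::fabs(m(i, k - 1) + m(k, j) - t) < EPS) {
        trace_M(i, k - 1); trace_M(k, j); return;
      }
    }
    stop("internal error: M traceback failed");
  }

  void trace_M2(int i, int j) {
    double t = m2(i, j);
    for (int k = i + 1; k <= j; ++k) {
      if (m(i, k - 1) < INF / 2 && m(k, j) < INF / 2 &&
          std::fabs(m(i, k - 1) + m(k, j) - t) < EPS) {
        trace_M(i, k - 1); trace_M(k, j); return;
      }
    }
    stop("internal error: M2 traceback failed");
  }

  void trace_W() {
    int j = n;
    while (j > 0) {
      if (std::fabs(W[j] - W[j - 1]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 1; i <= j; ++i) {
        if (v(i - 1, j - 1) < INF / 2 &&
            std::fabs(W[i - 1] + v(i - 1, j - 1) - W[j]) < EPS) {
          trace_V(i - 1, j - 1);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) stop("internal error: W traceback failed");
    }
  }
};

void Fold::trace_V(int i, int j) {
  partner[i] = j;
  partner[j] = i;
  double t = v(i, j);
  if (std::fabs(hairpin_term(i, j) - t) < EPS) return;
  if (pc(i + 1, j - 1) >= 0 && v(i + 1, j - 1) < INF / 2 &&
      std::fabs(STACK[pc(i, j)][pc(i + 1, j - 1)] + v(i + 1, j - 1) - t) < EPS) {
    trace_V(i + 1, j - 1); return;
  }
  for (int k = i + 1; k <= std::min(i + 1 + MAXLOOP, j - 2); ++k) {
    int n1 = k - i - 1;
    for (int l = j - 1; l > k; --l) {
      int n2 = j - l - 1;
      if (n1 + n2 < 1) continue;
      if (n1 + n2 > MAXLOOP) break;
      if (v(k, l) >= INF / 2) continue;
      if (std::fabs(interior_loop_energy(n1, n2) + v(k, l) - t) < EPS) {
        trace_V(k, l); return;
      }
    }
  }
  if (j - i >= 6 && m2(i + 1, j - 1) < INF / 2 &&
      std::fabs(MULTI_A + MULTI_B + m2(i + 1, j - 1) - t) < EPS) {
    trace_M2(i + 1, j - 1); return;
  }
  stop("internal error: V traceback failed");
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq) {
  init_stack();
  int n = (int)seq.size();
  if (n < 1) stop("empty sequence");
  Fold f;
  f.n = n;
  f.s.resize(n);
  for (int i = 0; i < n; ++i) {
    int c = base_code(std::toupper((unsigned char)seq[i]));
    if (c < 0) stop("sequence contains a non-ACGTU character");
    f.s[i] = c;
  }
  f.partner.assign(n, -1);
  double mfe = 0.0;
  if (n >= 5) {
    f.fill();
    mfe = f.W[n];
    if (mfe > 0) mfe = 0.0; else f.trace_W();
  }
  std::string db(n, '.');
  IntegerVector partner(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (f.partner[i] >= 0) {
      partner[i] = f.partner[i] + 1;  // 1-based for R
      db[i] = (f.partner[i] > i) ? '(' : ')';
    }
  }
  return List::create(_["mfe"] = mfe,
                      _["dot_bracket"] = db,
                      _["partner"] = partner);
}
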