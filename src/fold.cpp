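// RNA secondary-structure prediction for hairpin screening.
//
// Two backends behind one contract:
//   * "nn"      -- minimum free energy under a simplified nearest-neighbor
//                  model: Watson-Crick + G:U stacking energies from a shipped
//                  parameter table, hairpin/bulge/interior loop length
//                  penalties with Jacobson-Stockmayer log extrapolation, no
//                  pseudoknots, minimum loop 3. Multibranch loops are not
//                  modelled: every stem is a stem-loop (with bulges and
//                  interior loops); the external loop may chain several
//                  stems. This keeps the fold quadratic, which is what a
//                  hairpin screen needs.
//   * "maxpair" -- Nussinov base-pair maximization (used for oracle tests).
//
// Energies are handled internally as integer centi-kcal/mol.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

static const int INF = 1000000;
static const int MAXLOOP = 30;     // largest interior/bulge loop considered
static const int MINLOOP = 3;      // minimum hairpin loop length
static const double RT37 = 0.6163; // kcal/mol at 37 C

// base coding: A=0 C=1 G=2 U=3, -1 otherwise
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

// pair types: AU=0 UA=1 CG=2 GC=3 GU=4 UG=5, -1 if unpairable
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// stacking energies (centi-kcal/mol), outer pair x inner pair,
// rows/cols ordered AU UA CG GC GU UG
static const int STACK[6][6] = {
  { -90, -110, -220, -210,  -60, -140 }, // AU
  { -130,  -90, -240, -210, -100, -130 }, // UA
  { -210, -210, -330, -240, -140, -210 }, // CG
  { -240, -220, -340, -330, -150, -250 }, // GC
  { -130, -140, -250, -210,  -50,  130 }, // GU
  { -100,  -60, -150, -140,   30,  -50 }  // UG
};

static const int HAIRPIN_INIT[10] = { INF, INF, INF, 540, 560, 570, 540, 600, 550, 640 };
static const int BULGE_INIT[7]    = { INF, 380, 280, 320, 360, 400, 440 };
static const int INTERIOR_INIT[7] = { INF, INF, 150, 180, 200, 220, 250 };

static inline int loop_extrap(int base, int n, int nref) {
  return base + (int) std::lround(175.0 * RT37 * std::log((double) n / nref));
}

static inline int hairpin_energy(int n) {
  if (n < MINLOOP) return INF;
  if (n <= 9) return HAIRPIN_INIT[n];
  return loop_extrap(HAIRPIN_INIT[9], n, 9);
}

static inline int bulge_energy(int n) {
  if (n <= 0) return INF;
  if (n <= 6) return BULGE_INIT[n];
  return loop_extrap(BULGE_INIT[6], n, 6);
}

static inline int interior_energy(int n1, int n2) {
  int n = n1 + n2;
  int base = (n <= 6) ? INTERIOR_INIT[n] : loop_extrap(INTERIOR_INIT[6], n, 6);
  int asym = 50 * std::abs(n1 - n2);
  if (asym > 300) asym = 300;
  return base + asym;
}

// lookup table for loop energies by (n1, n2) unpaired counts, filled once
static int LOOP_TAB[MAXLOOP + 1][MAXLOOP + 1];
static bool LOOP_TAB_READY = false;

static void init_loop_tab() {
  if (LOOP_TAB_READY) return;
  for (int n1 = 0; n1 <= MAXLOOP; ++n1)
    for (int n2 = 0; n2 <= MAXLOOP; ++n2) {
      if (n1 == 0 && n2 == 0) LOOP_TAB[n1][n2] = 0; // stack handled separately
      else if (n1 == 0 || n2 == 0) LOOP_TAB[n1][n2] = bulge_energy(n1 + n2);
      else LOOP_TAB[n1][n2] = interior_energy(n1, n2);
    }
  LOOP_TAB_READY = true;
}

// energy of the loop closed by (i,j) with inner pair (k,l)
static inline int internal_loop_energy(int i, int j, int k, int l,
                                       int pt_ij, int pt_kl) {
  int n1 = k - i - 1, n2 = j - l - 1;
  if (n1 == 0 && n2 == 0) return STACK[pt_ij][pt_kl];
  return LOOP_TAB[n1][n2];
}

struct FoldMat {
  int n;
  std::vector<int> V;
  int at(const std::vector<int>& M, int i, int j) const { return M[i * n + j]; }
  void set(std::vector<int>& M, int i, int j, int v) { M[i * n + j] = v; }
};

static void fill_nn(const std::vector<int>& s, FoldMat& F, std::vector<int>& W) {
  int n = F.n;
  init_loop_tab();
  F.V.assign((size_t) n * n, INF);
  for (int d = MINLOOP + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int pt = pair_type(s[i], s[j]);
      if (pt < 0) continue;
      int best = hairpin_energy(j - i - 1);
      // stack / bulge / interior
      int kmax = std::min(i + MAXLOOP + 1, j - MINLOOP - 1);
      for (int k = i + 1; k <= kmax; ++k) {
        int lmin = std::max(k + MINLOOP + 1, j - 1 - (MAXLOOP - (k - i - 1)));
        const int* Vk = &F.V[(size_t) k * n];
        for (int l = lmin; l < j; ++l) {
          int vkl = Vk[l];
          if (vkl >= INF) continue;
          int e = internal_loop_energy(i, j, k, l, pt,
                                       pair_type(s[k], s[l])) + vkl;
          if (e < best) best = e;
        }
      }
      F.set(F.V, i, j, best);
    }
  }
  // external loop: chain of stem-loops separated by unpaired stretches
  W.assign(n + 1, 0);
  for (int j = 0; j < n; ++j) {
    int best = W[j]; // j unpaired (W indexed with offset 1)
    for (int k = 0; k <= j - MINLOOP - 1; ++k) {
      int v = F.at(F.V, k, j);
      if (v < INF) {
        int e = v + W[k];
        if (e < best) best = e;
      }
    }
    W[j + 1] = best;
  }
}

static void traceback_V(const std::vector<int>& s, const FoldMat& F,
                        int i, int j, std::vector<int>& pair) {
  int v = F.at(F.V, i, j);
  if (v >= INF) return;
  pair[i] = j;
  pair[j] = i;
  int pt = pair_type(s[i], s[j]);
  if (v == hairpin_energy(j - i - 1)) return;
  int kmax = std::min(i + MAXLOOP + 1, j - MINLOOP - 1);
  for (int k = i + 1; k <= kmax; ++k) {
    int lmin = std::max(k + MINLOOP + 1, j - 1 - (MAXLOOP - (k - i - 1)));
    for (int l = lmin; l < j; ++l) {
      int ptkl = pair_type(s[k], s[l]);
      if (ptkl < 0) continue;
      int vkl = F.at(F.V, k, l);
      if (vkl < INF && internal_loop_energy(i, j, k, l, pt, ptkl) + vkl == v) {
        traceback_V(s, F, k, l, pair);
        return;
      }
    }
  }
}

static std::vector<int> encode(const std::string& seq) {
  std::vector<int> s(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    int c = base_code(seq[i]);
    if (c < 0) stop("fold: sequence contains a non-ACGU character at position %d", (int) (i + 1));
    s[i] = c;
  }
  return s;
}

static List fold_result(const std::string& seq, const std::vector<int>& pair,
                        double dg) {
  int n = (int) seq.size();
  std::string db(n, '.');
  IntegerVector ptab(n);
  for (int i = 0; i < n; ++i) {
    if (pair[i] >= 0) {
      db[i] = (pair[i] > i) ? '(' : ')';
      ptab[i] = pair[i] + 1;
    } else {
      ptab[i] = 0;
    }
  }
  return List::create(_["sequence"] = seq, _["structure"] = db,
                      _["delta_g"] = dg, _["pair_table"] = ptab);
}

// [[Rcpp::export(name = ".fold_nn_cpp")]]
List fold_nn_cpp(std::string seq) {
  std::vector<int> s = encode(seq);
  int n = (int) s.size();
  FoldMat F;
  F.n = n;
  std::vector<int> W;
  fill_nn(s, F, W);
  std::vector<int> pair(n, -1);
  // external traceback
  int j = n - 1;
  while (j >= 0) {
    if (W[j + 1] == W[j]) { --j; continue; }
    bool found = false;
    for (int k = 0; k <= j - MINLOOP - 1; ++k) {
      int v = F.at(F.V, k, j);
      if (v < INF && v + W[k] == W[j + 1]) {
        traceback_V(s, F, k, j, pair);
        j = k - 1;
        found = true;
        break;
      }
    }
    if (!found) --j;
  }
  return fold_result(seq, pair, W[n] / 100.0);
}

// [[Rcpp::export(name = ".fold_maxpair_cpp")]]
List fold_maxpair_cpp(std::string seq) {
  std::vector<int> s = encode(seq);
  int n = (int) s.size();
  std::vector<int> M((size_t) n * n, 0);
  for (int d = MINLOOP + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int best = M[(i + 1) * n + j]; // i unpaired
      for (int k = i + MINLOOP + 1; k <= j; ++k) {
        if (pair_type(s[i], s[k]) < 0) continue;
        int e = 1 + (k - i > MINLOOP + 1 ? M[(i + 1) * n + (k - 1)] : 0)
                  + (k < j ? M[(k + 1) * n + j] : 0);
        if (e > best) best = e;
      }
      M[i * n + j] = best;
    }
  }
  std::vector<int> pair(n, -1);
  // iterative traceback over segments
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= MINLOOP) continue;
    if (M[i * n + j] == M[(i + 1) * n + j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    for (int k = i + MINLOOP + 1; k <= j; ++k) {
      if (pair_type(s[i], s[k]) < 0) continue;
      int e = 1 + (k - i > MINLOOP + 1 ? M[(i + 1) * n + (k - 1)] : 0)
                + (k < j ? M[(k + 1) * n + j] : 0);
      if (e == M[i * n + j]) {
        pair[i] = k;
        pair[k] = i;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }
  int npair = n > 0 ? M[0 * n + (n - 1)] : 0;
  List res = fold_result(seq, pair, -(double) npair);
  res["n_pairs"] = npair;
  return res;
}
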