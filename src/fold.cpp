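// Minimum-free-energy nested secondary structure under a simplified
// nearest-neighbour model: stacking energies per pair step, size-dependent
// hairpin/bulge/interior penalties, affine multiloops.  Energies are handled
// as integer centi-kcal so ties are exact.  Interior/bulge loops larger than
// `max_interior` unpaired nucleotides are disallowed by the model.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static const int INF = INT32_MAX / 4;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
  }
  return -1;
}

// pair indices: AU=0, UA=1, CG=2, GC=3, GU=4, UG=5; -1 = not pairable
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct FoldCtx {
  int n, min_hp, max_int, ml_a, ml_b, ml_c;
  std::vector<int> s;            // base codes
  std::vector<int> hp, bu, in_;  // loop penalties by size (centi-kcal)
  int stack[6][6];
  std::vector<int> V, WM;        // n*n, row-major
  std::vector<int> W;            // suffix MFE, size n+1
  inline int &v(int i, int j) { return V[i * n + j]; }
  inline int &wm(int i, int j) { return WM[i * n + j]; }
  inline int pt(int i, int j) { return pair_type(s[i], s[j]); }
};

static void fill_tables(FoldCtx &c) {
  int n = c.n;
  c.V.assign((size_t)n * n, INF);
  // WM(i,j): minimum energy of a multiloop segment holding >= 1 branch;
  // a lone unpaired base holds none, so the diagonal stays infinite.
  c.WM.assign((size_t)n * n, INF);
  for (int span = 1; span <= n - 1; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      // --- V(i,j)
      if (c.pt(i, j) >= 0 && j - i - 1 >= c.min_hp) {
        int best = c.hp[j - i - 1];
        // interior / bulge / stack
        for (int k = i + 1; k < j; ++k) {
          int n1 = k - i - 1;
          if (n1 > c.max_int) break;
          for (int l = j - 1; l > k; --l) {
            int n2 = j - l - 1;
            if (n1 + n2 > c.max_int) break;
            int vkl = c.v(k, l);
            if (vkl >= INF) continue;
            int loop;
            if (n1 == 0 && n2 == 0)
              loop = c.stack[c.pt(i, j)][c.pt(k, l)];
            else if (n1 == 0 || n2 == 0)
              loop = c.bu[n1 + n2];
            else
              loop = c.in_[n1 + n2];
            int e = vkl + loop;
            if (e < best) best = e;
          }
        }
        // multiloop closing
        for (int h = i + 2; h <= j - 2; ++h) {
          int a = c.wm(i + 1, h), b = c.wm(h + 1, j - 1);
          if (a >= INF || b >= INF) continue;
          int e = c.ml_a + c.ml_b + a + b;
          if (e < best) best = e;
        }
        c.v(i, j) = best;
      }
      // --- WM(i,j)
      {
        int best = INF;
        int a;
        a = c.wm(i + 1, j); if (a < INF && a + c.ml_c < best) best = a + c.ml_c;
        a = c.wm(i, j - 1); if (a < INF && a + c.ml_c < best) best = a + c.ml_c;
        a = c.v(i, j);      if (a < INF && a + c.ml_b < best) best = a + c.ml_b;
        for (int h = i; h < j; ++h) {
          int x = c.wm(i, h), y = c.wm(h + 1, j);
          if (x < INF && y < INF && x + y < best) best = x + y;
        }
        c.wm(i, j) = best;
      }
    }
  }
  // exterior (suffix) array; exterior bases are free
  c.W.assign(n + 1, 0);
  for (int i = n - 1; i >= 0; --i) {
    int best = c.W[i + 1];
    for (int j = i + 1; j < n; ++j) {
      int vij = c.v(i, j);
      if (vij < INF && vij + c.W[j + 1] < best) best = vij + c.W[j + 1];
    }
    c.W[i] = best;
  }
}

// traceback; ties prefer pairing the leftmost base
static void trace_V(FoldCtx &c, int i, int j, std::string &db);
static void trace_WM(FoldCtx &c, int i, int j, std::string &db);

static void trace_V(FoldCtx &c, int i, int j, std::string &db) {
  db[i] = '('; db[j] = ')';
  int target = c.v(i, j);
  for (int k = i + 1; k < j; ++k) {
    int n1 = k - i - 1;
    if (n1 > c.max_int) break;
    for (int l = j - 1; l > k; --l) {
      int n2 = j - l - 1;
      if (n1 + n2 > c.max_int) break;
      int vkl = c.v(k, l);
      if (vkl >= INF) continue;
      int loop;
      if (n1 == 0 && n2 == 0) loop = c.stack[c.pt(i, j)][c.pt(k, l)];
      else if (n1 == 0 || n2 == 0) loop = c.bu[n1 + n2];
      else loop = c.in_[n1 + n2];
      if (vkl + loop == target) { trace_V(c, k, l, db); return; }
    }
  }
  for (int h = i + 2; h <= j - 2; ++h) {
    int a = c.wm(i + 1, h), b = c.wm(h + 1, j - 1);
    if (a < INF && b < INF && c.ml_a + c.ml_b + a + b == target) {
      trace_WM(c, i + 1, h, db); trace_WM(c, h + 1, j - 1, db); return;
    }
  }
  // hairpin: enclosed bases stay dots
}

static void trace_WM(FoldCtx &c, int i, int j, std::string &db) {
  int target = c.wm(i, j);
  if (i == j) return;  // single unpaired base
  if (c.v(i, j) < INF && c.v(i, j) + c.ml_b == target) { trace_V(c, i, j, db); return; }
  for (int h = i; h < j; ++h) {
    int x = c.wm(i, h), y = c.wm(h + 1, j);
    if (x < INF && y < INF && x + y == target) {
      trace_WM(c, i, h, db); trace_WM(c, h + 1, j, db); return;
    }
  }
  if (c.wm(i + 1, j) < INF && c.wm(i + 1, j) + c.ml_c == target) { trace_WM(c, i + 1, j, db); return; }
  if (c.wm(i, j - 1) < INF && c.wm(i, j - 1) + c.ml_c == target) { trace_WM(c, i, j - 1, db); return; }
  Rcpp::stop("internal traceback failure in multiloop region");
}

// [[Rcpp::export]]
List fold_cpp(std::string seq, IntegerMatrix stack_centi,
              IntegerVector hp_centi, IntegerVector bu_centi,
              IntegerVector in_centi, int ml_a, int ml_b, int ml_c,
              int min_hairpin, int max_interior) {
  FoldCtx c;
  c.n = (int)seq.size();
  c.min_hp = min_hairpin; c.max_int = max_interior;
  c.ml_a = ml_a; c.ml_b = ml_b; c.ml_c = ml_c;
  c.s.resize(c.n);
  for (int i = 0; i < c.n; ++i) {
    c.s[i] = base_code(seq[i]);
    if (c.s[i] < 0) Rcpp::stop("non-ACGU character in sequence");
  }
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) c.stack[a][b] = stack_centi(a, b);
  c.hp.assign(hp_centi.begin(), hp_centi.end());
  c.bu.assign(bu_centi.begin(), bu_centi.end());
  c.in_.assign(in_centi.begin(), in_centi.end());
  if ((int)c.hp.size() < c.n || (int)c.bu.size() <= c.max_int ||
      (int)c.in_.size() <= c.max_int)
    Rcpp::stop("penalty vectors shorter than required");

  fill_tables(c);
  int mfe = c.W[0];
  std::string db(c.n, '.');
  // exterior traceback, preferring to pair the leftmost base
  int i = 0;
  while (i < c.n) {
    if (c.W[i] == c.W[i + 1]) {
      bool paired = false;
      for (int j = i + 1; j < c.n; ++j) {
        int vij = c.v(i, j);
        if (vij < INF && vij + c.W[j + 1] == c.W[i]) {
          trace_V(c, i, j, db); i = j + 1; paired = true; break;
        }
      }
      if (!paired) ++i;
    } else {
      bool paired = false;
      for (int j = i + 1; j < c.n; ++j) {
        int vij = c.v(i, j);
        if (vij < INF && vij + c.W[j + 1] == c.W[i]) {
          trace_V(c, i, j, db); i = j + 1; paired = true; break;
        }
      }
      if (!paired) Rcpp::stop("internal traceback failure in exterior");
    }
  }
  return List::create(_["energy_centi"] = mfe, _["structure"] = db);
}
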