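#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, U=3.
// Pair types (first base 5' of second on the same strand reading outward):
// 0=AU 1=UA 2=CG 3=GC 4=GU 5=UG, -1 = not pairable.

static const double INF = 1e9;
static const double EPS = 1e-6;

static inline int ptype(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Model {
  double stack[6][6];
  double hairpin_a, hairpin_b;
  double bulge_a, bulge_b;
  double internal_a, internal_b;
  double ml_init, ml_branch, ml_unpaired;
  double pair_bonus;
  int min_helix, min_hairpin, max_internal;
};

static Model read_model(const List& par) {
  Model m;
  NumericMatrix st = par["stack"];
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) m.stack[i][j] = st(i, j);
  m.hairpin_a = par["hairpin_a"];   m.hairpin_b = par["hairpin_b"];
  m.bulge_a = par["bulge_a"];       m.bulge_b = par["bulge_b"];
  m.internal_a = par["internal_a"]; m.internal_b = par["internal_b"];
  m.ml_init = par["ml_init"];       m.ml_branch = par["ml_branch"];
  m.ml_unpaired = par["ml_unpaired"];
  m.pair_bonus = par["pair_bonus"];
  m.min_helix = as<int>(par["min_helix"]);
  m.min_hairpin = as<int>(par["min_hairpin"]);
  m.max_internal = as<int>(par["max_internal"]);
  return m;
}

class Folder {
public:
  int n;
  std::vector<int> s;
  Model m;
  // Cm[i][j]: best energy, (i,j) outermost pair of a helix of length >= min_helix.
  // L[i][j]:  best energy of the loop closed by pair (i,j) (hairpin / internal /
  //           multibranch), i.e. the continuation after the innermost helix pair.
  // WM[i][j]: best energy of a multiloop segment holding >= 1 helix branch.
  std::vector<double> Cm, Lm, WM;
  std::vector<double> W;
  std::vector<int> pairvec;

  Folder(const std::vector<int>& seq, const Model& mod) : n(seq.size()), s(seq), m(mod) {
    Cm.assign((size_t)n * n, INF);
    Lm.assign((size_t)n * n, INF);
    WM.assign((size_t)n * n, INF);
    W.assign(n > 0 ? n : 1, 0.0);
    pairvec.assign(n, -1);
  }

  inline double& C(int i, int j) { return Cm[(size_t)i * n + j]; }
  inline double& Lp(int i, int j) { return Lm[(size_t)i * n + j]; }
  inline double& M(int i, int j) { return WM[(size_t)i * n + j]; }
  inline double Cg(int i, int j) const {
    return (i >= 0 && j < n && i < j) ? Cm[(size_t)i * n + j] : INF;
  }
  inline double Mg(int i, int j) const {
    return (i >= 0 && j < n && i <= j) ? WM[(size_t)i * n + j] : INF;
  }

  double loop_energy_hairpin(int len) const {
    return m.hairpin_a + m.hairpin_b * (len - 3);
  }
  double loop_penalty(int l1, int l2) const {
    int ls = l1 + l2;
    if (l1 == 0 || l2 == 0) return m.bulge_a + m.bulge_b * ls;
    return m.internal_a + m.internal_b * ls;
  }

  // loop continuation after innermost helix pair (p,q); uses interior cells only
  double compute_loop(int p, int q) const {
    double best = INF;
    int hl = q - p - 1;
    if (hl >= m.min_hairpin) best = loop_energy_hairpin(hl);
    // bulge / internal loop to the next helix
    for (int p2 = p + 1; p2 < q; ++p2) {
      int l1 = p2 - p - 1;
      if (l1 > m.max_internal) break;
      for (int q2 = q - 1; q2 > p2; --q2) {
        int l2 = q - q2 - 1;
        int ls = l1 + l2;
        if (ls > m.max_internal) break;
        if (ls < 1) continue; // stacked pair: handled inside the helix sum
        double c = Cg(p2, q2);
        if (c < INF / 2) {
          double v = loop_penalty(l1, l2) + c;
          if (v < best - 1e-12) best = v;
        }
      }
    }
    // multibranch loop: >= 2 branches inside
    for (int k = p + 1; k <= q - 2; ++k) {
      double a = Mg(p + 1, k), b = Mg(k + 1, q - 1);
      if (a < INF / 2 && b < INF / 2) {
        double v = m.ml_init + m.ml_branch + a + b;
        if (v < best - 1e-12) best = v;
      }
    }
    return best;
  }

  void compute() {
    if (n == 0) return;
    for (int len = 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        // loop table for (i,j) as an innermost helix pair
        if (ptype(s[i], s[j]) >= 0 && j - i - 1 >= m.min_hairpin)
          Lp(i, j) = compute_loop(i, j);
        // C: enumerate helix lengths from the outer pair (i,j) inward
        double best = INF;
        double cum = 0;
        int prev_pt = -1;
        for (int t = 0;; ++t) {
          int p = i + t, q = j - t;
          if (q - p - 1 < m.min_hairpin) break;
          int pt = ptype(s[p], s[q]);
          if (pt < 0) break;
          if (t > 0) cum += m.stack[prev_pt][pt];
          prev_pt = pt;
          int h = t + 1;
          if (h >= m.min_helix) {
            double lp = Lp(p, q);
            if (lp < INF / 2) {
              double v = cum + h * m.pair_bonus + lp;
              if (v < best - 1e-12) best = v;
            }
          }
        }
        C(i, j) = best;
        // WM
        double w = INF;
        double x = Mg(i + 1, j);
        if (x < INF / 2) w = std::min(w, x + m.ml_unpaired);
        x = Mg(i, j - 1);
        if (x < INF / 2) w = std::min(w, x + m.ml_unpaired);
        if (best < INF / 2) w = std::min(w, best + m.ml_branch);
        for (int k = i + 1; k <= j; ++k) {
          double a = Mg(i, k - 1), b = Mg(k, j);
          if (a < INF / 2 && b < INF / 2) w = std::min(w, a + b);
        }
        M(i, j) = w;
      }
    }
    // external
    for (int j = 0; j < n; ++j) {
      double w = (j > 0) ? W[j - 1] : 0.0;
      for (int k = 0; k <= j; ++k) {
        double c = Cg(k, j);
        if (c < INF / 2) {
          double base = (k > 0) ? W[k - 1] : 0.0;
          if (base + c < w) w = base + c;
        }
      }
      W[j] = w;
    }
  }

  double mfe() const {
    if (n == 0) return 0.0;
    return std::min(0.0, W[n - 1]);
  }

  static inline bool eq(double a, double b) { return std::fabs(a - b) < EPS; }

  void trace_loop(int p, int q, double target);
  void trace_C(int i, int j);
  void trace_WM(int i, int j, double target);

  void trace_external() {
    if (n == 0 || W[n - 1] >= -EPS) return;
    int j = n - 1;
    while (j >= 0) {
      if (j > 0 && eq(W[j], W[j - 1])) { --j; continue; }
      if (eq(W[j], 0.0)) break;
      bool found = false;
      for (int k = 0; k <= j; ++k) {
        double c = Cg(k, j);
        if (c < INF / 2) {
          double base = (k > 0) ? W[k - 1] : 0.0;
          if (eq(W[j], base + c)) { trace_C(k, j); j = k - 1; found = true; break; }
        }
      }
      if (!found) break; // defensive; should not happen
    }
  }
};

void Folder::trace_C(int i, int j) {
  double target = C(i, j);
  double cum = 0;
  int prev_pt = -1;
  for (int t = 0;; ++t) {
    int p = i + t, q = j - t;
    if (q - p - 1 < m.min_hairpin) break;
    int pt = ptype(s[p], s[q]);
    if (pt < 0) break;
    if (t > 0) cum += m.stack[prev_pt][pt];
    prev_pt = pt;
    int h = t + 1;
    if (h >= m.min_helix) {
      double lp = Lp(p, q);
      if (lp < INF / 2 && eq(target, cum + h * m.pair_bonus + lp)) {
        for (int u = 0; u < h; ++u) { pairvec[i + u] = j - u; pairvec[j - u] = i + u; }
        trace_loop(p, q, lp);
        return;
      }
    }
  }
}

void Folder::trace_loop(int p, int q, double target) {
  int hl = q - p - 1;
  if (hl >= m.min_hairpin && eq(target, loop_energy_hairpin(hl))) return;
  for (int p2 = p + 1; p2 < q; ++p2) {
    int l1 = p2 - p - 1;
    if (l1 > m.max_internal) break;
    for (int q2 = q - 1; q2 > p2; --q2) {
      int l2 = q - q2 - 1;
      int ls = l1 + l2;
      if (ls > m.max_internal) break;
      if (ls < 1) continue;
      double c = Cg(p2, q2);
      if (c < INF / 2 && eq(target, loop_penalty(l1, l2) + c)) {
        trace_C(p2, q2);
        return;
      }
    }
  }
  for (int k = p + 1; k <= q - 2; ++k) {
    double a = Mg(p + 1, k), b = Mg(k + 1, q - 1);
    if (a < INF / 2 && b < INF / 2 &&
        eq(target, m.ml_init + m.ml_branch + a + b)) {
      trace_WM(p + 1, k, a);
      trace_WM(k + 1, q - 1, b);
      return;
    }
  }
}

void Folder::trace_WM(int i, int j, double target) {
  while (true) {
    double x = Mg(i + 1, j);
    if (x < INF / 2 && eq(target, x + m.ml_unpaired)) { ++i; target = x; continue; }
    x = Mg(i, j - 1);
    if (x < INF / 2 && eq(target, x + m.ml_unpaired)) { --j; target = x; continue; }
    double c = Cg(i, j);
    if (c < INF / 2 && eq(target, c + m.ml_branch)) { trace_C(i, j); return; }
    for (int k = i + 1; k <= j; ++k) {
      double a = Mg(i, k - 1), b = Mg(k, j);
      if (a < INF / 2 && b < INF / 2 && eq(target, a + b)) {
        trace_WM(i, k - 1, a);
        trace_WM(k, j, b);
        return;
      }
    }
    return; // defensive
  }
}

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seq_codes, List params) {
  std::vector<int> s(seq_codes.begin(), seq_codes.end());
  Model m = read_model(params);
  Folder f(s, m);
  f.compute();
  double e = f.mfe();
  if (e < -EPS) f.trace_external();
  int n = s.size();
  std::string db(n, '.');
  IntegerVector pr(n, 0);
  for (int i = 0; i < n; ++i) {
    if (f.pairvec[i] > i) db[i] = '(';
    else if (f.pairvec[i] >= 0 && f.pairvec[i] < i) db[i] = ')';
    if (f.pairvec[i] >= 0) pr[i] = f.pairvec[i] + 1; // 1-based partner
  }
  return List::create(_["mfe"] = e, _["structure"] = db, _["pairing"] = pr);
}

// Hybridization energy of an ungapped antiparallel duplex.
// mi and site are both 5'->3'; miRNA position k aligns site position L-k+1.
// Energy = sum of nearest-neighbor stacks over adjacent paired columns plus
// pair_bonus per paired column; unpaired columns contribute nothing.
// [[Rcpp::export]]
double duplex_energy_cpp(IntegerVector mi, IntegerVector site,
                         NumericMatrix stack, double pair_bonus) {
  int L = mi.size();
  std::vector<int> pt(L, -1);
  for (int k = 0; k < L; ++k) pt[k] = ptype(mi[k], site[L - 1 - k]);
  double e = 0;
  int np = 0;
  for (int k = 0; k < L; ++k) {
    if (pt[k] >= 0) ++np;
    if (k + 1 < L && pt[k] >= 0 && pt[k + 1] >= 0) e += stack(pt[k], pt[k + 1]);
  }
  return e + pair_bonus * np;
}

// Ungapped antiparallel scan of a miRNA against a transcript. For every
// window with at most max_mm non-Watson-Crick columns (G:U counts as a
// non-match here), returns the 1-based window start, a per-position profile
// over miRNA positions 1..L ('M' match, 'G' G:U wobble, 'm' mismatch) and
// the duplex hybridization energy.
// [[Rcpp::export]]
List scan_windows_cpp(IntegerVector mi, IntegerVector tx,
                      NumericMatrix stack, double pair_bonus, int max_mm) {
  int L = mi.size(), T = tx.size();
  std::vector<int> starts;
  std::vector<std::string> profiles;
  std::vector<double> energies;
  if (T >= L && L > 0) {
    for (int w = 0; w + L <= T; ++w) {
      int mm = 0;
      for (int k = 0; k < L && mm <= max_mm; ++k) {
        int a = mi[k], b = tx[w + L - 1 - k];
        bool wc = (a == 0 && b == 3) || (a == 3 && b == 0) ||
                  (a == 1 && b == 2) || (a == 2 && b == 1);
        if (!wc) ++mm;
      }
      if (mm > max_mm) continue;
      std::string prof(L, 'm');
      double e = 0;
      int prev = -1, np = 0;
      for (int k = 0; k < L; ++k) {
        int a = mi[k], b = tx[w + L - 1 - k];
        int pt = ptype(a, b);
        bool wc = (pt >= 0 && pt < 4);
        if (wc) prof[k] = 'M';
        else if (pt >= 0) prof[k] = 'G';
        if (pt >= 0) {
          ++np;
          if (prev >= 0) e += stack(prev, pt);
        }
        prev = pt;
      }
      e += pair_bonus * np;
      starts.push_back(w + 1);
      profiles.push_back(prof);
      energies.push_back(e);
    }
  }
  return List::create(_["start"] = wrap(starts),
                      _["profile"] = wrap(profiles),
                      _["energy"] = wrap(energies));
}

// Locate a 3' adapter in each read by best (longest, then leftmost)
// ungapped suffix(read)-prefix(adapter) overlap of at least min_overlap
// with at most max_mismatch mismatches. Returns the 0-based insert length
// (position where the adapter starts), or -1 when no overlap qualifies.
// [[Rcpp::export]]
IntegerVector locate_adapter_cpp(CharacterVector reads, std::string adapter,
                                 int min_overlap, int max_mismatch) {
  int nr = reads.size();
  int al = adapter.size();
  IntegerVector out(nr, -1);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    int rl = rd.size();
    for (int t = 0; t <= rl - min_overlap; ++t) {
      int ov = std::min(rl - t, al);
      if (ov < min_overlap) break;
      int mm = 0;
      for (int k = 0; k < ov && mm <= max_mismatch; ++k)
        if (rd[t + k] != adapter[k]) ++mm;
      if (mm <= max_mismatch) { out[r] = t; break; }
    }
  }
  return out;
}
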