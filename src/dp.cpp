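// Dynamic programs for the loop-additive RNA energy model:
//  - constrained MFE folding with deterministic traceback
//  - McCaskill-style partition function (optionally with positions forced
//    unpaired, which yields exact unpaired probabilities by a ratio of
//    partition functions)
//  - intermolecular hybrid duplex minimisation anchored at a terminal pair
//
// Bases are encoded 0=A, 1=C, 2=G, 3=U; negative codes mark unpairable
// placeholder (linker) positions.  All energies in kcal/mol.  Pairing is
// restricted to Watson-Crick and G-U wobble pairs, a hairpin needs at least
// three unpaired bases (j - i > 3), each base has at most one partner and
// structures are nested (the recursions cannot emit pseudoknots).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e9;

struct EnergyPar {
  double pe[4][4];       // closing-pair energies, BIG if not pairable
  double stack_bonus;
  double h0, h_per;      // hairpin
  double b0, b_per;      // bulge
  double i0, i_per;      // interior
  double ml_close, ml_branch, ml_unpaired;
  double rt;
};

static EnergyPar readPar(const List& par) {
  EnergyPar p;
  NumericMatrix pe = par["pair_energy"];
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      p.pe[a][b] = R_finite(pe(a, b)) ? pe(a, b) : BIG;
  p.stack_bonus = as<double>(par["stack_bonus"]);
  p.h0 = as<double>(par["hairpin_base"]);
  p.h_per = as<double>(par["hairpin_per_nt"]);
  p.b0 = as<double>(par["bulge_base"]);
  p.b_per = as<double>(par["bulge_per_nt"]);
  p.i0 = as<double>(par["interior_base"]);
  p.i_per = as<double>(par["interior_per_nt"]);
  p.ml_close = as<double>(par["multiloop_close"]);
  p.ml_branch = as<double>(par["multiloop_branch"]);
  p.ml_unpaired = as<double>(par["multiloop_unpaired"]);
  p.rt = as<double>(par["rt"]);
  return p;
}

static inline bool canPair(const std::vector<int>& s, const EnergyPar& p,
                           int i, int j) {
  if (j - i <= 3) return false;
  if (s[i] < 0 || s[j] < 0) return false;
  return p.pe[s[i]][s[j]] < BIG / 2;
}

static inline double pairE(const std::vector<int>& s, const EnergyPar& p,
                           int i, int j) {
  return p.pe[s[i]][s[j]];
}

// energy of the loop closed by (i,j) with a single immediately interior
// pair (k,l): stack / bulge / interior loop
static inline double twoLoopE(const EnergyPar& p, double pe_ij,
                              int i, int j, int k, int l) {
  int g1 = k - i - 1, g2 = j - l - 1;
  if (g1 == 0 && g2 == 0) return pe_ij + p.stack_bonus;
  if (g1 == 0 || g2 == 0) return pe_ij + p.b0 + p.b_per * (g1 + g2);
  return pe_ij + p.i0 + p.i_per * (g1 + g2);
}

// ---------------------------------------------------------------- MFE ----

struct FoldMat {
  int n;
  std::vector<std::vector<double> > V, WM;
};

static void fillFold(const std::vector<int>& s, const EnergyPar& p,
                     FoldMat& F) {
  int n = s.size();
  F.n = n;
  F.V.assign(n, std::vector<double>(n, BIG));
  F.WM.assign(n, std::vector<double>(n, BIG));
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // V(i,j): minimum energy given (i,j) paired
      if (canPair(s, p, i, j)) {
        double pe_ij = pairE(s, p, i, j);
        double best = pe_ij + p.h0 + p.h_per * (j - i - 1); // hairpin
        for (int k = i + 1; k < j; ++k) {
          for (int l = k + 4; l < j; ++l) {
            if (F.V[k][l] >= BIG / 2) continue;
            double cand = twoLoopE(p, pe_ij, i, j, k, l) + F.V[k][l];
            if (cand < best) best = cand;
          }
        }
        // multiloop: first interior branch (k,l), remainder has >= 1 branch
        int a = i + 1, b = j - 1;
        for (int k = a; k <= b - 5; ++k) {
          for (int l = k + 4; l <= b - 1; ++l) {
            if (F.V[k][l] >= BIG / 2) continue;
            if (l + 1 > b || F.WM[l + 1][b] >= BIG / 2) continue;
            double cand = pe_ij + p.ml_close + p.ml_unpaired * (k - a) +
              F.V[k][l] + p.ml_branch + F.WM[l + 1][b];
            if (cand < best) best = cand;
          }
        }
        F.V[i][j] = best;
      }
      // WM(i,j): segment inside a multiloop containing >= 1 branch
      double wm = BIG;
      if (i + 1 <= j && F.WM[i + 1][j] < BIG / 2)
        wm = F.WM[i + 1][j] + p.ml_unpaired;
      for (int l = i + 4; l <= j; ++l) {
        if (F.V[i][l] >= BIG / 2) continue;
        double tail;
        if (l == j) tail = 0.0;
        else {
          tail = p.ml_unpaired * (j - l);
          if (F.WM[l + 1][j] < BIG / 2 && F.WM[l + 1][j] < tail)
            tail = F.WM[l + 1][j];
        }
        double cand = F.V[i][l] + p.ml_branch + tail;
        if (cand < wm) wm = cand;
      }
      F.WM[i][j] = wm;
    }
  }
}

static const double EPS = 1e-7;

// deterministic traceback helpers ----------------------------------------

static void traceV(const std::vector<int>& s, const EnergyPar& p,
                   const FoldMat& F, int i, int j, std::vector<int>& pt);

static void traceWM(const std::vector<int>& s, const EnergyPar& p,
                    const FoldMat& F, int i, int j, std::vector<int>& pt) {
  // mirror the WM recursion; prefer "i unpaired" first, then 5'-most branch
  if (i + 1 <= j && F.WM[i + 1][j] < BIG / 2 &&
      std::fabs(F.WM[i][j] - (F.WM[i + 1][j] + p.ml_unpaired)) < EPS) {
    traceWM(s, p, F, i + 1, j, pt);
    return;
  }
  for (int l = i + 4; l <= j; ++l) {
    if (F.V[i][l] >= BIG / 2) continue;
    if (l == j) {
      if (std::fabs(F.WM[i][j] - (F.V[i][l] + p.ml_branch)) < EPS) {
        traceV(s, p, F, i, l, pt);
        return;
      }
    } else {
      double allUn = p.ml_unpaired * (j - l);
      if (std::fabs(F.WM[i][j] - (F.V[i][l] + p.ml_branch + allUn)) < EPS) {
        traceV(s, p, F, i, l, pt);
        return;
      }
      if (F.WM[l + 1][j] < BIG / 2 &&
          std::fabs(F.WM[i][j] -
                    (F.V[i][l] + p.ml_branch + F.WM[l + 1][j])) < EPS) {
        traceV(s, p, F, i, l, pt);
        traceWM(s, p, F, l + 1, j, pt);
        return;
      }
    }
  }
  stop("internal traceback failure (WM)");
}

static void traceV(const std::vector<int>& s, const EnergyPar& p,
                   const FoldMat& F, int i, int j, std::vector<int>& pt) {
  pt[i] = j; pt[j] = i;
  double pe_ij = pairE(s, p, i, j);
  double target = F.V[i][j];
  if (std::fabs(target - (pe_ij + p.h0 + p.h_per * (j - i - 1))) < EPS)
    return; // hairpin
  for (int k = i + 1; k < j; ++k)
    for (int l = k + 4; l < j; ++l) {
      if (F.V[k][l] >= BIG / 2) continue;
      if (std::fabs(target - (twoLoopE(p, pe_ij, i, j, k, l) +
                              F.V[k][l])) < EPS) {
        traceV(s, p, F, k, l, pt);
        return;
      }
    }
  int a = i + 1, b = j - 1;
  for (int k = a; k <= b - 5; ++k)
    for (int l = k + 4; l <= b - 1; ++l) {
      if (F.V[k][l] >= BIG / 2) continue;
      if (l + 1 > b || F.WM[l + 1][b] >= BIG / 2) continue;
      double cand = pe_ij + p.ml_close + p.ml_unpaired * (k - a) +
        F.V[k][l] + p.ml_branch + F.WM[l + 1][b];
      if (std::fabs(target - cand) < EPS) {
        traceV(s, p, F, k, l, pt);
        traceWM(s, p, F, l + 1, b, pt);
        return;
      }
    }
  stop("internal traceback failure (V)");
}

// [[Rcpp::export]]
List cpp_fold(IntegerVector code, List par) {
  EnergyPar p = readPar(par);
  std::vector<int> s(code.begin(), code.end());
  int n = s.size();
  FoldMat F;
  fillFold(s, p, F);
  // exterior recursion
  std::vector<double> W(n + 1, 0.0);     // W[j+1]: best over prefix [0..j]
  for (int j = 0; j < n; ++j) {
    double best = W[j]; // j unpaired
    for (int i = 0; i + 4 <= j; ++i)
      if (F.V[i][j] < BIG / 2 && W[i] + F.V[i][j] < best)
        best = W[i] + F.V[i][j];
    W[j + 1] = best;
  }
  // traceback, preferring unpaired then 5'-most pairs
  std::vector<int> pt(n, -1);
  int j = n - 1;
  while (j >= 0) {
    if (std::fabs(W[j + 1] - W[j]) < EPS) { --j; continue; }
    int found = -1;
    for (int i = 0; i + 4 <= j; ++i)
      if (F.V[i][j] < BIG / 2 &&
          std::fabs(W[j + 1] - (W[i] + F.V[i][j])) < EPS) { found = i; break; }
    if (found < 0) stop("internal traceback failure (exterior)");
    traceV(s, p, F, found, j, pt);
    j = found - 1;
  }
  IntegerVector pairTable(n);
  for (int q = 0; q < n; ++q) pairTable[q] = pt[q] >= 0 ? pt[q] + 1 : 0;
  return List::create(_["pair_table"] = pairTable, _["energy"] = W[n]);
}

// --------------------------------------------------- partition function --

static double partitionQ(const std::vector<int>& s, const EnergyPar& p,
                         const std::vector<bool>& forceUnpaired) {
  int n = s.size();
  std::vector<std::vector<double> > Qb(n, std::vector<double>(n, 0.0));
  std::vector<std::vector<double> > QM(n, std::vector<double>(n, 0.0));
  double rt = p.rt;
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      bool ok = canPair(s, p, i, j) && !forceUnpaired[i] && !forceUnpaired[j];
      if (ok) {
        double pe_ij = pairE(s, p, i, j);
        double q = std::exp(-(pe_ij + p.h0 + p.h_per * (j - i - 1)) / rt);
        for (int k = i + 1; k < j; ++k)
          for (int l = k + 4; l < j; ++l) {
            if (Qb[k][l] == 0.0) continue;
            q += std::exp(-twoLoopE(p, pe_ij, i, j, k, l) / rt) * Qb[k][l];
          }
        int a = i + 1, b = j - 1;
        for (int k = a; k <= b - 5; ++k)
          for (int l = k + 4; l <= b - 1; ++l) {
            if (Qb[k][l] == 0.0 || QM[l + 1][b] == 0.0) continue;
            q += std::exp(-(pe_ij + p.ml_close + p.ml_unpaired * (k - a) +
                            p.ml_branch) / rt) * Qb[k][l] * QM[l + 1][b];
          }
        Qb[i][j] = q;
      }
      // QM: >= 1 branch, decomposed uniquely by the first branch
      double qm = 0.0;
      if (i + 1 <= j)
        qm += std::exp(-p.ml_unpaired / rt) * QM[i + 1][j];
      for (int l = i + 4; l <= j; ++l) {
        if (Qb[i][l] == 0.0) continue;
        double tail = std::exp(-p.ml_unpaired * (j - l) / rt); // rest unpaired
        if (l + 1 <= j) tail += QM[l + 1][j];
        else tail = 1.0;
        qm += Qb[i][l] * std::exp(-p.ml_branch / rt) * tail;
      }
      QM[i][j] = qm;
    }
  }
  // exterior: unpaired bases contribute no energy
  std::vector<double> Q(n + 1, 1.0);
  for (int j = 0; j < n; ++j) {
    double q = Q[j];
    for (int i = 0; i + 4 <= j; ++i)
      if (Qb[i][j] != 0.0) q += Q[i] * Qb[i][j];
    Q[j + 1] = q;
  }
  return Q[n];
}

// [[Rcpp::export]]
double cpp_partition(IntegerVector code, List par) {
  EnergyPar p = readPar(par);
  std::vector<int> s(code.begin(), code.end());
  std::vector<bool> fu(s.size(), false);
  return partitionQ(s, p, fu);
}

// probability that all of [i0..k0] (1-based, inclusive) are unpaired
// [[Rcpp::export]]
double cpp_unpaired_prob(IntegerVector code, List par, int i0, int k0) {
  EnergyPar p = readPar(par);
  std::vector<int> s(code.begin(), code.end());
  int n = s.size();
  if (i0 < 1 || k0 > n || i0 > k0) stop("invalid interval");
  std::vector<bool> fu(n, false);
  double Z = partitionQ(s, p, fu);
  for (int q = i0 - 1; q <= k0 - 1; ++q) fu[q] = true;
  double Zu = partitionQ(s, p, fu);
  return Zu / Z;
}

// Pu for every interval with span <= maxspan; entry (i,k) 1-based, NA outside
// [[Rcpp::export]]
NumericMatrix cpp_pu_matrix(IntegerVector code, List par, int maxspan) {
  EnergyPar p = readPar(par);
  std::vector<int> s(code.begin(), code.end());
  int n = s.size();
  NumericMatrix out(n, n);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<bool> fu(n, false);
  double Z = partitionQ(s, p, fu);
  for (int i = 0; i < n; ++i) {
    for (int k = i; k < n && k - i + 1 <= maxspan; ++k) {
      std::vector<bool> m(n, false);
      for (int q = i; q <= k; ++q) m[q] = true;
      out(i, k) = partitionQ(s, p, m) / Z;
    }
  }
  return out;
}

// -------------------------------------------------------- hybrid duplex --

// Minimal intermolecular duplex energies anchored at the pair
// (i0 of seq1, l0 of seq2); D(a,b) = minimal duplex energy (no initiation
// term) whose first pair is (i0,l0) and last pair is (a,b), with seq1
// consumed 5'->3' and seq2 3'->5' (antiparallel).  Unpaired stretches
// between consecutive pairs are scored as stacks/bulges/interior loops.
// [[Rcpp::export]]
NumericMatrix cpp_hybrid_anchor(IntegerVector code1, IntegerVector code2,
                                List par, int i0, int l0, int maxInterval) {
  EnergyPar p = readPar(par);
  std::vector<int> s1(code1.begin(), code1.end());
  std::vector<int> s2(code2.begin(), code2.end());
  int n1 = s1.size(), n2 = s2.size();
  --i0; --l0; // to 0-based
  NumericMatrix D(n1, n2);
  std::fill(D.begin(), D.end(), NA_REAL);
  if (i0 < 0 || i0 >= n1 || l0 < 0 || l0 >= n2) stop("anchor out of range");
  if (s1[i0] < 0 || s2[l0] < 0 || p.pe[s1[i0]][s2[l0]] >= BIG / 2)
    return D; // anchor cannot pair
  int aMax = std::min(n1 - 1, i0 + maxInterval - 1);
  int bMin = std::max(0, l0 - maxInterval + 1);
  D(i0, l0) = p.pe[s1[i0]][s2[l0]];
  for (int a = i0; a <= aMax; ++a) {
    for (int b = l0; b >= bMin; --b) {
      if (a == i0 && b == l0) continue;
      if (s1[a] < 0 || s2[b] < 0) continue;
      double pe_ab = p.pe[s1[a]][s2[b]];
      if (pe_ab >= BIG / 2) continue;
      double best = BIG;
      for (int ap = i0; ap < a; ++ap) {
        for (int bp = l0; bp > b; --bp) {
          if (!R_finite(D(ap, bp))) continue;
          int g1 = a - ap - 1, g2 = bp - b - 1;
          double loop;
          if (g1 == 0 && g2 == 0) loop = p.stack_bonus;
          else if (g1 == 0 || g2 == 0) loop = p.b0 + p.b_per * (g1 + g2);
          else loop = p.i0 + p.i_per * (g1 + g2);
          double cand = D(ap, bp) + loop + pe_ab;
          if (cand < best) best = cand;
        }
      }
      if (best < BIG / 2) D(a, b) = best;
    }
  }
  return D;
}
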