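// Dynamic programming engine for Plan 7 profile HMMs.
//
// State layout per model position p (1-based): Match M_p, Insertion I_p,
// Deletion D_p.  Begin / End plus, in local mode, DeletionIn / DeletionOut.
// DeletionIn/DeletionOut are parameterized by a shared (continue, exit) pair
// and folded into effective entry[p] / exit[p] vectors: entering at M_p via
// DeletionIn skips positions 1..p-1, leaving at M_p via DeletionOut skips
// positions p+1..n.
//
// Transition matrix columns: 0 MM, 1 MI, 2 MD, 3 MDO, 4 IM, 5 II, 6 DM, 7 DD.
// Begin vector: 0 B->M1, 1 B->D1, 2 B->DeletionIn.
// DIO vector: 0 dinContinue, 1 dinExit, 2 doutContinue, 3 doutExit.
//
// Forward/backward values are kept in linear space with per-time scale
// factors (row tau = 0 is unscaled).  Residue codes: 0..3 = A,C,G,T;
// -1 = ambiguous (emits with probability 1); -2 = masked (for hit scanning).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG_BIG = -1e30;

struct P7 {
  int n;
  NumericMatrix ME;   // n x 4 match emissions
  NumericVector IE;   // 4 insert emissions
  NumericMatrix TR;   // n x 8 transitions
  NumericVector BG;   // 3 begin
  NumericVector DIO;  // 4 deletion-in/out
  bool local;

  P7(List m)
    : n(as<int>(m["n"])),
      ME(as<NumericMatrix>(m["ME"])),
      IE(as<NumericVector>(m["IE"])),
      TR(as<NumericMatrix>(m["TR"])),
      BG(as<NumericVector>(m["BG"])),
      DIO(as<NumericVector>(m["DIO"])),
      local(as<bool>(m["local"])) {}

  inline double eM(int p, int d) const {  // p 1-based
    if (d < 0) return d == -1 ? 1.0 : 0.0;
    return ME(p - 1, d);
  }
  inline double eI(int d) const {
    if (d < 0) return d == -1 ? 1.0 : 0.0;
    return IE[d];
  }
  // effective silent entry probability Begin ~> M_p
  inline double entry(int p) const {
    if (p == 1) return BG[0];
    if (!local) return 0.0;
    return BG[2] * std::pow(DIO[0], p - 2) * DIO[1];
  }
  // effective silent exit probability M_p ~> End
  inline double exitv(int p) const {
    if (p == n) {
      double e = TR(n - 1, 0) + TR(n - 1, 2);
      if (local) e += TR(n - 1, 3) * DIO[3];
      return e;
    }
    if (!local) return 0.0;
    return TR(p - 1, 3) * std::pow(DIO[2], n - p) * DIO[3];
  }
};

// silent tau = 0 deletion chain: B -> D_1 -> D_2 ...
static void alpha_row0(const P7& m, NumericMatrix& aD, NumericMatrix& aM,
                       NumericMatrix& aI) {
  for (int p = 0; p < m.n; ++p) { aM(0, p) = 0.0; aI(0, p) = 0.0; }
  aD(0, 0) = m.BG[1];
  for (int p = 2; p <= m.n; ++p)
    aD(0, p - 1) = aD(0, p - 2) * m.TR(p - 2, 7);
}

// one forward time step tau (>=1), writing row tau from row tau-1; returns
// unscaled row sum.  Caller scales.
static double alpha_step(const P7& m, int tau, int d, NumericMatrix& aM,
                         NumericMatrix& aI, NumericMatrix& aD) {
  const int n = m.n;
  for (int p = 1; p <= n; ++p) {
    double fm = 0.0;
    if (p > 1)
      fm = aM(tau - 1, p - 2) * m.TR(p - 2, 0) +
           aI(tau - 1, p - 2) * m.TR(p - 2, 4) +
           aD(tau - 1, p - 2) * m.TR(p - 2, 6);
    if (tau == 1) fm += m.entry(p);
    aM(tau, p - 1) = m.eM(p, d) * fm;
    aI(tau, p - 1) = m.eI(d) * (aM(tau - 1, p - 1) * m.TR(p - 1, 1) +
                                aI(tau - 1, p - 1) * m.TR(p - 1, 5));
  }
  aD(tau, 0) = 0.0;
  for (int p = 2; p <= n; ++p)
    aD(tau, p - 1) = aM(tau, p - 2) * m.TR(p - 2, 2) +
                     aD(tau, p - 2) * m.TR(p - 2, 7);
  double s = 0.0;
  for (int p = 0; p < n; ++p) s += aM(tau, p) + aI(tau, p) + aD(tau, p);
  return s;
}

// scaled terminal likelihood from the last forward row
static double alpha_terminal(const P7& m, int K, const NumericMatrix& aM,
                             const NumericMatrix& aI, const NumericMatrix& aD) {
  double L = 0.0;
  for (int p = 1; p <= m.n; ++p) L += aM(K, p - 1) * m.exitv(p);
  L += aI(K, m.n - 1) * m.TR(m.n - 1, 4);
  L += aD(K, m.n - 1) * m.TR(m.n - 1, 6);
  return L;
}

// [[Rcpp::export]]
List cpp_forward(List model, IntegerVector seq) {
  P7 m(model);
  const int K = seq.size(), n = m.n;
  NumericMatrix aM(K + 1, n), aI(K + 1, n), aD(K + 1, n);
  NumericVector scales(K + 1);
  scales[0] = 1.0;
  alpha_row0(m, aD, aM, aI);
  double logscale = 0.0;
  for (int tau = 1; tau <= K; ++tau) {
    double s = alpha_step(m, tau, seq[tau - 1], aM, aI, aD);
    if (!(s > 0.0))
      stop("sequence has zero probability under the model (position %d)", tau);
    scales[tau] = s;
    logscale += std::log(s);
    for (int p = 0; p < n; ++p) {
      aM(tau, p) /= s; aI(tau, p) /= s; aD(tau, p) /= s;
    }
  }
  double Lhat = alpha_terminal(m, K, aM, aI, aD);
  double ll = (Lhat > 0.0) ? std::log(Lhat) + logscale : R_NegInf;
  return List::create(_["M"] = aM, _["I"] = aI, _["D"] = aD,
                      _["scales"] = scales, _["Lhat"] = Lhat,
                      _["loglik"] = ll);
}

// backward fill-in, scaled by the forward scale factors
static void beta_fill(const P7& m, const IntegerVector& seq,
                      const NumericVector& scales, NumericMatrix& bM,
                      NumericMatrix& bI, NumericMatrix& bD) {
  const int K = seq.size(), n = m.n;
  bD(K, n - 1) = m.TR(n - 1, 6);
  for (int p = n - 1; p >= 1; --p)
    bD(K, p - 1) = m.TR(p - 1, 7) * bD(K, p);
  for (int p = 1; p <= n; ++p) {
    // exit directly (DeletionOut / final position) or through the trailing
    // silent deletion chain
    bM(K, p - 1) = m.exitv(p) +
        ((p < n) ? m.TR(p - 1, 2) * bD(K, p) : 0.0);
    bI(K, p - 1) = (p == n) ? m.TR(n - 1, 4) : 0.0;
  }
  for (int tau = K - 1; tau >= 0; --tau) {
    const int d = seq[tau];           // residue emitted at time tau + 1
    const double c = scales[tau + 1];
    bD(tau, n - 1) = 0.0;
    for (int p = n - 1; p >= 1; --p)
      bD(tau, p - 1) = m.TR(p - 1, 6) * m.eM(p + 1, d) * bM(tau + 1, p) / c +
                       m.TR(p - 1, 7) * bD(tau, p);
    for (int p = 1; p <= n; ++p) {
      if (p < n) {
        bM(tau, p - 1) =
            m.TR(p - 1, 0) * m.eM(p + 1, d) * bM(tau + 1, p) / c +
            m.TR(p - 1, 1) * m.eI(d) * bI(tau + 1, p - 1) / c +
            m.TR(p - 1, 2) * bD(tau, p);
        bI(tau, p - 1) =
            m.TR(p - 1, 4) * m.eM(p + 1, d) * bM(tau + 1, p) / c +
            m.TR(p - 1, 5) * m.eI(d) * bI(tau + 1, p - 1) / c;
      } else {
        bM(tau, p - 1) = m.TR(n - 1, 1) * m.eI(d) * bI(tau + 1, n - 1) / c;
        bI(tau, p - 1) = m.TR(n - 1, 5) * m.eI(d) * bI(tau + 1, n - 1) / c;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_backward(List model, IntegerVector seq, NumericVector scales) {
  P7 m(model);
  const int K = seq.size(), n = m.n;
  NumericMatrix bM(K + 1, n), bI(K + 1, n), bD(K + 1, n);
  beta_fill(m, seq, scales, bM, bI, bD);
  double Lhat = m.BG[1] * bD(0, 0);
  if (K >= 1)
    for (int p = 1; p <= n; ++p)
      Lhat += m.entry(p) * m.eM(p, seq[0]) * bM(1, p - 1) / scales[1];
  return List::create(_["M"] = bM, _["I"] = bI, _["D"] = bD,
                      _["Lhat"] = Lhat);
}

// forward log-likelihood only (two-row recursion, no stored matrices)
static double loglik_one(const P7& m, const IntegerVector& seq) {
  const int K = seq.size(), n = m.n;
  std::vector<double> M0(n, 0.0), I0(n, 0.0), D0(n, 0.0),
      M1(n), I1(n), D1(n);
  D0[0] = m.BG[1];
  for (int p = 2; p <= n; ++p) D0[p - 1] = D0[p - 2] * m.TR(p - 2, 7);
  double logscale = 0.0;
  for (int tau = 1; tau <= K; ++tau) {
    const int d = seq[tau - 1];
    for (int p = 1; p <= n; ++p) {
      double fm = 0.0;
      if (p > 1)
        fm = M0[p - 2] * m.TR(p - 2, 0) + I0[p - 2] * m.TR(p - 2, 4) +
             D0[p - 2] * m.TR(p - 2, 6);
      if (tau == 1) fm += m.entry(p);
      M1[p - 1] = m.eM(p, d) * fm;
      I1[p - 1] = m.eI(d) * (M0[p - 1] * m.TR(p - 1, 1) +
                             I0[p - 1] * m.TR(p - 1, 5));
    }
    D1[0] = 0.0;
    for (int p = 2; p <= n; ++p)
      D1[p - 1] = M1[p - 2] * m.TR(p - 2, 2) + D1[p - 2] * m.TR(p - 2, 7);
    double s = 0.0;
    for (int p = 0; p < n; ++p) s += M1[p] + I1[p] + D1[p];
    if (!(s > 0.0)) return R_NegInf;
    logscale += std::log(s);
    for (int p = 0; p < n; ++p) {
      M0[p] = M1[p] / s; I0[p] = I1[p] / s; D0[p] = D1[p] / s;
    }
  }
  double L = 0.0;
  for (int p = 1; p <= m.n; ++p) L += M0[p - 1] * m.exitv(p);
  L += I0[n - 1] * m.TR(n - 1, 4) + D0[n - 1] * m.TR(n - 1, 6);
  return (L > 0.0) ? std::log(L) + logscale : R_NegInf;
}

// [[Rcpp::export]]
NumericVector cpp_loglik(List model, List seqs) {
  P7 m(model);
  const int S = seqs.size();
  NumericVector out(S);
  for (int s = 0; s < S; ++s) out[s] = loglik_one(m, as<IntegerVector>(seqs[s]));
  return out;
}

// Recompute forward columns (state rows, in the state-major view) for model
// positions >= fromPos, reusing earlier columns and the stored scale factors.
// [[Rcpp::export]]
List cpp_forward_rows(List model, IntegerVector seq, List fwd, int fromPos) {
  P7 m(model);
  const int K = seq.size(), n = m.n;
  NumericMatrix aM = clone(as<NumericMatrix>(fwd["M"]));
  NumericMatrix aI = clone(as<NumericMatrix>(fwd["I"]));
  NumericMatrix aD = clone(as<NumericMatrix>(fwd["D"]));
  NumericVector scales = as<NumericVector>(fwd["scales"]);
  if (fromPos < 1 || fromPos > n) stop("fromPos outside the model");
  for (int p = fromPos; p <= n; ++p) {
    if (p == 1) aD(0, 0) = m.BG[1];
    else aD(0, p - 1) = aD(0, p - 2) * m.TR(p - 2, 7);
    for (int tau = 1; tau <= K; ++tau) {
      const int d = seq[tau - 1];
      const double c = scales[tau];
      double fm = 0.0;
      if (p > 1)
        fm = aM(tau - 1, p - 2) * m.TR(p - 2, 0) +
             aI(tau - 1, p - 2) * m.TR(p - 2, 4) +
             aD(tau - 1, p - 2) * m.TR(p - 2, 6);
      if (tau == 1) fm += m.entry(p);
      aM(tau, p - 1) = m.eM(p, d) * fm / c;
      aI(tau, p - 1) = m.eI(d) * (aM(tau - 1, p - 1) * m.TR(p - 1, 1) +
                                  aI(tau - 1, p - 1) * m.TR(p - 1, 5)) / c;
      if (p == 1) aD(tau, 0) = 0.0;
      else aD(tau, p - 1) = aM(tau, p - 2) * m.TR(p - 2, 2) +
                            aD(tau, p - 2) * m.TR(p - 2, 7);
    }
  }
  double Lhat = alpha_terminal(m, K, aM, aI, aD);
  double logscale = 0.0;
  for (int tau = 1; tau <= K; ++tau) logscale += std::log(scales[tau]);
  double ll = (Lhat > 0.0) ? std::log(Lhat) + logscale : R_NegInf;
  return List::create(_["M"] = aM, _["I"] = aI, _["D"] = aD,
                      _["scales"] = scales, _["Lhat"] = Lhat,
                      _["loglik"] = ll);
}

struct CountAcc {
  NumericMatrix cME, cTR, perIns, perDel;
  NumericVector cIE, cBG, cDIO, ll;
  CountAcc(int n, int S)
    : cME(n, 4), cTR(n, 8), perIns(S, n), perDel(S, n),
      cIE(4), cBG(3), cDIO(4), ll(S) {}
};

// accumulate full expected counts for one sequence given alpha/beta
static void accumulate_counts(const P7& m, const IntegerVector& seq,
                              const NumericMatrix& aM, const NumericMatrix& aI,
                              const NumericMatrix& aD, const NumericMatrix& bM,
                              const NumericMatrix& bI, const NumericMatrix& bD,
                              const NumericVector& scales, double Lhat,
                              int s, CountAcc& A) {
  const int K = seq.size(), n = m.n;
  const double invL = 1.0 / Lhat;
  for (int tau = 1; tau <= K; ++tau) {
    const int d = seq[tau - 1];
    for (int p = 0; p < n; ++p) {
      const double pM = aM(tau, p) * bM(tau, p) * invL;
      const double pI = aI(tau, p) * bI(tau, p) * invL;
      if (d >= 0) { A.cME(p, d) += pM; A.cIE[d] += pI; }
      A.perIns(s, p) += pI;
    }
  }
  for (int tau = 0; tau <= K; ++tau)
    for (int p = 0; p < n; ++p)
      A.perDel(s, p) += aD(tau, p) * bD(tau, p) * invL;
  for (int tau = 0; tau < K; ++tau) {
    const int d = seq[tau];
    const double c = scales[tau + 1];
    for (int p = 1; p <= n; ++p) {
      if (p < n) {
        const double em = m.eM(p + 1, d) * bM(tau + 1, p) / c;
        A.cTR(p - 1, 0) += aM(tau, p - 1) * m.TR(p - 1, 0) * em * invL;
        A.cTR(p - 1, 4) += aI(tau, p - 1) * m.TR(p - 1, 4) * em * invL;
        A.cTR(p - 1, 6) += aD(tau, p - 1) * m.TR(p - 1, 6) * em * invL;
      }
      const double ei = m.eI(d) * bI(tau + 1, p - 1) / c;
      A.cTR(p - 1, 1) += aM(tau, p - 1) * m.TR(p - 1, 1) * ei * invL;
      A.cTR(p - 1, 5) += aI(tau, p - 1) * m.TR(p - 1, 5) * ei * invL;
    }
  }
  for (int tau = 0; tau <= K; ++tau)
    for (int p = 1; p < n; ++p) {
      A.cTR(p - 1, 2) += aM(tau, p - 1) * m.TR(p - 1, 2) * bD(tau, p) * invL;
      A.cTR(p - 1, 7) += aD(tau, p - 1) * m.TR(p - 1, 7) * bD(tau, p) * invL;
    }
  // terminal transitions at tau = K
  for (int p = 1; p < n; ++p) {
    if (m.local) {
      const double w = aM(K, p - 1) * m.exitv(p) * invL;
      A.cTR(p - 1, 3) += w;
      A.cDIO[2] += w * (n - p);
      A.cDIO[3] += w;
    }
  }
  A.cTR(n - 1, 0) += aM(K, n - 1) * m.TR(n - 1, 0) * invL;
  A.cTR(n - 1, 2) += aM(K, n - 1) * m.TR(n - 1, 2) * invL;
  if (m.local) {
    const double w = aM(K, n - 1) * m.TR(n - 1, 3) * m.DIO[3] * invL;
    A.cTR(n - 1, 3) += w;
    A.cDIO[3] += w;
  }
  A.cTR(n - 1, 4) += aI(K, n - 1) * m.TR(n - 1, 4) * invL;
  A.cTR(n - 1, 6) += aD(K, n - 1) * m.TR(n - 1, 6) * invL;
  // entry usage (first emission)
  if (K >= 1) {
    const int d0 = seq[0];
    A.cBG[0] += m.entry(1) * m.eM(1, d0) * bM(1, 0) / scales[1] * invL;
    for (int p = 2; p <= n; ++p) {
      const double g = m.entry(p) * m.eM(p, d0) * bM(1, p - 1) / scales[1] * invL;
      A.cBG[2] += g;
      A.cDIO[0] += g * (p - 2);
      A.cDIO[1] += g;
    }
  }
  A.cBG[1] += m.BG[1] * bD(0, 0) * invL;
}

// [[Rcpp::export]]
List cpp_counts(List model, List seqs) {
  P7 m(model);
  const int S = seqs.size(), n = m.n;
  CountAcc A(n, S);
  for (int s = 0; s < S; ++s) {
    IntegerVector seq = as<IntegerVector>(seqs[s]);
    const int K = seq.size();
    NumericMatrix aM(K + 1, n), aI(K + 1, n), aD(K + 1, n);
    NumericMatrix bM(K + 1, n), bI(K + 1, n), bD(K + 1, n);
    NumericVector scales(K + 1);
    scales[0] = 1.0;
    alpha_row0(m, aD, aM, aI);
    double logscale = 0.0;
    for (int tau = 1; tau <= K; ++tau) {
      double sc = alpha_step(m, tau, seq[tau - 1], aM, aI, aD);
      if (!(sc > 0.0))
        stop("sequence %d has zero probability under the model", s + 1);
      scales[tau] = sc;
      logscale += std::log(sc);
      for (int p = 0; p < n; ++p) {
        aM(tau, p) /= sc; aI(tau, p) /= sc; aD(tau, p) /= sc;
      }
    }
    double Lhat = alpha_terminal(m, K, aM, aI, aD);
    if (!(Lhat > 0.0))
      stop("sequence %d has zero probability under the model", s + 1);
    A.ll[s] = std::log(Lhat) + logscale;
    beta_fill(m, seq, scales, bM, bI, bD);
    accumulate_counts(m, seq, aM, aI, aD, bM, bI, bD, scales, Lhat, s, A);
  }
  return List::create(_["ME"] = A.cME, _["IE"] = A.cIE, _["TR"] = A.cTR,
                      _["BG"] = A.cBG, _["DIO"] = A.cDIO,
                      _["perSeqIns"] = A.perIns, _["perSeqDel"] = A.perDel,
                      _["loglik"] = A.ll);
}

// Conditional Baum-Welch sweep over a column-major (state-major) layout:
// each position group is updated in turn using the current values of all
// other parameters; alpha columns before the active position are reused,
// beta columns after it stay valid until their parameters change.
// ---------------------------------------------------------------------------

struct DynModel {
  std::vector<std::array<double, 4>> ME;
  std::vector<std::array<double, 8>> TR;
  std::array<double, 4> IE;
  std::array<double, 3> BG;
  std::array<double, 4> DIO;
  bool local;
  int n() const { return (int)ME.size(); }
  double eM(int p, int d) const {  // 0-based position
    if (d < 0) return d == -1 ? 1.0 : 0.0;
    return ME[p][d];
  }
  double eI(int d) const {
    if (d < 0) return d == -1 ? 1.0 : 0.0;
    return IE[d];
  }
  double entry(int p) const {
    if (p == 0) return BG[0];
    if (!local) return 0.0;
    return BG[2] * std::pow(DIO[0], p - 1) * DIO[1];
  }
  double exitv(int p) const {
    const int last = n() - 1;
    if (p == last) {
      double e = TR[last][0] + TR[last][2];
      if (local) e += TR[last][3] * DIO[3];
      return e;
    }
    if (!local) return 0.0;
    return TR[p][3] * std::pow(DIO[2], last - p) * DIO[3];
  }
};

struct SeqDP {
  std::vector<int> code;
  std::vector<double> scales;                  // length K+1, fixed per sweep
  std::vector<std::vector<double>> aM, aI, aD; // [position][tau]
  std::vector<std::vector<double>> bM, bI, bD;
  int K() const { return (int)code.size(); }
};

// recompute one scaled forward column from the previous column
static void dyn_alpha_col(const DynModel& m, SeqDP& s, int p) {
  const int K = s.K();
  s.aM[p][0] = 0.0; s.aI[p][0] = 0.0;
  s.aD[p][0] = (p == 0) ? m.BG[1] : s.aD[p - 1][0] * m.TR[p - 1][7];
  for (int tau = 1; tau <= K; ++tau) {
    const int d = s.code[tau - 1];
    const double c = s.scales[tau];
    double fm = 0.0;
    if (p > 0)
      fm = s.aM[p - 1][tau - 1] * m.TR[p - 1][0] +
           s.aI[p - 1][tau - 1] * m.TR[p - 1][4] +
           s.aD[p - 1][tau - 1] * m.TR[p - 1][6];
    if (tau == 1) fm += m.entry(p);
    s.aM[p][tau] = m.eM(p, d) * fm / c;
    s.aI[p][tau] = m.eI(d) * (s.aM[p][tau - 1] * m.TR[p][1] +
                              s.aI[p][tau - 1] * m.TR[p][5]) / c;
    s.aD[p][tau] = (p == 0) ? 0.0
        : s.aM[p - 1][tau] * m.TR[p - 1][2] +
          s.aD[p - 1][tau] * m.TR[p - 1][7];
  }
}

// fill one scaled backward column from the next column (or the terminal
// conditions when p is the last position)
static void dyn_beta_col(const DynModel& m, SeqDP& s, int p) {
  const int K = s.K(), last = m.n() - 1;
  if (p == last) {
    s.bD[p][K] = m.TR[last][6];
    s.bM[p][K] = m.exitv(p);
    s.bI[p][K] = m.TR[last][4];
  } else {
    s.bD[p][K] = m.TR[p][7] * s.bD[p + 1][K];
    s.bM[p][K] = m.exitv(p) + m.TR[p][2] * s.bD[p + 1][K];
    s.bI[p][K] = 0.0;
  }
  for (int tau = K - 1; tau >= 0; --tau) {
    const int d = s.code[tau];
    const double c = s.scales[tau + 1];
    if (p < last) {
      const double em = m.eM(p + 1, d) * s.bM[p + 1][tau + 1] / c;
      s.bD[p][tau] = m.TR[p][6] * em + m.TR[p][7] * s.bD[p + 1][tau];
      s.bM[p][tau] = m.TR[p][0] * em +
                     m.TR[p][1] * m.eI(d) * s.bI[p][tau + 1] / c +
                     m.TR[p][2] * s.bD[p + 1][tau];
      s.bI[p][tau] = m.TR[p][4] * em +
                     m.TR[p][5] * m.eI(d) * s.bI[p][tau + 1] / c;
    } else {
      s.bD[p][tau] = 0.0;
      s.bM[p][tau] = m.TR[last][1] * m.eI(d) * s.bI[p][tau + 1] / c;
      s.bI[p][tau] = m.TR[last][5] * m.eI(d) * s.bI[p][tau + 1] / c;
    }
  }
}

static void dyn_beta_all(const DynModel& m, SeqDP& s) {
  for (int p = m.n() - 1; p >= 0; --p) dyn_beta_col(m, s, p);
}

static double dyn_terminal(const DynModel& m, const SeqDP& s) {
  const int n = m.n(), K = s.K();
  double L = 0.0;
  for (int p = 0; p < n; ++p) L += s.aM[p][K] * m.exitv(p);
  L += s.aI[n - 1][K] * m.TR[n - 1][4] + s.aD[n - 1][K] * m.TR[n - 1][6];
  return L;
}

// scaled likelihood via the transition cut between positions p-1 and p:
// valid mid-sweep because alpha columns < p carry already-updated
// parameters while beta columns >= p carry not-yet-updated ones.
static double dyn_boundary_L(const DynModel& m, const SeqDP& s, int p) {
  const int K = s.K(), n = m.n();
  double L = 0.0;
  if (K >= 1)
    for (int q = p; q < n; ++q)
      L += m.entry(q) * m.eM(q, s.code[0]) * s.bM[q][1] / s.scales[1];
  if (p == 0) return L + m.BG[1] * s.bD[0][0];
  for (int tau = 0; tau < K; ++tau) {
    const int d = s.code[tau];
    const double c = s.scales[tau + 1];
    const double em = m.eM(p, d) * s.bM[p][tau + 1] / c;
    L += s.aM[p - 1][tau] * m.TR[p - 1][0] * em;
    L += s.aI[p - 1][tau] * m.TR[p - 1][4] * em;
    L += s.aD[p - 1][tau] * m.TR[p - 1][6] * em;
  }
  for (int tau = 0; tau <= K; ++tau) {
    L += s.aM[p - 1][tau] * m.TR[p - 1][2] * s.bD[p][tau];
    L += s.aD[p - 1][tau] * m.TR[p - 1][7] * s.bD[p][tau];
  }
  for (int j = 0; j < p; ++j) L += s.aM[j][K] * m.exitv(j);
  return L;
}

// two-row forward log-likelihood for the dynamic model
static double dyn_loglik(const DynModel& m, const std::vector<int>& code) {
  const int K = (int)code.size(), n = m.n();
  std::vector<double> M0(n, 0.0), I0(n, 0.0), D0(n, 0.0), M1(n), I1(n), D1(n);
  D0[0] = m.BG[1];
  for (int p = 1; p < n; ++p) D0[p] = D0[p - 1] * m.TR[p - 1][7];
  double logscale = 0.0;
  for (int tau = 1; tau <= K; ++tau) {
    const int d = code[tau - 1];
    for (int p = 0; p < n; ++p) {
      double fm = 0.0;
      if (p > 0)
        fm = M0[p - 1] * m.TR[p - 1][0] + I0[p - 1] * m.TR[p - 1][4] +
             D0[p - 1] * m.TR[p - 1][6];
      if (tau == 1) fm += m.entry(p);
      M1[p] = m.eM(p, d) * fm;
      I1[p] = m.eI(d) * (M0[p] * m.TR[p][1] + I0[p] * m.TR[p][5]);
      D1[p] = (p == 0) ? 0.0
            : M1[p - 1] * m.TR[p - 1][2] + D1[p - 1] * m.TR[p - 1][7];
    }
    double sc = 0.0;
    for (int p = 0; p < n; ++p) sc += M1[p] + I1[p] + D1[p];
    if (!(sc > 0.0)) return R_NegInf;
    logscale += std::log(sc);
    for (int p = 0; p < n; ++p) {
      M0[p] = M1[p] / sc; I0[p] = I1[p] / sc; D0[p] = D1[p] / sc;
    }
  }
  double L = 0.0;
  for (int p = 0; p < n; ++p) L += M0[p] * m.exitv(p);
  L += I0[n - 1] * m.TR[n - 1][4] + D0[n - 1] * m.TR[n - 1][6];
  return (L > 0.0) ? std::log(L) + logscale : R_NegInf;
}

// (counts + pseudocounts) normalized over idx, floored, renormalized
// pin floored entries and share the remaining mass among the rest until
// every entry respects the floor exactly
static void floor_renorm(std::vector<double>& w, double fl) {
  const int k = (int)w.size();
  for (int guard = 0; guard <= k; ++guard) {
    double lowMass = 0.0, highMass = 0.0;
    int nLow = 0;
    for (int i = 0; i < k; ++i) {
      if (w[i] <= fl) { ++nLow; lowMass += fl; }
      else highMass += w[i];
    }
    if (nLow == k) { for (int i = 0; i < k; ++i) w[i] = 1.0 / k; return; }
    bool again = false;
    const double scale = (1.0 - lowMass) / highMass;
    for (int i = 0; i < k; ++i) {
      if (w[i] <= fl) w[i] = fl;
      else {
        w[i] *= scale;
        if (w[i] < fl) again = true;
      }
    }
    if (!again) return;
  }
}

static void dyn_norm(double* v, const double* counts, const double* prior,
                     const int* idx, int k, double fl) {
  std::vector<double> w(k);
  double ssum = 0.0;
  for (int i = 0; i < k; ++i) { w[i] = counts[idx[i]] + prior[idx[i]]; ssum += w[i]; }
  if (!(ssum > 0.0)) stop("degenerate update: zero counts and zero pseudocounts");
  for (int i = 0; i < k; ++i) w[i] /= ssum;
  floor_renorm(w, fl);
  for (int i = 0; i < k; ++i) v[idx[i]] = w[i];
}

// [[Rcpp::export]]
List cpp_cbw_sweep(List model, List seqs, List priors, double floorv,
                   bool track) {
  DynModel m;
  {
    NumericMatrix ME = as<NumericMatrix>(model["ME"]);
    NumericMatrix TR = as<NumericMatrix>(model["TR"]);
    NumericVector IE = as<NumericVector>(model["IE"]);
    NumericVector BG = as<NumericVector>(model["BG"]);
    NumericVector DIO = as<NumericVector>(model["DIO"]);
    m.local = as<bool>(model["local"]);
    const int n0 = ME.nrow();
    m.ME.resize(n0); m.TR.resize(n0);
    for (int p = 0; p < n0; ++p) {
      for (int a = 0; a < 4; ++a) m.ME[p][a] = ME(p, a);
      for (int j = 0; j < 8; ++j) m.TR[p][j] = TR(p, j);
    }
    for (int a = 0; a < 4; ++a) m.IE[a] = IE[a];
    for (int j = 0; j < 3; ++j) m.BG[j] = BG[j];
    for (int j = 0; j < 4; ++j) m.DIO[j] = DIO[j];
  }
  std::array<double, 4> pME, pIE, pDIO;
  std::array<double, 8> pTR;
  std::array<double, 3> pBG;
  {
    NumericVector a = as<NumericVector>(priors["ME"]);
    NumericVector b = as<NumericVector>(priors["TR"]);
    NumericVector c = as<NumericVector>(priors["IE"]);
    NumericVector d = as<NumericVector>(priors["BG"]);
    NumericVector e = as<NumericVector>(priors["DIO"]);
    for (int i = 0; i < 4; ++i) { pME[i] = a[i]; pIE[i] = c[i]; pDIO[i] = e[i]; }
    for (int i = 0; i < 8; ++i) pTR[i] = b[i];
    for (int i = 0; i < 3; ++i) pBG[i] = d[i];
  }
  const int S = seqs.size();
  std::vector<SeqDP> sd(S);
  NumericVector ll(S);

  // initial forward (time-major, to fix the scale factors), then backward
  for (int s = 0; s < S; ++s) {
    IntegerVector code = as<IntegerVector>(seqs[s]);
    SeqDP& q = sd[s];
    q.code.assign(code.begin(), code.end());
    const int K = q.K(), n = m.n();
    auto alloc = [&](std::vector<std::vector<double>>& v) {
      v.assign(n, std::vector<double>(K + 1, 0.0));
    };
    alloc(q.aM); alloc(q.aI); alloc(q.aD);
    alloc(q.bM); alloc(q.bI); alloc(q.bD);
    q.scales.assign(K + 1, 1.0);
    q.aD[0][0] = m.BG[1];
    for (int p = 1; p < n; ++p) q.aD[p][0] = q.aD[p - 1][0] * m.TR[p - 1][7];
    double logscale = 0.0;
    for (int tau = 1; tau <= K; ++tau) {
      const int d = q.code[tau - 1];
      for (int p = 0; p < n; ++p) {
        double fm = 0.0;
        if (p > 0)
          fm = q.aM[p - 1][tau - 1] * m.TR[p - 1][0] +
               q.aI[p - 1][tau - 1] * m.TR[p - 1][4] +
               q.aD[p - 1][tau - 1] * m.TR[p - 1][6];
        if (tau == 1) fm += m.entry(p);
        q.aM[p][tau] = m.eM(p, d) * fm;
        q.aI[p][tau] = m.eI(d) * (q.aM[p][tau - 1] * m.TR[p][1] +
                                  q.aI[p][tau - 1] * m.TR[p][5]);
        q.aD[p][tau] = (p == 0) ? 0.0
            : q.aM[p - 1][tau] * m.TR[p - 1][2] +
              q.aD[p - 1][tau] * m.TR[p - 1][7];
      }
      double sc = 0.0;
      for (int p = 0; p < n; ++p) sc += q.aM[p][tau] + q.aI[p][tau] + q.aD[p][tau];
      if (!(sc > 0.0))
        stop("sequence %d has zero probability under the model", s + 1);
      q.scales[tau] = sc;
      logscale += std::log(sc);
      for (int p = 0; p < n; ++p) {
        q.aM[p][tau] /= sc; q.aI[p][tau] /= sc; q.aD[p][tau] /= sc;
      }
    }
    double Lh = dyn_terminal(m, q);
    if (!(Lh > 0.0))
      stop("sequence %d has zero probability under the model", s + 1);
    ll[s] = std::log(Lh) + logscale;
    dyn_beta_all(m, q);
  }

  std::vector<std::array<double, 4>> cME(m.n(), std::array<double, 4>{});
  std::vector<std::array<double, 8>> cTR(m.n(), std::array<double, 8>{});
  std::vector<std::vector<double>> insUse(m.n(), std::vector<double>(S, 0.0));
  std::vector<std::vector<double>> delUse = insUse;
  std::vector<double> obj;

  const int idx4[4] = {0, 1, 2, 3};
  const int idxMloc[4] = {0, 1, 2, 3};
  const int idxMglo[3] = {0, 1, 2};
  const int idxI[2] = {4, 5}, idxD[2] = {6, 7};

  auto penalty = [&]() {
    double pen = 0.0;
    for (int p = 0; p < m.n(); ++p) {
      for (int a = 0; a < 4; ++a)
        if (pME[a] > 0.0) pen += pME[a] * std::log(m.ME[p][a]);
      for (int j = 0; j < 8; ++j)
        if (pTR[j] > 0.0) pen += pTR[j] * std::log(m.TR[p][j]);
    }
    for (int a = 0; a < 4; ++a)
      if (pIE[a] > 0.0) pen += pIE[a] * std::log(m.IE[a]);
    for (int j = 0; j < 3; ++j)
      if (pBG[j] > 0.0) pen += pBG[j] * std::log(m.BG[j]);
    for (int j = 0; j < 4; ++j)
      if (pDIO[j] > 0.0) pen += pDIO[j] * std::log(m.DIO[j]);
    return pen;
  };
  auto objective = [&]() {
    double o = penalty();
    for (int s = 0; s < S; ++s) o += dyn_loglik(m, sd[s].code);
    return o;
  };

  int p = 0;
  while (p < m.n()) {
    std::array<double, 4> gE{};
    std::array<double, 8> gT{};
    const int last = m.n() - 1;
    for (int s = 0; s < S; ++s) {
      SeqDP& q = sd[s];
      dyn_alpha_col(m, q, p);                  // current parameters at p
      const double Lh = dyn_boundary_L(m, q, p);
      if (!(Lh > 0.0)) stop("zero mid-sweep likelihood at position %d", p + 1);
      const double invL = 1.0 / Lh;
      const int K = q.K();
      double pIns = 0.0, pDel = 0.0;
      for (int tau = 1; tau <= K; ++tau) {
        const int d = q.code[tau - 1];
        if (d >= 0) gE[d] += q.aM[p][tau] * q.bM[p][tau] * invL;
        pIns += q.aI[p][tau] * q.bI[p][tau] * invL;
      }
      for (int tau = 0; tau <= K; ++tau)
        pDel += q.aD[p][tau] * q.bD[p][tau] * invL;
      insUse[p][s] = pIns;
      delUse[p][s] = pDel;
      for (int tau = 0; tau < K; ++tau) {
        const int d = q.code[tau];
        const double c = q.scales[tau + 1];
        if (p < last) {
          const double em = m.eM(p + 1, d) * q.bM[p + 1][tau + 1] / c;
          gT[0] += q.aM[p][tau] * m.TR[p][0] * em * invL;
          gT[4] += q.aI[p][tau] * m.TR[p][4] * em * invL;
          gT[6] += q.aD[p][tau] * m.TR[p][6] * em * invL;
        }
        const double ei = m.eI(d) * q.bI[p][tau + 1] / c;
        gT[1] += q.aM[p][tau] * m.TR[p][1] * ei * invL;
        gT[5] += q.aI[p][tau] * m.TR[p][5] * ei * invL;
      }
      if (p < last) {
        for (int tau = 0; tau <= K; ++tau) {
          gT[2] += q.aM[p][tau] * m.TR[p][2] * q.bD[p + 1][tau] * invL;
          gT[7] += q.aD[p][tau] * m.TR[p][7] * q.bD[p + 1][tau] * invL;
        }
        if (m.local) gT[3] += q.aM[p][K] * m.exitv(p) * invL;
      } else {
        gT[0] += q.aM[last][K] * m.TR[last][0] * invL;
        gT[2] += q.aM[last][K] * m.TR[last][2] * invL;
        if (m.local) gT[3] += q.aM[last][K] * m.TR[last][3] * m.DIO[3] * invL;
        gT[4] += q.aI[last][K] * m.TR[last][4] * invL;
        gT[6] += q.aD[last][K] * m.TR[last][6] * invL;
      }
    }
    cME[p] = gE;
    cTR[p] = gT;
    dyn_norm(m.ME[p].data(), gE.data(), pME.data(), idx4, 4, floorv);
    if (m.local)
      dyn_norm(m.TR[p].data(), gT.data(), pTR.data(), idxMloc, 4, floorv);
    else
      dyn_norm(m.TR[p].data(), gT.data(), pTR.data(), idxMglo, 3, floorv);
    dyn_norm(m.TR[p].data(), gT.data(), pTR.data(), idxI, 2, floorv);
    dyn_norm(m.TR[p].data(), gT.data(), pTR.data(), idxD, 2, floorv);
    for (int s = 0; s < S; ++s) dyn_alpha_col(m, sd[s], p);
    if (track) obj.push_back(objective());
    p += 1;
  }

  const int n = m.n();
  // state-independent group: restricted E-step with the current parameters
  std::array<double, 4> cIE{};
  std::array<double, 3> cBG{};
  std::array<double, 4> cDIO{};
  for (int s = 0; s < S; ++s) {
    SeqDP& q = sd[s];
    const int K = q.K();
    dyn_beta_all(m, q);
    const double Lh = dyn_terminal(m, q);
    if (!(Lh > 0.0)) stop("zero likelihood before the global update");
    const double invL = 1.0 / Lh;
    for (int tau = 1; tau <= K; ++tau) {
      const int d = q.code[tau - 1];
      if (d < 0) continue;
      for (int pp = 0; pp < n; ++pp)
        cIE[d] += q.aI[pp][tau] * q.bI[pp][tau] * invL;
    }
    if (K >= 1) {
      const int d0 = q.code[0];
      cBG[0] += m.entry(0) * m.eM(0, d0) * q.bM[0][1] / q.scales[1] * invL;
      for (int pp = 1; pp < n; ++pp) {
        const double g =
            m.entry(pp) * m.eM(pp, d0) * q.bM[pp][1] / q.scales[1] * invL;
        cBG[2] += g;
        cDIO[0] += g * (pp - 1);
        cDIO[1] += g;
      }
    }
    cBG[1] += m.BG[1] * q.bD[0][0] * invL;
    if (m.local) {
      for (int pp = 0; pp < n - 1; ++pp) {
        const double w = q.aM[pp][K] * m.exitv(pp) * invL;
        cDIO[2] += w * (n - 1 - pp);
        cDIO[3] += w;
      }
      cDIO[3] += q.aM[n - 1][K] * m.TR[n - 1][3] * m.DIO[3] * invL;
    }
  }
  dyn_norm(m.IE.data(), cIE.data(), pIE.data(), idx4, 4, floorv);
  {
    const int idxBloc[3] = {0, 1, 2}, idxBglo[2] = {0, 1};
    if (m.local) dyn_norm(m.BG.data(), cBG.data(), pBG.data(), idxBloc, 3, floorv);
    else dyn_norm(m.BG.data(), cBG.data(), pBG.data(), idxBglo, 2, floorv);
    if (m.local) {
      const int gin[2] = {0, 1}, gout[2] = {2, 3};
      dyn_norm(m.DIO.data(), cDIO.data(), pDIO.data(), gin, 2, floorv);
      dyn_norm(m.DIO.data(), cDIO.data(), pDIO.data(), gout, 2, floorv);
    }
  }
  if (track) obj.push_back(objective());

  NumericMatrix outME(n, 4), outTR(n, 8), perIns(S, n), perDel(S, n);
  for (int pp = 0; pp < n; ++pp) {
    for (int a = 0; a < 4; ++a) outME(pp, a) = m.ME[pp][a];
    for (int j = 0; j < 8; ++j) outTR(pp, j) = m.TR[pp][j];
    for (int s = 0; s < S; ++s) {
      perIns(s, pp) = insUse[pp][s];
      perDel(s, pp) = delUse[pp][s];
    }
  }
  NumericVector outIE(4), outBG(3), outDIO(4);
  for (int a = 0; a < 4; ++a) outIE[a] = m.IE[a];
  for (int j = 0; j < 3; ++j) outBG[j] = m.BG[j];
  for (int j = 0; j < 4; ++j) outDIO[j] = m.DIO[j];
  return List::create(
      _["ME"] = outME, _["IE"] = outIE, _["TR"] = outTR, _["BG"] = outBG,
      _["DIO"] = outDIO, _["perSeqIns"] = perIns, _["perSeqDel"] = perDel,
      _["loglik"] = ll,
      _["objective"] = NumericVector(obj.begin(), obj.end()));
}

// ---------------------------------------------------------------------------
// Local Viterbi (local in the sequence; model entry/exit via DeletionIn/Out)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_viterbi_local(List model, IntegerVector seq) {
  P7 m(model);
  const int K = seq.size(), n = m.n;
  if (K == 0)
    return List::create(_["score"] = R_NegInf, _["start"] = 0, _["end"] = 0,
                        _["path"] = IntegerMatrix(0, 3));
  auto lg = [](double x) { return x > 0.0 ? std::log(x) : NEG_BIG; };
  std::vector<double> lbg(4);
  for (int a = 0; a < 4; ++a) lbg[a] = lg(m.IE[a]);
  // log-odds emission scores; masked residues block all paths
  auto sM = [&](int p, int d) {
    if (d == -1) return 0.0;
    if (d == -2) return NEG_BIG;
    return lg(m.ME(p - 1, d)) - lbg[d];
  };
  auto sI = [&](int d) {
    if (d == -1) return 0.0;
    if (d == -2) return NEG_BIG;
    return lg(m.IE[d]) - lbg[d];
  };
  std::vector<double> lentry(n + 1), lexit(n + 1);
  for (int p = 1; p <= n; ++p) {
    lentry[p] = lg(m.entry(p));
    lexit[p] = lg(m.exitv(p));
  }
  // choice codes: 0 entry, 1 from M, 2 from D, 3 from I (tie-break order)
  NumericMatrix VM(K + 1, n), VI(K + 1, n), VD(K + 1, n);
  IntegerMatrix cM(K + 1, n), cI(K + 1, n), cD(K + 1, n);
  std::fill(VM.begin(), VM.end(), NEG_BIG);
  std::fill(VI.begin(), VI.end(), NEG_BIG);
  std::fill(VD.begin(), VD.end(), NEG_BIG);
  double best = NEG_BIG;
  int bestTau = 0, bestP = 0;
  for (int tau = 1; tau <= K; ++tau) {
    const int d = seq[tau - 1];
    for (int p = 1; p <= n; ++p) {
      double v = lentry[p];
      int ch = 0;
      if (p > 1) {
        const double fm = VM(tau - 1, p - 2) + lg(m.TR(p - 2, 0));
        const double fd = VD(tau - 1, p - 2) + lg(m.TR(p - 2, 6));
        const double fi = VI(tau - 1, p - 2) + lg(m.TR(p - 2, 4));
        if (fm > v) { v = fm; ch = 1; }
        if (fd > v) { v = fd; ch = 2; }
        if (fi > v) { v = fi; ch = 3; }
      }
      VM(tau, p - 1) = sM(p, d) + v;
      cM(tau, p - 1) = ch;
      const double im = VM(tau - 1, p - 1) + lg(m.TR(p - 1, 1));
      const double ii = VI(tau - 1, p - 1) + lg(m.TR(p - 1, 5));
      VI(tau, p - 1) = sI(d) + std::max(im, ii);
      cI(tau, p - 1) = (im >= ii) ? 1 : 3;
    }
    for (int p = 2; p <= n; ++p) {
      const double dm = VM(tau, p - 2) + lg(m.TR(p - 2, 2));
      const double dd = VD(tau, p - 2) + lg(m.TR(p - 2, 7));
      VD(tau, p - 1) = std::max(dm, dd);
      cD(tau, p - 1) = (dm >= dd) ? 1 : 2;
    }
    for (int p = 1; p <= n; ++p) {
      const double sc = VM(tau, p - 1) + lexit[p];
      if (sc > best) { best = sc; bestTau = tau; bestP = p; }
    }
  }
  if (best <= NEG_BIG / 2)
    return List::create(_["score"] = R_NegInf, _["start"] = 0, _["end"] = 0,
                        _["path"] = IntegerMatrix(0, 3));
  // traceback
  std::vector<int> Ppos, Prole, Ptau;
  int tau = bestTau, p = bestP, role = 0;  // role 0 M, 1 I, 2 D
  while (true) {
    Ppos.push_back(p); Prole.push_back(role); Ptau.push_back(tau);
    if (role == 0) {
      const int ch = cM(tau, p - 1);
      if (ch == 0) break;
      role = (ch == 1) ? 0 : (ch == 2) ? 2 : 1;
      p -= 1; tau -= 1;
    } else if (role == 1) {
      const int ch = cI(tau, p - 1);
      role = (ch == 1) ? 0 : 1;
      tau -= 1;
    } else {
      const int ch = cD(tau, p - 1);
      role = (ch == 1) ? 0 : 2;
      p -= 1;
    }
  }
  const int len = Ppos.size();
  IntegerMatrix path(len, 3);
  int startTau = bestTau;
  for (int i = 0; i < len; ++i) {
    path(i, 0) = Ppos[len - 1 - i];
    path(i, 1) = Prole[len - 1 - i];
    path(i, 2) = Ptau[len - 1 - i];
    if (Prole[len - 1 - i] != 2) startTau = std::min(startTau, Ptau[len - 1 - i]);
  }
  return List::create(_["score"] = best, _["start"] = startTau,
                      _["end"] = bestTau, _["path"] = path);
}
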