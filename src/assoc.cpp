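// Association-state solver for the dimer-gel free energy.
//
// For sticker concentrations (c1, c2) and parameters (L1, L2, Kd, Kb), the
// specific free-energy density (per kBT, concentrations in mM)
//
//   Fs = -x(r1) - x(r2) + rd ln(e Kd rd) + x(r1-rd) + x(r2-rd)
//        - x(q1) - x(q2) + cb ln(e Kb cb) + x(h1) + x(h2)
//
// with x(t) = t ln t (0 at 0), r_i = c_i/L_i, q_i = c_i - L_i rd,
// h_i = q_i - cb, is minimized over 0 <= rd <= min(r1, r2),
// 0 <= cb <= min(q1, q2).  Stationarity gives
//
//   g1 = ln(Kd rd) - ln(r1-rd) - ln(r2-rd) + L1 ln(q1/h1) + L2 ln(q2/h2) = 0
//   g2 = ln(Kb cb) - ln(h1 h2) = 0.
//
// Numerics: in the strong-binding regime the minimizer sits exponentially
// close to the boundary (rd -> min(r1, r2) or cb -> min(q1, q2)), where
// forming q = c - L rd by subtraction destroys all precision.  The solver
// therefore parametrizes by the *excess* e = min(r1, r2) - rd, so
// q_min = L_min_side * e exactly, and for each e solves the bond channel in
// closed form: with dq = q_max - q_min, the residual h_min = q_min - cb obeys
//   h^2 + (dq + Kb) h - Kb q_min = 0,
// whose positive root is cancellation-free; cb = h_min h_max / Kb then
// satisfies g2 to machine precision.  What remains is a 1-D problem in e,
// solved by a sign-change scan over a logit grid plus bisection; multiple
// stationary points (the dimer/gel bistability) are all refined and the
// lowest-Fs one returned.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double xlx(double t) { return t > 0.0 ? t * std::log(t) : 0.0; }

struct Prob {
  double c1, c2, L1, L2, lKd, lKb, Kb;
  double r1, r2, rm, rM, Lm, LM;  // rm = min(r1,r2) etc., Lm its valence
  bool swapped;                   // true when species 2 is the minority
  bool no_dimer, no_bond;
};

// bond channel given dimer excess e (= rm - rd):
// fills q (sticker excesses), h (free stickers), cb; returns g2 residual
struct BondState { double qm, qM, hm, hM, cb; };

BondState bond_solve(const Prob& P, double e) {
  BondState B;
  B.qm = P.Lm * e;
  B.qM = P.LM * (e + (P.rM - P.rm));
  if (P.no_bond || B.qm <= 0.0) {
    B.hm = B.qm; B.hM = B.qM; B.cb = 0.0;
    return B;
  }
  double dq = B.qM - B.qm;
  double s = dq + P.Kb;
  // positive root of h^2 + s h - Kb qm = 0
  B.hm = 2.0 * P.Kb * B.qm / (s + std::sqrt(s * s + 4.0 * P.Kb * B.qm));
  B.hM = B.hm + dq;
  B.cb = B.hm * B.hM / P.Kb;
  return B;
}

// dimer stationarity residual g1 at excess e and dimer concentration rd
// (e and rd are supplied separately, each computed without cancellation)
double g1_at(const Prob& P, double e, double rd, const BondState& B) {
  double eM = e + (P.rM - P.rm);
  return P.lKd + std::log(rd) - std::log(e) - std::log(eM) +
         P.Lm * (std::log(B.qm) - std::log(B.hm)) +
         P.LM * (std::log(B.qM) - std::log(B.hM));
}

double fs_at(const Prob& P, double e, double rd) {
  BondState B = bond_solve(P, e);
  double eM = e + (P.rM - P.rm);
  double out = -xlx(P.r1) - xlx(P.r2);
  if (rd > 0) out += rd * P.lKd + xlx(rd) + rd;
  out += xlx(e) + xlx(eM) - xlx(B.qm) - xlx(B.qM);
  if (B.cb > 0) out += B.cb * P.lKb + xlx(B.cb) + B.cb;
  out += xlx(B.hm) + xlx(B.hM);
  return out;
}

}  // namespace

// Solve the association state for vectors of concentrations.  Returns a
// matrix with columns rho_d, cb, fs, res1, res2, converged.
// [[Rcpp::export(name = ".assoc_solve_cpp")]]
NumericMatrix assoc_solve_cpp(NumericVector c1v, NumericVector c2v, double L1,
                              double L2, double Kd, double Kb) {
  int n = c1v.size();
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("rho_d", "cb", "fs", "res1", "res2",
                                          "converged");
  bool no_dimer = !R_finite(Kd) || Kd > 1e290;
  bool no_bond = !R_finite(Kb) || Kb > 1e290;

  const int NSCAN = 241;

  for (int idx = 0; idx < n; ++idx) {
    double c1 = c1v[idx], c2 = c2v[idx];
    if (c1 <= 0.0 || c2 <= 0.0 || (no_dimer && no_bond)) {
      out(idx, 0) = 0; out(idx, 1) = 0; out(idx, 2) = 0;
      out(idx, 3) = 0; out(idx, 4) = 0; out(idx, 5) = 1;
      continue;
    }
    Prob P;
    P.c1 = c1; P.c2 = c2; P.L1 = L1; P.L2 = L2;
    P.lKd = no_dimer ? 0.0 : std::log(Kd);
    P.lKb = no_bond ? 0.0 : std::log(Kb);
    P.Kb = Kb;
    P.r1 = c1 / L1; P.r2 = c2 / L2;
    P.swapped = P.r2 < P.r1;
    P.rm = P.swapped ? P.r2 : P.r1;
    P.rM = P.swapped ? P.r1 : P.r2;
    P.Lm = P.swapped ? L2 : L1;
    P.LM = P.swapped ? L1 : L2;
    P.no_dimer = no_dimer; P.no_bond = no_bond;

    double rd, cb, fs, g1 = 0.0, g2 = 0.0;
    bool conv = true;

    if (no_dimer) {
      BondState B = bond_solve(P, P.rm);  // e = rm means rd = 0
      rd = 0.0; cb = B.cb;
      fs = fs_at(P, P.rm, 0.0);
      if (!P.no_bond && cb > 0)
        g2 = P.lKb + std::log(cb) - std::log(B.hm) - std::log(B.hM);
    } else {
      // scan the logit variable u: e = rm sigma(u), rd = rm sigma(-u),
      // both computed without cancellation
      auto split = [&](double u, double& e, double& rdv) {
        e = P.rm / (1.0 + std::exp(-u));
        rdv = P.rm / (1.0 + std::exp(u));
      };
      auto g1_u = [&](double u) {
        double e, rdv;
        split(u, e, rdv);
        BondState B = bond_solve(P, e);
        return g1_at(P, e, rdv, B);
      };
      const double ulo = -34.0, uhi = 34.0;
      std::vector<double> uv(NSCAN), g1v(NSCAN);
      for (int i = 0; i < NSCAN; ++i) {
        uv[i] = ulo + (uhi - ulo) * i / (NSCAN - 1.0);
        g1v[i] = g1_u(uv[i]);
      }
      // bisect every sign-change bracket in u
      double best_fs = R_PosInf, best_u = NA_REAL;
      bool found = false;
      for (int i = 0; i + 1 < NSCAN; ++i) {
        if (!R_finite(g1v[i]) || !R_finite(g1v[i + 1])) continue;
        if ((g1v[i] > 0) == (g1v[i + 1] > 0)) continue;
        double lo = uv[i], hi = uv[i + 1];
        double glo = g1v[i];
        for (int it = 0; it < 120; ++it) {
          double mid = 0.5 * (lo + hi);
          if (mid <= lo || mid >= hi) break;
          double gm = g1_u(mid);
          if (!R_finite(gm)) break;
          if ((gm > 0) == (glo > 0)) { lo = mid; glo = gm; }
          else hi = mid;
        }
        double u = 0.5 * (lo + hi), e, rdv;
        split(u, e, rdv);
        double f = fs_at(P, e, rdv);
        if (f < best_fs) { best_fs = f; best_u = u; found = true; }
      }
      // boundary candidate: no dimers at all (rd = 0)
      double f_nodim = fs_at(P, P.rm, 0.0);
      if (f_nodim < best_fs || !found) {
        rd = 0.0; fs = f_nodim;
        BondState B = bond_solve(P, P.rm);
        cb = B.cb;
        if (cb > 0 && !P.no_bond)
          g2 = P.lKb + std::log(cb) - std::log(B.hm) - std::log(B.hM);
      } else {
        double e;
        split(best_u, e, rd);
        BondState B = bond_solve(P, e);
        cb = B.cb;
        fs = best_fs;
        g1 = g1_at(P, e, rd, B);
        if (cb > 0 && !P.no_bond)
          g2 = P.lKb + std::log(cb) - std::log(B.hm) - std::log(B.hM);
        if (std::fabs(g1) > 1e-8) conv = false;
      }
    }
    out(idx, 0) = rd; out(idx, 1) = cb; out(idx, 2) = fs;
    out(idx, 3) = g1; out(idx, 4) = g2; out(idx, 5) = conv ? 1.0 : 0.0;
  }
  return out;
}
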