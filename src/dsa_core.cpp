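// Design-space screening of candidate regulation architectures.
//
// A regulation scheme assigns to each of the five regulated quantities
// q in {p0, p1, q1, eta1, eta2} either no regulation (code 0) or regulation
// by one of the four cell types with a sign (codes 1..8):
//   code c in 1..8:  source = (c-1) / 2  (0=S, 1=P, 2=TDl, 3=TDm)
//                    sign   = (c-1) % 2  (0 = negative, 1 = positive)
//
// Regulated quantities are Hill-1 functions of their regulator,
//   negative: r = r_max / (1 + g X),   positive: r = r_max g X / (1 + g X),
// and the ODEs are recast as sums of signed power-law terms: numerators of
// the composite factors (2p0-1), (1-p0), (2p1-1), (1-p1-q1) are expanded
// exactly, and every Hill denominator (1 + gX) is replaced by its dominant
// monomial (regime branch gX < 1 or gX > 1, chosen globally per quantity).
// The sign of (2 p1_max - 1) is not fixed a priori, so that sign regime is
// enumerated as well.  Per equation one dominant source and one dominant
// sink term are kept (an equation with no source or no sink cannot balance
// and yields no subsystem).  A subsystem survives at a parameter point if
// its log-linear equilibrium exists, every dominance / regime inequality
// holds strictly there, and the subsystem Jacobian has all eigenvalue real
// parts negative.  A scheme is accepted if at least one subsystem survives
// at at least one point of the supplied parameter sample.
//
// log-parameter layout (length 12):
//   [0] log p0_max [1] log p1_max [2] log q1_max [3] log eta1_max
//   [4] log eta2_max [5] log d_l [6] log d_m [7..11] log gamma_q for
//   q = p0, p1, q1, eta1, eta2.
//
// Composite coefficient codes (evaluated per parameter point):
//   0: 1   1: 2 p0_max - 1   2: 1 - p0_max   3: |2 p1_max - 1|
//   4: 1 - p1_max   5: 1 - q1_max   6: 1 - p1_max - q1_max

#include <RcppArmadillo.h>
using namespace Rcpp;

struct Term {                    // coef * exp(c0 + pw.logtheta) * X^e
  double c0;
  int coef;
  double pw[12];
  double e[4];
};

static Term term_unit() {
  Term t;
  t.c0 = 0.0; t.coef = 0;
  std::fill(t.pw, t.pw + 12, 0.0);
  std::fill(t.e, t.e + 4, 0.0);
  return t;
}

static void term_mul(Term& a, const Term& b) {
  a.c0 += b.c0;
  if (b.coef) a.coef = b.coef;   // at most one composite coefficient/term
  for (int i = 0; i < 12; ++i) a.pw[i] += b.pw[i];
  for (int i = 0; i < 4; ++i) a.e[i] += b.e[i];
}

struct LinExpr {                 // log A - log B, A and B terms
  double c0;
  int coefp, coefm;
  double pw[12];
  double e[4];
};

static LinExpr expr_diff(const Term& a, const Term& b) {
  LinExpr d;
  d.c0 = a.c0 - b.c0; d.coefp = a.coef; d.coefm = b.coef;
  for (int i = 0; i < 12; ++i) d.pw[i] = a.pw[i] - b.pw[i];
  for (int i = 0; i < 4; ++i) d.e[i] = a.e[i] - b.e[i];
  return d;
}

static double term_logval(const Term& t, const double* lt,
                          const double* clog, const double* y) {
  double v = t.c0 + clog[t.coef];
  for (int i = 0; i < 12; ++i) v += t.pw[i] * lt[i];
  for (int i = 0; i < 4; ++i) v += t.e[i] * y[i];
  return v;
}

static double expr_val(const LinExpr& x, const double* lt,
                       const double* clog, const double* y) {
  double v = x.c0 + clog[x.coefp] - clog[x.coefm];
  for (int i = 0; i < 12; ++i) v += x.pw[i] * lt[i];
  for (int i = 0; i < 4; ++i) v += x.e[i] * y[i];
  return v;
}

struct SSys {
  arma::mat44 M;
  arma::mat44 Minv;
  LinExpr b[4];                  // log(sink) - log(source) per equation
  std::vector<LinExpr> ineq;     // each must exceed the margin
  Term src[4];                   // dominant sources (Jacobian weights)
  int combo, branchmask, p1hi;
};

// gamma*X monomial and 1/denominator-branch monomial for quantity q.
static Term gmono(int q, int src) {
  Term t = term_unit();
  t.pw[7 + q] = 1.0; t.e[src] = 1.0;
  return t;
}
static Term dinv(int q, int src, int branch) {
  Term t = term_unit();
  if (branch == 1) { t.pw[7 + q] = -1.0; t.e[src] = -1.0; }
  return t;
}

static Term coef_term(int code, double lognum = 0.0) {
  Term t = term_unit();
  t.coef = code; t.c0 = lognum;
  return t;
}

// Multiplicative quantity value q1/eta1/eta2: numerator / denominator
// branch (collapses to the familiar asymptotic branches).
static Term mult_quantity(int q, int code, int branch) {
  Term t = term_unit();
  t.pw[q] = 1.0;
  if (code == 0) return t;
  int src = (code - 1) / 2, sign = (code - 1) % 2;
  if (sign == 1) term_mul(t, gmono(q, src));
  term_mul(t, dinv(q, src, branch));
  return t;
}

// Build all subsystems for one scheme, branch mask and p1 sign regime.
static void build_subsystems(const int* code, int branchmask, int p1hi,
                             const std::vector<int>& regq,
                             std::vector<SSys>& out) {
  const double LOG2 = std::log(2.0);
  int branch[5] = {0, 0, 0, 0, 0};
  for (size_t k = 0; k < regq.size(); ++k)
    branch[regq[k]] = (branchmask >> k) & 1;

  int s0 = code[0] ? (code[0] - 1) / 2 : -1;   // p0 regulator
  int sg0 = code[0] ? (code[0] - 1) % 2 : -1;  // 0 neg / 1 pos
  int s1 = code[1] ? (code[1] - 1) / 2 : -1;   // p1 regulator
  int sg1 = code[1] ? (code[1] - 1) % 2 : -1;
  int s2 = code[2] ? (code[2] - 1) / 2 : -1;   // q1 regulator
  int sg2 = code[2] ? (code[2] - 1) % 2 : -1;

  Term e1S = mult_quantity(3, code[3], branch[3]);  // eta1 factor
  e1S.e[0] += 1.0;                                  // ... times S
  Term e2P = mult_quantity(4, code[4], branch[4]);  // eta2 factor
  e2P.e[1] += 1.0;                                  // ... times P
  Term d0i = code[0] ? dinv(0, s0, branch[0]) : term_unit();
  Term d1i = code[1] ? dinv(1, s1, branch[1]) : term_unit();
  Term d2i = code[2] ? dinv(2, s2, branch[2]) : term_unit();

  std::vector<Term> srcS, snkS, srcP, snkP, srcL, snkL, srcM, snkM;
  Term t;

  // --- S equation: (2 p0 - 1) eta1 S --------------------------------
  if (code[0] == 0) {
    t = coef_term(1); term_mul(t, e1S); srcS.push_back(t);
    // no sink: the equation cannot balance, handled below
  } else if (sg0 == 0) {
    t = coef_term(1); term_mul(t, e1S); term_mul(t, d0i); srcS.push_back(t);
    t = gmono(0, s0); term_mul(t, e1S); term_mul(t, d0i); snkS.push_back(t);
  } else {
    t = coef_term(1); term_mul(t, gmono(0, s0)); term_mul(t, e1S);
    term_mul(t, d0i); srcS.push_back(t);
    t = e1S; term_mul(t, d0i); snkS.push_back(t);
  }

  // --- P equation: 2 (1 - p0) eta1 S + (2 p1 - 1) eta2 P ------------
  if (code[0] == 0) {
    t = coef_term(2, LOG2); term_mul(t, e1S); srcP.push_back(t);
  } else if (sg0 == 0) {
    t = coef_term(2, LOG2); term_mul(t, e1S); term_mul(t, d0i);
    srcP.push_back(t);
    t = coef_term(0, LOG2); term_mul(t, gmono(0, s0)); term_mul(t, e1S);
    term_mul(t, d0i); srcP.push_back(t);
  } else {
    t = coef_term(0, LOG2); term_mul(t, e1S); term_mul(t, d0i);
    srcP.push_back(t);
    t = coef_term(2, LOG2); term_mul(t, gmono(0, s0)); term_mul(t, e1S);
    term_mul(t, d0i); srcP.push_back(t);
  }
  if (code[1] == 0) {
    t = coef_term(3); term_mul(t, e2P);
    (p1hi ? srcP : snkP).push_back(t);
  } else if (sg1 == 0) {
    t = coef_term(3); term_mul(t, e2P); term_mul(t, d1i);
    (p1hi ? srcP : snkP).push_back(t);
    t = gmono(1, s1); term_mul(t, e2P); term_mul(t, d1i); snkP.push_back(t);
  } else {
    t = coef_term(3); term_mul(t, gmono(1, s1)); term_mul(t, e2P);
    term_mul(t, d1i);
    (p1hi ? srcP : snkP).push_back(t);
    t = e2P; term_mul(t, d1i); snkP.push_back(t);
  }

  // --- TDl equation: 2 q1 eta2 P - d_l TDl --------------------------
  t = coef_term(0, LOG2); term_mul(t, mult_quantity(2, code[2], branch[2]));
  term_mul(t, e2P); srcL.push_back(t);
  t = term_unit(); t.pw[5] = 1.0; t.e[2] = 1.0; snkL.push_back(t);

  // --- TDm equation: 2 (1 - p1 - q1) eta2 P - d_m TDm ---------------
  // exact expansion of (1 - p1 - q1) over the p1 and q1 denominators
  {
    std::vector<Term> num;       // numerator terms (all positive)
    Term g3 = code[1] ? gmono(1, s1) : term_unit();
    Term g4 = code[2] ? gmono(2, s2) : term_unit();
    int c1m = code[1] ? (sg1 == 0 ? 1 : 2) : 0;  // 1 neg, 2 pos, 0 none
    int c2m = code[2] ? (sg2 == 0 ? 1 : 2) : 0;
    if (c1m == 0 && c2m == 0) {
      num.push_back(coef_term(6));
    } else if (c1m == 0) {       // p1 unregulated, q1 regulated
      if (c2m == 1) {            // (1-p1-q1) + (1-p1) g4
        num.push_back(coef_term(6));
        t = coef_term(4); term_mul(t, g4); num.push_back(t);
      } else {                   // (1-p1) + (1-p1-q1) g4
        num.push_back(coef_term(4));
        t = coef_term(6); term_mul(t, g4); num.push_back(t);
      }
    } else if (c2m == 0) {       // q1 unregulated, p1 regulated
      if (c1m == 1) {
        num.push_back(coef_term(6));
        t = coef_term(5); term_mul(t, g3); num.push_back(t);
      } else {
        num.push_back(coef_term(5));
        t = coef_term(6); term_mul(t, g3); num.push_back(t);
      }
    } else {
      // both regulated: four terms, signs all positive
      int c1c, cg3, cg4, c34;
      if (c1m == 1 && c2m == 1)      { c1c = 6; cg3 = 5; cg4 = 4; c34 = 0; }
      else if (c1m == 1 && c2m == 2) { c1c = 4; cg3 = 0; cg4 = 6; c34 = 5; }
      else if (c1m == 2 && c2m == 1) { c1c = 5; cg3 = 6; cg4 = 0; c34 = 4; }
      else                           { c1c = 0; cg3 = 4; cg4 = 5; c34 = 6; }
      num.push_back(coef_term(c1c));
      t = coef_term(cg3); term_mul(t, g3); num.push_back(t);
      t = coef_term(cg4); term_mul(t, g4); num.push_back(t);
      t = coef_term(c34); term_mul(t, g3); term_mul(t, g4);
      num.push_back(t);
    }
    for (size_t i = 0; i < num.size(); ++i) {
      t = num[i]; t.c0 += LOG2;
      term_mul(t, e2P); term_mul(t, d1i); term_mul(t, d2i);
      srcM.push_back(t);
    }
    t = term_unit(); t.pw[6] = 1.0; t.e[3] = 1.0; snkM.push_back(t);
  }

  if (srcS.empty() || snkS.empty() || srcP.empty() || snkP.empty())
    return;                      // some equation cannot balance

  std::vector<Term>* srcs[4] = {&srcS, &srcP, &srcL, &srcM};
  std::vector<Term>* snks[4] = {&snkS, &snkP, &snkL, &snkM};
  int nsrc[4], nsnk[4];
  for (int i = 0; i < 4; ++i) {
    nsrc[i] = srcs[i]->size(); nsnk[i] = snks[i]->size();
  }
  int choice[4][2];
  for (choice[0][0] = 0; choice[0][0] < nsrc[0]; ++choice[0][0])
  for (choice[0][1] = 0; choice[0][1] < nsnk[0]; ++choice[0][1])
  for (choice[1][0] = 0; choice[1][0] < nsrc[1]; ++choice[1][0])
  for (choice[1][1] = 0; choice[1][1] < nsnk[1]; ++choice[1][1])
  for (choice[2][0] = 0; choice[2][0] < nsrc[2]; ++choice[2][0])
  for (choice[2][1] = 0; choice[2][1] < nsnk[2]; ++choice[2][1])
  for (choice[3][0] = 0; choice[3][0] < nsrc[3]; ++choice[3][0])
  for (choice[3][1] = 0; choice[3][1] < nsnk[3]; ++choice[3][1]) {
    SSys ss;
    ss.branchmask = branchmask; ss.p1hi = p1hi;
    ss.combo = ((choice[1][0] * 2 + choice[1][1]) * 4 + choice[3][0]) * 4 +
               choice[0][0];
    for (int i = 0; i < 4; ++i) {
      const Term& a = (*srcs[i])[choice[i][0]];
      const Term& b = (*snks[i])[choice[i][1]];
      for (int j = 0; j < 4; ++j) ss.M(i, j) = a.e[j] - b.e[j];
      ss.b[i] = expr_diff(b, a);
      ss.src[i] = a;
    }
    double det = arma::det(ss.M);
    if (!std::isfinite(det) || std::fabs(det) < 1e-10) continue;
    ss.Minv = arma::inv(ss.M);
    // dominance of the chosen terms over the alternatives
    for (int i = 0; i < 4; ++i) {
      for (int k = 0; k < nsrc[i]; ++k)
        if (k != choice[i][0])
          ss.ineq.push_back(expr_diff((*srcs[i])[choice[i][0]],
                                      (*srcs[i])[k]));
      for (int k = 0; k < nsnk[i]; ++k)
        if (k != choice[i][1])
          ss.ineq.push_back(expr_diff((*snks[i])[choice[i][1]],
                                      (*snks[i])[k]));
    }
    // regime inequalities: branch per regulated quantity
    for (int q = 0; q < 5; ++q) {
      if (code[q] == 0) continue;
      int src = (code[q] - 1) / 2;
      double sgn = branch[q] ? 1.0 : -1.0;
      LinExpr r; r.c0 = 0; r.coefp = r.coefm = 0;
      std::fill(r.pw, r.pw + 12, 0.0);
      std::fill(r.e, r.e + 4, 0.0);
      r.pw[7 + q] = sgn; r.e[src] = sgn;
      ss.ineq.push_back(r);
    }
    // p1 sign regime: sgn * (log 2 + log p1_max) > 0
    {
      LinExpr r; r.coefp = r.coefm = 0;
      std::fill(r.pw, r.pw + 12, 0.0);
      std::fill(r.e, r.e + 4, 0.0);
      double sgn = p1hi ? 1.0 : -1.0;
      r.c0 = sgn * std::log(2.0); r.pw[1] = sgn;
      ss.ineq.push_back(r);
    }
    out.push_back(ss);
  }
}

// Establishment (boot-up) requirement: starting from a small seed of
// stem cells, the S equation must have positive net growth in the
// small-population regime (all Hill denominators ~ 1).  The sign of S'
// as populations -> 0 is set by the lowest-degree term; a scheme whose
// sink dominates there (positively regulated p0, whose basal value lies
// below 1/2) can never establish hematopoiesis and is rejected.
static bool establishment_ok(const int* code) {
  std::vector<int> regq;                       // low branches everywhere
  for (int q = 0; q < 5; ++q) if (code[q] != 0) regq.push_back(q);
  std::vector<SSys> dummy;
  // rebuild the S-equation term lists directly (mask 0 = all low)
  int branch[5] = {0, 0, 0, 0, 0};
  int s0 = code[0] ? (code[0] - 1) / 2 : -1;
  int sg0 = code[0] ? (code[0] - 1) % 2 : -1;
  Term e1S = mult_quantity(3, code[3], branch[3]);
  e1S.e[0] += 1.0;
  std::vector<Term> srcS, snkS;
  Term t;
  if (code[0] == 0) {
    t = coef_term(1); term_mul(t, e1S); srcS.push_back(t);
  } else if (sg0 == 0) {
    t = coef_term(1); term_mul(t, e1S); srcS.push_back(t);
    t = gmono(0, s0); term_mul(t, e1S); snkS.push_back(t);
  } else {
    t = coef_term(1); term_mul(t, gmono(0, s0)); term_mul(t, e1S);
    srcS.push_back(t);
    t = e1S; snkS.push_back(t);
  }
  if (snkS.empty()) return true;
  double dsrc = 1e9, dsnk = 1e9;
  for (size_t i = 0; i < srcS.size(); ++i) {
    double d = 0; for (int j = 0; j < 4; ++j) d += srcS[i].e[j];
    dsrc = std::min(dsrc, d);
  }
  for (size_t i = 0; i < snkS.size(); ++i) {
    double d = 0; for (int j = 0; j < 4; ++j) d += snkS[i].e[j];
    dsnk = std::min(dsnk, d);
  }
  return dsrc < dsnk;
}

// Composite coefficient logs for one natural-scale parameter point.
static void coef_logs(const double* lt, double* clog) {
  double p0 = std::exp(lt[0]), p1 = std::exp(lt[1]), q1 = std::exp(lt[2]);
  clog[0] = 0.0;
  clog[1] = std::log(2.0 * p0 - 1.0);
  clog[2] = std::log(1.0 - p0);
  clog[3] = std::log(std::fabs(2.0 * p1 - 1.0));
  clog[4] = std::log(1.0 - p1);
  clog[5] = std::log(1.0 - q1);
  clog[6] = std::log(1.0 - p1 - q1);
}

static int eval_ssys(const SSys& ss, const double* lt, const double* clog,
                     double margin, double* y_out) {
  double b[4];
  const double zero4[4] = {0, 0, 0, 0};   // b has no state dependence
  for (int i = 0; i < 4; ++i) b[i] = expr_val(ss.b[i], lt, clog, zero4);
  if (!std::isfinite(b[0] + b[1] + b[2] + b[3])) return 0;
  double y[4];
  for (int i = 0; i < 4; ++i) {
    double v = 0.0;
    for (int j = 0; j < 4; ++j) v += ss.Minv(i, j) * b[j];
    if (!std::isfinite(v) || std::fabs(v) > 200.0) return 0;
    y[i] = v;
  }
  for (size_t k = 0; k < ss.ineq.size(); ++k) {
    double v = expr_val(ss.ineq[k], lt, clog, y);
    if (!(v > margin)) return 0;
  }
  arma::mat44 B;
  for (int i = 0; i < 4; ++i) {
    double lw = term_logval(ss.src[i], lt, clog, y) - y[i];
    if (!std::isfinite(lw) || std::fabs(lw) > 200.0) return 0;
    double w = std::exp(lw);
    for (int j = 0; j < 4; ++j) B(i, j) = w * ss.M(i, j);
  }
  arma::cx_vec ev;
  if (!arma::eig_gen(ev, B)) return 0;
  double scale = 0.0;
  for (int i = 0; i < 4; ++i) scale = std::max(scale, std::abs(ev(i)));
  for (int i = 0; i < 4; ++i)
    if (ev(i).real() >= -1e-9 * scale) return 0;
  if (y_out) std::copy(y, y + 4, y_out);
  return 1;
}

// Screen a batch of schemes against a fixed log-parameter sample.
// [[Rcpp::export]]
DataFrame cpp_dsa_screen(IntegerMatrix schemes, NumericMatrix logtheta,
                         double margin = 1e-9, bool count_all = true) {
  int n = schemes.nrow(), K = logtheta.nrow();
  if (schemes.ncol() != 5 || logtheta.ncol() != 12) stop("bad dimensions");
  std::vector<std::vector<double> > lts(K, std::vector<double>(12));
  std::vector<std::vector<double> > clogs(K, std::vector<double>(7));
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < 12; ++j) lts[k][j] = logtheta(k, j);
    coef_logs(&lts[k][0], &clogs[k][0]);
  }
  LogicalVector accepted(n);
  IntegerVector nsurv(n), p0class(n);
  for (int r = 0; r < n; ++r) {
    int code[5];
    for (int q = 0; q < 5; ++q) code[q] = schemes(r, q);
    std::vector<int> regq;
    for (int q = 0; q < 5; ++q) {
      if (code[q] < 0 || code[q] > 8) stop("scheme codes must be in 0..8");
      if (code[q] != 0) regq.push_back(q);
    }
    int nmask = 1 << regq.size();
    int surv = 0;
    bool done = !establishment_ok(code);
    for (int p1hi = 0; p1hi < 2 && !done; ++p1hi) {
      for (int mask = 0; mask < nmask && !done; ++mask) {
        std::vector<SSys> sss;
        build_subsystems(code, mask, p1hi, regq, sss);
        for (size_t s = 0; s < sss.size(); ++s) {
          for (int k = 0; k < K; ++k) {
            if (eval_ssys(sss[s], &lts[k][0], &clogs[k][0], margin, NULL)) {
              ++surv;
              if (!count_all) done = true;
              break;
            }
          }
          if (done) break;
        }
      }
    }
    nsurv[r] = surv;
    accepted[r] = surv > 0;
    int c0 = code[0];
    p0class[r] = (c0 != 0 && (c0 - 1) % 2 == 0) ? (c0 - 1) / 2 + 1 : 0;
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["accepted"] = accepted,
                           _["n_surviving"] = nsurv,
                           _["p0_class"] = p0class);
}

// Detailed evaluation of every subsystem of one scheme at one parameter
// point; used for cross-checking against the R implementation and for
// extracting equilibrium witnesses.
// [[Rcpp::export]]
DataFrame cpp_dsa_detail(IntegerVector scheme, NumericVector logtheta,
                         double margin = 1e-9) {
  if (scheme.size() != 5 || logtheta.size() != 12) stop("bad dimensions");
  int code[5];
  for (int q = 0; q < 5; ++q) {
    code[q] = scheme[q];
    if (code[q] < 0 || code[q] > 8) stop("scheme codes must be in 0..8");
  }
  std::vector<int> regq;
  for (int q = 0; q < 5; ++q) if (code[q] != 0) regq.push_back(q);
  int nmask = 1 << regq.size();
  std::vector<double> lt(logtheta.begin(), logtheta.end());
  double clog[7];
  coef_logs(&lt[0], clog);
  std::vector<int> vmask, vp1, vcombo, vpass;
  std::vector<double> yS, yP, yL, yM;
  for (int p1hi = 0; p1hi < 2; ++p1hi)
    for (int mask = 0; mask < nmask; ++mask) {
      std::vector<SSys> sss;
      build_subsystems(code, mask, p1hi, regq, sss);
      for (size_t s = 0; s < sss.size(); ++s) {
        double y[4] = {NA_REAL, NA_REAL, NA_REAL, NA_REAL};
        int pass = eval_ssys(sss[s], &lt[0], clog, margin, y);
        vmask.push_back(mask); vp1.push_back(p1hi);
        vcombo.push_back(sss[s].combo); vpass.push_back(pass);
        yS.push_back(pass ? std::exp(y[0]) : NA_REAL);
        yP.push_back(pass ? std::exp(y[1]) : NA_REAL);
        yL.push_back(pass ? std::exp(y[2]) : NA_REAL);
        yM.push_back(pass ? std::exp(y[3]) : NA_REAL);
      }
    }
  return DataFrame::create(_["branchmask"] = wrap(vmask),
                           _["p1_high"] = wrap(vp1),
                           _["combo"] = wrap(vcombo),
                           _["pass"] = wrap(vpass),
                           _["S"] = wrap(yS), _["P"] = wrap(yP),
                           _["TDl"] = wrap(yL), _["TDm"] = wrap(yM));
}
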