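// Dynamic programming core for the reduced nearest-neighbor model:
//  - MFE folding (Zuker-style V / M / M1 / W recursions)
//  - partition function in scaled linear space (McCaskill recursions)
//  - base-pair probabilities by the outside algorithm
//  - stochastic (Boltzmann) traceback sampling
//  - interval DP maximizing an arbitrary pair/unpaired gain (MEA / centroid)
//
// Sequence codes: A=0, C=1, G=2, U=3, N=4.  N never pairs.
// Pair codes: AU=0, UA=1, CG=2, GC=3, GU=4, UG=5.
// Minimum hairpin loop: 3 unpaired bases (pairs require j - i >= 4).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <tuple>
using namespace Rcpp;

static const int MIN_HP = 3;
static const double INF_E = 1e18;

struct EnergyModel {
  double RT;
  double stack[6][6];
  std::vector<double> hairpin, bulge, internal_;
  double ml_a, ml_b, ml_c;
  double terminal_au;
  double ln_coeff;
  int max_loop;
};

static EnergyModel model_from_list(const List& par) {
  EnergyModel em;
  em.RT = as<double>(par["RT"]);
  NumericMatrix st = par["stack"];
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b) em.stack[a][b] = st(a, b);
  em.hairpin = as<std::vector<double> >(par["hairpin"]);
  em.bulge = as<std::vector<double> >(par["bulge"]);
  em.internal_ = as<std::vector<double> >(par["internal"]);
  em.ml_a = as<double>(par["ml_a"]);
  em.ml_b = as<double>(par["ml_b"]);
  em.ml_c = as<double>(par["ml_c"]);
  em.terminal_au = as<double>(par["terminal_au"]);
  em.ln_coeff = as<double>(par["ln_coeff"]);
  em.max_loop = as<int>(par["max_loop"]);
  return em;
}

static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 3 && b == 0) return 1;  // UA
  if (a == 1 && b == 2) return 2;  // CG
  if (a == 2 && b == 1) return 3;  // GC
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

static inline double loop_pen(const std::vector<double>& tab, int len,
                              double ln_coeff) {
  if (len <= 30) return tab[len];
  return tab[30] + ln_coeff * std::log((double)len / 30.0);
}

static inline double au_pen(const EnergyModel& em, int pc) {
  // terminal AU/GU penalty at each helix end bordering a non-stack loop
  return (pc == 0 || pc == 1 || pc == 4 || pc == 5) ? em.terminal_au : 0.0;
}

static inline double interior_energy(const EnergyModel& em, int b1, int b2) {
  int tot = b1 + b2;
  if (b1 == 0 || b2 == 0) return loop_pen(em.bulge, tot, em.ln_coeff);
  return loop_pen(em.internal_, tot, em.ln_coeff);
}

// ---------------------------------------------------------------------------
// MFE tables

struct MfeTables {
  int n;
  std::vector<double> V, M, M1, W;  // V,M,M1: n*n; W: n+1 (W[0] = empty)
  std::vector<int> pc;              // pair codes, n*n (-1 if not pairable)
  double energy;
};

static void fill_mfe(const std::vector<int>& s, const EnergyModel& em,
                     MfeTables& T) {
  int n = (int)s.size();
  T.n = n;
  T.V.assign((size_t)n * n, INF_E);
  T.M.assign((size_t)n * n, INF_E);
  T.M1.assign((size_t)n * n, INF_E);
  T.W.assign(n + 1, 0.0);
  T.pc.assign((size_t)n * n, -1);
#define IX(i, j) ((size_t)(i) * n + (j))
  for (int i = 0; i < n; ++i)
    for (int j = i + MIN_HP + 1; j < n; ++j) T.pc[IX(i, j)] = pair_code(s[i], s[j]);

  for (int i = n - 1; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) {
      int pcij = T.pc[IX(i, j)];
      if (pcij >= 0) {
        double au = au_pen(em, pcij);
        double best = loop_pen(em.hairpin, j - i - 1, em.ln_coeff) + au;
        // stacks / bulges / internal loops
        for (int k = i + 1; k <= j - MIN_HP - 2 && k - i - 1 <= em.max_loop; ++k) {
          int b1 = k - i - 1;
          int lmin = k + MIN_HP + 1;
          int lcap = j - 1 - (em.max_loop - b1);
          if (lcap > lmin) lmin = lcap;
          for (int l = j - 1; l >= lmin; --l) {
            int pckl = T.pc[IX(k, l)];
            if (pckl < 0 || T.V[IX(k, l)] >= INF_E) continue;
            int b2 = j - l - 1;
            double e;
            if (b1 == 0 && b2 == 0)
              e = em.stack[pcij][pckl];
            else
              e = interior_energy(em, b1, b2) + au + au_pen(em, pckl);
            e += T.V[IX(k, l)];
            if (e < best) best = e;
          }
        }
        // multiloop: last branch starts at k, >=1 branch in (i+1 .. k-1)
        for (int k = i + 2; k <= j - MIN_HP - 2; ++k) {
          double mleft = T.M[IX(i + 1, k - 1)];
          double m1r = T.M1[IX(k, j - 1)];
          if (mleft >= INF_E || m1r >= INF_E) continue;
          double e = em.ml_a + em.ml_b + au + mleft + m1r;
          if (e < best) best = e;
        }
        T.V[IX(i, j)] = best;
      }
      // M1: branch starting exactly at i, trailing unpaired to j
      {
        double best = INF_E;
        if (j > i && T.M1[IX(i, j - 1)] < INF_E)
          best = T.M1[IX(i, j - 1)] + em.ml_c;
        if (pcij >= 0 && T.V[IX(i, j)] < INF_E) {
          double e = T.V[IX(i, j)] + em.ml_b + au_pen(em, pcij);
          if (e < best) best = e;
        }
        T.M1[IX(i, j)] = best;
      }
      // M: >=1 branch, arbitrary unpaired
      {
        double best = T.M1[IX(i, j)];
        if (j > i) {
          double e = T.M[IX(i + 1, j)];
          if (e < INF_E && e + em.ml_c < best) best = e + em.ml_c;
        }
        for (int k = i + 1; k <= j - MIN_HP - 1; ++k) {
          double ml = T.M[IX(i, k - 1)], mr = T.M1[IX(k, j)];
          if (ml < INF_E && mr < INF_E && ml + mr < best) best = ml + mr;
        }
        T.M[IX(i, j)] = best;
      }
    }
  }
  // exterior
  for (int j = 0; j < n; ++j) {
    double best = T.W[j];  // j unpaired (W is 1-offset: W[j] = prefix [0..j-1])
    for (int i = 0; i + MIN_HP + 1 <= j; ++i) {
      int pcij = T.pc[IX(i, j)];
      if (pcij < 0 || T.V[IX(i, j)] >= INF_E) continue;
      double e = T.W[i] + T.V[IX(i, j)] + au_pen(em, pcij);
      if (e < best) best = e;
    }
    T.W[j + 1] = best;
  }
  T.energy = n > 0 ? T.W[n] : 0.0;
#undef IX
}

// MFE traceback; ties prefer unpaired, then candidates in fixed scan order.
static void traceback_mfe(const std::vector<int>& s, const EnergyModel& em,
                          const MfeTables& T, std::vector<int>& pi,
                          std::vector<int>& pj) {
  int n = T.n;
  const double eps = 1e-9;
#define IX(i, j) ((size_t)(i) * n + (j))
  enum St { EXT, PAIR, MM, MM1 };
  std::vector<std::tuple<int, int, int> > stk;
  stk.push_back(std::make_tuple((int)EXT, 0, n));  // W over prefix length n
  while (!stk.empty()) {
    int st = std::get<0>(stk.back());
    int a = std::get<1>(stk.back());
    int b = std::get<2>(stk.back());
    stk.pop_back();
    if (st == EXT) {
      int j = b;  // prefix [0 .. j-1]
      while (j > 0) {
        if (T.W[j - 1] <= T.W[j] + eps) { --j; continue; }
        bool done = false;
        for (int i = 0; i + MIN_HP + 1 <= j - 1; ++i) {
          int pcij = T.pc[IX(i, j - 1)];
          if (pcij < 0 || T.V[IX(i, j - 1)] >= INF_E) continue;
          if (T.W[i] + T.V[IX(i, j - 1)] + au_pen(em, pcij) <= T.W[j] + eps) {
            stk.push_back(std::make_tuple((int)PAIR, i, j - 1));
            j = i;
            done = true;
            break;
          }
        }
        if (!done) --j;  // defensive; should not happen
      }
    } else if (st == PAIR) {
      int i = a, j = b;
      pi.push_back(i);
      pj.push_back(j);
      int pcij = T.pc[IX(i, j)];
      double au = au_pen(em, pcij);
      double tgt = T.V[IX(i, j)];
      if (loop_pen(em.hairpin, j - i - 1, em.ln_coeff) + au <= tgt + eps) continue;
      bool done = false;
      for (int k = i + 1; !done && k <= j - MIN_HP - 2 && k - i - 1 <= em.max_loop; ++k) {
        int b1 = k - i - 1;
        int lmin = k + MIN_HP + 1;
        int lcap = j - 1 - (em.max_loop - b1);
        if (lcap > lmin) lmin = lcap;
        for (int l = j - 1; l >= lmin; --l) {
          int pckl = T.pc[IX(k, l)];
          if (pckl < 0 || T.V[IX(k, l)] >= INF_E) continue;
          int b2 = j - l - 1;
          double e = (b1 == 0 && b2 == 0)
                         ? em.stack[pcij][pckl]
                         : interior_energy(em, b1, b2) + au + au_pen(em, pckl);
          if (e + T.V[IX(k, l)] <= tgt + eps) {
            stk.push_back(std::make_tuple((int)PAIR, k, l));
            done = true;
            break;
          }
        }
      }
      if (done) continue;
      for (int k = i + 2; k <= j - MIN_HP - 2; ++k) {
        double mleft = T.M[IX(i + 1, k - 1)], m1r = T.M1[IX(k, j - 1)];
        if (mleft >= INF_E || m1r >= INF_E) continue;
        if (em.ml_a + em.ml_b + au + mleft + m1r <= tgt + eps) {
          stk.push_back(std::make_tuple((int)MM, i + 1, k - 1));
          stk.push_back(std::make_tuple((int)MM1, k, j - 1));
          break;
        }
      }
    } else if (st == MM1) {
      int i = a, j = b;
      double tgt = T.M1[IX(i, j)];
      // peel trailing unpaired
      while (j > i && T.M1[IX(i, j - 1)] + em.ml_c <= tgt + eps) {
        --j;
        tgt = T.M1[IX(i, j)];
      }
      stk.push_back(std::make_tuple((int)PAIR, i, j));
    } else {  // MM
      int i = a, j = b;
      for (;;) {
        double tgt = T.M[IX(i, j)];
        if (j > i && T.M[IX(i + 1, j)] + em.ml_c <= tgt + eps) { ++i; continue; }
        if (T.M1[IX(i, j)] <= tgt + eps) {
          stk.push_back(std::make_tuple((int)MM1, i, j));
          break;
        }
        bool done = false;
        for (int k = i + 1; k <= j - MIN_HP - 1; ++k) {
          double ml = T.M[IX(i, k - 1)], mr = T.M1[IX(k, j)];
          if (ml < INF_E && mr < INF_E && ml + mr <= tgt + eps) {
            stk.push_back(std::make_tuple((int)MM1, k, j));
            j = k - 1;
            done = true;
            break;
          }
        }
        if (!done) {
          stk.push_back(std::make_tuple((int)MM1, i, j));  // defensive
          break;
        }
      }
    }
  }
#undef IX
}

// [[Rcpp::export(name = "c_mfe_fold")]]
List c_mfe_fold(IntegerVector codes, List par) {
  std::vector<int> s = as<std::vector<int> >(codes);
  EnergyModel em = model_from_list(par);
  MfeTables T;
  fill_mfe(s, em, T);
  std::vector<int> pi, pj;
  // at optimum 0 the empty structure attains it and ties prefer unpaired
  if (T.energy < -1e-12 || T.energy > 1e-12) traceback_mfe(s, em, T, pi, pj);
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    pairs(k, 0) = pi[k] + 1;
    pairs(k, 1) = pj[k] + 1;
  }
  return List::create(_["energy"] = T.energy, _["pairs"] = pairs);
}

// ---------------------------------------------------------------------------
// Partition function tables (scaled linear space)

struct PfTables {
  int n;
  double qsc, lqsc;                    // per-base scale factor, log
  std::vector<double> Qb, QM, QM1;     // n*n, scaled by qsc^len
  std::vector<double> Qpre, Qsuf;      // n+1 each; Qpre[j] = prefix [0..j-1]
  std::vector<double> qpow, upow;      // qsc^k, (exp(-c/RT)*qsc)^k
  std::vector<int> pc;
  double logZ;
};

static void fill_pf(const std::vector<int>& s, const EnergyModel& em,
                    PfTables& P) {
  int n = (int)s.size();
  P.n = n;
  // choose scale from MFE
  MfeTables T;
  fill_mfe(s, em, T);
  double e0 = (n > 0 && T.energy < 0.0) ? 1.07 * T.energy / n : 0.0;
  P.qsc = std::exp(e0 / em.RT);
  P.lqsc = e0 / em.RT;
  P.Qb.assign((size_t)n * n, 0.0);
  P.QM.assign((size_t)n * n, 0.0);
  P.QM1.assign((size_t)n * n, 0.0);
  P.Qpre.assign(n + 1, 0.0);
  P.Qsuf.assign(n + 2, 0.0);
  P.qpow.assign(n + 2, 0.0);
  P.upow.assign(n + 2, 0.0);
  P.pc.assign((size_t)n * n, -1);
  double ec = std::exp(-em.ml_c / em.RT) * P.qsc;
  P.qpow[0] = 1.0;
  P.upow[0] = 1.0;
  for (int k = 1; k <= n + 1; ++k) {
    P.qpow[k] = P.qpow[k - 1] * P.qsc;
    P.upow[k] = P.upow[k - 1] * ec;
  }
  const double RT = em.RT;
#define IX(i, j) ((size_t)(i) * n + (j))
  for (int i = 0; i < n; ++i)
    for (int j = i + MIN_HP + 1; j < n; ++j) P.pc[IX(i, j)] = pair_code(s[i], s[j]);

  for (int i = n - 1; i >= 0; --i) {
    for (int j = i + 1; j < n; ++j) {
      int pcij = P.pc[IX(i, j)];
      if (pcij >= 0) {
        double au = au_pen(em, pcij);
        double q = std::exp(-(loop_pen(em.hairpin, j - i - 1, em.ln_coeff) + au) / RT) *
                   P.qpow[j - i + 1];
        for (int k = i + 1; k <= j - MIN_HP - 2 && k - i - 1 <= em.max_loop; ++k) {
          int b1 = k - i - 1;
          int lmin = k + MIN_HP + 1;
          int lcap = j - 1 - (em.max_loop - b1);
          if (lcap > lmin) lmin = lcap;
          for (int l = j - 1; l >= lmin; --l) {
            int pckl = P.pc[IX(k, l)];
            if (pckl < 0) continue;
            double qb = P.Qb[IX(k, l)];
            if (qb <= 0.0) continue;
            int b2 = j - l - 1;
            double e = (b1 == 0 && b2 == 0)
                           ? em.stack[pcij][pckl]
                           : interior_energy(em, b1, b2) + au + au_pen(em, pckl);
            q += std::exp(-e / RT) * qb * P.qpow[b1 + b2 + 2];
          }
        }
        double mlq = 0.0;
        for (int k = i + 2; k <= j - MIN_HP - 2; ++k) {
          double ml = P.QM[IX(i + 1, k - 1)], mr = P.QM1[IX(k, j - 1)];
          if (ml > 0.0 && mr > 0.0) mlq += ml * mr;
        }
        q += std::exp(-(em.ml_a + em.ml_b + au) / RT) * P.qpow[2] * mlq;
        P.Qb[IX(i, j)] = q;
      }
      // QM1
      {
        double q = (j > i) ? P.QM1[IX(i, j - 1)] * ec : 0.0;
        if (pcij >= 0 && P.Qb[IX(i, j)] > 0.0)
          q += P.Qb[IX(i, j)] * std::exp(-(em.ml_b + au_pen(em, pcij)) / RT);
        P.QM1[IX(i, j)] = q;
      }
      // QM: decompose by start k of the last branch
      {
        double q = 0.0;
        for (int k = i; k <= j - MIN_HP - 1; ++k) {
          double m1 = P.QM1[IX(k, j)];
          if (m1 <= 0.0) continue;
          double before = P.upow[k - i];
          if (k > i) before += P.QM[IX(i, k - 1)];
          q += before * m1;
        }
        P.QM[IX(i, j)] = q;
      }
    }
  }
  // exterior
  P.Qpre[0] = 1.0;
  for (int j = 0; j < n; ++j) {
    double q = P.Qpre[j] * P.qsc;
    for (int i = 0; i + MIN_HP + 1 <= j; ++i) {
      int pcij = P.pc[IX(i, j)];
      if (pcij < 0) continue;
      double qb = P.Qb[IX(i, j)];
      if (qb <= 0.0) continue;
      q += P.Qpre[i] * qb * std::exp(-au_pen(em, pcij) / RT);
    }
    P.Qpre[j + 1] = q;
  }
  P.Qsuf[n] = 1.0;
  for (int i = n - 1; i >= 0; --i) {
    double q = P.Qsuf[i + 1] * P.qsc;
    for (int j = i + MIN_HP + 1; j < n; ++j) {
      int pcij = P.pc[IX(i, j)];
      if (pcij < 0) continue;
      double qb = P.Qb[IX(i, j)];
      if (qb <= 0.0) continue;
      q += qb * std::exp(-au_pen(em, pcij) / RT) * P.Qsuf[j + 1];
    }
    P.Qsuf[i] = q;
  }
  P.logZ = std::log(P.Qpre[n]) - n * P.lqsc;
#undef IX
}

// [[Rcpp::export(name = "c_partition")]]
List c_partition(IntegerVector codes, List par) {
  std::vector<int> s = as<std::vector<int> >(codes);
  EnergyModel em = model_from_list(par);
  PfTables P;
  fill_pf(s, em, P);
  return List::create(_["logZ"] = P.logZ);
}

// [[Rcpp::export(name = "c_basepair_probs")]]
NumericMatrix c_basepair_probs(IntegerVector codes, List par) {
  std::vector<int> s = as<std::vector<int> >(codes);
  EnergyModel em = model_from_list(par);
  int n = (int)s.size();
  PfTables P;
  fill_pf(s, em, P);
  const double RT = em.RT;
  NumericMatrix prob(n, n);
  if (n == 0) return prob;
#define IX(i, j) ((size_t)(i) * n + (j))
  std::vector<double> Ob((size_t)n * n, 0.0);
  double Zt = P.Qpre[n];
  for (int span = n; span >= MIN_HP + 2; --span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      int pcij = P.pc[IX(i, j)];
      if (pcij < 0 || P.Qb[IX(i, j)] <= 0.0) continue;
      double au = au_pen(em, pcij);
      double o = P.Qpre[i] * P.Qsuf[j + 1] * std::exp(-au / RT);
      // enclosed in an interior loop (incl. stack) closed by (h,l)
      for (int h = i - 1; h >= 0 && i - h - 1 <= em.max_loop; --h) {
        int b1 = i - h - 1;
        for (int l = j + 1; l < n && b1 + (l - j - 1) <= em.max_loop; ++l) {
          int pchl = P.pc[IX(h, l)];
          if (pchl < 0) continue;
          double oh = Ob[IX(h, l)];
          if (oh <= 0.0) continue;
          int b2 = l - j - 1;
          double e = (b1 == 0 && b2 == 0)
                         ? em.stack[pchl][pcij]
                         : interior_energy(em, b1, b2) + au + au_pen(em, pchl);
          o += oh * std::exp(-e / RT) * P.qpow[b1 + b2 + 2];
        }
      }
      // enclosed as a branch of a multiloop closed by (h,l)
      double mlsum = 0.0;
      for (int h = 0; h <= i - 1; ++h) {
        for (int l = j + 1; l < n; ++l) {
          int pchl = P.pc[IX(h, l)];
          if (pchl < 0) continue;
          double oh = Ob[IX(h, l)];
          if (oh <= 0.0) continue;
          double uL = P.upow[i - h - 1];
          double uR = P.upow[l - j - 1];
          double qmL = (h + 1 <= i - 1) ? P.QM[IX(h + 1, i - 1)] : 0.0;
          double qmR = (j + 1 <= l - 1) ? P.QM[IX(j + 1, l - 1)] : 0.0;
          double inner = uL * qmR + qmL * uR + qmL * qmR;
          if (inner <= 0.0) continue;
          mlsum += oh * std::exp(-(em.ml_a + em.ml_b + au_pen(em, pchl)) / RT) *
                   P.qpow[2] * inner;
        }
      }
      o += mlsum * std::exp(-(em.ml_b + au) / RT);
      Ob[IX(i, j)] = o;
      double p = P.Qb[IX(i, j)] * o / Zt;
      if (p < 0.0) p = 0.0;
      if (p > 1.0) p = 1.0;
      prob(i, j) = p;
      prob(j, i) = p;
    }
  }
#undef IX
  return prob;
}

// ---------------------------------------------------------------------------
// Stochastic traceback (Boltzmann sampling); uses R's RNG.

// [[Rcpp::export(name = "c_sample_structures")]]
List c_sample_structures(IntegerVector codes, List par, int nsamples) {
  std::vector<int> s = as<std::vector<int> >(codes);
  EnergyModel em = model_from_list(par);
  int n = (int)s.size();
  PfTables P;
  fill_pf(s, em, P);
  const double RT = em.RT;
  double ec = std::exp(-em.ml_c / em.RT) * P.qsc;
#define IX(i, j) ((size_t)(i) * n + (j))
  List out(nsamples);
  enum St { EXT, PAIR, MM, MM1 };
  for (int rep = 0; rep < nsamples; ++rep) {
    std::vector<int> pi, pj;
    std::vector<std::tuple<int, int, int> > stk;
    stk.push_back(std::make_tuple((int)EXT, 0, n));
    while (!stk.empty()) {
      int st = std::get<0>(stk.back());
      int a = std::get<1>(stk.back());
      int b = std::get<2>(stk.back());
      stk.pop_back();
      if (st == EXT) {
        int j = b;  // prefix [0..j-1]
        while (j > 0) {
          double r = unif_rand() * P.Qpre[j];
          r -= P.Qpre[j - 1] * P.qsc;
          if (r < 0) { --j; continue; }
          bool done = false;
          for (int i = 0; i + MIN_HP + 1 <= j - 1; ++i) {
            int pcij = P.pc[IX(i, j - 1)];
            if (pcij < 0) continue;
            double qb = P.Qb[IX(i, j - 1)];
            if (qb <= 0.0) continue;
            r -= P.Qpre[i] * qb * std::exp(-au_pen(em, pcij) / RT);
            if (r < 0) {
              stk.push_back(std::make_tuple((int)PAIR, i, j - 1));
              j = i;
              done = true;
              break;
            }
          }
          if (!done) --j;  // numerical slack: treat as unpaired
        }
      } else if (st == PAIR) {
        int i = a, j = b;
        pi.push_back(i);
        pj.push_back(j);
        int pcij = P.pc[IX(i, j)];
        double au = au_pen(em, pcij);
        double r = unif_rand() * P.Qb[IX(i, j)];
        r -= std::exp(-(loop_pen(em.hairpin, j - i - 1, em.ln_coeff) + au) / RT) *
             P.qpow[j - i + 1];
        if (r < 0) continue;
        bool done = false;
        for (int k = i + 1; !done && k <= j - MIN_HP - 2 && k - i - 1 <= em.max_loop;
             ++k) {
          int b1 = k - i - 1;
          int lmin = k + MIN_HP + 1;
          int lcap = j - 1 - (em.max_loop - b1);
          if (lcap > lmin) lmin = lcap;
          for (int l = j - 1; l >= lmin; --l) {
            int pckl = P.pc[IX(k, l)];
            if (pckl < 0) continue;
            double qb = P.Qb[IX(k, l)];
            if (qb <= 0.0) continue;
            int b2 = j - l - 1;
            double e = (b1 == 0 && b2 == 0)
                           ? em.stack[pcij][pckl]
                           : interior_energy(em, b1, b2) + au + au_pen(em, pckl);
            r -= std::exp(-e / RT) * qb * P.qpow[b1 + b2 + 2];
            if (r < 0) {
              stk.push_back(std::make_tuple((int)PAIR, k, l));
              done = true;
              break;
            }
          }
        }
        if (done) continue;
        double emlc = std::exp(-(em.ml_a + em.ml_b + au) / RT) * P.qpow[2];
        for (int k = i + 2; k <= j - MIN_HP - 2; ++k) {
          double ml = P.QM[IX(i + 1, k - 1)], mr = P.QM1[IX(k, j - 1)];
          if (ml <= 0.0 || mr <= 0.0) continue;
          r -= emlc * ml * mr;
          if (r < 0) {
            stk.push_back(std::make_tuple((int)MM, i + 1, k - 1));
            stk.push_back(std::make_tuple((int)MM1, k, j - 1));
            done = true;
            break;
          }
        }
        // if numerical slack remains, leave as hairpin (no children)
      } else if (st == MM1) {
        int i = a, j = b;
        double r = unif_rand() * P.QM1[IX(i, j)];
        int lsel = -1;
        for (int l = j; l >= i + MIN_HP + 1; --l) {
          int pcil = P.pc[IX(i, l)];
          if (pcil < 0) continue;
          double qb = P.Qb[IX(i, l)];
          if (qb <= 0.0) continue;
          r -= qb * std::exp(-(em.ml_b + au_pen(em, pcil)) / RT) * P.upow[j - l];
          if (r < 0) { lsel = l; break; }
        }
        if (lsel < 0) {  // numerical slack: pick the largest feasible l
          for (int l = j; l >= i + MIN_HP + 1; --l)
            if (P.pc[IX(i, l)] >= 0 && P.Qb[IX(i, l)] > 0.0) { lsel = l; break; }
        }
        if (lsel >= 0) stk.push_back(std::make_tuple((int)PAIR, i, lsel));
      } else {  // MM
        int i = a, j = b;
        double r = unif_rand() * P.QM[IX(i, j)];
        for (int k = i; k <= j - MIN_HP - 1; ++k) {
          double m1 = P.QM1[IX(k, j)];
          if (m1 <= 0.0) continue;
          double t1 = P.upow[k - i] * m1;
          r -= t1;
          if (r < 0) {
            stk.push_back(std::make_tuple((int)MM1, k, j));
            break;
          }
          if (k > i) {
            double t2 = P.QM[IX(i, k - 1)] * m1;
            r -= t2;
            if (r < 0) {
              stk.push_back(std::make_tuple((int)MM, i, k - 1));
              stk.push_back(std::make_tuple((int)MM1, k, j));
              break;
            }
          }
        }
      }
    }
    IntegerMatrix pairs(pi.size(), 2);
    for (size_t k = 0; k < pi.size(); ++k) {
      pairs(k, 0) = pi[k] + 1;
      pairs(k, 1) = pj[k] + 1;
    }
    out[rep] = pairs;
  }
#undef IX
  (void)ec;
  return out;
}

// ---------------------------------------------------------------------------
// Interval DP maximizing sum of pair gains + unpaired gains (MEA / centroid).
// gain: n x n matrix (upper triangle used); up: length-n unpaired gains.
// Ties prefer leaving a base unpaired, then the pair with smallest j.

// [[Rcpp::export(name = "c_max_weight_struct")]]
List c_max_weight_struct(NumericMatrix gain, NumericVector up) {
  int n = gain.nrow();
  std::vector<double> W((size_t)n * n, 0.0);
#define IX(i, j) ((size_t)(i) * n + (j))
  const double eps = 1e-12;
  for (int i = n - 1; i >= 0; --i) {
    for (int j = i; j < n; ++j) {
      double best = up[i] + ((i + 1 <= j) ? W[IX(i + 1, j)] : 0.0);
      for (int k = i + MIN_HP + 1; k <= j; ++k) {
        double v = gain(i, k);
        if (i + 1 <= k - 1) v += W[IX(i + 1, k - 1)];
        if (k + 1 <= j) v += W[IX(k + 1, j)];
        if (v > best) best = v;
      }
      W[IX(i, j)] = best;
    }
  }
  double score = n > 0 ? W[IX(0, n - 1)] : 0.0;
  std::vector<int> pi, pj;
  std::vector<std::pair<int, int> > stk;
  if (n > 0) stk.push_back(std::make_pair(0, n - 1));
  while (!stk.empty()) {
    int i = stk.back().first, j = stk.back().second;
    stk.pop_back();
    while (i <= j) {
      double tgt = W[IX(i, j)];
      double unp = up[i] + ((i + 1 <= j) ? W[IX(i + 1, j)] : 0.0);
      if (unp >= tgt - eps) { ++i; continue; }
      bool done = false;
      for (int k = i + MIN_HP + 1; k <= j; ++k) {
        double v = gain(i, k);
        if (i + 1 <= k - 1) v += W[IX(i + 1, k - 1)];
        if (k + 1 <= j) v += W[IX(k + 1, j)];
        if (v >= tgt - eps) {
          pi.push_back(i);
          pj.push_back(k);
          if (k + 1 <= j) stk.push_back(std::make_pair(k + 1, j));
          j = k - 1;
          ++i;
          done = true;
          break;
        }
      }
      if (!done) ++i;  // defensive
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) {
    pairs(k, 0) = pi[k] + 1;
    pairs(k, 1) = pj[k] + 1;
  }
  return List::create(_["score"] = score, _["pairs"] = pairs);
#undef IX
}

// ---------------------------------------------------------------------------
// Banded global alignment of two symbol strings (used for the dot-bracket
// similarity stand-in). Linear gap penalty. Returns 1-based column maps.

// [[Rcpp::export(name = "c_band_align")]]
List c_band_align(IntegerVector a, IntegerVector b, int band,
                  double match, double mismatch, double gap) {
  int na = a.size(), nb = b.size();
  if (band < std::abs(na - nb) + 1) band = std::abs(na - nb) + 1;
  const double NEG = -1e17;
  // dp[i][j] over (0..na) x (0..nb), banded: |i - j| <= band
  std::vector<std::vector<double> > dp(na + 1, std::vector<double>(nb + 1, NEG));
  std::vector<std::vector<char> > tb(na + 1, std::vector<char>(nb + 1, 0));
  dp[0][0] = 0.0;
  for (int j = 1; j <= nb && j <= band; ++j) { dp[0][j] = j * gap; tb[0][j] = 2; }
  for (int i = 1; i <= na; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(nb, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      if (i == 0 && j == 0) continue;
      double best = NEG; char how = 0;
      if (j == 0) { best = i * gap; how = 1; }
      else {
        if (dp[i - 1][j - 1] > NEG / 2) {
          double d = dp[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
          if (d > best) { best = d; how = 3; }
        }
        if (dp[i - 1][j] > NEG / 2 && dp[i - 1][j] + gap > best) {
          best = dp[i - 1][j] + gap; how = 1;
        }
        if (dp[i][j - 1] > NEG / 2 && dp[i][j - 1] + gap > best) {
          best = dp[i][j - 1] + gap; how = 2;
        }
      }
      dp[i][j] = best; tb[i][j] = how;
    }
  }
  // traceback
  std::vector<int> colA(na), colB(nb);
  int i = na, j = nb, col = 0;
  std::vector<std::pair<char, int> > ops;
  while (i > 0 || j > 0) {
    char how = tb[i][j];
    if (how == 0) how = (i > 0) ? 1 : 2;  // defensive
    ops.push_back(std::make_pair(how, 0));
    if (how == 3) { --i; --j; }
    else if (how == 1) { --i; }
    else { --j; }
  }
  int ncol = (int)ops.size();
  i = 0; j = 0; col = 0;
  for (int k = ncol - 1; k >= 0; --k) {
    ++col;
    char how = ops[k].first;
    if (how == 3) { colA[i++] = col; colB[j++] = col; }
    else if (how == 1) { colA[i++] = col; }
    else { colB[j++] = col; }
  }
  return List::create(_["ncol"] = ncol, _["mapA"] = IntegerVector(colA.begin(), colA.end()),
                      _["mapB"] = IntegerVector(colB.begin(), colB.end()));
}
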