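#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Read-stack likelihoods P(reads | g) for g = 0, 1, 2 alternate alleles.
// Reads are independent; an alt read is seen with probability
// p(1 - eps) + (1 - p) eps where p = g / 2.
static inline void read_likelihoods(double refc, double altc, double eps,
                                    double* L) {
  for (int g = 0; g < 3; ++g) {
    double p = 0.5 * g;
    double pa = p * (1.0 - eps) + (1.0 - p) * eps;
    L[g] = std::pow(pa, altc) * std::pow(1.0 - pa, refc);
  }
}

struct Workspace {
  std::vector<double> f;     // T x KK scaled forward
  std::vector<double> E;     // T x KK emissions
  std::vector<double> Lmat;  // T x 3 read likelihoods
  std::vector<double> c;     // T scaling constants
  std::vector<char> hasread; // T flags
  std::vector<double> beta, bnew, gamma, M, f1, f2, g1, g2;
  std::vector<double> Ma1, Ma2, Mf1, Mf2;
  void resize(int T, int K) {
    int KK = K * K;
    f.assign((size_t)T * KK, 0.0);
    E.assign((size_t)T * KK, 0.0);
    Lmat.assign((size_t)T * 3, 0.0);
    c.assign(T, 0.0);
    hasread.assign(T, 0);
    beta.assign(KK, 0.0); bnew.assign(KK, 0.0);
    gamma.assign(KK, 0.0); M.assign(KK, 0.0);
    f1.assign(K, 0.0); f2.assign(K, 0.0);
    g1.assign(K, 0.0); g2.assign(K, 0.0);
    Ma1.assign(K, 0.0); Ma2.assign(K, 0.0);
    Mf1.assign(K, 0.0); Mf2.assign(K, 0.0);
  }
};

// Forward-backward for one sample.  The hidden state is an ordered pair of
// ancestral haplotypes; the two copying chains jump independently across
// each interval with probability rho (rho = 1 resets them at chromosome
// boundaries), landing on haplotype k with probability alpha[k].  The
// emission marginalises the two latent allele copies (Bernoulli in the
// haplotype dosages theta) over the read-stack likelihood.  Scaled
// recursions; the returned log-likelihood is exact.  Optionally
// accumulates EM sufficient statistics (num/den for theta, expected
// copying usage, expected jump landings for alpha) and per-site genotype
// posteriors.
static double fb_one_sample(const double* refc, const double* altc, int T,
                            const double* theta, int K, const double* rho,
                            const double* alpha, double eps, Workspace& W,
                            double* num, double* den,        // K x T or NULL
                            double* usage,                    // K or NULL
                            double* jump,                     // K or NULL
                            double* gamma_out,                // KK x T or NULL
                            double* gp,                       // 3 x T or NULL
                            double* dosage) {                 // T or NULL
  const int KK = K * K;
  W.resize(T, K);
  double loglik = 0.0;

  // ---- forward ----
  for (int t = 0; t < T; ++t) {
    double* Lt = &W.Lmat[(size_t)t * 3];
    bool has = (refc[t] > 0.0 || altc[t] > 0.0);
    W.hasread[t] = has;
    double* Et = &W.E[(size_t)t * KK];
    const double* th = theta + (size_t)t * K;
    if (has) {
      read_likelihoods(refc[t], altc[t], eps, Lt);
      // e = c0 + cs (th1 + th2) + cx th1 th2, hoisted over k2
      double c0 = Lt[0], cs = Lt[1] - Lt[0];
      double cx = Lt[0] - 2.0 * Lt[1] + Lt[2];
      for (int k2 = 0; k2 < K; ++k2) {
        double a = c0 + cs * th[k2];
        double b = cs + cx * th[k2];
        double* row = Et + k2 * K;
        for (int k1 = 0; k1 < K; ++k1) row[k1] = a + b * th[k1];
      }
    } else {
      Lt[0] = Lt[1] = Lt[2] = 1.0;
      for (int i = 0; i < KK; ++i) Et[i] = 1.0;
    }

    double* ft = &W.f[(size_t)t * KK];
    double ct = 0.0;
    if (t == 0) {
      for (int k2 = 0; k2 < K; ++k2) {
        double a2 = alpha[k2];
        double* row = ft + k2 * K;
        const double* erow = Et + k2 * K;
        for (int k1 = 0; k1 < K; ++k1) row[k1] = alpha[k1] * a2 * erow[k1];
      }
    } else {
      const double* fp = &W.f[(size_t)(t - 1) * KK];
      double r = rho[t - 1], s = 1.0 - r;
      double s2 = s * s, sr = s * r, rr = r * r;
      for (int k = 0; k < K; ++k) { W.f1[k] = 0.0; W.f2[k] = 0.0; }
      for (int k2 = 0; k2 < K; ++k2) {
        const double* row = fp + k2 * K;
        double rowsum = 0.0;
        for (int k1 = 0; k1 < K; ++k1) {
          W.f1[k1] += row[k1];
          rowsum += row[k1];
        }
        W.f2[k2] = rowsum;
      }
      for (int k2 = 0; k2 < K; ++k2) {
        double u = sr * alpha[k2];
        double w2 = sr * W.f2[k2] + rr * alpha[k2];
        const double* frow = fp + k2 * K;
        const double* erow = Et + k2 * K;
        double* row = ft + k2 * K;
        for (int k1 = 0; k1 < K; ++k1)
          row[k1] = (s2 * frow[k1] + u * W.f1[k1] + w2 * alpha[k1])
            * erow[k1];
      }
    }
    for (int i = 0; i < KK; ++i) ct += ft[i];
    if (ct <= 0.0) stop("zero forward probability at site %d", t + 1);
    double inv = 1.0 / ct;
    for (int i = 0; i < KK; ++i) ft[i] *= inv;
    W.c[t] = ct;
    loglik += std::log(ct);
  }

  // ---- backward, accumulating statistics as gamma becomes available ----
  for (int i = 0; i < KK; ++i) W.beta[i] = 1.0;
  for (int t = T - 1; t >= 0; --t) {
    const double* ft = &W.f[(size_t)t * KK];
    double gsum = 0.0;
    for (int i = 0; i < KK; ++i) {
      W.gamma[i] = ft[i] * W.beta[i];
      gsum += W.gamma[i];
    }
    double ginv = 1.0 / gsum;
    for (int i = 0; i < KK; ++i) W.gamma[i] *= ginv;
    if (gamma_out)
      for (int i = 0; i < KK; ++i) gamma_out[(size_t)t * KK + i] = W.gamma[i];

    const double* th = theta + (size_t)t * K;
    const double* Lt = &W.Lmat[(size_t)t * 3];
    const double* Et = &W.E[(size_t)t * KK];

    // chain marginals of gamma, reused by several accumulators
    for (int k = 0; k < K; ++k) { W.g1[k] = 0.0; W.g2[k] = 0.0; }
    for (int k2 = 0; k2 < K; ++k2) {
      const double* row = &W.gamma[k2 * K];
      double rowsum = 0.0;
      for (int k1 = 0; k1 < K; ++k1) {
        W.g1[k1] += row[k1];
        rowsum += row[k1];
      }
      W.g2[k2] = rowsum;
    }

    if (gp || dosage) {
      double g0 = 0.0, g2v = 0.0, ds = 0.0;
      for (int k2 = 0; k2 < K; ++k2) {
        double th2 = th[k2];
        const double* row = &W.gamma[k2 * K];
        for (int k1 = 0; k1 < K; ++k1) {
          double g = row[k1], th1 = th[k1];
          g0 += g * (1.0 - th1) * (1.0 - th2);
          g2v += g * th1 * th2;
          ds += g * (th1 + th2);
        }
      }
      if (gp) {
        double g1v = 1.0 - g0 - g2v;
        if (g1v < 0.0) g1v = 0.0;
        double tot = g0 + g1v + g2v;
        gp[(size_t)t * 3 + 0] = g0 / tot;
        gp[(size_t)t * 3 + 1] = g1v / tot;
        gp[(size_t)t * 3 + 2] = g2v / tot;
      }
      if (dosage) dosage[t] = ds;
    }

    if (num && den) {
      double* numt = num + (size_t)t * K;
      double* dent = den + (size_t)t * K;
      if (!W.hasread[t]) {
        // no reads: each chain's allele responsibility is its haplotype's
        // own dosage, so only the marginals matter
        for (int k = 0; k < K; ++k) {
          double m = W.g1[k] + W.g2[k];
          numt[k] += m * th[k];
          dent[k] += m;
        }
      } else {
        double L1 = Lt[1], L2 = Lt[2];
        for (int k2 = 0; k2 < K; ++k2) {
          double th2 = th[k2];
          double p = L1 * (1.0 - th2);        // pa1 = th1 (p + th2 L2) / e
          double q = th2 * L2;
          const double* grow = &W.gamma[k2 * K];
          const double* erow = Et + k2 * K;
          for (int k1 = 0; k1 < K; ++k1) {
            double g = grow[k1];
            if (g == 0.0) continue;
            double th1 = th[k1];
            double inv_e = g / erow[k1];
            double n1 = th1 * (p + q) * inv_e;
            double n2 = th2 * (L1 * (1.0 - th1) + th1 * L2) * inv_e;
            numt[k1] += n1;
            numt[k2] += n2;
          }
          for (int k1 = 0; k1 < K; ++k1) {
            dent[k1] += grow[k1];
            dent[k2] += grow[k1];
          }
        }
      }
    }

    if (usage)
      for (int k = 0; k < K; ++k) usage[k] += W.g1[k] + W.g2[k];

    if (jump && t == 0)
      // the initial draw from alpha counts as a landing for both chains
      for (int k = 0; k < K; ++k) jump[k] += W.g1[k] + W.g2[k];

    if (t == 0) break;

    // transition step of the backward recursion (interval t-1 -> t)
    double r = rho[t - 1], s = 1.0 - r;
    double inv_ct = 1.0 / W.c[t];
    if (W.hasread[t]) {
      for (int i = 0; i < KK; ++i)
        W.M[i] = W.E[(size_t)t * KK + i] * W.beta[i];
    } else {
      std::copy(W.beta.begin(), W.beta.end(), W.M.begin());
    }
    for (int k = 0; k < K; ++k) { W.Ma1[k] = 0.0; W.Ma2[k] = 0.0; }
    double S = 0.0;
    for (int l2 = 0; l2 < K; ++l2) {
      double a2 = alpha[l2];
      const double* row = &W.M[l2 * K];
      double acc = 0.0;
      for (int l1 = 0; l1 < K; ++l1) {
        W.Ma1[l1] += a2 * row[l1];
        acc += alpha[l1] * row[l1];
      }
      W.Ma2[l2] = acc;
      S += a2 * acc;
    }

    if (jump && r > 0.0) {
      // expected landings of each chain's jump across this interval:
      // J1(l1) = r a(l1)/c * (s sum_l2 f2(l2) M(l1,l2) + r Ma1(l1)),
      // J2 symmetrically
      const double* fp = &W.f[(size_t)(t - 1) * KK];
      for (int k = 0; k < K; ++k) { W.f1[k] = 0.0; W.f2[k] = 0.0; }
      for (int k2 = 0; k2 < K; ++k2) {
        const double* row = fp + k2 * K;
        double rowsum = 0.0;
        for (int k1 = 0; k1 < K; ++k1) {
          W.f1[k1] += row[k1];
          rowsum += row[k1];
        }
        W.f2[k2] = rowsum;
      }
      for (int k = 0; k < K; ++k) { W.Mf1[k] = 0.0; W.Mf2[k] = 0.0; }
      for (int l2 = 0; l2 < K; ++l2) {
        double fl2 = W.f2[l2];
        const double* row = &W.M[l2 * K];
        double acc = 0.0;
        for (int l1 = 0; l1 < K; ++l1) {
          W.Mf2[l1] += fl2 * row[l1];
          acc += W.f1[l1] * row[l1];
        }
        W.Mf1[l2] = acc;
      }
      double rs = r * s * inv_ct, rr = r * r * inv_ct;
      for (int k = 0; k < K; ++k) {
        jump[k] += alpha[k] * (rs * W.Mf2[k] + rr * W.Ma1[k]);
        jump[k] += alpha[k] * (rs * W.Mf1[k] + rr * W.Ma2[k]);
      }
    }

    double s2 = s * s, sr = s * r, rrS = r * r * S;
    for (int k2 = 0; k2 < K; ++k2) {
      double add2 = sr * W.Ma2[k2] + rrS;
      const double* mrow = &W.M[k2 * K];
      double* brow = &W.bnew[k2 * K];
      for (int k1 = 0; k1 < K; ++k1)
        brow[k1] = (s2 * mrow[k1] + sr * W.Ma1[k1] + add2) * inv_ct;
    }
    std::swap(W.beta, W.bnew);
  }

  return loglik;
}

// [[Rcpp::export(name = ".fb_diploid_cpp")]]
List fb_diploid_cpp(NumericVector refc, NumericVector altc,
                    NumericMatrix theta, NumericVector rho,
                    NumericVector alpha, double eps) {
  int T = refc.size();
  int K = theta.nrow();
  if (theta.ncol() != T) stop("theta must be K x T");
  if (rho.size() != T - 1) stop("rho must have length T - 1");
  Workspace W;
  NumericVector gamma(Dimension(K, K, T));
  double ll = fb_one_sample(REAL(refc), REAL(altc), T, REAL(theta), K,
                            REAL(rho), REAL(alpha), eps, W,
                            NULL, NULL, NULL, NULL, REAL(gamma), NULL, NULL);
  return List::create(_["gamma"] = gamma, _["loglik"] = ll);
}

// One E-pass over all samples: accumulates the EM sufficient statistics and
// optionally the per-sample genotype posteriors.  refc/altc are N x T.
// [[Rcpp::export(name = ".em_pass_cpp")]]
List em_pass_cpp(NumericMatrix refc, NumericMatrix altc, NumericMatrix theta,
                 NumericVector rho, NumericVector alpha, double eps,
                 bool want_output) {
  int N = refc.nrow(), T = refc.ncol();
  int K = theta.nrow();
  if (theta.ncol() != T) stop("theta must be K x T");
  if (rho.size() != T - 1) stop("rho must have length T - 1");
  NumericMatrix num(K, T), den(K, T);
  NumericVector usage(K), jump(K), loglik(N);
  NumericMatrix gp0, gp1, gp2, dosage;
  if (want_output) {
    gp0 = NumericMatrix(N, T); gp1 = NumericMatrix(N, T);
    gp2 = NumericMatrix(N, T); dosage = NumericMatrix(N, T);
  }
  Workspace W;
  std::vector<double> rvec(T), avec(T), gpbuf((size_t)T * 3), dsbuf(T);
  for (int i = 0; i < N; ++i) {
    for (int t = 0; t < T; ++t) { rvec[t] = refc(i, t); avec[t] = altc(i, t); }
    loglik[i] = fb_one_sample(&rvec[0], &avec[0], T, REAL(theta), K,
                              REAL(rho), REAL(alpha), eps, W,
                              REAL(num), REAL(den), REAL(usage), REAL(jump),
                              NULL,
                              want_output ? &gpbuf[0] : NULL,
                              want_output ? &dsbuf[0] : NULL);
    if (want_output)
      for (int t = 0; t < T; ++t) {
        gp0(i, t) = gpbuf[(size_t)t * 3 + 0];
        gp1(i, t) = gpbuf[(size_t)t * 3 + 1];
        gp2(i, t) = gpbuf[(size_t)t * 3 + 2];
        dosage(i, t) = dsbuf[t];
      }
  }
  List out = List::create(_["loglik"] = loglik, _["num"] = num,
                          _["den"] = den, _["usage"] = usage,
                          _["jump"] = jump);
  if (want_output) {
    out["gp0"] = gp0; out["gp1"] = gp1; out["gp2"] = gp2;
    out["dosage"] = dosage;
  }
  return out;
}
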