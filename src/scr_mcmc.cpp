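// Metropolis-within-Gibbs sampler for the multi-strata random-thinning
// spatial capture-recapture model with data augmentation.
//
// Model (per stratum, K occasions collapsed to summed counts):
//   s_i  ~ Categorical( lambda(cell) / sum lambda ),  lambda(c) = exp(b1*A + b2*A^2)
//   z_i  ~ Bernoulli(psi), observed individuals fixed at z = 1
//   sex_i~ Bernoulli(p_male)
//   lam_ij = lam0_{sex_i}(j) * exp(-d2(s_i, j) / (2 sigma_sex^2)),
//            lam0 = exp(aF*[F] + b*eff + c*eff^2), exactly 0 where effort = 0
//   Y_ij | z_i = 1 ~ Poisson(K * theta * lam_ij)          (identified)
//   C_j          ~ Poisson(K * (1-theta) * Lambda_j),  Lambda_j = sum_i z_i lam_ij
// sigma_F, sigma_M are shared across strata; all other parameters are
// stratum-specific. Continuous parameters move by adaptive Gaussian
// random walks on transformed scales (log sigma, logit for probabilities)
// with the matching Jacobians; z, inactive s and latent sexes are Gibbs
// updates; active s moves by a Hastings-corrected neighbourhood proposal.
//
// All randomness comes from R's RNG (unif_rand / norm_rand), so chains
// are bit-reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double COEF_SD = 3.0;     // Normal prior sd on coefficients
static const double SIG_LO = 0.1, SIG_HI = 20.0;  // Uniform prior on sigma

struct Stratum {
  int J, K, M, n_obs;
  NumericMatrix D2;                 // J x J squared centroid distances
  std::vector<double> alt, eff;     // standardized covariates
  std::vector<int> eff_pos;         // effort > 0 indicator
  std::vector<std::vector<int>> ycells;     // per observed ind, cells hit
  std::vector<std::vector<double>> ycounts; // matching summed counts
  std::vector<double> C;            // unidentified counts per cell (summed)
  std::vector<int> cpos;            // cells with C > 0
  double Ytot, Ctot;
  std::vector<std::vector<int>> nbr;  // neighbourhood for s proposals

  // state
  std::vector<int> z, s, sex;       // sex: 0 = F, 1 = M
  std::vector<int> sex_known;       // 1 = fixed by data
  double beta1, beta2, aF, bEff, cEff, psi, theta, pmale;

  // caches
  std::vector<double> lam0F, lam0M;     // J
  std::vector<double> logpi;            // log intensity, normalized
  std::vector<double> pi_cum;           // cumulative for Gibbs draws
  std::vector<double> Kg;               // M x J kernel rows (row-major)
  std::vector<double> KgFsum, KgMsum;   // kernel-row sums of active, by sex
  std::vector<double> tmp_row, tmp_row2;
  std::vector<double> sigbuf;           // scratch rows for sigma proposals
};

static inline double runif1() { return unif_rand(); }
static inline double rnorm1() { return norm_rand(); }

static void rebuild_lam0(Stratum &st) {
  for (int j = 0; j < st.J; ++j) {
    if (!st.eff_pos[j]) { st.lam0F[j] = 0.0; st.lam0M[j] = 0.0; continue; }
    double lp = st.bEff * st.eff[j] + st.cEff * st.eff[j] * st.eff[j];
    st.lam0M[j] = std::exp(lp);
    st.lam0F[j] = std::exp(lp + st.aF);
  }
}

static void rebuild_pi(Stratum &st) {
  double mx = R_NegInf;
  for (int j = 0; j < st.J; ++j) {
    double lp = st.beta1 * st.alt[j] + st.beta2 * st.alt[j] * st.alt[j];
    st.logpi[j] = lp;
    if (lp > mx) mx = lp;
  }
  double sum = 0.0;
  for (int j = 0; j < st.J; ++j) sum += std::exp(st.logpi[j] - mx);
  double lse = mx + std::log(sum);
  double cum = 0.0;
  for (int j = 0; j < st.J; ++j) {
    st.logpi[j] -= lse;
    cum += std::exp(st.logpi[j]);
    st.pi_cum[j] = cum;
  }
}

static inline void kernel_row(const Stratum &st, int cell, double sigma,
                              double *out) {
  const double inv = 1.0 / (2.0 * sigma * sigma);
  const double *d2 = &st.D2(0, cell);   // column `cell` (symmetric matrix)
  // beyond 40 log-units the kernel is < 5e-18: numerically inert in every
  // accumulated sum, so skip the exp call
  for (int j = 0; j < st.J; ++j) {
    double a = d2[j] * inv;
    out[j] = (a > 40.0) ? 0.0 : std::exp(-a);
  }
}

// Refresh active-row caches and the by-sex row sums from scratch.
static void refresh_rows(Stratum &st, double sigF, double sigM) {
  std::fill(st.KgFsum.begin(), st.KgFsum.end(), 0.0);
  std::fill(st.KgMsum.begin(), st.KgMsum.end(), 0.0);
  for (int i = 0; i < st.M; ++i) {
    if (!st.z[i]) continue;
    double sg = st.sex[i] ? sigM : sigF;
    kernel_row(st, st.s[i], sg, &st.Kg[(size_t)i * st.J]);
    std::vector<double> &dst = st.sex[i] ? st.KgMsum : st.KgFsum;
    const double *row = &st.Kg[(size_t)i * st.J];
    for (int j = 0; j < st.J; ++j) dst[j] += row[j];
  }
}

// Lambda_j (active encounter-rate sum) at one cell, from caches.
static inline double Lam_at(const Stratum &st, int j) {
  return st.lam0F[j] * st.KgFsum[j] + st.lam0M[j] * st.KgMsum[j];
}

// S = sum_j Lambda_j = total expected per-occasion encounter rate.
static double total_S(const Stratum &st) {
  double S = 0.0;
  for (int j = 0; j < st.J; ++j) S += Lam_at(st, j);
  return S;
}

// Detection log-likelihood kernel of one stratum given current caches:
//   sum_y Y * log(K * theta * lam) + sum_c C * log(K * (1-theta) * Lambda)
//   - K * S
static double det_loglik(const Stratum &st) {
  double ll = 0.0;
  const double lth = std::log(st.K * st.theta);
  for (int i = 0; i < st.n_obs; ++i) {
    const double *row = &st.Kg[(size_t)i * st.J];
    const std::vector<double> &l0 = st.sex[i] ? st.lam0M : st.lam0F;
    for (size_t t = 0; t < st.ycells[i].size(); ++t) {
      int j = st.ycells[i][t];
      double lam = l0[j] * row[j];
      ll += st.ycounts[i][t] * (lth + std::log(lam));
    }
  }
  const double lct = std::log(st.K * (1.0 - st.theta));
  for (size_t t = 0; t < st.cpos.size(); ++t) {
    int j = st.cpos[t];
    ll += st.C[j] * (lct + std::log(Lam_at(st, j)));
  }
  ll -= st.K * total_S(st);
  return ll;
}

// Full log kernel (detection + point process + z + sex + priors local to
// the stratum). Shared sigma priors are added by the caller.
static double stratum_log_kernel(const Stratum &st) {
  double ll = det_loglik(st);
  int n1 = 0, nm = 0;
  for (int i = 0; i < st.M; ++i) {
    ll += st.logpi[st.s[i]];
    n1 += st.z[i];
    nm += st.sex[i];
  }
  ll += n1 * std::log(st.psi) + (st.M - n1) * std::log(1.0 - st.psi);
  ll += nm * std::log(st.pmale) + (st.M - nm) * std::log(1.0 - st.pmale);
  ll += R::dnorm(st.beta1, 0.0, COEF_SD, 1) + R::dnorm(st.beta2, 0.0, COEF_SD, 1);
  ll += R::dnorm(st.aF, 0.0, COEF_SD, 1) + R::dnorm(st.bEff, 0.0, COEF_SD, 1) +
        R::dnorm(st.cEff, 0.0, COEF_SD, 1);
  return ll;
}

struct Adapt {
  double ls;      // log proposal sd
  double n_prop = 0.0, n_acc = 0.0;
  explicit Adapt(double ls0 = -1.0) : ls(ls0) {}
  void tune(bool acc, int iter, int burnin) {
    n_prop += 1.0; if (acc) n_acc += 1.0;
    if (iter < burnin) {
      double step = std::min(0.25, 2.0 / std::sqrt((double)iter + 1.0));
      ls += step * ((acc ? 1.0 : 0.0) - 0.44);
      if (ls < -8.0) ls = -8.0;
      if (ls > 4.0) ls = 4.0;
    }
  }
};

// [[Rcpp::export]]
List scr_mcmc_chain(List strata_data, List init, int n_iter, int burnin,
                    bool store_surface = true) {
  int n_str = strata_data.size();
  std::vector<Stratum> st(n_str);

  for (int k = 0; k < n_str; ++k) {
    List d = strata_data[k];
    Stratum &s = st[k];
    s.D2 = as<NumericMatrix>(d["D2"]);
    s.J = s.D2.nrow();
    s.K = as<int>(d["K"]);
    s.M = as<int>(d["M"]);
    s.alt = as<std::vector<double>>(d["alt"]);
    s.eff = as<std::vector<double>>(d["eff"]);
    s.eff_pos = as<std::vector<int>>(d["eff_pos"]);
    List yc = d["ycells"], yn = d["ycounts"];
    s.n_obs = yc.size();
    s.ycells.resize(s.n_obs); s.ycounts.resize(s.n_obs);
    s.Ytot = 0.0;
    for (int i = 0; i < s.n_obs; ++i) {
      s.ycells[i] = as<std::vector<int>>(yc[i]);
      s.ycounts[i] = as<std::vector<double>>(yn[i]);
      for (double v : s.ycounts[i]) s.Ytot += v;
    }
    s.C = as<std::vector<double>>(d["C"]);
    s.Ctot = 0.0;
    for (int j = 0; j < s.J; ++j)
      if (s.C[j] > 0) { s.cpos.push_back(j); s.Ctot += s.C[j]; }
    List nb = d["nbr"];
    s.nbr.resize(s.J);
    for (int j = 0; j < s.J; ++j) s.nbr[j] = as<std::vector<int>>(nb[j]);

    List in = as<List>(as<List>(init["strata"])[k]);
    s.z = as<std::vector<int>>(in["z"]);
    s.s = as<std::vector<int>>(in["s"]);
    s.sex = as<std::vector<int>>(in["sex"]);
    s.sex_known = as<std::vector<int>>(in["sex_known"]);
    s.beta1 = as<double>(in["beta1"]); s.beta2 = as<double>(in["beta2"]);
    s.aF = as<double>(in["aF"]); s.bEff = as<double>(in["bEff"]);
    s.cEff = as<double>(in["cEff"]);
    s.psi = as<double>(in["psi"]); s.theta = as<double>(in["theta"]);
    s.pmale = as<double>(in["pmale"]);

    s.lam0F.resize(s.J); s.lam0M.resize(s.J);
    s.logpi.resize(s.J); s.pi_cum.resize(s.J);
    s.Kg.assign((size_t)s.M * s.J, 0.0);
    s.KgFsum.resize(s.J); s.KgMsum.resize(s.J);
    s.tmp_row.resize(s.J); s.tmp_row2.resize(s.J);
    s.sigbuf.assign((size_t)s.M * s.J, 0.0);
  }
  double sigF = as<double>(init["sigmaF"]);
  double sigM = as<double>(init["sigmaM"]);

  for (int k = 0; k < n_str; ++k) {
    rebuild_lam0(st[k]);
    rebuild_pi(st[k]);
    refresh_rows(st[k], sigF, sigM);
  }

  // adaptive scales: per stratum {b1, b2, aF, bEff, cEff, psi, theta,
  // pmale}, then shared {sigF, sigM}, and one s-move scale bookkeeping
  std::vector<std::vector<Adapt>> ad(n_str, std::vector<Adapt>(8, Adapt(-1.5)));
  Adapt adSigF(-2.5), adSigM(-2.5);

  int n_par = 11 * n_str + 2;  // per stratum: 8 params + N, Nmale, Nfemale
  int n_store = n_iter - burnin;
  NumericMatrix draws(n_store, n_par);
  std::vector<NumericMatrix> surfT, surfM;
  for (int k = 0; k < n_str; ++k) {
    surfT.push_back(NumericMatrix(st[k].J, 1));
    surfM.push_back(NumericMatrix(st[k].J, 1));
  }

  for (int iter = 0; iter < n_iter; ++iter) {
    for (int k = 0; k < n_str; ++k) {
      Stratum &s = st[k];

      // ---- density coefficients (point-process term only) ----
      for (int p = 0; p < 2; ++p) {
        double cur = p == 0 ? s.beta1 : s.beta2;
        double prop = cur + std::exp(ad[k][p].ls) * rnorm1();
        double ll_cur = 0.0, ll_prop = 0.0;
        // sum over all M of logpi at current s; recompute both normalizers
        double b1c = s.beta1, b2c = s.beta2;
        double b1p = p == 0 ? prop : s.beta1;
        double b2p = p == 1 ? prop : s.beta2;
        double mxc = R_NegInf, mxp = R_NegInf;
        for (int j = 0; j < s.J; ++j) {
          double a = s.alt[j];
          double lc = b1c * a + b2c * a * a, lp = b1p * a + b2p * a * a;
          if (lc > mxc) mxc = lc;
          if (lp > mxp) mxp = lp;
        }
        double sc = 0.0, sp = 0.0;
        for (int j = 0; j < s.J; ++j) {
          double a = s.alt[j];
          sc += std::exp(b1c * a + b2c * a * a - mxc);
          sp += std::exp(b1p * a + b2p * a * a - mxp);
        }
        double lse_c = mxc + std::log(sc), lse_p = mxp + std::log(sp);
        for (int i = 0; i < s.M; ++i) {
          double a = s.alt[s.s[i]];
          ll_cur += b1c * a + b2c * a * a;
          ll_prop += b1p * a + b2p * a * a;
        }
        ll_cur -= s.M * lse_c; ll_prop -= s.M * lse_p;
        double lr = ll_prop - ll_cur +
          R::dnorm(prop, 0.0, COEF_SD, 1) - R::dnorm(cur, 0.0, COEF_SD, 1);
        bool acc = std::log(runif1()) < lr;
        if (acc) { if (p == 0) s.beta1 = prop; else s.beta2 = prop; rebuild_pi(s); }
        ad[k][p].tune(acc, iter, burnin);
      }

      // ---- baseline-rate coefficients ----
      for (int p = 2; p < 5; ++p) {
        double cur = p == 2 ? s.aF : (p == 3 ? s.bEff : s.cEff);
        double prop = cur + std::exp(ad[k][p].ls) * rnorm1();
        double aFp = p == 2 ? prop : s.aF;
        double bp = p == 3 ? prop : s.bEff;
        double cp = p == 4 ? prop : s.cEff;
        // candidate lam0 vectors
        double ll_cur = 0.0, ll_prop = 0.0;
        double Sp = 0.0, Sc = 0.0;
        for (int j = 0; j < s.J; ++j) {
          if (!s.eff_pos[j]) { s.tmp_row[j] = 0.0; s.tmp_row2[j] = 0.0; continue; }
          double lp = bp * s.eff[j] + cp * s.eff[j] * s.eff[j];
          s.tmp_row2[j] = std::exp(lp);            // male
          s.tmp_row[j] = std::exp(lp + aFp);       // female
          Sp += s.tmp_row[j] * s.KgFsum[j] + s.tmp_row2[j] * s.KgMsum[j];
          Sc += Lam_at(s, j);
        }
        for (int i = 0; i < s.n_obs; ++i) {
          const std::vector<double> &l0c = s.sex[i] ? s.lam0M : s.lam0F;
          const double *l0p = s.sex[i] ? s.tmp_row2.data() : s.tmp_row.data();
          for (size_t t = 0; t < s.ycells[i].size(); ++t) {
            int j = s.ycells[i][t];
            ll_cur += s.ycounts[i][t] * std::log(l0c[j]);
            ll_prop += s.ycounts[i][t] * std::log(l0p[j]);
          }
        }
        for (size_t t = 0; t < s.cpos.size(); ++t) {
          int j = s.cpos[t];
          ll_cur += s.C[j] * std::log(Lam_at(s, j));
          ll_prop += s.C[j] * std::log(s.tmp_row[j] * s.KgFsum[j] +
                                       s.tmp_row2[j] * s.KgMsum[j]);
        }
        ll_cur -= s.K * Sc; ll_prop -= s.K * Sp;
        double lr = ll_prop - ll_cur +
          R::dnorm(prop, 0.0, COEF_SD, 1) - R::dnorm(cur, 0.0, COEF_SD, 1);
        bool acc = std::log(runif1()) < lr;
        if (acc) {
          if (p == 2) s.aF = prop; else if (p == 3) s.bEff = prop; else s.cEff = prop;
          std::copy(s.tmp_row.begin(), s.tmp_row.end(), s.lam0F.begin());
          std::copy(s.tmp_row2.begin(), s.tmp_row2.end(), s.lam0M.begin());
        }
        ad[k][p].tune(acc, iter, burnin);
      }

      // ---- psi, theta, pmale: logit random walks, Uniform(0,1) priors ----
      int n1 = 0, nmale = 0;
      for (int i = 0; i < s.M; ++i) { n1 += s.z[i]; nmale += s.sex[i]; }
      {
        double cur = s.psi;
        double lo = std::log(cur / (1.0 - cur)) + std::exp(ad[k][5].ls) * rnorm1();
        double prop = 1.0 / (1.0 + std::exp(-lo));
        double lr = n1 * std::log(prop / cur) +
          (s.M - n1) * std::log((1.0 - prop) / (1.0 - cur)) +
          std::log(prop * (1.0 - prop)) - std::log(cur * (1.0 - cur));
        bool acc = std::log(runif1()) < lr;
        if (acc) s.psi = prop;
        ad[k][5].tune(acc, iter, burnin);
      }
      {
        double cur = s.theta;
        double lo = std::log(cur / (1.0 - cur)) + std::exp(ad[k][6].ls) * rnorm1();
        double prop = 1.0 / (1.0 + std::exp(-lo));
        double lr = s.Ytot * std::log(prop / cur) +
          s.Ctot * std::log((1.0 - prop) / (1.0 - cur)) +
          std::log(prop * (1.0 - prop)) - std::log(cur * (1.0 - cur));
        bool acc = std::log(runif1()) < lr;
        if (acc) s.theta = prop;
        ad[k][6].tune(acc, iter, burnin);
      }
      {
        double cur = s.pmale;
        double lo = std::log(cur / (1.0 - cur)) + std::exp(ad[k][7].ls) * rnorm1();
        double prop = 1.0 / (1.0 + std::exp(-lo));
        double lr = nmale * std::log(prop / cur) +
          (s.M - nmale) * std::log((1.0 - prop) / (1.0 - cur)) +
          std::log(prop * (1.0 - prop)) - std::log(cur * (1.0 - cur));
        bool acc = std::log(runif1()) < lr;
        if (acc) s.pmale = prop;
        ad[k][7].tune(acc, iter, burnin);
      }

      // ---- latent sexes ----
      for (int i = 0; i < s.M; ++i) {
        if (s.sex_known[i]) continue;
        if (!s.z[i]) {            // prior-only conditional
          s.sex[i] = runif1() < s.pmale ? 1 : 0;
          continue;
        }
        double sgF = sigF, sgM = sigM;
        double *rowF = s.tmp_row.data(), *rowM = s.tmp_row2.data();
        kernel_row(s, s.s[i], sgF, rowF);
        kernel_row(s, s.s[i], sgM, rowM);
        // log-likelihood difference (male minus female)
        double dS = 0.0;
        for (int j = 0; j < s.J; ++j)
          dS += s.lam0M[j] * rowM[j] - s.lam0F[j] * rowF[j];
        double dll = -s.K * dS;
        const double *curRow = &s.Kg[(size_t)i * s.J];
        bool curMale = s.sex[i] == 1;
        for (size_t t = 0; t < s.cpos.size(); ++t) {
          int j = s.cpos[t];
          double lamCur = (curMale ? s.lam0M[j] : s.lam0F[j]) * curRow[j];
          double base = Lam_at(s, j) - lamCur;
          dll += s.C[j] * (std::log(base + s.lam0M[j] * rowM[j]) -
                           std::log(base + s.lam0F[j] * rowF[j]));
        }
        if (i < s.n_obs) {
          for (size_t t = 0; t < s.ycells[i].size(); ++t) {
            int j = s.ycells[i][t];
            dll += s.ycounts[i][t] * (std::log(s.lam0M[j] * rowM[j]) -
                                      std::log(s.lam0F[j] * rowF[j]));
          }
        }
        double pM = s.pmale * std::exp(dll);
        pM = pM / (pM + (1.0 - s.pmale));
        int newsex = runif1() < pM ? 1 : 0;
        if (newsex != s.sex[i]) {
          // swap cached row and sums
          const double *oldRow = curRow;
          std::vector<double> &oldSum = curMale ? s.KgMsum : s.KgFsum;
          std::vector<double> &newSum = newsex ? s.KgMsum : s.KgFsum;
          double *newRow = newsex ? rowM : rowF;
          double *kg = &s.Kg[(size_t)i * s.J];
          for (int j = 0; j < s.J; ++j) {
            oldSum[j] -= oldRow[j];
            newSum[j] += newRow[j];
            kg[j] = newRow[j];
          }
          s.sex[i] = newsex;
        } else {
          // refresh row under (possibly new) sigma of the kept sex
          double *kg = &s.Kg[(size_t)i * s.J];
          double *keep = s.sex[i] ? rowM : rowF;
          std::vector<double> &sum = s.sex[i] ? s.KgMsum : s.KgFsum;
          for (int j = 0; j < s.J; ++j) {
            sum[j] += keep[j] - kg[j];
            kg[j] = keep[j];
          }
        }
      }

      // ---- activity centres ----
      for (int i = 0; i < s.M; ++i) {
        if (!s.z[i]) {
          // Gibbs from the intensity prior
          double u = runif1();
          int lo = 0, hi = s.J - 1;
          while (lo < hi) { int mid = (lo + hi) / 2;
            if (s.pi_cum[mid] < u) lo = mid + 1; else hi = mid; }
          s.s[i] = lo;
          continue;
        }
        int a = s.s[i];
        const std::vector<int> &na = s.nbr[a];
        if (na.empty()) continue;
        int b = na[(int)(runif1() * na.size()) % na.size()];
        if (b == a) continue;
        double sg = s.sex[i] ? sigM : sigF;
        double *rowB = s.tmp_row.data();
        kernel_row(s, b, sg, rowB);
        const double *rowA = &s.Kg[(size_t)i * s.J];
        const std::vector<double> &l0 = s.sex[i] ? s.lam0M : s.lam0F;
        double dS = 0.0;
        for (int j = 0; j < s.J; ++j) dS += l0[j] * (rowB[j] - rowA[j]);
        double dll = -s.K * dS + s.logpi[b] - s.logpi[a];
        for (size_t t = 0; t < s.cpos.size(); ++t) {
          int j = s.cpos[t];
          double lamA = l0[j] * rowA[j], lamB = l0[j] * rowB[j];
          double base = Lam_at(s, j);
          dll += s.C[j] * (std::log(base - lamA + lamB) - std::log(base));
        }
        if (i < s.n_obs) {
          for (size_t t = 0; t < s.ycells[i].size(); ++t) {
            int j = s.ycells[i][t];
            dll += s.ycounts[i][t] * (std::log(rowB[j]) - std::log(rowA[j]));
          }
        }
        // Hastings correction for unequal neighbourhood sizes
        dll += std::log((double)na.size() / (double)s.nbr[b].size());
        if (std::log(runif1()) < dll) {
          std::vector<double> &sum = s.sex[i] ? s.KgMsum : s.KgFsum;
          double *kg = &s.Kg[(size_t)i * s.J];
          for (int j = 0; j < s.J; ++j) {
            sum[j] += rowB[j] - kg[j];
            kg[j] = rowB[j];
          }
          s.s[i] = b;
        }
      }

      // ---- inclusion indicators (augmented individuals only) ----
      for (int i = s.n_obs; i < s.M; ++i) {
        double sg = s.sex[i] ? sigM : sigF;
        double *row = s.tmp_row.data();
        kernel_row(s, s.s[i], sg, row);
        const std::vector<double> &l0 = s.sex[i] ? s.lam0M : s.lam0F;
        double rowsum = 0.0;
        for (int j = 0; j < s.J; ++j) rowsum += l0[j] * row[j];
        double dll = -s.K * rowsum;   // all-zero history + c-rate shift
        if (s.z[i]) {
          for (size_t t = 0; t < s.cpos.size(); ++t) {
            int j = s.cpos[t];
            double lam = l0[j] * (&s.Kg[(size_t)i * s.J])[j];
            double base = Lam_at(s, j) - lam;
            dll += s.C[j] * std::log1p((l0[j] * row[j]) / base);
          }
        } else {
          for (size_t t = 0; t < s.cpos.size(); ++t) {
            int j = s.cpos[t];
            dll += s.C[j] * std::log1p((l0[j] * row[j]) / Lam_at(s, j));
          }
        }
        double p1 = s.psi * std::exp(dll);
        p1 = p1 / (p1 + (1.0 - s.psi));
        int newz = runif1() < p1 ? 1 : 0;
        if (newz != s.z[i]) {
          std::vector<double> &sum = s.sex[i] ? s.KgMsum : s.KgFsum;
          double *kg = &s.Kg[(size_t)i * s.J];
          if (newz) {
            for (int j = 0; j < s.J; ++j) { kg[j] = row[j]; sum[j] += row[j]; }
          } else {
            for (int j = 0; j < s.J; ++j) { sum[j] -= kg[j]; }
          }
          s.z[i] = newz;
        } else if (s.z[i]) {
          // z stayed 1 but the stored row may predate this iteration's
          // sigma; row was just recomputed, synchronize
          std::vector<double> &sum = s.sex[i] ? s.KgMsum : s.KgFsum;
          double *kg = &s.Kg[(size_t)i * s.J];
          for (int j = 0; j < s.J; ++j) { sum[j] += row[j] - kg[j]; kg[j] = row[j]; }
        }
      }
    }

    // ---- shared movement scales (one proposal per sex, all strata) ----
    for (int sexp = 0; sexp < 2; ++sexp) {
      Adapt &adS = sexp ? adSigM : adSigF;
      double cur = sexp ? sigM : sigF;
      double prop = cur * std::exp(std::exp(adS.ls) * rnorm1());
      bool acc = false;
      if (prop > SIG_LO && prop < SIG_HI) {
        double lr = std::log(prop) - std::log(cur);   // log-scale Jacobian
        // candidate rows for active individuals of this sex, all strata
        for (int k = 0; k < n_str; ++k) {
          Stratum &s = st[k];
          std::vector<double> sumP(s.J, 0.0);
          double ll_cur = 0.0, ll_prop = 0.0;
          for (int i = 0; i < s.M; ++i) {
            if (!s.z[i] || s.sex[i] != sexp) continue;
            double *rp = &s.sigbuf[(size_t)i * s.J];
            kernel_row(s, s.s[i], prop, rp);
            for (int j = 0; j < s.J; ++j) sumP[j] += rp[j];
            if (i < s.n_obs) {
              const double *rc = &s.Kg[(size_t)i * s.J];
              for (size_t t = 0; t < s.ycells[i].size(); ++t) {
                int j = s.ycells[i][t];
                ll_cur += s.ycounts[i][t] * std::log(rc[j]);
                ll_prop += s.ycounts[i][t] * std::log(rp[j]);
              }
            }
          }
          const std::vector<double> &sumC = sexp ? s.KgMsum : s.KgFsum;
          const std::vector<double> &l0 = sexp ? s.lam0M : s.lam0F;
          const std::vector<double> &l0o = sexp ? s.lam0F : s.lam0M;
          const std::vector<double> &sumO = sexp ? s.KgFsum : s.KgMsum;
          double Sc = 0.0, Sp = 0.0;
          for (int j = 0; j < s.J; ++j) {
            Sc += l0[j] * sumC[j];
            Sp += l0[j] * sumP[j];
          }
          for (size_t t = 0; t < s.cpos.size(); ++t) {
            int j = s.cpos[t];
            double other = l0o[j] * sumO[j];
            ll_cur += s.C[j] * std::log(other + l0[j] * sumC[j]);
            ll_prop += s.C[j] * std::log(other + l0[j] * sumP[j]);
          }
          ll_cur -= s.K * Sc; ll_prop -= s.K * Sp;
          lr += ll_prop - ll_cur;
        }
        acc = std::log(runif1()) < lr;
        if (acc) {
          if (sexp) sigM = prop; else sigF = prop;
          for (int k = 0; k < n_str; ++k) {
            Stratum &s = st[k];
            std::vector<double> &sum = sexp ? s.KgMsum : s.KgFsum;
            std::fill(sum.begin(), sum.end(), 0.0);
            for (int i = 0; i < s.M; ++i) {
              if (!s.z[i] || s.sex[i] != sexp) continue;
              double *kg = &s.Kg[(size_t)i * s.J];
              const double *rp = &s.sigbuf[(size_t)i * s.J];
              for (int j = 0; j < s.J; ++j) { kg[j] = rp[j]; sum[j] += kg[j]; }
            }
          }
        }
      }
      adS.tune(acc, iter, burnin);
    }

    // periodic cache refresh against floating-point drift
    if ((iter + 1) % 250 == 0)
      for (int k = 0; k < n_str; ++k) refresh_rows(st[k], sigF, sigM);

    // ---- store ----
    if (iter >= burnin) {
      int r = iter - burnin, c = 0;
      for (int k = 0; k < n_str; ++k) {
        Stratum &s = st[k];
        int n1 = 0, nm1 = 0;
        for (int i = 0; i < s.M; ++i)
          if (s.z[i]) { ++n1; nm1 += s.sex[i]; }
        draws(r, c++) = s.beta1; draws(r, c++) = s.beta2;
        draws(r, c++) = s.aF; draws(r, c++) = s.bEff; draws(r, c++) = s.cEff;
        draws(r, c++) = s.psi; draws(r, c++) = s.theta; draws(r, c++) = s.pmale;
        draws(r, c++) = n1; draws(r, c++) = nm1; draws(r, c++) = n1 - nm1;
        if (store_surface) {
          for (int i = 0; i < s.M; ++i) {
            if (!s.z[i]) continue;
            surfT[k](s.s[i], 0) += 1.0;
            if (s.sex[i]) surfM[k](s.s[i], 0) += 1.0;
          }
        }
      }
      draws(r, c++) = sigF; draws(r, c++) = sigM;
    }
  }

  double final_kernel = 0.0;
  for (int k = 0; k < n_str; ++k) final_kernel += stratum_log_kernel(st[k]);
  final_kernel += R::dunif(sigF, SIG_LO, SIG_HI, 1) +
                  R::dunif(sigM, SIG_LO, SIG_HI, 1);

  List fstate(n_str);
  for (int k = 0; k < n_str; ++k) {
    Stratum &s = st[k];
    fstate[k] = List::create(
      _["z"] = wrap(s.z), _["s"] = wrap(s.s), _["sex"] = wrap(s.sex),
      _["beta1"] = s.beta1, _["beta2"] = s.beta2, _["aF"] = s.aF,
      _["bEff"] = s.bEff, _["cEff"] = s.cEff, _["psi"] = s.psi,
      _["theta"] = s.theta, _["pmale"] = s.pmale);
  }
  List surf(n_str);
  for (int k = 0; k < n_str; ++k)
    surf[k] = List::create(_["total"] = surfT[k], _["male"] = surfM[k],
                           _["n_draws"] = n_store);
  return List::create(
    _["draws"] = draws,
    _["surface"] = surf,
    _["final_state"] = fstate,
    _["final_sigma"] = NumericVector::create(sigF, sigM),
    _["final_log_kernel"] = final_kernel);
}
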