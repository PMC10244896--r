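// Multistate mark-recapture machinery: exact marginal likelihood of a
// post-recruitment sighting vector over latent breeder/nonbreeder sequences
// (forward algorithm), and an adaptive Metropolis-within-Gibbs sampler for
// the mixed-effects logistic transition model.
//
// Latent states: F (first-time breeder, entry only), B (breeder),
// N (nonbreeder). Emissions: P(y=1|B)=p, P(y=0|B)=1-p, P(y=1|N)=0.
// Histories are conditioned on first capture: at the recruitment occasion the
// state is F and the sighting (a 1) has probability one.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Colony {
  int nF, nT, variant, n_cohort;
  IntegerMatrix obs;        // -1 before recruitment, else 0/1
  IntegerVector recruit;    // 0-based occasion of first sighting
  NumericMatrix zage;       // standardised age, female x occasion
  NumericVector zlw;        // standardised weaning length, per female
  IntegerVector cohort;     // 0-based cohort index
  IntegerMatrix parity_obs; // observed parity group 1..3 entering occasion t
  bool use_obs_parity;
  NumericVector gh_x, gh_w; // Gauss-Hermite rule for sigma_omega > 0
};

static Colony unpack_colony(const List& data) {
  Colony c;
  c.obs = as<IntegerMatrix>(data["obs"]);
  c.recruit = as<IntegerVector>(data["recruit"]);
  c.zage = as<NumericMatrix>(data["zage"]);
  c.zlw = as<NumericVector>(data["zlw"]);
  c.cohort = as<IntegerVector>(data["cohort"]);
  c.n_cohort = as<int>(data["n_cohort"]);
  c.parity_obs = as<IntegerMatrix>(data["parity_obs"]);
  c.use_obs_parity = as<bool>(data["use_obs_parity"]);
  c.variant = as<int>(data["variant"]);
  c.gh_x = as<NumericVector>(data["gh_x"]);
  c.gh_w = as<NumericVector>(data["gh_w"]);
  c.nF = c.obs.nrow();
  c.nT = c.obs.ncol();
  return c;
}

struct Pars {
  double mu, l1, l2, l3F, l3B, l3N, l5, l6, p, sigma_omega;
  const double* lcoh;   // length n_cohort, first entry 0
  const double* beta;   // length nF
  const double* theta;  // length nT
};

// P(state_t = B | prev state, covariates); prev: 0=F, 1=B, 2=N; par: prior
// birth-count group 1..3 (only used by the parity variant).
static inline double psi_prob(const Colony& C, const Pars& P,
                              int i, int t, int prev, int par) {
  double a = C.zage(i, t);
  double lp = P.mu + P.l1 * a + P.l2 * a * a + P.beta[i] + P.theta[t];
  lp += (prev == 0) ? P.l3F : ((prev == 1) ? P.l3B : P.l3N);
  double z = C.zlw[i];
  switch (C.variant) {
    case 1: lp += P.l5 * z; break;
    case 2: lp += P.l5 * z + P.l6 * z * z; break;
    case 3: lp += P.l5 * z + ((par == 1) ? P.l6 * z : 0.0); break;
    case 4: lp += P.l5 * z + P.lcoh[C.cohort[i]]; break;
    default: break;
  }
  if (P.sigma_omega > 0.0 && C.gh_x.size() > 0) {
    double s = 0.0;
    for (int k = 0; k < C.gh_x.size(); ++k)
      s += C.gh_w[k] * inv_logit(lp + P.sigma_omega * C.gh_x[k]);
    return s;
  }
  return inv_logit(lp);
}

// Marginal log-likelihood of one female's post-recruitment sightings.
// If occ != NULL it receives the per-occasion increments
// log P(y_t | y_{recruit..t-1}) at positions recruit+1 .. nT-1.
static double female_ll(const Colony& C, const Pars& P, int i,
                        double* occ = NULL) {
  const int r = C.recruit[i], nT = C.nT;
  if (r >= nT - 1) return 0.0;
  double ll = 0.0;

  if (C.variant == 3 && !C.use_obs_parity) {
    // expanded state space (B/N x prior-birth group 1..3); recruitment birth
    // is the first, so the female enters her first transition in group 1
    double aB[3] = {0, 0, 0}, aN[3] = {0, 0, 0};
    bool first = true;
    for (int t = r + 1; t < nT; ++t) {
      double nB[3] = {0, 0, 0}, nN[3] = {0, 0, 0};
      if (first) {
        double ps = psi_prob(C, P, i, t, 0, 1);
        nB[1] = ps;       // a second birth moves her to group 2
        nN[0] = 1.0 - ps; // skipping keeps her in group 1
        first = false;
      } else {
        for (int m = 0; m < 3; ++m) {
          int m2 = (m + 1 < 2) ? m + 1 : 2;
          if (aB[m] > 0.0) {
            double ps = psi_prob(C, P, i, t, 1, m + 1);
            nB[m2] += aB[m] * ps;
            nN[m] += aB[m] * (1.0 - ps);
          }
          if (aN[m] > 0.0) {
            double ps = psi_prob(C, P, i, t, 2, m + 1);
            nB[m2] += aN[m] * ps;
            nN[m] += aN[m] * (1.0 - ps);
          }
        }
      }
      int y = C.obs(i, t);
      double c = 0.0;
      for (int m = 0; m < 3; ++m) {
        if (y == 1) { nB[m] *= P.p; nN[m] = 0.0; }
        else        { nB[m] *= (1.0 - P.p); }
        c += nB[m] + nN[m];
      }
      if (!(c > 0.0)) return R_NegInf;
      ll += std::log(c);
      if (occ) occ[t] = std::log(c);
      for (int m = 0; m < 3; ++m) { aB[m] = nB[m] / c; aN[m] = nN[m] / c; }
    }
    return ll;
  }

  double aB = 0.0, aN = 0.0;
  bool first = true;
  for (int t = r + 1; t < nT; ++t) {
    int par = C.use_obs_parity ? C.parity_obs(i, t) : 1;
    double nb, nn;
    if (first) {
      double ps = psi_prob(C, P, i, t, 0, par);
      nb = ps; nn = 1.0 - ps;
      first = false;
    } else {
      double psB = psi_prob(C, P, i, t, 1, par);
      double psN = psi_prob(C, P, i, t, 2, par);
      nb = aB * psB + aN * psN;
      nn = aB * (1.0 - psB) + aN * (1.0 - psN);
    }
    int y = C.obs(i, t);
    if (y == 1) { nb *= P.p; nn = 0.0; }
    else        { nb *= (1.0 - P.p); }
    double c = nb + nn;
    if (!(c > 0.0)) return R_NegInf;
    ll += std::log(c);
    if (occ) occ[t] = std::log(c);
    aB = nb / c; aN = nn / c;
  }
  return ll;
}

static Pars unpack_pars(const List& pars) {
  Pars P;
  P.mu = as<double>(pars["mu"]);
  P.l1 = as<double>(pars["lambda1"]);
  P.l2 = as<double>(pars["lambda2"]);
  P.l3F = as<double>(pars["lambda3F"]);
  P.l3B = as<double>(pars["lambda3B"]);
  P.l3N = as<double>(pars["lambda3N"]);
  P.l5 = as<double>(pars["lambda5"]);
  P.l6 = as<double>(pars["lambda6"]);
  P.p = as<double>(pars["p"]);
  P.sigma_omega = as<double>(pars["sigma_omega"]);
  return P;
}

// [[Rcpp::export]]
NumericVector msms_colony_loglik_cpp(List data, List pars) {
  Colony C = unpack_colony(data);
  Pars P = unpack_pars(pars);
  NumericVector lcoh = as<NumericVector>(pars["lambda_cohort"]);
  NumericVector beta = as<NumericVector>(pars["beta"]);
  NumericVector theta = as<NumericVector>(pars["theta"]);
  P.lcoh = lcoh.begin(); P.beta = beta.begin(); P.theta = theta.begin();
  NumericVector out(C.nF);
  for (int i = 0; i < C.nF; ++i) out[i] = female_ll(C, P, i);
  return out;
}

// Single-female forward log-likelihood; obs starts at the recruitment
// occasion (obs[0] must be the recruitment sighting).
// [[Rcpp::export]]
double msms_forward_loglik_cpp(IntegerVector obs, NumericVector zage,
                               double zlw, List pars, NumericVector theta,
                               double beta, int variant, int cohort,
                               int n_cohort, IntegerVector parity_obs,
                               bool use_obs_parity, NumericVector gh_x,
                               NumericVector gh_w) {
  int nT = obs.size();
  Colony C;
  C.nF = 1; C.nT = nT; C.variant = variant; C.n_cohort = n_cohort;
  C.obs = IntegerMatrix(1, nT);
  C.zage = NumericMatrix(1, nT);
  C.parity_obs = IntegerMatrix(1, nT);
  for (int t = 0; t < nT; ++t) {
    C.obs(0, t) = obs[t];
    C.zage(0, t) = zage[t];
    C.parity_obs(0, t) = parity_obs[t];
  }
  C.recruit = IntegerVector::create(0);
  C.zlw = NumericVector::create(zlw);
  C.cohort = IntegerVector::create(cohort);
  C.use_obs_parity = use_obs_parity;
  C.gh_x = gh_x; C.gh_w = gh_w;
  Pars P = unpack_pars(pars);
  NumericVector lcoh = as<NumericVector>(pars["lambda_cohort"]);
  P.lcoh = lcoh.begin();
  double b = beta;
  P.beta = &b;
  P.theta = theta.begin();
  return female_ll(C, P, 0);
}

// Pointwise log-likelihoods across posterior draws, for WAIC.
// fixed: draws x 10 [mu,l1,l2,l3F,l3B,l3N,l5,l6,p,sigma_omega];
// lcoh: draws x n_cohort; beta: draws x nF; theta: draws x nT.
// per_occasion=false -> draws x nF; true -> draws x n_units where units are
// post-recruitment occasions, female-major.
// [[Rcpp::export]]
NumericMatrix msms_loglik_draws_cpp(List data, NumericMatrix fixed,
                                    NumericMatrix lcoh, NumericMatrix beta,
                                    NumericMatrix theta, bool per_occasion) {
  Colony C = unpack_colony(data);
  int S = fixed.nrow();
  int n_units = 0;
  std::vector<int> unit_off(C.nF, 0);
  for (int i = 0; i < C.nF; ++i) {
    unit_off[i] = n_units;
    int k = C.nT - 1 - C.recruit[i];
    n_units += (k > 0) ? k : 0;
  }
  NumericMatrix out(S, per_occasion ? n_units : C.nF);
  std::vector<double> lc(C.n_cohort), bv(C.nF), tv(C.nT), occ(C.nT);
  for (int s = 0; s < S; ++s) {
    Pars P;
    P.mu = fixed(s, 0); P.l1 = fixed(s, 1); P.l2 = fixed(s, 2);
    P.l3F = fixed(s, 3); P.l3B = fixed(s, 4); P.l3N = fixed(s, 5);
    P.l5 = fixed(s, 6); P.l6 = fixed(s, 7);
    P.p = fixed(s, 8); P.sigma_omega = fixed(s, 9);
    for (int j = 0; j < C.n_cohort; ++j) lc[j] = lcoh(s, j);
    for (int i = 0; i < C.nF; ++i) bv[i] = beta(s, i);
    for (int t = 0; t < C.nT; ++t) tv[t] = theta(s, t);
    P.lcoh = lc.data(); P.beta = bv.data(); P.theta = tv.data();
    for (int i = 0; i < C.nF; ++i) {
      double ll = female_ll(C, P, i, per_occasion ? occ.data() : NULL);
      if (per_occasion) {
        int r = C.recruit[i];
        for (int t = r + 1; t < C.nT; ++t)
          out(s, unit_off[i] + (t - r - 1)) = occ[t];
      } else {
        out(s, i) = ll;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sampler
// ---------------------------------------------------------------------------

// lower Cholesky of a small SPD matrix (with ridge); returns false on failure
static bool chol_lower(const std::vector<double>& A, int d,
                       std::vector<double>& L) {
  L.assign(d * d, 0.0);
  for (int j = 0; j < d; ++j) {
    double s = A[j + j * d];
    for (int k = 0; k < j; ++k) s -= L[j + k * d] * L[j + k * d];
    if (s <= 0.0) return false;
    L[j + j * d] = std::sqrt(s);
    for (int i = j + 1; i < d; ++i) {
      double t = A[i + j * d];
      for (int k = 0; k < j; ++k) t -= L[i + k * d] * L[j + k * d];
      L[i + j * d] = t / L[j + j * d];
    }
  }
  return true;
}

struct FixedMap {
  // coordinate layout of the fixed block: mu,l1,l2,l3F,l3B,[l5],[l6],
  // [lcoh_2..lcoh_nc], logit_p (always last)
  int d, i_l5, i_l6, i_coh0, n_coh_free, i_p;
};

static FixedMap make_map(int variant, int n_cohort) {
  FixedMap m;
  m.i_l5 = m.i_l6 = m.i_coh0 = -1;
  m.n_coh_free = 0;
  int k = 5;
  if (variant >= 1) { m.i_l5 = k++; }
  if (variant == 2 || variant == 3) { m.i_l6 = k++; }
  if (variant == 4) { m.i_coh0 = k; m.n_coh_free = n_cohort - 1; k += m.n_coh_free; }
  m.i_p = k++;
  m.d = k;
  return m;
}

static void map_pars(const FixedMap& M, const double* x, Pars& P,
                     std::vector<double>& lcoh) {
  P.mu = x[0]; P.l1 = x[1]; P.l2 = x[2];
  P.l3F = x[3]; P.l3B = x[4]; P.l3N = -(x[3] + x[4]);
  P.l5 = (M.i_l5 >= 0) ? x[M.i_l5] : 0.0;
  P.l6 = (M.i_l6 >= 0) ? x[M.i_l6] : 0.0;
  for (size_t j = 0; j < lcoh.size(); ++j)
    lcoh[j] = (M.i_coh0 >= 0 && j >= 1) ? x[M.i_coh0 + (int)j - 1] : 0.0;
  P.p = inv_logit(x[M.i_p]);
  P.sigma_omega = 0.0;
  P.lcoh = lcoh.data();
}

// log prior of the fixed block: N(0, prior_sd) on regression coordinates,
// Uniform(p_lo, p_hi) on p expressed on the logit scale (Jacobian included).
static double fixed_logprior(const FixedMap& M, const double* x,
                             double prior_sd, double p_lo, double p_hi) {
  double lp = 0.0;
  for (int j = 0; j < M.d - 1; ++j)
    lp += R::dnorm(x[j], 0.0, prior_sd, 1);
  double p = inv_logit(x[M.i_p]);
  if (p <= p_lo || p >= p_hi) return R_NegInf;
  lp += std::log(p) + std::log(1.0 - p); // d p / d logit(p)
  return lp;
}

// truncated Gamma draw for a random-effect precision: tau ~ Gamma(shape,rate)
// restricted to tau >= 1/upper^2 (i.e. sigma <= upper)
static double draw_sigma(double S, int n, double upper) {
  double shape = (n - 1.0) / 2.0, rate = S / 2.0;
  if (!(rate > 0.0)) return upper * R::unif_rand();
  double tmin = 1.0 / (upper * upper);
  for (int k = 0; k < 200; ++k) {
    double tau = R::rgamma(shape, 1.0 / rate);
    if (tau >= tmin) return 1.0 / std::sqrt(tau);
  }
  return upper;
}

// [[Rcpp::export]]
List msms_sampler_cpp(List data, List cfg) {
  Colony C = unpack_colony(data);
  const int nF = C.nF, nT = C.nT;
  const FixedMap M = make_map(C.variant, C.n_cohort);
  const int d = M.d;

  const int n_burn = as<int>(cfg["n_burn"]);
  const int n_iter = as<int>(cfg["n_iter"]);
  const int thin = as<int>(cfg["thin"]);
  const double prior_sd = as<double>(cfg["prior_sd"]);
  const double sig_up = as<double>(cfg["sigma_upper"]);
  const double p_lo = as<double>(cfg["p_lo"]);
  const double p_hi = as<double>(cfg["p_hi"]);

  // initial state
  std::vector<double> x(as<std::vector<double> >(cfg["init_fixed"]));
  if ((int)x.size() != d) stop("init_fixed has wrong length");
  std::vector<double> beta(as<std::vector<double> >(cfg["init_beta"]));
  std::vector<double> theta(as<std::vector<double> >(cfg["init_theta"]));
  double sb = as<double>(cfg["init_sigma_beta"]);
  double st = as<double>(cfg["init_sigma_theta"]);

  Pars P;
  std::vector<double> lcoh(std::max(C.n_cohort, 1));
  map_pars(M, x.data(), P, lcoh);
  P.beta = beta.data(); P.theta = theta.data();

  std::vector<double> ll(nF), llp(nF);
  double ll_tot = 0.0;
  for (int i = 0; i < nF; ++i) { ll[i] = female_ll(C, P, i); ll_tot += ll[i]; }
  if (!R_finite(ll_tot)) stop("initial state has zero likelihood");

  // adaptation state
  double ls_fixed = std::log(0.3 / std::sqrt((double)d));
  double ls_beta = std::log(0.8), ls_theta = std::log(0.25 / std::sqrt((double)nT));
  double ls_trA = std::log(0.3), ls_trB = std::log(0.3);
  double ls_ncb = std::log(0.2), ls_nct = std::log(0.2);
  std::vector<double> am_mean(d, 0.0), am_cov(d * d, 0.0), Lp;
  bool have_L = false;
  int am_n = 0;

  const int n_total = n_burn + n_iter;
  const int n_kept = n_iter / thin;
  const int ncol_out = d + 1 /*l3N*/ + 2 /*sigmas*/ + nF + nT;
  NumericMatrix draws(n_kept, ncol_out);

  std::vector<double> xp(d), z(d), bp(nF), tp(nT);
  double acc_fixed = 0, acc_beta = 0, acc_theta = 0, n_aft = 0;
  int kept = 0;

  for (int iter = 0; iter < n_total; ++iter) {
    const bool adapting = iter < n_burn;
    const double eta = std::min(0.25, 3.0 / std::sqrt(iter + 10.0));

    // --- fixed block (adaptive MVN random walk) ---
    {
      const double g = std::exp(ls_fixed);
      for (int j = 0; j < d; ++j) z[j] = R::norm_rand();
      if (have_L) {
        for (int j = 0; j < d; ++j) {
          double s = 0.0;
          for (int k = 0; k <= j; ++k) s += Lp[j + k * d] * z[k];
          xp[j] = x[j] + g * s;
        }
      } else {
        for (int j = 0; j < d; ++j) xp[j] = x[j] + g * 0.2 * z[j];
      }
      double dpr = fixed_logprior(M, xp.data(), prior_sd, p_lo, p_hi) -
                   fixed_logprior(M, x.data(), prior_sd, p_lo, p_hi);
      double a = 0.0;
      bool acc = false;
      if (R_finite(dpr)) {
        Pars Pp;
        std::vector<double> lcp(lcoh.size());
        map_pars(M, xp.data(), Pp, lcp);
        Pp.beta = beta.data(); Pp.theta = theta.data();
        double lt = 0.0;
        for (int i = 0; i < nF; ++i) { llp[i] = female_ll(C, Pp, i); lt += llp[i]; }
        a = lt - ll_tot + dpr;
        if (R_finite(a) && std::log(R::unif_rand()) < a) {
          x = xp; ll = llp; ll_tot = lt;
          lcoh = lcp;
          map_pars(M, x.data(), P, lcoh);
          P.beta = beta.data(); P.theta = theta.data();
          acc = true;
        }
      }
      if (!adapting && iter >= n_burn) acc_fixed += acc;
      if (adapting) {
        ls_fixed += eta * ((acc ? 1.0 : 0.0) - 0.25);
        // running mean / sum-of-squares (Welford) for the proposal shape:
        // dj uses the pre-update mean, dk the post-update mean
        ++am_n;
        std::vector<double> dold(d);
        for (int j = 0; j < d; ++j) {
          dold[j] = x[j] - am_mean[j];
          am_mean[j] += dold[j] / am_n;
        }
        for (int j = 0; j < d; ++j)
          for (int k = 0; k <= j; ++k)
            am_cov[j + k * d] += dold[j] * (x[k] - am_mean[k]);
        if (am_n > 20 * d && iter % 25 == 0) {
          std::vector<double> A(d * d);
          double sc = 2.38 * 2.38 / d / std::max(am_n - 1, 1);
          for (int j = 0; j < d; ++j)
            for (int k = 0; k < d; ++k) {
              double v = (k <= j) ? am_cov[j + k * d] : am_cov[k + j * d];
              // diagonal ridge keeps a floor under every coordinate's step
              // so a coordinate that started frozen can still escape
              A[j + k * d] = sc * v + ((j == k) ? 2.5e-3 : 0.0);
            }
          std::vector<double> Ltmp;
          if (chol_lower(A, d, Ltmp)) {
            Lp = Ltmp;
            if (!have_L) { have_L = true; ls_fixed = 0.0; }
          }
        }
      }
    }

    // --- female effects (vectorised componentwise random walk) ---
    {
      const double g = std::exp(ls_beta);
      for (int i = 0; i < nF; ++i) bp[i] = beta[i] + g * R::norm_rand();
      Pars Pp = P;
      Pp.beta = bp.data(); Pp.theta = theta.data(); Pp.lcoh = lcoh.data();
      double nacc = 0.0;
      for (int i = 0; i < nF; ++i) {
        double li = female_ll(C, Pp, i);
        double a = li - ll[i] +
                   R::dnorm(bp[i], 0.0, sb, 1) - R::dnorm(beta[i], 0.0, sb, 1);
        if (R_finite(a) && std::log(R::unif_rand()) < a) {
          ll_tot += li - ll[i];
          beta[i] = bp[i]; ll[i] = li;
          nacc += 1.0;
        }
      }
      if (!adapting) acc_beta += nacc / nF;
      else ls_beta += eta * (nacc / nF - 0.44);
    }

    // --- year effects (joint random-walk block) ---
    {
      const double g = std::exp(ls_theta);
      double dpr = 0.0;
      for (int t = 0; t < nT; ++t) {
        tp[t] = theta[t] + g * R::norm_rand();
        dpr += R::dnorm(tp[t], 0.0, st, 1) - R::dnorm(theta[t], 0.0, st, 1);
      }
      Pars Pp = P;
      Pp.beta = beta.data(); Pp.theta = tp.data(); Pp.lcoh = lcoh.data();
      double lt = 0.0;
      for (int i = 0; i < nF; ++i) { llp[i] = female_ll(C, Pp, i); lt += llp[i]; }
      double a = lt - ll_tot + dpr;
      bool acc = R_finite(a) && std::log(R::unif_rand()) < a;
      if (acc) {
        theta = tp; ll = llp; ll_tot = lt;
        P.theta = theta.data();
      }
      if (!adapting) acc_theta += acc;
      else ls_theta += eta * ((acc ? 1.0 : 0.0) - 0.25);
    }

    // --- translation moves (likelihood-invariant; break intercept/random-
    //     effect coupling). mu' = mu + delta, beta' = beta - delta ---
    {
      double del = std::exp(ls_trA) * R::norm_rand();
      double sumb = 0.0;
      for (int i = 0; i < nF; ++i) sumb += beta[i];
      double a = R::dnorm(x[0] + del, 0.0, prior_sd, 1) -
                 R::dnorm(x[0], 0.0, prior_sd, 1) -
                 (nF * del * del - 2.0 * del * sumb) / (2.0 * sb * sb);
      bool acc = std::log(R::unif_rand()) < a;
      if (acc) {
        x[0] += del;
        for (int i = 0; i < nF; ++i) beta[i] -= del;
        map_pars(M, x.data(), P, lcoh);
        P.beta = beta.data(); P.theta = theta.data();
      }
      if (adapting) ls_trA += eta * ((acc ? 1.0 : 0.0) - 0.44);

      double del2 = std::exp(ls_trB) * R::norm_rand();
      double sumt = 0.0;
      for (int t = 0; t < nT; ++t) sumt += theta[t];
      double a2 = R::dnorm(x[0] + del2, 0.0, prior_sd, 1) -
                  R::dnorm(x[0], 0.0, prior_sd, 1) -
                  (nT * del2 * del2 - 2.0 * del2 * sumt) / (2.0 * st * st);
      bool acc2 = std::log(R::unif_rand()) < a2;
      if (acc2) {
        x[0] += del2;
        for (int t = 0; t < nT; ++t) theta[t] -= del2;
        map_pars(M, x.data(), P, lcoh);
        P.beta = beta.data(); P.theta = theta.data();
      }
      if (adapting) ls_trB += eta * ((acc2 ? 1.0 : 0.0) - 0.44);
    }

    // --- variance components (Gibbs, Uniform(0, sigma_upper) prior on sd) ---
    {
      double Sb = 0.0, St = 0.0;
      for (int i = 0; i < nF; ++i) Sb += beta[i] * beta[i];
      for (int t = 0; t < nT; ++t) St += theta[t] * theta[t];
      sb = draw_sigma(Sb, nF, sig_up);
      st = draw_sigma(St, nT, sig_up);
    }

    // --- interweaved (non-centred) scale moves: holding beta/sigma_beta
    //     fixed, rescale the effects with their sd. Breaks the funnel
    //     coupling between a variance component and its effects. Target on
    //     the log-sd scale carries a +log(sigma'/sigma) Jacobian; the
    //     standardised effects' N(0,1) prior is unchanged by construction ---
    {
      double eps = std::exp(ls_ncb) * R::norm_rand();
      double sb2 = sb * std::exp(eps);
      bool acc = false;
      if (sb2 < sig_up) {
        double sc = sb2 / sb;
        for (int i = 0; i < nF; ++i) bp[i] = beta[i] * sc;
        Pars Pp = P;
        Pp.beta = bp.data(); Pp.theta = theta.data(); Pp.lcoh = lcoh.data();
        double lt = 0.0;
        for (int i = 0; i < nF; ++i) { llp[i] = female_ll(C, Pp, i); lt += llp[i]; }
        double a = lt - ll_tot + eps;
        if (R_finite(a) && std::log(R::unif_rand()) < a) {
          beta = bp; ll = llp; ll_tot = lt; sb = sb2;
          P.beta = beta.data();
          acc = true;
        }
      }
      if (adapting) ls_ncb += eta * ((acc ? 1.0 : 0.0) - 0.44);

      double eps2 = std::exp(ls_nct) * R::norm_rand();
      double st2 = st * std::exp(eps2);
      bool acc2 = false;
      if (st2 < sig_up) {
        double sc = st2 / st;
        for (int t = 0; t < nT; ++t) tp[t] = theta[t] * sc;
        Pars Pp = P;
        Pp.beta = beta.data(); Pp.theta = tp.data(); Pp.lcoh = lcoh.data();
        double lt = 0.0;
        for (int i = 0; i < nF; ++i) { llp[i] = female_ll(C, Pp, i); lt += llp[i]; }
        double a = lt - ll_tot + eps2;
        if (R_finite(a) && std::log(R::unif_rand()) < a) {
          theta = tp; ll = llp; ll_tot = lt; st = st2;
          P.theta = theta.data();
          acc2 = true;
        }
      }
      if (adapting) ls_nct += eta * ((acc2 ? 1.0 : 0.0) - 0.44);
    }

    if (!adapting) {
      n_aft += 1.0;
      int post = iter - n_burn;
      if ((post + 1) % thin == 0 && kept < n_kept) {
        int c = 0;
        for (int j = 0; j < d; ++j)
          draws(kept, c++) = (j == M.i_p) ? inv_logit(x[j]) : x[j];
        draws(kept, c++) = -(x[3] + x[4]); // lambda3N
        draws(kept, c++) = sb;
        draws(kept, c++) = st;
        for (int i = 0; i < nF; ++i) draws(kept, c++) = beta[i];
        for (int t = 0; t < nT; ++t) draws(kept, c++) = theta[t];
        ++kept;
      }
    }
  }

  return List::create(
    _["draws"] = draws,
    _["acc_fixed"] = acc_fixed / std::max(n_aft, 1.0),
    _["acc_beta"] = acc_beta / std::max(n_aft, 1.0),
    _["acc_theta"] = acc_theta / std::max(n_aft, 1.0),
    _["d_fixed"] = d,
    _["loglik_final"] = ll_tot);
}
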