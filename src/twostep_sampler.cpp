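#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// MCMC core for the hierarchical Two-Step closed CMR model.
//
// Latent structure: z_g ~ Bern(psi_g) inclusion of each (observed or
// augmented) group; W_gk ~ Bern(z_g * p_g) group detections; within an
// observed group, per-sweep individual detection counts are Binomial(T, p_i)
// in detected sweeps, conditioned on each observed individual being detected
// at least once; n_g ~ zero-truncated Binomial(m_g, pstar_g); m_g ~
// zero-truncated Poisson(lambda). The pstar^{n_g} factors cancel between the
// conditional multinomial and the truncated binomial, so the group-level
// remainder is choose(m_g, n_g) (1-pstar)^{m_g-n_g} / (1 - (1-pstar)^{m_g})
// with log(1-pstar_g) = T * d_g * log(1 - p_i), d_g = detected sweeps.
//
// Updates: p_g, psi_g, p_s, psi_s and the augmented inclusion counts are
// conjugate Gibbs (augmented all-zero rows are exchangeable, so their
// inclusion count is a single Binomial draw). p_i and lambda use slice
// sampling with interval shrinkage on their bounded supports. m_g uses an
// exact categorical draw on the truncated grid [max(n_g, min_size), m_cap].
// Sizes of included never-detected groups are fresh prior draws each
// iteration (they carry no likelihood), which is the marginalized update.

static double slice_sample(double x0, double lo, double hi,
                           std::function<double(double)> logf) {
  double y = logf(x0) - R::exp_rand();
  double L = lo, R_ = hi;
  for (int it = 0; it < 200; ++it) {
    double x1 = R::runif(L, R_);
    if (logf(x1) >= y) return x1;
    if (x1 < x0) L = x1; else R_ = x1;
  }
  return x0;  // shrinkage exhausted; keep current value
}

// zero-truncated Poisson draw: rejection (fast when P(X < min) is small,
// which holds for the rates of interest), inverse-CDF fallback
static int rztpois1(double lambda, int min_size) {
  for (int t = 0; t < 50; ++t) {
    int x = (int) R::rpois(lambda);
    if (x >= min_size) return x;
  }
  double p0 = R::ppois(min_size - 1, lambda, 1, 0);
  double u = p0 + R::unif_rand() * (1.0 - p0);
  if (u >= 1.0) u = 1.0 - 1e-16;
  return (int) R::qpois(u, lambda, 1, 0);
}

// log P(Poisson(lambda) >= min_size)
static double ztpois_lognorm(double lambda, int min_size) {
  return R::ppois(min_size - 1, lambda, 0, 1);
}

// [[Rcpp::export(rng = true)]]
NumericMatrix twostep_mcmc_chain(
    IntegerVector n_g,        // observed members per observed group
    IntegerVector d_g,        // detected sweeps per observed group
    int Sw,                   // total group-level detections in W
    double S_ind,             // total individual detections (all sweeps)
    double Tr_ind,            // total individual trials: sum n_g * T * d_g
    int K, int T_occ,
    int M_groups,             // total group rows incl. augmentation
    int min_size,             // group-size truncation bound
    double lambda_upper,      // upper bound of uniform prior on lambda
    int n_sol, double S_sol,  // observed solitaries, their total detections
    int M_sol,                // total solitary rows incl. augmentation (0 = no solitary component)
    int n_iter, int burn_in, int m_cap,
    double pg0, double pi0, double lam0) {

  const int nG = n_g.size();
  const int M_extra = M_groups - nG;
  const bool sol = (M_sol > 0);
  const int Ms_extra = M_sol - n_sol;

  // lchoose(m, n_g) lookup: rows m = 0..m_cap, one column per observed group
  NumericMatrix lch(m_cap + 1, nG);
  for (int g = 0; g < nG; ++g)
    for (int m = n_g[g]; m <= m_cap; ++m)
      lch(m, g) = R::lchoose((double) m, (double) n_g[g]);

  // state
  double p_g = pg0, p_i = pi0, lambda = lam0;
  double psi_g = 0.5, p_s = 0.3, psi_s = 0.5;
  int z0 = M_extra / 4, zs0 = Ms_extra / 4;
  IntegerVector m(nG);
  for (int g = 0; g < nG; ++g) m[g] = std::max(n_g[g], min_size);

  const int n_keep = n_iter - burn_in;
  const int ncol = sol ? 9 : 6;
  NumericMatrix out(n_keep, ncol);

  std::vector<double> lgam(m_cap + 2);
  for (int m_ = 0; m_ <= m_cap + 1; ++m_) lgam[m_] = R::lgammafn(m_ + 1.0);

  for (int it = 0; it < n_iter; ++it) {
    // --- group detection probability (conjugate) ---
    double trials = (double) K * (nG + z0);
    p_g = R::rbeta(1.0 + Sw, 1.0 + trials - Sw);

    // --- inclusion of augmented all-zero group rows ---
    double pz = psi_g * std::pow(1.0 - p_g, K);
    double q = pz / (pz + (1.0 - psi_g));
    z0 = (M_extra > 0) ? (int) R::rbinom(M_extra, q) : 0;
    psi_g = R::rbeta(1.0 + nG + z0, 1.0 + (M_extra - z0));

    // --- individual detection probability (slice) ---
    // extra (1-p) exponent from the (m_g - n_g) undetected members
    double extra = 0.0;
    std::vector<double> Td_m(nG);
    for (int g = 0; g < nG; ++g) {
      extra += (double)(m[g] - n_g[g]) * T_occ * d_g[g];
      Td_m[g] = (double) T_occ * d_g[g] * m[g];
    }
    auto ll_pi = [&](double p) {
      if (p <= 0.0 || p >= 1.0) return R_NegInf;
      double l1p = std::log1p(-p);
      double ll = S_ind * std::log(p) + (Tr_ind - S_ind + extra) * l1p;
      for (int g = 0; g < nG; ++g) {
        double t = Td_m[g] * l1p;
        if (t > -37.0) ll -= std::log1p(-std::exp(t));
      }
      return ll;
    };
    p_i = slice_sample(p_i, 0.0, 1.0, ll_pi);

    // --- group sizes of observed groups (exact categorical on grid) ---
    double llam = std::log(lambda);
    double l1pi = std::log1p(-p_i);
    // grid upper bound: the conditional tail of m_g is lighter than the
    // ZT-Poisson prior tail, so lambda + 8*sqrt(lambda) + 10 is conservative
    int hi_dyn = std::min(m_cap, (int) std::ceil(lambda + 8.0 * std::sqrt(lambda) + 10.0));
    for (int g = 0; g < nG; ++g) {
      int a = std::max(n_g[g], min_size);
      int hi = std::max(a, hi_dyn);
      double c1 = (double) T_occ * d_g[g] * l1pi;  // log(1 - pstar_g)
      int len = hi - a + 1;
      std::vector<double> lw(len);
      double mx = R_NegInf;
      for (int j = 0; j < len; ++j) {
        int mm = a + j;
        double v = mm * llam - lgam[mm] + lch(mm, g)
          + (double)(mm - n_g[g]) * c1;
        double t = mm * c1;
        if (t > -37.0) v -= std::log1p(-std::exp(t));
        lw[j] = v;
        if (v > mx) mx = v;
      }
      double tot = 0.0;
      for (int j = 0; j < len; ++j) { lw[j] = std::exp(lw[j] - mx); tot += lw[j]; }
      double u = R::unif_rand() * tot, acc = 0.0;
      int pick = len - 1;
      for (int j = 0; j < len; ++j) { acc += lw[j]; if (u <= acc) { pick = j; break; } }
      m[g] = a + pick;
    }

    // --- mean group size (slice on (0, lambda_upper)) ---
    double Sm = 0.0;
    for (int g = 0; g < nG; ++g) Sm += m[g];
    auto ll_lam = [&](double lam) {
      if (lam <= 0.0) return R_NegInf;
      return Sm * std::log(lam) - nG * lam - nG * ztpois_lognorm(lam, min_size);
    };
    lambda = slice_sample(lambda, 1e-8, lambda_upper, ll_lam);

    // --- solitary component (conjugate, mirrors the group-level step) ---
    int S_count = 0;
    if (sol) {
      double tr_s = (double) K * (n_sol + zs0);
      p_s = R::rbeta(1.0 + S_sol, 1.0 + tr_s - S_sol);
      double pzs = psi_s * std::pow(1.0 - p_s, K);
      double qs = pzs / (pzs + (1.0 - psi_s));
      zs0 = (Ms_extra > 0) ? (int) R::rbinom(Ms_extra, qs) : 0;
      psi_s = R::rbeta(1.0 + n_sol + zs0, 1.0 + (Ms_extra - zs0));
      S_count = n_sol + zs0;
    }

    // --- derived abundance: observed-group sizes + prior draws for the
    //     included never-detected groups (+ solitaries) ---
    if (it >= burn_in) {
      double N = Sm;
      for (int j = 0; j < z0; ++j) N += rztpois1(lambda, min_size);
      int row = it - burn_in;
      out(row, 0) = p_g;
      out(row, 1) = p_i;
      out(row, 2) = psi_g;
      out(row, 3) = lambda;
      out(row, 4) = nG + z0;          // number of groups G
      out(row, 5) = N + S_count;      // total abundance N
      if (sol) {
        out(row, 6) = p_s;
        out(row, 7) = psi_s;
        out(row, 8) = S_count;        // number of solitaries S
      }
    }
  }
  colnames(out) = sol
    ? CharacterVector::create("p_g", "p_i", "psi_g", "lambda", "G", "N",
                              "p_s", "psi_s", "S")
    : CharacterVector::create("p_g", "p_i", "psi_g", "lambda", "G", "N");
  return out;
}

// MCMC core for the conventional One-Step closed CMR model.
// y_ik ~ Bern(z_i * p), z_i ~ Bern(psi); observed rows (>=1 detection) have
// z_i = 1 with probability one, and the M augmented all-zero rows are
// exchangeable, so the sampler reduces to three conjugate scalar draws.
// [[Rcpp::export(rng = true)]]
NumericMatrix onestep_mcmc_chain(int n_obs, double S_det, int K,
                                 int M_ind, int n_iter, int burn_in,
                                 double p0) {
  const int M_extra = M_ind - n_obs;
  double p = p0, psi = 0.5;
  int z0 = M_extra / 4;
  const int n_keep = n_iter - burn_in;
  NumericMatrix out(n_keep, 3);
  for (int it = 0; it < n_iter; ++it) {
    double trials = (double) K * (n_obs + z0);
    p = R::rbeta(1.0 + S_det, 1.0 + trials - S_det);
    double pz = psi * std::pow(1.0 - p, K);
    double q = pz / (pz + (1.0 - psi));
    z0 = (M_extra > 0) ? (int) R::rbinom(M_extra, q) : 0;
    psi = R::rbeta(1.0 + n_obs + z0, 1.0 + (M_extra - z0));
    if (it >= burn_in) {
      int row = it - burn_in;
      out(row, 0) = p;
      out(row, 1) = psi;
      out(row, 2) = n_obs + z0;  // abundance N
    }
  }
  colnames(out) = CharacterVector::create("p", "psi", "N");
  return out;
}
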