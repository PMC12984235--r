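// Joint negative log-likelihood of the time-varying surplus production
// state-space model.
//
// Latent states: log-biomass on the Euler grid (step dt), annual log fishing
// mortality (random walk), and up to two Ornstein-Uhlenbeck deviation paths
// driving maximum net productivity m_t and carrying capacity K_t.
// Observations: annual catch and multi-fleet abundance indices, both
// lognormal. Scenario codes select which OU paths are active and how the
// m- and K-deviations are coupled.

#define TMB_LIB_INIT R_init_tvspm
#include <TMB.hpp>

// Scenario codes (keep in sync with scenario_spec() on the R side)
// 0 CM, 1 RM, 2 KM, 3 PKRM, 4 LKRM, 5 IKRM

template <class Type>
Type ou_nll(const vector<Type> &U, Type psi, Type sigma, Type dt) {
  // Exact Gaussian transitions of dX = -psi X dt + sigma dW, stationary init.
  Type nll = Type(0);
  Type statsd = sigma / sqrt(Type(2) * psi);
  nll -= dnorm(U(0), Type(0), statsd, true);
  Type rho = exp(-psi * dt);
  Type tsd = sigma * sqrt((Type(1) - exp(Type(-2) * psi * dt)) / (Type(2) * psi));
  for (int i = 1; i < U.size(); i++)
    nll -= dnorm(U(i), rho * U(i - 1), tsd, true);
  return nll;
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_INTEGER(nyears);
  DATA_INTEGER(nsub);         // Euler sub-steps per year (1/dt)
  DATA_INTEGER(fox);          // 1 = Fox limit production function
  DATA_INTEGER(scenario);     // 0..5, see above
  DATA_SCALAR(d0);            // initial depletion B0/K0 (fixed)
  DATA_INTEGER(f_dynamics);   // 1 = latent annual log-F random walk
  DATA_INTEGER(mean_correct); // 1 = lognormal obs mean correction (-sd^2/2)
  DATA_INTEGER(report_ref);   // 1 = ADREPORT annual reference-point series
  DATA_VECTOR(obsvec);        // log observations in time order
  DATA_IVECTOR(obstype);      // 0 = catch, 1 = index
  DATA_IVECTOR(obsyear);      // 0-based year of each observation
  DATA_IVECTOR(obsfleet);     // 0-based fleet (index obs), -1 for catch
  DATA_VECTOR_INDICATOR(keep, obsvec);
  DATA_VECTOR(prior_logr);    // (mean, sd, use-flag)
  DATA_VECTOR(prior_logK);
  DATA_VECTOR(prior_logalpha); // weak prior on log(sdi/sdb), per fleet
  DATA_VECTOR(prior_logbeta);  // weak prior on log(sdc/sdf)

  PARAMETER(logr);
  PARAMETER(logK);
  PARAMETER(logn);            // shape; mapped off for Schaefer/Fox
  PARAMETER_VECTOR(logq);     // per-fleet catchability
  PARAMETER(logsdb);          // biomass process SD
  PARAMETER(logsdf);          // log-F random-walk SD (annual)
  PARAMETER(logsdc);          // catch observation SD
  PARAMETER_VECTOR(logsdi);   // per-fleet index observation SD
  PARAMETER(logpsim);         // OU mean reversion, m side
  PARAMETER(logsigm);         // OU diffusion SD, m side
  PARAMETER(logpsik);         // OU mean reversion, K side
  PARAMETER(logsigk);         // OU diffusion SD, K side
  PARAMETER(lambda);          // power-law coupling exponent (LKRM)
  PARAMETER_VECTOR(logF);     // nyears, constant within year
  PARAMETER_VECTOR(logB);     // ns latent grid points (1..ns); point 0 fixed
  PARAMETER_VECTOR(Um);       // OU path, m side (ns+1; mapped to 0 if off)
  PARAMETER_VECTOR(Uk);       // OU path, K side (ns+1; mapped to 0 if off)

  int ns = nyears * nsub;
  Type dt = Type(1) / Type(nsub);
  Type r = exp(logr), K = exp(logK);
  Type n = exp(logn);
  Type ee = exp(Type(1));

  // m = r K n^{-n/(n-1)}; Fox limit: m = r K / e
  Type npow = Type(0), gamma = Type(0), mbar;
  if (fox) {
    mbar = r * K / ee;
  } else {
    npow = pow(n, n / (n - Type(1)));
    gamma = npow / (n - Type(1));
    mbar = r * K / npow;
  }

  Type nll = Type(0);

  // OU deviation paths (active set depends on scenario)
  bool um_active = (scenario == 1 || scenario == 5);
  bool uk_active = (scenario >= 2 && scenario <= 5);
  Type psim = exp(logpsim), sigm = exp(logsigm);
  Type psik = exp(logpsik), sigk = exp(logsigk);
  if (um_active) nll += ou_nll(Um, psim, sigm, dt);
  if (uk_active) nll += ou_nll(Uk, psik, sigk, dt);

  // Couple deviations: logGm drives m_t, logGk drives K_t
  vector<Type> logGm(ns + 1), logGk(ns + 1);
  logGm.setZero();
  logGk.setZero();
  for (int i = 0; i <= ns; i++) {
    switch (scenario) {
    case 1: // RM: m varies, K constant
      logGm(i) = Um(i);
      break;
    case 2: // KM: K varies, r held constant => m tracks K
      logGm(i) = Uk(i);
      logGk(i) = Uk(i);
      break;
    case 3: // PKRM: G(r) = G(K) => logGm = 2 logGk
      logGm(i) = Type(2) * Uk(i);
      logGk(i) = Uk(i);
      break;
    case 4: // LKRM: G(r) = G(K)^lambda => logGm = (1 + lambda) logGk
      logGm(i) = (Type(1) + lambda) * Uk(i);
      logGk(i) = Uk(i);
      break;
    case 5: // IKRM: independent OU on m and K
      logGm(i) = Um(i);
      logGk(i) = Uk(i);
      break;
    default: // CM
      break;
    }
  }

  // Biomass path on the grid; point 0 pinned at d0 * K_0
  vector<Type> B(ns + 1), mt(ns + 1), Kt(ns + 1);
  for (int i = 0; i <= ns; i++) {
    mt(i) = mbar * exp(logGm(i));
    Kt(i) = K * exp(logGk(i));
  }
  B(0) = d0 * Kt(0);
  for (int i = 1; i <= ns; i++) B(i) = exp(logB(i - 1));

  // Euler-Maruyama transitions of log B (Ito-corrected drift)
  Type sdb = exp(logsdb);
  Type sdbdt = sdb * sqrt(dt);
  for (int i = 0; i < ns; i++) {
    int y = i / nsub;
    Type Fi = exp(logF(y));
    Type rel = B(i) / Kt(i);
    Type prodrate; // net production per unit biomass
    if (fox) {
      prodrate = ee * mt(i) / Kt(i) * log(Type(1) / rel);
    } else {
      prodrate = gamma * mt(i) / Kt(i) * (Type(1) - pow(rel, n - Type(1)));
    }
    Type mu = log(B(i)) + (prodrate - Fi - sdb * sdb / Type(2)) * dt;
    nll -= dnorm(log(B(i + 1)), mu, sdbdt, true);
  }

  // Annual log-F random walk
  if (f_dynamics) {
    Type sdf = exp(logsdf);
    for (int y = 1; y < nyears; y++)
      nll -= dnorm(logF(y), logF(y - 1), sdf, true);
  }

  // Annual summaries: trapezoid integral of B over each year equals the
  // annual mean (year length 1); predicted catch = F_y * integral
  vector<Type> Bbar(nyears), Chat(nyears);
  for (int y = 0; y < nyears; y++) {
    Type s = Type(0);
    for (int j = 0; j < nsub; j++)
      s += (B(y * nsub + j) + B(y * nsub + j + 1)) / Type(2);
    Bbar(y) = s * dt;
    Chat(y) = exp(logF(y)) * Bbar(y);
  }

  // Observations
  Type sdc = exp(logsdc);
  for (int j = 0; j < obsvec.size(); j++) {
    Type pred, sd;
    if (obstype(j) == 0) {
      pred = log(Chat(obsyear(j)));
      sd = sdc;
    } else {
      int f = obsfleet(j);
      sd = exp(logsdi(f));
      pred = logq(f) + log(Bbar(obsyear(j)));
    }
    if (mean_correct) pred -= sd * sd / Type(2);
    nll -= keep(j) * dnorm(obsvec(j), pred, sd, true);
  }

  // Priors on log r and log K
  if (prior_logr(2) > Type(0.5))
    nll -= dnorm(logr, prior_logr(0), prior_logr(1), true);
  if (prior_logK(2) > Type(0.5))
    nll -= dnorm(logK, prior_logK(0), prior_logK(1), true);
  // Weakly informative priors regularizing the noise-variance ratios
  // (stabilize the sdi/sdb and sdc/sdf decompositions)
  if (prior_logalpha(2) > Type(0.5))
    for (int f = 0; f < logsdi.size(); f++)
      nll -= dnorm(logsdi(f) - logsdb, prior_logalpha(0), prior_logalpha(1), true);
  if (prior_logbeta(2) > Type(0.5))
    nll -= dnorm(logsdc - logsdf, prior_logbeta(0), prior_logbeta(1), true);

  // Annualized productivity and reference-point series (trapezoid weights)
  Type logbfac = fox ? Type(-1) : -log(n) / (n - Type(1)); // log(Bmsy/K)
  Type logrfac = fox ? Type(1) : log(npow);                 // log(r K / m)
  vector<Type> logm_y(nyears), logK_y(nyears), logr_y(nyears);
  vector<Type> logBmsy_y(nyears), logFmsy_y(nyears), logMSY_y(nyears);
  vector<Type> logBBmsy(nyears), logFFmsy(nyears);
  for (int y = 0; y < nyears; y++) {
    Type gm = Type(0), gk = Type(0);
    for (int j = 0; j < nsub; j++) {
      gm += (logGm(y * nsub + j) + logGm(y * nsub + j + 1)) / Type(2);
      gk += (logGk(y * nsub + j) + logGk(y * nsub + j + 1)) / Type(2);
    }
    gm *= dt;
    gk *= dt;
    logm_y(y) = log(mbar) + gm;
    logK_y(y) = logK + gk;
    logr_y(y) = logm_y(y) - logK_y(y) + logrfac;
    logBmsy_y(y) = logK_y(y) + logbfac;
    logMSY_y(y) = logm_y(y);
    logFmsy_y(y) = logm_y(y) - logBmsy_y(y);
    logBBmsy(y) = log(Bbar(y)) - logBmsy_y(y);
    logFFmsy(y) = logF(y) - logFmsy_y(y);
  }

  REPORT(B);
  REPORT(Bbar);
  REPORT(Chat);
  REPORT(logGm);
  REPORT(logGk);
  REPORT(mt);
  REPORT(Kt);
  REPORT(logm_y);
  REPORT(logK_y);
  REPORT(logr_y);
  REPORT(logBmsy_y);
  REPORT(logFmsy_y);
  REPORT(logMSY_y);
  REPORT(logBBmsy);
  REPORT(logFFmsy);
  if (report_ref) {
    ADREPORT(logm_y);
    ADREPORT(logK_y);
    ADREPORT(logr_y);
    ADREPORT(logBmsy_y);
    ADREPORT(logFmsy_y);
    ADREPORT(logMSY_y);
    ADREPORT(logBBmsy);
    ADREPORT(logFFmsy);
  }

  return nll;
}
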