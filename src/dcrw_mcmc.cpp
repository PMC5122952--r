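#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Metropolis-within-Gibbs kernel for the first-difference correlated
// random walk state-space model. Log-densities drop additive constants
// that cancel in every Metropolis ratio (the exported R-side
// dcrw_log_posterior carries the full constants for testing).

static inline double norm_l(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd);
}

static inline double t_l(double x, double mu, double scale, double nu) {
  double z = (x - mu) / scale;
  return -0.5 * (nu + 1.0) * std::log1p(z * z / nu) - std::log(scale);
}

struct DcrwState {
  std::vector<double> lon, lat;        // latent positions, length n
  double gamma, theta, sigma, tau;
  int n;
  // observations grouped by day (0-based)
  std::vector<std::vector<int> > obs_at;
  const double *olon, *olat, *omult;
  double nu, fsd;

  // log-density of the process step *into* position t (0-based, t >= 1)
  double proc_term(int t) const {
    double ct = std::cos(theta), st = std::sin(theta);
    return proc_term_at(t, lon[t], lat[t], gamma, ct, st, sigma);
  }

  double proc_term_at(int t, double xlon, double xlat,
                      double g, double ct, double st, double s) const {
    if (t == 1) {
      return norm_l(xlon, lon[0], fsd) + norm_l(xlat, lat[0], fsd);
    }
    double dl = lon[t - 1] - lon[t - 2];
    double db = lat[t - 1] - lat[t - 2];
    double ml = lon[t - 1] + g * (ct * dl - st * db);
    double mb = lat[t - 1] + g * (st * dl + ct * db);
    return norm_l(xlon, ml, s) + norm_l(xlat, mb, s);
  }

  double obs_term(int t, double xlon, double xlat, double tau_) const {
    double out = 0.0;
    const std::vector<int> &ix = obs_at[t];
    for (size_t k = 0; k < ix.size(); ++k) {
      int j = ix[k];
      double sc = tau_ * omult[j];
      out += t_l(olon[j], xlon, sc, nu) + t_l(olat[j], xlat, sc, nu);
    }
    return out;
  }

  // local log-density of all terms touching position t, evaluated with
  // candidate coordinates substituted at t
  double local(int t, double xlon, double xlat) const {
    double ct = std::cos(theta), st = std::sin(theta);
    double out = obs_term(t, xlon, xlat, tau);
    // term t: candidate is the arrival position
    if (t >= 1) out += proc_term_at(t, xlon, xlat, gamma, ct, st, sigma);
    // term t+1: candidate plays x_{t}, the departure position
    if (t + 1 < n) {
      if (t + 1 == 1) {
        out += norm_l(lon[1], xlon, fsd) + norm_l(lat[1], xlat, fsd);
      } else {
        double dl = xlon - lon[t - 1], db = xlat - lat[t - 1];
        double ml = xlon + gamma * (ct * dl - st * db);
        double mb = xlat + gamma * (st * dl + ct * db);
        out += norm_l(lon[t + 1], ml, sigma) + norm_l(lat[t + 1], mb, sigma);
      }
    }
    // term t+2: candidate plays x_{t}, two steps back
    if (t + 2 < n && t + 2 >= 2) {
      double dl = lon[t + 1] - xlon, db = lat[t + 1] - xlat;
      double ml = lon[t + 1] + gamma * (ct * dl - st * db);
      double mb = lat[t + 1] + gamma * (st * dl + ct * db);
      out += norm_l(lon[t + 2], ml, sigma) + norm_l(lat[t + 2], mb, sigma);
    }
    return out;
  }

  double total_process(double g, double th, double s) const {
    double ct = std::cos(th), st = std::sin(th), out = 0.0;
    for (int t = 2; t < n; ++t) {
      out += proc_term_at(t, lon[t], lat[t], g, ct, st, s);
    }
    return out;
  }

  double total_obs(double tau_) const {
    double out = 0.0;
    for (int t = 0; t < n; ++t) out += obs_term(t, lon[t], lat[t], tau_);
    return out;
  }
};

class Adapt {
public:
  double step;
  int acc, tries;
  explicit Adapt(double s) : step(s), acc(0), tries(0) {}
  void hit(bool a) { tries++; if (a) acc++; }
  void maybe_adapt() {
    if (tries >= 50) {
      double rate = (double)acc / tries;
      step *= (rate > 0.44) ? 1.15 : 0.87;
      if (step < 1e-7) step = 1e-7;
      acc = 0; tries = 0;
    }
  }
};

// [[Rcpp::export]]
List dcrw_chain_cpp(NumericMatrix x0, IntegerVector obs_day,
                    NumericVector obs_lon, NumericVector obs_lat,
                    NumericVector obs_mult,
                    double gamma0, double theta0, double sigma0, double tau0,
                    int n_iter, int burn_in, int thin,
                    double gamma_lo, double gamma_hi,
                    double theta_lo, double theta_hi,
                    double sigma_hn, double tau_hn,
                    double nu, double first_step_sd) {
  int n = x0.nrow();
  DcrwState st;
  st.n = n;
  st.lon.assign(n, 0.0);
  st.lat.assign(n, 0.0);
  for (int i = 0; i < n; ++i) { st.lon[i] = x0(i, 0); st.lat[i] = x0(i, 1); }
  st.gamma = gamma0; st.theta = theta0; st.sigma = sigma0; st.tau = tau0;
  st.nu = nu; st.fsd = first_step_sd;
  st.obs_at.assign(n, std::vector<int>());
  for (int j = 0; j < obs_day.size(); ++j) {
    st.obs_at[obs_day[j] - 1].push_back(j);
  }
  st.olon = obs_lon.begin(); st.olat = obs_lat.begin();
  st.omult = obs_mult.begin();

  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix keep_lon(n_keep, n), keep_lat(n_keep, n);
  NumericVector keep_gamma(n_keep), keep_theta(n_keep),
                keep_sigma(n_keep), keep_tau(n_keep);

  std::vector<Adapt> sx(n, Adapt(0.05));
  Adapt ag(0.1), at(0.2), as(0.4), atu(0.4);

  int row = 0;
  for (int it = 1; it <= n_iter; ++it) {
    bool adapting = it <= burn_in;

    // latent positions, joint lon/lat proposal per day
    for (int t = 0; t < n; ++t) {
      double cl = st.lon[t] + R::norm_rand() * sx[t].step;
      double cb = st.lat[t] + R::norm_rand() * sx[t].step;
      double lr = st.local(t, cl, cb) - st.local(t, st.lon[t], st.lat[t]);
      bool a = std::log(R::unif_rand()) < lr;
      if (a) { st.lon[t] = cl; st.lat[t] = cb; }
      if (adapting) { sx[t].hit(a); sx[t].maybe_adapt(); }
    }

    // gamma (uniform prior: reject outside support)
    {
      double cand = st.gamma + R::norm_rand() * ag.step;
      bool a = false;
      if (cand >= gamma_lo && cand <= gamma_hi) {
        double lr = st.total_process(cand, st.theta, st.sigma)
                  - st.total_process(st.gamma, st.theta, st.sigma);
        a = std::log(R::unif_rand()) < lr;
        if (a) st.gamma = cand;
      }
      if (adapting) { ag.hit(a); ag.maybe_adapt(); }
    }

    // theta
    {
      double cand = st.theta + R::norm_rand() * at.step;
      bool a = false;
      if (cand >= theta_lo && cand <= theta_hi) {
        double lr = st.total_process(st.gamma, cand, st.sigma)
                  - st.total_process(st.gamma, st.theta, st.sigma);
        a = std::log(R::unif_rand()) < lr;
        if (a) st.theta = cand;
      }
      if (adapting) { at.hit(a); at.maybe_adapt(); }
    }

    // sigma: log-scale random walk, half-Normal prior, log-Jacobian
    {
      double cand = st.sigma * std::exp(R::norm_rand() * as.step);
      double zc = cand / sigma_hn, z0 = st.sigma / sigma_hn;
      double lr = st.total_process(st.gamma, st.theta, cand)
                - st.total_process(st.gamma, st.theta, st.sigma)
                - 0.5 * (zc * zc - z0 * z0)
                + std::log(cand / st.sigma);
      bool a = std::log(R::unif_rand()) < lr;
      if (a) st.sigma = cand;
      if (adapting) { as.hit(a); as.maybe_adapt(); }
    }

    // tau: log-scale random walk, half-Normal prior
    {
      double cand = st.tau * std::exp(R::norm_rand() * atu.step);
      double zc = cand / tau_hn, z0 = st.tau / tau_hn;
      double lr = st.total_obs(cand) - st.total_obs(st.tau)
                - 0.5 * (zc * zc - z0 * z0)
                + std::log(cand / st.tau);
      bool a = std::log(R::unif_rand()) < lr;
      if (a) st.tau = cand;
      if (adapting) { atu.hit(a); atu.maybe_adapt(); }
    }

    if (it > burn_in && (it - burn_in) % thin == 0) {
      for (int t = 0; t < n; ++t) {
        keep_lon(row, t) = st.lon[t];
        keep_lat(row, t) = st.lat[t];
      }
      keep_gamma[row] = st.gamma;
      keep_theta[row] = st.theta;
      keep_sigma[row] = st.sigma;
      keep_tau[row] = st.tau;
      ++row;
    }
  }

  return List::create(_["lon"] = keep_lon, _["lat"] = keep_lat,
                      _["gamma"] = keep_gamma, _["theta"] = keep_theta,
                      _["sigma"] = keep_sigma, _["tau"] = keep_tau);
}
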