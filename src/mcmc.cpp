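// Metropolis-within-Gibbs sampler for the shared spatial-component model.
//
// Single-site adaptive random-walk Metropolis updates for the intercepts,
// regression coefficients, unstructured effects u, shared CAR field phi,
// treatment-specific CAR fields s and the free log-weights, with conjugate
// Gibbs draws for every precision (Gamma for CAR and fixed-effect
// precisions, Wishart for the precision matrix of u). The linear predictor
// eta and its log(1 + exp(eta)) cache are maintained incrementally; CAR
// fields are re-centred per connected component at the end of every
// iteration (the usual intrinsic-CAR identification device), with eta kept
// consistent. All randomness flows through R's RNG so a fixed R seed gives
// byte-identical chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double log1pe(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct Adapt {
  std::vector<double> scale;
  std::vector<int> acc, att;
  Adapt(int n, double s0) : scale(n, s0), acc(n, 0), att(n, 0) {}
  void tune() {
    for (size_t i = 0; i < scale.size(); ++i) {
      if (att[i] < 10) continue;
      double r = double(acc[i]) / att[i];
      if (r > 0.5) scale[i] *= 1.3;
      else if (r < 0.3) scale[i] /= 1.3;
      acc[i] = 0; att[i] = 0;
    }
  }
};

// [[Rcpp::export]]
List mcmc_chain_cpp(const arma::mat& y, const arma::mat& X,
                    const arma::ivec& area,
                    const List& area_rows, const List& col_rows,
                    const List& nbr, const arma::ivec& comp, int n_comp,
                    const List& init, const List& flags, const List& hyper,
                    int n_iter, int burn_in, int thin, int adapt_interval) {
  const int n = y.n_rows;
  const int p = X.n_cols;
  const int A = area_rows.size();

  const bool include_u = as<bool>(flags["include_u"]);
  const bool u_mvn = as<bool>(flags["u_mvn"]);
  const bool include_s = as<bool>(flags["include_s"]);
  const bool include_shared = as<bool>(flags["include_shared"]);
  const bool flat_fixed = as<bool>(flags["flat_fixed"]);
  IntegerVector pairR = flags["pair"];           // 0-based, length 0 or 2
  const bool has_pair = pairR.size() == 2;
  const int pk1 = has_pair ? pairR[0] : -1;
  const int pk2 = has_pair ? pairR[1] : -1;

  const double a_fixed = as<double>(hyper["a_fixed"]);
  const double b_fixed = as<double>(hyper["b_fixed"]);
  const double a_car = as<double>(hyper["a_car"]);
  const double b_car = as<double>(hyper["b_car"]);
  const double wish_df = as<double>(hyper["wishart_df"]);
  const arma::mat wish_scale = as<arma::mat>(hyper["wishart_scale"]);
  const double prec_delta = as<double>(hyper["prec_log_delta"]);
  const double flat_prec = as<double>(hyper["flat_prec"]);
  const double a_u = as<double>(hyper["a_u"]);
  const double b_u = as<double>(hyper["b_u"]);

  // state
  arma::vec alpha = as<arma::vec>(init["alpha"]);
  arma::mat beta = as<arma::mat>(init["beta"]);        // p x 3
  arma::mat u = as<arma::mat>(init["u"]);              // A x 3
  arma::mat s = as<arma::mat>(init["s"]);              // A x 3
  arma::vec phi = as<arma::vec>(init["phi"]);          // A
  arma::vec nu = as<arma::vec>(init["nu"]);            // 2 free log-weights
  arma::vec phi2 = as<arma::vec>(init["phi2"]);        // A (unused w/o pair)
  double nu2 = as<double>(init["nu2"]);
  double tau_phi = as<double>(init["tau_phi"]);
  arma::vec tau_s = as<arma::vec>(init["tau_s"]);
  double tau_alpha = as<double>(init["tau_alpha"]);
  arma::vec tau_beta = as<arma::vec>(init["tau_beta"]);
  arma::vec tau_u = as<arma::vec>(init["tau_u"]);
  double tau_phi2 = as<double>(init["tau_phi2"]);
  arma::mat P = as<arma::mat>(init["P"]);              // 3 x 3 precision of u

  arma::vec delta(3);
  auto set_delta = [&]() {
    delta[0] = std::exp(nu[0]);
    delta[1] = std::exp(nu[1]);
    delta[2] = std::exp(-(nu[0] + nu[1]));
  };
  set_delta();
  double d2a = std::exp(nu2), d2b = std::exp(-nu2);    // pair weights

  // index structures
  std::vector<arma::uvec> arows(A), crows(p), neigh(A);
  for (int a = 0; a < A; ++a) {
    arows[a] = as<arma::uvec>(area_rows[a]);
    neigh[a] = as<arma::uvec>(nbr[a]);
  }
  for (int m = 0; m < p; ++m) crows[m] = as<arma::uvec>(col_rows[m]);
  // unordered edge list for CAR quadratic forms
  std::vector<std::pair<int,int>> edges;
  for (int a = 0; a < A; ++a)
    for (arma::uword t = 0; t < neigh[a].n_elem; ++t)
      if ((int)neigh[a][t] > a) edges.push_back({a, (int)neigh[a][t]});
  const int rankL = A - n_comp;

  // linear predictor and log(1+exp(eta)) cache
  arma::mat eta = X * beta;
  for (int k = 0; k < 3; ++k) {
    for (int j = 0; j < n; ++j) {
      int a = area[j];
      double e = alpha[k];
      if (include_u) e += u(a, k);
      if (include_shared) e += delta[k] * phi[a];
      if (include_s) e += s(a, k);
      if (has_pair) {
        if (k == pk1) e += d2a * phi2[a];
        else if (k == pk2) e += d2b * phi2[a];
      }
      eta(j, k) += e;
    }
  }
  arma::mat lse(n, 3);
  for (int k = 0; k < 3; ++k)
    for (int j = 0; j < n; ++j) lse(j, k) = log1pe(eta(j, k));

  auto dll_rows = [&](const arma::uvec& rows, int k, double d) {
    double out = 0.0;
    for (arma::uword t = 0; t < rows.n_elem; ++t) {
      int j = rows[t];
      out += y(j, k) * d - log1pe(eta(j, k) + d) + lse(j, k);
    }
    return out;
  };
  auto apply_rows = [&](const arma::uvec& rows, int k, double d) {
    for (arma::uword t = 0; t < rows.n_elem; ++t) {
      int j = rows[t];
      eta(j, k) += d;
      lse(j, k) = log1pe(eta(j, k));
    }
  };
  auto car_quad = [&](const arma::vec& x) {
    double q = 0.0;
    for (auto& e : edges) { double d = x[e.first] - x[e.second]; q += d * d; }
    return q;
  };
  auto rgamma_rate = [&](double shape, double rate) {
    return R::rgamma(shape, 1.0 / rate);
  };

  // adaptive RW scales
  Adapt ad_alpha(3, 0.1), ad_beta(p * 3, 0.2), ad_u(A * 3, 0.5),
        ad_phi(A, 0.5), ad_s(A * 3, 0.5), ad_nu(2, 0.1),
        ad_phi2(A, 0.5), ad_nu2(1, 0.1);

  // storage
  const int n_ret = (n_iter - burn_in) / thin;
  arma::mat alpha_d(n_ret, 3), beta_d(n_ret, p * 3), nu_d(n_ret, 3);
  arma::mat u_d(n_ret, A * 3), s_d(n_ret, A * 3), phi_d(n_ret, A);
  arma::mat tau_d(n_ret, 9);   // tau_phi, tau_s(3), tau_alpha, tau_beta(3), tau_phi2
  arma::mat tauu_d(n_ret, 3), P_d(n_ret, 9), dev_d(n_ret, 1);
  arma::mat phi2_d, nu2_d;
  if (has_pair) { phi2_d.set_size(n_ret, A); nu2_d.set_size(n_ret, 2); }

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- intercepts ---------------------------------------------------
    for (int k = 0; k < 3; ++k) {
      ad_alpha.att[k] += 1;
      double d = ad_alpha.scale[k] * R::norm_rand();
      double prec = flat_fixed ? flat_prec : tau_alpha;
      double lr = -0.5 * prec * (2.0 * d * alpha[k] + d * d);
      for (int j = 0; j < n; ++j)
        lr += y(j, k) * d - log1pe(eta(j, k) + d) + lse(j, k);
      if (std::log(R::unif_rand()) < lr) {
        ad_alpha.acc[k] += 1;
        alpha[k] += d;
        for (int j = 0; j < n; ++j) { eta(j, k) += d; lse(j, k) = log1pe(eta(j, k)); }
      }
    }
    // --- regression coefficients --------------------------------------
    for (int k = 0; k < 3; ++k) {
      for (int m = 0; m < p; ++m) {
        int id = k * p + m;
        ad_beta.att[id] += 1;
        double d = ad_beta.scale[id] * R::norm_rand();
        double prec = flat_fixed ? flat_prec : tau_beta[k];
        double lr = -0.5 * prec * (2.0 * d * beta(m, k) + d * d)
                  + dll_rows(crows[m], k, d);
        if (std::log(R::unif_rand()) < lr) {
          ad_beta.acc[id] += 1;
          beta(m, k) += d;
          apply_rows(crows[m], k, d);
        }
      }
    }
    // --- unstructured effects u ---------------------------------------
    if (include_u) {
      for (int a = 0; a < A; ++a) {
        for (int k = 0; k < 3; ++k) {
          int id = k * A + a;
          ad_u.att[id] += 1;
          double d = ad_u.scale[id] * R::norm_rand();
          double lr;
          if (u_mvn) {
            double cross = 0.0;
            for (int l = 0; l < 3; ++l) cross += P(k, l) * u(a, l);
            lr = -0.5 * (2.0 * d * cross + d * d * P(k, k));
          } else {
            lr = -0.5 * tau_u[k] * (2.0 * d * u(a, k) + d * d);
          }
          lr += dll_rows(arows[a], k, d);
          if (std::log(R::unif_rand()) < lr) {
            ad_u.acc[id] += 1;
            u(a, k) += d;
            apply_rows(arows[a], k, d);
          }
        }
      }
    }
    // --- shared CAR field phi -----------------------------------------
    if (include_shared) {
      for (int a = 0; a < A; ++a) {
        ad_phi.att[a] += 1;
        double d = ad_phi.scale[a] * R::norm_rand();
        double deg = neigh[a].n_elem;
        double snb = 0.0;
        for (arma::uword t = 0; t < neigh[a].n_elem; ++t) snb += phi[neigh[a][t]];
        double lr = -0.5 * tau_phi * (2.0 * d * (deg * phi[a] - snb) + deg * d * d);
        for (int k = 0; k < 3; ++k) lr += dll_rows(arows[a], k, delta[k] * d);
        if (std::log(R::unif_rand()) < lr) {
          ad_phi.acc[a] += 1;
          phi[a] += d;
          for (int k = 0; k < 3; ++k) apply_rows(arows[a], k, delta[k] * d);
        }
      }
      // --- free log-weights ------------------------------------------
      for (int w = 0; w < 2; ++w) {
        ad_nu.att[w] += 1;
        double d = ad_nu.scale[w] * R::norm_rand();
        double nu_new = nu[w] + d;
        arma::vec nu_prop = nu; nu_prop[w] = nu_new;
        arma::vec delta_new(3);
        delta_new[0] = std::exp(nu_prop[0]);
        delta_new[1] = std::exp(nu_prop[1]);
        delta_new[2] = std::exp(-(nu_prop[0] + nu_prop[1]));
        double lr = -0.5 * prec_delta * (nu_new * nu_new - nu[w] * nu[w]);
        // columns w (direct) and 2 (through the product constraint) change
        int cols[2] = {w, 2};
        for (int c = 0; c < 2; ++c) {
          int k = cols[c];
          double dd_scale = delta_new[k] - delta[k];
          if (dd_scale == 0.0) continue;
          for (int j = 0; j < n; ++j) {
            double dd = dd_scale * phi[area[j]];
            lr += y(j, k) * dd - log1pe(eta(j, k) + dd) + lse(j, k);
          }
        }
        if (std::log(R::unif_rand()) < lr) {
          ad_nu.acc[w] += 1;
          for (int c = 0; c < 2; ++c) {
            int k = cols[c];
            double dd_scale = delta_new[k] - delta[k];
            if (dd_scale == 0.0) continue;
            for (int j = 0; j < n; ++j) {
              eta(j, k) += dd_scale * phi[area[j]];
              lse(j, k) = log1pe(eta(j, k));
            }
          }
          nu = nu_prop;
          set_delta();
        }
      }
    }
    // --- treatment-specific CAR fields s ------------------------------
    if (include_s) {
      for (int k = 0; k < 3; ++k) {
        for (int a = 0; a < A; ++a) {
          int id = k * A + a;
          ad_s.att[id] += 1;
          double d = ad_s.scale[id] * R::norm_rand();
          double deg = neigh[a].n_elem;
          double snb = 0.0;
          for (arma::uword t = 0; t < neigh[a].n_elem; ++t) snb += s(neigh[a][t], k);
          double lr = -0.5 * tau_s[k] * (2.0 * d * (deg * s(a, k) - snb) + deg * d * d)
                    + dll_rows(arows[a], k, d);
          if (std::log(R::unif_rand()) < lr) {
            ad_s.acc[id] += 1;
            s(a, k) += d;
            apply_rows(arows[a], k, d);
          }
        }
      }
    }
    // --- second shared component --------------------------------------
    if (has_pair) {
      for (int a = 0; a < A; ++a) {
        ad_phi2.att[a] += 1;
        double d = ad_phi2.scale[a] * R::norm_rand();
        double deg = neigh[a].n_elem;
        double snb = 0.0;
        for (arma::uword t = 0; t < neigh[a].n_elem; ++t) snb += phi2[neigh[a][t]];
        double lr = -0.5 * tau_phi2 * (2.0 * d * (deg * phi2[a] - snb) + deg * d * d)
                  + dll_rows(arows[a], pk1, d2a * d) + dll_rows(arows[a], pk2, d2b * d);
        if (std::log(R::unif_rand()) < lr) {
          ad_phi2.acc[a] += 1;
          phi2[a] += d;
          apply_rows(arows[a], pk1, d2a * d);
          apply_rows(arows[a], pk2, d2b * d);
        }
      }
      { // single free log-weight of the pair
        ad_nu2.att[0] += 1;
        double d = ad_nu2.scale[0] * R::norm_rand();
        double nu2_new = nu2 + d;
        double a_new = std::exp(nu2_new), b_new = std::exp(-nu2_new);
        double lr = -0.5 * prec_delta * (nu2_new * nu2_new - nu2 * nu2);
        for (int j = 0; j < n; ++j) {
          double dda = (a_new - d2a) * phi2[area[j]];
          double ddb = (b_new - d2b) * phi2[area[j]];
          lr += y(j, pk1) * dda - log1pe(eta(j, pk1) + dda) + lse(j, pk1);
          lr += y(j, pk2) * ddb - log1pe(eta(j, pk2) + ddb) + lse(j, pk2);
        }
        if (std::log(R::unif_rand()) < lr) {
          ad_nu2.acc[0] += 1;
          for (int j = 0; j < n; ++j) {
            eta(j, pk1) += (a_new - d2a) * phi2[area[j]];
            eta(j, pk2) += (b_new - d2b) * phi2[area[j]];
            lse(j, pk1) = log1pe(eta(j, pk1));
            lse(j, pk2) = log1pe(eta(j, pk2));
          }
          nu2 = nu2_new; d2a = a_new; d2b = b_new;
        }
      }
    }
    // --- conjugate precision updates ----------------------------------
    if (include_shared)
      tau_phi = rgamma_rate(a_car + 0.5 * rankL, b_car + 0.5 * car_quad(phi));
    if (include_s)
      for (int k = 0; k < 3; ++k)
        tau_s[k] = rgamma_rate(a_car + 0.5 * rankL, b_car + 0.5 * car_quad(s.col(k)));
    if (has_pair)
      tau_phi2 = rgamma_rate(a_car + 0.5 * rankL, b_car + 0.5 * car_quad(phi2));
    if (!flat_fixed) {
      tau_alpha = rgamma_rate(a_fixed + 1.5, b_fixed + 0.5 * arma::dot(alpha, alpha));
      for (int k = 0; k < 3; ++k)
        tau_beta[k] = rgamma_rate(a_fixed + 0.5 * p,
                                  b_fixed + 0.5 * arma::dot(beta.col(k), beta.col(k)));
    }
    if (include_u) {
      if (u_mvn) {
        // Wishart full conditional in the BUGS parameterisation:
        // P ~ dwish(scale + U'U, df + A); sampled by Bartlett decomposition
        arma::mat R_post = wish_scale + u.t() * u;
        double df_post = wish_df + A;
        arma::mat V = arma::inv_sympd(R_post);
        arma::mat Lc = arma::chol(V, "lower");
        arma::mat B(3, 3, arma::fill::zeros);
        for (int i = 0; i < 3; ++i) {
          B(i, i) = std::sqrt(R::rchisq(df_post - i));
          for (int j2 = 0; j2 < i; ++j2) B(i, j2) = R::norm_rand();
        }
        arma::mat LB = Lc * B;
        P = LB * LB.t();
      } else {
        for (int k = 0; k < 3; ++k)
          tau_u[k] = rgamma_rate(a_u + 0.5 * A,
                                 b_u + 0.5 * arma::dot(u.col(k), u.col(k)));
      }
    }
    // --- per-component re-centring of CAR fields ----------------------
    {
      arma::vec cnt(n_comp, arma::fill::zeros);
      for (int a = 0; a < A; ++a) cnt[comp[a]] += 1.0;
      bool changed = false;
      arma::vec m_phi(n_comp, arma::fill::zeros), m_phi2(n_comp, arma::fill::zeros);
      arma::mat m_s(n_comp, 3, arma::fill::zeros);
      if (include_shared) {
        for (int a = 0; a < A; ++a) m_phi[comp[a]] += phi[a];
        m_phi /= cnt;
        for (int a = 0; a < A; ++a) phi[a] -= m_phi[comp[a]];
        changed = true;
      }
      if (include_s) {
        for (int a = 0; a < A; ++a)
          for (int k = 0; k < 3; ++k) m_s(comp[a], k) += s(a, k);
        m_s.each_col() /= cnt;
        for (int a = 0; a < A; ++a)
          for (int k = 0; k < 3; ++k) s(a, k) -= m_s(comp[a], k);
        changed = true;
      }
      if (has_pair) {
        for (int a = 0; a < A; ++a) m_phi2[comp[a]] += phi2[a];
        m_phi2 /= cnt;
        for (int a = 0; a < A; ++a) phi2[a] -= m_phi2[comp[a]];
        changed = true;
      }
      if (changed && n > 0) {
        for (int j = 0; j < n; ++j) {
          int c = comp[area[j]];
          for (int k = 0; k < 3; ++k) {
            double adj = 0.0;
            if (include_shared) adj += delta[k] * m_phi[c];
            if (include_s) adj += m_s(c, k);
            if (has_pair) {
              if (k == pk1) adj += d2a * m_phi2[c];
              else if (k == pk2) adj += d2b * m_phi2[c];
            }
            if (adj != 0.0) { eta(j, k) -= adj; lse(j, k) = log1pe(eta(j, k)); }
          }
        }
      }
    }
    // --- adaptation (burn-in only) ------------------------------------
    if (iter <= burn_in && iter % adapt_interval == 0) {
      ad_alpha.tune(); ad_beta.tune(); ad_u.tune(); ad_phi.tune();
      ad_s.tune(); ad_nu.tune(); ad_phi2.tune(); ad_nu2.tune();
    }
    // --- retention ----------------------------------------------------
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      int r = (iter - burn_in) / thin - 1;
      for (int k = 0; k < 3; ++k) alpha_d(r, k) = alpha[k];
      for (int k = 0; k < 3; ++k)
        for (int m = 0; m < p; ++m) beta_d(r, k * p + m) = beta(m, k);
      nu_d(r, 0) = nu[0]; nu_d(r, 1) = nu[1]; nu_d(r, 2) = -(nu[0] + nu[1]);
      for (int k = 0; k < 3; ++k)
        for (int a = 0; a < A; ++a) {
          u_d(r, k * A + a) = u(a, k);
          s_d(r, k * A + a) = s(a, k);
        }
      for (int a = 0; a < A; ++a) phi_d(r, a) = phi[a];
      tau_d(r, 0) = tau_phi;
      for (int k = 0; k < 3; ++k) tau_d(r, 1 + k) = tau_s[k];
      tau_d(r, 4) = tau_alpha;
      for (int k = 0; k < 3; ++k) tau_d(r, 5 + k) = tau_beta[k];
      tau_d(r, 8) = tau_phi2;
      for (int k = 0; k < 3; ++k) tauu_d(r, k) = tau_u[k];
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l) P_d(r, k * 3 + l) = P(l, k);
      if (has_pair) {
        for (int a = 0; a < A; ++a) phi2_d(r, a) = phi2[a];
        nu2_d(r, 0) = nu2; nu2_d(r, 1) = -nu2;
      }
      double dev = 0.0;
      for (int k = 0; k < 3; ++k)
        for (int j = 0; j < n; ++j) dev += y(j, k) * eta(j, k) - lse(j, k);
      dev_d(r, 0) = -2.0 * dev;
    }
  }

  List out = List::create(
    _["alpha"] = alpha_d, _["beta"] = beta_d, _["log_delta"] = nu_d,
    _["u"] = u_d, _["s"] = s_d, _["phi"] = phi_d,
    _["tau"] = tau_d, _["tau_u"] = tauu_d, _["Sigma_u_prec"] = P_d,
    _["deviance"] = dev_d);
  if (has_pair) { out["phi2"] = phi2_d; out["log_delta2"] = nu2_d; }
  return out;
}
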