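// Evolutionary stochastic search engine for multi-trait Bayesian variable
// selection: parallel tempered chains, fast-scan Metropolis-Hastings
// add/delete moves, uniform crossover and exchange global moves, and a
// random-walk update of the g selection coefficient.
//
// The marginal likelihood only depends on the q x q quadratic form
// Qm = M' G^{-1} M with G = X_gamma' X_gamma and M = X_gamma' Y, so each
// chain maintains G^{-1} (A), B = G^{-1} M and Qm for a full-rank "basis"
// subset of its model, updated by rank-one Schur-complement formulas.
// Columns that are numerically dependent on the basis stay in the model
// (they count towards the size prior) but do not change the likelihood,
// mirroring the rank handling of the pivoted-QR reference evaluator.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct Shared {
  const mat *X;           // n x p, covariate-projected, centered
  mat Y;                  // n x q
  mat XtY;                // p x q
  vec colssq;             // p
  mat YtY;                // q x q
  int n, p, q;
  double neff;            // n - c_eff
  double g_rate;          // inverse-gamma rate n/2
  vec lp_size;            // log prior of a model of size k, k = 0..T
  int T;
  std::vector<vec> xtx_cache;   // lazily computed rows of X'X
  std::vector<char> cached;

  const vec &row(int j) {
    if (!cached[j]) {
      xtx_cache[j] = (X->col(j).t() * (*X)).t();
      cached[j] = 1;
    }
    return xtx_cache[j];
  }
};

struct Chain {
  std::vector<int> model;      // sorted SNP indices (0-based)
  std::vector<char> isbasis;   // parallel to model
  std::vector<int> basis;      // basis SNP indices, in insertion order
  std::vector<char> inmodel;   // length p membership flags
  mat A;                       // k x k inverse gram of basis columns
  mat B;                       // k x q
  mat Qm;                      // q x q quadratic form
  double g;
  double logml, lp_gamma, lp_g;
  int n_dependent;

  double logpost() const { return logml + lp_gamma + lp_g; }
};

double logdet_shrunk(const Shared &sh, const mat &Qm, double g) {
  // symmetrize: the rank-one updates of Qm leave harmless asymmetry at eps level
  mat S = arma::symmatu(sh.YtY - (g / (1.0 + g)) * Qm);
  mat L;
  if (arma::chol(L, S, "lower")) {
    return 2.0 * arma::sum(arma::log(L.diag()));
  }
  vec ev;
  arma::eig_sym(ev, S);
  double fl = 1e-12 * arma::trace(S) / sh.q;
  if (fl <= 0) fl = 1e-300;
  double ld = 0.0;
  for (uword i = 0; i < ev.n_elem; ++i) ld += std::log(std::max(ev(i), fl));
  return ld;
}

double logml_value(const Shared &sh, int k_rank, const mat &Qm, double g) {
  return -0.5 * k_rank * sh.q * std::log1p(g) -
         0.5 * sh.neff * logdet_shrunk(sh, Qm, g);
}

double log_prior_g(const Shared &sh, double g) {
  // inverse-gamma(1/2, n/2)
  return 0.5 * std::log(sh.g_rate) - std::lgamma(0.5) -
         1.5 * std::log(g) - sh.g_rate / g;
}

const double DEP_TOL = 1e-9;

// Evaluate a candidate model from scratch: greedy basis over the gram matrix
// assembled from cached X'X rows. Fills A, B, Qm, basis, isbasis.
void build_structures(Shared &sh, const std::vector<int> &model,
                      std::vector<char> &isbasis, std::vector<int> &basis,
                      mat &A, mat &B, mat &Qm) {
  int q = sh.q;
  isbasis.assign(model.size(), 0);
  basis.clear();
  A.set_size(0, 0);
  B.set_size(0, q);
  Qm.zeros(q, q);
  for (size_t ii = 0; ii < model.size(); ++ii) {
    int j = model[ii];
    const vec &rj = sh.row(j);
    int k = basis.size();
    vec c(k), u;
    for (int b = 0; b < k; ++b) c(b) = rj(basis[b]);
    double s = sh.colssq(j);
    vec d = sh.XtY.row(j).t();
    if (k > 0) {
      u = A * c;
      s -= arma::dot(c, u);
      d -= B.t() * c;
    }
    if (s > DEP_TOL * sh.colssq(j) && sh.colssq(j) > 0) {
      // extend the inverse gram by the Schur complement
      mat Anew(k + 1, k + 1);
      if (k > 0) {
        Anew.submat(0, 0, k - 1, k - 1) = A + (u * u.t()) / s;
        Anew.submat(0, k, k - 1, k) = -u / s;
        Anew.submat(k, 0, k, k - 1) = (-u / s).t();
      }
      Anew(k, k) = 1.0 / s;
      A = Anew;
      mat Bnew(k + 1, q);
      if (k > 0) Bnew.rows(0, k - 1) = B - (u * d.t()) / s;
      Bnew.row(k) = d.t() / s;
      B = Bnew;
      Qm += (d * d.t()) / s;
      basis.push_back(j);
      isbasis[ii] = 1;
    }
  }
}

void rebuild(Shared &sh, Chain &ch) {
  build_structures(sh, ch.model, ch.isbasis, ch.basis, ch.A, ch.B, ch.Qm);
  ch.n_dependent = (int)ch.model.size() - (int)ch.basis.size();
  ch.logml = logml_value(sh, ch.basis.size(), ch.Qm, ch.g);
  ch.lp_gamma = sh.lp_size((int)ch.model.size());
  ch.lp_g = log_prior_g(sh, ch.g);
}

// Propose adding SNP j. Returns rank increment (0 or 1) and fills the
// candidate quadratic form pieces.
struct AddEval {
  double s;
  vec c, u, d;
  bool independent;
  double logml_new;
};

void eval_add(Shared &sh, const Chain &ch, int j, AddEval &ev) {
  const vec &rj = sh.row(j);
  int k = ch.basis.size();
  ev.c.set_size(k);
  for (int b = 0; b < k; ++b) ev.c(b) = rj(ch.basis[b]);
  ev.s = sh.colssq(j);
  ev.d = sh.XtY.row(j).t();
  if (k > 0) {
    ev.u = ch.A * ev.c;
    ev.s -= arma::dot(ev.c, ev.u);
    ev.d -= ch.B.t() * ev.c;
  } else {
    ev.u.set_size(0);
  }
  ev.independent = (sh.colssq(j) > 0) && (ev.s > DEP_TOL * sh.colssq(j));
  if (ev.independent) {
    mat Qnew = ch.Qm + (ev.d * ev.d.t()) / ev.s;
    ev.logml_new = logml_value(sh, k + 1, Qnew, ch.g);
  } else {
    ev.logml_new = ch.logml;  // rank unchanged
  }
}

void apply_add(Shared &sh, Chain &ch, int j, const AddEval &ev) {
  // insert into sorted model
  std::vector<int>::iterator it =
      std::lower_bound(ch.model.begin(), ch.model.end(), j);
  size_t pos = it - ch.model.begin();
  ch.model.insert(it, j);
  ch.isbasis.insert(ch.isbasis.begin() + pos, ev.independent ? 1 : 0);
  ch.inmodel[j] = 1;
  if (ev.independent) {
    int k = ch.basis.size();
    int q = sh.q;
    mat Anew(k + 1, k + 1);
    if (k > 0) {
      Anew.submat(0, 0, k - 1, k - 1) = ch.A + (ev.u * ev.u.t()) / ev.s;
      Anew.submat(0, k, k - 1, k) = -ev.u / ev.s;
      Anew.submat(k, 0, k, k - 1) = (-ev.u / ev.s).t();
    }
    Anew(k, k) = 1.0 / ev.s;
    ch.A = Anew;
    mat Bnew(k + 1, q);
    if (k > 0) Bnew.rows(0, k - 1) = ch.B - (ev.u * ev.d.t()) / ev.s;
    Bnew.row(k) = ev.d.t() / ev.s;
    ch.B = Bnew;
    ch.Qm += (ev.d * ev.d.t()) / ev.s;
    ch.basis.push_back(j);
  } else {
    ch.n_dependent += 1;
  }
  ch.logml = ev.logml_new;
  ch.lp_gamma = sh.lp_size((int)ch.model.size());
}

struct DelEval {
  bool basis_col;
  bool slow;          // requires full rebuild of the candidate
  int basis_pos;
  double logml_new;
  // slow-path results
  std::vector<char> isbasis2;
  std::vector<int> basis2;
  mat A2, B2, Qm2;
};

void eval_delete(Shared &sh, const Chain &ch, size_t pos, DelEval &ev) {
  ev.basis_col = ch.isbasis[pos] != 0;
  ev.slow = false;
  if (!ev.basis_col) {
    ev.logml_new = ch.logml;  // dependent column: likelihood unchanged
    return;
  }
  int j = ch.model[pos];
  if (ch.n_dependent == 0) {
    int k = ch.basis.size();
    int ib = -1;
    for (int b = 0; b < k; ++b) if (ch.basis[b] == j) { ib = b; break; }
    ev.basis_pos = ib;
    double a = ch.A(ib, ib);
    arma::rowvec Brow = ch.B.row(ib);
    mat Qnew = ch.Qm - (Brow.t() * Brow) / a;
    ev.logml_new = logml_value(sh, k - 1, Qnew, ch.g);
  } else {
    // removing a basis column may free a dependent one: re-derive the basis
    ev.slow = true;
    std::vector<int> cand(ch.model);
    cand.erase(cand.begin() + pos);
    build_structures(sh, cand, ev.isbasis2, ev.basis2, ev.A2, ev.B2, ev.Qm2);
    ev.logml_new = logml_value(sh, ev.basis2.size(), ev.Qm2, ch.g);
  }
}

void apply_delete(Shared &sh, Chain &ch, size_t pos, const DelEval &ev) {
  int j = ch.model[pos];
  if (!ev.basis_col) {
    ch.model.erase(ch.model.begin() + pos);
    ch.isbasis.erase(ch.isbasis.begin() + pos);
    ch.inmodel[j] = 0;
    ch.n_dependent -= 1;
  } else if (!ev.slow) {
    int k = ch.basis.size();
    int ib = ev.basis_pos;
    double a = ch.A(ib, ib);
    vec acol = ch.A.col(ib);
    arma::rowvec Brow = ch.B.row(ib);
    arma::uvec keep(k - 1);
    int w = 0;
    for (int b = 0; b < k; ++b) if (b != ib) keep(w++) = b;
    vec v = acol.elem(keep);
    mat Asub = ch.A.submat(keep, keep) - (v * v.t()) / a;
    mat Bsub = ch.B.rows(keep) - (v * Brow) / a;
    ch.A = Asub;
    ch.B = Bsub;
    ch.Qm -= (Brow.t() * Brow) / a;
    ch.basis.erase(ch.basis.begin() + ib);
    ch.model.erase(ch.model.begin() + pos);
    ch.isbasis.erase(ch.isbasis.begin() + pos);
    ch.inmodel[j] = 0;
  } else {
    ch.model.erase(ch.model.begin() + pos);
    ch.isbasis = ev.isbasis2;
    ch.basis = ev.basis2;
    ch.A = ev.A2;
    ch.B = ev.B2;
    ch.Qm = ev.Qm2;
    ch.inmodel[j] = 0;
    ch.n_dependent = (int)ch.model.size() - (int)ch.basis.size();
  }
  ch.logml = ev.logml_new;
  ch.lp_gamma = sh.lp_size((int)ch.model.size());
}

}  // namespace

// [[Rcpp::export]]
List ess_run_cpp(const arma::mat &X, const arma::mat &Y,
                 double neff, double g_rate,
                 const arma::vec &lp_size, int T,
                 double prior_a, double prior_b, double pi_avg, bool beta_binomial,
                 int n_sweeps, int burn_in, int n_chains,
                 double scan_frac, double p_crossover,
                 double ladder_base, double g_step_init,
                 double exch_lo, double exch_hi, double g_acc_target,
                 int adapt_window, int refresh_every,
                 bool record_all_chains) {
  Shared sh;
  sh.X = &X;
  sh.Y = Y;
  sh.n = X.n_rows;
  sh.p = X.n_cols;
  sh.q = Y.n_cols;
  sh.neff = neff;
  sh.g_rate = g_rate;
  sh.XtY = X.t() * Y;
  sh.colssq = arma::sum(arma::square(X), 0).t();
  sh.YtY = Y.t() * Y;
  sh.lp_size = lp_size;
  sh.T = T;
  sh.xtx_cache.resize(sh.p);
  sh.cached.assign(sh.p, 0);

  const int L = n_chains;
  const int p = sh.p;
  double b = ladder_base;
  std::vector<double> temp(L), g_step(L, g_step_init);
  for (int l = 0; l < L; ++l) temp[l] = std::pow(b, l);
  temp[0] = 1.0;

  // ---- initialization: model size from the (truncated) prior, g from its prior
  std::vector<Chain> chains(L);
  int max_init = std::min(T, (int)neff - sh.q - 1);
  for (int l = 0; l < L; ++l) {
    Chain &ch = chains[l];
    ch.inmodel.assign(p, 0);
    ch.g = 1.0 / R::rgamma(0.5, 1.0 / sh.g_rate);
    int k = -1;
    for (int tries = 0; tries < 1000 && (k < 0 || k > max_init); ++tries) {
      double om = beta_binomial ? R::rbeta(prior_a, prior_b) : pi_avg;
      k = (int)R::rbinom(p, om);
    }
    if (k < 0 || k > max_init) k = std::min(max_init, 1);
    ch.model.clear();
    while ((int)ch.model.size() < k) {
      int j = (int)std::floor(unif_rand() * p);
      if (j >= p) j = p - 1;
      if (!ch.inmodel[j]) { ch.inmodel[j] = 1; ch.model.push_back(j); }
    }
    std::sort(ch.model.begin(), ch.model.end());
    rebuild(sh, ch);
  }

  // ---- recording
  mat size_tr, lp_tr, g_tr;
  if (record_all_chains) {
    size_tr.set_size(n_sweeps, L);
    lp_tr.set_size(n_sweeps, L);
    g_tr.set_size(n_sweeps, L);
  } else {
    size_tr.set_size(n_sweeps, 1);
    lp_tr.set_size(n_sweeps, 1);
    g_tr.set_size(n_sweeps, 1);
  }
  std::vector<int> hist_sizes, hist_flat;
  std::vector<double> hist_lp, hist_g;
  hist_sizes.reserve(std::max(0, n_sweeps - burn_in));

  long fsmh_prop = 0, fsmh_acc = 0, overT_rej = 0;
  long xo_prop = 0, xo_acc = 0, ex_prop = 0, ex_acc = 0;
  long g_prop = 0, g_acc = 0;
  long ex_win_prop = 0, ex_win_acc = 0;
  std::vector<long> g_win_prop(L, 0), g_win_acc(L, 0);

  AddEval aev;
  DelEval dev;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    bool in_burn = sweep < burn_in;

    // ---- local fast-scan MH sweep, every chain
    for (int l = 0; l < L; ++l) {
      Chain &ch = chains[l];
      double invt = 1.0 / temp[l];
      for (int j = 0; j < p; ++j) {
        if (scan_frac < 1.0 && unif_rand() > scan_frac) continue;
        if (!ch.inmodel[j]) {
          if ((int)ch.model.size() >= T ||
              (int)ch.model.size() >= (int)neff - sh.q - 1) {
            ++overT_rej;  // proposals beyond the permitted size are rejected outright
            continue;
          }
          ++fsmh_prop;
          eval_add(sh, ch, j, aev);
          double delta = (aev.logml_new - ch.logml) +
                         (sh.lp_size((int)ch.model.size() + 1) - ch.lp_gamma);
          if (delta >= 0 || std::log(unif_rand()) < invt * delta) {
            apply_add(sh, ch, j, aev);
            ++fsmh_acc;
          }
        } else {
          ++fsmh_prop;
          std::vector<int>::iterator it =
              std::lower_bound(ch.model.begin(), ch.model.end(), j);
          size_t pos = it - ch.model.begin();
          eval_delete(sh, ch, pos, dev);
          double delta = (dev.logml_new - ch.logml) +
                         (sh.lp_size((int)ch.model.size() - 1) - ch.lp_gamma);
          if (delta >= 0 || std::log(unif_rand()) < invt * delta) {
            apply_delete(sh, ch, pos, dev);
            ++fsmh_acc;
          }
        }
      }
    }

    // ---- one global move: crossover or exchange
    if (L >= 2) {
      if (unif_rand() < p_crossover) {
        ++xo_prop;
        int c1 = (int)std::floor(unif_rand() * L);
        int c2 = (int)std::floor(unif_rand() * (L - 1));
        if (c2 >= c1) ++c2;
        if (c1 > c2) std::swap(c1, c2);
        Chain &p1 = chains[c1], &p2 = chains[c2];
        // uniform crossover over the union of the two parents
        std::vector<int> o1, o2;
        {
          size_t i1 = 0, i2 = 0;
          while (i1 < p1.model.size() || i2 < p2.model.size()) {
            int j;
            bool in1 = false, in2 = false;
            if (i1 < p1.model.size() &&
                (i2 >= p2.model.size() || p1.model[i1] <= p2.model[i2])) {
              j = p1.model[i1];
              in1 = true;
              if (i2 < p2.model.size() && p2.model[i2] == j) in2 = true;
            } else {
              j = p2.model[i2];
              in2 = true;
            }
            if (in1) ++i1;
            if (in2) ++i2;
            if (in1 && in2) { o1.push_back(j); o2.push_back(j); }
            else if (unif_rand() < 0.5) o1.push_back(j);
            else o2.push_back(j);
          }
        }
        if ((int)o1.size() <= T && (int)o2.size() <= T &&
            (int)o1.size() < (int)neff - sh.q &&
            (int)o2.size() < (int)neff - sh.q) {
          std::vector<char> ib1, ib2;
          std::vector<int> bs1, bs2;
          mat A1, B1, Q1, A2, B2, Q2;
          build_structures(sh, o1, ib1, bs1, A1, B1, Q1);
          build_structures(sh, o2, ib2, bs2, A2, B2, Q2);
          double lml1 = logml_value(sh, bs1.size(), Q1, p1.g);
          double lml2 = logml_value(sh, bs2.size(), Q2, p2.g);
          double lp1n = lml1 + sh.lp_size((int)o1.size());
          double lp2n = lml2 + sh.lp_size((int)o2.size());
          double lp1o = p1.logml + p1.lp_gamma;
          double lp2o = p2.logml + p2.lp_gamma;
          double delta = (lp1n - lp1o) / temp[c1] + (lp2n - lp2o) / temp[c2];
          if (delta >= 0 || std::log(unif_rand()) < delta) {
            ++xo_acc;
            p1.model = o1; p1.isbasis = ib1; p1.basis = bs1;
            p1.A = A1; p1.B = B1; p1.Qm = Q1;
            p1.logml = lml1; p1.lp_gamma = sh.lp_size((int)o1.size());
            p1.n_dependent = (int)o1.size() - (int)bs1.size();
            std::fill(p1.inmodel.begin(), p1.inmodel.end(), 0);
            for (size_t ii = 0; ii < o1.size(); ++ii) p1.inmodel[o1[ii]] = 1;
            p2.model = o2; p2.isbasis = ib2; p2.basis = bs2;
            p2.A = A2; p2.B = B2; p2.Qm = Q2;
            p2.logml = lml2; p2.lp_gamma = sh.lp_size((int)o2.size());
            p2.n_dependent = (int)o2.size() - (int)bs2.size();
            std::fill(p2.inmodel.begin(), p2.inmodel.end(), 0);
            for (size_t ii = 0; ii < o2.size(); ++ii) p2.inmodel[o2[ii]] = 1;
          }
        }
      } else {
        ++ex_prop;
        ++ex_win_prop;
        int l = (int)std::floor(unif_rand() * (L - 1));
        double delta = (1.0 / temp[l] - 1.0 / temp[l + 1]) *
                       (chains[l + 1].logpost() - chains[l].logpost());
        if (delta >= 0 || std::log(unif_rand()) < delta) {
          std::swap(chains[l], chains[l + 1]);
          ++ex_acc;
          ++ex_win_acc;
        }
      }
    }

    // ---- g update, every chain (random walk on log g)
    for (int l = 0; l < L; ++l) {
      Chain &ch = chains[l];
      ++g_prop;
      ++g_win_prop[l];
      double gn = ch.g * std::exp(g_step[l] * norm_rand());
      if (!std::isfinite(gn) || gn <= 0) continue;  // overflow: reject outright
      double lml_n = logml_value(sh, ch.basis.size(), ch.Qm, gn);
      double lpg_n = log_prior_g(sh, gn);
      double delta = ((lml_n + lpg_n) - (ch.logml + ch.lp_g)) / temp[l] +
                     std::log(gn) - std::log(ch.g);
      if (delta >= 0 || std::log(unif_rand()) < delta) {
        ch.g = gn;
        ch.logml = lml_n;
        ch.lp_g = lpg_n;
        ++g_acc;
        ++g_win_acc[l];
      }
    }

    // ---- adaptation, confined to burn-in
    if (in_burn && adapt_window > 0 && (sweep + 1) % adapt_window == 0) {
      if (L >= 2 && ex_win_prop > 0) {
        double rate = (double)ex_win_acc / (double)ex_win_prop;
        if (rate < exch_lo) b = 1.0 + (b - 1.0) * 0.8;
        else if (rate > exch_hi) b = std::min(10.0, 1.0 + (b - 1.0) / 0.8);
        for (int l = 0; l < L; ++l) temp[l] = std::pow(b, l);
        temp[0] = 1.0;
        ex_win_prop = ex_win_acc = 0;
      }
      for (int l = 0; l < L; ++l) {
        if (g_win_prop[l] > 0) {
          double rate = (double)g_win_acc[l] / (double)g_win_prop[l];
          g_step[l] *= std::exp(0.6 * (rate - g_acc_target));
          g_step[l] = std::min(50.0, std::max(1e-3, g_step[l]));
          g_win_prop[l] = g_win_acc[l] = 0;
        }
      }
    }

    // ---- periodic refresh against numerical drift
    if (refresh_every > 0 && (sweep + 1) % refresh_every == 0) {
      for (int l = 0; l < L; ++l) rebuild(sh, chains[l]);
    }

    // ---- recording at the end of the sweep
    int nrec = record_all_chains ? L : 1;
    for (int l = 0; l < nrec; ++l) {
      size_tr(sweep, l) = chains[l].model.size();
      lp_tr(sweep, l) = chains[l].logpost();
      g_tr(sweep, l) = chains[l].g;
    }
    if (!in_burn) {
      const Chain &c0 = chains[0];
      hist_sizes.push_back((int)c0.model.size());
      hist_lp.push_back(c0.logpost());
      hist_g.push_back(c0.g);
      for (size_t ii = 0; ii < c0.model.size(); ++ii)
        hist_flat.push_back(c0.model[ii] + 1);  // 1-based for R
    }

    if ((sweep & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector temps(L), gsteps(L);
  for (int l = 0; l < L; ++l) { temps[l] = temp[l]; gsteps[l] = g_step[l]; }

  return List::create(
      _["history_sizes"] = wrap(hist_sizes),
      _["history_models"] = wrap(hist_flat),
      _["history_logpost"] = wrap(hist_lp),
      _["history_g"] = wrap(hist_g),
      _["trace_size"] = size_tr,
      _["trace_logpost"] = lp_tr,
      _["trace_g"] = g_tr,
      _["ladder"] = temps,
      _["ladder_base"] = b,
      _["g_steps"] = gsteps,
      _["counters"] = List::create(
          _["fsmh_proposed"] = (double)fsmh_prop,
          _["fsmh_accepted"] = (double)fsmh_acc,
          _["truncation_rejects"] = (double)overT_rej,
          _["crossover_proposed"] = (double)xo_prop,
          _["crossover_accepted"] = (double)xo_acc,
          _["exchange_proposed"] = (double)ex_prop,
          _["exchange_accepted"] = (double)ex_acc,
          _["g_proposed"] = (double)g_prop,
          _["g_accepted"] = (double)g_acc));
}
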