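// Trial-by-trial replay likelihoods for all model families.
// Mirrors the R-level step functions in R/models.R; both are checked
// against an independently coded oracle in the test suite.
#include <Rcpp.h>
using namespace Rcpp;

// model ids (keep in sync with .model_id() in R/models.R)
enum ModelId {
  M_SQL = 1, M_SQL2 = 2, M_RPD = 3, M_RPA = 4, M_RPM = 5, M_DIF = 6,
  M_HYB = 7, M_FQL = 8, M_EWA = 9, M_SBE = 10, M_RELASYM = 11,
  M_OL1 = 12, M_OL2 = 13
};

static inline double log_sigmoid(double x) {
  // log(1 / (1 + exp(-x))), stable for large |x|
  if (x >= 0.0) return -log1p(std::exp(-x));
  return x - log1p(std::exp(x));
}

static inline double sigmoid(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// recency weights alpha*(1-alpha)^(t-i) over one option's sample history,
// renormalized to a proper distribution (empty history -> pseudo-sample at q0)
static void sbe_weights(const std::vector<double>& rew,
                        const std::vector<int>& tidx,
                        int tcur, double alpha, double q0, bool normalize,
                        std::vector<double>& vals, std::vector<double>& wts) {
  vals.clear(); wts.clear();
  const size_t n = rew.size();
  if (n == 0) {
    vals.push_back(q0);
    wts.push_back(1.0);
    return;
  }
  double tot = 0.0;
  for (size_t i = 0; i < n; ++i) {
    double w = alpha * std::pow(1.0 - alpha, (double)(tcur - tidx[i]));
    vals.push_back(rew[i]);
    wts.push_back(w);
    tot += w;
  }
  if (normalize && tot > 0.0)
    for (size_t i = 0; i < n; ++i) wts[i] /= tot;
}

// [[Rcpp::export(name = ".ol_replay_cpp")]]
List ol_replay_cpp(int model, NumericVector params,
                   IntegerVector chosen, IntegerVector unchosen,
                   IntegerVector context, IntegerVector tidx,
                   NumericVector r_ch, NumericVector r_un,
                   bool complete, double q0, bool sbe_normalize,
                   bool want_trial_p) {
  const int T = chosen.size();
  std::vector<double> q(4, q0);
  std::vector<double> v(2, q0);
  std::vector<double> nw(4, 1.0);               // EWA experience weights
  std::vector<std::vector<double> > hist_r(4);  // SBE sample history
  std::vector<std::vector<int> > hist_t(4);

  // parameter unpacking: params follows the registry order for each model
  double beta = params[0];
  double a1 = 0, a2 = 0, a3 = 0, w = 1, phi = 0, rho = 0, delta = 0;
  double aconf = 0, adisc = 0;
  switch (model) {
  case M_SQL: case M_DIF: case M_SBE:
    a1 = params[1]; break;
  case M_SQL2: case M_FQL:
    a1 = params[1]; a2 = params[2]; break;
  case M_RPD: case M_RPA: case M_RPM:
    a1 = params[1]; a2 = params[2];
    if (complete) a3 = params[3];
    break;
  case M_HYB:
    a1 = params[1]; w = params[2]; break;
  case M_EWA:
    phi = params[1]; rho = params[2];
    delta = complete ? params[3] : 0.0;
    break;
  case M_RELASYM:
    a1 = params[1]; aconf = params[2]; adisc = params[3]; break;
  case M_OL1:
    a1 = params[1]; a2 = a1;
    w = complete ? params[2] : 1.0;
    break;
  case M_OL2:
    a1 = params[1]; a2 = params[2];
    w = complete ? params[3] : 1.0;
    break;
  default:
    stop("unknown model id");
  }

  NumericVector trial_p = want_trial_p ? NumericVector(T) : NumericVector(0);
  double nll = 0.0;

  for (int t = 0; t < T; ++t) {
    const int ch = chosen[t] - 1, un = unchosen[t] - 1, cx = context[t] - 1;
    const double rch = r_ch[t];
    const double run = complete ? r_un[t] : NA_REAL;

    // ---- choice likelihood with pre-update values ----
    double p;
    if (model == M_SBE) {
      std::vector<double> vc, wc, vu, wu;
      sbe_weights(hist_r[ch], hist_t[ch], tidx[t], a1, q0, sbe_normalize, vc, wc);
      sbe_weights(hist_r[un], hist_t[un], tidx[t], a1, q0, sbe_normalize, vu, wu);
      p = 0.0;
      for (size_t j = 0; j < vc.size(); ++j)
        for (size_t k = 0; k < vu.size(); ++k)
          p += wc[j] * wu[k] * sigmoid(beta * (vc[j] - vu[k]));
      nll -= std::log(p);
    } else {
      double x = beta * (q[ch] - q[un]);
      nll -= log_sigmoid(x);
      p = sigmoid(x);
    }
    if (want_trial_p) trial_p[t] = p;

    // ---- state update ----
    switch (model) {
    case M_SQL: {
      q[ch] += a1 * (rch - q[ch]);
      break;
    }
    case M_SQL2: {
      q[ch] += a1 * (rch - q[ch]);
      q[un] += a2 * (run - q[un]);
      break;
    }
    case M_RPD: case M_RPA: case M_RPM: {
      double rx;
      if (model == M_RPD) rx = rch;
      else if (model == M_RPA) rx = complete ? (rch + run) / 2.0 : (rch + q[un]) / 2.0;
      else rx = complete ? std::max(rch, run) : std::max(rch, q[un]);
      v[cx] += a1 * (rx - v[cx]);
      q[ch] += a2 * ((rch - v[cx]) - q[ch]);
      if (complete) q[un] += a3 * ((run - v[cx]) - q[un]);
      break;
    }
    case M_DIF: {
      q[ch] += a1 * ((rch - run) - q[ch]);
      break;
    }
    case M_HYB: {
      double cf = complete ? run : q[un];
      double rhyb = w * rch + (1.0 - w) * (rch - cf);
      q[ch] += a1 * (rhyb - q[ch]);
      break;
    }
    case M_FQL: {
      q[ch] += a1 * (rch - q[ch]);
      q[un] *= a2;
      break;
    }
    case M_EWA: {
      double n_old = nw[ch], n_new = rho * n_old + 1.0;
      q[ch] = (q[ch] * n_old * phi + rch) / n_new;
      nw[ch] = n_new;
      if (complete) {
        double m_old = nw[un], m_new = rho * m_old + 1.0;
        q[un] = (q[un] * m_old * phi + delta * run) / m_new;
        nw[un] = m_new;
      }
      break;
    }
    case M_SBE: {
      hist_r[ch].push_back(rch); hist_t[ch].push_back(tidx[t]);
      if (complete) { hist_r[un].push_back(run); hist_t[un].push_back(tidx[t]); }
      break;
    }
    case M_RELASYM: {
      double rx = complete ? (rch + run) / 2.0 : (rch + q[un]) / 2.0;
      v[cx] += a1 * (rx - v[cx]);
      double dch = (rch - v[cx]) - q[ch];
      q[ch] += (dch > 0 ? aconf : adisc) * dch;
      if (complete) {
        double dun = (run - v[cx]) - q[un];
        q[un] += (dun < 0 ? aconf : adisc) * dun;
      }
      break;
    }
    case M_OL1: case M_OL2: {
      double d;
      if (complete) d = (w * rch + (1.0 - w) * (rch - run)) - q[ch];
      else d = rch - q[ch];
      q[ch] += a1 * d;
      q[un] -= a2 * d;
      break;
    }
    }
  }

  return List::create(_["nll"] = nll,
                      _["q"] = NumericVector(q.begin(), q.end()),
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["n"] = NumericVector(nw.begin(), nw.end()),
                      _["trial_p"] = trial_p);
}
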