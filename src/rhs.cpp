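// Compiled right-hand side of the lung-mitochondrion bioenergetics ODEs.
// Mirrors the reference R evaluator (eval_network_fluxes / network_rhs_r);
// the two are pinned against each other in the test suite.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Net {
  int n_states, n_sp, iHm, iHe, iPsi, nf;
  std::vector<double> prefK, keq0, ph_sign, n_charge, n_h_in, o2_km;
  std::vector<int> ph_matrix, o2_idx;
  // ragged per-flux arrays
  std::vector<std::vector<int>> sub_idx, prod_idx;
  std::vector<std::vector<double>> sub_coef, sub_K, prod_coef, prod_K;
  std::vector<std::vector<int>> sub_dnm, prod_dnm;
  std::vector<double> S;            // n_states x (nf+1), column-major
  std::vector<double> charge_coef, hm_coef, he_coef;
  double leak_pref, fac_e, beta_matrix, beta_buffer, F_RT_mV;
  bool has_r123;
  int iRm, iRe;
  double r_p, r_z, r_dm, r_de;
};

static double ipow(double x, double a) {
  if (a == 1.0) return x;
  if (a == 2.0) return x * x;
  return std::pow(x, a);
}

// [[Rcpp::export]]
SEXP net_compile(List spec) {
  Net* net = new Net();
  net->n_states = as<int>(spec["n_states"]);
  net->n_sp = as<int>(spec["n_sp"]);
  net->iHm = as<int>(spec["iHm"]);
  net->iHe = as<int>(spec["iHe"]);
  net->iPsi = as<int>(spec["iPsi"]);
  net->prefK = as<std::vector<double>>(spec["prefK"]);
  net->keq0 = as<std::vector<double>>(spec["keq0"]);
  net->ph_sign = as<std::vector<double>>(spec["ph_sign"]);
  net->ph_matrix = as<std::vector<int>>(spec["ph_matrix"]);
  net->n_charge = as<std::vector<double>>(spec["n_charge"]);
  net->n_h_in = as<std::vector<double>>(spec["n_h_in"]);
  net->o2_km = as<std::vector<double>>(spec["o2_km"]);
  net->o2_idx = as<std::vector<int>>(spec["o2_idx"]);
  net->nf = net->prefK.size();
  List si = spec["sub_idx"], sc = spec["sub_coef"], sk = spec["sub_K"],
       sd = spec["sub_dnm"], pi = spec["prod_idx"], pc = spec["prod_coef"],
       pk = spec["prod_K"], pd = spec["prod_dnm"];
  for (int f = 0; f < net->nf; ++f) {
    net->sub_idx.push_back(as<std::vector<int>>(si[f]));
    net->sub_coef.push_back(as<std::vector<double>>(sc[f]));
    net->sub_K.push_back(as<std::vector<double>>(sk[f]));
    net->sub_dnm.push_back(as<std::vector<int>>(sd[f]));
    net->prod_idx.push_back(as<std::vector<int>>(pi[f]));
    net->prod_coef.push_back(as<std::vector<double>>(pc[f]));
    net->prod_K.push_back(as<std::vector<double>>(pk[f]));
    net->prod_dnm.push_back(as<std::vector<int>>(pd[f]));
  }
  NumericMatrix S = spec["S"];
  net->S.assign(S.begin(), S.end());
  net->charge_coef = as<std::vector<double>>(spec["charge_coef"]);
  net->hm_coef = as<std::vector<double>>(spec["hm_coef"]);
  net->he_coef = as<std::vector<double>>(spec["he_coef"]);
  net->leak_pref = as<double>(spec["leak_pref"]);
  net->fac_e = as<double>(spec["fac_e"]);
  net->beta_matrix = as<double>(spec["beta_matrix"]);
  net->beta_buffer = as<double>(spec["beta_buffer"]);
  net->F_RT_mV = as<double>(spec["F_RT_mV"]);
  NumericVector r = spec["r123"];
  net->has_r123 = r.size() > 0;
  if (net->has_r123) {
    net->iRm = (int) r[0]; net->iRe = (int) r[1];
    net->r_p = r[2]; net->r_z = r[3]; net->r_dm = r[4]; net->r_de = r[5];
  }
  XPtr<Net> ptr(net, true);
  return ptr;
}

static void eval_fluxes(const Net* net, const double* y, double* J) {
  const int nsp = net->n_sp;
  double Hm = y[net->iHm] > 1e-12 ? y[net->iHm] : 1e-12;
  double He = y[net->iHe] > 1e-12 ? y[net->iHe] : 1e-12;
  double psi = y[net->iPsi];
  std::vector<double> conc(nsp);
  for (int i = 0; i < nsp; ++i) conc[i] = y[i] > 0 ? y[i] : 0.0;
  for (int f = 0; f < net->nf; ++f) {
    double keq = net->keq0[f];
    if (net->ph_sign[f] != 0) {
      double pH = -std::log10(net->ph_matrix[f] ? Hm : He);
      keq *= std::pow(10.0, net->ph_sign[f] * (pH - 7.0));
    }
    if (net->n_charge[f] != 0)
      keq *= std::exp(-net->n_charge[f] * psi * net->F_RT_mV);
    if (net->n_h_in[f] != 0)
      keq *= std::pow(He / Hm, net->n_h_in[f]);
    double prodS = 1.0, prodP = 1.0, denom = 1.0;
    const std::vector<int>& sidx = net->sub_idx[f];
    for (size_t k = 0; k < sidx.size(); ++k) {
      double c = conc[sidx[k]], a = net->sub_coef[f][k];
      prodS *= ipow(c, a);
      if (net->sub_dnm[f][k])
        denom *= 1.0 + ipow(c / net->sub_K[f][k], a);
    }
    const std::vector<int>& pidx = net->prod_idx[f];
    for (size_t k = 0; k < pidx.size(); ++k) {
      double c = conc[pidx[k]], b = net->prod_coef[f][k];
      prodP *= ipow(c, b);
      if (net->prod_dnm[f][k])
        denom *= 1.0 + ipow(c / net->prod_K[f][k], b);
    }
    double Jf = net->prefK[f] * (prodS - prodP / keq) / denom;
    if (net->o2_km[f] > 0) {
      double o2 = conc[net->o2_idx[f]];
      Jf *= o2 / (net->o2_km[f] + o2);
    }
    J[f] = Jf;
  }
  // proton leak (GHK), positive IMS -> matrix
  double w = psi * net->F_RT_mV;
  if (std::fabs(w) < 1e-6) {
    J[net->nf] = net->leak_pref * ((He - Hm) + w * (He + Hm) / 2.0);
  } else {
    double ew = std::exp(w);
    J[net->nf] = net->leak_pref * w * (He * ew - Hm) / (ew - 1.0);
  }
}

// [[Rcpp::export]]
NumericVector net_fluxes(SEXP ptr_, NumericVector y) {
  XPtr<Net> ptr(ptr_);
  NumericVector J(ptr->nf + 1);
  eval_fluxes(ptr.get(), y.begin(), J.begin());
  return J;
}

// [[Rcpp::export]]
NumericVector net_rhs(SEXP ptr_, double t, NumericVector y) {
  XPtr<Net> ptr(ptr_);
  const Net* net = ptr.get();
  int nfl = net->nf + 1, ns = net->n_states;
  std::vector<double> J(nfl);
  eval_fluxes(net, y.begin(), J.data());
  NumericVector dy(ns);
  for (int f = 0; f < nfl; ++f) {
    double Jf = J[f];
    if (Jf == 0.0) continue;
    const double* Scol = &net->S[(size_t) f * ns];
    for (int i = 0; i < ns; ++i)
      if (Scol[i] != 0.0) dy[i] += Scol[i] * Jf;
  }
  double Hm = y[net->iHm] > 1e-12 ? y[net->iHm] : 1e-12;
  double He = y[net->iHe] > 1e-12 ? y[net->iHe] : 1e-12;
  double jh_m = 0, jh_e = 0, jq = 0;
  for (int f = 0; f < nfl; ++f) {
    jh_m += net->hm_coef[f] * J[f];
    jh_e += net->he_coef[f] * J[f];
    jq += net->charge_coef[f] * J[f];
  }
  const double LN10 = 2.302585092994046;
  dy[net->iHm] = Hm * LN10 * jh_m / net->beta_matrix;
  dy[net->iHe] = He * LN10 * jh_e * net->fac_e / net->beta_buffer;
  dy[net->iPsi] = jq;
  if (net->has_r123) {
    double w = net->r_z * y[net->iPsi] * net->F_RT_mV;
    double Re = y[net->iRe], Rm = y[net->iRm], Jr;
    if (std::fabs(w) < 1e-6) {
      Jr = net->r_p * ((Re - Rm) + w * (Re + Rm) / 2.0);
    } else {
      double ew = std::exp(w);
      Jr = net->r_p * w * (Re * ew - Rm) / (ew - 1.0);
    }
    dy[net->iRm] = Jr * net->r_dm;
    dy[net->iRe] = -Jr * net->r_de;
  }
  return dy;
}
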