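// Full-batch training loop for the graph convolutional autoencoder with
// contrastive self-supervised refinement. Mirrors the R-level operations
// (gcn_encode / gcn_decode / readout / discriminate / csl_loss) exactly;
// weight initialization and the per-iteration corruption permutations are
// generated R-side from the seeded RNG, so training is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline void relu_(mat& m) { m.for_each([](double& v) { if (v < 0) v = 0; }); }

inline mat sigm(const mat& m) { return 1.0 / (1.0 + exp(-m)); }

inline vec clampv(vec p, double eps) {
  p.for_each([eps](double& v) {
    if (v < eps) v = eps; else if (v > 1 - eps) v = 1 - eps;
  });
  return p;
}

struct AdamD {
  mat m, v;
  void init(const mat& w) { m.zeros(size(w)); v.zeros(size(w)); }
  void step(mat& w, const mat& g, double lr, int t) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * square(g);
    const double c1 = 1.0 - std::pow(0.9, t), c2 = 1.0 - std::pow(0.999, t);
    w -= lr * (m / c1) / (sqrt(v / c2) + 1e-8);
  }
};

} // namespace

// [[Rcpp::export]]
Rcpp::List gcn_train_cpp(const arma::mat& X, const arma::sp_mat& L,
                         const arma::sp_mat& Q,
                         const Rcpp::IntegerMatrix& perms,
                         const Rcpp::List& init, double alpha, double beta,
                         double lr, int n_iter, double eps) {
  const uword n = X.n_rows, F = X.n_cols;
  Rcpp::List We_ = init["We"], be_ = init["be"], Wd_ = init["Wd"],
             bd_ = init["bd"];
  const int nl = We_.size();
  std::vector<mat> We(nl), Wd(nl);
  std::vector<rowvec> be(nl), bd(nl);
  for (int l = 0; l < nl; ++l) {
    We[l] = Rcpp::as<mat>(We_[l]);
    Wd[l] = Rcpp::as<mat>(Wd_[l]);
    be[l] = Rcpp::as<rowvec>(be_[l]);
    bd[l] = Rcpp::as<rowvec>(bd_[l]);
  }
  mat Wdisc = Rcpp::as<mat>(init["Wdisc"]);
  const sp_mat Qt = Q.t();

  std::vector<AdamD> aWe(nl), aWd(nl), abe(nl), abd(nl);
  AdamD aWdisc; aWdisc.init(Wdisc);
  mat bem, bdm;
  for (int l = 0; l < nl; ++l) {
    aWe[l].init(We[l]); aWd[l].init(Wd[l]);
    abe[l].init(mat(be[l])); abd[l].init(mat(bd[l]));
  }

  const mat LX = L * X;
  mat losses(n_iter, 4);

  std::vector<mat> Ae(nl), Pe(nl), Ze(nl), Aec(nl), Pec(nl), Zec(nl),
                   Ad(nl), Pd(nl), Hd(nl);
  std::vector<mat> dWe(nl), dWd(nl);
  std::vector<rowvec> dbe(nl), dbd(nl);
  mat Xc(n, F);

  for (int t = 0; t < n_iter; ++t) {
    for (uword j = 0; j < F; ++j) {
      const double* src = X.colptr(j);
      double* dst = Xc.colptr(j);
      for (uword i = 0; i < n; ++i) dst[i] = src[perms(t, i) - 1];
    }

    // encoder, real and corrupted, shared weights
    for (int l = 0; l < nl; ++l) {
      Ae[l] = (l == 0) ? LX : L * Ze[l - 1];
      Aec[l] = (l == 0) ? mat(L * Xc) : L * Zec[l - 1];
      Pe[l] = Ae[l] * We[l];  Pe[l].each_row() += be[l];
      Pec[l] = Aec[l] * We[l]; Pec[l].each_row() += be[l];
      Ze[l] = Pe[l];  relu_(Ze[l]);
      Zec[l] = Pec[l]; relu_(Zec[l]);
    }
    const mat& Z = Ze[nl - 1];
    const mat& Zc = Zec[nl - 1];

    // decoder (real pass reconstructs the real input)
    for (int l = 0; l < nl; ++l) {
      Ad[l] = L * (l == 0 ? Z : Hd[l - 1]);
      Pd[l] = Ad[l] * Wd[l]; Pd[l].each_row() += bd[l];
      Hd[l] = Pd[l]; relu_(Hd[l]);
    }
    const mat& H = Hd[nl - 1];

    // read-out summaries and bilinear discriminator scores
    const mat S = sigm(mat(Q * Z));
    const mat Sc = sigm(mat(Q * Zc));
    const mat ZW = Z * Wdisc;
    const mat ZcW = Zc * Wdisc;
    const vec p_pos = clampv(1.0 / (1.0 + exp(-sum(ZW % S, 1))), eps);
    const vec p_neg = clampv(1.0 / (1.0 + exp(-sum(ZcW % S, 1))), eps);
    const vec p_pos_c = clampv(1.0 / (1.0 + exp(-sum(ZcW % Sc, 1))), eps);
    const vec p_neg_c = clampv(1.0 / (1.0 + exp(-sum(ZW % Sc, 1))), eps);

    const double recon = accu(square(X - H));
    const double l_csl = -(accu(log(p_pos)) + accu(log(1.0 - p_neg))) / (2.0 * n);
    const double l_cslc =
      -(accu(log(p_pos_c)) + accu(log(1.0 - p_neg_c))) / (2.0 * n);
    const double total = alpha * recon + beta * (l_csl + l_cslc);
    losses(t, 0) = total; losses(t, 1) = recon;
    losses(t, 2) = l_csl; losses(t, 3) = l_cslc;
    if (!std::isfinite(total)) {
      Rcpp::stop("GCN training loss diverged (non-finite) at iteration %d",
                 t + 1);
    }

    // ---- backward ----
    mat dH = 2.0 * alpha * (H - X);
    for (int l = nl - 1; l >= 0; --l) {
      mat dP = dH % (Pd[l] > 0);
      dWd[l] = Ad[l].t() * dP;
      dbd[l] = sum(dP, 0);
      dH = L * (dP * Wd[l].t());
    }

    const vec du_pos = -beta * (1.0 - p_pos) / (2.0 * n);
    const vec du_neg = beta * p_neg / (2.0 * n);
    const vec du_pos_c = -beta * (1.0 - p_pos_c) / (2.0 * n);
    const vec du_neg_c = beta * p_neg_c / (2.0 * n);

    const mat Wt = Wdisc.t();
    mat dZ = dH + (S.each_col() % du_pos) * Wt + (Sc.each_col() % du_neg_c) * Wt;
    mat dZc = (S.each_col() % du_neg) * Wt + (Sc.each_col() % du_pos_c) * Wt;
    mat dS = (Z.each_col() % du_pos) * Wdisc + (Zc.each_col() % du_neg) * Wdisc;
    mat dSc = (Zc.each_col() % du_pos_c) * Wdisc + (Z.each_col() % du_neg_c) * Wdisc;
    const mat dWdisc = Z.t() * (S.each_col() % du_pos) +
                       Zc.t() * (S.each_col() % du_neg) +
                       Zc.t() * (Sc.each_col() % du_pos_c) +
                       Z.t() * (Sc.each_col() % du_neg_c);

    dZ += Qt * mat(dS % S % (1.0 - S));
    dZc += Qt * mat(dSc % Sc % (1.0 - Sc));

    for (int l = nl - 1; l >= 0; --l) {
      mat dP = dZ % (Pe[l] > 0);
      mat dPc = dZc % (Pec[l] > 0);
      dWe[l] = Ae[l].t() * dP + Aec[l].t() * dPc;
      dbe[l] = sum(dP, 0) + sum(dPc, 0);
      if (l > 0) {
        dZ = L * (dP * We[l].t());
        dZc = L * (dPc * We[l].t());
      }
    }

    const int step = t + 1;
    for (int l = 0; l < nl; ++l) {
      aWe[l].step(We[l], dWe[l], lr, step);
      aWd[l].step(Wd[l], dWd[l], lr, step);
      bem = mat(be[l]); abe[l].step(bem, mat(dbe[l]), lr, step); be[l] = bem.row(0);
      bdm = mat(bd[l]); abd[l].step(bdm, mat(dbd[l]), lr, step); bd[l] = bdm.row(0);
    }
    aWdisc.step(Wdisc, dWdisc, lr, step);
  }

  Rcpp::List We_out(nl), be_out(nl), Wd_out(nl), bd_out(nl);
  for (int l = 0; l < nl; ++l) {
    We_out[l] = We[l]; be_out[l] = rowvec(be[l]);
    Wd_out[l] = Wd[l]; bd_out[l] = rowvec(bd[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("We") = We_out, Rcpp::Named("be") = be_out,
    Rcpp::Named("Wd") = Wd_out, Rcpp::Named("bd") = bd_out,
    Rcpp::Named("Wdisc") = Wdisc,
    Rcpp::Named("losses") = losses);
}
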