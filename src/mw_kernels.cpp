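// Hot numerical loops for the multiwavelet stack and the MPS engine.
// Tensor blocks are stored column-major with the first index fastest,
// i.e. x[i1 + d1*(i2 + d2*i3)] for a block of dim (d1, d2, d3).

#include <RcppArmadillo.h>
using namespace Rcpp;

// y[j1,j2,j3] = sum_i A1[j1,i1] A2[j2,i2] A3[j3,i3] x[i1,i2,i3]
static arma::vec mode3_core(const arma::mat& A1, const arma::mat& A2,
                            const arma::mat& A3, const arma::vec& x) {
  const arma::uword d1 = A1.n_cols, d2 = A2.n_cols, d3 = A3.n_cols;
  const arma::uword m1 = A1.n_rows, m2 = A2.n_rows, m3 = A3.n_rows;
  // mode 1
  arma::mat X1(const_cast<double*>(x.memptr()), d1, d2 * d3, false, true);
  arma::mat Y1 = A1 * X1;                      // m1 x (d2*d3)
  // mode 2: treat as blocks over i3
  arma::mat Y2(m1 * m2, d3);
  for (arma::uword i3 = 0; i3 < d3; ++i3) {
    arma::mat blk(Y1.colptr(i3 * d2), m1, d2, false, true);
    arma::mat r = blk * A2.t();                // m1 x m2
    std::memcpy(Y2.colptr(i3), r.memptr(), sizeof(double) * m1 * m2);
  }
  // mode 3
  arma::mat Y3 = Y2 * A3.t();                  // (m1*m2) x m3
  return arma::vectorise(Y3);
}

// [[Rcpp::export]]
arma::vec cpp_mode3(const arma::mat& A1, const arma::mat& A2,
                    const arma::mat& A3, const arma::vec& x) {
  return mode3_core(A1, A2, A3, x);
}

// Batched application of one matrix per dimension to many blocks.
// X: (d^3) x n matrix of blocks, A: m x d. Returns (m^3) x n.
// [[Rcpp::export]]
arma::mat cpp_mode3_batch(const arma::mat& A, const arma::mat& X) {
  const arma::uword n = X.n_cols;
  const arma::uword m = A.n_rows, d = A.n_cols;
  arma::mat out(m * m * m, n);
  for (arma::uword c = 0; c < n; ++c) {
    arma::vec x = X.col(c);
    out.col(c) = mode3_core(A, A, A, x);
  }
  return out;
}

// Non-standard-form convolution, one scale at a time.
//
// src_joint : (mj^3) x nsrc child-representation blocks (mj = 2*(k+1))
// src_spar  : (k1^3) x nsrc parent-scale scaling blocks
// src_nrm   : nsrc vector of joint block norms (screening)
// pair_*    : npair source/target column indices (0-based) and displacement
//             indices (0-based into the third dim of the per-term cubes)
// terms     : list of lists with elements
//               Aj   cube (mj x mj x nd)   child-level operator matrices
//               Bj   cube (mj x k1 x nd)   Up %*% T_n(Delta) (pure part)
//               nA   vec nd   Frobenius norms of Aj slices
//               nM   vec nd   norms of the scale-modified part
//               coef scalar
// cut       : absolute screening threshold on a contribution's norm bound
// ntgt      : number of target columns
// Returns (mj^3) x ntgt accumulated joint output blocks.
// [[Rcpp::export]]
arma::mat cpp_conv_scale(const arma::mat& src_joint, const arma::mat& src_spar,
                         const arma::vec& src_nrm,
                         const IntegerVector& pair_src, const IntegerVector& pair_tgt,
                         const IntegerVector& pair_dx, const IntegerVector& pair_dy,
                         const IntegerVector& pair_dz,
                         const List& terms, const double cut, const int ntgt) {
  const arma::uword mj3 = src_joint.n_rows;
  arma::mat out(mj3, (arma::uword)ntgt, arma::fill::zeros);
  const int npair = pair_src.size();
  const int nterm = terms.size();

  std::vector<arma::cube> Ajs(nterm), Bjs(nterm);
  std::vector<arma::vec> nAs(nterm), nMs(nterm);
  std::vector<double> cfs(nterm);
  for (int t = 0; t < nterm; ++t) {
    List tl = terms[t];
    Ajs[t] = as<arma::cube>(tl["Aj"]);
    Bjs[t] = as<arma::cube>(tl["Bj"]);
    nAs[t] = as<arma::vec>(tl["nA"]);
    nMs[t] = as<arma::vec>(tl["nM"]);
    cfs[t] = as<double>(tl["coef"]);
  }

  for (int p = 0; p < npair; ++p) {
    const int s = pair_src[p], g = pair_tgt[p];
    const int dx = pair_dx[p], dy = pair_dy[p], dz = pair_dz[p];
    const double sn = src_nrm[s];
    arma::vec xj = src_joint.col(s);
    arma::vec xs = src_spar.col(s);
    for (int t = 0; t < nterm; ++t) {
      const double ax = nAs[t][dx], ay = nAs[t][dy], az = nAs[t][dz];
      const double mx = nMs[t][dx], my = nMs[t][dy], mz = nMs[t][dz];
      // telescoped bound on the scale-modified 3D block norm
      const double bnd = std::fabs(cfs[t]) *
        (mx * ay * az + ax * my * az + ax * ay * mz +
         mx * my * az + mx * ay * mz + ax * my * mz + mx * my * mz);
      if (bnd * sn < cut) continue;
      arma::vec full = mode3_core(Ajs[t].slice(dx), Ajs[t].slice(dy),
                                  Ajs[t].slice(dz), xj);
      arma::vec pure = mode3_core(Bjs[t].slice(dx), Bjs[t].slice(dy),
                                  Bjs[t].slice(dz), xs);
      out.col(g) += cfs[t] * (full - pure);
    }
  }
  return out;
}

// ---- MPS utilities ----------------------------------------------------

// Expectation of a product of single-site operators against an MPS.
// mps: list of arrays (chi_l, d, chi_r); ops: list (one per site, can be
// R_NilValue for identity) of d x d matrices.  Assumes <psi|psi> handled by
// caller (no normalization applied here).
// [[Rcpp::export]]
double cpp_mps_expect_prod(const List& mps, const List& ops) {
  const int M = mps.size();
  arma::mat E(1, 1, arma::fill::ones);
  for (int s = 0; s < M; ++s) {
    NumericVector Av = mps[s];
    IntegerVector dm = Av.attr("dim");
    const arma::uword cl = dm[0], d = dm[1], cr = dm[2];
    arma::cube A(Av.begin(), cl, d, cr, false);
    arma::mat acc(cr, cr, arma::fill::zeros);
    bool ident = Rf_isNull(ops[s]);
    arma::mat O;
    if (!ident) O = as<arma::mat>(ops[s]);
    // acc[a',b'] = sum_{p,q} O[p,q] sum_{a,b} A[a,p,a'] E[a,b] A[b,q,b']
    for (arma::uword q = 0; q < d; ++q) {
      arma::mat Aqc(cl, cr);
      for (arma::uword r = 0; r < cr; ++r)
        for (arma::uword a = 0; a < cl; ++a) Aqc(a, r) = A(a, q, r);
      arma::mat EB = E * Aqc;                      // cl x cr
      for (arma::uword pidx = 0; pidx < d; ++pidx) {
        double o = ident ? (pidx == q ? 1.0 : 0.0) : O(pidx, q);
        if (o == 0.0) continue;
        arma::mat Apc(cl, cr);
        for (arma::uword r = 0; r < cr; ++r)
          for (arma::uword a = 0; a < cl; ++a) Apc(a, r) = A(a, pidx, r);
        acc += o * (Apc.t() * EB);
      }
    }
    E = acc;
  }
  return E(0, 0);
}

// Expectation of an operator string against a LEFT-CANONICAL MPS.
// The string spans sites smin..smax (1-based); ops is a list of 4 x 4
// matrices (including any parity factors), one per spanned site.  rhoR is
// the list of right identity environments: rhoR[[s]] covers sites s..M,
// rhoR[[M+1]] = 1.  Left of smin the transfer is the identity because the
// state is left-canonical.
// [[Rcpp::export]]
double cpp_mps_string_expect(const List& mps, const List& rhoR,
                             const int smin, const int smax, const List& ops) {
  NumericVector A0v = mps[smin - 1];
  IntegerVector d0 = A0v.attr("dim");
  arma::mat E(d0[0], d0[0], arma::fill::eye);
  for (int s = smin; s <= smax; ++s) {
    NumericVector Av = mps[s - 1];
    IntegerVector dm = Av.attr("dim");
    const arma::uword cl = dm[0], d = dm[1], cr = dm[2];
    arma::cube A(Av.begin(), cl, d, cr, false);
    arma::mat O = as<arma::mat>(ops[s - smin]);
    arma::mat acc(cr, cr, arma::fill::zeros);
    // cache contiguous physical slices
    std::vector<arma::mat> Ap(d);
    for (arma::uword p = 0; p < d; ++p) {
      Ap[p].set_size(cl, cr);
      for (arma::uword r = 0; r < cr; ++r)
        for (arma::uword a = 0; a < cl; ++a) Ap[p](a, r) = A(a, p, r);
    }
    for (arma::uword q = 0; q < d; ++q) {
      arma::mat EA = E * Ap[q];
      for (arma::uword p = 0; p < d; ++p) {
        const double o = O(p, q);
        if (o == 0.0) continue;
        acc += o * (Ap[p].t() * EA);
      }
    }
    E = acc;
  }
  arma::mat rho = as<arma::mat>(rhoR[smax]);  // rhoR[[smax + 1]] in R
  return arma::accu(E % rho);
}

// right identity environments of a (real) MPS: rho[[s]] covers sites s..M
// [[Rcpp::export]]
List cpp_mps_rho_right(const List& mps) {
  const int M = mps.size();
  List out(M + 1);
  arma::mat rho(1, 1, arma::fill::ones);
  out[M] = rho;  // R index M+1
  for (int s = M - 1; s >= 0; --s) {
    NumericVector Av = mps[s];
    IntegerVector dm = Av.attr("dim");
    const arma::uword cl = dm[0], d = dm[1], cr = dm[2];
    arma::cube A(Av.begin(), cl, d, cr, false);
    arma::mat nr(cl, cl, arma::fill::zeros);
    for (arma::uword p = 0; p < d; ++p) {
      arma::mat Ap(cl, cr);
      for (arma::uword r = 0; r < cr; ++r)
        for (arma::uword a = 0; a < cl; ++a) Ap(a, r) = A(a, p, r);
      nr += Ap * rho * Ap.t();
    }
    rho = nr;
    out[s] = rho;
  }
  return out;
}

// Product of two functions on one node: descend both parent blocks to the
// 8 children, evaluate at the children's tensor quadrature points,
// multiply pointwise, project back and filter up.
// D0, D1: (k1 x k1) descent matrices (t(H0), t(H1)); E: (q x k1) values of
// the scaling functions at the quadrature nodes; P: (k1 x q) projector.
// scale_eval = 2^{1.5 (n+1)} * (2L)^{-1.5} folds all normalizations.
// Returns list(children = (k1^3 x 8), s = filtered parent block,
//              csq = sum of squared child norms).
// [[Rcpp::export]]
List cpp_product_node(const arma::vec& sa, const arma::vec& sb,
                      const arma::mat& D0, const arma::mat& D1,
                      const arma::mat& E, const arma::mat& P,
                      const arma::mat& H0, const arma::mat& H1,
                      const double scale_eval) {
  const arma::uword k1 = D0.n_rows;
  arma::mat children(k1 * k1 * k1, 8);
  double csq = 0;
  for (int b = 0; b < 8; ++b) {
    const arma::mat& B1 = (b & 1) ? D1 : D0;
    const arma::mat& B2 = (b & 2) ? D1 : D0;
    const arma::mat& B3 = (b & 4) ? D1 : D0;
    arma::vec da = mode3_core(B1, B2, B3, sa);
    arma::vec db = mode3_core(B1, B2, B3, sb);
    arma::vec va = mode3_core(E, E, E, da);
    arma::vec vb = mode3_core(E, E, E, db);
    arma::vec prod = scale_eval * (va % vb);
    arma::vec sc = mode3_core(P, P, P, prod);
    children.col(b) = sc;
    csq += arma::dot(sc, sc);
  }
  // filter up: s = sum_b (H_b1 (x) H_b2 (x) H_b3) child_b
  arma::vec s(k1 * k1 * k1, arma::fill::zeros);
  for (int b = 0; b < 8; ++b) {
    const arma::mat& F1 = (b & 1) ? H1 : H0;
    const arma::mat& F2 = (b & 2) ? H1 : H0;
    const arma::mat& F3 = (b & 4) ? H1 : H0;
    s += mode3_core(F1, F2, F3, arma::vec(children.col(b)));
  }
  return List::create(Named("children") = children, Named("s") = s,
                      Named("csq") = csq);
}
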