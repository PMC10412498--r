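// Low-level finite-element kernels on P1 tetrahedra.
// Assembly routines return COO triplets; sparse factorization is done in R
// through the Matrix package.
#include <RcppArmadillo.h>
using namespace Rcpp;

// Gradients of the 4 barycentric basis functions of a tet and its volume.
// nodes: 4 x 3 (rows = vertices). grads: 4 x 3 output. Returns volume.
static double tet_grads(const arma::mat& X, arma::mat& G) {
  arma::mat J(3, 3);
  for (int k = 0; k < 3; ++k)
    J.col(k) = (X.row(k + 1) - X.row(0)).t();
  double det = arma::det(J);
  double V = det / 6.0;
  arma::mat Ji = arma::inv(J);
  // grad lambda_i (i=1..3) = row i of J^{-1}
  for (int i = 0; i < 3; ++i)
    G.row(i + 1) = Ji.row(i);
  G.row(0) = -(G.row(1) + G.row(2) + G.row(3));
  return V;
}

// Linear elastostatics: K[(i,a),(j,b)] = V [ mu (g_i.g_j d_ab + g_j[a] g_i[b])
//                                           + lambda g_i[a] g_j[b] ]
// dof index = a*N + i (0-based; R side adds 1).
// [[Rcpp::export]]
List cpp_asm_elasticity(const arma::mat& nodes, const arma::imat& tets,
                        double mu, double lambda) {
  const int M = tets.n_rows, N = nodes.n_rows;
  const int per = 144;
  std::vector<int> I(per * (size_t)M), Jj(per * (size_t)M);
  std::vector<double> X(per * (size_t)M);
  arma::mat Xe(4, 3), G(4, 3);
  size_t k = 0;
  for (int e = 0; e < M; ++e) {
    for (int v = 0; v < 4; ++v) Xe.row(v) = nodes.row(tets(e, v) - 1);
    double V = tet_grads(Xe, G);
    if (V <= 0) stop("negative or zero tet volume in elasticity assembly (element %d)", e + 1);
    for (int i = 0; i < 4; ++i) for (int a = 0; a < 3; ++a) {
      int di = a * N + (tets(e, i) - 1);
      for (int j = 0; j < 4; ++j) for (int b = 0; b < 3; ++b) {
        int dj = b * N + (tets(e, j) - 1);
        double gij = arma::dot(G.row(i), G.row(j));
        double val = V * (mu * ((a == b ? gij : 0.0) + G(j, a) * G(i, b))
                          + lambda * G(i, a) * G(j, b));
        I[k] = di; Jj[k] = dj; X[k] = val; ++k;
      }
    }
  }
  return List::create(_["i"] = IntegerVector(I.begin(), I.end()),
                      _["j"] = IntegerVector(Jj.begin(), Jj.end()),
                      _["x"] = NumericVector(X.begin(), X.end()));
}

// Per-cell velocity gradient (row-major 3x3: G[r][c] = d u_r / d x_c),
// its singular values (descending), and the cell volume.
// [[Rcpp::export]]
List cpp_cell_gradients(const arma::mat& nodes, const arma::imat& tets,
                        const arma::mat& u) {
  const int M = tets.n_rows;
  arma::mat grads(M, 9), sv(M, 3);
  arma::vec vol(M);
  arma::mat Xe(4, 3), G(4, 3), g(3, 3);
  arma::vec s;
  for (int e = 0; e < M; ++e) {
    for (int v = 0; v < 4; ++v) Xe.row(v) = nodes.row(tets(e, v) - 1);
    double V = tet_grads(Xe, G);
    vol(e) = V;
    g.zeros();
    for (int i = 0; i < 4; ++i) {
      const arma::rowvec ui = u.row(tets(e, i) - 1);
      for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c)
        g(r, c) += ui(r) * G(i, c);
    }
    for (int r = 0; r < 3; ++r) for (int c = 0; c < 3; ++c)
      grads(e, 3 * r + c) = g(r, c);
    if (!arma::svd(s, g)) s.zeros(3);
    sv(e, 0) = s(0); sv(e, 1) = s(1); sv(e, 2) = s(2);
  }
  return List::create(_["grad"] = grads, _["sv"] = sv, _["vol"] = vol);
}

// Assemble one semi-implicit ALE Navier-Stokes step (P1-P1, SUPG/PSPG,
// RIIS valve penalty).  Unknown ordering: u_x (N), u_y (N), u_z (N),
// p (N).  dt <= 0 requests the steady form (no time-derivative terms).
//
// The RIIS layer term int (R/eps)(u - u_G) . v delta dx can be supplied in
// two quadratures:
//  - riis_node: nodal-lumped coefficients sum_i (R_i/eps_i) delta_i
//    [kg/(m^3 s)], adequate when eps is resolved by the mesh;
//  - surface quadrature (riis_elem/riis_bary/riis_w): sample points on the
//    immersed surface with weights w_q = (R/eps) A_q [kg/s / m ...], the
//    consistent evaluation when eps is much smaller than the mesh size
//    (the delta layer collapses onto the surface).
// u_gamma: prescribed immersed-surface velocity (N x 3), usually zero.
#include "asm_core.h"

void asm_ns_core(const double* nodes_p, int N, const int* tets_p, int M,
                 const double* u_old_p, const double* u_ale_p,
                 const double* musgs_p, const double* riis_p,
                 const double* ug_p,
                 double rho, double mu, double dt,
                 bool supg, bool pspg, bool lsic,
                 const int* riis_elem_p, const double* riis_bary_p,
                 const double* riis_w_p, int nq,
                 const double* tau_react_p, const double* pspg_proj_p,
                 const double* gd_react_p,
                 const int* fixed_p, const double* fixedv_p, int nfix,
                 const double* rhs_extra_p,
                 std::vector<int>& I, std::vector<int>& Jj,
                 std::vector<double>& X, std::vector<double>& RHS) {
  // zero-copy views over the caller's column-major arrays
  const arma::mat nodes(const_cast<double*>(nodes_p), N, 3, false, true);
  const arma::mat u_old(const_cast<double*>(u_old_p), N, 3, false, true);
  const arma::mat u_ale(const_cast<double*>(u_ale_p), N, 3, false, true);
  const arma::vec musgs_cell(const_cast<double*>(musgs_p), M, false, true);
  const arma::vec riis_node(const_cast<double*>(riis_p), N, false, true);
  const arma::mat u_gamma(const_cast<double*>(ug_p), N, 3, false, true);
  const arma::mat riis_bary(const_cast<double*>(riis_bary_p), nq, 4, false, true);
  const arma::vec riis_w(const_cast<double*>(riis_w_p), nq, false, true);
  const arma::vec tau_react(const_cast<double*>(tau_react_p), M, false, true);
  const arma::mat pspg_proj(const_cast<double*>(pspg_proj_p), M, 3, false, true);
  const arma::vec gd_react(const_cast<double*>(gd_react_p), M, false, true);
  auto TET = [&](int e, int v) { return tets_p[(size_t)v * M + e]; };
  const bool unsteady = (dt > 0) && arma::is_finite(dt);
  const double idt = unsteady ? 1.0 / dt : 0.0;
  // entries per element (generous upper bound)
  const size_t per = 480;
  I.clear(); Jj.clear(); X.clear();
  I.reserve(per * (size_t)M);
  Jj.reserve(per * (size_t)M);
  X.reserve(per * (size_t)M);
  RHS.assign(4 * (size_t)N, 0.0);
  arma::vec rhs(RHS.data(), 4 * (size_t)N, false, true);
  arma::mat Xe(4, 3), G(4, 3);
  const int NP = 3 * N;  // offset of pressure dofs

  // Dirichlet elimination on the fly: rows of constrained dofs become the
  // identity, column contributions move to the right-hand side.
  std::vector<char> isfix(4 * (size_t)N, 0);
  std::vector<double> fixval(4 * (size_t)N, 0.0);
  for (int k = 0; k < nfix; ++k) {
    isfix[fixed_p[k]] = 1;
    fixval[fixed_p[k]] = fixedv_p[k];
  }
  for (size_t k = 0; k < 4 * (size_t)N; ++k) rhs(k) += rhs_extra_p[k];
  auto add = [&](int r, int c, double v) {
    if (isfix[r]) return;
    if (isfix[c]) { rhs(r) -= v * fixval[c]; return; }
    I.push_back(r); Jj.push_back(c); X.push_back(v);
  };

  // surface-quadrature RIIS: per-element reaction magnitude (for the
  // stabilization parameter) and the penalty matrix/rhs contributions
  arma::vec coef_surf(M, arma::fill::zeros);
  arma::vec tauv(M, arma::fill::zeros);
  for (int q = 0; q < nq; ++q) {
    int e = riis_elem_p[q] - 1;
    if (e < 0) continue;
    double wq = riis_w(q);
    arma::mat Xe4(4, 3), G4(4, 3);
    int nd[4];
    for (int v = 0; v < 4; ++v) { nd[v] = TET(e, v) - 1; Xe4.row(v) = nodes.row(nd[v]); }
    double V = tet_grads(Xe4, G4);
    coef_surf(e) += wq / V;
    for (int i = 0; i < 4; ++i) {
      double bi = riis_bary(q, i);
      if (bi == 0) continue;
      for (int j = 0; j < 4; ++j) {
        double w2 = wq * bi * riis_bary(q, j);
        if (w2 == 0) continue;
        for (int aC = 0; aC < 3; ++aC) {
          add(aC * N + nd[i], aC * N + nd[j], w2);
        }
      }
      double ug[3] = {0, 0, 0};
      for (int j = 0; j < 4; ++j)
        for (int aC = 0; aC < 3; ++aC)
          ug[aC] += riis_bary(q, j) * u_gamma(nd[j], aC);
      for (int aC = 0; aC < 3; ++aC)
        rhs(aC * N + nd[i]) += wq * bi * ug[aC];
    }
  }

  for (int e = 0; e < M; ++e) {
    int nd[4];
    for (int v = 0; v < 4; ++v) { nd[v] = TET(e, v) - 1; Xe.row(v) = nodes.row(nd[v]); }
    double V = tet_grads(Xe, G);
    if (V <= 0) stop("negative or zero tet volume in NS assembly (element %d)", e + 1);
    double mu_eff = mu + musgs_cell(e);
    // element-mean advection velocity a = u_old - u_ale
    arma::rowvec a(3, arma::fill::zeros);
    double coef = 0.0;  // element-mean RIIS reaction coefficient
    for (int v = 0; v < 4; ++v) {
      a += (u_old.row(nd[v]) - u_ale.row(nd[v]));
      coef += riis_node(nd[v]);
    }
    a *= 0.25;
    double coef_nodal = coef * 0.25;
    coef = coef_nodal + tau_react(e);   // reaction seen by tau (nodal path)
    double anorm = arma::norm(a, 2);
    double h = std::cbrt(6.0 * V);
    // stabilization parameter (units m^3 s / kg after the 1/rho factor);
    // includes the RIIS reaction term so the layer stays consistent
    double nu_eff = mu_eff / rho;
    double s1 = unsteady ? (2.0 * idt) : 0.0;
    double s2 = 2.0 * anorm / h;
    double s3 = 12.0 * nu_eff / (h * h);
    double s4 = coef / rho;
    double tau = 1.0 / (rho * std::sqrt(s1 * s1 + s2 * s2 + s3 * s3 + s4 * s4 + 1e-300));
    tauv(e) = tau;
    // grad-div parameter, strengthened by the per-cell reaction coefficient
    // gd_react: the caller boosts it in cells near the closed membrane
    // (damping the spurious circulation at the fringe of the under-resolved
    // pressure jump) while leaving cells near a regurgitant orifice at the
    // plain advective-diffusive value so the channel still conducts
    double tau0 = 1.0 / (rho * std::sqrt(s1 * s1 + s2 * s2 + s3 * s3 +
                         (gd_react(e) / rho) * (gd_react(e) / rho) + 1e-300));
    double tau_l = lsic ? (h * h / (4.0 * tau0)) : 0.0;
    double adg[4];
    for (int i = 0; i < 4; ++i) adg[i] = arma::dot(a, G.row(i));

    for (int i = 0; i < 4; ++i) {
      const int ni = nd[i];
      // lumped mass + lumped RIIS penalty (diagonal in components)
      double mlump = unsteady ? rho * V * 0.25 * idt : 0.0;
      double plump = riis_node(ni) * V * 0.25;
      for (int aC = 0; aC < 3; ++aC) {
        int di = aC * N + ni;
        add(di, di, mlump + plump);
        rhs(di) += mlump * u_old(ni, aC) + plump * u_gamma(ni, aC);
      }
      for (int j = 0; j < 4; ++j) {
        const int njn = nd[j];
        double gij = arma::dot(G.row(i), G.row(j));
        // convection (Galerkin): rho (a . grad u_j) phi_i, same component
        double conv = rho * adg[j] * V * 0.25;
        for (int aC = 0; aC < 3; ++aC) {
          int di = aC * N + ni;
          // velocity-velocity block: convection + viscous 2 mu_eff D(u):D(v)
          // + grad-div, emitted as one entry per component pair
          for (int bC = 0; bC < 3; ++bC) {
            double val = mu_eff * V * G(j, aC) * G(i, bC)
                       + tau_l * V * G(i, aC) * G(j, bC);
            if (aC == bC) val += conv + mu_eff * V * gij;
            add(di, bC * N + njn, val);
          }
          // pressure gradient: -int p div v
          add(di, NP + njn, -V * 0.25 * G(i, aC));
          // continuity: int q div u
          add(NP + ni, aC * N + njn, V * 0.25 * G(j, aC));
        }
      }
      if (pspg) {
        // (tau/rho) int grad q . r_m,
        // r_m = rho u'/dt + rho a.grad u + grad p + coef (u - u_G).
        // In elements cut by an immersed valve the test gradient (and the
        // trial pressure gradient) are projected onto the valve tangent
        // plane: the continuous-pressure space cannot represent the
        // transvalvular jump, and the unprojected term acts as an
        // artificial permeability across the membrane.
        arma::rowvec nrm = pspg_proj.row(e);
        double n2 = arma::dot(nrm, nrm);
        arma::rowvec gi = G.row(i);
        if (n2 > 0.5) gi -= arma::dot(gi, nrm) * nrm;
        for (int j = 0; j < 4; ++j) {
          const int njn = nd[j];
          arma::rowvec gj = G.row(j);
          if (n2 > 0.5) gj -= arma::dot(gj, nrm) * nrm;
          add(NP + ni, NP + njn, tau * V * arma::dot(gi, gj)); // grad p part
          // time + convection + RIIS reaction parts of the residual, one
          // entry per velocity dof
          double ctime = unsteady ? tau * rho * idt * V * 0.25 : 0.0;
          double cconv = tau * rho * adg[j] * V;
          double creac = tau * coef_nodal * V * 0.25;
          for (int bC = 0; bC < 3; ++bC) {
            add(NP + ni, bC * N + njn, (ctime + creac) * gi(bC) + cconv * gi(bC));
            if (unsteady) rhs(NP + ni) += ctime * gi(bC) * u_old(njn, bC);
            if (coef_nodal != 0.0) rhs(NP + ni) += creac * gi(bC) * u_gamma(njn, bC);
          }
        }
      }
      if (supg) {
        // tau int (rho a . grad v) . r_m ; test weight w_i = rho tau adg[i]
        double wi = rho * tau * adg[i];
        {
          for (int j = 0; j < 4; ++j) {
            const int njn = nd[j];
            double ct = unsteady ? wi * rho * idt * V * 0.25 : 0.0;
            double cc = wi * rho * adg[j] * V;
            double cr = wi * coef_nodal * V * 0.25;
            for (int aC = 0; aC < 3; ++aC) {
              int di = aC * N + ni;
              add(di, aC * N + njn, ct + cc + cr);
              if (unsteady) rhs(di) += ct * u_old(njn, aC);
              if (coef_nodal != 0.0) rhs(di) += cr * u_gamma(njn, aC);
              add(di, NP + njn, wi * G(j, aC) * V);
            }
          }
        }
      }
    }
  }
  // stabilization consistency of the surface-quadrature RIIS term: the
  // momentum residual carries the sharp penalty, so PSPG/SUPG see it with
  // the same surface quadrature
  if (pspg || supg) {
    for (int q = 0; q < nq; ++q) {
      int e = riis_elem_p[q] - 1;
      if (e < 0) continue;
      double wq = riis_w(q);
      double tau = tauv(e);
      arma::mat Xe4(4, 3), G4(4, 3);
      int nd[4];
      for (int v = 0; v < 4; ++v) { nd[v] = TET(e, v) - 1; Xe4.row(v) = nodes.row(nd[v]); }
      tet_grads(Xe4, G4);
      arma::rowvec a(3, arma::fill::zeros);
      for (int v = 0; v < 4; ++v) a += (u_old.row(nd[v]) - u_ale.row(nd[v]));
      a *= 0.25;
      for (int i = 0; i < 4; ++i) {
        const int ni = nd[i];
        if (pspg) {
          // tau int grad q . coef (u - u_G) delta_Gamma (projected gradient)
          arma::rowvec nrm = pspg_proj.row(e);
          double n2 = arma::dot(nrm, nrm);
          arma::rowvec gi = G4.row(i);
          if (n2 > 0.5) gi -= arma::dot(gi, nrm) * nrm;
          for (int j = 0; j < 4; ++j) {
            double bj = riis_bary(q, j);
            if (bj == 0) continue;
            for (int bC = 0; bC < 3; ++bC) {
              double cr = tau * wq * bj * gi(bC);
              add(NP + ni, bC * N + nd[j], cr);
              rhs(NP + ni) += cr * u_gamma(nd[j], bC);
            }
          }
        }
        if (supg) {
          // tau int (rho a . grad v) . coef (u - u_G) delta_Gamma
          double wsup = rho * tau * arma::dot(a, G4.row(i));
          if (wsup != 0.0) {
            for (int j = 0; j < 4; ++j) {
              double bj = riis_bary(q, j);
              if (bj == 0) continue;
              for (int aC = 0; aC < 3; ++aC) {
                double cr = wsup * wq * bj;
                add(aC * N + ni, aC * N + nd[j], cr);
                rhs(aC * N + ni) += cr * u_gamma(nd[j], aC);
              }
            }
          }
        }
      }
    }
  }
  for (int k = 0; k < nfix; ++k) {
    int d = fixed_p[k];
    I.push_back(d); Jj.push_back(d); X.push_back(1.0);
    rhs(d) = fixval[d];
  }
}

// Exported triplet interface (kept for verification and experiments).
// [[Rcpp::export]]
List cpp_asm_ns(const arma::mat& nodes, const arma::imat& tets,
                const arma::mat& u_old, const arma::mat& u_ale,
                const arma::vec& musgs_cell, const arma::vec& riis_node,
                const arma::mat& u_gamma,
                double rho, double mu, double dt,
                bool supg, bool pspg, bool lsic,
                const arma::ivec& riis_elem, const arma::mat& riis_bary,
                const arma::vec& riis_w, const arma::vec& tau_react,
                const arma::mat& pspg_proj, const arma::vec& gd_react,
                const arma::ivec& fixed_dofs, const arma::vec& fixed_vals,
                const arma::vec& rhs_extra) {
  std::vector<int> I, Jj;
  std::vector<double> X, RHS;
  asm_ns_core(nodes.memptr(), nodes.n_rows, tets.memptr(), tets.n_rows,
              u_old.memptr(), u_ale.memptr(), musgs_cell.memptr(),
              riis_node.memptr(), u_gamma.memptr(), rho, mu, dt,
              supg, pspg, lsic,
              riis_elem.memptr(), riis_bary.memptr(), riis_w.memptr(),
              riis_elem.n_elem,
              tau_react.memptr(), pspg_proj.memptr(), gd_react.memptr(),
              fixed_dofs.memptr(), fixed_vals.memptr(), fixed_dofs.n_elem,
              rhs_extra.memptr(), I, Jj, X, RHS);
  return List::create(_["i"] = IntegerVector(I.begin(), I.end()),
                      _["j"] = IntegerVector(Jj.begin(), Jj.end()),
                      _["x"] = NumericVector(X.begin(), X.end()),
                      _["rhs"] = NumericVector(RHS.begin(), RHS.end()));
}

// Exact unsigned distance from a point to a triangle (Eberly's region scheme).
static double point_tri_dist2(const arma::rowvec& p, const arma::rowvec& a,
                              const arma::rowvec& b, const arma::rowvec& c) {
  arma::rowvec ab = b - a, ac = c - a, ap = p - a;
  double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return arma::dot(ap, ap);
  arma::rowvec bp = p - b;
  double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return arma::dot(bp, bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    arma::rowvec q = ap - v * ab; return arma::dot(q, q);
  }
  arma::rowvec cp = p - c;
  double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return arma::dot(cp, cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    arma::rowvec q = ap - w * ac; return arma::dot(q, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    arma::rowvec q = bp + w * (c - b); return arma::dot(q, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  arma::rowvec q = ap - (v * ab + w * ac);
  return arma::dot(q, q);
}

// Unsigned distance from each query point to a triangulated surface.
// Distances larger than `cap` (if cap > 0) may be reported as any value
// >= cap (bounding-box pruning); pass cap <= 0 for exact everywhere.
// [[Rcpp::export]]
NumericVector cpp_dist_to_surface(const arma::mat& pts, const arma::mat& verts,
                                  const arma::imat& tris, double cap) {
  const int P = pts.n_rows, T = tris.n_rows;
  arma::mat lo(T, 3), hi(T, 3);
  for (int t = 0; t < T; ++t) {
    arma::mat tv(3, 3);
    for (int v = 0; v < 3; ++v) tv.row(v) = verts.row(tris(t, v) - 1);
    lo.row(t) = arma::min(tv, 0);
    hi.row(t) = arma::max(tv, 0);
  }
  NumericVector out(P);
  for (int i = 0; i < P; ++i) {
    arma::rowvec p = pts.row(i);
    double best = std::numeric_limits<double>::infinity();
    if (cap > 0) best = cap * cap;
    for (int t = 0; t < T; ++t) {
      // lower bound on squared distance from box
      double lb = 0;
      for (int k = 0; k < 3; ++k) {
        double d = std::max({lo(t, k) - p(k), p(k) - hi(t, k), 0.0});
        lb += d * d;
      }
      if (lb >= best) continue;
      double d2 = point_tri_dist2(p, verts.row(tris(t, 0) - 1),
                                  verts.row(tris(t, 1) - 1),
                                  verts.row(tris(t, 2) - 1));
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Closest point on a triangulated surface for each query point.
// [[Rcpp::export]]
List cpp_closest_on_surface(const arma::mat& pts, const arma::mat& verts,
                            const arma::imat& tris) {
  const int P = pts.n_rows, T = tris.n_rows;
  arma::mat lo(T, 3), hi(T, 3);
  for (int t = 0; t < T; ++t) {
    arma::mat tv(3, 3);
    for (int v = 0; v < 3; ++v) tv.row(v) = verts.row(tris(t, v) - 1);
    lo.row(t) = arma::min(tv, 0);
    hi.row(t) = arma::max(tv, 0);
  }
  arma::mat cp(P, 3);
  arma::vec dist(P);
  for (int i = 0; i < P; ++i) {
    arma::rowvec p = pts.row(i);
    double best = std::numeric_limits<double>::infinity();
    arma::rowvec bestq(3, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      double lb = 0;
      for (int k = 0; k < 3; ++k) {
        double d = std::max({lo(t, k) - p(k), p(k) - hi(t, k), 0.0});
        lb += d * d;
      }
      if (lb >= best) continue;
      const arma::rowvec a = verts.row(tris(t, 0) - 1);
      const arma::rowvec b = verts.row(tris(t, 1) - 1);
      const arma::rowvec c = verts.row(tris(t, 2) - 1);
      // recompute closest point explicitly (same region logic as distance)
      arma::rowvec ab = b - a, ac = c - a, ap = p - a;
      double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
      arma::rowvec q;
      if (d1 <= 0 && d2 <= 0) q = a;
      else {
        arma::rowvec bp = p - b;
        double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
        if (d3 >= 0 && d4 <= d3) q = b;
        else {
          double vc = d1 * d4 - d3 * d2;
          if (vc <= 0 && d1 >= 0 && d3 <= 0) q = a + (d1 / (d1 - d3)) * ab;
          else {
            arma::rowvec cpv = p - c;
            double d5 = arma::dot(ab, cpv), d6 = arma::dot(ac, cpv);
            if (d6 >= 0 && d5 <= d6) q = c;
            else {
              double vb = d5 * d2 - d1 * d6;
              if (vb <= 0 && d2 >= 0 && d6 <= 0) q = a + (d2 / (d2 - d6)) * ac;
              else {
                double va = d3 * d6 - d5 * d4;
                if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
                  q = b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b);
                else {
                  double denom = 1.0 / (va + vb + vc);
                  q = a + (vb * denom) * ab + (vc * denom) * ac;
                }
              }
            }
          }
        }
      }
      double d2q = arma::dot(p - q, p - q);
      if (d2q < best) { best = d2q; bestq = q; }
    }
    cp.row(i) = bestq;
    dist(i) = std::sqrt(best);
  }
  return List::create(_["point"] = cp, _["dist"] = dist);
}

// Locate query points inside a tet mesh; returns 1-based element index
// (0 if not found within tolerance) and barycentric coordinates.
// [[Rcpp::export]]
List cpp_locate_points(const arma::mat& nodes, const arma::imat& tets,
                       const arma::mat& query, double tol) {
  const int M = tets.n_rows, Q = query.n_rows;
  arma::mat lo(M, 3), hi(M, 3);
  std::vector<arma::mat> Jinv(M);
  arma::mat X0(M, 3);
  for (int e = 0; e < M; ++e) {
    arma::mat Xe(4, 3);
    for (int v = 0; v < 4; ++v) Xe.row(v) = nodes.row(tets(e, v) - 1);
    lo.row(e) = arma::min(Xe, 0); hi.row(e) = arma::max(Xe, 0);
    arma::mat J(3, 3);
    for (int k = 0; k < 3; ++k) J.col(k) = (Xe.row(k + 1) - Xe.row(0)).t();
    Jinv[e] = arma::inv(J);
    X0.row(e) = Xe.row(0);
  }
  IntegerVector elem(Q);
  NumericMatrix bary(Q, 4);
  for (int q = 0; q < Q; ++q) {
    arma::rowvec p = query.row(q);
    int found = 0; double bestneg = -1e30; arma::vec bestl(4, arma::fill::zeros);
    for (int e = 0; e < M; ++e) {
      bool out = false;
      for (int k = 0; k < 3; ++k)
        if (p(k) < lo(e, k) - tol || p(k) > hi(e, k) + tol) { out = true; break; }
      if (out) continue;
      arma::vec l123 = Jinv[e] * (p - X0.row(e)).t();
      double l0 = 1.0 - arma::accu(l123);
      double mn = std::min({l0, l123(0), l123(1), l123(2)});
      if (mn >= -tol) {
        found = e + 1;
        bestl(0) = l0; bestl(1) = l123(0); bestl(2) = l123(1); bestl(3) = l123(2);
        break;
      }
      if (mn > bestneg) {
        bestneg = mn;
        bestl(0) = l0; bestl(1) = l123(0); bestl(2) = l123(1); bestl(3) = l123(2);
      }
    }
    elem[q] = found;
    for (int v = 0; v < 4; ++v) bary(q, v) = bestl(v);
  }
  return List::create(_["elem"] = elem, _["bary"] = bary);
}
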