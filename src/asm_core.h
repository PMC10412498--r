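#pragma once
#include <vector>

// Assemble one semi-implicit stabilized Navier-Stokes step into COO triplets
// (0-based) and the right-hand side.  Plain-pointer interface so the
// assembly (Armadillo translation unit) and the linear solver (Eigen
// translation unit) can share it without mixing the two header stacks.
void asm_ns_core(const double* nodes, int N, const int* tets, int M,
                 const double* u_old, const double* u_ale,
                 const double* musgs_cell, const double* riis_node,
                 const double* u_gamma,
                 double rho, double mu, double dt,
                 bool supg, bool pspg, bool lsic,
                 const int* riis_elem, const double* riis_bary,
                 const double* riis_w, int nq,
                 const double* tau_react, const double* pspg_proj,
                 const double* gd_react,
                 const int* fixed_dofs, const double* fixed_vals, int nfix,
                 const double* rhs_extra,
                 std::vector<int>& I, std::vector<int>& J,
                 std::vector<double>& X, std::vector<double>& RHS);
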