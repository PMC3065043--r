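#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 7-point Laplacian with zero-flux (mirror ghost) boundaries.
// A missing neighbour contributes nothing to the flux balance, which keeps
// the discrete divergence theorem exact: the output sums to zero.
static void laplacian3d(const double* f, double* out,
                        int nx, int ny, int nz, double h) {
  const double ih2 = 1.0 / (h * h);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
        const double fc = f[idx];
        double acc = 0.0;
        if (i > 0)      acc += f[idx - 1] - fc;
        if (i < nx - 1) acc += f[idx + 1] - fc;
        if (j > 0)      acc += f[idx - nx] - fc;
        if (j < ny - 1) acc += f[idx + nx] - fc;
        if (k > 0)      acc += f[idx - (R_xlen_t)nx * ny] - fc;
        if (k < nz - 1) acc += f[idx + (R_xlen_t)nx * ny] - fc;
        out[idx] = acc * ih2;
      }
    }
  }
}

static void get_dims(const NumericVector& f, int dims[3]) {
  if (!f.hasAttribute("dim")) stop("field must be a 3D array");
  IntegerVector d = f.attr("dim");
  if (d.size() != 3) stop("field must be a 3D array");
  dims[0] = d[0]; dims[1] = d[1]; dims[2] = d[2];
}

// [[Rcpp::export]]
NumericVector cpp_laplacian_noflux(NumericVector f, double h) {
  int d[3]; get_dims(f, d);
  NumericVector out(f.size());
  out.attr("dim") = f.attr("dim");
  laplacian3d(REAL(f), REAL(out), d[0], d[1], d[2], h);
  return out;
}

struct ModelPars {
  double a1, D2, al, be, ga, a2, de, mlim, D3, D4, lC, lD, nC, nD, mu, AC, AD;
};

static ModelPars read_pars(List pars) {
  ModelPars p;
  p.a1 = pars["alpha1_t"]; p.D2 = pars["D2_t"];
  p.al = pars["alpha_t"]; p.be = pars["beta_t"]; p.ga = pars["gamma_t"];
  p.a2 = pars["alpha2_t"]; p.de = pars["delta_t"]; p.mlim = pars["m_lim"];
  p.D3 = pars["D3_t"]; p.D4 = pars["D4_t"];
  p.lC = pars["lambdaC_t"]; p.lD = pars["lambdaD_t"];
  p.nC = pars["nuC_t"]; p.nD = pars["nuD_t"]; p.mu = pars["mu_t"];
  p.AC = pars["AC_t"]; p.AD = pars["AD_t"];
  return p;
}

// One forward-Euler update of every field, reading old values only.
// gam/rpC/rpD hold Gamma_i(t) and the normalized per-day release-profile
// values for each of the nQ carrier fields at the current time.
static void do_step(double* pn, double* pm, double* pc, double* pd,
                    std::vector<double*>& pC, int nQ,
                    const double* gam, const double* rpC, const double* rpD,
                    const int dim[3], double h, double dt,
                    const ModelPars& P, bool chemo, bool anti, int form,
                    std::vector<double>& lap_n, std::vector<double>& lap_m,
                    std::vector<double>& lap_c, std::vector<double>& lap_d) {
  const R_xlen_t len = (R_xlen_t)dim[0] * dim[1] * dim[2];
  laplacian3d(pn, lap_n.data(), dim[0], dim[1], dim[2], h);
  laplacian3d(pm, lap_m.data(), dim[0], dim[1], dim[2], h);
  laplacian3d(pc, lap_c.data(), dim[0], dim[1], dim[2], h);
  laplacian3d(pd, lap_d.data(), dim[0], dim[1], dim[2], h);

  for (R_xlen_t i = 0; i < len; ++i) {
    const double ni = pn[i], mi = pm[i], ci = pc[i], di = pd[i];

    double RC = 0.0, RD = 0.0;
    for (int q = 0; q < nQ; ++q) {
      RC += rpC[q] * pC[q][i];
      RD += rpD[q] * pC[q][i];
    }

    double fn = lap_n[i] + ni * (1.0 - ni) + P.a1 * mi * ni;
    if (chemo) fn -= P.AD * di * ni;
    double fm = P.D2 * lap_m[i] + mi * (P.al + P.be * mi + P.ga * mi * mi) +
                P.a2 * ni * mi;
    if (anti) fm -= P.AC * ci * mi;
    const double fc = P.D3 * lap_c[i] + P.lC * RC - P.nC * ci;
    const double fd = P.D4 * lap_d[i] + P.lD * RD - P.mu * mi * di -
                      P.nD * di;

    // vascular delivery efficiency from the old vessel field
    const double fdel = (form == 0)
      ? mi * std::exp(-(mi / P.mlim) * (mi / P.mlim))
      : mi * std::exp(-mi * mi / P.mlim);
    for (int q = 0; q < nQ; ++q) {
      double v = pC[q][i] + dt * P.de * gam[q] * fdel;
      pC[q][i] = v > 0.0 ? v : 0.0;
    }

    double vn = ni + dt * fn; pn[i] = vn > 0.0 ? vn : 0.0;
    double vm = mi + dt * fm; pm[i] = vm > 0.0 ? vm : 0.0;
    double vc = ci + dt * fc; pc[i] = vc > 0.0 ? vc : 0.0;
    double vd = di + dt * fd; pd[i] = vd > 0.0 ? vd : 0.0;
  }
}

// Single step, exposed for the step() R API.  All fields are modified in
// place; the caller owns (and has duplicated) them.
// [[Rcpp::export]]
void cpp_step_inplace(NumericVector n, NumericVector m, List Cs,
                      NumericVector c, NumericVector d,
                      double h, double dt, List pars,
                      NumericVector gamma_vals,
                      NumericVector rpC, NumericVector rpD,
                      bool chemo, bool anti, int form) {
  int dim[3]; get_dims(n, dim);
  const R_xlen_t len = n.size();
  const int nQ = Cs.size();
  if (gamma_vals.size() != nQ || rpC.size() != nQ || rpD.size() != nQ)
    stop("carrier/schedule length mismatch");
  std::vector<double*> pC(nQ);
  for (int q = 0; q < nQ; ++q) {
    NumericVector Cq = Cs[q];
    if (Cq.size() != len) stop("carrier/grid shape mismatch");
    pC[q] = REAL(Cq);
  }
  ModelPars P = read_pars(pars);
  std::vector<double> l1(len), l2(len), l3(len), l4(len);
  do_step(REAL(n), REAL(m), REAL(c), REAL(d), pC, nQ,
          REAL(gamma_vals), REAL(rpC), REAL(rpD),
          dim, h, dt, P, chemo, anti, form, l1, l2, l3, l4);
}

// Full integration loop.  dts has one entry per step; gammaM/rpCM/rpDM are
// nQ x nsteps matrices of per-step scalars (zero before each dose time, so
// carriers can be allocated up front).  After each step index listed in
// record_steps (1-based) the count of voxels with n >= c_th is recorded;
// a non-finite field aborts with a negative count.  n, m, c, d and the
// returned carrier fields hold the final state.
// [[Rcpp::export]]
List cpp_run(NumericVector n, NumericVector m, NumericVector c,
             NumericVector d, int n_carriers, double h, NumericVector dts,
             List pars, NumericMatrix gammaM, NumericMatrix rpCM,
             NumericMatrix rpDM, bool chemo, bool anti, int form,
             IntegerVector record_steps, double c_th) {
  int dim[3]; get_dims(n, dim);
  const R_xlen_t len = n.size();
  const int S = dts.size();
  if (gammaM.nrow() != n_carriers || gammaM.ncol() != S ||
      rpCM.nrow() != n_carriers || rpCM.ncol() != S ||
      rpDM.nrow() != n_carriers || rpDM.ncol() != S)
    stop("per-step scalar matrices must be n_carriers x nsteps");

  List Cs(n_carriers);
  std::vector<double*> pC(n_carriers);
  for (int q = 0; q < n_carriers; ++q) {
    NumericVector Cq(len);
    Cq.attr("dim") = n.attr("dim");
    Cs[q] = Cq;
    pC[q] = REAL(Cq);
  }
  ModelPars P = read_pars(pars);
  std::vector<double> l1(len), l2(len), l3(len), l4(len);
  NumericVector counts(record_steps.size());
  double* pn = REAL(n); double* pm = REAL(m);
  double* pc = REAL(c); double* pd = REAL(d);

  int r = 0;
  for (int s = 0; s < S; ++s) {
    const double* gs = n_carriers > 0 ? &gammaM(0, s) : (const double*)0;
    const double* cs = n_carriers > 0 ? &rpCM(0, s) : (const double*)0;
    const double* ds = n_carriers > 0 ? &rpDM(0, s) : (const double*)0;
    do_step(pn, pm, pc, pd, pC, n_carriers, gs, cs, ds,
            dim, h, dts[s], P, chemo, anti, form, l1, l2, l3, l4);
    while (r < record_steps.size() && record_steps[r] == s + 1) {
      double cnt = 0.0; bool ok = true;
      for (R_xlen_t i = 0; i < len; ++i) {
        if (!std::isfinite(pn[i]) || !std::isfinite(pm[i])) { ok = false; break; }
        if (pn[i] >= c_th) cnt += 1.0;
      }
      counts[r] = ok ? cnt : -1.0;
      if (!ok) return List::create(_["counts"] = counts,
                                   _["carriers"] = Cs,
                                   _["aborted_step"] = s + 1);
      ++r;
    }
  }
  return List::create(_["counts"] = counts, _["carriers"] = Cs,
                      _["aborted_step"] = -1);
}
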