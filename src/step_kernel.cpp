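#include <Rcpp.h>
using namespace Rcpp;

// Growing plus-end density: Cg[k] = sum_l rho_g[k - il, il] * dx
// (column il holds lengths ~ il*dx; plus end of (ix, il) sits at cell ix+il)
static void cg_profile_into(const NumericMatrix& rho_g, double dx,
                            std::vector<double>& cg) {
  const int nx = rho_g.nrow(), nl = rho_g.ncol();
  std::fill(cg.begin(), cg.end(), 0.0);
  const int lmax = std::min(nl, nx);
  for (int il = 0; il < lmax; ++il) {
    const double* col = &rho_g(0, il);
    for (int k = il; k < nx; ++k) cg[k] += col[k - il] * dx;
  }
}

// Polymer mass density: each microtubule in (ix, il) covers cells ix..ix+il
static void m_profile_into(const NumericMatrix& rho_g,
                           const NumericMatrix& rho_s, double dx,
                           std::vector<double>& m) {
  const int nx = rho_g.nrow(), nl = rho_g.ncol();
  std::fill(m.begin(), m.end(), 0.0);
  std::vector<double> s(nx + 1);
  const double dx2 = dx * dx;
  for (int il = 0; il < nl; ++il) {
    const double* cg_ = &rho_g(0, il);
    const double* cs_ = &rho_s(0, il);
    s[0] = 0.0;
    for (int k = 0; k < nx; ++k) s[k + 1] = s[k] + cg_[k] + cs_[k];
    const int w = il + 1;  // covered cells
    for (int k = 0; k < nx; ++k) {
      const int lo = std::max(k + 1 - w, 0);
      m[k] += (s[k + 1] - s[lo]) * dx2;
    }
  }
}

// [[Rcpp::export(name = ".run_steps_cpp")]]
List run_steps_cpp(NumericMatrix rho_g, NumericMatrix rho_s,
                   int n_steps, double dt, double dx,
                   int shift_g, int shift_s,
                   double fcat, double fres,
                   int plus_end_mode, double rate, double K, int clamp,
                   int renucleate) {
  const int nx = rho_g.nrow(), nl = rho_g.ncol();
  NumericMatrix g = clone(rho_g), s = clone(rho_s);

  // exact two-state switching kernel over half a step
  const double tot = fcat + fres, E = std::exp(-tot * dt / 2.0);
  const double k_gg = (fres + fcat * E) / tot, k_sg = (fres - fres * E) / tot;
  const double k_gs = (fcat - fcat * E) / tot, k_ss = (fcat + fres * E) / tot;

  std::vector<double> cg(nx), m(plus_end_mode ? 0 : nx);
  const int b = std::min(shift_s, nl);

  for (int step = 0; step < n_steps; ++step) {
    // half exchange
    for (int il = 0; il < nl; ++il) {
      double* pg = &g(0, il);
      double* ps = &s(0, il);
      for (int ix = 0; ix < nx; ++ix) {
        const double gg = pg[ix], ss = ps[ix];
        pg[ix] = k_gg * gg + k_sg * ss;
        ps[ix] = k_gs * gg + k_ss * ss;
      }
    }

    // advect: growing +shift_g cells in l, shrinking -shift_s with absorption
    for (int il = nl - 1; il >= shift_g; --il) {
      double* dst = &g(0, il);
      const double* src = &g(0, il - shift_g);
      std::copy(src, src + nx, dst);
    }
    for (int il = 0; il < shift_g; ++il) {
      std::fill(&g(0, il), &g(0, il) + nx, 0.0);
    }
    double lost0 = 0.0;
    for (int il = 0; il < b; ++il) lost0 += s(0, il) * dx;
    for (int il = 0; il + shift_s < nl; ++il) {
      double* dst = &s(0, il);
      const double* src = &s(0, il + shift_s);
      std::copy(src, src + nx, dst);
    }
    for (int il = std::max(nl - shift_s, 0); il < nl; ++il) {
      std::fill(&s(0, il), &s(0, il) + nx, 0.0);
    }
    if (renucleate) g(0, 0) += lost0 / dx;

    // half exchange
    for (int il = 0; il < nl; ++il) {
      double* pg = &g(0, il);
      double* ps = &s(0, il);
      for (int ix = 0; ix < nx; ++ix) {
        const double gg = pg[ix], ss = ps[ix];
        pg[ix] = k_gg * gg + k_sg * ss;
        ps[ix] = k_gs * gg + k_ss * ss;
      }
    }

    // nucleation: logistic in local Cg, compounded over the step, newborns
    // spread over the first shift_g length cells at the plus-end position
    if (rate > 0) {
      cg_profile_into(g, dx, cg);
      if (!plus_end_mode) m_profile_into(g, s, dx, m);
      const double inv = 1.0 / ((double)shift_g * dx);
      for (int k = 0; k < nx; ++k) {
        const double c = cg[k];
        double logistic = (K == R_PosInf) ? 1.0 : (1.0 - c / K);
        double q = plus_end_mode ? rate * c * logistic : rate * m[k] * logistic;
        if (clamp && q < 0) q = 0;
        // compounding only in plus-end mode (bounded effective rate q/Cg);
        // polymer-mode births come from the lattice, plain q*dt
        double born;
        if (plus_end_mode && c > 0) {
          born = c * std::expm1((q / c) * dt);
        } else {
          born = q * dt;
        }
        if (born != 0.0) {
          const double dep = born * inv;
          for (int j = 0; j < shift_g; ++j) g(k, j) += dep;
        }
      }
    }
  }

  return List::create(_["rho_g"] = g, _["rho_s"] = s);
}

// [[Rcpp::export(name = ".cg_profile_cpp")]]
NumericVector cg_profile_cpp(NumericMatrix rho_g, double dx) {
  std::vector<double> cg(rho_g.nrow());
  cg_profile_into(rho_g, dx, cg);
  return wrap(cg);
}

// [[Rcpp::export(name = ".m_profile_cpp")]]
NumericVector m_profile_cpp(NumericMatrix rho_g, NumericMatrix rho_s,
                            double dx) {
  std::vector<double> m(rho_g.nrow());
  m_profile_into(rho_g, rho_s, dx, m);
  return wrap(m);
}
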