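// Compiled kernels for the cavity bioconvection solver.
//
// Field layout: arma::mat with rows indexed by i (x1, 0..Nx-1 spanning [0,A])
// and columns by j (x2, 0..Ny-1 spanning [0,1]); gravity acts along -x2.
// Velocity convention: u = dpsi/dx2, v = -dpsi/dx1, so that lap(psi) = -omega
// with omega = dv/dx1 - du/dx2.

#include <RcppArmadillo.h>
#include <map>
#include <stdexcept>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Tridiagonal (Thomas) solver
// ---------------------------------------------------------------------------

static arma::vec thomas(const arma::vec& lo, const arma::vec& di,
                        const arma::vec& up, const arma::vec& rhs) {
  const arma::uword m = di.n_elem;
  arma::vec c(m), d(m), x(m);
  double piv = di(0);
  if (piv == 0.0) throw std::runtime_error("singular tridiagonal system: zero pivot at row 1");
  c(0) = (m > 1) ? up(0) / piv : 0.0;
  d(0) = rhs(0) / piv;
  for (arma::uword k = 1; k < m; ++k) {
    piv = di(k) - lo(k) * c(k - 1);
    if (piv == 0.0) {
      throw std::runtime_error("singular tridiagonal system: zero pivot at row " +
                               std::to_string(k + 1));
    }
    if (k + 1 < m) c(k) = up(k) / piv;
    d(k) = (rhs(k) - lo(k) * d(k - 1)) / piv;
  }
  x(m - 1) = d(m - 1);
  for (arma::uword k = m - 1; k-- > 0;) x(k) = d(k) - c(k) * x(k + 1);
  return x;
}

// [[Rcpp::export]]
arma::vec cpp_thomas(const arma::vec& lo, const arma::vec& di,
                     const arma::vec& up, const arma::vec& rhs) {
  return thomas(lo, di, up, rhs);
}

// ---------------------------------------------------------------------------
// Direct Poisson solve for the stream function: lap(psi) = -omega, psi = 0 on
// all walls.  Sine expansion along x2 (constant interior size across the
// production meshes), Thomas solves along x1.
// ---------------------------------------------------------------------------

static const arma::mat& sine_matrix(int n2) {
  static std::map<int, arma::mat> cache;
  auto it = cache.find(n2);
  if (it != cache.end()) return it->second;
  arma::mat S(n2, n2);
  const double pi = arma::datum::pi;
  for (int a = 0; a < n2; ++a)
    for (int b = 0; b < n2; ++b)
      S(a, b) = std::sin((a + 1.0) * (b + 1.0) * pi / (n2 + 1.0));
  return cache.emplace(n2, std::move(S)).first->second;
}

static void poisson_psi(const arma::mat& omega, double dx1, double dx2,
                        arma::mat& psi) {
  const int Nx = omega.n_rows, Ny = omega.n_cols;
  const int m = Nx - 2, n2 = Ny - 2;
  const double pi = arma::datum::pi;
  const arma::mat& S = sine_matrix(n2);

  arma::mat B = -omega.submat(1, 1, Nx - 2, Ny - 2);  // m x n2
  arma::mat Bh = B * S;

  const double offd = 1.0 / (dx1 * dx1);
  arma::vec cwork(m), dwork(m);
  for (int k = 0; k < n2; ++k) {
    const double mu = (2.0 * std::cos((k + 1.0) * pi / (n2 + 1.0)) - 2.0) / (dx2 * dx2);
    const double diag = mu - 2.0 / (dx1 * dx1);
    // specialised constant-coefficient Thomas along x1 (contiguous column)
    double* col = Bh.colptr(k);
    double piv = diag;
    cwork(0) = offd / piv;
    dwork(0) = col[0] / piv;
    for (int i = 1; i < m; ++i) {
      piv = diag - offd * cwork(i - 1);
      cwork(i) = offd / piv;
      dwork(i) = (col[i] - offd * dwork(i - 1)) / piv;
    }
    col[m - 1] = dwork(m - 1);
    for (int i = m - 2; i >= 0; --i) col[i] = dwork(i) - cwork(i) * col[i + 1];
  }

  psi.zeros(Nx, Ny);
  psi.submat(1, 1, Nx - 2, Ny - 2) = (2.0 / (n2 + 1.0)) * (Bh * S);
}

// [[Rcpp::export]]
arma::mat cpp_poisson_psi(const arma::mat& omega, double dx1, double dx2) {
  arma::mat psi;
  poisson_psi(omega, dx1, dx2, psi);
  return psi;
}

// ---------------------------------------------------------------------------
// ADI half-sweep for d f/dt + d(u f)/dx1 + d(veff f)/dx2 = D lap(f) + src
// dir = 0: x1-implicit, dir = 1: x2-implicit.  Each half-sweep advances dt/2.
// Boundary values of f are treated as known (Dirichlet) during the sweep;
// the caller re-applies the physical boundary conditions afterwards.
// ---------------------------------------------------------------------------

static void adi_half(arma::mat& f, const arma::mat& u, const arma::mat& veff,
                     double D, const arma::mat& src, double dt,
                     double dx1, double dx2, int dir) {
  const int Nx = f.n_rows, Ny = f.n_cols;
  const double dth = 0.5 * dt;
  const double ax = dth * D / (dx1 * dx1);
  const double ay = dth * D / (dx2 * dx2);
  const arma::mat f0 = f;  // explicit terms read the frozen half-step state

  if (dir == 0) {
    const int m = Nx - 2;
    arma::vec lo(m), di(m), up(m), rhs(m);
    for (int j = 1; j <= Ny - 2; ++j) {
      for (int i = 1; i <= Nx - 2; ++i) {
        const int k = i - 1;
        lo(k) = -dth * u(i - 1, j) / (2.0 * dx1) - ax;
        di(k) = 1.0 + 2.0 * ax;
        up(k) = dth * u(i + 1, j) / (2.0 * dx1) - ax;
        if (std::abs(lo(k)) + std::abs(up(k)) > di(k) + 1e-12)
          throw std::runtime_error("unstable ADI step: advective term breaks diagonal dominance (reduce dt)");
        const double expl =
            -(veff(i, j + 1) * f0(i, j + 1) - veff(i, j - 1) * f0(i, j - 1)) / (2.0 * dx2) +
            D * (f0(i, j + 1) - 2.0 * f0(i, j) + f0(i, j - 1)) / (dx2 * dx2) + src(i, j);
        rhs(k) = f0(i, j) + dth * expl;
      }
      rhs(0)     -= lo(0) * f(0, j);
      rhs(m - 1) -= up(m - 1) * f(Nx - 1, j);
      arma::vec sol = thomas(lo, di, up, rhs);
      for (int i = 1; i <= Nx - 2; ++i) f(i, j) = sol(i - 1);
    }
  } else {
    const int m = Ny - 2;
    arma::vec lo(m), di(m), up(m), rhs(m);
    for (int i = 1; i <= Nx - 2; ++i) {
      for (int j = 1; j <= Ny - 2; ++j) {
        const int k = j - 1;
        lo(k) = -dth * veff(i, j - 1) / (2.0 * dx2) - ay;
        di(k) = 1.0 + 2.0 * ay;
        up(k) = dth * veff(i, j + 1) / (2.0 * dx2) - ay;
        if (std::abs(lo(k)) + std::abs(up(k)) > di(k) + 1e-12)
          throw std::runtime_error("unstable ADI step: advective term breaks diagonal dominance (reduce dt)");
        const double expl =
            -(u(i + 1, j) * f0(i + 1, j) - u(i - 1, j) * f0(i - 1, j)) / (2.0 * dx1) +
            D * (f0(i + 1, j) - 2.0 * f0(i, j) + f0(i - 1, j)) / (dx1 * dx1) + src(i, j);
        rhs(k) = f0(i, j) + dth * expl;
      }
      rhs(0)     -= lo(0) * f(i, 0);
      rhs(m - 1) -= up(m - 1) * f(i, Ny - 1);
      arma::vec sol = thomas(lo, di, up, rhs);
      for (int j = 1; j <= Ny - 2; ++j) f(i, j) = sol(j - 1);
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_adi_half(const arma::mat& f, const arma::mat& u, const arma::mat& veff,
                       double D, const arma::mat& src, double dt,
                       double dx1, double dx2, int dir) {
  arma::mat out = f;
  adi_half(out, u, veff, D, src, dt, dx1, dx2, dir);
  return out;
}

// ---------------------------------------------------------------------------
// Conservative (finite-volume) ADI half-sweep for the no-net-flux species
// (microorganisms, nanoparticles).  Node-centred cells with half-cells at the
// walls (weights match the trapezoidal quadrature); interface fluxes
//   F = u_half * (f_l + f_r)/2 - D (f_r - f_l)/h - dTm (th_r - th_l)/h
// and the wall-normal flux is the Robin balance itself: zero for a
// conservative closure, or the prescribed leak -leak_coef * f_wall (the
// literal printed microorganism balance with the extra Pen term).  Total
// content sum(w_i w_j f_ij) is conserved to roundoff when the wall fluxes
// vanish.  All nodes (walls included) evolve; no nodal BC is re-applied.
// ---------------------------------------------------------------------------

static void adi_fv_half(arma::mat& f, const arma::mat& u, const arma::mat& veff,
                        double D, const arma::mat& th, double dTm,
                        double leak_coef, double dt,
                        double dx1, double dx2, int dir) {
  const int Nx = f.n_rows, Ny = f.n_cols;
  const double dth = 0.5 * dt;
  const arma::mat f0 = f;  // explicit fluxes read the frozen half-step state

  // y-interface flux between (i,j) and (i,j+1); the theta part rides along
  auto Fy = [&](int i, int j) {
    const double vh = 0.5 * (veff(i, j) + veff(i, j + 1));
    return vh * 0.5 * (f0(i, j) + f0(i, j + 1)) -
           D * (f0(i, j + 1) - f0(i, j)) / dx2 -
           dTm * (th(i, j + 1) - th(i, j)) / dx2;
  };
  auto Fx = [&](int i, int j) {
    const double uh = 0.5 * (u(i, j) + u(i + 1, j));
    return uh * 0.5 * (f0(i, j) + f0(i + 1, j)) -
           D * (f0(i + 1, j) - f0(i, j)) / dx1 -
           dTm * (th(i + 1, j) - th(i, j)) / dx1;
  };

  if (dir == 0) {  // x1-implicit
    arma::vec lo(Nx), di(Nx), up(Nx), rhs(Nx);
    for (int j = 0; j < Ny; ++j) {
      const double wy = (j == 0 || j == Ny - 1) ? 0.5 * dx2 : dx2;
      for (int i = 0; i < Nx; ++i) {
        const double wx = (i == 0 || i == Nx - 1) ? 0.5 * dx1 : dx1;
        // explicit y-direction flux divergence (wall fluxes are the BC)
        double FyU = (j < Ny - 1) ? Fy(i, j) : -leak_coef * f0(i, j);
        double FyL = (j > 0)      ? Fy(i, j - 1) : -leak_coef * f0(i, j);
        const double expl = -(FyU - FyL) / wy;
        // implicit x-direction: assemble band from the two interface fluxes
        double a = 0.0, b = 1.0, c = 0.0, r = f0(i, j) + dth * expl;
        if (i < Nx - 1) {  // interface i+1/2
          const double uh = 0.5 * (u(i, j) + u(i + 1, j));
          b += dth / wx * (0.5 * uh + D / dx1);
          c += dth / wx * (0.5 * uh - D / dx1);
          r += dth / wx * dTm * (th(i + 1, j) - th(i, j)) / dx1;
        }
        if (i > 0) {       // interface i-1/2 (enters with minus sign)
          const double uh = 0.5 * (u(i - 1, j) + u(i, j));
          a -= dth / wx * (0.5 * uh + D / dx1);
          b -= dth / wx * (0.5 * uh - D / dx1);
          r -= dth / wx * dTm * (th(i, j) - th(i - 1, j)) / dx1;
        }
        lo(i) = a; di(i) = b; up(i) = c; rhs(i) = r;
        if (std::abs(a) + std::abs(c) > b + 1e-12)
          throw std::runtime_error("unstable ADI step: advective term breaks diagonal dominance (reduce dt)");
      }
      arma::vec sol = thomas(lo, di, up, rhs);
      for (int i = 0; i < Nx; ++i) f(i, j) = sol(i);
    }
  } else {  // x2-implicit
    arma::vec lo(Ny), di(Ny), up(Ny), rhs(Ny);
    for (int i = 0; i < Nx; ++i) {
      const double wx = (i == 0 || i == Nx - 1) ? 0.5 * dx1 : dx1;
      for (int j = 0; j < Ny; ++j) {
        const double wy = (j == 0 || j == Ny - 1) ? 0.5 * dx2 : dx2;
        double FxU = (i < Nx - 1) ? Fx(i, j) : 0.0;
        double FxL = (i > 0)      ? Fx(i - 1, j) : 0.0;
        const double expl = -(FxU - FxL) / wx;
        double a = 0.0, b = 1.0, c = 0.0, r = f0(i, j) + dth * expl;
        if (j < Ny - 1) {
          const double vh = 0.5 * (veff(i, j) + veff(i, j + 1));
          b += dth / wy * (0.5 * vh + D / dx2);
          c += dth / wy * (0.5 * vh - D / dx2);
          r += dth / wy * dTm * (th(i, j + 1) - th(i, j)) / dx2;
        } else {
          b += dth / wy * (-leak_coef);  // top wall leak flux -leak*f
        }
        if (j > 0) {
          const double vh = 0.5 * (veff(i, j - 1) + veff(i, j));
          a -= dth / wy * (0.5 * vh + D / dx2);
          b -= dth / wy * (0.5 * vh - D / dx2);
          r -= dth / wy * dTm * (th(i, j) - th(i, j - 1)) / dx2;
        } else {
          b -= dth / wy * (-leak_coef);  // bottom wall leak flux
        }
        lo(j) = a; di(j) = b; up(j) = c; rhs(j) = r;
        if (std::abs(a) + std::abs(c) > std::abs(b) + 1e-12)
          throw std::runtime_error("unstable ADI step: advective term breaks diagonal dominance (reduce dt)");
      }
      arma::vec sol = thomas(lo, di, up, rhs);
      for (int j = 0; j < Ny; ++j) f(i, j) = sol(j);
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_adi_fv_half(const arma::mat& f, const arma::mat& u,
                          const arma::mat& veff, double D, const arma::mat& th,
                          double dTm, double leak_coef, double dt,
                          double dx1, double dx2, int dir) {
  arma::mat out = f;
  adi_fv_half(out, u, veff, D, th, dTm, leak_coef, dt, dx1, dx2, dir);
  return out;
}

// ---------------------------------------------------------------------------
// Velocity recovery u = dpsi/dx2, v = -dpsi/dx1 (centred interior,
// second-order one-sided at walls).
// ---------------------------------------------------------------------------

static void velocity(const arma::mat& psi, double dx1, double dx2,
                     arma::mat& u, arma::mat& v) {
  const int Nx = psi.n_rows, Ny = psi.n_cols;
  u.set_size(Nx, Ny);
  v.set_size(Nx, Ny);
  for (int j = 0; j < Ny; ++j) {
    for (int i = 0; i < Nx; ++i) {
      double px2, px1;
      if (j == 0)
        px2 = (-3.0 * psi(i, 0) + 4.0 * psi(i, 1) - psi(i, 2)) / (2.0 * dx2);
      else if (j == Ny - 1)
        px2 = (3.0 * psi(i, j) - 4.0 * psi(i, j - 1) + psi(i, j - 2)) / (2.0 * dx2);
      else
        px2 = (psi(i, j + 1) - psi(i, j - 1)) / (2.0 * dx2);
      if (i == 0)
        px1 = (-3.0 * psi(0, j) + 4.0 * psi(1, j) - psi(2, j)) / (2.0 * dx1);
      else if (i == Nx - 1)
        px1 = (3.0 * psi(i, j) - 4.0 * psi(i - 1, j) + psi(i - 2, j)) / (2.0 * dx1);
      else
        px1 = (psi(i + 1, j) - psi(i - 1, j)) / (2.0 * dx1);
      u(i, j) = px2;
      v(i, j) = -px1;
    }
  }
}

// [[Rcpp::export]]
List cpp_velocity(const arma::mat& psi, double dx1, double dx2) {
  arma::mat u, v;
  velocity(psi, dx1, dx2, u, v);
  return List::create(_["u"] = u, _["v"] = v);
}

// ---------------------------------------------------------------------------
// Boundary conditions
// ---------------------------------------------------------------------------

// Thom first-order wall-vorticity closure.
static void wall_vorticity(const arma::mat& psi, arma::mat& om,
                           double dx1, double dx2) {
  const int Nx = psi.n_rows, Ny = psi.n_cols;
  for (int i = 0; i < Nx; ++i) {
    om(i, 0)      = -2.0 * psi(i, 1)      / (dx2 * dx2);
    om(i, Ny - 1) = -2.0 * psi(i, Ny - 2) / (dx2 * dx2);
  }
  for (int j = 0; j < Ny; ++j) {
    om(0, j)      = -2.0 * psi(1, j)      / (dx1 * dx1);
    om(Nx - 1, j) = -2.0 * psi(Nx - 2, j) / (dx1 * dx1);
  }
}

// [[Rcpp::export]]
arma::mat cpp_apply_wall_vorticity(const arma::mat& psi, const arma::mat& omega,
                                   double dx1, double dx2) {
  arma::mat om = omega;
  wall_vorticity(psi, om, dx1, dx2);
  return om;
}

static void bc_theta(arma::mat& th, const arma::vec& bottom, const arma::vec& top,
                     const arma::vec& left, const arma::vec& right) {
  const int Nx = th.n_rows, Ny = th.n_cols;
  for (int j = 0; j < Ny; ++j) { th(0, j) = left(j); th(Nx - 1, j) = right(j); }
  for (int i = 0; i < Nx; ++i) { th(i, 0) = bottom(i); th(i, Ny - 1) = top(i); }
}

// Homogeneous Neumann on the side walls (second-order one-sided).
static void bc_sides_neumann(arma::mat& f) {
  const int Nx = f.n_rows, Ny = f.n_cols;
  for (int j = 0; j < Ny; ++j) {
    f(0, j)      = (4.0 * f(1, j)      - f(2, j))      / 3.0;
    f(Nx - 1, j) = (4.0 * f(Nx - 2, j) - f(Nx - 3, j)) / 3.0;
  }
}

// Microorganism flux balance Pe_eff*n - dn/dx2 = 0 at x2 = 0, 1.
static void bc_n(arma::mat& nf, double Pe_eff, double dx2) {
  const int Nx = nf.n_rows, Ny = nf.n_cols;
  bc_sides_neumann(nf);
  for (int i = 0; i < Nx; ++i) {
    nf(i, 0) = (4.0 * nf(i, 1) - nf(i, 2)) / (3.0 + 2.0 * dx2 * Pe_eff);
    nf(i, Ny - 1) = (4.0 * nf(i, Ny - 2) - nf(i, Ny - 3)) / (3.0 - 2.0 * dx2 * Pe_eff);
  }
}

// Nanoparticle flux balance dBm*dphi/dx2 + dTm*dtheta/dx2 - Pen*phi = 0 at
// the horizontal walls.  With zero_net_flux the side walls carry the
// matching thermophoretic Robin balance dBm*dphi/dx1 + dTm*dtheta/dx1 = 0
// (total phi conserved); otherwise plain homogeneous Neumann.
static void bc_phi(arma::mat& ph, const arma::mat& th, double dBm, double dTm,
                   double Pen, double dx2, bool zero_net_flux) {
  const int Nx = ph.n_rows, Ny = ph.n_cols;
  if (zero_net_flux) {
    for (int j = 0; j < Ny; ++j) {
      const double tpl = -3.0 * th(0, j) + 4.0 * th(1, j) - th(2, j);
      const double tpr = 3.0 * th(Nx - 1, j) - 4.0 * th(Nx - 2, j) + th(Nx - 3, j);
      ph(0, j) = (dBm * (4.0 * ph(1, j) - ph(2, j)) + dTm * tpl) / (3.0 * dBm);
      ph(Nx - 1, j) = (dBm * (4.0 * ph(Nx - 2, j) - ph(Nx - 3, j)) - dTm * tpr) /
                      (3.0 * dBm);
    }
  } else {
    bc_sides_neumann(ph);
  }
  for (int i = 0; i < Nx; ++i) {
    const double tpb = -3.0 * th(i, 0) + 4.0 * th(i, 1) - th(i, 2);           // 2*dx2 * dtheta/dx2 at bottom
    const double tpt = 3.0 * th(i, Ny - 1) - 4.0 * th(i, Ny - 2) + th(i, Ny - 3);
    ph(i, 0) = (dBm * (4.0 * ph(i, 1) - ph(i, 2)) + dTm * tpb) /
               (3.0 * dBm + 2.0 * dx2 * Pen);
    ph(i, Ny - 1) = (dBm * (4.0 * ph(i, Ny - 2) - ph(i, Ny - 3)) - dTm * tpt) /
                    (3.0 * dBm - 2.0 * dx2 * Pen);
  }
}

// [[Rcpp::export]]
List cpp_apply_flux_bcs(const arma::mat& psi, const arma::mat& n,
                        const arma::mat& theta, const arma::mat& phi,
                        const List& tb, double Pe_eff, double Pen,
                        double dBm, double dTm, double dx2,
                        bool phi_zero_net_flux) {
  arma::mat P = psi, N = n, TH = theta, PH = phi;
  bc_theta(TH, as<arma::vec>(tb["bottom"]), as<arma::vec>(tb["top"]),
           as<arma::vec>(tb["left"]), as<arma::vec>(tb["right"]));
  bc_n(N, Pe_eff, dx2);
  bc_phi(PH, TH, dBm, dTm, Pen, dx2, phi_zero_net_flux);
  const int Nx = P.n_rows, Ny = P.n_cols;
  P.row(0).zeros(); P.row(Nx - 1).zeros();
  P.col(0).zeros(); P.col(Ny - 1).zeros();
  return List::create(_["psi"] = P, _["n"] = N, _["theta"] = TH, _["phi"] = PH);
}

// ---------------------------------------------------------------------------
// Full coupled time step
// ---------------------------------------------------------------------------

struct Par {
  double Ra, RaT, Ran, Sc, Le, Pe, Pen, dBm, dTm, rrho;
  bool pen_in_nbc, phi_drift;
};

static Par par_from_list(const List& p) {
  Par P;
  P.Ra  = p["Ra"];   P.RaT = p["RaT"]; P.Ran = p["Ran"];
  P.Sc  = p["Sc"];   P.Le  = p["Le"];  P.Pe  = p["Pe"];  P.Pen = p["Pen"];
  P.dBm = p["delta_Bm"]; P.dTm = p["delta_Tm"]; P.rrho = p["r_rho"];
  P.pen_in_nbc = as<bool>(p["micro_bc_includes_pen"]);
  P.phi_drift = as<bool>(p["phi_zero_net_flux"]);
  return P;
}

struct Work {
  arma::mat u, v, veff, src, zsrc;
  void init(int Nx, int Ny) {
    u.set_size(Nx, Ny); v.set_size(Nx, Ny); veff.set_size(Nx, Ny);
    src.zeros(Nx, Ny); zsrc.zeros(Nx, Ny);
  }
};

static void step_core(arma::mat& psi, arma::mat& om, arma::mat& n,
                      arma::mat& th, arma::mat& ph, const Par& P,
                      const arma::vec& tbb, const arma::vec& tbt,
                      const arma::vec& tbl, const arma::vec& tbr,
                      double dt, double dx1, double dx2, Work& W) {
  const int Nx = psi.n_rows, Ny = psi.n_cols;

  // (1) velocities at the current stream function
  velocity(psi, dx1, dx2, W.u, W.v);

  // (2) vorticity with buoyancy forcing from same-level scalars
  for (int j = 1; j <= Ny - 2; ++j)
    for (int i = 1; i <= Nx - 2; ++i)
      W.src(i, j) =
          (-P.Sc * P.Ra  * (n(i + 1, j)  - n(i - 1, j)) +
            P.Le * P.Sc * P.RaT * (th(i + 1, j) - th(i - 1, j)) -
            P.Le * P.Sc * P.Ran * (ph(i + 1, j) - ph(i - 1, j))) / (2.0 * dx1);
  adi_half(om, W.u, W.v, P.Sc, W.src, dt, dx1, dx2, 0);
  adi_half(om, W.u, W.v, P.Sc, W.src, dt, dx1, dx2, 1);

  // (3) stream function, (4) wall vorticity closure
  poisson_psi(om, dx1, dx2, psi);
  wall_vorticity(psi, om, dx1, dx2);

  // (5) microorganisms, advected with updated velocities plus upward
  // swimming, in conservative flux form: the wall flux IS the Robin balance
  // (zero by default; the literal printed form leaks -Pen*n at the walls)
  velocity(psi, dx1, dx2, W.u, W.v);
  W.veff = W.v + P.Pe;
  const double leak_n = P.pen_in_nbc ? P.Pen : 0.0;
  adi_fv_half(n, W.u, W.veff, 1.0, th, 0.0, leak_n, dt, dx1, dx2, 0);
  adi_fv_half(n, W.u, W.veff, 1.0, th, 0.0, leak_n, dt, dx1, dx2, 1);

  // (6) temperature with explicit Brownian/thermophoretic coupling terms
  for (int j = 1; j <= Ny - 2; ++j)
    for (int i = 1; i <= Nx - 2; ++i) {
      const double tx1 = (th(i + 1, j) - th(i - 1, j)) / (2.0 * dx1);
      const double tx2 = (th(i, j + 1) - th(i, j - 1)) / (2.0 * dx2);
      const double px1 = (ph(i + 1, j) - ph(i - 1, j)) / (2.0 * dx1);
      const double px2 = (ph(i, j + 1) - ph(i, j - 1)) / (2.0 * dx2);
      W.src(i, j) = P.rrho * P.dBm * (px1 * tx1 + px2 * tx2) +
                    P.rrho * P.dTm * (tx1 * tx1 + tx2 * tx2);
    }
  adi_half(th, W.u, W.v, P.Le, W.src, dt, dx1, dx2, 0);
  bc_theta(th, tbb, tbt, tbl, tbr);
  adi_half(th, W.u, W.v, P.Le, W.src, dt, dx1, dx2, 1);
  bc_theta(th, tbb, tbt, tbl, tbr);

  // (7) nanoparticles.  Conservative closure (default): vertical Pen drift,
  // thermophoretic transport dTm*grad(theta) folded into the interface
  // fluxes, wall fluxes zero -- the Robin balance in flux form; total phi is
  // conserved to roundoff.  Literal closure: node-centred advection without
  // drift, explicit dTm*lap(theta) source, nodal Robin walls (drains mass).
  if (P.phi_drift) {
    W.veff = W.v + P.Pen;
    adi_fv_half(ph, W.u, W.veff, P.dBm, th, P.dTm, 0.0, dt, dx1, dx2, 0);
    adi_fv_half(ph, W.u, W.veff, P.dBm, th, P.dTm, 0.0, dt, dx1, dx2, 1);
  } else {
    for (int j = 1; j <= Ny - 2; ++j)
      for (int i = 1; i <= Nx - 2; ++i)
        W.src(i, j) = P.dTm *
            ((th(i + 1, j) - 2.0 * th(i, j) + th(i - 1, j)) / (dx1 * dx1) +
             (th(i, j + 1) - 2.0 * th(i, j) + th(i, j - 1)) / (dx2 * dx2));
    adi_half(ph, W.u, W.v, P.dBm, W.src, dt, dx1, dx2, 0);
    bc_phi(ph, th, P.dBm, P.dTm, P.Pen, dx2, false);
    adi_half(ph, W.u, W.v, P.dBm, W.src, dt, dx1, dx2, 1);
    bc_phi(ph, th, P.dBm, P.dTm, P.Pen, dx2, false);
  }
}

static const char* first_nonfinite(const arma::mat& psi, const arma::mat& om,
                                   const arma::mat& n, const arma::mat& th,
                                   const arma::mat& ph) {
  if (!om.is_finite())  return "omega";
  if (!psi.is_finite()) return "psi";
  if (!n.is_finite())   return "n";
  if (!th.is_finite())  return "theta";
  if (!ph.is_finite())  return "phi";
  return nullptr;
}

// [[Rcpp::export]]
List cpp_time_step(const List& state, const List& par, const List& tb,
                   double dt, double dx1, double dx2) {
  arma::mat psi = as<arma::mat>(state["psi"]), om = as<arma::mat>(state["omega"]);
  arma::mat n = as<arma::mat>(state["n"]), th = as<arma::mat>(state["theta"]);
  arma::mat ph = as<arma::mat>(state["phi"]);
  const Par P = par_from_list(par);
  Work W; W.init(psi.n_rows, psi.n_cols);
  arma::vec tbb = as<arma::vec>(tb["bottom"]), tbt = as<arma::vec>(tb["top"]);
  arma::vec tbl = as<arma::vec>(tb["left"]),   tbr = as<arma::vec>(tb["right"]);
  step_core(psi, om, n, th, ph, P, tbb, tbt, tbl, tbr, dt, dx1, dx2, W);
  const char* bad = first_nonfinite(psi, om, n, th, ph);
  if (bad) stop(std::string("numerical divergence: non-finite values in field '") + bad + "'");
  return List::create(_["psi"] = psi, _["omega"] = om, _["n"] = n,
                      _["theta"] = th, _["phi"] = ph,
                      _["t"] = as<double>(state["t"]) + dt);
}

// [[Rcpp::export]]
List cpp_run(const List& state, const List& par, const List& tb,
             double dt, double dx1, double dx2,
             double epsilon, int max_iters) {
  arma::mat psi = as<arma::mat>(state["psi"]), om = as<arma::mat>(state["omega"]);
  arma::mat n = as<arma::mat>(state["n"]), th = as<arma::mat>(state["theta"]);
  arma::mat ph = as<arma::mat>(state["phi"]);
  double t = as<double>(state["t"]);
  const Par P = par_from_list(par);
  Work W; W.init(psi.n_rows, psi.n_cols);
  arma::vec tbb = as<arma::vec>(tb["bottom"]), tbt = as<arma::vec>(tb["top"]);
  arma::vec tbl = as<arma::vec>(tb["left"]),   tbr = as<arma::vec>(tb["right"]);

  arma::mat p0, o0, n0, t0, f0;
  NumericVector hist(max_iters);
  bool converged = false, diverged = false;
  std::string dreason;
  int it = 0;

  for (; it < max_iters; ++it) {
    p0 = psi; o0 = om; n0 = n; t0 = th; f0 = ph;
    try {
      step_core(psi, om, n, th, ph, P, tbb, tbt, tbl, tbr, dt, dx1, dx2, W);
    } catch (const std::runtime_error& e) {
      diverged = true; dreason = e.what();
      psi = p0; om = o0; n = n0; th = t0; ph = f0;
      break;
    }
    const char* bad = first_nonfinite(psi, om, n, th, ph);
    if (bad) {
      diverged = true;
      dreason = std::string("non-finite values in field '") + bad + "'";
      break;
    }
    t += dt;
    double res = arma::abs(psi - p0).max();
    res = std::max(res, arma::abs(om - o0).max());
    res = std::max(res, arma::abs(n - n0).max());
    res = std::max(res, arma::abs(th - t0).max());
    res = std::max(res, arma::abs(ph - f0).max());
    hist[it] = res;
    if (res <= epsilon) { converged = true; ++it; break; }
    if ((it & 0x1FF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector hist_out(hist.begin(), hist.begin() + it);
  return List::create(
      _["psi"] = psi, _["omega"] = om, _["n"] = n, _["theta"] = th,
      _["phi"] = ph, _["t"] = t,
      _["converged"] = converged, _["iterations"] = it,
      _["residual_history"] = hist_out,
      _["diverged"] = diverged, _["divergence_reason"] = dreason);
}
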