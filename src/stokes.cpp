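#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Steady Stokes flow on a voxelized duct, staggered (MAC) grid.
//
// Domain: nx * ny * nz cells, flow along +z. Cell labels: 1 fluid, 0 solid.
// Lateral domain boundaries (x, y) are no-slip walls (cartridge housing).
// Inlet (z = 0 plane): uniform Dirichlet normal velocity U over fluid cells,
// zero tangential velocity. Outlet (z = nz plane): do-nothing outflow with
// gauge pressure pinned to 0 in the outlet ghost layer.
//
// Unknowns: u on x-faces, v on y-faces, w on z-faces, scaled pressure
// q = p*h/mu on cells. Momentum rows are scaled by h^2/mu so all matrix
// entries are O(1); the system
//   [ A  -D^T ] [u]   [b_u]
//   [ -D   0  ] [q] = [b_q]
// is symmetric indefinite and solved with preconditioned MINRES
// (Jacobi on the velocity block). No-slip at solid walls uses the halfway
// (ghost-reflection) convention for tangential components.

struct StokesOps {
  int nx, ny, nz;
  R_xlen_t Nu, Nv, Nw, Nq, N;
  const int* fl;  // fluid mask, nx*ny*nz
  std::vector<uint8_t> au, av, aw;   // active flags per face
  std::vector<double> diag;          // diagonal of the full system (q rows: precond value)
  std::vector<double> b;             // rhs
  double U;                          // inlet velocity

  R_xlen_t iu(int i, int j, int k) const { return i + (R_xlen_t)(nx + 1) * (j + (R_xlen_t)ny * k); }
  R_xlen_t iv(int i, int j, int k) const { return i + (R_xlen_t)nx * (j + (R_xlen_t)(ny + 1) * k); }
  R_xlen_t iw(int i, int j, int k) const { return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k); }
  R_xlen_t ic(int i, int j, int k) const { return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k); }
  bool fluid(int i, int j, int k) const {
    if (k == nz) return true;  // outlet ghost layer is open
    return fl[ic(i, j, k)] != 0;
  }

  void setup(double Uin) {
    U = Uin;
    Nu = (R_xlen_t)(nx + 1) * ny * nz;
    Nv = (R_xlen_t)nx * (ny + 1) * nz;
    Nw = (R_xlen_t)nx * ny * (nz + 1);
    Nq = (R_xlen_t)nx * ny * nz;
    N = Nu + Nv + Nw + Nq;
    au.assign(Nu, 0); av.assign(Nv, 0); aw.assign(Nw, 0);
    diag.assign(N, 1.0);
    b.assign(N, 0.0);

    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 1; i < nx; ++i)
          if (fluid(i - 1, j, k) && fluid(i, j, k)) au[iu(i, j, k)] = 1;
    for (int k = 0; k < nz; ++k)
      for (int j = 1; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          if (fluid(i, j - 1, k) && fluid(i, j, k)) av[iv(i, j, k)] = 1;
    for (int k = 1; k <= nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i)
          if (fluid(i, j, k - 1) && fluid(i, j, k)) aw[iw(i, j, k)] = 1;

    // diagonals + rhs
    // tangential neighbour classification: returns diag contribution
    auto tang = [&](bool inb, bool c1, bool c2) -> double {
      if (!inb) return 2.0;                 // beyond domain wall: reflection
      if (c1 && c2) return 1.0;             // active neighbour
      if (!c1 && !c2) return 2.0;           // pure wall halfway: reflection
      return 1.0;                           // stair-step mixed: Dirichlet 0 at face
    };

    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 1; i < nx; ++i) {
          R_xlen_t f = iu(i, j, k);
          if (!au[f]) continue;
          double d = 2.0;  // normal (x) neighbours always Dirichlet-or-active: +1 each
          d += tang(j - 1 >= 0, j - 1 >= 0 && fluid(i - 1, j - 1, k), j - 1 >= 0 && fluid(i, j - 1, k));
          d += tang(j + 1 < ny, j + 1 < ny && fluid(i - 1, j + 1, k), j + 1 < ny && fluid(i, j + 1, k));
          // z tangential: below inlet -> reflection (plug inlet, zero tangential)
          if (k - 1 >= 0) d += tang(true, fluid(i - 1, j, k - 1), fluid(i, j, k - 1));
          else d += 2.0;
          // beyond outlet -> zero-gradient (contributes 0)
          if (k + 1 < nz) d += tang(true, fluid(i - 1, j, k + 1), fluid(i, j, k + 1));
          diag[f] = d;
        }

    for (int k = 0; k < nz; ++k)
      for (int j = 1; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t f = iv(i, j, k);
          if (!av[f]) continue;
          double d = 2.0;
          d += tang(i - 1 >= 0, i - 1 >= 0 && fluid(i - 1, j - 1, k), i - 1 >= 0 && fluid(i - 1, j, k));
          d += tang(i + 1 < nx, i + 1 < nx && fluid(i + 1, j - 1, k), i + 1 < nx && fluid(i + 1, j, k));
          if (k - 1 >= 0) d += tang(true, fluid(i, j - 1, k - 1), fluid(i, j, k - 1));
          else d += 2.0;
          if (k + 1 < nz) d += tang(true, fluid(i, j - 1, k + 1), fluid(i, j, k + 1));
          diag[Nu + f] = d;
        }

    for (int k = 1; k <= nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t f = iw(i, j, k);
          if (!aw[f]) continue;
          double d = 0.0;
          d += 1.0;                        // z-normal below (active, wall or inlet Dirichlet)
          if (k + 1 <= nz) d += 1.0;       // z-normal above; k == nz: beyond outlet, 0
          d += tang(i - 1 >= 0, i - 1 >= 0 && fluid(i - 1, j, k - 1), i - 1 >= 0 && fluid(i - 1, j, k));
          d += tang(i + 1 < nx, i + 1 < nx && fluid(i + 1, j, k - 1), i + 1 < nx && fluid(i + 1, j, k));
          d += tang(j - 1 >= 0, j - 1 >= 0 && fluid(i, j - 1, k - 1), j - 1 >= 0 && fluid(i, j - 1, k));
          d += tang(j + 1 < ny, j + 1 < ny && fluid(i, j + 1, k - 1), j + 1 < ny && fluid(i, j + 1, k));
          diag[Nu + Nv + f] = d;
          if (k == 1 && fl[ic(i, j, 0)]) b[Nu + Nv + f] = U;  // inlet Dirichlet neighbour
        }

    // continuity rows (scaled by -1): rhs -U in inlet-adjacent fluid cells
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (fl[ic(i, j, 0)]) b[Nu + Nv + Nw + ic(i, j, 0)] = -U;
  }

  // y = K x
  void apply(const double* x, double* y) const {
    const double* xu = x;
    const double* xv = x + Nu;
    const double* xw = x + Nu + Nv;
    const double* xq = x + Nu + Nv + Nw;
    double* yu = y;
    double* yv = y + Nu;
    double* yw = y + Nu + Nv;
    double* yq = y + Nu + Nv + Nw;

    // u momentum
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i <= nx; ++i) {
          R_xlen_t f = iu(i, j, k);
          if (!au[f]) { yu[f] = 0.0; continue; }
          double s = diag[f] * xu[f];
          if (au[iu(i - 1, j, k)]) s -= xu[iu(i - 1, j, k)];
          if (au[iu(i + 1, j, k)]) s -= xu[iu(i + 1, j, k)];
          if (j - 1 >= 0 && au[iu(i, j - 1, k)]) s -= xu[iu(i, j - 1, k)];
          if (j + 1 < ny && au[iu(i, j + 1, k)]) s -= xu[iu(i, j + 1, k)];
          if (k - 1 >= 0 && au[iu(i, j, k - 1)]) s -= xu[iu(i, j, k - 1)];
          if (k + 1 < nz && au[iu(i, j, k + 1)]) s -= xu[iu(i, j, k + 1)];
          s += xq[ic(i, j, k)] - xq[ic(i - 1, j, k)];
          yu[f] = s;
        }

    // v momentum
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j <= ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t f = iv(i, j, k);
          if (!av[f]) { yv[f] = 0.0; continue; }
          double s = diag[Nu + f] * xv[f];
          if (av[iv(i, j - 1, k)]) s -= xv[iv(i, j - 1, k)];
          if (av[iv(i, j + 1, k)]) s -= xv[iv(i, j + 1, k)];
          if (i - 1 >= 0 && av[iv(i - 1, j, k)]) s -= xv[iv(i - 1, j, k)];
          if (i + 1 < nx && av[iv(i + 1, j, k)]) s -= xv[iv(i + 1, j, k)];
          if (k - 1 >= 0 && av[iv(i, j, k - 1)]) s -= xv[iv(i, j, k - 1)];
          if (k + 1 < nz && av[iv(i, j, k + 1)]) s -= xv[iv(i, j, k + 1)];
          s += xq[ic(i, j, k)] - xq[ic(i, j - 1, k)];
          yv[f] = s;
        }

    // w momentum
    for (int k = 0; k <= nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t f = iw(i, j, k);
          if (!aw[f] || k == 0) { yw[f] = 0.0; continue; }
          double s = diag[Nu + Nv + f] * xw[f];
          if (k - 1 >= 1 && aw[iw(i, j, k - 1)]) s -= xw[iw(i, j, k - 1)];
          if (k + 1 <= nz && aw[iw(i, j, k + 1)]) s -= xw[iw(i, j, k + 1)];
          if (i - 1 >= 0 && aw[iw(i - 1, j, k)]) s -= xw[iw(i - 1, j, k)];
          if (i + 1 < nx && aw[iw(i + 1, j, k)]) s -= xw[iw(i + 1, j, k)];
          if (j - 1 >= 0 && aw[iw(i, j - 1, k)]) s -= xw[iw(i, j - 1, k)];
          if (j + 1 < ny && aw[iw(i, j + 1, k)]) s -= xw[iw(i, j + 1, k)];
          double qlo = xq[ic(i, j, k - 1)];
          double qhi = (k < nz) ? xq[ic(i, j, k)] : 0.0;  // outlet ghost p = 0
          s += qhi - qlo;
          yw[f] = s;
        }

    // continuity (times -1)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t c = ic(i, j, k);
          if (!fl[c]) { yq[c] = 0.0; continue; }
          double div = 0.0;
          if (au[iu(i + 1, j, k)]) div += xu[iu(i + 1, j, k)];
          if (au[iu(i, j, k)]) div -= xu[iu(i, j, k)];
          if (av[iv(i, j + 1, k)]) div += xv[iv(i, j + 1, k)];
          if (av[iv(i, j, k)]) div -= xv[iv(i, j, k)];
          if (aw[iw(i, j, k + 1)]) div += xw[iw(i, j, k + 1)];
          if (k > 0 && aw[iw(i, j, k)]) div -= xw[iw(i, j, k)];
          yq[c] = -div;
        }
  }

  // z = M^-1 r (Jacobi on velocity block, identity on pressure block)
  void msolve(const double* r, double* z) const {
    for (R_xlen_t f = 0; f < Nu; ++f) z[f] = au[f] ? r[f] / diag[f] : 0.0;
    for (R_xlen_t f = 0; f < Nv; ++f) z[Nu + f] = av[f] ? r[Nu + f] / diag[Nu + f] : 0.0;
    for (R_xlen_t f = 0; f < Nw; ++f)
      z[Nu + Nv + f] = aw[f] ? r[Nu + Nv + f] / diag[Nu + Nv + f] : 0.0;
    const double* rq = r + Nu + Nv + Nw;
    double* zq = z + Nu + Nv + Nw;
    for (R_xlen_t c = 0; c < Nq; ++c) zq[c] = fl[c] ? rq[c] : 0.0;
  }
};

static double vdot(const std::vector<double>& a, const std::vector<double>& b) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}

// [[Rcpp::export]]
List cpp_solve_stokes(IntegerVector fluid, IntegerVector dims, double h,
                      double Q, double mu, double tol, int maxiter,
                      int record_every) {
  StokesOps op;
  op.nx = dims[0]; op.ny = dims[1]; op.nz = dims[2];
  op.fl = INTEGER(fluid);

  // inlet velocity from flow rate over inlet-face fluid cells
  R_xlen_t n_in = 0;
  for (int j = 0; j < op.ny; ++j)
    for (int i = 0; i < op.nx; ++i)
      if (op.fl[op.ic(i, j, 0)]) ++n_in;
  if (n_in == 0) stop("no fluid cells on the inlet face");
  double U = Q / (h * h * (double)n_in);

  op.setup(U);
  R_xlen_t N = op.N;

  std::vector<double> x(N, 0.0), r1(N), r2(N), y(N), v(N), wv(N, 0.0),
      w1(N, 0.0), w2(N, 0.0);
  std::vector<double> resid_hist;

  // MINRES (Paige & Saunders), preconditioned
  for (R_xlen_t i = 0; i < N; ++i) r1[i] = op.b[i];
  op.msolve(r1.data(), y.data());
  double beta1 = vdot(r1, y);
  int converged = 0;
  int iters = 0;
  double rnorm = 0.0;

  if (beta1 > 0.0) {
    beta1 = std::sqrt(beta1);
    double oldb = 0.0, beta = beta1, dbar = 0.0, epsln = 0.0;
    double phibar = beta1, rhs1 = beta1;
    double cs = -1.0, sn = 0.0, oldeps = 0.0;
    (void)rhs1;
    r2 = r1;
    rnorm = phibar;

    for (int it = 1; it <= maxiter; ++it) {
      iters = it;
      double s = 1.0 / beta;
      for (R_xlen_t i = 0; i < N; ++i) v[i] = s * y[i];
      op.apply(v.data(), y.data());
      if (it >= 2) {
        double c0 = beta / oldb;
        for (R_xlen_t i = 0; i < N; ++i) y[i] -= c0 * r1[i];
      }
      double alfa = vdot(v, y);
      double c1 = alfa / beta;
      for (R_xlen_t i = 0; i < N; ++i) y[i] -= c1 * r2[i];
      r1 = r2;
      r2 = y;
      op.msolve(r2.data(), y.data());
      oldb = beta;
      beta = vdot(r2, y);
      if (beta < 0.0) stop("preconditioner lost positive definiteness");
      beta = std::sqrt(beta);

      oldeps = epsln;
      double delta = cs * dbar + sn * alfa;
      double gbar = sn * dbar - cs * alfa;
      epsln = sn * beta;
      dbar = -cs * beta;
      double gamma = std::sqrt(gbar * gbar + beta * beta);
      if (gamma < 1e-300) gamma = 1e-300;
      cs = gbar / gamma;
      sn = beta / gamma;
      double phi = cs * phibar;
      phibar = sn * phibar;

      double denom = 1.0 / gamma;
      w1 = w2;
      w2 = wv;
      for (R_xlen_t i = 0; i < N; ++i)
        wv[i] = (v[i] - oldeps * w1[i] - delta * w2[i]) * denom;
      for (R_xlen_t i = 0; i < N; ++i) x[i] += phi * wv[i];

      rnorm = phibar;
      if (it % record_every == 0 || rnorm / beta1 < tol)
        resid_hist.push_back(rnorm / beta1);
      if (rnorm / beta1 < tol) { converged = 1; break; }
    }
  } else {
    converged = 1;  // zero rhs -> zero solution
    beta1 = 1.0;
  }

  // unpack
  NumericVector U_ = NumericVector(op.Nu), V_ = NumericVector(op.Nv),
               W_ = NumericVector(op.Nw), P_ = NumericVector(op.Nq);
  for (R_xlen_t i = 0; i < op.Nu; ++i) U_[i] = x[i];
  for (R_xlen_t i = 0; i < op.Nv; ++i) V_[i] = x[op.Nu + i];
  for (R_xlen_t i = 0; i < op.Nw; ++i) W_[i] = x[op.Nu + op.Nv + i];
  for (int j = 0; j < op.ny; ++j)          // inlet Dirichlet faces
    for (int i = 0; i < op.nx; ++i)
      if (op.fl[op.ic(i, j, 0)]) W_[op.iw(i, j, 0)] = U;
  for (R_xlen_t i = 0; i < op.Nq; ++i)
    P_[i] = x[op.Nu + op.Nv + op.Nw + i] * mu / h;  // physical pressure, Pa
  U_.attr("dim") = IntegerVector::create(op.nx + 1, op.ny, op.nz);
  V_.attr("dim") = IntegerVector::create(op.nx, op.ny + 1, op.nz);
  W_.attr("dim") = IntegerVector::create(op.nx, op.ny, op.nz + 1);
  P_.attr("dim") = IntegerVector::create(op.nx, op.ny, op.nz);

  return List::create(
      _["u"] = U_, _["v"] = V_, _["w"] = W_, _["p"] = P_,
      _["inlet_velocity"] = U, _["iterations"] = iters,
      _["converged"] = converged, _["rel_residual"] = rnorm / beta1,
      _["residual_history"] = NumericVector(resid_hist.begin(), resid_hist.end()));
}
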