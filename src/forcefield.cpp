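// Surrogate classical potential: harmonic bonds and angles, cosine
// torsions, 12-6 van der Waals and Coulomb terms over fixed partial
// charges.  Energies in kcal/mol, lengths in Angstrom.  Parameters are
// assembled on the R side (ff_params()); this file only evaluates the
// potential, its analytic gradient, and runs a deterministic L-BFGS
// minimiser on it.
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct FF {
  arma::imat bond_ij;   arma::vec bond_k, bond_r0;
  arma::imat ang_ijk;   arma::vec ang_k, ang_th0;
  arma::imat tor_ijkl;  arma::vec tor_k; arma::ivec tor_n; arma::vec tor_d;
  arma::imat nb_ij;     arma::vec nb_eps, nb_sig, nb_qq;
};

FF unpack(const List& par) {
  FF f;
  f.bond_ij  = as<arma::imat>(par["bond_ij"]);
  f.bond_k   = as<arma::vec>(par["bond_k"]);
  f.bond_r0  = as<arma::vec>(par["bond_r0"]);
  f.ang_ijk  = as<arma::imat>(par["ang_ijk"]);
  f.ang_k    = as<arma::vec>(par["ang_k"]);
  f.ang_th0  = as<arma::vec>(par["ang_th0"]);
  f.tor_ijkl = as<arma::imat>(par["tor_ijkl"]);
  f.tor_k    = as<arma::vec>(par["tor_k"]);
  f.tor_n    = as<arma::ivec>(par["tor_n"]);
  f.tor_d    = as<arma::vec>(par["tor_d"]);
  f.nb_ij    = as<arma::imat>(par["nb_ij"]);
  f.nb_eps   = as<arma::vec>(par["nb_eps"]);
  f.nb_sig   = as<arma::vec>(par["nb_sig"]);
  f.nb_qq    = as<arma::vec>(par["nb_qq"]);
  return f;
}

// energy + gradient; X is N x 3
double eval_ff(const FF& f, const arma::mat& X, arma::mat& G) {
  const double COUL = 332.0637;  // e^2 / (4 pi eps0 Angstrom) in kcal/mol
  double E = 0.0;
  G.zeros(X.n_rows, 3);

  // bonds: k (r - r0)^2
  for (arma::uword b = 0; b < f.bond_k.n_elem; ++b) {
    int i = f.bond_ij(b, 0), j = f.bond_ij(b, 1);
    arma::rowvec d = X.row(i) - X.row(j);
    double r = arma::norm(d);
    double dr = r - f.bond_r0(b);
    E += f.bond_k(b) * dr * dr;
    arma::rowvec g = 2.0 * f.bond_k(b) * dr * d / r;
    G.row(i) += g; G.row(j) -= g;
  }

  // angles: k (theta - theta0)^2 at central atom j
  for (arma::uword a = 0; a < f.ang_k.n_elem; ++a) {
    int i = f.ang_ijk(a, 0), j = f.ang_ijk(a, 1), k = f.ang_ijk(a, 2);
    arma::rowvec u = X.row(i) - X.row(j);
    arma::rowvec v = X.row(k) - X.row(j);
    double nu = arma::norm(u), nv = arma::norm(v);
    double c = arma::dot(u, v) / (nu * nv);
    c = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, c));
    double th = std::acos(c);
    double dth = th - f.ang_th0(a);
    E += f.ang_k(a) * dth * dth;
    double s = std::sqrt(1.0 - c * c);
    double pref = -2.0 * f.ang_k(a) * dth / s;  // dE/dcos
    arma::rowvec gi = pref * (v / (nu * nv) - c * u / (nu * nu));
    arma::rowvec gk = pref * (u / (nu * nv) - c * v / (nv * nv));
    G.row(i) += gi; G.row(k) += gk; G.row(j) -= gi + gk;
  }

  // torsions: k (1 + cos(n phi - delta))
  for (arma::uword t = 0; t < f.tor_k.n_elem; ++t) {
    int i = f.tor_ijkl(t, 0), j = f.tor_ijkl(t, 1),
        k = f.tor_ijkl(t, 2), l = f.tor_ijkl(t, 3);
    arma::rowvec rij = X.row(i) - X.row(j);
    arma::rowvec rkj = X.row(k) - X.row(j);
    arma::rowvec rkl = X.row(k) - X.row(l);
    arma::rowvec m = arma::cross(rij, rkj);
    arma::rowvec n = arma::cross(rkj, rkl);
    double nm = arma::norm(m), nn = arma::norm(n), nrkj = arma::norm(rkj);
    if (nm < 1e-9 || nn < 1e-9) continue;  // collinear, torsion undefined
    double phi = std::atan2(arma::dot(arma::cross(m, n), rkj) / nrkj,
                            arma::dot(m, n));
    double nn_d = (double)f.tor_n(t);
    E += f.tor_k(t) * (1.0 + std::cos(nn_d * phi - f.tor_d(t)));
    double dV = -f.tor_k(t) * nn_d * std::sin(nn_d * phi - f.tor_d(t));
    // forces (negative gradients), standard rigid-rotor decomposition
    arma::rowvec Fi = -(dV * nrkj / (nm * nm)) * m;
    arma::rowvec Fl =  (dV * nrkj / (nn * nn)) * n;
    double p = arma::dot(rij, rkj) / (nrkj * nrkj);
    double q = arma::dot(rkl, rkj) / (nrkj * nrkj);
    arma::rowvec sv = p * Fi - q * Fl;
    G.row(i) -= Fi;
    G.row(j) -= -Fi + sv;
    G.row(k) -= -Fl - sv;
    G.row(l) -= Fl;
  }

  // nonbonded: 4 eps [ (sig/r)^12 - (sig/r)^6 ] + COUL qq / r
  for (arma::uword p = 0; p < f.nb_eps.n_elem; ++p) {
    int i = f.nb_ij(p, 0), j = f.nb_ij(p, 1);
    arma::rowvec d = X.row(i) - X.row(j);
    double r2 = arma::dot(d, d);
    double r = std::sqrt(r2);
    if (r < 0.05) r = 0.05;  // guard against overlapped input atoms
    double sr2 = f.nb_sig(p) * f.nb_sig(p) / (r * r);
    double sr6 = sr2 * sr2 * sr2;
    double elj = 4.0 * f.nb_eps(p) * (sr6 * sr6 - sr6);
    double ec = COUL * f.nb_qq(p) / r;
    E += elj + ec;
    double dEdr = (-4.0 * f.nb_eps(p) * (12.0 * sr6 * sr6 - 6.0 * sr6) - ec) / r;
    arma::rowvec g = dEdr * d / r;
    G.row(i) += g; G.row(j) -= g;
  }
  return E;
}

}  // namespace

// [[Rcpp::export(name = ".ff_energy_gradient")]]
List ff_energy_gradient_cpp(const arma::mat& coords, const List& params) {
  FF f = unpack(params);
  arma::mat G;
  double E = eval_ff(f, coords, G);
  return List::create(_["energy"] = E, _["gradient"] = G);
}

// Deterministic L-BFGS (history m = 8) with Armijo backtracking.
// [[Rcpp::export(name = ".ff_minimize")]]
List ff_minimize_cpp(const arma::mat& coords, const List& params,
                     int max_steps, double grad_tol) {
  FF f = unpack(params);
  const int m = 8;
  arma::mat X = coords, G, Gnew;
  double E = eval_ff(f, X, G);

  std::vector<arma::vec> S, Y;
  std::vector<double> rho;
  int steps = 0;
  bool converged = arma::abs(G).max() <= grad_tol;

  while (!converged && steps < max_steps) {
    arma::vec g = arma::vectorise(G.t());
    // two-loop recursion
    arma::vec q = g;
    int h = (int)S.size();
    std::vector<double> alpha(h);
    for (int idx = h - 1; idx >= 0; --idx) {
      alpha[idx] = rho[idx] * arma::dot(S[idx], q);
      q -= alpha[idx] * Y[idx];
    }
    double gamma = 1.0;
    if (h > 0) gamma = arma::dot(S[h - 1], Y[h - 1]) / arma::dot(Y[h - 1], Y[h - 1]);
    q *= gamma;
    for (int idx = 0; idx < h; ++idx) {
      double beta = rho[idx] * arma::dot(Y[idx], q);
      q += (alpha[idx] - beta) * S[idx];
    }
    arma::vec dir = -q;
    double gd = arma::dot(g, dir);
    if (gd > -1e-14) { dir = -g; gd = arma::dot(g, dir); S.clear(); Y.clear(); rho.clear(); }

    // Armijo backtracking, cap step length at 0.5 A per atom coordinate
    double step = 1.0;
    double dmax = arma::abs(dir).max();
    if (dmax * step > 0.5) step = 0.5 / dmax;
    double Enew = E; bool ok = false;
    arma::mat Xnew;
    for (int bt = 0; bt < 40; ++bt) {
      Xnew = X;
      arma::vec xv = arma::vectorise(X.t()) + step * dir;
      Xnew = arma::reshape(xv, 3, X.n_rows).t();
      Enew = eval_ff(f, Xnew, Gnew);
      if (std::isfinite(Enew) && Enew <= E + 1e-4 * step * gd) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) break;  // line search failed; report current point

    arma::vec s = step * dir;
    arma::vec y = arma::vectorise(Gnew.t()) - g;
    double sy = arma::dot(s, y);
    if (sy > 1e-10) {
      S.push_back(s); Y.push_back(y); rho.push_back(1.0 / sy);
      if ((int)S.size() > m) { S.erase(S.begin()); Y.erase(Y.begin()); rho.erase(rho.begin()); }
    }
    X = Xnew; E = Enew; G = Gnew;
    ++steps;
    converged = arma::abs(G).max() <= grad_tol;
  }

  return List::create(_["coords"] = X, _["energy"] = E,
                      _["grad_max"] = arma::abs(G).max(),
                      _["steps"] = steps, _["converged"] = converged);
}
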