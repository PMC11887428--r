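// Collision cross section engines.
//
// Projection approximation: Monte-Carlo orientation average of the
// projected area of the union of atom-centred hard disks.
//
// Trajectory method: momentum-transfer collision integral Omega(1,1) at
// temperature T.  Relative-speed average by Gauss-Legendre quadrature on
// the transformed Maxwell-Boltzmann integrand, uniform orientation
// average, impact-parameter Monte-Carlo of (1 - cos chi) 2 pi b db, with
// the deflection angle chi from classical trajectories in the solute-gas
// potential V = sum_i 4 eps_i [(sig_i/r_i)^12 - (sig_i/r_i)^6]
//              - (alpha/2) |E(r)|^2,
// E being the electric field of the solute partial charges.
//
// All randomness is drawn from R's RNG so results are reproducible under
// set.seed().  Units: Angstrom, Da, kcal/mol, ps.
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

const double COUL = 332.0637;        // kcal/mol per e^2/Angstrom
const double INDUC = COUL / 2.0;     // (1/2) prefactor for -alpha E^2
const double ACC = 418.4;            // (kcal/mol/A)/Da -> A/ps^2

// uniform random rotation matrix (Shoemake quaternion method, R RNG)
arma::mat33 rand_rotation() {
  double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
  double q1 = std::sqrt(1 - u1) * std::sin(2 * M_PI * u2);
  double q2 = std::sqrt(1 - u1) * std::cos(2 * M_PI * u2);
  double q3 = std::sqrt(u1) * std::sin(2 * M_PI * u3);
  double q4 = std::sqrt(u1) * std::cos(2 * M_PI * u3);
  arma::mat33 R;
  R(0,0) = 1 - 2*(q3*q3 + q4*q4); R(0,1) = 2*(q2*q3 - q1*q4); R(0,2) = 2*(q2*q4 + q1*q3);
  R(1,0) = 2*(q2*q3 + q1*q4); R(1,1) = 1 - 2*(q2*q2 + q4*q4); R(1,2) = 2*(q3*q4 - q1*q2);
  R(2,0) = 2*(q2*q4 - q1*q3); R(2,1) = 2*(q3*q4 + q1*q2); R(2,2) = 1 - 2*(q2*q2 + q3*q3);
  return R;
}

}  // namespace

// [[Rcpp::export(name = ".pa_ccs")]]
List pa_ccs_cpp(const arma::mat& coords, const arma::vec& radii,
                int n_orientations, int n_darts) {
  RNGScope scope;
  arma::mat X = coords;
  X.each_row() -= arma::mean(X, 0);
  const int N = X.n_rows;
  arma::vec area(n_orientations);

  for (int o = 0; o < n_orientations; ++o) {
    arma::mat33 R = rand_rotation();
    arma::mat P = X * R.t();          // rotated; project onto xy plane
    double xmin = arma::datum::inf, xmax = -arma::datum::inf;
    double ymin = arma::datum::inf, ymax = -arma::datum::inf;
    for (int i = 0; i < N; ++i) {
      xmin = std::min(xmin, P(i,0) - radii(i)); xmax = std::max(xmax, P(i,0) + radii(i));
      ymin = std::min(ymin, P(i,1) - radii(i)); ymax = std::max(ymax, P(i,1) + radii(i));
    }
    double box = (xmax - xmin) * (ymax - ymin);
    int hits = 0;
    for (int d = 0; d < n_darts; ++d) {
      double x = xmin + unif_rand() * (xmax - xmin);
      double y = ymin + unif_rand() * (ymax - ymin);
      for (int i = 0; i < N; ++i) {
        double dx = x - P(i,0), dy = y - P(i,1);
        if (dx*dx + dy*dy <= radii(i)*radii(i)) { ++hits; break; }
      }
    }
    area(o) = box * (double)hits / (double)n_darts;
  }
  double omega = arma::mean(area);
  double se = arma::stddev(area) / std::sqrt((double)n_orientations);
  return List::create(_["omega"] = omega, _["stderr"] = se);
}

namespace {

struct TMPot {
  arma::mat X;         // N x 3 (possibly rotated copy)
  arma::vec eps, sig, q;
  double alpha;
  bool has_charge;

  // potential and force at gas position r (force = -grad V)
  double eval(const arma::rowvec& r, arma::rowvec& F) const {
    double V = 0.0;
    F.zeros(3);
    arma::rowvec Efield(3, arma::fill::zeros);
    const int N = X.n_rows;
    for (int i = 0; i < N; ++i) {
      arma::rowvec d = r - X.row(i);
      double r2 = arma::dot(d, d);
      double ri = std::sqrt(r2);
      double s2 = sig(i) * sig(i) / r2;
      double s6 = s2 * s2 * s2;
      V += 4.0 * eps(i) * (s6 * s6 - s6);
      double dEdr = -4.0 * eps(i) * (12.0 * s6 * s6 - 6.0 * s6) / ri;
      F -= dEdr * d / ri;
      if (has_charge) Efield += q(i) * d / (r2 * ri);
    }
    if (has_charge) {
      V -= INDUC * alpha * arma::dot(Efield, Efield);
      // grad of -(alpha/2)|E|^2: accumulate analytically
      for (int i = 0; i < N; ++i) {
        arma::rowvec d = r - X.row(i);
        double r2 = arma::dot(d, d);
        double ri = std::sqrt(r2);
        double r3 = r2 * ri, r5 = r2 * r3;
        // dV/dr_l = -alpha*COUL * sum_i q_i (E_l / r^3 - 3 (E.d) d_l / r^5)
        arma::rowvec gi = q(i) * (Efield / r3 - 3.0 * arma::dot(Efield, d) * d / r5);
        F += 2.0 * INDUC * alpha * gi;  // F = -grad V
      }
    }
    return V;
  }

  double pot_only(const arma::rowvec& r) const {
    arma::rowvec F;
    return eval(r, F);
  }
};

// integrate one trajectory; returns (1 - cos chi), or -1 on failure
double run_traj(const TMPot& pot, double g, double b, double d0,
                double mu, int max_steps) {
  arma::rowvec r = {b, 0.0, -d0};
  arma::rowvec v = {0.0, 0.0, g};
  arma::rowvec F;
  double V = pot.eval(r, F);
  double E0 = 0.5 * mu * g * g / ACC + V;   // kcal/mol, conserved quantity
  double Eref = 0.5 * mu * g * g / ACC;     // kinetic scale for tolerances
  double Eprev = E0;
  double dt = 0.02 / g;                     // start: ~0.02 A per step
  const double dt_min = 1e-7 / g;
  double d0sq = d0 * d0;

  for (int s = 0; s < max_steps; ++s) {
    // velocity Verlet; halve the step while the per-step energy change
    // exceeds tolerance, grow it again when the change is negligible
    for (;;) {
      arma::rowvec a1 = ACC * F / mu;
      arma::rowvec rn = r + v * dt + 0.5 * a1 * dt * dt;
      arma::rowvec Fn;
      double Vn = pot.eval(rn, Fn);
      arma::rowvec a2 = ACC * Fn / mu;
      arma::rowvec vn = v + 0.5 * (a1 + a2) * dt;
      double En = 0.5 * mu * arma::dot(vn, vn) / ACC + Vn;
      double dE = std::abs(En - Eprev);
      if (dE <= 1e-8 * Eref || dt <= dt_min) {
        r = rn; v = vn; F = Fn; V = Vn; Eprev = En;
        if (std::abs(En - E0) > 1e-4 * Eref) return -1.0;  // cumulative drift
        if (dE < 1e-10 * Eref) dt *= 1.25;
        double vmag = arma::norm(v);
        if (vmag * dt > 1.0) dt = 1.0 / vmag;      // cap displacement, 1 A
        break;
      }
      dt *= 0.5;
    }
    if (arma::dot(r, r) > d0sq * 1.02 && arma::dot(r, v) > 0) {
      double c = v(2) / arma::norm(v);
      return 1.0 - c;
    }
  }
  return -1.0;  // did not exit
}

}  // namespace

// [[Rcpp::export(name = ".tm_ccs")]]
List tm_ccs_cpp(const arma::mat& coords, const arma::vec& eps,
                const arma::vec& sig, const arma::vec& charges,
                double alpha, double mu, double kT,
                int cycles, const arma::vec& vel_nodes,
                const arma::vec& vel_weights, int n_mc,
                int n_orient_cal, int max_steps) {
  RNGScope scope;
  TMPot pot;
  pot.X = coords;
  pot.X.each_row() -= arma::mean(pot.X, 0);
  pot.eps = eps; pot.sig = sig; pot.q = charges; pot.alpha = alpha;
  pot.has_charge = arma::abs(charges).max() > 1e-12;

  const int nvel = vel_nodes.n_elem;
  // Gauss-Legendre nodes u in (0,1); x = -log(1-u), weight x^2
  arma::vec xs(nvel), gs(nvel), ws(nvel);
  for (int i = 0; i < nvel; ++i) {
    xs(i) = -std::log(1.0 - vel_nodes(i));
    gs(i) = std::sqrt(2.0 * xs(i) * kT * ACC / mu);  // A/ps
    ws(i) = vel_weights(i) * xs(i) * xs(i);
  }
  double wsum = arma::accu(ws);

  // geometric extent and far-field start distance
  double rext = 0.0, sigmax = 0.0;
  for (arma::uword i = 0; i < pot.X.n_rows; ++i) {
    rext = std::max(rext, arma::norm(pot.X.row(i)));
    sigmax = std::max(sigmax, sig(i));
  }
  double epsmax = eps.max();
  double r_lj = sigmax * std::pow(4.0 * epsmax / 1e-6, 1.0 / 6.0);
  double r_ind = 0.0;
  double qtot = arma::accu(charges);
  if (pot.has_charge)
    r_ind = std::pow(2.0 * INDUC * pot.alpha * std::max(qtot * qtot, 0.25) / 1e-6, 0.25);
  double r_far = std::max(r_lj, r_ind);   // |V| < 1e-6 kcal/mol beyond this

  // adaptive b_max per velocity node: grow until max deflection < 1e-3 rad
  // over a small deterministic orientation sample
  arma::vec bmax(nvel);
  int ncal = std::max(4, n_orient_cal / 250);
  for (int iv = 0; iv < nvel; ++iv) {
    double b = rext + 1.5 * sigmax;
    double d0 = std::max(b, rext) + r_far;
    for (int it = 0; it < 60; ++it) {
      double worst = 0.0;
      for (int o = 0; o < ncal; ++o) {
        TMPot p2 = pot;
        p2.X = pot.X * rand_rotation().t();
        double om = run_traj(p2, gs(iv), b, d0, mu, max_steps);
        if (om >= 0) {
          double chi = std::acos(std::max(-1.0, std::min(1.0, 1.0 - om)));
          worst = std::max(worst, chi);
        } else {
          worst = 1.0;  // failed trajectory at this b: push b outward
        }
      }
      if (worst < 1e-3) break;
      b *= 1.15;
      d0 = std::max(b, rext) + r_far;
    }
    bmax(iv) = b;
  }

  // main Monte-Carlo cycles
  arma::vec omega_c(cycles);
  int n_failed = 0;
  for (int c = 0; c < cycles; ++c) {
    double acc_num = 0.0;
    for (int iv = 0; iv < nvel; ++iv) {
      double d0 = std::max(bmax(iv), rext) + r_far;
      double sum_om = 0.0;
      int n_ok = 0;
      for (int t = 0; t < n_mc; ++t) {
        TMPot p2 = pot;
        p2.X = pot.X * rand_rotation().t();
        // stratified impact-parameter sampling: u in [t/n, (t+1)/n)
        double u = ((double)t + unif_rand()) / (double)n_mc;
        double b = bmax(iv) * std::sqrt(u);
        double om = run_traj(p2, gs(iv), b, d0, mu, max_steps);
        if (om >= 0.0) { sum_om += om; ++n_ok; } else { ++n_failed; }
      }
      double Q = (n_ok > 0) ? M_PI * bmax(iv) * bmax(iv) * sum_om / n_ok : 0.0;
      acc_num += ws(iv) * Q;
    }
    omega_c(c) = acc_num / wsum;
  }

  double omega = arma::mean(omega_c);
  double se = (cycles > 1) ? arma::stddev(omega_c) / std::sqrt((double)cycles) : 0.0;
  return List::create(_["omega"] = omega, _["stderr"] = se,
                      _["omega_cycles"] = omega_c,
                      _["n_failed"] = n_failed, _["b_max"] = bmax);
}

// [[Rcpp::export(name = ".kabsch_rmsd")]]
double kabsch_rmsd_cpp(const arma::mat& A, const arma::mat& B) {
  arma::mat X = A; X.each_row() -= arma::mean(A, 0);
  arma::mat Y = B; Y.each_row() -= arma::mean(B, 0);
  arma::mat C = X.t() * Y;
  arma::mat U, V; arma::vec s;
  arma::svd(U, s, V, C);
  double d = arma::det(V * U.t());
  arma::vec sg = {1.0, 1.0, (d < 0) ? -1.0 : 1.0};
  double tr = arma::accu(s % sg);
  double e = (arma::accu(X % X) + arma::accu(Y % Y) - 2.0 * tr) / A.n_rows;
  return std::sqrt(std::max(0.0, e));
}

// [[Rcpp::export(name = ".rmsd_matrix")]]
arma::mat rmsd_matrix_cpp(const List& coord_list) {
  int n = coord_list.size();
  std::vector<arma::mat> Cs(n);
  for (int i = 0; i < n; ++i) Cs[i] = as<arma::mat>(coord_list[i]);
  arma::mat D(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      D(i, j) = D(j, i) = kabsch_rmsd_cpp(Cs[i], Cs[j]);
  return D;
}
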