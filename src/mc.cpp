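#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Full energy recomputation for a C-alpha chain: 6-12 Lennard-Jones,
// hydrophobic, electrostatic (pairs with sequence separation >= 3) and
// the steric nmw * ncn coupling. Must stay numerically identical to the
// pure-R total_energy() reference.
static void chain_energy(const std::vector<double> &x,
                         const std::vector<double> &y,
                         const std::vector<double> &z,
                         const NumericVector &H, const NumericVector &Q,
                         const NumericVector &nmw,
                         double eps, double sigma, double ch, double cel,
                         double cst, double cn_cutoff, double rfloor,
                         double out[4]) {
  int n = x.size();
  double lj = 0.0, hp = 0.0, el = 0.0;
  std::vector<int> cn(n, 0);
  for (int j = 0; j < n; ++j) {
    for (int k = j + 3; k < n; ++k) {
      double dx = x[j] - x[k], dy = y[j] - y[k], dz = z[j] - z[k];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < cn_cutoff) { cn[j]++; cn[k]++; }
      if (r < rfloor) r = rfloor;
      double sr6 = std::pow(sigma / r, 6.0);
      lj += 4.0 * eps * (sr6 * sr6 - sr6);
      hp -= ch * (H[j] + H[k] - 1.0) / r;
      el += cel * Q[j] * Q[k] / r;
    }
  }
  int mx = 0;
  for (int j = 0; j < n; ++j) if (cn[j] > mx) mx = cn[j];
  double st = 0.0;
  if (mx > 0) {
    for (int j = 0; j < n; ++j) st += nmw[j] * (double)cn[j] / (double)mx;
  }
  st *= cst;
  out[0] = lj; out[1] = hp; out[2] = el; out[3] = st;
}

static bool window_ok(double d, double lo, double hi) {
  return d >= lo - 1e-9 && d <= hi + 1e-9;
}

static double site_dist(const std::vector<double> &x,
                        const std::vector<double> &y,
                        const std::vector<double> &z, int a, int b) {
  double dx = x[a] - x[b], dy = y[a] - y[b], dz = z[a] - z[b];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
List cg_mc_run(NumericMatrix coords, NumericVector H, NumericVector Q,
               NumericVector nmw, double eps, double sigma, double ch,
               double cel, double cst, double cn_cutoff, double rfloor,
               int steps, int stride, double temperature, double max_disp,
               double bond_lo, double bond_hi, double d13_lo,
               double d13_hi) {
  int n = coords.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  RNGScope scope;
  double terms[4];
  chain_energy(x, y, z, H, Q, nmw, eps, sigma, ch, cel, cst, cn_cutoff,
               rfloor, terms);
  double e_cur = terms[0] + terms[1] + terms[2] + terms[3];

  int n_snap = steps / stride;
  List snapshots(n_snap);
  NumericMatrix energies(n_snap, 6);
  int accepted = 0, isnap = 0, constraint_rejected = 0;

  for (int step = 1; step <= steps; ++step) {
    int i = (int)std::floor(unif_rand() * n);
    if (i >= n) i = n - 1;
    double ox = x[i], oy = y[i], oz = z[i];
    x[i] += (2.0 * unif_rand() - 1.0) * max_disp;
    y[i] += (2.0 * unif_rand() - 1.0) * max_disp;
    z[i] += (2.0 * unif_rand() - 1.0) * max_disp;

    bool ok = true;
    if (i > 0) ok = ok && window_ok(site_dist(x, y, z, i - 1, i), bond_lo, bond_hi);
    if (i < n - 1) ok = ok && window_ok(site_dist(x, y, z, i, i + 1), bond_lo, bond_hi);
    if (i > 1) ok = ok && window_ok(site_dist(x, y, z, i - 2, i), d13_lo, d13_hi);
    if (i < n - 2) ok = ok && window_ok(site_dist(x, y, z, i, i + 2), d13_lo, d13_hi);

    double t_new[4];
    bool accept = false;
    if (!ok) ++constraint_rejected;
    if (ok) {
      chain_energy(x, y, z, H, Q, nmw, eps, sigma, ch, cel, cst,
                   cn_cutoff, rfloor, t_new);
      double e_new = t_new[0] + t_new[1] + t_new[2] + t_new[3];
      double de = e_new - e_cur;
      if (de <= 0.0) {
        accept = true;
      } else if (temperature > 0.0) {
        accept = unif_rand() < std::exp(-de / temperature);
      }
      if (accept) {
        e_cur = e_new;
        for (int t = 0; t < 4; ++t) terms[t] = t_new[t];
      }
    }
    if (!accept) { x[i] = ox; y[i] = oy; z[i] = oz; } else { ++accepted; }

    if (step % stride == 0 && isnap < n_snap) {
      NumericMatrix snap(n, 3);
      for (int r = 0; r < n; ++r) {
        snap(r, 0) = x[r]; snap(r, 1) = y[r]; snap(r, 2) = z[r];
      }
      snapshots[isnap] = snap;
      energies(isnap, 0) = step;
      energies(isnap, 1) = terms[0];
      energies(isnap, 2) = terms[1];
      energies(isnap, 3) = terms[2];
      energies(isnap, 4) = terms[3];
      energies(isnap, 5) = e_cur;
      ++isnap;
    }
  }
  return List::create(Named("snapshots") = snapshots,
                      Named("energies") = energies,
                      Named("accepted") = accepted,
                      Named("constraint_rejected") = constraint_rejected);
}
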