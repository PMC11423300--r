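#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise DLVO energy in kBT. Prefactors are precomputed in R:
//   A     = H_A / (6 kB T)                        (dimensionless)
//   Y     = Z_eff^2 * L_B * (e^{kr}/(1+kr))^2     (nm)
//   kappa = 1 / Debye length                      (nm^-1)
// d <= 2r is a hard-core overlap and is handled by the caller.
static inline double pair_energy(double d, double radius,
                                 double A, double Y, double kappa) {
  double u = 0.0;
  if (A != 0.0) {
    double r2 = radius * radius;
    double d2 = d * d;
    double x = 4.0 * r2 / d2;
    u -= A * (2.0 * r2 / (d2 - 4.0 * r2) + 2.0 * r2 / d2 + std::log1p(-x));
  }
  if (Y != 0.0) {
    u += Y * std::exp(-kappa * d) / d;
  }
  return u;
}

static inline double min_image(double dx, double box) {
  return dx - box * std::nearbyint(dx / box);
}

static inline double pair_dist2(const double* p, int i, int j, int n, double box) {
  double dx = min_image(p[i] - p[j], box);
  double dy = min_image(p[i + n] - p[j + n], box);
  double dz = min_image(p[i + 2 * n] - p[j + 2 * n], box);
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export]]
NumericMatrix cpp_insert_random(int n, double box, double radius,
                                int max_attempts) {
  NumericMatrix pos(n, 3);
  double* p = REAL(pos);
  double d2min = 4.0 * radius * radius;
  for (int i = 0; i < n; ++i) {
    bool placed = false;
    for (int att = 0; att < max_attempts; ++att) {
      double x = unif_rand() * box;
      double y = unif_rand() * box;
      double z = unif_rand() * box;
      p[i] = x; p[i + n] = y; p[i + 2 * n] = z;
      bool ok = true;
      for (int j = 0; j < i; ++j) {
        if (pair_dist2(p, i, j, n, box) <= d2min) { ok = false; break; }
      }
      if (ok) { placed = true; break; }
    }
    if (!placed)
      stop("random insertion failed after %d attempts for particle %d; "
           "lower the number density", max_attempts, i + 1);
  }
  return pos;
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, double box, double radius,
                        double A, double Y, double kappa, double cutoff) {
  int n = pos.nrow();
  const double* p = REAL(pos);
  double c2 = cutoff * cutoff;
  double d2min = 4.0 * radius * radius;
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = pair_dist2(p, i, j, n, box);
      if (d2 <= d2min) return R_PosInf;
      if (d2 < c2) e += pair_energy(std::sqrt(d2), radius, A, Y, kappa);
    }
  }
  return e;
}

// Energy of particle i against all others, positions given explicitly for i.
// Returns +Inf on hard-core overlap.
static double particle_energy(const double* p, int n, int i,
                              double xi, double yi, double zi,
                              double box, double radius,
                              double A, double Y, double kappa, double c2) {
  double d2min = 4.0 * radius * radius;
  double e = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = min_image(xi - p[j], box);
    double dy = min_image(yi - p[j + n], box);
    double dz = min_image(zi - p[j + 2 * n], box);
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 <= d2min) return R_PosInf;
    if (d2 < c2) e += pair_energy(std::sqrt(d2), radius, A, Y, kappa);
  }
  return e;
}

static inline double wrap(double x, double box) {
  x -= box * std::floor(x / box);
  if (x >= box) x -= box;   // guard against floating rounding at the edge
  return x;
}

// Run n_steps single-particle Metropolis moves. snapshot_steps (1-based,
// sorted, may be empty) selects steps after which the configuration is
// copied out. energy0 is the current total energy (kBT); bookkeeping is
// incremental. Uses R's RNG so runs are reproducible via set.seed().
// [[Rcpp::export]]
List cpp_mc_chain(NumericMatrix pos, double box, double radius,
                  double A, double Y, double kappa, double cutoff,
                  int n_steps, double max_disp, double energy0,
                  IntegerVector snapshot_steps) {
  NumericMatrix cur = clone(pos);
  int n = cur.nrow();
  double* p = REAL(cur);
  double c2 = cutoff * cutoff;
  double energy = energy0;
  double esum = 0.0;
  long accepted = 0;
  int n_snap = snapshot_steps.size();
  List snaps(n_snap);
  int next_snap = 0;

  for (int s = 1; s <= n_steps; ++s) {
    int i = (int)(unif_rand() * n);
    if (i == n) i = n - 1;
    double xi = p[i], yi = p[i + n], zi = p[i + 2 * n];
    double xn = wrap(xi + (unif_rand() * 2.0 - 1.0) * max_disp, box);
    double yn = wrap(yi + (unif_rand() * 2.0 - 1.0) * max_disp, box);
    double zn = wrap(zi + (unif_rand() * 2.0 - 1.0) * max_disp, box);
    double e_new = particle_energy(p, n, i, xn, yn, zn, box, radius,
                                   A, Y, kappa, c2);
    if (R_finite(e_new)) {
      double e_old = particle_energy(p, n, i, xi, yi, zi, box, radius,
                                     A, Y, kappa, c2);
      double dE = e_new - e_old;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE)) {
        p[i] = xn; p[i + n] = yn; p[i + 2 * n] = zn;
        energy += dE;
        ++accepted;
      }
    }
    esum += energy;
    while (next_snap < n_snap && snapshot_steps[next_snap] == s) {
      snaps[next_snap] = clone(cur);
      ++next_snap;
    }
  }
  return List::create(_["positions"] = cur,
                      _["energy"] = energy,
                      _["mean_energy"] = esum / n_steps,
                      _["accepted"] = (double)accepted,
                      _["n_steps"] = (double)n_steps,
                      _["snapshots"] = snaps);
}

// Histogram of unique minimum-image pair distances over a list of
// configurations. Breaks are the n_bins+1 bin edges (ascending).
// [[Rcpp::export]]
NumericVector cpp_pair_histogram(List snapshots, double box,
                                 NumericVector breaks) {
  int n_bins = breaks.size() - 1;
  NumericVector counts(n_bins);
  double lo = breaks[0], hi = breaks[n_bins];
  double width = (hi - lo) / n_bins;
  for (int k = 0; k < snapshots.size(); ++k) {
    NumericMatrix snap = snapshots[k];
    int n = snap.nrow();
    const double* p = REAL(snap);
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double d = std::sqrt(pair_dist2(p, i, j, n, box));
        if (d >= lo && d < hi) {
          int b = (int)((d - lo) / width);
          if (b >= 0 && b < n_bins) counts[b] += 1.0;
        }
      }
    }
  }
  return counts;
}

// [[Rcpp::export]]
double cpp_min_pair_distance(NumericMatrix pos, double box) {
  int n = pos.nrow();
  const double* p = REAL(pos);
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d2 = pair_dist2(p, i, j, n, box);
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
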