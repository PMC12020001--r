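#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pair potential kernels for the 2D rose water model.
//
// Body-frame convention: the three hydrogen-bond arms of a molecule point at
// 60, 180 and 300 degrees in its body frame, i.e. at the minima of the
// orientational term a1*cos(3t) + a2*cos(6t) (cos(3t) = -1). All angles are
// radians; boxes are rectangular and periodic (minimum image).

struct RoseParams {
  double eps_lj, sigma_lj, eps_hb, r_hb, r_fwhm, r_l, r_u;
  double a1, a2, a_max, lj_cutoff, lj_shift;
  bool ideal;
};

static RoseParams unpack(const List& par) {
  RoseParams p;
  p.eps_lj   = as<double>(par["eps_lj"]);
  p.sigma_lj = as<double>(par["sigma_lj"]);
  p.eps_hb   = as<double>(par["eps_hb"]);
  p.r_hb     = as<double>(par["r_hb"]);
  p.r_fwhm   = as<double>(par["r_fwhm"]);
  p.r_l      = as<double>(par["r_l"]);
  p.r_u      = as<double>(par["r_u"]);
  p.a1       = as<double>(par["a1"]);
  p.a2       = as<double>(par["a2"]);
  p.a_max    = as<double>(par["a_max"]);
  p.lj_cutoff = as<double>(par["lj_cutoff"]);
  p.lj_shift  = as<double>(par["lj_shift"]);
  p.ideal = (p.eps_lj == 0.0 && p.eps_hb == 0.0);
  return p;
}

static inline void min_image(double& dx, double& dy, double bx, double by) {
  dx -= bx * std::nearbyint(dx / bx);
  dy -= by * std::nearbyint(dy / by);
}

static inline double lj_e(double r, const RoseParams& p) {
  if (r >= p.lj_cutoff || p.eps_lj == 0.0) return 0.0;
  double sr2 = p.sigma_lj * p.sigma_lj / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * p.eps_lj * (sr6 * sr6 - sr6) - p.lj_shift;
}

static inline double lj_de(double r, const RoseParams& p) {
  if (r >= p.lj_cutoff || p.eps_lj == 0.0) return 0.0;
  double sr2 = p.sigma_lj * p.sigma_lj / (r * r);
  double sr6 = sr2 * sr2 * sr2;
  return 4.0 * p.eps_lj * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
}

static inline double switch_s(double r, const RoseParams& p) {
  double u = std::fabs(r - p.r_hb) / p.r_fwhm;
  if (u >= 1.0) return 0.0;
  return 1.0 - 3.0 * u * u + 2.0 * u * u * u;
}

static inline double switch_ds(double r, const RoseParams& p) {
  double d = r - p.r_hb;
  double u = std::fabs(d) / p.r_fwhm;
  if (u >= 1.0) return 0.0;
  double s = (d >= 0.0) ? 1.0 : -1.0;
  return (-6.0 * u + 6.0 * u * u) * s / p.r_fwhm;
}

static inline double rose_val(double t, const RoseParams& p) {
  return (p.a1 * std::cos(3.0 * t) + p.a2 * std::cos(6.0 * t)) / p.a_max;
}

static inline double rose_dval(double t, const RoseParams& p) {
  return (-3.0 * p.a1 * std::sin(3.0 * t) - 6.0 * p.a2 * std::sin(6.0 * t)) / p.a_max;
}

// Total energy, forces, torques and pair virial of a periodic configuration.
// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix pos, NumericVector ori,
                       NumericVector box, List par) {
  RoseParams p = unpack(par);
  int n = pos.nrow();
  NumericMatrix f(n, 2);
  NumericVector tq(n);
  double e = 0.0, w = 0.0;
  if (!p.ideal) {
    double rmax = std::max(p.lj_cutoff, p.r_u);
    double rmax2 = rmax * rmax;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
        min_image(dx, dy, box[0], box[1]);
        double r2 = dx * dx + dy * dy;
        if (r2 >= rmax2) continue;
        double r = std::sqrt(r2);
        if (r <= 0.0) stop("coincident molecular centers");
        double alpha = std::atan2(dy, dx);
        double de = lj_de(r, p);
        e += lj_e(r, p);
        double dUda = 0.0;
        if (r > p.r_l && r < p.r_u && p.eps_hb != 0.0) {
          double s = switch_s(r, p), ds = switch_ds(r, p);
          double ti = alpha - ori[i];
          double tj = alpha + M_PI - ori[j];
          double ri = rose_val(ti, p), rj = rose_val(tj, p);
          double dri = rose_dval(ti, p), drj = rose_dval(tj, p);
          double half = 0.5 * p.eps_hb;
          e += half * (ri + rj) * s;
          de += half * (ri + rj) * ds;
          dUda = half * s * (dri + drj);
          tq[i] += half * s * dri;
          tq[j] += half * s * drj;
        }
        double ux = dx / r, uy = dy / r;
        // force on i: dU/dr * rhat - dU/dalpha * (dy,-dx)/r^2
        double fix = de * ux - dUda * dy / r2;
        double fiy = de * uy + dUda * dx / r2;
        f(i, 0) += fix; f(i, 1) += fiy;
        f(j, 0) -= fix; f(j, 1) -= fiy;
        w += -de * r;  // radial (distance-derivative) virial only
      }
    }
  }
  return List::create(_["energy"] = e, _["forces"] = f,
                      _["torques"] = tq, _["virial"] = w);
}

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, NumericVector ori,
                        NumericVector box, List par) {
  RoseParams p = unpack(par);
  int n = pos.nrow();
  double e = 0.0;
  if (p.ideal) return e;
  double rmax = std::max(p.lj_cutoff, p.r_u);
  double rmax2 = rmax * rmax;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
      min_image(dx, dy, box[0], box[1]);
      double r2 = dx * dx + dy * dy;
      if (r2 >= rmax2) continue;
      double r = std::sqrt(r2);
      if (r <= 0.0) stop("coincident molecular centers");
      e += lj_e(r, p);
      if (r > p.r_l && r < p.r_u && p.eps_hb != 0.0) {
        double alpha = std::atan2(dy, dx);
        double s = switch_s(r, p);
        e += 0.5 * p.eps_hb * s *
             (rose_val(alpha - ori[i], p) + rose_val(alpha + M_PI - ori[j], p));
      }
    }
  return e;
}

// Interaction energy of molecule i (0-based) with all others.
// [[Rcpp::export]]
double cpp_particle_energy(int i, NumericMatrix pos, NumericVector ori,
                           NumericVector box, List par) {
  RoseParams p = unpack(par);
  int n = pos.nrow();
  double e = 0.0;
  if (p.ideal) return e;
  double rmax = std::max(p.lj_cutoff, p.r_u);
  double rmax2 = rmax * rmax;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
    min_image(dx, dy, box[0], box[1]);
    double r2 = dx * dx + dy * dy;
    if (r2 >= rmax2) continue;
    double r = std::sqrt(r2);
    if (r <= 0.0) stop("coincident molecular centers");
    e += lj_e(r, p);
    if (r > p.r_l && r < p.r_u && p.eps_hb != 0.0) {
      double alpha = std::atan2(dy, dx);
      double s = switch_s(r, p);
      e += 0.5 * p.eps_hb * s *
           (rose_val(alpha - ori[i], p) + rose_val(alpha + M_PI - ori[j], p));
    }
  }
  return e;
}

static double particle_energy_raw(int i, const NumericMatrix& pos,
                                  const NumericVector& ori,
                                  double bx, double by,
                                  const RoseParams& p) {
  int n = pos.nrow();
  double e = 0.0;
  if (p.ideal) return e;
  double rmax = std::max(p.lj_cutoff, p.r_u);
  double rmax2 = rmax * rmax;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
    min_image(dx, dy, bx, by);
    double r2 = dx * dx + dy * dy;
    if (r2 >= rmax2) continue;
    double r = std::sqrt(r2);
    if (r <= 0.0) stop("coincident molecular centers");
    e += lj_e(r, p);
    if (r > p.r_l && r < p.r_u && p.eps_hb != 0.0) {
      double alpha = std::atan2(dy, dx);
      double s = switch_s(r, p);
      e += 0.5 * p.eps_hb * s *
           (rose_val(alpha - ori[i], p) + rose_val(alpha + M_PI - ori[j], p));
    }
  }
  return e;
}

static double total_energy_raw(const NumericMatrix& pos,
                               const NumericVector& ori,
                               double bx, double by, const RoseParams& p) {
  int n = pos.nrow();
  double e = 0.0;
  if (p.ideal) return e;
  for (int i = 0; i < n; ++i)
    e += particle_energy_raw(i, pos, ori, bx, by, p);
  return 0.5 * e;
}

// One nested-sampling random walk: L * N single-particle moves with one
// volume attempt per N sub-steps, every move accepted only below the
// enthalpy limit. Volume moves are log-uniform proposals accepted with the
// (V'/V)^(N+1) factor of the V^N dV configuration-space measure in an
// isotropically rescalable square cell bounded by V0. Uses R's RNG, so the
// walk is reproducible under set.seed().
// [[Rcpp::export]]
List cpp_ns_walk(NumericMatrix pos_, NumericVector ori_, double V, double U,
                 double H_lim, double pressure, int L, double step,
                 double vstep, double V0, List par) {
  RoseParams p = unpack(par);
  NumericMatrix pos = clone(pos_);
  NumericVector ori = clone(ori_);
  int n = pos.nrow();
  double Lbox = std::sqrt(V);
  int acc = 0, tries = 0;
  RNGScope scope;
  for (int m = 1; m <= L * n; ++m) {
    int j = (int)(R::unif_rand() * n);
    if (j >= n) j = n - 1;
    double ox = pos(j, 0), oy = pos(j, 1), oo = ori[j];
    double e_old = particle_energy_raw(j, pos, ori, Lbox, Lbox, p);
    double nx = ox + R::unif_rand() * 2.0 * step - step;
    double ny = oy + R::unif_rand() * 2.0 * step - step;
    nx -= Lbox * std::floor(nx / Lbox);
    ny -= Lbox * std::floor(ny / Lbox);
    pos(j, 0) = nx; pos(j, 1) = ny;
    ori[j] = oo + (R::unif_rand() * 2.0 - 1.0) * M_PI;
    double e_new = particle_energy_raw(j, pos, ori, Lbox, Lbox, p);
    double U_new = U + e_new - e_old;
    ++tries;
    if (U_new + pressure * V < H_lim) {
      U = U_new;
      ++acc;
    } else {
      pos(j, 0) = ox; pos(j, 1) = oy; ori[j] = oo;
    }
    if (m % n == 0) {
      double V_new = V * std::exp((R::unif_rand() * 2.0 - 1.0) * vstep);
      if (V_new <= V0 &&
          R::unif_rand() < std::pow(V_new / V, (double)(n + 1))) {
        double s = std::sqrt(V_new / V);
        double U_new2;
        if (p.ideal) {
          U_new2 = 0.0;
        } else {
          NumericMatrix pos2(n, 2);
          for (int i = 0; i < n; ++i) {
            pos2(i, 0) = pos(i, 0) * s;
            pos2(i, 1) = pos(i, 1) * s;
          }
          double Lnew = std::sqrt(V_new);
          U_new2 = total_energy_raw(pos2, ori, Lnew, Lnew, p);
          if (U_new2 + pressure * V_new < H_lim) {
            pos = pos2;
          }
        }
        if (U_new2 + pressure * V_new < H_lim) {
          if (p.ideal)
            for (int i = 0; i < n; ++i) {
              pos(i, 0) *= s; pos(i, 1) *= s;
            }
          V = V_new; U = U_new2;
          Lbox = std::sqrt(V);
        }
      }
    }
  }
  return List::create(_["pos"] = pos, _["ori"] = ori, _["V"] = V,
                      _["U"] = U, _["acc"] = acc, _["tries"] = tries);
}

// Hydrogen bonds per molecule: a pair bonds when its HB energy (both halves)
// is below `cut`.
// [[Rcpp::export]]
IntegerVector cpp_hb_counts(NumericMatrix pos, NumericVector ori,
                            NumericVector box, List par, double cut) {
  RoseParams p = unpack(par);
  int n = pos.nrow();
  IntegerVector cnt(n);
  if (p.eps_hb == 0.0) return cnt;
  double rmax2 = p.r_u * p.r_u;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
      min_image(dx, dy, box[0], box[1]);
      double r2 = dx * dx + dy * dy;
      if (r2 >= rmax2) continue;
      double r = std::sqrt(r2);
      if (r <= p.r_l) continue;
      double alpha = std::atan2(dy, dx);
      double s = switch_s(r, p);
      double e = 0.5 * p.eps_hb * s *
                 (rose_val(alpha - ori[i], p) + rose_val(alpha + M_PI - ori[j], p));
      if (e < cut) { cnt[i] += 1; cnt[j] += 1; }
    }
  return cnt;
}

// Ordered-pair table for angular distribution functions: for every ordered
// pair (i, j) with r_ij <= rmax, the distance and the angle (degrees, in
// [-60, 60)) between molecule i's nearest arm and the connecting line.
// [[Rcpp::export]]
List cpp_adf_pairs(NumericMatrix pos, NumericVector ori,
                   NumericVector box, double rmax) {
  int n = pos.nrow();
  std::vector<double> rr, aa;
  rr.reserve(4 * n); aa.reserve(4 * n);
  double rmax2 = rmax * rmax;
  const double arm0 = M_PI / 3.0;          // first arm in the body frame
  const double period = 2.0 * M_PI / 3.0;  // arms every 120 degrees
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
      min_image(dx, dy, box[0], box[1]);
      double r2 = dx * dx + dy * dy;
      if (r2 > rmax2 || r2 == 0.0) continue;
      double th = std::atan2(dy, dx) - ori[i] - arm0;  // rel. to nearest arm
      th = th - period * std::nearbyint(th / period);  // fold to [-60, 60)
      rr.push_back(std::sqrt(r2));
      aa.push_back(th * 180.0 / M_PI);
    }
  return List::create(_["r"] = wrap(rr), _["angle"] = wrap(aa));
}

// Minimum-image pair distances (unordered pairs), for g(r) and neighbor
// cutoffs.
// [[Rcpp::export]]
NumericVector cpp_pair_distances(NumericMatrix pos, NumericVector box,
                                 double rmax) {
  int n = pos.nrow();
  std::vector<double> rr;
  rr.reserve(4 * n);
  double rmax2 = rmax * rmax;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
      min_image(dx, dy, box[0], box[1]);
      double r2 = dx * dx + dy * dy;
      if (r2 <= rmax2) rr.push_back(std::sqrt(r2));
    }
  return wrap(rr);
}

// psi_k bond-orientational order: |mean_j exp(i k phi_ij)| per molecule,
// averaged over molecules with at least one neighbor within `cutoff`.
// Returns the order parameter and the number of neighborless molecules.
// [[Rcpp::export]]
List cpp_bond_order(NumericMatrix pos, NumericVector box, int k,
                    double cutoff) {
  int n = pos.nrow();
  double c2 = cutoff * cutoff;
  double acc = 0.0;
  int lonely = 0;
  for (int i = 0; i < n; ++i) {
    double sre = 0.0, sim = 0.0;
    int nb = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
      min_image(dx, dy, box[0], box[1]);
      if (dx * dx + dy * dy > c2) continue;
      double phi = std::atan2(dy, dx);
      sre += std::cos(k * phi);
      sim += std::sin(k * phi);
      ++nb;
    }
    if (nb == 0) { ++lonely; continue; }
    acc += std::sqrt(sre * sre + sim * sim) / nb;
  }
  return List::create(_["psi"] = acc / n, _["n_neighborless"] = lonely);
}
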