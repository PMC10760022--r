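// Metropolis kernel on the modified prior.
//
// Full rescoring per step: excluded volume over bead pairs (pairs within one
// rigid body exempt), one-sided harmonic chain connectivity, and the
// sigmoid crosslink term for the prior-set crosslinks.  Proposals translate
// one flexible bead (isotropic Gaussian) or translate-and-rotate one rigid
// body about its centroid.  All randomness comes from R's RNG so runs are
// reproducible from R seeds.  An R reference implementation of the same
// kernel exists for cross-validation in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

double score_coords(const double* x, const double* y, const double* z,
                    int n,
                    const NumericVector& radius,
                    const IntegerVector& rb_id,
                    const IntegerVector& conn_i,
                    const IntegerVector& conn_j,
                    const NumericVector& conn_rest,
                    const IntegerVector& pxl_i,
                    const IntegerVector& pxl_j,
                    double d0, double slope, double omega,
                    double k_ev, double k_conn) {
  double s = 0.0;

  if (k_ev > 0.0) {
    const double* r = radius.begin();
    const int* rb = rb_id.begin();
    for (int i = 0; i < n - 1; ++i) {
      const double xi = x[i], yi = y[i], zi = z[i], ri = r[i];
      const int rbi = rb[i];
      for (int j = i + 1; j < n; ++j) {
        if (rbi != 0 && rbi == rb[j]) continue;
        const double dx = xi - x[j];
        const double dy = yi - y[j];
        const double dz = zi - z[j];
        const double rs = ri + r[j];
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < rs * rs) {
          const double ov = rs - std::sqrt(d2);
          s -= 0.5 * k_ev * ov * ov;
        }
      }
    }
  }

  if (k_conn > 0.0) {
    for (int k = 0; k < conn_i.size(); ++k) {
      const int i = conn_i[k] - 1, j = conn_j[k] - 1;
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      const double dz = z[i] - z[j];
      const double stretch = std::sqrt(dx * dx + dy * dy + dz * dz) -
        conn_rest[k];
      if (stretch > 0.0) s -= 0.5 * k_conn * stretch * stretch;
    }
  }

  for (int k = 0; k < pxl_i.size(); ++k) {
    const int i = pxl_i[k] - 1, j = pxl_j[k] - 1;
    const double dx = x[i] - x[j];
    const double dy = y[i] - y[j];
    const double dz = z[i] - z[j];
    const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    s += std::log(omega + (1.0 - omega) / (1.0 + std::exp((d - d0) / slope)));
  }

  return s;
}


void random_axis(double* a) {
  double norm = 0.0;
  do {
    a[0] = norm_rand();
    a[1] = norm_rand();
    a[2] = norm_rand();
    norm = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
  } while (norm < 1e-12);
  a[0] /= norm; a[1] /= norm; a[2] /= norm;
}

}  // namespace

// [[Rcpp::export(name = ".mcmc_kernel_cpp")]]
List mcmc_kernel_cpp(NumericMatrix coords, int n_steps,
                     IntegerVector flex_idx, List rb_list,
                     NumericVector radius, IntegerVector rb_id,
                     IntegerVector conn_i, IntegerVector conn_j,
                     NumericVector conn_rest,
                     IntegerVector pxl_i, IntegerVector pxl_j,
                     double d0, double slope, double omega,
                     double k_ev, double k_conn,
                     double bead_step, double rb_trans_step,
                     double rb_rot_step) {
  RNGScope scope;
  NumericMatrix X = clone(coords);
  const int n = X.nrow();
  double* xc = X.begin();
  double* yc = xc + n;
  double* zc = xc + 2 * n;
  const int n_flex = flex_idx.size();
  const int n_rb = rb_list.size();
  const int n_units = n_flex + n_rb;

  double lp = score_coords(xc, yc, zc, n, radius, rb_id, conn_i, conn_j,
                           conn_rest, pxl_i, pxl_j, d0, slope, omega,
                           k_ev, k_conn);
  int accepted = 0;

  std::vector<double> keep_x, keep_y, keep_z;

  for (int step = 0; step < n_steps; ++step) {
    int u = (int)(unif_rand() * n_units);
    if (u >= n_units) u = n_units - 1;

    if (u < n_flex) {
      const int i = flex_idx[u] - 1;
      const double ox = xc[i], oy = yc[i], oz = zc[i];
      xc[i] += norm_rand() * bead_step;
      yc[i] += norm_rand() * bead_step;
      zc[i] += norm_rand() * bead_step;
      const double lpp = score_coords(xc, yc, zc, n, radius, rb_id, conn_i,
                                      conn_j, conn_rest, pxl_i, pxl_j, d0,
                                      slope, omega, k_ev, k_conn);
      if (lpp - lp > std::log(unif_rand())) {
        lp = lpp;
        ++accepted;
      } else {
        xc[i] = ox; yc[i] = oy; zc[i] = oz;
      }
    } else {
      IntegerVector idx = rb_list[u - n_flex];
      const int m = idx.size();
      keep_x.resize(m); keep_y.resize(m); keep_z.resize(m);
      double cx = 0.0, cy = 0.0, cz = 0.0;
      for (int k = 0; k < m; ++k) {
        const int i = idx[k] - 1;
        keep_x[k] = xc[i]; keep_y[k] = yc[i]; keep_z[k] = zc[i];
        cx += xc[i]; cy += yc[i]; cz += zc[i];
      }
      cx /= m; cy /= m; cz /= m;

      double axis[3];
      random_axis(axis);
      const double angle = norm_rand() * rb_rot_step;
      const double ca = std::cos(angle), sa = std::sin(angle);
      const double tx = cx + norm_rand() * rb_trans_step;
      const double ty = cy + norm_rand() * rb_trans_step;
      const double tz = cz + norm_rand() * rb_trans_step;

      for (int k = 0; k < m; ++k) {
        const int i = idx[k] - 1;
        const double px = keep_x[k] - cx, py = keep_y[k] - cy,
                     pz = keep_z[k] - cz;
        // Rodrigues: p cos a + (axis x p) sin a + axis (axis.p)(1 - cos a)
        const double dot = axis[0] * px + axis[1] * py + axis[2] * pz;
        const double crx = axis[1] * pz - axis[2] * py;
        const double cry = axis[2] * px - axis[0] * pz;
        const double crz = axis[0] * py - axis[1] * px;
        xc[i] = tx + px * ca + crx * sa + axis[0] * dot * (1.0 - ca);
        yc[i] = ty + py * ca + cry * sa + axis[1] * dot * (1.0 - ca);
        zc[i] = tz + pz * ca + crz * sa + axis[2] * dot * (1.0 - ca);
      }

      const double lpp = score_coords(xc, yc, zc, n, radius, rb_id, conn_i,
                                      conn_j, conn_rest, pxl_i, pxl_j, d0,
                                      slope, omega, k_ev, k_conn);
      if (lpp - lp > std::log(unif_rand())) {
        lp = lpp;
        ++accepted;
      } else {
        for (int k = 0; k < m; ++k) {
          const int i = idx[k] - 1;
          xc[i] = keep_x[k]; yc[i] = keep_y[k]; zc[i] = keep_z[k];
        }
      }
    }
  }

  return List::create(Named("coords") = X,
                      Named("log_modified_prior") = lp,
                      Named("accepted") = accepted);
}

// [[Rcpp::export(name = ".score_modified_prior_cpp")]]
double score_modified_prior_cpp(NumericMatrix coords,
                                NumericVector radius, IntegerVector rb_id,
                                IntegerVector conn_i, IntegerVector conn_j,
                                NumericVector conn_rest,
                                IntegerVector pxl_i, IntegerVector pxl_j,
                                double d0, double slope, double omega,
                                double k_ev, double k_conn) {
  const int n = coords.nrow();
  const double* xc = coords.begin();
  return score_coords(xc, xc + n, xc + 2 * n, n, radius, rb_id, conn_i,
                      conn_j, conn_rest, pxl_i, pxl_j, d0, slope, omega,
                      k_ev, k_conn);
}
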