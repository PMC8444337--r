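#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Overdamped Langevin dynamics on a 1-D polynomial potential with an
// accumulating well-tempered metadynamics bias. The bias potential and its
// derivative are kept on a fine uniform grid (linear interpolation between
// nodes); hills are also recorded individually so the R side can keep the
// exact unmerged register. Uses R's RNG (norm_rand), so runs are
// reproducible under set.seed().

static inline double poly_deriv(const NumericVector &c, double x) {
  double d = 0.0, xp = 1.0;
  for (int j = 1; j < c.size(); ++j) {
    d += j * c[j] * xp;
    xp *= x;
  }
  return d;
}

// [[Rcpp::export]]
List metad_langevin_cpp(NumericVector coefs, double n_steps_d, double dt,
                        double D, double kBT, double x0, double xmin,
                        double xmax, double dx, bool biased, double h0,
                        double sigma, double kB_dT, int stride_steps,
                        int record_stride) {
  const long n_steps = (long)n_steps_d;
  const int ngrid = (int)std::lround((xmax - xmin) / dx) + 1;
  std::vector<double> Vb(ngrid, 0.0), dVb(ngrid, 0.0);

  const double mob = D / kBT;              // mobility, A^2/fs per kcal/mol/A
  const double noise = std::sqrt(2.0 * D * dt);
  const double s2 = sigma * sigma;
  const int wing = (int)std::ceil(6.0 * sigma / dx);

  std::vector<double> rec_x, rec_t, hc, hh, ht;
  rec_x.reserve(n_steps / record_stride + 2);
  rec_t.reserve(n_steps / record_stride + 2);
  if (biased) {
    hc.reserve(n_steps / stride_steps + 2);
    hh.reserve(n_steps / stride_steps + 2);
    ht.reserve(n_steps / stride_steps + 2);
  }

  double x = x0;
  long error_step = -1;
  rec_x.push_back(x);
  rec_t.push_back(0.0);

  for (long step = 1; step <= n_steps; ++step) {
    // bias force by linear interpolation
    double fbias = 0.0;
    if (biased) {
      double u = (x - xmin) / dx;
      int i0 = (int)u;
      if (i0 >= ngrid - 1) i0 = ngrid - 2;
      double fr = u - i0;
      fbias = -(dVb[i0] * (1.0 - fr) + dVb[i0 + 1] * fr);
    }
    double f = -poly_deriv(coefs, x) + fbias;
    x += mob * f * dt + noise * norm_rand();
    if (x < xmin || x > xmax) {
      error_step = step;
      break;
    }
    if (biased && step % stride_steps == 0) {
      double u = (x - xmin) / dx;
      int i0 = (int)u;
      if (i0 >= ngrid - 1) i0 = ngrid - 2;
      double fr = u - i0;
      double vhere = Vb[i0] * (1.0 - fr) + Vb[i0 + 1] * fr;
      double h = h0 * std::exp(-vhere / kB_dT);
      int jc = (int)std::lround(u);
      int jlo = jc - wing < 0 ? 0 : jc - wing;
      int jhi = jc + wing >= ngrid ? ngrid - 1 : jc + wing;
      for (int j = jlo; j <= jhi; ++j) {
        double dxj = xmin + j * dx - x;
        double g = h * std::exp(-dxj * dxj / (2.0 * s2));
        Vb[j] += g;
        dVb[j] += -dxj / s2 * g;
      }
      hc.push_back(x);
      hh.push_back(h);
      ht.push_back(step * dt);
    }
    if (step % record_stride == 0) {
      rec_x.push_back(x);
      rec_t.push_back(step * dt);
    }
  }

  return List::create(
      _["cv"] = NumericVector(rec_x.begin(), rec_x.end()),
      _["cv_times"] = NumericVector(rec_t.begin(), rec_t.end()),
      _["hill_centers"] = NumericVector(hc.begin(), hc.end()),
      _["hill_heights"] = NumericVector(hh.begin(), hh.end()),
      _["hill_times"] = NumericVector(ht.begin(), ht.end()),
      _["bias_grid"] = NumericVector(Vb.begin(), Vb.end()),
      _["error_step"] = (double)error_step,
      _["x_final"] = x);
}
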