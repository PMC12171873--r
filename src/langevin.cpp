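#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) in a 2-D branching-channel potential:
//   U = kx*(x^2 - c^2*s(y))^2/c^4            flat stem splitting into two wells
//     - basin_depth*exp(-(x^2+y^2)/2*sb^2)   binding basin at the origin
//     - f*y                                  gentle egress tilt
//     + k_wall*(y - y_min)^2  for y < y_min  lower wall
//     + block*exp(...)                       optional branch-blocking barrier
// s(y) is a logistic switch opening the two branches beyond y_split.
// Absorbing exits at y >= y_exit; branch 1 = x < 0, branch 2 = x >= 0.
// Positions recorded every `stride` steps (step 0 and the absorbing step
// always included).  Uses R's RNG (norm_rand) for reproducibility.
// `wells` is a matrix with columns (x, y, depth, sigma): attractive
// Gaussian sites along the tunnel where the ligand dwells (metastable
// interaction sites); may have zero rows.
// [[Rcpp::export]]
List simulate_egress_cpp(double x0, double y0, int max_steps, int stride,
                         double dt, double D, double kT,
                         double kx, double c, double y_split, double w,
                         double f, double basin_depth, double basin_sigma,
                         double k_wall, double y_min, double y_exit,
                         double block_height, double block_x, double block_y,
                         double block_sigma, NumericMatrix wells) {
  std::vector<double> xs, ys;
  xs.reserve(max_steps / stride + 2);
  ys.reserve(max_steps / stride + 2);
  double x = x0, y = y0;
  double c2 = c * c, c4 = c2 * c2;
  double sb2 = basin_sigma * basin_sigma;
  double bl2 = block_sigma * block_sigma;
  double pref = D * dt / kT;
  double noise = std::sqrt(2.0 * D * dt);
  int branch = 0;
  int exit_step = NA_INTEGER;
  xs.push_back(x); ys.push_back(y);
  for (int t = 1; t <= max_steps; ++t) {
    double s = 1.0 / (1.0 + std::exp(-(y - y_split) / w));
    double sp = s * (1.0 - s) / w;
    double q = x * x - c2 * s;
    double dUdx = 4.0 * kx * x * q / c4;
    double dUdy = -2.0 * kx * q * c2 * sp / c4 - f;
    double g = basin_depth * std::exp(-(x * x + y * y) / (2.0 * sb2));
    dUdx += g * x / sb2;
    dUdy += g * y / sb2;
    if (y < y_min) dUdy += 2.0 * k_wall * (y - y_min);
    for (int wi = 0; wi < wells.nrow(); ++wi) {
      double wx = x - wells(wi, 0), wy = y - wells(wi, 1);
      double ws2 = wells(wi, 3) * wells(wi, 3);
      double gw = wells(wi, 2) * std::exp(-(wx * wx + wy * wy) / (2.0 * ws2));
      dUdx += gw * wx / ws2;
      dUdy += gw * wy / ws2;
    }
    if (block_height > 0.0) {
      double bx = x - block_x, by = y - block_y;
      double b = block_height * std::exp(-(bx * bx + by * by) / (2.0 * bl2));
      dUdx += -b * bx / bl2;
      dUdy += -b * by / bl2;
    }
    if (!std::isfinite(dUdx) || !std::isfinite(dUdy))
      stop("non-finite force encountered; rejecting channel specification");
    x += -pref * dUdx + noise * norm_rand();
    y += -pref * dUdy + noise * norm_rand();
    if (y >= y_exit) {
      branch = (x < 0.0) ? 1 : 2;
      exit_step = t;
      xs.push_back(x); ys.push_back(y);
      break;
    }
    if (t % stride == 0) { xs.push_back(x); ys.push_back(y); }
  }
  int nrec = xs.size();
  NumericMatrix coords(nrec, 2);
  for (int i = 0; i < nrec; ++i) { coords(i, 0) = xs[i]; coords(i, 1) = ys[i]; }
  return List::create(_["coords"] = coords, _["branch"] = branch,
                      _["exit_step"] = exit_step);
}
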