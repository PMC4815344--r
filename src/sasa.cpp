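#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Deterministic quasi-uniform point set on the unit sphere: golden-angle
// (Fibonacci) spiral. The same n always yields the same points, so ASA is
// reproducible bit-for-bit for a fixed n_points.
static void spiral_points(int n, std::vector<double>& px,
                          std::vector<double>& py, std::vector<double>& pz) {
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  px.resize(n); py.resize(n); pz.resize(n);
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n;  // midpoints of n equal-height bands
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * i;
    px[i] = r * std::cos(th);
    py[i] = r * std::sin(th);
    pz[i] = z;
  }
}

// Shrake-Rupley accessible surface area, one value per atom.
// xyz: n x 3 coordinates (Angstrom); radius: van der Waals radii;
// probe: solvent probe radius; n_points: test points per atom sphere.
// [[Rcpp::export]]
NumericVector sasa_atoms_cpp(NumericMatrix xyz, NumericVector radius,
                             double probe, int n_points) {
  int n = xyz.nrow();
  if (n == 0) stop("structure has no atoms");
  if (radius.size() != n) stop("radius length must match atom count");
  if (probe <= 0) stop("probe radius must be positive");
  if (n_points < 92) stop("n_points must be at least 92");

  std::vector<double> px, py, pz;
  spiral_points(n_points, px, py, pz);

  NumericVector out(n);
  std::vector<double> ex(n);  // expanded radii
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (radius[i] <= 0) stop("van der Waals radii must be positive");
    ex[i] = radius[i] + probe;
    if (ex[i] > rmax) rmax = ex[i];
  }

  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    double ri = ex[i];
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    // neighbours whose expanded sphere can occlude points on atom i's sphere
    nb.clear();
    double cut = ri + rmax;
    double cut2 = cut * cut;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < cut2) {
        double c = ri + ex[j];
        if (d2 < c * c) nb.push_back(j);
      }
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = xi + ri * px[k], qy = yi + ri * py[k], qz = zi + ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double dx = qx - xyz(j, 0), dy = qy - xyz(j, 1), dz = qz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < ex[j] * ex[j]) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * ((double)acc / (double)n_points);
  }
  return out;
}
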