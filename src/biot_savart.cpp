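#include <Rcpp.h>
using namespace Rcpp;

// Regularized Biot-Savart summation over straight filament segments
// (midpoint rule). All geometry in metres; circulation in m^2/s; output m/s.
//
// The Gaussian (Lamb-Oseen-type) core factor 1 - exp(-r^2 / (2 sigma^2))
// removes the 1/r singularity: the induced speed stays bounded even for
// evaluation points on a filament node. Segments farther than ~7 core radii
// contribute the bare kernel (the factor is 1 to machine precision there),
// which lets us skip the exp() for almost all pairs.
//
// points: N x 3, seg_a/seg_b: M x 3 segment endpoints, gamma: length-M signed
// circulation carried by each segment's parent filament, core: length-M core
// radius sigma (m).
// [[Rcpp::export(name = ".bs_velocity_cpp")]]
NumericMatrix bs_velocity_cpp(const NumericMatrix& points,
                              const NumericMatrix& seg_a,
                              const NumericMatrix& seg_b,
                              const NumericVector& gamma,
                              const NumericVector& core) {
  const int n = points.nrow();
  const int m = seg_a.nrow();
  if (seg_b.nrow() != m || gamma.size() != m || core.size() != m)
    stop("segment arrays must have matching lengths");

  NumericMatrix out(n, 3);
  const double c4pi = 1.0 / (4.0 * M_PI);

  std::vector<double> mx(m), my(m), mz(m), dlx(m), dly(m), dlz(m),
      gam(m), s2(m), far2(m);
  for (int j = 0; j < m; ++j) {
    dlx[j] = seg_b(j, 0) - seg_a(j, 0);
    dly[j] = seg_b(j, 1) - seg_a(j, 1);
    dlz[j] = seg_b(j, 2) - seg_a(j, 2);
    mx[j] = 0.5 * (seg_a(j, 0) + seg_b(j, 0));
    my[j] = 0.5 * (seg_a(j, 1) + seg_b(j, 1));
    mz[j] = 0.5 * (seg_a(j, 2) + seg_b(j, 2));
    gam[j] = gamma[j] * c4pi;
    s2[j] = 2.0 * core[j] * core[j];
    far2[j] = 50.0 * core[j] * core[j];  // exp(-25) ~ 1e-11: factor == 1
  }

  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1), pz = points(i, 2);
    double ux = 0.0, uy = 0.0, uz = 0.0;
    for (int j = 0; j < m; ++j) {
      const double rx = px - mx[j], ry = py - my[j], rz = pz - mz[j];
      const double r2 = rx * rx + ry * ry + rz * rz;
      if (r2 < 1e-30) continue;  // on a node: dl x r vanishes as well
      const double r3inv = 1.0 / (r2 * std::sqrt(r2));
      double w = gam[j] * r3inv;
      if (r2 < far2[j]) w *= 1.0 - std::exp(-r2 / s2[j]);
      ux += w * (dly[j] * rz - dlz[j] * ry);
      uy += w * (dlz[j] * rx - dlx[j] * rz);
      uz += w * (dlx[j] * ry - dly[j] * rx);
    }
    out(i, 0) = ux;
    out(i, 1) = uy;
    out(i, 2) = uz;
  }
  return out;
}
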