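#include <Rcpp.h>
using namespace Rcpp;

// Relative difference prior over unordered 6-neighbour pairs:
//   U(f) = sum_{j<k adj} (f_j - f_k)^2 / (f_j + f_k + gamma*|f_j - f_k| + eps)
// f is a 3D array passed with its dimensions.

// [[Rcpp::export]]
double rdp_penalty_c(NumericVector f, IntegerVector dim, double gamma,
                     double eps) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double *x = f.begin();
  double val = 0.0;
  const int s1 = 1, s2 = n1, s3 = n1 * n2;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const int idx = i * s1 + j * s2 + k * s3;
        const double a = x[idx];
        if (i + 1 < n1) {
          const double b = x[idx + s1], d = a - b;
          val += d * d / (a + b + gamma * std::fabs(d) + eps);
        }
        if (j + 1 < n2) {
          const double b = x[idx + s2], d = a - b;
          val += d * d / (a + b + gamma * std::fabs(d) + eps);
        }
        if (k + 1 < n3) {
          const double b = x[idx + s3], d = a - b;
          val += d * d / (a + b + gamma * std::fabs(d) + eps);
        }
      }
  return val;
}

// gradient of rdp_penalty_c; per pair (a, b) the derivative w.r.t. a is
//   (a - b) * (a + 3b + gamma*|a - b| + 2*eps) / (a + b + gamma*|a - b| + eps)^2
// and the pair contributes the mirrored term to b.

// [[Rcpp::export]]
NumericVector rdp_gradient_c(NumericVector f, IntegerVector dim, double gamma,
                             double eps) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double *x = f.begin();
  NumericVector out(f.size());
  double *g = out.begin();
  const int s1 = 1, s2 = n1, s3 = n1 * n2;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        const int idx = i * s1 + j * s2 + k * s3;
        const double a = x[idx];
        for (int ax = 0; ax < 3; ++ax) {
          int step;
          bool ok;
          if (ax == 0) { step = s1; ok = i + 1 < n1; }
          else if (ax == 1) { step = s2; ok = j + 1 < n2; }
          else { step = s3; ok = k + 1 < n3; }
          if (!ok) continue;
          const double b = x[idx + step];
          const double d = a - b;
          const double ad = std::fabs(d);
          const double q = a + b + gamma * ad + eps;
          const double q2 = q * q;
          g[idx] += d * (a + 3.0 * b + gamma * ad + 2.0 * eps) / q2;
          g[idx + step] += -d * (b + 3.0 * a + gamma * ad + 2.0 * eps) / q2;
        }
      }
  out.attr("dim") = dim;
  return out;
}

// anterior attenuation-factor array for an internal-layout [y, x, z]
// attenuation map: att[y,x,z] = exp(-vox * (cumsum_y(mu) - mu/2)),
// the midpoint (half self-voxel) line-integral convention

// [[Rcpp::export]]
NumericVector att_factors_c(NumericVector mu, IntegerVector dim, double vox) {
  const int ny = dim[0], nxz = dim[1] * dim[2];
  const double *m = mu.begin();
  NumericVector out(mu.size());
  double *a = out.begin();
  for (int c = 0; c < nxz; ++c) {
    const int base = c * ny;
    double cum = 0.0;
    for (int y = 0; y < ny; ++y) {
      const double v = m[base + y];
      cum += v;
      a[base + y] = std::exp(-vox * (cum - 0.5 * v));
    }
  }
  out.attr("dim") = dim;
  return out;
}

// back-projection spread: out[y,x,z] = att[y,x,z] * p[z,x]
// (p is the (nz, nx) projection matrix)

// [[Rcpp::export]]
NumericVector spread_weight_c(NumericMatrix p, NumericVector att,
                              IntegerVector dim) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  NumericVector out(att.size());
  const double *a = att.begin();
  double *o = out.begin();
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const double pv = p(z, x);
      const int base = (z * nx + x) * ny;
      for (int y = 0; y < ny; ++y) o[base + y] = a[base + y] * pv;
    }
  out.attr("dim") = dim;
  return out;
}

// attenuated anterior ray sum: out[z,x] = sens * vox * sum_y act*att

// [[Rcpp::export]]
NumericMatrix project_sum_c(NumericVector act, NumericVector att,
                            IntegerVector dim, double scale) {
  const int ny = dim[0], nx = dim[1], nz = dim[2];
  const double *f = act.begin(), *a = att.begin();
  NumericMatrix out(nz, nx);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const int base = (z * nx + x) * ny;
      double s = 0.0;
      for (int y = 0; y < ny; ++y) s += f[base + y] * a[base + y];
      out(z, x) = scale * s;
    }
  return out;
}
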