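#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parallel-beam forward projection of a 2D slice f(nz, nx) at the given
// angles (radians). Detector coordinate u runs along the rotated x axis
// (nu = nx detector pixels, same sampling as the grid); rays integrate
// along the rotated z axis with unit (1 voxel) steps and bilinear
// interpolation. Rotation by angle t maps ray sample s on detector u to
//   x = cx + u*cos(t) - s*sin(t),  z = cz + u*sin(t) + s*cos(t).
// [[Rcpp::export(name = ".forwardProject2d")]]
NumericMatrix forward_project_2d(NumericMatrix f, NumericVector angles) {
  const int nz = f.nrow(), nx = f.ncol();
  const int nu = nx, na = angles.size();
  const double cz = 0.5 * (nz - 1), cx = 0.5 * (nx - 1);
  const int ns = (int)std::ceil(std::hypot((double)nz, (double)nx)) + 2;
  const double s0 = -0.5 * (ns - 1);
  NumericMatrix out(nu, na);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int iu = 0; iu < nu; ++iu) {
      const double u = iu - cx;
      double acc = 0.0;
      for (int is = 0; is < ns; ++is) {
        const double s = s0 + is;
        const double x = cx + u * ct - s * st;
        const double z = cz + u * st + s * ct;
        // zero-padded bilinear: points within one voxel of the border
        // still collect the in-bounds share of their interpolation
        if (x <= -1 || x >= nx || z <= -1 || z >= nz) continue;
        const int x0 = (int)std::floor(x), z0 = (int)std::floor(z);
        const double fx = x - x0, fz = z - z0;
        const double w00 = (1 - fz) * (1 - fx), w01 = (1 - fz) * fx;
        const double w10 = fz * (1 - fx), w11 = fz * fx;
        if (z0 >= 0 && x0 >= 0) acc += w00 * f(z0, x0);
        if (z0 >= 0 && x0 + 1 < nx) acc += w01 * f(z0, x0 + 1);
        if (z0 + 1 < nz && x0 >= 0) acc += w10 * f(z0 + 1, x0);
        if (z0 + 1 < nz && x0 + 1 < nx) acc += w11 * f(z0 + 1, x0 + 1);
      }
      out(iu, a) = acc;
    }
  }
  return out;
}

// Backprojection (adjoint-style, with linear interpolation on the
// detector) of a sinogram p(nu, na) onto an (nz, nx) grid.
// [[Rcpp::export(name = ".backProject2d")]]
NumericMatrix back_project_2d(NumericMatrix p, NumericVector angles,
                              int nz, int nx) {
  const int nu = p.nrow(), na = p.ncol();
  const double cz = 0.5 * (nz - 1), cx = 0.5 * (nx - 1);
  const double cu = 0.5 * (nu - 1);
  NumericMatrix out(nz, nx);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int ix = 0; ix < nx; ++ix) {
      const double xr = ix - cx;
      for (int iz = 0; iz < nz; ++iz) {
        const double zr = iz - cz;
        const double u = xr * ct + zr * st + cu;
        if (u <= -1 || u >= nu) continue;
        const int u0 = (int)std::floor(u);
        const double fu = u - u0;
        if (u0 >= 0) out(iz, ix) += (1 - fu) * p(u0, a);
        if (u0 + 1 < nu) out(iz, ix) += fu * p(u0 + 1, a);
      }
    }
  }
  return out;
}
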