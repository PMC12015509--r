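#include <Rcpp.h>
using namespace Rcpp;

// Real-space projection geometry.
//
// Conventions (must stay in sync with the R layer):
//  - volumes are N x N x N column-major arrays, voxel (i,j,k) 0-based;
//  - the rotation/projection center sits at c = floor(N/2) on every axis;
//  - a rotation R moves centered voxel coordinates x -> R x; the projector
//    deposits every voxel's density at its rotated position with trilinear
//    splatting (voxels carried outside the grid are clipped) and sums the
//    result along the third (k) axis, so image x/y match volume x/y at the
//    identity pose and the identity projection preserves total intensity
//    exactly;
//  - cpp_rotate_backproject is the exact adjoint (trilinear gather).

// [[Rcpp::export]]
NumericMatrix cpp_rotate_project(NumericVector vol, NumericMatrix R, int N) {
  NumericMatrix img(N, N);
  const double *v = vol.begin();
  double c = std::floor(N / 2.0);
  double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  double r20 = R(2, 0), r21 = R(2, 1), r22 = R(2, 2);
  for (int k = 0; k < N; ++k) {
    double pz = k - c;
    for (int j = 0; j < N; ++j) {
      double py = j - c;
      for (int i = 0; i < N; ++i) {
        double val = v[i + (size_t)N * (j + (size_t)N * k)];
        if (val == 0.0) continue;
        double px = i - c;
        double x = r00 * px + r01 * py + r02 * pz + c;
        double y = r10 * px + r11 * py + r12 * pz + c;
        double z = r20 * px + r21 * py + r22 * pz + c;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        double fx = x - x0, fy = y - y0, fz = z - z0;
        for (int dz = 0; dz < 2; ++dz) {
          int zz = z0 + dz;
          if (zz < 0 || zz >= N) continue;  // clipped in z like the volume splat
          double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy < 2; ++dy) {
            int yy = y0 + dy;
            if (yy < 0 || yy >= N) continue;
            double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx < 2; ++dx) {
              int xx = x0 + dx;
              if (xx < 0 || xx >= N) continue;
              double wx = dx ? fx : 1.0 - fx;
              img(xx, yy) += val * wx * wy * wz;
            }
          }
        }
      }
    }
  }
  return img;
}

// Exact adjoint of cpp_rotate_project: gathers an image-space gradient into
// volume space through the same trilinear weights.
// [[Rcpp::export]]
NumericVector cpp_rotate_backproject(NumericMatrix img, NumericMatrix R, int N) {
  NumericVector vol((size_t)N * N * N);
  double *v = vol.begin();
  double c = std::floor(N / 2.0);
  double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  double r20 = R(2, 0), r21 = R(2, 1), r22 = R(2, 2);
  for (int k = 0; k < N; ++k) {
    double pz = k - c;
    for (int j = 0; j < N; ++j) {
      double py = j - c;
      for (int i = 0; i < N; ++i) {
        double px = i - c;
        double x = r00 * px + r01 * py + r02 * pz + c;
        double y = r10 * px + r11 * py + r12 * pz + c;
        double z = r20 * px + r21 * py + r22 * pz + c;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        double fx = x - x0, fy = y - y0, fz = z - z0;
        double acc = 0.0;
        for (int dz = 0; dz < 2; ++dz) {
          int zz = z0 + dz;
          if (zz < 0 || zz >= N) continue;
          double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy < 2; ++dy) {
            int yy = y0 + dy;
            if (yy < 0 || yy >= N) continue;
            double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx < 2; ++dx) {
              int xx = x0 + dx;
              if (xx < 0 || xx >= N) continue;
              double wx = dx ? fx : 1.0 - fx;
              acc += wx * wy * wz * img(xx, yy);
            }
          }
        }
        v[i + (size_t)N * (j + (size_t)N * k)] = acc;
      }
    }
  }
  vol.attr("dim") = IntegerVector::create(N, N, N);
  return vol;
}

// Full rotated volume by trilinear splatting; utility for tests.
// [[Rcpp::export]]
NumericVector cpp_rotate_volume(NumericVector vol, NumericMatrix R, int N) {
  NumericVector out((size_t)N * N * N);
  const double *v = vol.begin();
  double *o = out.begin();
  double c = std::floor(N / 2.0);
  double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  double r20 = R(2, 0), r21 = R(2, 1), r22 = R(2, 2);
  for (int k = 0; k < N; ++k) {
    double pz = k - c;
    for (int j = 0; j < N; ++j) {
      double py = j - c;
      for (int i = 0; i < N; ++i) {
        double val = v[i + (size_t)N * (j + (size_t)N * k)];
        if (val == 0.0) continue;
        double px = i - c;
        double x = r00 * px + r01 * py + r02 * pz + c;
        double y = r10 * px + r11 * py + r12 * pz + c;
        double z = r20 * px + r21 * py + r22 * pz + c;
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
            z0 = (int)std::floor(z);
        double fx = x - x0, fy = y - y0, fz = z - z0;
        for (int dz = 0; dz < 2; ++dz) {
          int zz = z0 + dz;
          if (zz < 0 || zz >= N) continue;
          double wz = dz ? fz : 1.0 - fz;
          for (int dy = 0; dy < 2; ++dy) {
            int yy = y0 + dy;
            if (yy < 0 || yy >= N) continue;
            double wy = dy ? fy : 1.0 - fy;
            for (int dx = 0; dx < 2; ++dx) {
              int xx = x0 + dx;
              if (xx < 0 || xx >= N) continue;
              double wx = dx ? fx : 1.0 - fx;
              o[xx + (size_t)N * (yy + (size_t)N * zz)] += val * wx * wy * wz;
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(N, N, N);
  return out;
}
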