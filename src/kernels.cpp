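// Low-level numerical kernels: 2D convolution forward/backward (im2col + BLAS),
// depthwise convolution, 3D connected components, mask dilation, surface
// voxel extraction and point-set minimum distances. All array arguments use
// R's column-major layout; images are (H, W, C, N).
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const double* x, int H, int W, int C,
                        int k, int stride, int pad, int Ho, int Wo) {
  arma::mat col(Ho * (arma::uword)Wo, (arma::uword)k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* dst = col.colptr(ki + k * (kj + k * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + ki - pad;
            if (hi < 0 || hi >= H) continue;
            dst[ho + (size_t)Ho * wo] = xc[hi + (size_t)H * wi];
          }
        }
      }
    }
  }
  return col;
}

static void col2im_add(const arma::mat& col, double* dx, int H, int W, int C,
                       int k, int stride, int pad, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* src = col.colptr(ki + k * (kj + k * c));
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - pad;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + ki - pad;
            if (hi < 0 || hi >= H) continue;
            xc[hi + (size_t)H * wi] += src[ho + (size_t)Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv2d_fwd: channel mismatch");
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)k * k * C, Cout, false);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo);
    arma::mat out = col * Wm;
    double* yp = y.begin() + (size_t)Ho * Wo * Cout * n;
    for (int co = 0; co < Cout; ++co) {
      const double* oc = out.colptr(co);
      double* yc = yp + (size_t)Ho * Wo * co;
      double bb = b[co];
      for (int i = 0; i < Ho * Wo; ++i) yc[i] = oc[i] + bb;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  int Ho = yd[0], Wo = yd[1];
  arma::mat Wm(const_cast<double*>(w.begin()), (arma::uword)k * k * C, Cout, false);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  arma::mat dW((arma::uword)k * k * C, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  for (int n = 0; n < N; ++n) {
    arma::mat col = im2col(x.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo);
    arma::mat dyM(const_cast<double*>(dy.begin()) + (size_t)Ho * Wo * Cout * n,
                  (arma::uword)Ho * Wo, Cout, false);
    dW += col.t() * dyM;
    db += arma::sum(dyM, 0).t();
    arma::mat dcol = dyM * Wm.t();
    col2im_add(dcol, dx.begin() + (size_t)H * W * C * n, H, W, C, k, stride, pad, Ho, Wo);
  }
  NumericVector dwv(dW.begin(), dW.end());
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
NumericVector dwconv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double bb = b[c];
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double acc = bb;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              acc += xc[hi + (size_t)H * wi] * wc[ki + k * kj];
            }
          }
          yc[ho + (size_t)Ho * wo] = acc;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int k = wd[0];
  int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw((size_t)k * k * C);
  dw.attr("dim") = wd;
  NumericVector db(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* wc = w.begin() + (size_t)k * k * c;
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* dwc = dw.begin() + (size_t)k * k * c;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dyc[ho + (size_t)Ho * wo];
          db[c] += g;
          for (int kj = 0; kj < k; ++kj) {
            int wi = wo * stride + kj - pad;
            if (wi < 0 || wi >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              int hi = ho * stride + ki - pad;
              if (hi < 0 || hi >= H) continue;
              dwc[ki + k * kj] += xc[hi + (size_t)H * wi] * g;
              dxc[hi + (size_t)H * wi] += wc[ki + k * kj] * g;
            }
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Connected components of a binary 3D array (Z = 1 gives 2D behaviour:
// connectivity 26 -> 8-connected in-plane, 6 -> 4-connected).
// [[Rcpp::export]]
IntegerVector label_components(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int X = d[0], Y = d[1], Z = (d.size() > 2) ? d[2] : 1;
  IntegerVector lab((size_t)X * Y * Z);
  lab.attr("dim") = IntegerVector::create(X, Y, Z);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < (size_t)X * Y * Z; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++next;
    stack.push_back(i);
    while (!stack.empty()) {
      size_t v = stack.back();
      stack.pop_back();
      int x = v % X, y = (v / X) % Y, z = v / ((size_t)X * Y);
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dyy = -1; dyy <= 1; ++dyy) {
          for (int dxx = -1; dxx <= 1; ++dxx) {
            if (dxx == 0 && dyy == 0 && dz == 0) continue;
            int nd = std::abs(dxx) + std::abs(dyy) + std::abs(dz);
            if (connectivity == 6 && nd != 1) continue;
            int nx = x + dxx, ny = y + dyy, nz = z + dz;
            if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
            size_t u = nx + (size_t)X * (ny + (size_t)Y * nz);
            if (mask[u] && lab[u] == 0) {
              lab[u] = next;
              stack.push_back(u);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Morphological dilation of a binary 3D array by one voxel.
// [[Rcpp::export]]
LogicalVector dilate_mask(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  int X = d[0], Y = d[1], Z = (d.size() > 2) ? d[2] : 1;
  LogicalVector out = clone(mask);
  out.attr("dim") = mask.attr("dim");
  for (int z = 0; z < Z; ++z) {
    for (int y = 0; y < Y; ++y) {
      for (int x = 0; x < X; ++x) {
        size_t v = x + (size_t)X * (y + (size_t)Y * z);
        if (!mask[v]) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          for (int dyy = -1; dyy <= 1; ++dyy) {
            for (int dxx = -1; dxx <= 1; ++dxx) {
              int nd = std::abs(dxx) + std::abs(dyy) + std::abs(dz);
              if (nd == 0 || (connectivity == 6 && nd != 1)) continue;
              int nx = x + dxx, ny = y + dyy, nz = z + dz;
              if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
              out[nx + (size_t)X * (ny + (size_t)Y * nz)] = true;
            }
          }
        }
      }
    }
  }
  return out;
}

// Surface voxels: foreground voxels with at least one in-bounds face
// neighbour in the background. If every foreground voxel is interior the
// caller falls back to the full mask.
// [[Rcpp::export]]
LogicalVector surface_voxels(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int X = d[0], Y = d[1], Z = (d.size() > 2) ? d[2] : 1;
  LogicalVector out((size_t)X * Y * Z);
  out.attr("dim") = mask.attr("dim");
  const int off[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int z = 0; z < Z; ++z) {
    for (int y = 0; y < Y; ++y) {
      for (int x = 0; x < X; ++x) {
        size_t v = x + (size_t)X * (y + (size_t)Y * z);
        if (!mask[v]) continue;
        bool surf = false;
        for (int j = 0; j < 6 && !surf; ++j) {
          int nx = x + off[j][0], ny = y + off[j][1], nz = z + off[j][2];
          if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z) continue;
          if (!mask[nx + (size_t)X * (ny + (size_t)Y * nz)]) surf = true;
        }
        out[v] = surf;
      }
    }
  }
  return out;
}

// For each row of A (n x 3, physical coordinates), the minimum Euclidean
// distance to any row of B.
// [[Rcpp::export]]
NumericVector min_point_dists(NumericMatrix A, NumericMatrix B) {
  int nA = A.nrow(), nB = B.nrow();
  NumericVector out(nA);
  for (int i = 0; i < nA; ++i) {
    double best = R_PosInf;
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < nB; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double dd = dx * dx + dy * dy + dz * dz;
      if (dd < best) best = dd;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
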