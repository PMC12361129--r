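// Building blocks for the 3D U-Net regressor: same-padded 3x3x3 convolution
// (im2col + GEMM), 2x2x2 max pooling, and kernel-2 stride-2 transposed
// convolution, each with the backward passes needed for training.
//
// Tensor layout everywhere: R numeric array with dim (d1, d2, d3, C),
// column-major, spatial index fastest. Weight layout for conv3: array
// (3, 3, 3, C_in, C_out); for upconv2: (2, 2, 2, C_in, C_out).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// colT(n, o + 27*c) = x[i+oi, j+oj, k+ok, c] with zero padding,
// n = i + d1*j + d1*d2*k, o = (oi+1) + 3*(oj+1) + 9*(ok+1), offsets in -1..1.
static arma::mat im2colT(const double* x, int d1, int d2, int d3, int C) {
  const arma::uword N = (arma::uword)d1 * d2 * d3;
  arma::mat colT(N, 27 * (arma::uword)C);
  for (int c = 0; c < C; c++) {
    const double* xc = x + N * (arma::uword)c;
    for (int ok = -1; ok <= 1; ok++) {
      for (int oj = -1; oj <= 1; oj++) {
        for (int oi = -1; oi <= 1; oi++) {
          int o = (oi + 1) + 3 * (oj + 1) + 9 * (ok + 1);
          double* dst = colT.colptr(o + 27 * (arma::uword)c);
          for (int k = 0; k < d3; k++) {
            int kk = k + ok;
            for (int j = 0; j < d2; j++) {
              int jj = j + oj;
              arma::uword base = (arma::uword)d1 * (j + (arma::uword)d2 * k);
              if (kk < 0 || kk >= d3 || jj < 0 || jj >= d2) {
                std::fill(dst + base, dst + base + d1, 0.0);
                continue;
              }
              const double* src = xc + (arma::uword)d1 * (jj + (arma::uword)d2 * kk);
              if (oi == 0) {
                std::copy(src, src + d1, dst + base);
              } else if (oi == 1) {
                std::copy(src + 1, src + d1, dst + base);
                dst[base + d1 - 1] = 0.0;
              } else {
                dst[base] = 0.0;
                std::copy(src, src + d1 - 1, dst + base + 1);
              }
            }
          }
        }
      }
    }
  }
  return colT;
}

// Scatter-add transpose of im2colT: xg[ii,jj,kk,c] += g(n, o + 27c).
static void col2imT(const arma::mat& g, double* xg, int d1, int d2, int d3, int C) {
  const arma::uword N = (arma::uword)d1 * d2 * d3;
  for (int c = 0; c < C; c++) {
    double* xc = xg + N * (arma::uword)c;
    for (int ok = -1; ok <= 1; ok++) {
      for (int oj = -1; oj <= 1; oj++) {
        for (int oi = -1; oi <= 1; oi++) {
          int o = (oi + 1) + 3 * (oj + 1) + 9 * (ok + 1);
          const double* src = g.colptr(o + 27 * (arma::uword)c);
          for (int k = 0; k < d3; k++) {
            int kk = k + ok;
            if (kk < 0 || kk >= d3) continue;
            for (int j = 0; j < d2; j++) {
              int jj = j + oj;
              if (jj < 0 || jj >= d2) continue;
              arma::uword base = (arma::uword)d1 * (j + (arma::uword)d2 * k);
              double* dstrow = xc + (arma::uword)d1 * (jj + (arma::uword)d2 * kk);
              const double* s = src + base;
              int i0 = (oi == -1) ? 1 : 0;          // ii = i + oi must stay in range
              int i1 = (oi == 1) ? d1 - 1 : d1;
              for (int i = i0; i < i1; i++) dstrow[i + oi] += s[i];
            }
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (d1, d2, d3, channels)");
  return d;
}

// [[Rcpp::export]]
NumericVector conv3_fwd(NumericVector x, NumericVector W, NumericVector b) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = W.attr("dim");
  int d1 = xd[0], d2 = xd[1], d3 = xd[2], Cin = xd[3], Cout = wd[4];
  if (wd[3] != Cin) stop("weight C_in does not match input channels");
  const arma::uword N = (arma::uword)d1 * d2 * d3;
  arma::mat colT = im2colT(x.begin(), d1, d2, d3, Cin);
  arma::mat Wm(W.begin(), 27 * (arma::uword)Cin, Cout, false);
  arma::mat out = colT * Wm;                       // N x Cout
  for (int co = 0; co < Cout; co++) out.col(co) += b[co];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(d1, d2, d3, Cout);
  return res;
}

// [[Rcpp::export]]
List conv3_bwd(NumericVector x, NumericVector dy, NumericVector W) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = W.attr("dim");
  int d1 = xd[0], d2 = xd[1], d3 = xd[2], Cin = xd[3], Cout = wd[4];
  const arma::uword N = (arma::uword)d1 * d2 * d3;
  arma::mat colT = im2colT(x.begin(), d1, d2, d3, Cin);
  arma::mat dY(dy.begin(), N, Cout, false);
  arma::mat Wm(W.begin(), 27 * (arma::uword)Cin, Cout, false);

  arma::mat dW = colT.t() * dY;                    // K x Cout
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dcolT = dY * Wm.t();                   // N x K

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  col2imT(dcolT, dx.begin(), d1, d2, d3, Cin);

  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dW"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export]]
List pool2_fwd(NumericVector x) {
  IntegerVector xd = dims4(x);
  int d1 = xd[0], d2 = xd[1], d3 = xd[2], C = xd[3];
  if (d1 % 2 || d2 % 2 || d3 % 2) stop("pooling needs even spatial dims");
  int e1 = d1 / 2, e2 = d2 / 2, e3 = d3 / 2;
  arma::uword No = (arma::uword)e1 * e2 * e3 * C;
  NumericVector out(No);
  IntegerVector idx(No);                           // 0-based argmax into x
  const double* xp = x.begin();
  arma::uword n = 0;
  for (int c = 0; c < C; c++) {
    arma::uword coff = (arma::uword)d1 * d2 * d3 * c;
    for (int k = 0; k < e3; k++) {
      for (int j = 0; j < e2; j++) {
        for (int i = 0; i < e1; i++) {
          double best = -1e300;
          arma::uword bidx = 0;
          for (int ok = 0; ok < 2; ok++) {
            for (int oj = 0; oj < 2; oj++) {
              for (int oi = 0; oi < 2; oi++) {
                arma::uword ii = coff + (2 * i + oi) +
                  (arma::uword)d1 * ((2 * j + oj) + (arma::uword)d2 * (2 * k + ok));
                if (xp[ii] > best) { best = xp[ii]; bidx = ii; }
              }
            }
          }
          out[n] = best;
          idx[n] = (int)bidx;
          n++;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(e1, e2, e3, C);
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector pool2_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  arma::uword Nx = (arma::uword)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx((R_xlen_t)Nx);
  dx.attr("dim") = xdim;
  for (R_xlen_t n = 0; n < dy.size(); n++) dx[idx[n]] += dy[n];
  return dx;
}

// [[Rcpp::export]]
NumericVector upconv2_fwd(NumericVector x, NumericVector W, NumericVector b) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = W.attr("dim");
  int d1 = xd[0], d2 = xd[1], d3 = xd[2], Cin = xd[3], Cout = wd[4];
  const arma::uword N = (arma::uword)d1 * d2 * d3;
  arma::mat X(x.begin(), N, Cin, false);
  int D1 = 2 * d1, D2 = 2 * d2, D3 = 2 * d3;
  NumericVector out((R_xlen_t)N * 8 * Cout);
  out.attr("dim") = IntegerVector::create(D1, D2, D3, Cout);
  double* op = out.begin();
  for (int ok = 0; ok < 2; ok++) {
    for (int oj = 0; oj < 2; oj++) {
      for (int oi = 0; oi < 2; oi++) {
        arma::mat Wo(Cin, Cout);
        for (int co = 0; co < Cout; co++)
          for (int ci = 0; ci < Cin; ci++)
            Wo(ci, co) = W[oi + 2 * (oj + 2 * (ok + 2 * (ci + (arma::uword)Cin * co)))];
        arma::mat Oo = X * Wo;                     // N x Cout
        for (int co = 0; co < Cout; co++) {
          const double* src = Oo.colptr(co);
          double bc = b[co];
          arma::uword coff = (arma::uword)D1 * D2 * D3 * co;
          for (int k = 0; k < d3; k++)
            for (int j = 0; j < d2; j++) {
              const double* s = src + (arma::uword)d1 * (j + (arma::uword)d2 * k);
              double* dst = op + coff + oi +
                (arma::uword)D1 * ((2 * j + oj) + (arma::uword)D2 * (2 * k + ok));
              for (int i = 0; i < d1; i++) dst[2 * i] = s[i] + bc;
            }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List upconv2_bwd(NumericVector x, NumericVector dy, NumericVector W) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = W.attr("dim");
  int d1 = xd[0], d2 = xd[1], d3 = xd[2], Cin = xd[3], Cout = wd[4];
  const arma::uword N = (arma::uword)d1 * d2 * d3;
  int D1 = 2 * d1, D2 = 2 * d2, D3 = 2 * d3;
  arma::mat X(x.begin(), N, Cin, false);
  arma::mat dX(N, Cin, arma::fill::zeros);
  NumericVector dWr(W.size());
  dWr.attr("dim") = wd;
  NumericVector db(Cout);
  const double* dyp = dy.begin();
  for (int ok = 0; ok < 2; ok++) {
    for (int oj = 0; oj < 2; oj++) {
      for (int oi = 0; oi < 2; oi++) {
        arma::mat dOo(N, Cout);
        for (int co = 0; co < Cout; co++) {
          double* dst = dOo.colptr(co);
          arma::uword coff = (arma::uword)D1 * D2 * D3 * co;
          for (int k = 0; k < d3; k++)
            for (int j = 0; j < d2; j++) {
              double* d = dst + (arma::uword)d1 * (j + (arma::uword)d2 * k);
              const double* s = dyp + coff + oi +
                (arma::uword)D1 * ((2 * j + oj) + (arma::uword)D2 * (2 * k + ok));
              for (int i = 0; i < d1; i++) d[i] = s[2 * i];
            }
        }
        arma::mat Wo(Cin, Cout);
        for (int co = 0; co < Cout; co++)
          for (int ci = 0; ci < Cin; ci++)
            Wo(ci, co) = W[oi + 2 * (oj + 2 * (ok + 2 * (ci + (arma::uword)Cin * co)))];
        dX += dOo * Wo.t();
        arma::mat dWo = X.t() * dOo;               // Cin x Cout
        for (int co = 0; co < Cout; co++) {
          for (int ci = 0; ci < Cin; ci++)
            dWr[oi + 2 * (oj + 2 * (ok + 2 * (ci + (arma::uword)Cin * co)))] = dWo(ci, co);
          db[co] += arma::accu(dOo.col(co));
        }
      }
    }
  }
  NumericVector dx(dX.begin(), dX.end());
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dW"] = dWr, _["db"] = db);
}
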