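// Low-level numeric kernels for the two-layer sparse predictive coding model.
//
// Layout conventions (shared with the R side):
//  * image / activity batches are cubes (H, W, n * C); slice index = i*C + ch
//    for image i (0-based), channel ch.
//  * a dictionary is a matrix (M, C*k*k); the patch vector for an output
//    position stacks channels outermost and is column-major within a kernel:
//    idx = ch*k*k + dc*k + dr.  This matches the R flattening of a
//    [k, k, C, M] array.
//  * pooling switch maps store the 0-based linear index of the winning input
//    element of the *unpadded* input cube, or -1 when the winner fell in the
//    zero padding (only possible when every real value in the window is
//    non-positive).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void im2col_image(const cube& x, int i, int C, int k, int stride,
                         int Hout, int Wout, mat& out, uword col0) {
  const int kk = k * k;
  for (int co = 0; co < Wout; ++co) {
    for (int ro = 0; ro < Hout; ++ro) {
      const uword col = col0 + (uword)co * Hout + ro;
      double* dst = out.colptr(col);
      for (int ch = 0; ch < C; ++ch) {
        for (int dc = 0; dc < k; ++dc) {
          for (int dr = 0; dr < k; ++dr) {
            dst[ch * kk + dc * k + dr] =
              x(ro * stride + dr, co * stride + dc, (uword)i * C + ch);
          }
        }
      }
    }
  }
}

static cube conv_forward_core(const cube& x, int C, const mat& W,
                              int k, int stride) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int n = x.n_slices / C;
  const int M = W.n_rows;
  const int Hout = (H - k) / stride + 1;
  const int Wout = (Wd - k) / stride + 1;
  if (Hout < 1 || Wout < 1) Rcpp::stop("kernel larger than input");
  const uword P = (uword)Hout * Wout;

  mat patches(W.n_cols, P * n);
  for (int i = 0; i < n; ++i)
    im2col_image(x, i, C, k, stride, Hout, Wout, patches, (uword)i * P);
  mat res = W * patches; // (M, P*n)

  cube out(Hout, Wout, (uword)n * M);
  for (int i = 0; i < n; ++i) {
    for (int m = 0; m < M; ++m) {
      double* dst = out.slice_memptr((uword)i * M + m);
      for (uword p = 0; p < P; ++p) dst[p] = res(m, (uword)i * P + p);
    }
  }
  return out;
}

static cube conv_transpose_core(const cube& g, int M, const mat& W,
                                int k, int stride, int C, int H, int Wd) {
  const int n = g.n_slices / M;
  const int Hout = g.n_rows, Wout = g.n_cols;
  const uword P = (uword)Hout * Wout;
  const int kk = k * k;

  mat gm(M, P * n);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < M; ++m) {
      const double* src = g.slice_memptr((uword)i * M + m);
      for (uword p = 0; p < P; ++p) gm(m, (uword)i * P + p) = src[p];
    }
  mat cols = W.t() * gm; // (C*k*k, P*n)

  cube out(H, Wd, (uword)n * C, fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int co = 0; co < Wout; ++co) {
      for (int ro = 0; ro < Hout; ++ro) {
        const uword col = (uword)i * P + (uword)co * Hout + ro;
        const double* src = cols.colptr(col);
        for (int ch = 0; ch < C; ++ch) {
          for (int dc = 0; dc < k; ++dc) {
            for (int dr = 0; dr < k; ++dr) {
              out(ro * stride + dr, co * stride + dc, (uword)i * C + ch) +=
                src[ch * kk + dc * k + dr];
            }
          }
        }
      }
    }
  }
  return out;
}

// ---------- pooling cores ----------

static void pool_spatial_core(const cube& x, int k, int stride,
                              int padT, int padL, int padB, int padR,
                              cube& out, cube& sw) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Hp = H + padT + padB, Wp = Wd + padL + padR;
  if (k < 1 || stride < 1) Rcpp::stop("empty pooling window");
  if ((Hp - k) % stride != 0 || (Wp - k) % stride != 0)
    Rcpp::stop("padded size incompatible with kernel/stride");
  const int Ho = (Hp - k) / stride + 1;
  const int Wo = (Wp - k) / stride + 1;
  const uword HW = (uword)H * Wd;

  out.set_size(Ho, Wo, x.n_slices);
  sw.set_size(Ho, Wo, x.n_slices);
  for (uword s = 0; s < x.n_slices; ++s) {
    for (int co = 0; co < Wo; ++co) {
      for (int ro = 0; ro < Ho; ++ro) {
        double best = -datum::inf;
        double bidx = -1.0;
        for (int dr = 0; dr < k; ++dr) {
          for (int dc = 0; dc < k; ++dc) {
            const int r = ro * stride + dr - padT;
            const int c = co * stride + dc - padL;
            const bool real = (r >= 0 && r < H && c >= 0 && c < Wd);
            const double v = real ? x(r, c, s) : 0.0;
            if (v > best) {
              best = v;
              bidx = real ? (double)(s * HW + (uword)c * H + r) : -1.0;
            }
          }
        }
        out(ro, co, s) = best;
        sw(ro, co, s) = bidx;
      }
    }
  }
}

static void pool_feat1d_core(const cube& x, int M, int k, cube& out, cube& sw) {
  if (k > M) Rcpp::stop("pooling kernel exceeds channel count");
  const int H = x.n_rows, Wd = x.n_cols;
  const int n = x.n_slices / M;
  const uword HW = (uword)H * Wd;

  out.set_size(H, Wd, x.n_slices);
  sw.set_size(H, Wd, x.n_slices);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < M; ++j) {
      for (int c = 0; c < Wd; ++c) {
        for (int r = 0; r < H; ++r) {
          double best = -datum::inf;
          uword bidx = 0;
          for (int d = 0; d < k; ++d) {
            const int m = (j + d) % M;
            const double v = x(r, c, (uword)i * M + m);
            if (v > best) {
              best = v;
              bidx = ((uword)i * M + m) * HW + (uword)c * H + r;
            }
          }
          out(r, c, (uword)i * M + j) = best;
          sw(r, c, (uword)i * M + j) = (double)bidx;
        }
      }
    }
  }
}

static void pool_feat2d_core(const cube& x, int M, int k, cube& out, cube& sw) {
  const int G = (int)std::lround(std::sqrt((double)M));
  if (G * G != M) Rcpp::stop("channel count must be a perfect square");
  const int H = x.n_rows, Wd = x.n_cols;
  const int n = x.n_slices / M;
  const uword HW = (uword)H * Wd;

  out.set_size(H, Wd, x.n_slices);
  sw.set_size(H, Wd, x.n_slices);
  for (int i = 0; i < n; ++i) {
    for (int gr = 0; gr < G; ++gr) {
      for (int gc = 0; gc < G; ++gc) {
        const int j = gr * G + gc;
        for (int c = 0; c < Wd; ++c) {
          for (int r = 0; r < H; ++r) {
            double best = -datum::inf;
            uword bidx = 0;
            for (int dr = 0; dr < k; ++dr) {
              for (int dc = 0; dc < k; ++dc) {
                const int m = ((gr + dr) % G) * G + ((gc + dc) % G);
                const double v = x(r, c, (uword)i * M + m);
                if (v > best) {
                  best = v;
                  bidx = ((uword)i * M + m) * HW + (uword)c * H + r;
                }
              }
            }
            out(r, c, (uword)i * M + j) = best;
            sw(r, c, (uword)i * M + j) = (double)bidx;
          }
        }
      }
    }
  }
}

static cube unpool_core(const cube& u, const cube& sw, int H, int Wd,
                        int nslices) {
  if (u.n_elem != sw.n_elem) Rcpp::stop("stale pooling assignment: shape mismatch");
  cube out(H, Wd, nslices, fill::zeros);
  for (uword idx = 0; idx < u.n_elem; ++idx) {
    const double b = sw[idx];
    if (b >= 0) out[(uword)b] += u[idx];
  }
  return out;
}

struct StageRec {
  int kind; // 0 identity, 1 spatial, 2 feat1d, 3 feat2d
  cube sw;
  int H, W, S; // input dims
};

static cube compose_pool(const cube& g, int n, const ivec& kind,
                         const ivec& kernel, const ivec& stride,
                         const imat& pads, std::vector<StageRec>& recs) {
  cube cur = g;
  recs.clear();
  for (uword si = 0; si < kind.n_elem; ++si) {
    StageRec rec;
    rec.kind = (int)kind[si];
    rec.H = cur.n_rows; rec.W = cur.n_cols; rec.S = cur.n_slices;
    const int M = cur.n_slices / n;
    cube out, sw;
    if (rec.kind == 0) {
      recs.push_back(std::move(rec));
      continue;
    } else if (rec.kind == 1) {
      pool_spatial_core(cur, kernel[si], stride[si], pads(si, 0), pads(si, 1),
                        pads(si, 2), pads(si, 3), out, sw);
    } else if (rec.kind == 2) {
      pool_feat1d_core(cur, M, kernel[si], out, sw);
    } else {
      pool_feat2d_core(cur, M, kernel[si], out, sw);
    }
    rec.sw = std::move(sw);
    recs.push_back(std::move(rec));
    cur = std::move(out);
  }
  return cur;
}

static cube uncompose_pool(const cube& u, const std::vector<StageRec>& recs) {
  cube cur = u;
  for (int i = (int)recs.size() - 1; i >= 0; --i) {
    if (recs[i].kind == 0) continue;
    cur = unpool_core(cur, recs[i].sw, recs[i].H, recs[i].W, recs[i].S);
  }
  return cur;
}

static inline void prox_nn(cube& z, double thr) {
  for (uword i = 0; i < z.n_elem; ++i) {
    const double v = z[i] - thr;
    z[i] = v > 0 ? v : 0;
  }
}

// ---------- exported primitives ----------

// correlation of x (H, W, n*C) with kernels W (M, C*k*k) -> (Hout, Wout, n*M)
// [[Rcpp::export]]
arma::cube cpp_conv_forward(const arma::cube& x, int C, const arma::mat& W,
                            int k, int stride) {
  return conv_forward_core(x, C, W, k, stride);
}

// transpose convolution (generative reconstruction)
// [[Rcpp::export]]
arma::cube cpp_conv_transpose(const arma::cube& g, int M, const arma::mat& W,
                              int k, int stride, int C, int H, int Wd) {
  return conv_transpose_core(g, M, W, k, stride, C, H, Wd);
}

// convolutional correlation of activities with an error map: the (negative)
// loss gradient with respect to the dictionary, (M, C*k*k)
// [[Rcpp::export]]
arma::mat cpp_dict_grad(const arma::cube& g, int M, const arma::cube& e, int C,
                        int k, int stride) {
  const int n = g.n_slices / M;
  const int Hout = g.n_rows, Wout = g.n_cols;
  const uword P = (uword)Hout * Wout;

  mat patches((uword)C * k * k, P * n);
  for (int i = 0; i < n; ++i)
    im2col_image(e, i, C, k, stride, Hout, Wout, patches, (uword)i * P);

  mat gm(M, P * n);
  for (int i = 0; i < n; ++i)
    for (int m = 0; m < M; ++m) {
      const double* src = g.slice_memptr((uword)i * M + m);
      for (uword p = 0; p < P; ++p) gm(m, (uword)i * P + p) = src[p];
    }
  return gm * patches.t();
}

// [[Rcpp::export]]
Rcpp::List cpp_pool_spatial(const arma::cube& x, int k, int stride,
                            int padT, int padL, int padB, int padR) {
  cube out, sw;
  pool_spatial_core(x, k, stride, padT, padL, padB, padR, out, sw);
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("sw") = sw);
}

// [[Rcpp::export]]
Rcpp::List cpp_pool_feat1d(const arma::cube& x, int M, int k) {
  cube out, sw;
  pool_feat1d_core(x, M, k, out, sw);
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("sw") = sw);
}

// [[Rcpp::export]]
Rcpp::List cpp_pool_feat2d(const arma::cube& x, int M, int k) {
  cube out, sw;
  pool_feat2d_core(x, M, k, out, sw);
  return Rcpp::List::create(Rcpp::Named("out") = out, Rcpp::Named("sw") = sw);
}

// [[Rcpp::export]]
arma::cube cpp_unpool(const arma::cube& u, const arma::cube& sw,
                      int H, int Wd, int nslices) {
  return unpool_core(u, sw, H, Wd, nslices);
}

// ---------- full inference loop ----------
//
// Monotone accelerated proximal gradient over the nonnegative sparse
// activities, alternating first/second-layer sweeps (Gauss-Seidel). A
// candidate is accepted only when its block objective (evaluated with the
// true max pooling) does not increase; otherwise the momentum sequence
// restarts at the current iterate. The loss trace is therefore
// non-increasing when the feedback term is active.
// [[Rcpp::export]]
Rcpp::List cpp_infer(const arma::cube& x, const arma::mat& W1, int k1, int s1,
                     const arma::mat& W2, int k2, int s2,
                     int M1, int M2, bool two,
                     const arma::ivec& st_kind, const arma::ivec& st_kernel,
                     const arma::ivec& st_stride, const arma::imat& st_pads,
                     double lam1, double lam2, double eta1, double eta2,
                     int cap, double tol, bool feedback) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int n = x.n_slices;
  const int H1 = (H - k1) / s1 + 1, W1d = (Wd - k1) / s1 + 1;

  cube gs(H1, W1d, (uword)n * M1, fill::zeros);
  cube eps_s = x; // x - 0
  cube gc, eps_c, pooled, recon_c;
  std::vector<StageRec> recs;
  int H2 = 0, W2d = 0;
  if (two) {
    pooled = compose_pool(gs, n, st_kind, st_kernel, st_stride, st_pads, recs);
    H2 = (pooled.n_rows - k2) / s2 + 1;
    W2d = (pooled.n_cols - k2) / s2 + 1;
    if (H2 < 1 || W2d < 1) Rcpp::stop("pooled map smaller than second-layer kernel");
    gc.zeros(H2, W2d, (uword)n * M2);
    recon_c.zeros(pooled.n_rows, pooled.n_cols, pooled.n_slices);
    eps_c = pooled;
  }
  cube ys = gs, yc = gc;
  double ts = 1, tc = 1;
  const bool use_fb = two && feedback;

  std::vector<double> trace;
  double prev = datum::nan;
  int inc_run = 0, it = 0;
  bool converged = false;

  while (true) {
    double F = 0.5 * accu(square(eps_s)) + lam1 * accu(gs);
    if (two) F = F + 0.5 * accu(square(eps_c)) + lam2 * accu(gc);
    trace.push_back(F);
    if (!std::isnan(prev)) {
      if (F > prev) ++inc_run; else inc_run = 0;
      if (inc_run > 10 && (!two || feedback))
        Rcpp::stop("inference diverged (loss increased for more than 10 "
                   "consecutive iterations); step sizes eta_S = %g, eta_C = %g",
                   eta1, eta2);
      if (std::abs(prev - F) <= tol * std::max(std::abs(prev), 1e-300)) {
        converged = true;
        break;
      }
    }
    prev = F;
    if (it >= cap) break;
    ++it;

    // ----- first-layer sweep
    {
      cube recon_ys = conv_transpose_core(ys, M1, W1, k1, s1, 1, H, Wd);
      cube grad = conv_forward_core(x - recon_ys, 1, W1, k1, s1);
      if (use_fb) {
        std::vector<StageRec> recs_y;
        cube pooled_y = compose_pool(ys, n, st_kind, st_kernel, st_stride, st_pads, recs_y);
        grad -= uncompose_pool(pooled_y - recon_c, recs_y);
      }
      cube zs = ys + eta1 * grad;
      prox_nn(zs, eta1 * lam1);
      cube recon_zs = conv_transpose_core(zs, M1, W1, k1, s1, 1, H, Wd);
      cube eps_zs = x - recon_zs;
      std::vector<StageRec> recs_z;
      cube pooled_z, eps_c_z;
      if (two) {
        pooled_z = compose_pool(zs, n, st_kind, st_kernel, st_stride, st_pads, recs_z);
        eps_c_z = pooled_z - recon_c;
      }
      double F_z = 0.5 * accu(square(eps_zs)) + lam1 * accu(zs);
      double F_x = 0.5 * accu(square(eps_s)) + lam1 * accu(gs);
      if (use_fb) {
        F_z += 0.5 * accu(square(eps_c_z));
        F_x += 0.5 * accu(square(eps_c));
      }
      const double t_new = (1 + std::sqrt(1 + 4 * ts * ts)) / 2;
      if (F_z <= F_x * (1 + 1e-12) + 1e-300) {
        ys = zs + ((ts - 1) / t_new) * (zs - gs);
        gs = std::move(zs);
        eps_s = std::move(eps_zs);
        if (two) {
          pooled = std::move(pooled_z);
          recs = std::move(recs_z);
          eps_c = pooled - recon_c;
        }
        ts = t_new;
      } else {
        ys = gs;
        ts = 1;
      }
      if (!gs.is_finite()) Rcpp::stop("non-finite activity encountered during inference");
    }

    // ----- second-layer sweep (lasso block given the pooled map)
    if (two) {
      cube recon_yc = conv_transpose_core(yc, M2, W2, k2, s2, M1,
                                          pooled.n_rows, pooled.n_cols);
      cube grad = conv_forward_core(pooled - recon_yc, M1, W2, k2, s2);
      cube zc = yc + eta2 * grad;
      prox_nn(zc, eta2 * lam2);
      cube recon_zc = conv_transpose_core(zc, M2, W2, k2, s2, M1,
                                          pooled.n_rows, pooled.n_cols);
      cube eps_c_zc = pooled - recon_zc;
      const double F_zc = 0.5 * accu(square(eps_c_zc)) + lam2 * accu(zc);
      const double F_xc = 0.5 * accu(square(eps_c)) + lam2 * accu(gc);
      const double t_new = (1 + std::sqrt(1 + 4 * tc * tc)) / 2;
      if (F_zc <= F_xc * (1 + 1e-12) + 1e-300) {
        yc = zc + ((tc - 1) / t_new) * (zc - gc);
        gc = std::move(zc);
        recon_c = std::move(recon_zc);
        eps_c = std::move(eps_c_zc);
        tc = t_new;
      } else {
        yc = gc;
        tc = 1;
      }
      if (!gc.is_finite()) Rcpp::stop("non-finite activity encountered during inference");
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("gs") = gs,
    Rcpp::Named("eps_s") = eps_s,
    Rcpp::Named("loss_trace") = trace,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
  if (two) {
    out["gc"] = gc;
    out["eps_c"] = eps_c;
    out["pooled"] = pooled;
  }
  return out;
}
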