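# Log-Gabor receptive-field model: log-normal radial envelope times Gaussian
# angular envelope in the frequency domain (single-sided, so the spatial
# filter is complex and its real/imaginary parts give the even/odd phases).

# complex spatial log-Gabor, orientation theta (radians, CCW from horizontal,
# matching make_grating), centred on the kernel
log_gabor_complex <- function(k, theta, f0, sigma_theta, sigma_f) {
  fr <- fft_freq(k); fc <- fft_freq(k)
  FR <- outer(fr, rep(1, k)); FC <- outer(rep(1, k), fc)
  f <- sqrt(FR^2 + FC^2)
  ang <- atan2(-FR, FC) # orientation of the plane wave at each bin
  d <- (ang - theta + pi) %% (2 * pi) - pi
  G <- ifelse(f > 1e-9,
              exp(-(log(pmax(f, 1e-9) / f0))^2 / (2 * sigma_f^2)) *
                exp(-d^2 / (2 * sigma_theta^2)),
              0)
  ctr <- (k + 1) / 2 - 1 # 0-based centre
  shift <- exp(-2i * pi * (FR * ctr + FC * ctr))
  h <- fft(G * shift, inverse = TRUE) / k^2
  h
}

#' Synthetic log-Gabor kernel
#'
#' Generates the real-valued spatial kernel of a log-Gabor filter with the
#' given preferred orientation, phase and frequency; useful for parameter
#' recovery checks and as an idealised simple-cell receptive field.
#'
#' @param k kernel side length in pixels.
#' @param theta preferred orientation, degrees.
#' @param phase preferred phase, degrees.
#' @param f0 preferred frequency, cycles/pixel.
#' @param sigma_theta angular envelope width (radians).
#' @param sigma_f radial (log-frequency) envelope width.
#' @param normalize rescale to unit Euclidean norm.
#' @return a `k x k` matrix.
#' @export
log_gabor_kernel <- function(k, theta, phase = 0, f0 = 0.2,
                             sigma_theta = 0.5, sigma_f = 0.4,
                             normalize = TRUE) {
  h <- log_gabor_complex(k, theta * pi / 180, f0, sigma_theta, sigma_f)
  ph <- phase * pi / 180
  out <- cos(ph) * Re(h) - sin(ph) * Im(h)
  if (normalize) out <- out / sqrt(sum(out^2))
  out
}

#' Fit a log-Gabor wavelet to a kernel
#'
#' Estimates a unit's preferred orientation, phase, spatial frequency and
#' bandwidths by least squares: for each candidate (theta, f0, bandwidths)
#' the even/odd pair of log-Gabor components is projected onto the kernel
#' (exact linear solve for amplitude and phase), a coarse grid picks the best
#' cell, and a Nelder-Mead search refines it. The orientation tuning HWHH
#' implied by the angular envelope is `sigma_theta * sqrt(2*log(2))`.
#'
#' @param kernel 2D numeric matrix (a receptive field).
#' @param theta_step grid resolution for orientation, degrees.
#' @param f_grid candidate frequencies, cycles/pixel.
#' @return a `"log_gabor_fit"`: `theta` (deg, `[0, 180)`), `phi` (deg,
#'   `[0, 360)`), `f0`, `sigma_theta`, `sigma_f`, `hwhh` (deg), `amplitude`,
#'   `residual` (relative), `fitted`.
#' @export
fit_log_gabor <- function(kernel, theta_step = 12,
                          f_grid = c(0.08, 0.11, 0.15, 0.2, 0.27, 0.36, 0.45)) {
  kernel <- as.matrix(kernel)
  k <- nrow(kernel)
  if (ncol(kernel) != k) stop("kernel must be square")
  knorm <- sqrt(sum(kernel^2))
  if (knorm < 1e-300) stop("all-zero kernel cannot be fitted")
  y <- as.numeric(kernel)

  solve_coefs <- function(h) {
    B <- cbind(as.numeric(Re(h)), as.numeric(Im(h)))
    g <- crossprod(B)
    if (rcond(g) < 1e-12) return(list(sse = sum(y^2), c = c(0, 0)))
    cf <- solve(g, crossprod(B, y))
    list(sse = sum((y - B %*% cf)^2), c = cf)
  }
  obj <- function(p) { # p = (theta_rad, log f0, log sig_t, log sig_f)
    h <- log_gabor_complex(k, p[1], exp(p[2]), exp(p[3]), exp(p[4]))
    solve_coefs(h)$sse
  }

  best <- NULL; best_sse <- Inf
  for (th in seq(0, 180 - theta_step, by = theta_step)) {
    for (f0 in f_grid) {
      for (st in c(0.35, 0.7)) {
        for (sf in c(0.3, 0.6)) {
          p <- c(th * pi / 180, log(f0), log(st), log(sf))
          v <- obj(p)
          if (v < best_sse) { best_sse <- v; best <- p }
        }
      }
    }
  }
  o <- optim(best, obj, method = "Nelder-Mead",
             control = list(maxit = 400, reltol = 1e-10))
  p <- o$par
  h <- log_gabor_complex(k, p[1], exp(p[2]), exp(p[3]), exp(p[4]))
  cf <- solve_coefs(h)$c
  A <- sqrt(sum(cf^2))
  phi <- atan2(-cf[2], cf[1])
  theta <- (p[1] * 180 / pi) %% 360
  if (theta >= 180) { # theta and theta+180 describe the same orientation
    theta <- theta - 180
    phi <- -phi
  }
  fitted <- cf[1] * Re(h) + cf[2] * Im(h)
  structure(list(theta = theta, phi = (phi * 180 / pi) %% 360,
                 f0 = exp(p[2]), sigma_theta = exp(p[3]),
                 sigma_f = exp(p[4]),
                 hwhh = exp(p[3]) * sqrt(2 * log(2)) * 180 / pi,
                 amplitude = A,
                 residual = sqrt(sum((y - as.numeric(fitted))^2)) / knorm,
                 fitted = matrix(fitted, k, k)),
            class = "log_gabor_fit")
}

#' @export
print.log_gabor_fit <- function(x, ...) {
  cat(sprintf("log-Gabor fit: theta = %.1f deg, phi = %.1f deg, f0 = %.3f c/px, HWHH = %.1f deg (rel. residual %.2f)\n",
              x$theta, x$phi, x$f0, x$hwhh, x$residual))
  invisible(x)
}

#' Linear back-projection of second-layer units into image space
#'
#' The second layer projects into the input through the pooling nonlinearity,
#' so its kernels have no direct image-space representation. This computes
#' the approximate linear mapping `V*` minimising
#' `0.5 * sum || x - V^T gamma_C ||^2 + 0.5 * ridge * ||V||^2` over a batch
#' of images, using the inferred second-layer responses; the resulting
#' kernels cover the composite receptive field and are what gets fitted with
#' log-Gabors to assign preferred stimuli to second-layer units.
#'
#' @param fit a fitted two-layer `"sdpc"` model.
#' @param images an image batch (`>= 1` images; more gives a better
#'   conditioned problem).
#' @param ridge ridge penalty.
#' @param gd_iters gradient-descent iterations for the least-squares solve.
#' @param infer_iters inference iteration cap used to compute `gamma_C`.
#' @return a `"backprojection"`: list with `kernels` (`[rf, rf, 1, M_C]`),
#'   `jump` (stride of second-layer units in input pixels), `residual_trace`,
#'   `mean_activity` (per-unit mean of `gamma_C`).
#' @export
backproject <- function(fit, images, ridge = 1e-3, gd_iters = 150L,
                        infer_iters = 60L) {
  if (length(fit$layers) != 2L) stop("backprojection needs a two-layer model")
  x <- array(images, dim = dim(images))
  n <- dim(x)[3]
  state <- sdpc_infer(x, fit, max_iters = infer_iters)
  gc <- state$gamma[[2]]
  Mc <- fit$layers[[2]]$n_units
  if (max(gc) <= 0) stop("gamma_C identically zero on the batch; cannot back-project")
  rf <- receptive_field(fit$layers, fit$pooling)[2]
  jump <- fit$layers[[1]]$stride * fit$layers[[2]]$stride
  for (s in fit$pooling$stages) if (s$kind == "spatial_2d") jump <- jump * s$stride
  dgc <- dim(gc)
  Ht <- (dgc[1] - 1L) * jump + rf
  Wt <- (dgc[2] - 1L) * jump + rf
  # centre the images in the reconstruction footprint
  xt <- array(0, dim = c(Ht, Wt, n))
  r0 <- max(0L, (Ht - dim(x)[1]) %/% 2L); c0 <- max(0L, (Wt - dim(x)[2]) %/% 2L)
  rr <- seq_len(min(Ht, dim(x)[1])); cc <- seq_len(min(Wt, dim(x)[2]))
  xt[r0 + rr, c0 + cc, ] <- x[rr, cc, ]

  Vm <- matrix(0, Mc, rf * rf) # kernels as dictionary matrix, C = 1
  # Lipschitz constant of the quadratic via power iteration on the data Gram
  v <- with_seed(11L, matrix(rnorm(Mc * rf * rf), Mc, rf * rf))
  L <- 1
  for (i in 1:12) {
    rec <- conv_transpose(gc, v, rf, jump, 1L, Ht, Wt)
    w <- dict_grad(gc, Mc, rec, 1L, rf, jump)
    L <- sum(v * w) / sum(v * v)
    w_nrm <- sqrt(sum(w^2)); if (w_nrm < 1e-300) break
    v <- w / w_nrm
  }
  step <- 0.9 / max(L + ridge, 1e-12)
  vel <- 0
  res_trace <- numeric(gd_iters)
  for (i in seq_len(gd_iters)) {
    rec <- conv_transpose(gc, Vm, rf, jump, 1L, Ht, Wt)
    res_trace[i] <- 0.5 * sum((xt - rec)^2) + 0.5 * ridge * sum(Vm^2)
    grad <- dict_grad(gc, Mc, rec - xt, 1L, rf, jump) + ridge * Vm
    vel <- 0.9 * vel - step * grad
    Vm <- Vm + vel
  }
  structure(list(kernels = mat_to_kernels(Vm, rf, 1L), jump = jump,
                 residual_trace = res_trace,
                 mean_activity = vapply(seq_len(Mc), function(m)
                   mean(gc[, , (seq_len(n) - 1L) * Mc + m]), 0)),
            class = "backprojection")
}
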