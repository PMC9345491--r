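#' Whiten an image batch
#'
#' Retina-style whitening with the low-pass-rolled-off ramp
#' `R(f) = f * exp(-(f/f_c)^4)`, `f_c = cutoff * Nyquist`. Each image's
#' spectrum is first divided by its own radially averaged amplitude (an
#' isotropic estimate of the 1/f trend, so oriented structure is preserved)
#' and then multiplied by `R(f)`; the DC component is removed (`R(0) = 0`)
#' and the batch is rescaled jointly so all values lie in `[-1, 1]`. Because
#' only the isotropic trend is normalised away, re-whitening changes the
#' radial spectrum by at most the within-bin variation of `R` (idempotent up
#' to rescaling).
#'
#' @param x image array `(H, W)` or `(H, W, n)`.
#' @param cutoff roll-off frequency as a fraction of Nyquist.
#' @return an `"image_batch"`: array `(H, W, n)` in `[-1, 1]` with attributes
#'   `whitened = TRUE` and `value_range`.
#' @export
whiten_images <- function(x, cutoff = 0.4) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  if (d[1] < 2L || d[2] < 2L) stop("images must be at least 2x2 pixels")
  R <- whitening_filter(d[1], d[2], cutoff)
  # integer radial bins of the frequency grid
  ir <- round(sqrt(outer((fft_freq(d[1]) * d[1])^2,
                         (fft_freq(d[2]) * d[2])^2, "+")))
  bins <- sort(unique(as.integer(ir)))
  out <- array(0, dim = d)
  for (i in seq_len(d[3])) {
    F <- fft(x[, , i])
    A <- Mod(F)
    prof <- vapply(bins, function(b) mean(A[ir == b]), 0)
    denom <- prof[match(as.integer(ir), bins)]
    dim(denom) <- dim(A)
    Fw <- ifelse(denom > 1e-300, F / denom, 0) * R
    out[, , i] <- Re(fft(Fw, inverse = TRUE)) / (d[1] * d[2])
  }
  mx <- max(abs(out))
  if (mx > 0) out <- out / mx
  structure(out, whitened = TRUE, value_range = range(out),
            class = "image_batch")
}

whitening_filter <- function(H, W, cutoff = 0.4) {
  fr <- fft_freq(H); fc <- fft_freq(W)
  f <- sqrt(outer(fr^2, fc^2, "+"))
  f_c <- cutoff * 0.5
  f * exp(-(f / f_c)^4)
}

fft_freq <- function(n) {
  i <- 0:(n - 1)
  ifelse(i <= n %/% 2, i, i - n) / n
}

# slope of the radially averaged log amplitude spectrum vs log frequency
spectral_slope <- function(img, fmax = 0.4) {
  d <- dim(img)
  A <- Mod(fft(img))
  f <- sqrt(outer(fft_freq(d[1])^2, fft_freq(d[2])^2, "+"))
  keep <- f > 1e-9 & f <= fmax
  bins <- cut(log(f[keep]), breaks = 12)
  mf <- tapply(log(f[keep]), bins, mean)
  ma <- tapply(A[keep], bins, mean)
  ok <- is.finite(mf) & is.finite(ma) & ma > 0
  if (sum(ok) < 3) return(NA_real_)
  unname(coef(lm(log(ma[ok]) ~ mf[ok]))[2])
}

#' Sinusoidal grating stimulus
#'
#' A cosine grating `contrast * cos(2*pi*f0*(x*cos(theta) + y*sin(theta)) +
#' phi)` inside a circular mask (strictly zero outside), with `theta` measured
#' counter-clockwise from the horizontal image axis.
#'
#' @param size image side length in pixels.
#' @param orientation theta in degrees, `[0, 180)`.
#' @param phase phi in degrees.
#' @param frequency f0 in cycles/pixel; must be `<= 0.5` (Nyquist).
#' @param mask_diameter diameter of the circular window in pixels.
#' @param contrast amplitude of the grating.
#' @return a `size x size` matrix.
#' @export
make_grating <- function(size, orientation = 0, phase = 0, frequency = 0.125,
                         mask_diameter = 14, contrast = 1) {
  if (frequency > 0.5) stop("frequency above Nyquist (0.5 cycles/pixel)")
  if (frequency <= 0) stop("frequency must be positive")
  ctr <- (size + 1) / 2
  xs <- outer(rep(1, size), seq_len(size) - ctr)   # column offsets
  ys <- outer(ctr - seq_len(size), rep(1, size))   # row offsets, y upward
  th <- orientation * pi / 180
  ph <- phase * pi / 180
  u <- xs * cos(th) + ys * sin(th)
  g <- contrast * cos(2 * pi * frequency * u + ph)
  mask <- sqrt(xs^2 + ys^2) <= mask_diameter / 2
  g * mask
}

#' Drifting or rotating grating sequence
#'
#' `mode = "drift"` sweeps the phase uniformly over one full 360 degree cycle
#' at fixed orientation; `mode = "rotate"` sweeps the orientation over one
#' 180 degree cycle (orientation is pi-periodic) at fixed phase.
#'
#' @param mode `"drift"` or `"rotate"`.
#' @param size,orientation,phase,frequency,mask_diameter,contrast see
#'   [make_grating()].
#' @param samples_per_cycle number of frames in the sweep.
#' @param whiten logical; whiten the frames jointly with the same filter used
#'   for training images (so probe statistics match the training input).
#' @return a `"stimulus_sequence"`: array `(size, size, T)` with attributes
#'   `mode`, `axis` (the swept phase/orientation values in degrees) and
#'   `cycle_definition` (360 for drift, 180 for rotate).
#' @export
grating_sequence <- function(mode = c("drift", "rotate"), size,
                             orientation = 0, phase = 0, frequency = 0.125,
                             mask_diameter = 14, contrast = 1,
                             samples_per_cycle = 32L, whiten = FALSE) {
  mode <- match.arg(mode)
  T <- as.integer(samples_per_cycle)
  cyc <- if (mode == "drift") 360 else 180
  axis <- (seq_len(T) - 1L) / T * cyc
  frames <- array(0, dim = c(size, size, T))
  for (t in seq_len(T)) {
    frames[, , t] <- if (mode == "drift")
      make_grating(size, orientation, phase + axis[t], frequency,
                   mask_diameter, contrast)
    else
      make_grating(size, orientation + axis[t], phase, frequency,
                   mask_diameter, contrast)
  }
  if (whiten) {
    wh <- whiten_images(frames)
    frames <- array(wh, dim = dim(frames))
  }
  structure(frames, mode = mode, axis = axis, cycle_definition = cyc,
            orientation = orientation, phase = phase, frequency = frequency,
            class = "stimulus_sequence")
}

#' Synthetic natural-like images
#'
#' Dead-leaves-style composites: a 1/f-amplitude noise background plus
#' randomly placed, randomly oriented smooth bars, normalised to `[-1, 1]`.
#' The radially averaged amplitude spectrum falls approximately like 1/f, and
#' bar orientations are uniform on `[0, 180)`. Fully deterministic given
#' `seed`.
#'
#' @param n number of images.
#' @param size side length in pixels.
#' @param n_edges oriented elements per image (default scales with area).
#' @param slope target spectral exponent of the noise background (amplitude
#'   ~ f^slope).
#' @param bg_scale amplitude of the noise background relative to the edge
#'   elements (the edges carry most of the contrast, as object contours do
#'   in natural scenes).
#' @param seed integer seed.
#' @param whiten logical; also apply [whiten_images()] before returning.
#' @return an `"image_batch"` array `(size, size, n)`; attribute `"edges"`
#'   holds a data frame of the generated edge elements (image, x, y, theta,
#'   length, width, amplitude).
#' @export
synthetic_images <- function(n, size, n_edges = max(4L, round(size^2 / 100)),
                             slope = -1, bg_scale = 0.4, seed = 1L,
                             whiten = FALSE) {
  stopifnot(n >= 0, size >= 4)
  out <- array(0, dim = c(size, size, max(n, 0L)))
  edges <- vector("list", n)
  with_seed(seed, {
    f <- sqrt(outer(fft_freq(size)^2, fft_freq(size)^2, "+"))
    amp <- ifelse(f > 1e-9, f^slope, 0)
    xs <- outer(rep(1, size), seq_len(size))
    ys <- outer(seq_len(size), rep(1, size))
    for (i in seq_len(n)) {
      wn <- fft(matrix(rnorm(size^2), size, size))
      bg <- Re(fft(wn * amp, inverse = TRUE)) / size^2
      bg <- bg_scale * bg / max(sd(bg), 1e-12)
      img <- bg
      es <- data.frame(image = integer(0))
      if (n_edges > 0) {
        theta <- runif(n_edges, 0, 180)
        cx <- runif(n_edges, 1, size)
        cy <- runif(n_edges, 1, size)
        len <- runif(n_edges, 0.3, 0.8) * size
        wid <- runif(n_edges, 0.7, 1.6)
        amp_e <- sample(c(-1, 1), n_edges, replace = TRUE) *
          runif(n_edges, 0.5, 1.2)
        for (e in seq_len(n_edges)) {
          th <- theta[e] * pi / 180
          dx <- xs - cx[e]; dy <- cy[e] - ys
          d_par <- dx * cos(th) + dy * sin(th)
          d_perp <- -dx * sin(th) + dy * cos(th)
          img <- img + amp_e[e] * exp(-d_perp^2 / (2 * wid[e]^2)) *
            exp(-d_par^2 / (2 * (len[e] / 2)^2))
        }
        es <- data.frame(image = i, x = cx, y = cy, theta = theta,
                         length = len, width = wid, amplitude = amp_e)
      }
      out[, , i] <- img
      edges[[i]] <- es
    }
  })
  mx <- max(abs(out), 1e-12)
  out <- out / mx
  res <- structure(out, whitened = FALSE, value_range = range(out),
                   edges = do.call(rbind, edges), class = "image_batch")
  if (whiten) {
    ed <- attr(res, "edges")
    res <- whiten_images(res)
    attr(res, "edges") <- ed
  }
  res
}

#' Load a natural-image dataset from disk
#'
#' Optional loader for external data: either a directory of grayscale PNG
#' files or an STL-10-style binary file of `3 x 96 x 96` uint8 records
#' (converted to grayscale by channel averaging). Images are centre-cropped
#' or randomly cropped to `size` deterministically given `seed`. No analysis
#' in this package requires external data; the synthetic generator stands in
#' for natural images at desk scale.
#'
#' @param path file or directory path.
#' @param n number of images to load.
#' @param size target side length in pixels.
#' @param seed seed controlling crop positions and file order.
#' @return an `"image_batch"` (not whitened).
#' @export
load_image_dataset <- function(path, n, size = 96L, seed = 1L) {
  if (missing(path) || is.null(path) || !file.exists(path))
    stop("external data not available at 'path'; use synthetic_images() instead")
  if (n == 0L)
    return(structure(array(0, dim = c(size, size, 0L)), whitened = FALSE,
                     class = "image_batch"))
  imgs <- NULL
  if (dir.exists(path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG directories requires the 'png' package")
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 1L) stop("no PNG files found in 'path'")
    files <- rep_len(files, n)
    imgs <- lapply(files, function(fp) {
      a <- png::readPNG(fp)
      if (length(dim(a)) == 3L) a <- apply(a[, , 1:3, drop = FALSE], c(1, 2), mean)
      a
    })
  } else {
    sz <- file.size(path)
    rec <- 3L * 96L * 96L
    n_avail <- sz %/% rec
    if (n_avail < 1L) stop("file too small for 96x96 records")
    con <- file(path, "rb")
    on.exit(close(con))
    imgs <- vector("list", min(n, n_avail))
    for (i in seq_along(imgs)) {
      raw <- readBin(con, "integer", n = rec, size = 1L, signed = FALSE)
      a <- array(raw, dim = c(96L, 96L, 3L)) # column-major per channel
      imgs[[i]] <- t(apply(a, c(1, 2), mean)) / 255
    }
    imgs <- rep_len(imgs, n)
  }
  out <- array(0, dim = c(size, size, n))
  with_seed(seed, {
    for (i in seq_len(n)) {
      a <- imgs[[i]]
      if (nrow(a) < size || ncol(a) < size)
        stop(sprintf("image %d smaller than requested size", i))
      r0 <- if (nrow(a) == size) 0L else sample.int(nrow(a) - size, 1L)
      c0 <- if (ncol(a) == size) 0L else sample.int(ncol(a) - size, 1L)
      out[, , i] <- a[r0 + seq_len(size), c0 + seq_len(size)]
    }
  })
  structure(out, whitened = FALSE, value_range = range(out),
            class = "image_batch")
}
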