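#' Tuning curve of one model unit
#'
#' Runs inference on every frame of a stimulus sequence (the frames form one
#' batch) and records the unit's steady-state activity at the spatial
#' position of its maximal response, chosen once on the best frame and then
#' held fixed across the sweep.
#'
#' @param fit a fitted `"sdpc"` model.
#' @param sequence a `"stimulus_sequence"` from [grating_sequence()].
#' @param layer 1 (simple-cell layer) or 2 (complex-cell layer).
#' @param unit channel index within the layer.
#' @param state optional precomputed `"sdpc_state"` for the sequence (lets
#'   callers probe many units from one inference pass).
#' @param ... passed to [sdpc_infer()].
#' @return a `"tuning_curve"`: list with `response` (length T, `>= 0`),
#'   `axis` (phase or orientation in degrees), `mode`, `unit`, `layer`,
#'   `position`.
#' @export
tuning_curve <- function(fit, sequence, layer = 2L, unit = 1L, state = NULL,
                         ...) {
  T <- dim(sequence)[3]
  if (is.null(state))
    state <- sdpc_infer(array(sequence, dim = dim(sequence)), fit, ...)
  g <- state$gamma[[layer]]
  M <- fit$layers[[layer]]$n_units
  resp_all <- g[, , (seq_len(T) - 1L) * M + unit, drop = FALSE]
  if (max(resp_all) <= 0) {
    warning(sprintf("unit %d (layer %d) never active on any frame", unit, layer))
    pos <- c(1L, 1L)
  } else {
    best <- which(resp_all == max(resp_all), arr.ind = TRUE)[1, ]
    pos <- c(best[1], best[2])
  }
  structure(list(response = resp_all[pos[1], pos[2], ],
                 axis = attr(sequence, "axis"),
                 mode = attr(sequence, "mode"),
                 cycle_definition = attr(sequence, "cycle_definition"),
                 layer = layer, unit = unit, position = pos),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("Tuning curve (%s), layer %d unit %d: F1/F0 = %.3f\n",
              x$mode, x$layer, x$unit, modulation_ratio(x)$f1f0))
  invisible(x)
}

#' Modulation ratio (F1/F0) of a tuning curve
#'
#' `F0` is the mean response over one stimulus cycle, `F1` the amplitude of
#' the discrete Fourier component at one cycle per sweep (`2*|X_1|/T`). Units
#' are classified simple when `F1/F0 > 1` and complex otherwise; a unit with
#' `F0 = 0` is flagged non-responsive (undefined ratio).
#'
#' @param curve a `"tuning_curve"` or a plain numeric vector covering exactly
#'   one uniformly sampled cycle.
#' @return list with `F0`, `F1`, `f1f0`, `classification` (`"simple"`,
#'   `"complex"` or `"nonresponsive"`).
#' @export
modulation_ratio <- function(curve) {
  r <- if (inherits(curve, "tuning_curve")) curve$response else as.numeric(curve)
  T <- length(r)
  F0 <- mean(r)
  if (F0 <= 0) {
    return(list(F0 = F0, F1 = 0, f1f0 = NA_real_,
                classification = "nonresponsive"))
  }
  z <- sum(r * exp(-2i * pi * (seq_len(T) - 1L) / T))
  F1 <- 2 * Mod(z) / T
  f1f0 <- F1 / F0
  list(F0 = F0, F1 = F1, f1f0 = f1f0,
       classification = if (f1f0 > 1) "simple" else "complex")
}

#' Fit the half-rectified sinusoid response model
#'
#' Least-squares fit of `r(phi) = (a*cos(phi - phi0) - b)+` to a tuning
#' curve; the rectification index is `chi = b/|a|`. When the best unclipped
#' cosine never crosses zero (`b <= -|a|`) the fit reduces to plain harmonic
#' regression, which is solved exactly; otherwise the exact solution seeds a
#' numerical refinement.
#'
#' @param curve a `"tuning_curve"` or numeric vector over one cycle.
#' @param axis stimulus values in degrees (one full cycle); taken from the
#'   curve when available.
#' @return a `"rectified_sine_fit"`: list with `a`, `b`, `phi0` (degrees),
#'   `chi`, `residual` (RMS), `fitted`.
#' @export
fit_rectified_sine <- function(curve, axis = NULL) {
  r <- if (inherits(curve, "tuning_curve")) curve$response else as.numeric(curve)
  if (is.null(axis)) {
    axis <- if (inherits(curve, "tuning_curve")) {
      curve$axis / curve$cycle_definition * 360
    } else (seq_along(r) - 1) / length(r) * 360
  }
  if (all(r == 0)) stop("all-zero curve: rectified-sine fit undefined")
  ph <- axis * pi / 180
  X <- cbind(1, cos(ph), sin(ph))
  cf <- solve(crossprod(X), crossprod(X, r))
  a0 <- sqrt(cf[2]^2 + cf[3]^2)
  phi0_0 <- atan2(cf[3], cf[2])
  b0 <- -cf[1]
  model <- function(p) pmax(p[1] * cos(ph - p[3]) - p[2], 0)
  sse <- function(p) sum((model(p) - r)^2)
  if (a0 > 0 && b0 <= -a0 + 1e-12 && all(X %*% cf >= -1e-10)) {
    p <- c(a0, b0, phi0_0) # unclipped regime: harmonic regression is exact
  } else {
    starts <- list(c(a0, b0, phi0_0),
                   c(a0 * 2, a0, phi0_0),
                   c(max(r), max(r) / 2, ph[which.max(r)]),
                   c(max(r) - min(r), -min(r), ph[which.max(r)]))
    p <- NULL; best <- Inf
    for (s in starts) {
      o <- optim(s, sse, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
      o <- optim(o$par, sse, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-14))
      if (o$value < best) { best <- o$value; p <- o$par }
    }
  }
  if (p[1] < 0) { # enforce a >= 0 (a sign flip is a 180 degree phase shift)
    p[1] <- -p[1]; p[3] <- p[3] + pi
  }
  phi0 <- (p[3] * 180 / pi) %% 360
  structure(list(a = p[1], b = p[2], phi0 = phi0,
                 chi = p[2] / abs(p[1]),
                 residual = sqrt(mean((model(p) - r)^2)),
                 fitted = model(p), axis = axis),
            class = "rectified_sine_fit")
}

#' @export
print.rectified_sine_fit <- function(x, ...) {
  cat(sprintf("(a cos(phi - phi0) - b)+ fit: a = %.3g, b = %.3g, phi0 = %.1f deg, chi = %.3f (RMS %.2g)\n",
              x$a, x$b, x$phi0, x$chi, x$residual))
  invisible(x)
}

#' Closed-form mapping from the rectification index to F1/F0
#'
#' For the half-rectified sinusoid response model, the modulation ratio is a
#' monotone function of `chi = b/|a|`:
#' `g(chi) = (-chi*sqrt(1-chi^2) + acos(chi)) / (sqrt(1-chi^2) -
#' chi*acos(chi))` for `-1 <= chi <= 1`, `-1/chi` for `chi < -1`, and
#' undefined for `chi > 1`. The two branches agree (value 1) at `chi = -1`.
#'
#' @param chi numeric vector, `chi <= 1`.
#' @return F1/F0 values.
#' @export
chi_to_f1f0 <- function(chi) {
  if (any(chi > 1)) stop("chi > 1: modulation ratio undefined")
  out <- numeric(length(chi))
  lo <- chi < -1
  out[lo] <- -1 / chi[lo]
  hi <- !lo & chi < 1
  x <- chi[hi]
  s <- sqrt(pmax(1 - x^2, 0))
  out[hi] <- (-x * s + acos(x)) / (s - x * acos(x))
  out[!lo & chi >= 1] <- 2 # limit of a vanishingly narrow rectified pulse
  out
}

#' Half-width at half-height of a tuning curve
#'
#' Width (in the stimulus units of the curve's axis) of the region around the
#' peak where the response exceeds baseline plus half the peak-minus-baseline
#' range, with linear interpolation at the crossings and circular wraparound.
#'
#' @param curve a `"tuning_curve"` or numeric vector.
#' @param axis stimulus values in degrees (defaults to the curve's axis).
#' @return the half-width at half height (half of the full width), degrees.
#' @export
hwhh <- function(curve, axis = NULL) {
  r <- if (inherits(curve, "tuning_curve")) curve$response else as.numeric(curve)
  if (is.null(axis))
    axis <- if (inherits(curve, "tuning_curve")) curve$axis
            else (seq_along(r) - 1) / length(r) * 180
  T <- length(r)
  if (max(r) <= min(r)) return(NA_real_)
  cyc <- if (inherits(curve, "tuning_curve")) curve$cycle_definition
         else max(axis) + diff(axis[1:2])
  half <- min(r) + (max(r) - min(r)) / 2
  pk <- which.max(r)
  above <- r >= half
  step <- cyc / T
  # contiguous above-half run around the peak, with wraparound
  left <- pk; nl <- 0L
  while (nl < T - 1L) {
    j <- if (left == 1L) T else left - 1L
    if (!above[j]) break
    left <- j; nl <- nl + 1L
  }
  right <- pk; nr <- 0L
  while (nl + nr < T - 1L) {
    j <- if (right == T) 1L else right + 1L
    if (!above[j]) break
    right <- j; nr <- nr + 1L
  }
  if (nl + nr >= T - 1L) return(cyc / 2)
  jl <- if (left == 1L) T else left - 1L
  jr <- if (right == T) 1L else right + 1L
  fl <- (r[left] - half) / (r[left] - r[jl])
  fr <- (r[right] - half) / (r[right] - r[jr])
  width <- (nl + nr + min(fl, 1) + min(fr, 1)) * step
  min(width, cyc) / 2
}
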