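#' Orientation preference map of a layer
#'
#' Fits a log-Gabor to every kernel of the requested layer (first-layer
#' kernels directly; second-layer units via their [backproject()]ed
#' image-space kernels) and arranges the preferred parameters on the feature
#' topology implied by the pooling specification: a sqrt(M) x sqrt(M)
#' toroidal grid for 2D feature pooling (channels laid out row-major, the
#' same mapping the pooling operator uses), a circular ring for 1D feature
#' pooling, and no topology otherwise.
#'
#' @param fit a fitted `"sdpc"` model.
#' @param layer layer index (default 1).
#' @param kernels optional kernel stack `[k, k, 1, M]` overriding the model's
#'   (e.g. a backprojection).
#' @param topology override the inferred topology.
#' @return an `"orientation_map"`: per-unit `theta`, `phi`, `f0`, `hwhh`,
#'   `residual` vectors, `topology`, `grid` (side length for grids).
#' @export
orientation_map <- function(fit, layer = 1L, kernels = NULL,
                            topology = NULL) {
  if (is.null(kernels)) {
    if (layer == 1L) kernels <- fit$kernels[[1]]
    else stop("for layer 2, pass kernels = backproject(fit, images)$kernels")
  }
  M <- dim(kernels)[4]
  fits <- lapply(seq_len(M), function(m) fit_log_gabor(kernels[, , 1, m]))
  if (is.null(topology)) topology <- feature_topology(fit$pooling)
  G <- if (topology == "grid_toroidal") as.integer(round(sqrt(M))) else NA_integer_
  structure(list(theta = vapply(fits, `[[`, 0, "theta"),
                 phi = vapply(fits, `[[`, 0, "phi"),
                 f0 = vapply(fits, `[[`, 0, "f0"),
                 hwhh = vapply(fits, `[[`, 0, "hwhh"),
                 residual = vapply(fits, `[[`, 0, "residual"),
                 topology = topology, grid = G, n_units = M, layer = layer),
            class = "orientation_map")
}

#' @export
print.orientation_map <- function(x, ...) {
  cat(sprintf("Orientation map: %d units, topology %s\n", x$n_units,
              x$topology))
  invisible(x)
}

#' @export
plot.orientation_map <- function(x, ...) {
  if (x$topology != "grid_toroidal")
    stop("plotting requires a 2D grid topology")
  th <- theta_grid(x)
  image(t(th[nrow(th):1, ]), col = hcl.colors(64, "Spectral"), axes = FALSE,
        zlim = c(0, 180), main = "preferred orientation (deg)",
        useRaster = TRUE)
  invisible(x)
}

# arrange a per-unit vector on the row-major feature grid
theta_grid <- function(map, values = map$theta) {
  G <- map$grid
  matrix(values, G, G, byrow = TRUE)
}

#' Local homogeneity index
#'
#' `LHI(m) = | sum_n w(n, m) exp(2i theta_n) | / sum_n w(n, m)` with Gaussian
#' weights `w = exp(-d(n, m)^2 / (2 sigma^2))` over the neighbours of `m`
#' (the site itself excluded), truncated at `3 sigma`; distances wrap around
#' the declared topology (torus or ring). Values near 1 mark iso-orientation
#' domains, values near 0 pinwheel centres.
#'
#' @param map an `"orientation_map"`, or a matrix (toroidal grid) / vector
#'   (circular ring) of preferred orientations in degrees.
#' @param sigma Gaussian width in grid units (pixels).
#' @param topology required when `map` is a plain matrix/vector.
#' @return an `"lhi_map"`: `lhi` (matrix or vector in `[0, 1]`), `sigma`,
#'   `topology`.
#' @export
compute_lhi <- function(map, sigma = 1, topology = NULL) {
  if (inherits(map, "orientation_map")) {
    topology <- map$topology
    theta <- if (topology == "grid_toroidal") theta_grid(map) else map$theta
  } else theta <- map
  if (is.null(topology) || topology == "none")
    stop("LHI needs a ring or toroidal grid topology")
  w <- as.integer(ceiling(3 * sigma))
  z <- exp(2i * (if (is.matrix(theta)) theta else as.numeric(theta)) * pi / 180)
  if (topology == "grid_toroidal") {
    stopifnot(is.matrix(theta))
    G1 <- nrow(theta); G2 <- ncol(theta)
    num <- matrix(0 + 0i, G1, G2); den <- 0
    for (dr in -w:w) for (dc in -w:w) {
      if (dr == 0L && dc == 0L) next
      g <- exp(-(dr^2 + dc^2) / (2 * sigma^2))
      shifted <- z[((seq_len(G1) - 1 + dr) %% G1) + 1,
                   ((seq_len(G2) - 1 + dc) %% G2) + 1, drop = FALSE]
      num <- num + g * shifted
      den <- den + g
    }
    lhi <- Mod(num) / den
  } else { # ring
    theta <- as.numeric(theta); M <- length(theta)
    z <- exp(2i * theta * pi / 180)
    num <- complex(M); den <- 0
    for (d in setdiff(-w:w, 0L)) {
      g <- exp(-d^2 / (2 * sigma^2))
      num <- num + g * z[((seq_len(M) - 1 + d) %% M) + 1]
      den <- den + g
    }
    lhi <- Mod(num) / den
  }
  structure(list(lhi = lhi, sigma = sigma, topology = topology),
            class = "lhi_map")
}

#' @export
print.lhi_map <- function(x, ...) {
  cat(sprintf("LHI map (%s): mean %.3f, min %.3f\n", x$topology,
              mean(x$lhi), min(x$lhi)))
  invisible(x)
}

#' Detect pinwheel singularities
#'
#' Pinwheels are positions that are strict local minima of the LHI within
#' their 3x3 toroidal neighbourhood and lie below `threshold`.
#'
#' @param lhi an `"lhi_map"` with grid topology, or an LHI matrix.
#' @param threshold LHI value below which a local minimum counts.
#' @return a `"pinwheel_report"`: `positions` (matrix of row/col indices),
#'   `count`, `lhi_values`, `threshold`.
#' @export
detect_pinwheels <- function(lhi, threshold = 0.2) {
  if (inherits(lhi, "lhi_map")) {
    if (lhi$topology != "grid_toroidal")
      stop("pinwheels are undefined on a 1D ring topology")
    L <- lhi$lhi
  } else L <- lhi
  stopifnot(is.matrix(L))
  G1 <- nrow(L); G2 <- ncol(L)
  pos <- NULL
  for (r in seq_len(G1)) for (c in seq_len(G2)) {
    v <- L[r, c]
    if (v >= threshold) next
    strict_min <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      nb <- L[((r - 1 + dr) %% G1) + 1, ((c - 1 + dc) %% G2) + 1]
      if (nb <= v) strict_min <- FALSE
    }
    if (strict_min) pos <- rbind(pos, c(r, c))
  }
  structure(list(positions = pos, count = if (is.null(pos)) 0L else nrow(pos),
                 lhi_values = if (is.null(pos)) numeric(0) else L[pos],
                 threshold = threshold, dim = c(G1, G2)),
            class = "pinwheel_report")
}

#' @export
print.pinwheel_report <- function(x, ...) {
  cat(sprintf("%d pinwheel(s) (LHI < %.2f, strict 3x3 minima)\n", x$count,
              x$threshold))
  invisible(x)
}

#' Pinwheel density
#'
#' The average cortical column covers `c = (180 / mean(HWHH))^2` map units;
#' the density is pinwheels per column area, `rho = n / (M_s / c)`. Setting
#' `per_area = FALSE` uses the alternative grouping `n / (M_s * c)`.
#'
#' @param report a `"pinwheel_report"` (or a plain count).
#' @param M_s number of first-layer units (map size).
#' @param mean_hwhh mean orientation-tuning HWHH of the map, degrees.
#' @param per_area use the pinwheels-per-column-area reading (default).
#' @return list with `rho`, `c` (column size), `count`.
#' @export
pinwheel_density <- function(report, M_s, mean_hwhh, per_area = TRUE) {
  n <- if (inherits(report, "pinwheel_report")) report$count else report
  if (!is.finite(mean_hwhh) || mean_hwhh <= 0)
    stop("mean_hwhh must be positive")
  cc <- (180 / mean_hwhh)^2
  if (M_s < cc) warning("map smaller than one cortical column")
  rho <- if (per_area) n / (M_s / cc) else n / (M_s * cc)
  list(rho = rho, c = cc, count = n)
}
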