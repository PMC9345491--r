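#' Pooling stage descriptor
#'
#' A single max-pooling stage. Three kinds are supported, mirroring the three
#' operators used to generate invariance in the two-layer network:
#' `"spatial_2d"` pools over retinotopic positions independently per feature
#' plane (default kernel 2x2, stride 2); `"feature_1d_circular"` pools over a
#' circular neighbourhood of adjacent feature planes (default kernel 4,
#' stride 1); `"feature_2d_toroidal"` arranges the M feature planes on a
#' sqrt(M) x sqrt(M) toroidal grid and pools 2x2 windows with wraparound
#' (default kernel 2, stride 1). `"identity"` passes activity through
#' unchanged.
#'
#' @param kind one of `"spatial_2d"`, `"feature_1d_circular"`,
#'   `"feature_2d_toroidal"`, `"identity"`.
#' @param kernel pooling kernel size (side length for 2D kinds). Defaults to
#'   the study value for the kind.
#' @param stride pooling stride. Only `"spatial_2d"` supports stride != 1.
#' @param pad zero padding added on each spatial side before a spatial stage,
#'   or `NULL` to pad minimally so the window arithmetic is exact.
#' @return an object of class `"pool_stage"`.
#' @export
pool_stage <- function(kind = c("spatial_2d", "feature_1d_circular",
                                "feature_2d_toroidal", "identity"),
                       kernel = NULL, stride = NULL, pad = NULL) {
  kind <- match.arg(kind)
  defaults <- list(
    spatial_2d = list(kernel = 2L, stride = 2L),
    feature_1d_circular = list(kernel = 4L, stride = 1L),
    feature_2d_toroidal = list(kernel = 2L, stride = 1L),
    identity = list(kernel = 1L, stride = 1L)
  )[[kind]]
  kernel <- as.integer(if (is.null(kernel)) defaults$kernel else kernel)
  stride <- as.integer(if (is.null(stride)) defaults$stride else stride)
  if (kernel < 1L) stop("empty pooling window: kernel must be >= 1")
  if (stride < 1L) stop("stride must be >= 1")
  if (kind %in% c("feature_1d_circular", "feature_2d_toroidal") && stride != 1L)
    stop("feature pooling stages use stride 1")
  structure(list(kind = kind, kernel = kernel, stride = stride, pad = pad),
            class = "pool_stage")
}

#' Pooling specification
#'
#' An ordered sequence of pooling stages applied between the first and second
#' layer of the network. Stages can be given as [pool_stage()] objects or as
#' kind strings (optionally combined with `"+"`, e.g.
#' `"spatial_2d+feature_1d_circular"`), in which case the study defaults for
#' kernel and stride are used. Spatial stages are listed before feature stages
#' in the composite operators.
#'
#' @param ... pooling stages (strings or [pool_stage()] objects). An empty
#'   call yields the identity specification.
#' @return an object of class `"pooling_spec"`.
#' @examples
#' pooling_spec("spatial_2d", "feature_2d_toroidal")
#' pooling_spec("spatial_2d+feature_1d_circular")
#' @export
pooling_spec <- function(...) {
  args <- list(...)
  stages <- list()
  for (a in args) {
    if (inherits(a, "pool_stage")) {
      stages[[length(stages) + 1L]] <- a
    } else if (is.character(a)) {
      for (kind in unlist(strsplit(a, "+", fixed = TRUE)))
        stages[[length(stages) + 1L]] <- pool_stage(trimws(kind))
    } else if (inherits(a, "pooling_spec")) {
      stages <- c(stages, a$stages)
    } else stop("pooling stages must be kind strings or pool_stage objects")
  }
  if (length(stages) == 0L) stages <- list(pool_stage("identity"))
  structure(list(stages = stages), class = "pooling_spec")
}

#' @export
print.pooling_spec <- function(x, ...) {
  lab <- vapply(x$stages, function(s)
    sprintf("%s[%dx%d/%d]", s$kind, s$kernel, s$kernel, s$stride), "")
  cat("Pooling:", paste(lab, collapse = " + "), "\n")
  invisible(x)
}

# label used in reports ("2D_S + 1D_F" style naming)
pooling_label <- function(spec) {
  short <- c(spatial_2d = "2D_S", feature_1d_circular = "1D_F",
             feature_2d_toroidal = "2D_F", identity = "id")
  paste(short[vapply(spec$stages, `[[`, "", "kind")], collapse = "+")
}

has_feature_stage <- function(spec)
  any(vapply(spec$stages, `[[`, "", "kind") %in%
        c("feature_1d_circular", "feature_2d_toroidal"))

feature_topology <- function(spec) {
  kinds <- vapply(spec$stages, `[[`, "", "kind")
  if ("feature_2d_toroidal" %in% kinds) "grid_toroidal"
  else if ("feature_1d_circular" %in% kinds) "ring_circular"
  else "none"
}

# maximum number of pooled outputs that can route to one input under
# unpooling (used to bound the norm of the feedback path)
unpool_multiplicity <- function(spec) {
  m <- 1
  for (s in spec$stages) {
    if (s$kind == "spatial_2d") {
      m <- m * max(1, ceiling(s$kernel / s$stride))^2
    } else if (s$kind == "feature_1d_circular") {
      m <- m * s$kernel
    } else if (s$kind == "feature_2d_toroidal") {
      m <- m * s$kernel^2
    }
  }
  m
}

spatial_pad <- function(H, W, k, stride, pad) {
  if (!is.null(pad)) {
    p <- as.integer(pad)
    pads <- c(p, p, p, p) # top, left, bottom, right
    if ((H + 2L * p - k) %% stride != 0L || (W + 2L * p - k) %% stride != 0L)
      stop("explicit pad incompatible with kernel/stride arithmetic")
    return(pads)
  }
  need <- function(n) (stride - ((n - k) %% stride)) %% stride
  ph <- need(H); pw <- need(W)
  c(ph %/% 2L, pw %/% 2L, ph - ph %/% 2L, pw - pw %/% 2L)
}

#' Apply a pooling specification
#'
#' Applies the stages of a [pooling_spec()] in order to an activity map,
#' recording per-stage argmax switches so the operation can be (approximately)
#' differentiated by unpooling. Ties within a window go to the first element
#' in a row-major (channel-major, for feature stages) scan.
#'
#' @param gamma activity array `(H, W, M)` for a single map or `(H, W, n*M)`
#'   for a batch of `n_images` maps (slice index `i*M + m`).
#' @param spec a [pooling_spec()].
#' @param n_images number of maps stacked in `gamma`.
#' @return a list with `output` (pooled array) and `assignment` (an object of
#'   class `"pool_assignment"` holding per-stage switch maps).
#' @seealso [unpool()]
#' @export
max_pool <- function(gamma, spec, n_images = 1L) {
  stopifnot(inherits(spec, "pooling_spec"), length(dim(gamma)) == 3L)
  n <- as.integer(n_images)
  if (dim(gamma)[3] %% n != 0L) stop("slice count not divisible by n_images")
  cur <- gamma
  stages <- list()
  for (si in seq_along(spec$stages)) {
    s <- spec$stages[[si]]
    M <- dim(cur)[3] %/% n
    d_in <- dim(cur)
    res <- switch(s$kind,
      identity = list(out = cur, sw = NULL),
      spatial_2d = {
        pads <- spatial_pad(d_in[1], d_in[2], s$kernel, s$stride, s$pad)
        cpp_pool_spatial(cur, s$kernel, s$stride,
                         pads[1], pads[2], pads[3], pads[4])
      },
      feature_1d_circular = {
        if (s$kernel > M)
          stop(sprintf("stage %d (%s): pooling kernel %d exceeds channel count %d",
                       si, s$kind, s$kernel, M))
        cpp_pool_feat1d(cur, M, s$kernel)
      },
      feature_2d_toroidal = {
        if (round(sqrt(M))^2 != M)
          stop(sprintf("stage %d (%s): channel count %d is not a perfect square",
                       si, s$kind, M))
        cpp_pool_feat2d(cur, M, s$kernel)
      })
    stages[[si]] <- list(kind = s$kind, sw = res$sw, in_dim = d_in,
                         out_dim = dim(res$out))
    cur <- res$out
  }
  assignment <- structure(list(stages = stages, n_images = n),
                          class = "pool_assignment")
  list(output = cur, assignment = assignment)
}

#' Route a pooled-space map back through recorded pooling switches
#'
#' The transpose of the switch-selection linear map: each value of `u` is sent
#' to the input position that won its pooling window, summing where
#' overlapping (stride-1 feature) windows share a winner. This is the
#' approximation of the max-pooling derivative used by the feedback term of
#' the inference update.
#'
#' @param u array with the shape of the pooled output.
#' @param assignment a `"pool_assignment"` from [max_pool()].
#' @return an array with the shape of the pooling input.
#' @export
unpool <- function(u, assignment) {
  stopifnot(inherits(assignment, "pool_assignment"))
  cur <- u
  for (st in rev(assignment$stages)) {
    if (!identical(dim(cur), st$out_dim) &&
        !all(dim(cur) == st$out_dim))
      stop("stale pooling assignment: shape mismatch")
    if (st$kind == "identity") next
    cur <- cpp_unpool(cur, st$sw, st$in_dim[1], st$in_dim[2], st$in_dim[3])
  }
  cur
}
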