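#' Non-negative soft thresholding
#'
#' The proximal operator of the non-negative l1 penalty used by the inference
#' updates: `max(x - threshold, 0)`, elementwise.
#'
#' @param x numeric vector or array.
#' @param threshold non-negative scalar.
#' @return object with the shape of `x`, all values `>= 0`.
#' @export
soft_threshold <- function(x, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("threshold must be a single nonnegative number")
  out <- pmax(x - threshold, 0)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Layer specification
#'
#' @param n_units number of convolutional kernels (feature planes) in the
#'   layer. Must be a perfect square when a 2D feature topology is pooled
#'   downstream.
#' @param kernel_size kernel side length in pixels.
#' @param stride convolution stride.
#' @param sparsity target l1 penalty (lambda) for the layer's activity.
#' @return an object of class `"sdpc_layer"`.
#' @export
sdpc_layer <- function(n_units, kernel_size, stride = 1L, sparsity = 0.1) {
  if (n_units < 1L || kernel_size < 1L || stride < 1L || sparsity < 0)
    stop("invalid layer specification: need kernel_size >= 1, stride >= 1, sparsity >= 0")
  structure(list(n_units = as.integer(n_units),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride),
                 sparsity = sparsity),
            class = "sdpc_layer")
}

#' Fitting and inference control parameters
#'
#' @param inference_step step size eta of the inference gradient updates, or
#'   `"auto"` (default) to derive it from the operator norms: eta = 0.9 / L
#'   per layer, with L the squared spectral norm of the layer's convolutional
#'   operator (estimated by 20 power iterations) plus, for the first layer,
#'   the maximum unpool multiplicity of the pooling spec (the feedback path
#'   contributes to the curvature of the first-layer update).
#' @param inference_max_iters cap on inference iterations.
#' @param inference_tol relative loss-change tolerance stopping inference.
#' @param train_inference_iters cap on inference iterations inside a training
#'   step (the tolerance still applies).
#' @param learning_rate dictionary learning step size omega.
#' @param momentum momentum beta of the dictionary updates, in `[0, 1)`.
#' @param iterations number of minibatch training iterations.
#' @param batch_size images per minibatch.
#' @param lambda_ramp fraction of training over which the sparsity penalties
#'   are ramped linearly from 0 to their target values.
#' @param feedback logical; `FALSE` removes the feedback (unpooled
#'   second-layer error) term from the first-layer inference update.
#' @param step_refresh re-estimate auto step sizes every this many training
#'   iterations.
#' @param seed integer seed making training fully reproducible.
#' @return an object of class `"sdpc_control"`.
#' @export
sdpc_control <- function(inference_step = "auto", inference_max_iters = 200L,
                         inference_tol = 1e-4, train_inference_iters = 16L,
                         learning_rate = 0.1, momentum = 0.9,
                         iterations = 1500L, batch_size = 8L,
                         lambda_ramp = 0.5, feedback = TRUE,
                         step_refresh = 25L, seed = 1L) {
  if (is.numeric(inference_step) && inference_step <= 0)
    stop("inference_step must be positive or \"auto\"")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(list(inference_step = inference_step,
                 inference_max_iters = as.integer(inference_max_iters),
                 inference_tol = inference_tol,
                 train_inference_iters = as.integer(train_inference_iters),
                 learning_rate = learning_rate, momentum = momentum,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 lambda_ramp = lambda_ramp, feedback = isTRUE(feedback),
                 step_refresh = as.integer(step_refresh),
                 seed = as.integer(seed)),
            class = "sdpc_control")
}

#' Untrained network
#'
#' Builds a network container with randomly initialised, unit-norm kernels.
#' One or two layers are supported; the pooling spec sits between them.
#'
#' @param layers list of [sdpc_layer()] objects (length 1 or 2).
#' @param pooling a [pooling_spec()].
#' @param seed seed for the kernel initialisation.
#' @param kernels optional list of kernel arrays `[k, k, C, M]` to use instead
#'   of random initialisation.
#' @return an object of class `"sdpc_net"`.
#' @export
sdpc_network <- function(layers, pooling = pooling_spec("identity"),
                         seed = 1L, kernels = NULL) {
  stopifnot(length(layers) %in% 1:2, all(vapply(layers, inherits, TRUE, "sdpc_layer")))
  if (feature_topology(pooling) == "grid_toroidal" &&
      round(sqrt(layers[[1]]$n_units))^2 != layers[[1]]$n_units)
    stop("toroidal feature pooling needs a perfect-square first-layer size")
  if (is.null(kernels)) {
    kernels <- with_seed(seed, {
      ks <- list()
      C <- 1L
      for (li in seq_along(layers)) {
        l <- layers[[li]]
        a <- array(rnorm(l$kernel_size^2 * C * l$n_units),
                   dim = c(l$kernel_size, l$kernel_size, C, l$n_units))
        ks[[li]] <- normalize_kernels(a)
        attr(ks[[li]], "dead") <- NULL
        C <- l$n_units
      }
      ks
    })
  }
  structure(list(layers = layers, pooling = pooling, kernels = kernels,
                 seed = as.integer(seed)),
            class = "sdpc_net")
}

normalize_kernels <- function(a, previous = NULL) {
  d <- dim(a)
  m <- matrix(a, prod(d[1:3]), d[4])
  nrm <- sqrt(colSums(m^2))
  dead <- nrm < 1e-10
  if (any(dead)) {
    if (!is.null(previous)) {
      pm <- matrix(previous, prod(d[1:3]), d[4])
      m[, dead] <- pm[, dead]
      nrm[dead] <- sqrt(colSums(m[, dead, drop = FALSE]^2))
    } else nrm[dead] <- 1
  }
  m <- sweep(m, 2, pmax(nrm, 1e-300), "/")
  out <- array(m, dim = d)
  attr(out, "dead") <- which(dead)
  out
}

# per-input geometry of the two-layer architecture
net_geometry <- function(net, in_dim) {
  l1 <- net$layers[[1]]
  H1 <- (in_dim[1] - l1$kernel_size) %/% l1$stride + 1L
  W1 <- (in_dim[2] - l1$kernel_size) %/% l1$stride + 1L
  if (H1 < 1L || W1 < 1L) stop("input smaller than first-layer kernel")
  g <- list(in_dim = in_dim, d_gs = c(H1, W1, l1$n_units))
  if (length(net$layers) == 2L) {
    mp <- max_pool(array(0, dim = c(H1, W1, l1$n_units)), net$pooling, 1L)
    dp <- dim(mp$output)
    l2 <- net$layers[[2]]
    H2 <- (dp[1] - l2$kernel_size) %/% l2$stride + 1L
    W2 <- (dp[2] - l2$kernel_size) %/% l2$stride + 1L
    if (H2 < 1L || W2 < 1L) stop("pooled map smaller than second-layer kernel")
    g$d_pool <- dp
    g$d_gc <- c(H2, W2, l2$n_units)
  }
  g
}

# encode a pooling_spec for the compiled inference loop: integer stage codes
# plus the per-stage spatial pads resolved against the first-layer map dims
encode_stages <- function(spec, d_gs, n) {
  kinds <- c(identity = 0L, spatial_2d = 1L, feature_1d_circular = 2L,
             feature_2d_toroidal = 3L)
  ns <- length(spec$stages)
  kind <- integer(ns); kernel <- integer(ns); stride <- integer(ns)
  pads <- matrix(0L, ns, 4)
  H <- d_gs[1]; W <- d_gs[2]
  for (i in seq_len(ns)) {
    s <- spec$stages[[i]]
    kind[i] <- kinds[[s$kind]]
    kernel[i] <- s$kernel
    stride[i] <- s$stride
    if (s$kind == "spatial_2d") {
      p <- spatial_pad(H, W, s$kernel, s$stride, s$pad)
      pads[i, ] <- p
      H <- (H + p[1] + p[3] - s$kernel) %/% s$stride + 1L
      W <- (W + p[2] + p[4] - s$kernel) %/% s$stride + 1L
    }
  }
  list(kind = kind, kernel = kernel, stride = stride, pads = pads)
}

# auto step sizes (see sdpc_control); returns c(eta_S, eta_C)
auto_steps <- function(net, in_dim) {
  l1 <- net$layers[[1]]
  W1m <- kernels_to_mat(net$kernels[[1]])
  L1 <- conv_sq_norm(W1m, l1$kernel_size, l1$stride, 1L, in_dim)
  if (length(net$layers) == 1L)
    return(c(0.9 / max(L1, 1e-12), NA_real_))
  geom <- net_geometry(net, in_dim)
  L1 <- L1 + unpool_multiplicity(net$pooling)
  l2 <- net$layers[[2]]
  W2m <- kernels_to_mat(net$kernels[[2]])
  L2 <- conv_sq_norm(W2m, l2$kernel_size, l2$stride, l1$n_units,
                     geom$d_pool[1:2])
  c(0.9 / max(L1, 1e-12), 0.9 / max(L2, 1e-12))
}

#' Loss of the hierarchical generative model
#'
#' Evaluates `0.5*||eps_S||^2 + 0.5*||eps_C||^2 + lambda_S*||gamma_S||_1 +
#' lambda_C*||gamma_C||_1` from scratch, with `eps_S = x - W_S^T gamma_S`
#' (transpose convolution) and `eps_C = p_S(gamma_S) - W_C^T gamma_C`.
#'
#' @param x input image array `(H, W, n)`.
#' @param net an `"sdpc_net"` or fitted `"sdpc"` object.
#' @param gamma list of activity arrays, one per layer (batch stacked in the
#'   slice dimension).
#' @param lambdas per-layer sparsity penalties; defaults to the layers'
#'   `sparsity` fields.
#' @return the scalar loss.
#' @export
sdpc_loss <- function(x, net, gamma, lambdas = NULL) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[3]
  if (is.null(lambdas)) lambdas <- vapply(net$layers, `[[`, 0, "sparsity")
  if (any(lambdas < 0)) stop("lambdas must be nonnegative")
  geom <- net_geometry(net, dim(x)[1:2])
  l1 <- net$layers[[1]]
  if (!all(dim(gamma[[1]]) == c(geom$d_gs[1:2], n * l1$n_units)))
    stop("dimension error: gamma_S shape inconsistent with architecture")
  W1m <- kernels_to_mat(net$kernels[[1]])
  recon <- conv_transpose(gamma[[1]], W1m, l1$kernel_size, l1$stride, 1L,
                          dim(x)[1], dim(x)[2])
  eps_s <- x - recon
  F <- 0.5 * sum(eps_s^2) + lambdas[1] * sum(abs(gamma[[1]]))
  if (length(net$layers) == 2L) {
    l2 <- net$layers[[2]]
    if (!all(dim(gamma[[2]]) == c(geom$d_gc[1:2], n * l2$n_units)))
      stop("dimension error: gamma_C shape inconsistent with architecture")
    pooled <- max_pool(gamma[[1]], net$pooling, n)$output
    W2m <- kernels_to_mat(net$kernels[[2]])
    recon_c <- conv_transpose(gamma[[2]], W2m, l2$kernel_size, l2$stride,
                              l1$n_units, dim(pooled)[1], dim(pooled)[2])
    eps_c <- pooled - recon_c
    F <- F + 0.5 * sum(eps_c^2) + lambdas[2] * sum(abs(gamma[[2]]))
  }
  F
}

#' Infer neural responses for a batch of images
#'
#' Proximal gradient descent on the model loss over the nonnegative sparse
#' activities of both layers, in alternating (Gauss-Seidel) sweeps with
#' Nesterov acceleration; a candidate step is accepted only when its block
#' objective does not increase (monotone variant), so the recorded loss trace
#' is non-increasing. Pooling switches are recomputed at every iteration.
#' The first-layer update receives the second-layer prediction error routed
#' backwards through the pooling switches unless `feedback = FALSE`.
#'
#' @param x image array `(H, W)` or `(H, W, n)`.
#' @param net an `"sdpc_net"` or fitted `"sdpc"` object.
#' @param lambdas per-layer sparsity penalties (defaults to the layer specs).
#' @param control an [sdpc_control()]; `inference_max_iters`, `inference_tol`,
#'   `inference_step` and `feedback` are honoured.
#' @param max_iters optional override of the iteration cap.
#' @param etas optional length-2 vector of precomputed step sizes (used by
#'   the trainer to avoid re-estimating them every minibatch).
#' @return an object of class `"sdpc_state"`: activities `gamma` (list),
#'   prediction errors `errors`, the pooled first-layer map and its
#'   assignment, and the recorded `loss_trace`.
#' @export
sdpc_infer <- function(x, net, lambdas = NULL, control = NULL,
                       max_iters = NULL, etas = NULL) {
  if (is.null(control))
    control <- if (!is.null(net$control)) net$control else sdpc_control()
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[3]
  if (is.null(lambdas)) lambdas <- vapply(net$layers, `[[`, 0, "sparsity")
  two <- length(net$layers) == 2L
  geom <- net_geometry(net, dim(x)[1:2])
  l1 <- net$layers[[1]]
  W1m <- kernels_to_mat(net$kernels[[1]])
  if (two) {
    l2 <- net$layers[[2]]
    W2m <- kernels_to_mat(net$kernels[[2]])
  }
  if (is.null(etas))
    etas <- if (is.numeric(control$inference_step))
      rep(control$inference_step, 2) else auto_steps(net, dim(x)[1:2])
  cap <- if (is.null(max_iters)) control$inference_max_iters else max_iters
  enc <- encode_stages(net$pooling, geom$d_gs, n)
  res <- cpp_infer(x, W1m, l1$kernel_size, l1$stride,
                   if (two) W2m else matrix(0, 1, 1),
                   if (two) l2$kernel_size else 1L,
                   if (two) l2$stride else 1L,
                   l1$n_units, if (two) l2$n_units else 0L, two,
                   enc$kind, enc$kernel, enc$stride, enc$pads,
                   lambdas[1], if (two) lambdas[2] else 0,
                   etas[1], if (two) etas[2] else 1,
                   cap, control$inference_tol, control$feedback)
  gs <- res$gs
  mp <- if (two) max_pool(gs, net$pooling, n) else NULL
  state <- structure(list(
    gamma = if (two) list(gs, res$gc) else list(gs),
    errors = if (two) list(res$eps_s, res$eps_c) else list(res$eps_s),
    pooled = if (two) mp$output else NULL,
    assignment = if (two) mp$assignment else NULL,
    loss_trace = as.numeric(res$loss_trace),
    iterations = res$iterations, converged = res$converged,
    n_images = n, etas = etas, lambdas = lambdas), class = "sdpc_state")
  return(state)

}

#' One dictionary learning step
#'
#' Hebbian-style momentum update `W <- W + omega * v`,
#' `v <- beta * v + corr(gamma, eps)` for each layer, where `corr` is the
#' convolutional correlation implied by the transpose-convolution generative
#' model (the negative loss gradient), followed by renormalisation of every
#' kernel to unit Euclidean norm. Kernels whose update collapses to zero norm
#' are kept at their previous value with a "dead kernel" warning.
#'
#' @param net an `"sdpc_net"`.
#' @param state an `"sdpc_state"` from [sdpc_infer()] for the same batch.
#' @param omega learning step size.
#' @param beta momentum in `[0, 1)`.
#' @param velocity list of velocity matrices from the previous step, or
#'   `NULL`.
#' @return list with updated `kernels`, `velocity`, and `dead` (indices of
#'   dead kernels per layer).
#' @export
sdpc_learning_step <- function(net, state, omega = 0.01, beta = 0.9,
                               velocity = NULL) {
  nl <- length(net$layers)
  kernels <- net$kernels
  dead <- vector("list", nl)
  if (is.null(velocity))
    velocity <- lapply(kernels, function(a) array(0, dim = dim(a)))
  for (li in seq_len(nl)) {
    l <- net$layers[[li]]
    C <- if (li == 1L) 1L else net$layers[[li - 1L]]$n_units
    g <- dict_grad(state$gamma[[li]], l$n_units, state$errors[[li]], C,
                   l$kernel_size, l$stride)
    gk <- mat_to_kernels(g, l$kernel_size, C)
    velocity[[li]] <- beta * velocity[[li]] + gk
    upd <- kernels[[li]] + omega * velocity[[li]]
    new <- normalize_kernels(upd, previous = kernels[[li]])
    if (length(attr(new, "dead")))
      warning(sprintf("dead kernel(s) in layer %d: %s (kept at previous value)",
                      li, paste(attr(new, "dead"), collapse = ", ")))
    dead[[li]] <- attr(new, "dead")
    attr(new, "dead") <- NULL
    kernels[[li]] <- new
  }
  list(kernels = kernels, velocity = velocity, dead = dead)
}

#' Composite receptive field sizes
#'
#' Side length, in input pixels, of the receptive field of a unit in each
#' layer, from the usual kernel/stride recursion `r <- r + (k - 1) * jump`;
#' only spatial pooling stages advance the recursion (feature pooling leaves
#' the retinotopic geometry unchanged).
#'
#' @param layers list of [sdpc_layer()] objects.
#' @param pooling a [pooling_spec()].
#' @return integer vector of receptive-field side lengths per layer.
#' @examples
#' receptive_field(list(sdpc_layer(36, 7), sdpc_layer(36, 4)),
#'                 pooling_spec("spatial_2d"))  # 7 14
#' @export
receptive_field <- function(layers, pooling = pooling_spec("identity")) {
  r <- 1L; j <- 1L
  out <- integer(length(layers))
  l1 <- layers[[1]]
  r <- r + (l1$kernel_size - 1L) * j
  j <- j * l1$stride
  out[1] <- r
  if (length(layers) >= 2L) {
    for (s in pooling$stages) {
      if (s$kind == "spatial_2d") {
        r <- r + (s$kernel - 1L) * j
        j <- j * s$stride
      }
    }
    l2 <- layers[[2]]
    r <- r + (l2$kernel_size - 1L) * j
    j <- j * l2$stride
    out[2] <- r
  }
  out
}
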