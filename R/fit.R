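#' Fit a two-layer sparse predictive coding model
#'
#' Trains the dictionaries of a two-layer convolutional sparse coding network
#' with hierarchical feedback by alternating inference ([sdpc_infer()]) and
#' dictionary learning ([sdpc_learning_step()]) over minibatches. The sparsity
#' penalties are ramped linearly from 0 to the layers' target values over the
#' first `lambda_ramp` fraction of the iterations and held constant
#' afterwards. Training is fully reproducible given `control$seed`.
#'
#' @param x training images: an array `(H, W, n)` or an `"image_batch"` from
#'   [whiten_images()] / [synthetic_images()], values in `[-1, 1]`.
#' @param layers list of one or two [sdpc_layer()] objects.
#' @param pooling a [pooling_spec()] applied between the layers.
#' @param control an [sdpc_control()].
#' @param log_file optional path; when given, the per-iteration trace is
#'   written there as CSV.
#' @return an object of class `c("sdpc", "sdpc_net")` with elements `kernels`
#'   (list of `[k, k, C, M]` arrays), `layers`, `pooling`, `control`, `trace`
#'   (a per-iteration data frame), `lambdas` (final penalties), `dead_log`,
#'   and `in_dim`.
#' @examples
#' imgs <- synthetic_images(16, size = 20, seed = 1)
#' fit <- sdpc(imgs,
#'             layers = list(sdpc_layer(9, 5), sdpc_layer(9, 3)),
#'             pooling = pooling_spec("spatial_2d"),
#'             control = sdpc_control(iterations = 5, batch_size = 4,
#'                                    train_inference_iters = 10))
#' print(fit)
#' @export
sdpc <- function(x,
                 layers = list(sdpc_layer(36, 7), sdpc_layer(36, 4)),
                 pooling = pooling_spec("spatial_2d", "feature_2d_toroidal"),
                 control = sdpc_control(),
                 log_file = NULL) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  n <- dim(x)[3]
  if (n < 1L) stop("empty dataset")
  check_whitened(x)
  net <- sdpc_network(layers, pooling, seed = control$seed)
  lam_target <- vapply(layers, `[[`, 0, "sparsity")
  iters <- control$iterations
  trace <- matrix(NA_real_, nrow = iters, ncol = 8L)
  colnames(trace) <- c("iteration", "loss", "eps_s_energy", "eps_c_energy",
                       "sparsity_s", "sparsity_c", "lambda_s", "lambda_c")
  velocity <- NULL
  dead_log <- list()
  etas <- NULL
  two <- length(layers) == 2L
  ramp_iters <- max(1, floor(control$lambda_ramp * iters))
  with_seed(control$seed, {
    for (it in seq_len(iters)) {
      lam <- lam_target * min(1, it / ramp_iters)
      idx <- sample.int(n, control$batch_size, replace = TRUE)
      xb <- x[, , idx, drop = FALSE]
      if (is.null(etas) || (it - 1L) %% control$step_refresh == 0L) {
        etas <- if (is.numeric(control$inference_step))
          rep(control$inference_step, 2) else auto_steps(net, dim(x)[1:2])
      }
      state <- withCallingHandlers(
        sdpc_infer(xb, net, lambdas = lam, control = control,
                   max_iters = control$train_inference_iters, etas = etas),
        warning = function(w) invokeRestart("muffleWarning"))
      # omega applies to the minibatch-mean gradient (the correlation in
      # sdpc_learning_step sums over the batch)
      ls <- withCallingHandlers(
        sdpc_learning_step(net, state,
                           omega = control$learning_rate / control$batch_size,
                           beta = control$momentum, velocity = velocity),
        warning = function(w) {
          dead_log[[length(dead_log) + 1L]] <<- list(iteration = it,
                                                     message = conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      net$kernels <- ls$kernels
      velocity <- ls$velocity
      gs <- state$gamma[[1]]
      trace[it, ] <- c(it, state$loss_trace[length(state$loss_trace)],
                       sum(state$errors[[1]]^2),
                       if (two) sum(state$errors[[2]]^2) else NA_real_,
                       mean(gs == 0),
                       if (two) mean(state$gamma[[2]] == 0) else NA_real_,
                       lam[1], if (two) lam[2] else NA_real_)
    }
  })
  fit <- structure(list(kernels = net$kernels, layers = layers,
                        pooling = pooling, control = control,
                        trace = as.data.frame(trace), lambdas = lam_target,
                        dead_log = dead_log, in_dim = dim(x)[1:2],
                        seed = control$seed, call = match.call()),
                   class = c("sdpc", "sdpc_net"))
  if (!is.null(log_file)) write.csv(fit$trace, log_file, row.names = FALSE)
  fit
}

check_whitened <- function(x) {
  wh <- attr(x, "whitened")
  if (isTRUE(wh)) return(invisible(TRUE))
  if (max(abs(x)) > 1 + 1e-8) {
    warning("input does not look whitened (values outside [-1, 1]); consider whiten_images()")
    return(invisible(FALSE))
  }
  # steeply falling amplitude spectrum suggests raw (unwhitened) images
  n <- dim(x)[3]
  sl <- mean(vapply(seq_len(min(n, 8L)), function(i)
    spectral_slope(x[, , i]), 0), na.rm = TRUE)
  if (is.finite(sl) && sl < -0.6)
    warning(sprintf(paste0("input amplitude spectrum falls like f^%.2f; ",
                           "this looks unwhitened (consider whiten_images())"), sl))
  invisible(TRUE)
}

#' @export
print.sdpc <- function(x, ...) {
  cat("Two-layer sparse predictive coding model\n")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d: %d kernels %dx%d, stride %d, lambda %.3g\n",
                i, l$n_units, l$kernel_size, l$kernel_size, l$stride,
                l$sparsity))
  }
  print(x$pooling)
  tr <- x$trace
  if (nrow(tr))
    cat(sprintf("  trained %d iterations (batch %d): loss %.4g -> %.4g\n",
                nrow(tr), x$control$batch_size, tr$loss[1],
                tr$loss[nrow(tr)]))
  invisible(x)
}

#' @export
summary.sdpc <- function(object, ...) {
  tr <- object$trace
  out <- list(
    architecture = vapply(object$layers, function(l)
      sprintf("%d x %dx%d", l$n_units, l$kernel_size, l$kernel_size), ""),
    pooling = pooling_label(object$pooling),
    receptive_field = receptive_field(object$layers, object$pooling),
    iterations = nrow(tr),
    loss = c(first = tr$loss[1], last = tr$loss[nrow(tr)]),
    final_sparsity = c(s = tr$sparsity_s[nrow(tr)], c = tr$sparsity_c[nrow(tr)]),
    lambdas = object$lambdas,
    feedback = object$control$feedback,
    n_dead_events = length(object$dead_log))
  class(out) <- "summary.sdpc"
  out
}

#' @export
print.summary.sdpc <- function(x, ...) {
  cat("Layers:", paste(x$architecture, collapse = " | "),
      " pooling:", x$pooling, "\n")
  cat("Receptive fields (px):", paste(x$receptive_field, collapse = ", "), "\n")
  cat(sprintf("Iterations: %d  loss %.4g -> %.4g\n", x$iterations,
              x$loss["first"], x$loss["last"]))
  cat(sprintf("Final zero fraction: layer 1 %.2f, layer 2 %.2f\n",
              x$final_sparsity["s"], x$final_sparsity["c"]))
  cat(sprintf("Feedback: %s; dead-kernel events: %d\n",
              x$feedback, x$n_dead_events))
  invisible(x)
}

#' @export
coef.sdpc <- function(object, layer = 1L, ...) object$kernels[[layer]]

#' Inferred responses for new images
#'
#' @param object a fitted `"sdpc"` model.
#' @param newdata image array `(H, W)` or `(H, W, n)`.
#' @param type `"activities"` returns the full inference state,
#'   `"reconstruction"` the first-layer reconstruction of the input,
#'   `"pooled"` the pooled first-layer map.
#' @param ... passed to [sdpc_infer()].
#' @export
predict.sdpc <- function(object, newdata,
                         type = c("activities", "reconstruction", "pooled"),
                         ...) {
  type <- match.arg(type)
  state <- sdpc_infer(newdata, object, ...)
  switch(type,
         activities = state,
         pooled = state$pooled,
         reconstruction = {
           if (length(dim(newdata)) == 2L) dim(newdata) <- c(dim(newdata), 1L)
           newdata - state$errors[[1]]
         })
}

#' @export
fitted.sdpc <- function(object, newdata, ...)
  predict(object, newdata, type = "reconstruction", ...)

#' @export
residuals.sdpc <- function(object, newdata, ...) {
  state <- sdpc_infer(newdata, object, ...)
  state$errors
}

#' Plot first-layer kernels or an orientation map
#'
#' @param x a fitted `"sdpc"` model.
#' @param what `"kernels"` draws the mosaic of first-layer kernels in their
#'   feature-space arrangement; `"map"` draws the preferred-orientation map.
#' @param layer which layer's kernels to draw.
#' @param ... ignored.
#' @export
plot.sdpc <- function(x, what = c("kernels", "map"), layer = 1L, ...) {
  what <- match.arg(what)
  if (what == "kernels") {
    kern <- x$kernels[[layer]]
    M <- dim(kern)[4]
    G <- ceiling(sqrt(M))
    k <- dim(kern)[1]
    mos <- matrix(NA_real_, G * (k + 1) - 1, G * (k + 1) - 1)
    for (m in seq_len(M)) {
      r <- (m - 1) %/% G; c <- (m - 1) %% G
      mos[r * (k + 1) + 1:k, c * (k + 1) + 1:k] <- kern[, , 1, m]
    }
    image(t(mos[nrow(mos):1, ]), col = gray.colors(128), axes = FALSE,
          main = sprintf("layer %d kernels", layer), useRaster = TRUE)
  } else {
    om <- orientation_map(x)
    plot(om)
  }
  invisible(x)
}
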