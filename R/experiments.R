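#' Build the pooling-by-size experiment grid
#'
#' Enumerates the Cartesian product of first- and second-layer sizes for each
#' pooling variant (6 x 6 sizes gives 36 networks per pooling function), with
#' a per-cell seed derived from the master seed by a counter.
#'
#' @param poolings character vector of pooling variants (see
#'   [pooling_spec()]; `"+"`-combined strings allowed).
#' @param sizes candidate layer sizes, used for both `M_s` and `M_c`.
#' @param seed master seed; cell `i` gets `seed + i`.
#' @param scale `"reduced"` or `"full"` training scale (stored on each
#'   config).
#' @return list of config lists (pooling, M_s, M_c, seed, scale), ordered
#'   pooling-major, then `M_s`, then `M_c`.
#' @export
experiment_grid <- function(poolings = c("spatial_2d", "feature_2d_toroidal",
                                         "spatial_2d+feature_1d_circular",
                                         "spatial_2d+feature_2d_toroidal"),
                            sizes = c(36, 49, 64, 81, 100, 121),
                            seed = 1L, scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  if (length(poolings) < 1L || length(sizes) < 1L)
    stop("need at least one pooling variant and one size")
  configs <- list()
  counter <- 0L
  for (p in poolings) {
    spec <- pooling_spec(p)
    for (Ms in sizes) {
      if (feature_topology(spec) == "grid_toroidal" &&
          round(sqrt(Ms))^2 != Ms)
        stop(sprintf("size %d is not a perfect square but pooling '%s' needs a 2D feature grid",
                     Ms, p))
      for (Mc in sizes) {
        counter <- counter + 1L
        configs[[counter]] <- list(pooling = p, M_s = as.integer(Ms),
                                   M_c = as.integer(Mc),
                                   seed = as.integer(seed + counter),
                                   scale = scale, index = counter)
      }
    }
  }
  configs
}

# study-scale defaults; "full" mirrors the published protocol and needs an
# external natural-image dataset
scale_defaults <- function(scale) {
  if (scale == "reduced") {
    list(image_size = 28L, n_images = 1024L, iterations = 800L,
         batch_size = 8L, samples_per_cycle = 16L, n_backproject = 32L,
         probe_infer_iters = 30L)
  } else {
    list(image_size = 96L, n_images = 100000L, iterations = 28125L,
         batch_size = 32L, samples_per_cycle = 32L, n_backproject = 200L,
         probe_infer_iters = 100L)
  }
}

#' Train and analyse one network configuration
#'
#' Trains a two-layer model at the configured pooling and sizes, probes the
#' requested layers with drifting/rotating gratings, and (when the pooling
#' defines a feature topology) computes the orientation map, LHI, pinwheels
#' and the HWHH-vs-LHI regression. Synthetic whitened images are generated
#' unless `images` is given. Fully deterministic given the config seed.
#'
#' @param config one cell from [experiment_grid()], or a list with fields
#'   `pooling`, `M_s`, `M_c`, `seed`, `scale`.
#' @param images optional training image batch (whitened).
#' @param probe_layers layers to probe (default 2; add 1 for first-layer
#'   modulation statistics; empty to skip probing, e.g. for map-only
#'   controls).
#' @param protocols grating protocols passed to [probe_population()].
#' @param optimal preferred-stimulus assignment mode, see [probe_population()].
#' @param iterations,batch_size optional overrides of the scale defaults.
#' @param feedback set `FALSE` for the feedback-ablated control.
#' @param lambda sparsity target for both layers.
#' @return a `"run_report"`: config, fitted model, per-unit probe table,
#'   `summary` ([population_summary()]), orientation map, LHI, pinwheels.
#' @export
run_experiment <- function(config, images = NULL, probe_layers = 2L,
                           protocols = c("drift", "rotate"),
                           optimal = "empirical",
                           iterations = NULL, batch_size = NULL,
                           feedback = TRUE, lambda = 0.1) {
  sc <- scale_defaults(if (is.null(config$scale)) "reduced" else config$scale)
  if (!is.null(iterations)) sc$iterations <- iterations
  if (!is.null(batch_size)) sc$batch_size <- batch_size
  if (is.null(images))
    images <- synthetic_images(sc$n_images, sc$image_size,
                               seed = config$seed, whiten = TRUE)
  ctrl <- sdpc_control(iterations = sc$iterations, batch_size = sc$batch_size,
                       feedback = feedback, seed = config$seed)
  fit <- sdpc(images,
              layers = list(sdpc_layer(config$M_s, 7, sparsity = lambda),
                            sdpc_layer(config$M_c, 4, sparsity = lambda)),
              pooling = pooling_spec(config$pooling),
              control = ctrl)
  bp_images <- array(images[, , seq_len(min(dim(images)[3], sc$n_backproject))],
                     dim = c(dim(images)[1:2],
                             min(dim(images)[3], sc$n_backproject)))
  units <- if (length(probe_layers))
    probe_population(fit, layers = probe_layers, images = bp_images,
                     samples_per_cycle = sc$samples_per_cycle,
                     infer_iters = sc$probe_infer_iters,
                     protocols = protocols, optimal = optimal)
  else NULL
  omap <- NULL; lhi <- NULL; pw <- NULL; density <- NULL
  if (feature_topology(fit$pooling) != "none") {
    omap <- orientation_map(fit, layer = 1L)
    lhi <- compute_lhi(omap)
    if (omap$topology == "grid_toroidal") {
      pw <- detect_pinwheels(lhi)
      mh <- mean(omap$hwhh, na.rm = TRUE)
      density <- tryCatch(
        suppressWarnings(pinwheel_density(pw, config$M_s, mh)),
        error = function(e) NULL)
    }
  }
  summ <- if (is.null(units)) NULL else population_summary(units, lhi = lhi)
  structure(list(config = config, fit = fit, units = units, summary = summ,
                 orientation_map = omap, lhi = lhi, pinwheels = pw,
                 pinwheel_density = density,
                 mean_lhi = if (is.null(lhi)) NA_real_ else mean(lhi$lhi),
                 schema_version = 1L),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run: pooling %s, M_s = %d, M_c = %d (seed %d)\n",
              x$config$pooling, x$config$M_s, x$config$M_c, x$config$seed))
  if (!is.null(x$summary)) print(x$summary)
  if (!is.null(x$pinwheels)) print(x$pinwheels)
  invisible(x)
}

#' Aggregate run reports into tables
#'
#' @param reports list of `"run_report"` objects.
#' @return list of data frames: `population` (R_phi/R_theta per layer and
#'   run) and `maps` (mean LHI, pinwheel count and density per run).
#' @export
experiment_report <- function(reports) {
  if (length(reports) < 1L) stop("need at least one run report")
  vers <- vapply(reports, function(r) r$schema_version %||% NA_integer_, 0L)
  if (length(unique(vers)) > 1L) stop("mixed report schema versions")
  pop <- do.call(rbind, lapply(reports, function(r) {
    d <- r$summary$per_layer
    cbind(data.frame(pooling = r$config$pooling, M_s = r$config$M_s,
                     M_c = r$config$M_c, seed = r$config$seed), d)
  }))
  maps <- do.call(rbind, lapply(reports, function(r) {
    data.frame(pooling = r$config$pooling, M_s = r$config$M_s,
               M_c = r$config$M_c,
               mean_lhi = r$mean_lhi,
               pinwheels = if (is.null(r$pinwheels)) NA_integer_ else r$pinwheels$count,
               rho = if (is.null(r$pinwheel_density)) NA_real_ else r$pinwheel_density$rho,
               column_size = if (is.null(r$pinwheel_density)) NA_real_ else r$pinwheel_density$c)
  }))
  list(population = pop, maps = maps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
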