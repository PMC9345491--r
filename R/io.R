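#' Save / load a model container
#'
#' A fitted model (kernels, layer and pooling specification, control
#' parameters, training trace) is stored in a single serialized container
#' with a versioned schema key.
#'
#' @param fit an `"sdpc"` (or `"sdpc_net"`) object.
#' @param path file path.
#' @return `read_sdpc` returns the stored object; `write_sdpc` the path,
#'   invisibly.
#' @export
write_sdpc <- function(fit, path) {
  stopifnot(inherits(fit, "sdpc_net") || inherits(fit, "sdpc"))
  saveRDS(list(schema_version = 1L, object = fit), path)
  invisible(path)
}

#' @rdname write_sdpc
#' @export
read_sdpc <- function(path) {
  x <- readRDS(path)
  if (!is.list(x) || is.null(x$schema_version))
    stop("not a model container (missing schema key)")
  if (x$schema_version != 1L)
    stop(sprintf("unsupported container schema version %s", x$schema_version))
  x$object
}

#' Read / write a network configuration file
#'
#' YAML configuration mirroring the constructor arguments: a `layers` list
#' (fields of [sdpc_layer()]), a `pooling` list of stage descriptors (fields
#' of [pool_stage()], kinds spelled `spatial_2d`, `feature_1d_circular`,
#' `feature_2d_toroidal`, `identity`), and a `control` block (fields of
#' [sdpc_control()]).
#'
#' @param path YAML file path.
#' @return `read_sdpc_config` returns `list(layers, pooling, control)`.
#' @export
read_sdpc_config <- function(path) {
  y <- yaml::read_yaml(path)
  layers <- lapply(y$layers, function(l) do.call(sdpc_layer, l))
  stages <- lapply(y$pooling, function(s) do.call(pool_stage, s))
  pooling <- do.call(pooling_spec, stages)
  control <- do.call(sdpc_control, if (is.null(y$control)) list() else y$control)
  list(layers = layers, pooling = pooling, control = control)
}

#' @rdname read_sdpc_config
#' @param layers,pooling,control the objects to serialise.
#' @export
write_sdpc_config <- function(path, layers, pooling, control = sdpc_control()) {
  y <- list(
    layers = lapply(layers, function(l) l[c("n_units", "kernel_size",
                                            "stride", "sparsity")]),
    pooling = lapply(pooling$stages, function(s) {
      out <- s[c("kind", "kernel", "stride")]
      if (!is.null(s$pad)) out$pad <- s$pad
      out
    }),
    control = unclass(control))
  yaml::write_yaml(y, path)
  invisible(path)
}
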