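# Brute-force reference implementations used as independent oracles.

# spatial max pooling by exhaustive window scan (no padding)
bf_pool_spatial <- function(g, k, stride) {
  d <- dim(g)
  Ho <- (d[1] - k) %/% stride + 1L
  Wo <- (d[2] - k) %/% stride + 1L
  out <- array(NA_real_, c(Ho, Wo, d[3]))
  for (s in seq_len(d[3]))
    for (r in seq_len(Ho))
      for (c in seq_len(Wo))
        out[r, c, s] <- max(g[(r - 1) * stride + 1:k,
                              (c - 1) * stride + 1:k, s])
  out
}

# circular 1D feature pooling oracle
bf_pool_feat1d <- function(g, k) {
  d <- dim(g)
  M <- d[3]
  out <- array(NA_real_, d)
  for (j in seq_len(M)) {
    win <- ((j - 1) + 0:(k - 1)) %% M + 1L
    out[, , j] <- apply(g[, , win, drop = FALSE], c(1, 2), max)
  }
  out
}

# toroidal 2D feature pooling oracle (row-major channel grid)
bf_pool_feat2d <- function(g, k) {
  d <- dim(g)
  M <- d[3]
  G <- as.integer(round(sqrt(M)))
  out <- array(NA_real_, d)
  for (gr in 0:(G - 1)) for (gc in 0:(G - 1)) {
    win <- integer(0)
    for (dr in 0:(k - 1)) for (dc in 0:(k - 1))
      win <- c(win, ((gr + dr) %% G) * G + ((gc + dc) %% G) + 1L)
    out[, , gr * G + gc + 1L] <- apply(g[, , win, drop = FALSE], c(1, 2), max)
  }
  out
}

# naive double-loop LHI on a toroidal grid
bf_lhi_grid <- function(theta, sigma = 1) {
  G1 <- nrow(theta); G2 <- ncol(theta)
  w <- ceiling(3 * sigma)
  out <- matrix(NA_real_, G1, G2)
  for (r in seq_len(G1)) for (c in seq_len(G2)) {
    num <- 0 + 0i; den <- 0
    for (dr in -w:w) for (dc in -w:w) {
      if (dr == 0 && dc == 0) next
      g <- exp(-(dr^2 + dc^2) / (2 * sigma^2))
      th <- theta[(r - 1 + dr) %% G1 + 1, (c - 1 + dc) %% G2 + 1]
      num <- num + g * exp(2i * th * pi / 180)
      den <- den + g
    }
    out[r, c] <- Mod(num) / den
  }
  out
}

# torus-consistent synthetic orientation map with an opposite-winding
# pinwheel pair (net index zero)
pinwheel_pair_map <- function(G = 15, p1 = c(4, 4), p2 = c(12, 12)) {
  outer(seq_len(G), seq_len(G), function(r, c)
    (0.5 * (atan2(r - p1[1], c - p1[2]) - atan2(r - p2[1], c - p2[2])) *
       180 / pi) %% 180)
}

# single-pinwheel map centred on a lattice point of an odd grid
pinwheel_map <- function(G = 11) {
  x0 <- (G + 1) / 2
  outer(seq_len(G), seq_len(G), function(r, c)
    (0.5 * atan2(r - x0, c - x0) * 180 / pi) %% 180)
}

# small random two-layer network + image for inference/learning tests
random_instance <- function(seed, pooling = pooling_spec("spatial_2d"),
                            size = 16L, M1 = 16L, M2 = 9L, k1 = 5L, k2 = 3L,
                            lambda = 0.05) {
  net <- sdpc_network(list(sdpc_layer(M1, k1, sparsity = lambda),
                           sdpc_layer(M2, k2, sparsity = lambda)),
                      pooling, seed = seed)
  x <- withr::with_seed(seed, array(runif(size * size, -1, 1),
                                    dim = c(size, size, 1)))
  list(net = net, x = x, lambda = lambda)
}

all_poolings <- function() list(
  pooling_spec("spatial_2d"),
  pooling_spec("feature_2d_toroidal"),
  pooling_spec("spatial_2d", "feature_1d_circular"),
  pooling_spec("spatial_2d", "feature_2d_toroidal"))
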