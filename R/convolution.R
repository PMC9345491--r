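# Internal convolution helpers. Kernels live in R as [k, k, C, M] arrays;
# the GEMM path wants them as an (M, C*k*k) matrix with the same flattening.

kernels_to_mat <- function(kern) {
  d <- dim(kern)
  t(matrix(kern, d[1] * d[2] * d[3], d[4]))
}

mat_to_kernels <- function(Wm, k, C) {
  M <- nrow(Wm)
  array(t(Wm), dim = c(k, k, C, M))
}

conv_forward <- function(x, Wm, k, stride = 1L, C = 1L) {
  cpp_conv_forward(x, as.integer(C), Wm, as.integer(k), as.integer(stride))
}

conv_transpose <- function(g, Wm, k, stride = 1L, C = 1L, H, W) {
  M <- nrow(Wm)
  cpp_conv_transpose(g, as.integer(M), Wm, as.integer(k), as.integer(stride),
                     as.integer(C), as.integer(H), as.integer(W))
}

dict_grad <- function(g, M, e, C, k, stride = 1L) {
  cpp_dict_grad(g, as.integer(M), e, as.integer(C), as.integer(k),
                as.integer(stride))
}

# squared spectral norm of the convolutional analysis/synthesis operator,
# estimated by power iteration on A^T A (A maps an activity map to its
# reconstruction).
conv_sq_norm <- function(Wm, k, stride, C, in_dim, n_iter = 20L) {
  H <- in_dim[1]; W <- in_dim[2]
  Hout <- (H - k) %/% stride + 1L
  Wout <- (W - k) %/% stride + 1L
  M <- nrow(Wm)
  v <- with_seed(7L, array(rnorm(Hout * Wout * M), dim = c(Hout, Wout, M)))
  v <- v / sqrt(sum(v^2))
  L <- 1
  for (i in seq_len(n_iter)) {
    u <- conv_transpose(v, Wm, k, stride, C, H, W)
    w <- conv_forward(u, Wm, k, stride, C)
    L <- sum(v * w)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) return(0)
    v <- w / nw
  }
  L
}

# evaluate `code` with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}
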