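test_that("soft thresholding follows the non-negative proximal rule", {
  expect_equal(soft_threshold(0.5, 0.1), 0.4)
  expect_equal(soft_threshold(0.05, 0.1), 0)
  expect_equal(soft_threshold(-0.3, 0), 0)
  a <- array(c(-1, 0.2, 0.6), dim = c(3, 1, 1))
  expect_equal(dim(soft_threshold(a, 0.25)), dim(a))
  expect_equal(as.numeric(soft_threshold(a, 0.25)), c(0, 0, 0.35))
  expect_error(soft_threshold(1, -0.1), "nonnegative")
})

test_that("the loss evaluator matches a term-by-term recomputation", {
  inst <- random_instance(11, pooling_spec("spatial_2d", "feature_1d_circular"))
  st <- sdpc_infer(inst$x, inst$net, max_iters = 15)
  # independent recomputation from definitions
  K1 <- inst$net$kernels[[1]]; K2 <- inst$net$kernels[[2]]
  gs <- st$gamma[[1]]; gc <- st$gamma[[2]]
  recon <- array(0, dim = dim(inst$x))
  d <- dim(gs)
  for (m in 1:16) for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    recon[r + 0:4, c + 0:4, 1] <- recon[r + 0:4, c + 0:4, 1] +
      gs[r, c, m] * K1[, , 1, m]
  }
  eps_s <- inst$x - recon
  pooled <- bf_pool_feat1d(bf_pool_spatial(gs, 2, 2), 4)
  recon_c <- array(0, dim = dim(pooled))
  dc <- dim(gc)
  for (m in 1:9) for (r in seq_len(dc[1])) for (c in seq_len(dc[2])) {
    recon_c[r + 0:2, c + 0:2, ] <- recon_c[r + 0:2, c + 0:2, ] +
      gc[r, c, m] * K2[, , , m]
  }
  eps_c <- pooled - recon_c
  F_bf <- 0.5 * sum(eps_s^2) + 0.5 * sum(eps_c^2) +
    inst$lambda * (sum(abs(gs)) + sum(abs(gc)))
  expect_equal(sdpc_loss(inst$x, inst$net, st$gamma), F_bf, tolerance = 1e-12)
  # zero-code case: loss reduces to the input energy
  g0 <- list(array(0, dim = dim(gs)), array(0, dim = dim(gc)))
  expect_equal(sdpc_loss(inst$x, inst$net, g0), 0.5 * sum(inst$x^2))
})

test_that("zero input is a fixed point of inference", {
  inst <- random_instance(12)
  st <- sdpc_infer(array(0, dim = dim(inst$x)), inst$net)
  expect_equal(sum(abs(st$gamma[[1]])), 0)
  expect_equal(sum(abs(st$gamma[[2]])), 0)
  expect_true(all(st$loss_trace == 0))
})

test_that("a single-layer first step equals the closed-form proximal update", {
  lam <- 0.03
  net <- sdpc_network(list(sdpc_layer(6, 5, sparsity = lam)),
                      pooling_spec("identity"), seed = 21)
  x <- withr::with_seed(21, array(runif(12 * 12, -1, 1), dim = c(12, 12, 1)))
  eta <- 0.05
  ctrl <- sdpc_control(inference_step = eta)
  st <- sdpc_infer(x, net, control = ctrl, max_iters = 1)
  Wm <- sdpcv1:::kernels_to_mat(net$kernels[[1]])
  expected <- pmax(eta * sdpcv1:::conv_forward(x, Wm, 5, 1, 1) - eta * lam, 0)
  expect_equal(st$gamma[[1]], expected, tolerance = 1e-12)
})

test_that("inference loss traces are non-increasing and activities non-negative", {
  pools <- all_poolings()
  for (i in 1:12) {
    inst <- random_instance(100 + i, pools[[(i %% 4) + 1]])
    st <- sdpc_infer(inst$x, inst$net, max_iters = 40)
    lt <- st$loss_trace
    expect_true(all(diff(lt) <= 1e-8 * pmax(abs(lt[-length(lt)]), 1e-300)))
    expect_true(all(st$gamma[[1]] >= 0))
    expect_true(all(st$gamma[[2]] >= 0))
    expect_true(all(is.finite(lt)))
  }
})

test_that("learning gradients match central finite differences of the loss", {
  inst <- random_instance(31, pooling_spec("spatial_2d"), size = 12L,
                          M1 = 8L, M2 = 4L, k1 = 5L, k2 = 3L)
  st <- sdpc_infer(inst$x, inst$net, max_iters = 25)
  lam <- c(inst$lambda, inst$lambda)
  h <- 1e-5
  for (layer in 1:2) {
    M <- inst$net$layers[[layer]]$n_units
    k <- inst$net$layers[[layer]]$kernel_size
    C <- if (layer == 1) 1L else inst$net$layers[[1]]$n_units
    g_an <- sdpcv1:::dict_grad(st$gamma[[layer]], M, st$errors[[layer]], C, k, 1L)
    set.seed(layer)
    for (trial in 1:8) {
      m <- sample(M, 1); i <- sample(k, 1); j <- sample(k, 1)
      ch <- sample(C, 1)
      netp <- inst$net; netp$kernels[[layer]][i, j, ch, m] <-
        netp$kernels[[layer]][i, j, ch, m] + h
      netm <- inst$net; netm$kernels[[layer]][i, j, ch, m] <-
        netm$kernels[[layer]][i, j, ch, m] - h
      fd <- (sdpc_loss(inst$x, netp, st$gamma, lam) -
             sdpc_loss(inst$x, netm, st$gamma, lam)) / (2 * h)
      an <- -g_an[m, (ch - 1) * k * k + (j - 1) * k + i]
      expect_equal(fd, an, tolerance = 1e-4)
    }
  }
})

test_that("learning keeps kernels at unit norm and zero error leaves them fixed", {
  inst <- random_instance(41)
  st <- sdpc_infer(inst$x, inst$net, max_iters = 20)
  ls <- sdpc_learning_step(inst$net, st, omega = 0.05, beta = 0.9)
  for (layer in 1:2) {
    d <- dim(ls$kernels[[layer]])
    nrm <- sqrt(colSums(matrix(ls$kernels[[layer]], prod(d[1:3]), d[4])^2))
    expect_true(all(abs(nrm - 1) < 1e-6))
  }
  # zero residuals: up to renormalisation the kernels are unchanged
  st0 <- st
  st0$errors <- lapply(st$errors, function(e) array(0, dim = dim(e)))
  ls0 <- sdpc_learning_step(inst$net, st0, omega = 0.05, beta = 0.9)
  expect_equal(ls0$kernels[[1]], inst$net$kernels[[1]], tolerance = 1e-12)
  expect_equal(ls0$kernels[[2]], inst$net$kernels[[2]], tolerance = 1e-12)
})

test_that("training is reproducible and zero iterations return the initialization", {
  imgs <- synthetic_images(12, 16, seed = 5, whiten = TRUE)
  layers <- list(sdpc_layer(9, 5), sdpc_layer(9, 3))
  ctrl <- sdpc_control(iterations = 8, batch_size = 4, seed = 7,
                       train_inference_iters = 8)
  f1 <- sdpc(imgs, layers, pooling_spec("spatial_2d"), ctrl)
  f2 <- sdpc(imgs, layers, pooling_spec("spatial_2d"), ctrl)
  expect_identical(f1$trace$loss, f2$trace$loss)
  expect_identical(f1$kernels, f2$kernels)
  ctrl0 <- sdpc_control(iterations = 0, seed = 7)
  f0 <- sdpc(imgs, layers, pooling_spec("spatial_2d"), ctrl0)
  net0 <- sdpc_network(layers, pooling_spec("spatial_2d"), seed = 7)
  expect_equal(f0$kernels, net0$kernels)
  expect_error(sdpc(array(0, dim = c(16, 16, 0)), layers,
                    pooling_spec("spatial_2d"), ctrl), "empty dataset")
})

test_that("lambda ramps monotonically to its target during training", {
  imgs <- synthetic_images(12, 16, seed = 5, whiten = TRUE)
  fit <- sdpc(imgs, list(sdpc_layer(9, 5, sparsity = 0.1), sdpc_layer(9, 3, sparsity = 0.1)),
              pooling_spec("spatial_2d"),
              sdpc_control(iterations = 12, batch_size = 4, seed = 7,
                           train_inference_iters = 6))
  lam <- fit$trace$lambda_s
  expect_true(all(diff(lam) >= 0))
  expect_equal(max(lam), 0.1)
})

test_that("disabling feedback removes exactly the second-layer error term from gamma_S", {
  inst <- random_instance(51, pooling_spec("spatial_2d", "feature_1d_circular"))
  eta <- 0.02
  ctrl_off <- sdpc_control(inference_step = eta, feedback = FALSE,
                           inference_tol = 1e-14)
  st_off <- sdpc_infer(inst$x, inst$net, control = ctrl_off, max_iters = 30)
  # without feedback, gamma_S evolves exactly as in a single-layer model:
  # the second layer can no longer influence it
  net1 <- sdpc_network(list(inst$net$layers[[1]]), pooling_spec("identity"),
                       kernels = list(inst$net$kernels[[1]]))
  st_solo <- sdpc_infer(inst$x, net1,
                        control = sdpc_control(inference_step = eta,
                                               inference_tol = 1e-14),
                        max_iters = 30)
  expect_equal(st_off$gamma[[1]], st_solo$gamma[[1]], tolerance = 1e-12)
  # with feedback on, the second layer does shape gamma_S
  ctrl_on <- sdpc_control(inference_step = eta, feedback = TRUE,
                          inference_tol = 1e-14)
  st_on <- sdpc_infer(inst$x, inst$net, control = ctrl_on, max_iters = 30)
  expect_gt(sum(abs(st_on$gamma[[1]] - st_off$gamma[[1]])), 1e-8)
})

test_that("receptive-field arithmetic reproduces the composite sizes", {
  layers <- list(sdpc_layer(36, 7), sdpc_layer(36, 4))
  expect_equal(receptive_field(layers, pooling_spec("spatial_2d")), c(7L, 14L))
  expect_equal(receptive_field(layers, pooling_spec("identity")), c(7L, 10L))
  expect_equal(receptive_field(layers, pooling_spec("feature_1d_circular")),
               c(7L, 10L)) # feature pooling leaves retinotopy unchanged
  expect_equal(receptive_field(layers,
                               pooling_spec("spatial_2d", "feature_2d_toroidal")),
               c(7L, 14L))
  expect_equal(receptive_field(list(sdpc_layer(4, 7)))[1], 7L)
})

test_that("an excessive fixed step size cannot make the loss diverge", {
  # candidate steps that would increase the loss are rejected, so even an
  # absurd step size leaves a finite, non-increasing trace
  inst <- random_instance(61, pooling_spec("spatial_2d"))
  ctrl <- sdpc_control(inference_step = 50)
  st <- sdpc_infer(inst$x, inst$net, control = ctrl, max_iters = 60)
  expect_true(all(is.finite(st$loss_trace)))
  expect_true(all(diff(st$loss_trace) <= 1e-12 * abs(st$loss_trace[-length(st$loss_trace)])))
  expect_true(all(is.finite(st$gamma[[1]])))
})
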