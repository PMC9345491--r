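test_that("spatial max pooling matches brute-force window enumeration", {
  set.seed(1)
  for (i in 1:50) {
    g <- array(runif(6 * 6 * 4), dim = c(6, 6, 4))
    mp <- max_pool(g, pooling_spec("spatial_2d"))
    expect_equal(mp$output, bf_pool_spatial(g, 2, 2))
  }
  # single window example
  g <- array(0, dim = c(2, 2, 1))
  g[, , 1] <- rbind(c(1, 3), c(2, 0))
  expect_equal(max_pool(g, pooling_spec("spatial_2d"))$output[1, 1, 1], 3)
  # constant map stays constant at reduced resolution
  g <- array(0.7, dim = c(4, 4, 2))
  expect_true(all(max_pool(g, pooling_spec("spatial_2d"))$output == 0.7))
})

test_that("circular 1D feature pooling matches its oracle and wraps", {
  g <- array(0, dim = c(1, 1, 6)); g[1, 1, ] <- 0:5
  spec <- pooling_spec(pool_stage("feature_1d_circular", kernel = 4))
  expect_equal(max_pool(g, spec)$output[1, 1, ], c(3, 4, 5, 5, 5, 5))
  set.seed(2)
  for (i in 1:50) {
    g <- array(runif(3 * 3 * 8), dim = c(3, 3, 8))
    expect_equal(max_pool(g, spec)$output, bf_pool_feat1d(g, 4))
  }
  # all channels equal -> unchanged
  g <- array(rep(runif(9), each = 1), dim = c(3, 3, 1))[, , rep(1, 8)]
  g <- array(g, dim = c(3, 3, 8))
  expect_equal(max_pool(g, spec)$output, bf_pool_feat1d(g, 4))
  # one-hot channel vector activates exactly `kernel` consecutive outputs
  g <- array(0, dim = c(1, 1, 8)); g[1, 1, 4] <- 1
  out <- max_pool(g, spec)$output[1, 1, ]
  expect_equal(sum(out > 0), 4)
  expect_equal(which(out > 0), 1:4) # windows 1..4 contain channel 4
})

test_that("toroidal 2D feature pooling matches its oracle", {
  spec <- pooling_spec("feature_2d_toroidal")
  g <- array(0, dim = c(1, 1, 4)); g[1, 1, ] <- c(9, 2, 3, 4)
  expect_equal(max_pool(g, spec)$output[1, 1, ], rep(9, 4))
  set.seed(3)
  for (i in 1:50) {
    g <- array(runif(2 * 2 * 9), dim = c(2, 2, 9))
    expect_equal(max_pool(g, spec)$output, bf_pool_feat2d(g, 2))
  }
  g <- array(1, dim = c(2, 2, 9))
  expect_true(all(max_pool(g, spec)$output == 1))
})

test_that("composite pooling equals sequential application of the oracles", {
  spec <- pooling_spec("spatial_2d", "feature_1d_circular")
  set.seed(4)
  for (i in 1:25) {
    g <- array(runif(6 * 6 * 8), dim = c(6, 6, 8))
    expect_equal(max_pool(g, spec)$output,
                 bf_pool_feat1d(bf_pool_spatial(g, 2, 2), 4))
  }
  spec2 <- pooling_spec("spatial_2d", "feature_2d_toroidal")
  g <- array(runif(6 * 6 * 9), dim = c(6, 6, 9))
  expect_equal(max_pool(g, spec2)$output,
               bf_pool_feat2d(bf_pool_spatial(g, 2, 2), 2))
  expect_equal(dim(max_pool(g, spec2)$output), c(3L, 3L, 9L))
  # identity passes through
  expect_equal(max_pool(g, pooling_spec("identity"))$output, g)
})

test_that("pooling is equivariant to circular shifts of the feature axis", {
  set.seed(5)
  g <- array(runif(3 * 3 * 8), dim = c(3, 3, 8))
  spec <- pooling_spec("feature_1d_circular")
  for (k in c(1, 3, 5)) {
    rolled <- g[, , ((seq_len(8) - 1 + k) %% 8) + 1]
    lhs <- max_pool(rolled, spec)$output
    rhs <- max_pool(g, spec)$output[, , ((seq_len(8) - 1 + k) %% 8) + 1]
    expect_equal(lhs, rhs)
  }
  # toroidal analogue: roll grid rows (shift channels by G)
  g9 <- array(runif(2 * 2 * 9), dim = c(2, 2, 9))
  spec9 <- pooling_spec("feature_2d_toroidal")
  perm <- ((0:8 + 3) %% 9) + 1 # shift by one grid row
  lhs <- max_pool(g9[, , perm], spec9)$output
  rhs <- max_pool(g9, spec9)$output[, , perm]
  expect_equal(lhs, rhs)
})

test_that("unpooling conserves mass and satisfies the fixed-switch adjoint identity", {
  set.seed(6)
  # mass conservation under non-overlapping spatial windows
  g <- array(runif(6 * 6 * 4), dim = c(6, 6, 4))
  mp <- max_pool(g, pooling_spec("spatial_2d"))
  u <- array(runif(prod(dim(mp$output))), dim = dim(mp$output))
  expect_equal(sum(unpool(u, mp$assignment)), sum(u))
  # one-hot routing
  u1 <- array(0, dim = dim(mp$output)); u1[2, 2, 3] <- 5
  up <- unpool(u1, mp$assignment)
  expect_equal(sum(up != 0), 1L)
  expect_equal(sum(up), 5)
  # adjoint identity <pool_lin_S(g2), u> = <g2, unpool(u)> for every operator
  for (spec in all_poolings()) {
    g <- array(runif(6 * 6 * 9), dim = c(6, 6, 9))
    mp <- max_pool(g, spec)
    u <- array(rnorm(prod(dim(mp$output))), dim = dim(mp$output))
    g2 <- array(rnorm(6 * 6 * 9), dim = c(6, 6, 9))
    # pool_lin_S: selection by the recorded switches
    sel <- function(gam) {
      out <- mp$output
      cur <- gam
      for (st in mp$assignment$stages) {
        if (st$kind == "identity") next
        nxt <- array(0, dim = st$out_dim)
        sw <- as.numeric(st$sw)
        vals <- as.numeric(cur)
        nxt[] <- ifelse(sw >= 0, vals[sw + 1], 0)
        cur <- nxt
      }
      cur
    }
    lhs <- sum(sel(g2) * u)
    rhs <- sum(g2 * unpool(u, mp$assignment))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("pooling errors are informative", {
  g <- array(runif(4 * 4 * 6), dim = c(4, 4, 6))
  expect_error(max_pool(g, pooling_spec(pool_stage("feature_1d_circular",
                                                   kernel = 7))),
               "exceeds channel count")
  expect_error(max_pool(g, pooling_spec("feature_2d_toroidal")),
               "perfect square")
  expect_error(pool_stage("spatial_2d", kernel = 0), "empty pooling window")
  mp <- max_pool(array(runif(16 * 4), dim = c(4, 4, 4)), pooling_spec("spatial_2d"))
  expect_error(unpool(array(0, dim = c(5, 5, 4)), mp$assignment), "shape")
})

test_that("pooled values dominate their windows", {
  set.seed(7)
  for (spec in all_poolings()) {
    g <- array(runif(6 * 6 * 9), dim = c(6, 6, 9))
    mp <- max_pool(g, spec)
    expect_true(all(mp$output >= 0))
    expect_true(max(mp$output) <= max(g) + 1e-15)
    expect_equal(max(mp$output), max(g))
  }
})
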