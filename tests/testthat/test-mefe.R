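test_that("edge response kills constants exactly, including borders", {
  for (v in c(0, -2.5, 13.7)) {
    f <- array(v, dim = c(1, 2, 5, 7))
    expect_identical(madev(edge_response(f), 0), 0)
  }
})

test_that("edge response is linear", {
  set.seed(31)
  f <- rand_feature_map(2, 3, 6, 6)
  g <- rand_feature_map(2, 3, 6, 6)
  expect_lt(madev(edge_response(2.5 * f), 2.5 * edge_response(f)), 1e-12)
  expect_lt(madev(edge_response(f + g),
                  edge_response(f) + edge_response(g)), 1e-12)
})

test_that("unit impulse yields the hand-computed high-pass stencil", {
  f <- array(0, dim = c(1, 1, 5, 5))
  f[1, 1, 3, 3] <- 1
  e <- edge_response(f)
  expect_equal(e[1, 1, 3, 3], 1 - 1 / 9)
  for (dh in -1:1) for (dw in -1:1) {
    if (dh == 0 && dw == 0) next
    expect_equal(e[1, 1, 3 + dh, 3 + dw], -1 / 9)
  }
})

test_that("output shape contract holds and oversized pools clamp with a warning", {
  set.seed(32)
  x <- rand_feature_map(2, 64, 32, 32)
  l <- mefe_layer(mefe_spec(64, 64, c(20, 18, 8)))
  y <- nn_forward(l, x)
  expect_identical(dim(y), c(2L, 64L, 32L, 32L))
  xs <- rand_feature_map(1, 64, 8, 8)
  expect_warning(ys <- nn_forward(l, xs), "clamped")
  expect_identical(dim(ys), c(1L, 64L, 8L, 8L))
})

test_that("spatially constant input with bias-free convolutions stays constant", {
  set.seed(33)
  l <- mefe_layer(mefe_spec(4, 4, c(4, 2), 2))
  # zero the branch conv biases; phi is bias-free by construction
  for (nm in names(l$children)) {
    ps <- l$children[[nm]]$params
    if ("bias" %in% names(ps)) l$children[[nm]]$params$bias[] <- 0
  }
  x <- array(0.83, dim = c(1, 4, 8, 8))
  y <- nn_forward(l, x)
  for (cc in seq_len(dim(y)[2])) {
    expect_lt(max(y[1, cc, , ]) - min(y[1, cc, , ]), 1e-10)
  }
})

test_that("single-branch parameter count matches the closed-form layer sum", {
  l <- mefe_layer(mefe_spec(4, 4, pool_sizes = 2, reduction_ratio = 2))
  # reduce 1x1 (4*2 + 2), depthwise 3x3 (2*9, no bias), pointwise (2*2 + 2),
  # phi = 2 bias-free DS layers (2*(2*9 + 2*2)), fusion 1x1 (2*4, no bias)
  expected <- (4 * 2 + 2) + 2 * 9 + (2 * 2 + 2) +
    2 * (2 * 9 + 2 * 2) + 2 * 4
  expect_identical(count_parameters(l), expected)
})

test_that("indivisible channel reduction is a configuration error", {
  expect_error(mefe_spec(6, reduction_ratio = 4), "divisible")
})
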