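test_that("adaptive kernel size matches the nearest-odd rule by enumeration", {
  for (C in 8:1024) {
    traw <- abs(log2(C) / 2 + 1 / 2)
    # brute force: odd candidate minimizing the distance, ties upward
    cand <- seq(1, 15, by = 2)
    d <- abs(cand - traw)
    best <- cand[d == min(d)]
    expect_equal(eca_kernel_size(C), max(3, max(best)),
                 info = paste("C =", C))
  }
  expect_equal(eca_kernel_size(64), 3L)
  expect_equal(eca_kernel_size(256), 5L)
})

test_that("zero-tap gates scale the input by exactly one half", {
  set.seed(11)
  x <- rand_feature_map(2, 8, 5, 5)
  y <- eca_gate(x, weights = numeric(eca_kernel_size(8)))
  expect_equal(y, 0.5 * x)
})

test_that("constant-per-channel inputs stay constant per channel", {
  set.seed(12)
  vals <- rnorm(6)
  x <- array(rep(rep(vals, each = 2), times = 16), dim = c(2, 6, 4, 4))
  y <- eca_gate(x, weights = rnorm(eca_kernel_size(6)))
  for (b in 1:2) for (cc in 1:6) {
    expect_equal(max(y[b, cc, , ]) - min(y[b, cc, , ]), 0)
  }
})

test_that("gate output preserves shape and rejects non-rank-4 input", {
  x <- rand_feature_map(1, 16, 3, 7)
  expect_identical(dim(eca_gate(x, numeric(3))), dim(x))
  expect_error(eca_gate(matrix(1, 2, 2)), "rank-4")
})

test_that("channel-attention gradients agree with finite differences", {
  set.seed(13)
  m <- nn_eca(8)
  x <- rand_feature_map(2, 8, 4, 4)
  y <- nn_forward(m, x)
  gy <- array(rnorm(length(y)), dim = dim(y))
  nn_zero_grad(m)
  nn_forward(m, x)
  gx <- nn_backward(m, gy)
  eps <- 1e-6
  for (i in sample(length(x), 5)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    num <- (sum(nn_forward(m, x1) * gy) - sum(nn_forward(m, x2) * gy)) /
      (2 * eps)
    expect_lt(abs(num - gx[i]), 1e-5)
  }
})
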