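test_that("attention normalizes to one over the receptive-field axis", {
  set.seed(21)
  for (case in list(c(1, 2, 5, 5), c(2, 4, 6, 4), c(2, 3, 3, 3))) {
    x <- rand_feature_map(case[1], case[2], case[3], case[4])
    A <- scarf_attention(x, scarf_spec(case[2], attention_groups = 1),
                         seed = 21)
    expect_true(all(A >= 0))
    expect_lt(madev(apply(A, c(1, 2, 4, 5), sum), 1), 1e-5)
    expect_identical(dim(A), as.integer(c(case[1], case[2], 9,
                                          case[3], case[4])))
  }
})

test_that("zero expansion weights give uniform 1/k^2 attention", {
  set.seed(22)
  l <- scarf_layer(scarf_spec(4))
  l$children$att_conv$params$weight[] <- 0
  l$children$att_conv$params$bias[] <- 0
  A <- scarf_attention(rand_feature_map(1, 4, 5, 5), l)
  expect_lt(madev(A, 1 / 9), 1e-12)
})

test_that("single-position attention equals a hand softmax of nine logits", {
  set.seed(23)
  l <- scarf_layer(scarf_spec(1))
  w <- rnorm(9)
  b <- rnorm(9)
  l$children$att_conv$params$weight[] <- w   # (9, 1, 1, 1)
  l$children$att_conv$params$bias[] <- b
  x <- array(1.7, dim = c(1, 1, 1, 1))
  # valid-tap average pooling of a single pixel is the pixel itself;
  # each logit is then w_s * pooled + b_s
  logits <- w * 1.7 + b
  expected <- exp(logits - max(logits))
  expected <- expected / sum(expected)
  A <- scarf_attention(x, l)
  expect_lt(madev(as.vector(A), expected), 1e-12)
})

test_that("output shape follows the stride and channel contract", {
  set.seed(24)
  x <- rand_feature_map(2, 64, 32, 32)
  y1 <- scarf_forward(x, scarf_spec(64, 64, 3, 1), seed = 24)
  expect_identical(dim(y1), c(2L, 64L, 32L, 32L))
  y2 <- scarf_forward(x, scarf_spec(64, 128, 3, 2), seed = 24)
  expect_identical(dim(y2), c(2L, 128L, 16L, 16L))
})

test_that("forward equals the enumerated weighted-sum oracle", {
  set.seed(25)
  cases <- expand.grid(B = 1:2, C = c(2, 4), H = c(4, 6), stride = 1:2)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    l <- scarf_layer(scarf_spec(cs$C, cs$C + 1, 3, cs$stride),
                     seed = 100 + i)
    x <- rand_feature_map(cs$B, cs$C, cs$H, cs$H)
    y <- nn_forward(l, x)
    expect_lt(madev(y, scarf_enumeration_oracle(l, x)), 1e-5)
  }
})

test_that("mismatched channels and bad specs are rejected", {
  expect_error(scarf_spec(4, kernel_size = 4), "odd")
  expect_error(scarf_spec(4, attention_groups = 3), "divide")
  l <- scarf_layer(scarf_spec(4))
  expect_error(nn_forward(l, rand_feature_map(1, 3, 4, 4)), "channels")
})
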