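sp_small <- function(alpha = 0.6) {
  seafec_spec(4, 4, 3, 1, pool_sizes = c(3, 2), reduction_ratio = 2,
              alpha_init = alpha)
}

test_that("the fusion logit initializes to the inverse sigmoid of alpha", {
  l <- seafec_layer(sp_small(0.6))
  expect_equal(as.numeric(l$params$alpha_logit), log(0.6 / 0.4),
               tolerance = 1e-12)
  expect_equal(seafec_alpha(l), 0.6, tolerance = 1e-12)
  for (a in c(0.4, 0.5)) {
    expect_equal(seafec_alpha(seafec_layer(sp_small(a))), a,
                 tolerance = 1e-12)
  }
  expect_error(seafec_spec(4, alpha_init = 1), "strictly")
})

test_that("a saturated logit collapses the fusion onto one branch", {
  set.seed(41)
  l <- seafec_layer(sp_small())
  x <- rand_feature_map(2, 4, 6, 6)
  ys <- nn_forward(l$children$scarf, x)
  l$params$alpha_logit[] <- 100
  expect_lt(madev(nn_forward(l, x), ys), 1e-6)
})

test_that("the output is affine in alpha and lies between the branches", {
  set.seed(42)
  l <- seafec_layer(sp_small())
  x <- rand_feature_map(1, 4, 6, 6)
  at <- function(logit) {
    l$params$alpha_logit[] <- logit
    nn_forward(l, x)
  }
  y0 <- at(-100)  # alpha -> 0: MEFE branch
  y1 <- at(100)   # alpha -> 1: SCARF branch
  ym <- at(log(0.3 / 0.7))
  expect_lt(madev(ym - y0, 0.3 * (y1 - y0)), 1e-6)
  lo <- pmin(y0, y1); hi <- pmax(y0, y1)
  expect_true(all(ym >= lo - 1e-9 & ym <= hi + 1e-9))
  for (logit in c(-30, -1, 0, 2, 30)) {
    a <- 1 / (1 + exp(-logit))
    expect_true(a > 0 && a < 1)
  }
})

test_that("every learnable tensor receives a nonzero gradient", {
  set.seed(43)
  l <- seafec_layer(sp_small())
  x <- rand_feature_map(2, 4, 6, 6)
  y <- nn_forward(l, x)
  nn_zero_grad(l)
  nn_forward(l, x)
  nn_backward(l, array(1, dim = dim(y)))
  ps <- nn_parameters(l)
  for (nm in names(ps)) {
    p <- ps[[nm]]
    expect_gt(max(abs(p$module$grads[[p$name]])), 0, label = nm)
  }
})

test_that("fusion gradients agree with finite differences", {
  set.seed(44)
  l <- seafec_layer(sp_small())
  x <- rand_feature_map(1, 4, 5, 5)
  y <- nn_forward(l, x)
  gy <- array(rnorm(length(y)), dim = dim(y))
  nn_zero_grad(l)
  nn_forward(l, x)
  gx <- nn_backward(l, gy)
  eps <- 1e-5
  # alpha logit
  f <- function(v) {
    old <- l$params$alpha_logit
    l$params$alpha_logit[] <- v
    r <- sum(nn_forward(l, x) * gy)
    l$params$alpha_logit <- old
    r
  }
  v0 <- as.numeric(l$params$alpha_logit)
  num <- (f(v0 + eps) - f(v0 - eps)) / (2 * eps)
  expect_lt(abs(num - as.numeric(l$grads$alpha_logit)), 1e-6)
  # input gradient, spot-checked
  for (i in sample(length(x), 4)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    num <- (sum(nn_forward(l, x1) * gy) - sum(nn_forward(l, x2) * gy)) /
      (2 * eps)
    expect_lt(abs(num - gx[i]), 1e-4)
  }
})

test_that("construction is bit-identical under a fixed seed", {
  l1 <- seafec_layer(sp_small(), seed = 42)
  l2 <- seafec_layer(sp_small(), seed = 42)
  expect_identical(state_dict(l1), state_dict(l2))
  set.seed(45)
  x <- rand_feature_map(1, 4, 6, 6)
  expect_identical(nn_forward(l1, x), nn_forward(l2, x))
  l3 <- seafec_layer(sp_small(), seed = 43)
  expect_false(identical(state_dict(l1), state_dict(l3)))
})

test_that("specs round-trip through YAML with stable keys", {
  sp <- seafec_spec(8, 16, 5, 2, pool_sizes = c(6, 4, 2),
                    reduction_ratio = 2, alpha_init = 0.4)
  txt <- seafec_spec_to_yaml(sp)
  for (key in c("kernel_size", "pool_sizes", "reduction_ratio",
                "alpha_init", "stride", "in_channels", "out_channels")) {
    expect_match(txt, key)
  }
  sp2 <- seafec_spec_from_yaml(txt)
  expect_equal(sp2$scarf$kernel_size, 5)
  expect_equal(sp2$mefe$pool_sizes, as.integer(c(6, 4, 2)))
  expect_equal(sp2$alpha_init, 0.4)
  expect_equal(sp2$scarf$stride, 2)
  path <- tempfile(fileext = ".yaml")
  seafec_spec_to_yaml(sp, path)
  expect_equal(seafec_spec_from_yaml(path)$mefe$reduction_ratio, 2)
})

test_that("parameters round-trip through the checkpoint container", {
  l <- seafec_layer(sp_small(), seed = 42)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(l, path)
  sd0 <- state_dict(l)
  # perturb, then restore
  l$params$alpha_logit[] <- 3
  l$children$scarf$children$fuse$params$weight[] <- 0
  load_checkpoint(l, path)
  expect_identical(state_dict(l), sd0)
})
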