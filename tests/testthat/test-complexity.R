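test_that("unit layers count parameters by closed form", {
  l <- nn_conv2d(64, 64, 3, bias = FALSE)
  expect_identical(count_parameters(l), 64 * 64 * 9)
  expect_identical(count_parameters(nn_batchnorm2d(64)), 128)
  expect_identical(count_parameters(nn_linear(512, 1000)),
                   512 * 1000 + 1000)
})

test_that("unit layers count MACs by closed form", {
  l <- nn_conv2d(64, 64, 3, padding = 1, bias = FALSE)
  expect_identical(count_macs(l, c(64, 32, 32)), 64 * 64 * 9 * 32 * 32)
  expect_identical(count_macs(nn_linear(512, 1000), c(1, 512)) -
                     512000, 0)
  # grouped and strided
  g <- nn_conv2d(8, 16, 3, stride = 2, padding = 1, groups = 4)
  expect_identical(count_macs(g, c(8, 8, 8)), 16 * 2 * 9 * 4 * 4)
})

test_that("counting is structural: weights do not affect counts", {
  a <- scarf_layer(scarf_spec(8), seed = 1)
  b <- scarf_layer(scarf_spec(8), seed = 2)
  expect_identical(count_parameters(a), count_parameters(b))
  expect_identical(count_macs(a, c(8, 6, 6)), count_macs(b, c(8, 6, 6)))
})

test_that("composite MAC accounting agrees with a per-layer hand sum", {
  l <- scarf_layer(scarf_spec(2, 3, 3, 1), seed = 3)
  H <- 6
  hand <- 18 * 1 * H * H +        # grouped 1x1 expansion (C_in/groups = 1)
    18 * 1 * 9 * H * H +          # depthwise kxk feature conv (C_g = 1)
    1 * 18 * eca_kernel_size(18) +  # channel attention 1-D conv
    3 * 2 * 9 * H * H             # stride-k fusion conv at H' x W'
  expect_identical(count_macs(l, c(2, H, H)), hand)
})

test_that("the complexity report computes signed percentage deltas", {
  base <- build_seafec_resnet18("baseline")
  var <- build_seafec_resnet18("mefe")
  r <- complexity_report(var, base)
  expect_equal(r$delta_params_pct,
               100 * (r$params - r$baseline_params) / r$baseline_params)
  expect_lt(r$delta_params_pct, 0)
  expect_lt(r$delta_macs_pct, 0)
  expect_output(print(r), "vs baseline")
})
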