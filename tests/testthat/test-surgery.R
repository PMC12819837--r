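test_that("every residual block's first conv is replaced, exactly eight times", {
  m <- build_seafec_resnet18("seafec", num_classes = 5)
  expect_identical(m$surgery_count, 8L)
  for (st in paste0("layer", 1:4)) {
    for (b in c("0", "1")) {
      expect_s3_class(m$children[[st]]$children[[b]]$children$conv1,
                      "nn_seafec")
      expect_s3_class(m$children[[st]]$children[[b]]$children$conv2,
                      "nn_conv2d")
    }
  }
})

test_that("an empty selector changes nothing; re-surgery raises an error", {
  m <- build_seafec_resnet18("baseline", num_classes = 3)
  p0 <- count_parameters(m)
  replace_convs(m, "^nothing-matches$",
                function(ci, co, s) nn_conv2d(ci, co, 3))
  expect_identical(m$surgery_count, 0L)
  expect_identical(count_parameters(m), p0)
  m2 <- build_seafec_resnet18("scarf", num_classes = 3)
  expect_error(
    replace_convs(m2, "^layer[1-4]\\.[01]\\.conv1$",
                  function(ci, co, s) nn_conv2d(ci, co, 3)),
    "not a plain")
})

test_that("all variants share input/output shapes and the downsampling schedule", {
  set.seed(51)
  x <- rand_feature_map(1, 3, 64, 64)
  for (v in c("baseline", "scarf", "mefe", "seafec")) {
    m <- build_seafec_resnet18(v, num_classes = 7)
    y <- suppressWarnings(nn_forward(m, x))
    expect_identical(dim(y), c(1L, 7L), label = v)
    # stage resolutions unchanged by surgery: probe stage outputs
    h <- suppressWarnings(nn_forward(m$children$maxpool,
           nn_forward(m$children$relu, nn_forward(m$children$bn1,
             nn_forward(m$children$conv1, x)))))
    sizes <- integer(0)
    for (st in paste0("layer", 1:4)) {
      h <- suppressWarnings(nn_forward(m$children[[st]], h))
      sizes <- c(sizes, dim(h)[3])
    }
    expect_identical(sizes, c(16L, 8L, 4L, 2L), label = v)
  }
})

test_that("parameter deltas have the reported directions and ordering", {
  p <- vapply(c("baseline", "scarf", "mefe", "seafec"),
              function(v) count_parameters(build_seafec_resnet18(v)),
              numeric(1))
  expect_lt(p["mefe"], p["baseline"])
  expect_gt(p["scarf"], p["baseline"])
  expect_gt(p["seafec"], p["scarf"])
  expect_gt(p["seafec"], p["mefe"])
})

test_that("the segmentation network builds, counts, and densely predicts", {
  p <- numeric(0)
  for (v in c("baseline", "scarf", "mefe", "seafec")) {
    m <- build_seafec_deeplabv3(v, num_classes = 3)
    p[v] <- count_parameters(m)
    if (v %in% c("baseline", "seafec")) {
      set.seed(52)
      y <- suppressWarnings(nn_forward(m, rand_feature_map(1, 3, 64, 64)))
      expect_identical(dim(y), c(1L, 3L, 64L, 64L), label = v)
    }
    if (v == "seafec") expect_identical(m$surgery_count, 3L)
    rm(m); gc(FALSE)
  }
  expect_gt(p["scarf"], p["baseline"])
  expect_gt(p["seafec"], p["scarf"])
  expect_gt(p["seafec"], p["mefe"])
})

test_that("surgery plans validate their fields", {
  expect_error(surgery_plan("resnet18", "bogus"))
  pl <- surgery_plan("deeplabv3_resnet50", "mefe")
  expect_equal(pl$alpha_init, 0.4)
  expect_equal(pl$pool_sizes, c(20, 15, 8))
})
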