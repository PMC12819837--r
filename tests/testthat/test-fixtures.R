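test_that("classification fixtures are balanced, bounded, and deterministic", {
  fx <- gen_classification_fixture(5, image_size = 32, seed = 9)
  expect_length(fx, 10)
  labs <- vapply(fx, `[[`, integer(1), "label")
  expect_identical(as.vector(table(labs)), c(5L, 5L))
  for (s in fx) {
    expect_true(all(s$image >= 0 & s$image <= 255))
    expect_identical(dim(s$image), c(32L, 32L, 3L))
  }
  fx2 <- gen_classification_fixture(5, image_size = 32, seed = 9)
  expect_identical(fx, fx2)
  expect_false(identical(
    fx, gen_classification_fixture(5, image_size = 32, seed = 10)))
  expect_error(gen_classification_fixture(3, image_size = 8), "at least")
})

test_that("spot images carry a smaller lesion-pixel share than strip images", {
  # lesions are warm-toned (R > G); leaf background the opposite
  frac <- function(s) mean(s$image[, , 1] > s$image[, , 2])
  spot <- gen_classification_fixture(50, image_size = 32, seed = 101)
  labs <- vapply(spot, `[[`, integer(1), "label")
  f_spot <- mean(vapply(spot[labs == 0L], frac, numeric(1)))
  f_strip <- mean(vapply(spot[labs == 1L], frac, numeric(1)))
  expect_lt(f_spot, f_strip)
})

test_that("segmentation masks use the three-class convention and hit the weed share", {
  fx <- gen_segmentation_fixture(50, image_size = 64, weed_fraction = 0.05,
                                 seed = 33)
  shares <- vapply(fx, function(s) {
    expect_true(all(s$mask %in% 0:2))
    mean(s$mask == 2L)
  }, numeric(1))
  expect_gte(mean(shares), 0.025)
  expect_lte(mean(shares), 0.075)
  # all three classes occur
  expect_true(all(vapply(fx, function(s) length(unique(as.vector(s$mask))),
                         numeric(1)) == 3))
  expect_error(gen_segmentation_fixture(2, weed_fraction = 0.6), "0.5")
})

test_that("pseudo-color mask rendering is a bijection", {
  fx <- gen_segmentation_fixture(3, image_size = 32, seed = 5)
  for (s in fx) {
    expect_identical(pseudocolor_to_mask(mask_to_pseudocolor(s$mask)),
                     s$mask)
  }
})

test_that("detection regimes obey their box-count and size contracts", {
  sparse <- gen_detection_fixture(5, image_size = 64, density = "sparse",
                                  seed = 61)
  dense <- gen_detection_fixture(5, image_size = 64, density = "dense",
                                 seed = 61)
  area <- function(b) (b$x_max - b$x_min) * (b$y_max - b$y_min)
  for (s in sparse) {
    expect_true(nrow(s$boxes) >= 1 && nrow(s$boxes) <= 3)
  }
  for (s in c(sparse, dense)) {
    expect_true(all(s$boxes$x_min >= 0 & s$boxes$x_min < s$boxes$x_max))
    expect_true(all(s$boxes$x_max <= 64 & s$boxes$y_max <= 64))
    expect_true(all(s$boxes$y_min >= 0 & s$boxes$y_min < s$boxes$y_max))
  }
  for (s in dense) expect_gte(nrow(s$boxes), 10)
  med_d <- stats::median(unlist(lapply(dense, function(s) area(s$boxes))))
  med_s <- stats::median(unlist(lapply(sparse, function(s) area(s$boxes))))
  expect_lt(med_d, med_s)
})

test_that("the doubling policy exactly doubles per-class counts", {
  base <- gen_classification_fixture(2, image_size = 32, seed = 70)
  counts <- c(511L, 524L, 562L)
  samples <- list()
  for (k in seq_along(counts)) {
    for (i in seq_len(counts[k])) {
      s <- base[[(i %% length(base)) + 1L]]
      s$label <- k - 1L
      samples[[length(samples) + 1L]] <- s
    }
  }
  aug <- augment_double(samples, seed = 71)
  labs <- vapply(aug, `[[`, integer(1), "label")
  expect_identical(as.vector(table(labs)), c(1022L, 1048L, 1124L))
  expect_length(augment_double(list()), 0)
  aug2 <- augment_double(samples[1:7], seed = 3)
  expect_length(aug2, 14)
})

test_that("right-angle rotation preserves the mask class histogram", {
  fx <- gen_segmentation_fixture(3, image_size = 32, seed = 80)
  pol <- augmentation_policy("rotation")
  # force right-angle rotations by retrying seeds until one occurs is
  # unnecessary: check histogram equality for the exact permutation cases
  for (s in fx) {
    for (kturn in 1:3) {
      r <- seafec:::rot90_plane(s$mask, kturn)
      expect_identical(sort(table(as.vector(r))),
                       sort(table(as.vector(s$mask))))
    }
  }
  # and transformed copies keep boxes inside bounds
  det <- gen_detection_fixture(4, image_size = 32, density = "dense",
                               seed = 81)
  aug <- augment_double(det, augmentation_policy(c("rotation", "cropping",
                                                   "scaling")), seed = 82)
  for (s in aug) {
    expect_true(all(s$boxes$x_min >= 0 & s$boxes$x_max <= 32 &
                      s$boxes$y_min >= 0 & s$boxes$y_max <= 32))
    expect_true(all(s$boxes$x_max > s$boxes$x_min))
  }
})

test_that("splits partition the set at per-class floor-rounded ratios", {
  fx <- gen_classification_fixture(10, image_size = 32, seed = 90)
  sp <- split_samples(fx, c(0.7, 0.2, 0.1), seed = 91)
  expect_length(sp$train, 14)
  expect_length(sp$val, 4)
  expect_length(sp$test, 2)
  expect_length(c(sp$train, sp$val, sp$test), length(fx))
  seg <- gen_segmentation_fixture(10, image_size = 32, seed = 92)
  sp2 <- split_samples(seg, c(0.6, 0.2, 0.2), seed = 93)
  expect_length(sp2$train, 6)
  expect_length(sp2$val, 2)
  expect_length(sp2$test, 2)
})

test_that("fixtures write to PNG and JSON on disk", {
  dir <- tempfile("fixture")
  fx <- gen_segmentation_fixture(2, image_size = 32, seed = 95)
  write_fixture(fx, dir)
  expect_true(file.exists(file.path(dir, "images", "0001.png")))
  expect_true(file.exists(file.path(dir, "masks", "0002.png")))
  png <- png::readPNG(file.path(dir, "masks", "0001.png"))
  expect_identical(pseudocolor_to_mask(png * 255), fx[[1]]$mask)
  ann <- jsonlite::read_json(file.path(dir, "annotations.json"))
  expect_length(ann, 2)
  unlink(dir, recursive = TRUE)
})
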