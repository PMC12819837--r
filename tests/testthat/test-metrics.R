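test_that("perfect predictions score one on every classification rate", {
  r <- classification_metrics(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0), 3)
  expect_true(all(r$metrics == 1))
})

test_that("the binary confusion example reproduces hand-computed rates", {
  # class 1 as positive: TP=3, FP=1, FN=2, TN=4
  truth <- c(rep(1, 5), rep(0, 5))
  pred <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  r <- classification_metrics(truth, pred, 2)
  expect_equal(unname(r$metrics["accuracy"]), 0.7)
  pc <- r$per_class
  expect_equal(pc$precision[pc$class == 1], 0.75)
  expect_equal(pc$recall[pc$class == 1], 0.6)
  expect_equal(pc$specificity[pc$class == 1], 0.8)
  expect_equal(pc$f1[pc$class == 1], 2 / 3)
})

test_that("an all-one-class prediction zeroes that class's specificity", {
  r <- classification_metrics(c(0, 1, 0, 1), c(1, 1, 1, 1), 2)
  pc <- r$per_class
  expect_equal(pc$specificity[pc$class == 1], 0)
})

test_that("absent classes are flagged with rates forced to zero", {
  r <- classification_metrics(c(0, 0, 1), c(0, 1, 1), 3)
  expect_identical(r$flags$undefined_classes, 2L)
  expect_equal(r$per_class$recall[3], 0)
})

test_that("classification metrics match the confusion-count oracle", {
  set.seed(201)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    n <- sample(3:30, 1)
    truth <- sample(0:(k - 1), n, replace = TRUE)
    pred <- sample(0:(k - 1), n, replace = TRUE)
    r <- classification_metrics(truth, pred, k)
    expect_equal(unname(r$metrics[c("accuracy", "precision", "recall",
                                    "specificity", "f1")]),
                 unname(cls_confusion_oracle(truth, pred, k)),
                 tolerance = 1e-12)
  }
})

test_that("segmentation IoU pools pixels and matches hand counts", {
  t1 <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  p1 <- matrix(c(0L, 1L, 1L, 1L), 2, 2)
  r <- segmentation_metrics(t1, p1, 2)
  expect_equal(r$per_class$iou, c(1 / 2, 2 / 3))
  expect_equal(unname(r$metrics["miou"]), 7 / 12)
  # identity and disjoint extremes
  expect_equal(unname(segmentation_metrics(t1, t1, 2)$metrics["miou"]), 1)
  d1 <- matrix(0L, 2, 2); d2 <- matrix(1L, 2, 2)
  expect_equal(segmentation_metrics(d1, d2, 2)$per_class$iou, c(0, 0))
})

test_that("segmentation metrics match the pixel-count oracle", {
  set.seed(202)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    masks_t <- lapply(1:2, function(j)
      matrix(sample(0:(k - 1), 16, replace = TRUE), 4, 4))
    masks_p <- lapply(1:2, function(j)
      matrix(sample(0:(k - 1), 16, replace = TRUE), 4, 4))
    r <- segmentation_metrics(masks_t, masks_p, k)
    o <- seg_count_oracle(masks_t, masks_p, k)
    expect_equal(unname(r$metrics["miou"]), unname(o["miou"]),
                 tolerance = 1e-12)
  }
})

bx <- function(x0, y0, x1, y1, cls = 0L, score = NULL) {
  d <- data.frame(x_min = x0, y_min = y0, x_max = x1, y_max = y1,
                  class = cls)
  if (!is.null(score)) d$score <- score
  d
}

test_that("exact detections score unit mAP; empty predictions score zero", {
  truth <- list(rbind(bx(0, 0, 10, 10), bx(20, 20, 30, 30)))
  pred <- list(rbind(bx(0, 0, 10, 10, score = 0.3),
                     bx(20, 20, 30, 30, score = 0.9)))
  r <- detection_map(truth, pred)
  expect_equal(unname(r$metrics["map50"]), 1)
  expect_equal(unname(r$metrics["map50_95"]), 1)
  r0 <- detection_map(truth, list(bx(0, 0, 1, 1, score = 1)[0, ]))
  expect_equal(unname(r0$metrics["map50"]), 0)
})

test_that("the ranked miss-hit-hit staircase integrates to the hand AP", {
  truth <- list(rbind(bx(0, 0, 10, 10), bx(30, 30, 40, 40)))
  pred <- list(rbind(
    bx(60, 60, 70, 70, score = 0.9),   # miss
    bx(0, 0, 10, 11, score = 0.8),     # hit (IoU 10/11)
    bx(30, 30, 40, 41, score = 0.7)))  # hit
  r <- detection_map(truth, pred, iou_thresholds = 0.5)
  # ranked: FP, TP, TP -> precision 0, 1/2, 2/3 at recall 0, 1/2, 1;
  # all-point interpolation gives 0.5 * 2/3 + 0.5 * 2/3 = 2/3
  expect_equal(unname(r$metrics["map50"]), 2 / 3, tolerance = 1e-12)
})

test_that("detection matching is invariant to presentation order", {
  set.seed(203)
  truth <- list(rbind(bx(0, 0, 10, 10), bx(5, 5, 15, 15), bx(30, 0, 40, 8)))
  pred_rows <- rbind(bx(1, 0, 10, 10, score = 0.9),
                     bx(5, 6, 15, 15, score = 0.6),
                     bx(31, 0, 40, 8, score = 0.4),
                     bx(50, 50, 55, 55, score = 0.2))
  r1 <- detection_map(truth, list(pred_rows))
  r2 <- detection_map(truth, list(pred_rows[c(3, 1, 4, 2), ]))
  expect_equal(r1$metrics, r2$metrics)
})

test_that("box IoU handles half-open coordinates and disjoint boxes", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(2, 2, 4, 4)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 2 / 6)
})
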