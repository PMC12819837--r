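test_that("one epoch on a small fixture yields finite bookkeeping", {
  fx <- gen_classification_fixture(4, image_size = 32, seed = 301)
  m <- build_seafec_resnet18("baseline", num_classes = 2)
  r <- smoke_train(m, fx, epochs = 1, seed = 42, stop_at_accuracy = 2)
  expect_identical(nrow(r$history), 1L)
  expect_true(is.finite(r$history$loss[1]))
  expect_s3_class(r$metrics, "metrics_report")
})

test_that("a single epoch descends the loss on a fixed batch ordering", {
  fx <- gen_classification_fixture(8, image_size = 32, seed = 302)
  m <- build_seafec_resnet18("baseline", num_classes = 2)
  b <- samples_to_batch(fx)
  l0 <- seafec:::ce_loss(nn_forward(m, b$x), b$y)$loss
  r <- smoke_train(m, fx, epochs = 1, seed = 42, stop_at_accuracy = 2)
  nn_set_training(m, TRUE)
  l1 <- seafec:::ce_loss(nn_forward(m, b$x), b$y)$loss
  expect_lt(l1, l0)
})

test_that("training is deterministic under the seed", {
  fx <- gen_classification_fixture(4, image_size = 32, seed = 303)
  m1 <- build_seafec_resnet18("baseline", num_classes = 2)
  m2 <- build_seafec_resnet18("baseline", num_classes = 2)
  r1 <- smoke_train(m1, fx, epochs = 2, seed = 7, stop_at_accuracy = 2)
  r2 <- smoke_train(m2, fx, epochs = 2, seed = 7, stop_at_accuracy = 2)
  expect_identical(r1$history, r2$history)
  expect_identical(state_dict(m1), state_dict(m2))
})
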