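# Desk-scale training harness: Adam on softmax cross-entropy, used to show
# that every backbone variant can fit the synthetic fixtures.

#' Convert classification samples to a batch tensor and label vector
#'
#' Pixels are scaled to \[0, 1\] and standardized with mean 0.5 / sd 0.25
#' per channel.
#'
#' @param samples list of classification samples
#' @return list with `x` of dim `(B, 3, H, W)` and integer `y`
#' @export
samples_to_batch <- function(samples) {
  B <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, dim = c(B, 3, d[1], d[2]))
  for (i in seq_len(B)) {
    img <- samples[[i]]$image / 255
    x[i, , , ] <- aperm(array(img, dim = d), c(3, 1, 2))
  }
  list(x = (x - 0.5) / 0.25,
       y = vapply(samples, function(s) as.integer(s$label), integer(1)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy over the batch; returns loss, dlogits, predictions
ce_loss <- function(logits, y) {
  p <- softmax_rows(logits)
  B <- nrow(logits)
  idx <- cbind(seq_len(B), y + 1L)
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = -mean(log(pmax(p[idx], 1e-12))),
       grad = g / B,
       pred = max.col(p, ties.method = "first") - 1L)
}

#' Adam optimizer state for a model
#' @param model a module tree
#' @param lr learning rate
#' @param beta1,beta2,eps Adam moment constants
#' @return an optimizer object
#' @export
optim_adam <- function(model, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  ps <- nn_parameters(model)
  st <- lapply(ps, function(p) {
    z <- p$module$params[[p$name]] * 0
    list(m = z, v = z)
  })
  e <- new.env(parent = emptyenv())
  e$ps <- ps; e$st <- st; e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2
  e$eps <- eps; e$t <- 0L
  class(e) <- "optim_adam"
  e
}

#' Apply one Adam update from the accumulated gradients
#' @param opt an [optim_adam()] object
#' @export
optim_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$ps)) {
    p <- opt$ps[[i]]
    g <- p$module$grads[[p$name]]
    s <- opt$st[[i]]
    s$m <- opt$beta1 * s$m + (1 - opt$beta1) * g
    s$v <- opt$beta2 * s$v + (1 - opt$beta2) * g^2
    opt$st[[i]] <- s
    p$module$params[[p$name]] <- p$module$params[[p$name]] -
      opt$lr * (s$m / bc1) / (sqrt(s$v / bc2) + opt$eps)
  }
  invisible(opt)
}

#' Fit a classification model on a fixture
#'
#' Minimizes softmax cross-entropy with Adam (learning rate 1e-3 by
#' default), recording per-epoch mean loss and training accuracy. Training
#' stops early once training accuracy reaches `stop_at_accuracy`. Fully
#' deterministic under `seed` (shuffling is the only randomness).
#'
#' @param model a classification model ([build_seafec_resnet18()])
#' @param samples list of classification samples
#' @param epochs maximum epochs
#' @param seed integer seed for batch shuffling
#' @param lr,batch_size optimizer settings
#' @param val_samples optional held-out samples; final metrics are computed
#'   on them (otherwise on the training set)
#' @param stop_at_accuracy early-stop threshold on training accuracy
#'   (default 1 = stop when the fixture is fit exactly)
#' @return list with `history` (data.frame epoch/loss/accuracy), `metrics`
#'   (a `metrics_report`), and `epochs_run`
#' @export
smoke_train <- function(model, samples, epochs = 30, seed = 42, lr = 1e-3,
                        batch_size = 32, val_samples = NULL,
                        stop_at_accuracy = 1.0) {
  stopifnot(length(samples) >= 2)
  n_classes <- model$num_classes
  if (is.null(n_classes)) stop("model is not a classification network")
  batch <- samples_to_batch(samples)
  opt <- optim_adam(model, lr = lr)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0))
  n <- length(samples)
  nn_set_training(model, TRUE)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      correct <- 0
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n)]
        xb <- batch$x[idx, , , , drop = FALSE]
        yb <- batch$y[idx]
        logits <- nn_forward(model, xb)
        l <- ce_loss(logits, yb)
        if (!is.finite(l$loss)) {
          stop("training diverged (non-finite loss) at epoch ", ep)
        }
        nn_zero_grad(model)
        nn_backward(model, l$grad)
        optim_step(opt)
        ep_loss <- ep_loss + l$loss * length(idx)
        correct <- correct + sum(l$pred == yb)
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                     accuracy = correct / n))
      if (correct / n >= stop_at_accuracy) break
    }
  })
  nn_set_training(model, FALSE)
  eval_set <- val_samples %||% samples
  eb <- samples_to_batch(eval_set)
  preds <- max.col(nn_forward(model, eb$x), ties.method = "first") - 1L
  list(history = hist,
       metrics = classification_metrics(eb$y, preds, n_classes),
       epochs_run = nrow(hist))
}
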