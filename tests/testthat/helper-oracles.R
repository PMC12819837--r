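# Independent oracles used across the suite. These deliberately avoid the
# package's fast paths: convolutions are enumerated position by position,
# metrics are recomputed from raw confusion counts.

# Weighted-sum oracle for the receptive-field attention convolution: for
# every output position, enumerate the k^2 attention-weighted samples and
# apply the fusion-convolution weights directly (no mosaic rearrangement).
scarf_enumeration_oracle <- function(layer, x) {
  spec <- layer$spec
  k <- spec$kernel_size
  kk <- k * k
  A <- scarf_attention(x, layer)                     # (B, C, kk, H', W')
  ch <- layer$children
  f <- nn_forward(ch$eca, nn_forward(ch$act,
         nn_forward(ch$bn, nn_forward(ch$feat_conv, x))))
  W <- ch$fuse$params$weight                          # (C_out, C, k, k)
  B <- dim(x)[1]; C <- spec$in_channels
  Hp <- dim(A)[4]; Wp <- dim(A)[5]
  y <- array(0, dim = c(B, spec$out_channels, Hp, Wp))
  for (b in seq_len(B)) for (o in seq_len(spec$out_channels)) {
    for (i in seq_len(Hp)) for (j in seq_len(Wp)) {
      acc <- 0
      for (cc in seq_len(C)) for (u in 0:(k - 1)) for (v in 0:(k - 1)) {
        s <- u * k + v
        acc <- acc + W[o, cc, u + 1, v + 1] *
          A[b, cc, s + 1, i, j] * f[b, (cc - 1) * kk + s + 1, i, j]
      }
      y[b, o, i, j] <- acc
    }
  }
  y
}

# Classification rates recomputed from an explicitly assembled confusion
# matrix, macro-averaged with zero-denominator rates set to 0.
cls_confusion_oracle <- function(truth, pred, n_classes) {
  cm <- matrix(0, n_classes, n_classes)
  for (i in seq_along(truth)) {
    cm[truth[i] + 1, pred[i] + 1] <- cm[truth[i] + 1, pred[i] + 1] + 1
  }
  n <- sum(cm)
  safe <- function(num, den) if (den > 0) num / den else 0
  pr <- re <- sp <- f1 <- numeric(n_classes)
  for (kq in seq_len(n_classes)) {
    tp <- cm[kq, kq]
    fp <- sum(cm[-kq, kq])
    fn <- sum(cm[kq, -kq])
    tn <- n - tp - fp - fn
    pr[kq] <- safe(tp, tp + fp)
    re[kq] <- safe(tp, tp + fn)
    sp[kq] <- safe(tn, tn + fp)
    f1[kq] <- safe(2 * tp, 2 * tp + fp + fn)
  }
  c(accuracy = sum(diag(cm)) / n, precision = mean(pr), recall = mean(re),
    specificity = mean(sp), f1 = mean(f1))
}

# Pixel-pooled IoU recomputed by direct counting.
seg_count_oracle <- function(truth, pred, n_classes) {
  iou <- numeric(n_classes)
  for (kq in 0:(n_classes - 1)) {
    inter <- un <- 0
    for (i in seq_along(truth)) {
      a <- truth[[i]] == kq
      b <- pred[[i]] == kq
      inter <- inter + sum(a & b)
      un <- un + sum(a | b)
    }
    iou[kq + 1] <- if (un > 0) inter / un else 0
  }
  c(miou = mean(iou), iou = iou)
}

rand_feature_map <- function(B, C, H, W) {
  array(stats::rnorm(B * C * H * W), dim = c(B, C, H, W))
}

# small helper: max absolute deviation
madev <- function(a, b) max(abs(a - b))
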