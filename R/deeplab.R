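# DeepLabV3 semantic segmentation: dilated ResNet-50 backbone (output
# stride 8), atrous spatial pyramid pooling head (rates 12/24/36), no
# auxiliary classifier; logits are bilinearly upsampled to the input size.

aspp_conv_branch <- function(in_ch, out_ch, dilation = NULL) {
  if (is.null(dilation)) {
    nn_sequential(conv = nn_conv2d(in_ch, out_ch, 1, bias = FALSE),
                  bn = nn_batchnorm2d(out_ch), relu = nn_relu())
  } else {
    nn_sequential(conv = nn_conv2d(in_ch, out_ch, 3, padding = dilation,
                                   dilation = dilation, bias = FALSE),
                  bn = nn_batchnorm2d(out_ch), relu = nn_relu())
  }
}

aspp_module <- function(in_ch = 2048, out_ch = 256,
                        rates = c(12, 24, 36)) {
  m <- new_module("nn_aspp", out_ch = out_ch)
  m$children <- list(
    b0 = aspp_conv_branch(in_ch, out_ch),
    b1 = aspp_conv_branch(in_ch, out_ch, rates[1]),
    b2 = aspp_conv_branch(in_ch, out_ch, rates[2]),
    b3 = aspp_conv_branch(in_ch, out_ch, rates[3]),
    pool_gap = nn_adaptive_avgpool2d(1),
    pool_conv = aspp_conv_branch(in_ch, out_ch),
    pool_up = nn_upsample_bilinear(),
    project = aspp_conv_branch(5 * out_ch, out_ch)
  )
  m
}

#' @export
nn_forward.nn_aspp <- function(m, x, ...) {
  ch <- m$children
  d <- dim(x)
  oc <- m$out_ch
  parts <- list(
    nn_forward(ch$b0, x), nn_forward(ch$b1, x),
    nn_forward(ch$b2, x), nn_forward(ch$b3, x),
    nn_forward(ch$pool_up,
               nn_forward(ch$pool_conv, nn_forward(ch$pool_gap, x)),
               size = c(d[3], d[4]))
  )
  out <- array(0, dim = c(d[1], 5 * oc, d[3], d[4]))
  for (i in 1:5) out[, (i - 1) * oc + seq_len(oc), , ] <- parts[[i]]
  nn_forward(ch$project, out)
}

#' @export
nn_backward.nn_aspp <- function(m, gy, ...) {
  ch <- m$children
  g <- nn_backward(ch$project, gy)
  d <- dim(g)
  oc <- m$out_ch
  take <- function(i) {
    s <- g[, (i - 1) * oc + seq_len(oc), , , drop = FALSE]
    dim(s) <- c(d[1], oc, d[3], d[4])
    s
  }
  gx <- nn_backward(ch$b0, take(1)) + nn_backward(ch$b1, take(2)) +
    nn_backward(ch$b2, take(3)) + nn_backward(ch$b3, take(4))
  gp <- nn_backward(ch$pool_gap,
          nn_backward(ch$pool_conv, nn_backward(ch$pool_up, take(5))))
  gx + gp
}

#' @export
nn_complexity.nn_aspp <- function(m, shape) {
  ch <- m$children
  macs <- nn_complexity(ch$b0, shape)$macs +
    nn_complexity(ch$b1, shape)$macs +
    nn_complexity(ch$b2, shape)$macs +
    nn_complexity(ch$b3, shape)$macs +
    nn_complexity(ch$pool_conv, c(shape[1], shape[2], 1, 1))$macs
  pr <- nn_complexity(ch$project,
                      c(shape[1], 5 * m$out_ch, shape[3], shape[4]))
  list(macs = macs + pr$macs, shape = pr$shape)
}

#' Build a DeepLabV3 segmentation network with a ResNet-50 backbone
#'
#' The backbone keeps its last two stages at 1/8 resolution with dilated
#' convolutions; the pyramid head uses atrous rates 12/24/36 and 256
#' channels; there is no auxiliary classifier.
#'
#' @param num_classes number of per-pixel classes
#' @param seed integer seed for parameter initialization
#' @return a segmentation model; [nn_forward()] maps `(B, 3, H, W)` to a
#'   `(B, num_classes, H, W)` score map
#' @export
deeplabv3_resnet50 <- function(num_classes = 21, seed = 42) {
  with_seed(seed, {
    m <- new_module("nn_deeplabv3", num_classes = num_classes)
    m$children <- list(
      backbone = resnet50_backbone(seed = seed + 1),
      aspp = aspp_module(),
      head_conv = nn_sequential(conv = nn_conv2d(256, 256, 3, padding = 1,
                                                 bias = FALSE),
                                bn = nn_batchnorm2d(256), relu = nn_relu()),
      classifier = nn_conv2d(256, num_classes, 1, bias = TRUE),
      up = nn_upsample_bilinear()
    )
    m
  })
}

#' @export
nn_forward.nn_deeplabv3 <- function(m, x, ...) {
  d <- dim(x)
  h <- nn_forward(m$children$backbone, x)
  h <- nn_forward(m$children$aspp, h)
  h <- nn_forward(m$children$head_conv, h)
  h <- nn_forward(m$children$classifier, h)
  nn_forward(m$children$up, h, size = c(d[3], d[4]))
}

#' @export
nn_backward.nn_deeplabv3 <- function(m, gy, ...) {
  g <- nn_backward(m$children$up, gy)
  g <- nn_backward(m$children$classifier, g)
  g <- nn_backward(m$children$head_conv, g)
  g <- nn_backward(m$children$aspp, g)
  nn_backward(m$children$backbone, g)
}

#' @export
nn_complexity.nn_deeplabv3 <- function(m, shape) {
  r <- nn_complexity(m$children$backbone, shape)
  r2 <- nn_complexity(m$children$aspp, r$shape)
  r3 <- nn_complexity(m$children$head_conv, r2$shape)
  r4 <- nn_complexity(m$children$classifier, r3$shape)
  list(macs = r$macs + r2$macs + r3$macs + r4$macs,
       shape = c(shape[1], m$num_classes, shape[3], shape[4]))
}
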