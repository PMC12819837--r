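# SCARF: spatial-channel adaptive receptive-field attention convolution.
#
# Attention path:  AvgPool(k, stride, same-pad, valid-tap counts)
#                  -> grouped 1x1 conv expanding C -> C*k^2
#                  -> softmax over the k^2 receptive-field axis.
# Feature path:    grouped (depthwise) k x k conv C -> C*k^2, BatchNorm,
#                  activation, channel recalibration.
# Fusion:          elementwise product, row-major mosaic rearrangement of
#                  the k^2 samples into a (k*H', k*W') grid, and a stride-k
#                  k x k convolution mapping C -> C_out.
#
# Internally the expanded tensors are carried as (B, k^2, C, H', W') arrays
# (receptive-field index fastest after batch); the public attention tensor
# uses the (B, C, k^2, H', W') axis order.

#' Build a SCARF layer
#'
#' @param spec a [scarf_spec()], or `in_channels` for the shorthand form
#' @param ... when `spec` is numeric, further arguments to [scarf_spec()]
#' @param seed integer seed for parameter initialization; the same seed
#'   reproduces bit-identical parameters
#' @return a module
#' @export
scarf_layer <- function(spec, ..., seed = 42) {
  if (!inherits(spec, "scarf_spec")) spec <- scarf_spec(spec, ...)
  k <- spec$kernel_size
  C <- spec$in_channels
  kk <- k * k
  with_seed(seed, {
    m <- new_module("nn_scarf", spec = spec, k = k, kk = kk)
    m$children <- list(
      pool = nn_avgpool2d(k, stride = spec$stride, padding = (k - 1) %/% 2,
                          count_include_pad = FALSE),
      att_conv = nn_conv2d(C, C * kk, 1, groups = spec$attention_groups,
                           bias = TRUE),
      feat_conv = nn_conv2d(C, C * kk, k, stride = spec$stride,
                            padding = (k - 1) %/% 2, groups = C,
                            bias = FALSE),
      bn = nn_batchnorm2d(C * kk),
      act = if (spec$activation == "relu") nn_relu() else nn_identity(),
      eca = nn_eca(C * kk, spec$eca_gamma, spec$eca_b),
      fuse = nn_conv2d(C, spec$out_channels, k, stride = k, padding = 0,
                       bias = FALSE)
    )
    m
  })
}

# softmax over the first axis of a (kk, M) matrix
softmax_cols <- function(L) {
  mx <- apply(L, 2, max)
  E <- exp(L - rep(mx, each = nrow(L)))
  E / rep(colSums(E), each = nrow(L))
}

# (B, kk*C, H, W) -> (kk, B*C*H*W) matrix with the kk axis extracted
expand_to_kkmat <- function(a, kk) {
  d <- dim(a)
  C <- d[2] / kk
  dim(a) <- c(d[1], kk, C, d[3], d[4])
  matrix(aperm(a, c(2, 1, 3, 4, 5)), nrow = kk)
}

kkmat_to_expand <- function(mat, kk, B, C, H, W) {
  a <- array(mat, dim = c(kk, B, C, H, W))
  a <- aperm(a, c(2, 1, 3, 4, 5))
  dim(a) <- c(B, kk * C, H, W)
  a
}

#' @export
nn_forward.nn_scarf <- function(m, x, ...) {
  check_feature_map(x)
  if (dim(x)[2] != m$spec$in_channels) {
    stop("input has ", dim(x)[2], " channels; spec expects ",
         m$spec$in_channels)
  }
  ch <- m$children
  k <- m$k; kk <- m$kk
  B <- dim(x)[1]; C <- m$spec$in_channels

  # attention path
  logits <- nn_forward(ch$att_conv, nn_forward(ch$pool, x))
  Hp <- dim(logits)[3]; Wp <- dim(logits)[4]
  P <- softmax_cols(expand_to_kkmat(logits, kk))

  # feature path
  f <- nn_forward(ch$eca, nn_forward(ch$act,
         nn_forward(ch$bn, nn_forward(ch$feat_conv, x))))
  if (dim(f)[3] != Hp || dim(f)[4] != Wp) {
    stop("attention/feature spatial shapes disagree")
  }
  Fm <- expand_to_kkmat(f, kk)

  Wm <- P * Fm
  Fw <- array(Wm, dim = c(kk, B, C, Hp, Wp))
  Fw <- aperm(Fw, c(2, 1, 3, 4, 5))          # (B, kk, C, H', W')

  # row-major mosaic: sample u*k+v of position (i, j) -> (i*k+u, j*k+v)
  dim(Fw) <- c(B, k, k, C, Hp, Wp)            # (b, v, u, c, i, j)
  M <- aperm(Fw, c(1, 4, 3, 5, 2, 6))         # (b, c, u, i, v, j)
  dim(M) <- c(B, C, k * Hp, k * Wp)

  y <- nn_forward(ch$fuse, M)
  m$cache <- list(P = P, Fm = Fm, B = B, C = C, Hp = Hp, Wp = Wp)
  y
}

#' @export
nn_backward.nn_scarf <- function(m, gy, ...) {
  ch <- m$children
  cc <- m$cache
  k <- m$k; kk <- m$kk
  B <- cc$B; C <- cc$C; Hp <- cc$Hp; Wp <- cc$Wp

  gM <- nn_backward(ch$fuse, gy)
  dim(gM) <- c(B, C, k, Hp, k, Wp)            # (b, c, u, i, v, j)
  gFw <- aperm(gM, c(1, 5, 3, 2, 4, 6))       # (b, v, u, c, i, j)
  dim(gFw) <- c(B, kk, C, Hp, Wp)
  gWm <- matrix(aperm(gFw, c(2, 1, 3, 4, 5)), nrow = kk)

  gP <- gWm * cc$Fm
  gF <- gWm * cc$P

  # feature path
  gf <- kkmat_to_expand(gF, kk, B, C, Hp, Wp)
  gx_feat <- nn_backward(ch$feat_conv,
               nn_backward(ch$bn,
                 nn_backward(ch$act, nn_backward(ch$eca, gf))))

  # softmax backward, then attention path
  glog <- cc$P * (gP - rep(colSums(cc$P * gP), each = kk))
  glogits <- kkmat_to_expand(glog, kk, B, C, Hp, Wp)
  gx_att <- nn_backward(ch$pool, nn_backward(ch$att_conv, glogits))

  gx_feat + gx_att
}

#' @export
nn_complexity.nn_scarf <- function(m, shape) {
  ch <- m$children
  p <- nn_complexity(ch$pool, shape)
  a <- nn_complexity(ch$att_conv, p$shape)
  f <- nn_complexity(ch$feat_conv, shape)
  e <- nn_complexity(ch$eca, f$shape)
  Hp <- f$shape[3]; Wp <- f$shape[4]
  mos <- c(shape[1], m$spec$in_channels, m$k * Hp, m$k * Wp)
  fu <- nn_complexity(ch$fuse, mos)
  list(macs = a$macs + f$macs + e$macs + fu$macs, shape = fu$shape)
}

#' Receptive-field attention tensor
#'
#' Runs only the attention path of a SCARF layer and returns the
#' softmax-normalized tensor over the `k^2` receptive-field axis.
#'
#' @param x feature map, `dim = c(B, C, H, W)`
#' @param layer a layer from [scarf_layer()], or a [scarf_spec()]
#' @param seed seed used when `layer` is a spec
#' @return array with `dim = c(B, C, k^2, H', W')`; entries are nonnegative
#'   and sum to 1 over the third axis at every position
#' @export
scarf_attention <- function(x, layer, seed = 42) {
  if (inherits(layer, "scarf_spec")) layer <- scarf_layer(layer, seed = seed)
  check_feature_map(x)
  if (dim(x)[2] != layer$spec$in_channels) {
    stop("input channels do not match the spec")
  }
  ch <- layer$children
  kk <- layer$kk
  logits <- nn_forward(ch$att_conv, nn_forward(ch$pool, x))
  Hp <- dim(logits)[3]; Wp <- dim(logits)[4]
  P <- softmax_cols(expand_to_kkmat(logits, kk))
  A <- array(P, dim = c(kk, dim(x)[1], layer$spec$in_channels, Hp, Wp))
  aperm(A, c(2, 3, 1, 4, 5))
}

#' Forward pass of the receptive-field attention convolution
#'
#' @param x feature map, `dim = c(B, C, H, W)`
#' @param layer a layer from [scarf_layer()], or a [scarf_spec()]
#' @param seed seed used when `layer` is a spec
#' @return feature map with `dim = c(B, C_out, ceil(H/stride),
#'   ceil(W/stride))`
#' @export
scarf_forward <- function(x, layer, seed = 42) {
  if (inherits(layer, "scarf_spec")) layer <- scarf_layer(layer, seed = seed)
  nn_forward(layer, x)
}
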