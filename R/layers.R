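# Primitive layers: convolution, batch normalization, activations, pooling,
# bilinear resize, linear head, sequential container.

#' 2-D convolution layer
#'
#' Weights are stored as `(C_out, C_in/groups, k, k)` arrays and initialized
#' with fan-in-scaled Gaussian draws from the current RNG stream; biases
#' start at zero.
#'
#' @param in_channels,out_channels channel counts
#' @param kernel_size square kernel size
#' @param stride,padding,dilation,groups usual convolution hyper-parameters
#' @param bias logical, include an additive per-channel bias
#' @param padding_mode `"zeros"` (default) or `"replicate"`; replicate
#'   padding clamps border coordinates so constant maps stay constant
#' @return a module
#' @export
nn_conv2d <- function(in_channels, out_channels, kernel_size, stride = 1,
                      padding = 0, dilation = 1, groups = 1, bias = TRUE,
                      padding_mode = c("zeros", "replicate")) {
  padding_mode <- match.arg(padding_mode)
  stopifnot(in_channels %% groups == 0, out_channels %% groups == 0)
  cg <- in_channels / groups
  fan_in <- cg * kernel_size^2
  w <- array(stats::rnorm(out_channels * cg * kernel_size^2) *
               sqrt(2 / fan_in),
             dim = c(out_channels, cg, kernel_size, kernel_size))
  m <- new_module("nn_conv2d",
                  in_channels = in_channels, out_channels = out_channels,
                  kernel_size = kernel_size, stride = stride,
                  padding = padding, dilation = dilation, groups = groups,
                  has_bias = bias,
                  pad_mode = if (padding_mode == "zeros") 0L else 1L)
  add_param(m, "weight", w)
  if (bias) add_param(m, "bias", numeric(out_channels))
  m
}

#' @export
nn_forward.nn_conv2d <- function(m, x, ...) {
  m$cache <- list(x = x)
  conv2d_fwd_cpp(x, m$params$weight,
                 if (m$has_bias) m$params$bias else NULL,
                 m$stride, m$padding, m$dilation, m$groups, m$pad_mode)
}

#' @export
nn_backward.nn_conv2d <- function(m, gy, ...) {
  r <- conv2d_bwd_cpp(m$cache$x, m$params$weight, gy,
                      m$stride, m$padding, m$dilation, m$groups,
                      TRUE, m$has_bias, m$pad_mode)
  m$grads$weight <- m$grads$weight + r$gw
  if (m$has_bias) m$grads$bias <- m$grads$bias + r$gb
  r$gx
}

#' @export
nn_complexity.nn_conv2d <- function(m, shape) {
  ho <- (shape[3] + 2 * m$padding - m$dilation * (m$kernel_size - 1) - 1) %/%
    m$stride + 1
  wo <- (shape[4] + 2 * m$padding - m$dilation * (m$kernel_size - 1) - 1) %/%
    m$stride + 1
  macs <- shape[1] * ho * wo * m$out_channels *
    (m$in_channels / m$groups) * m$kernel_size^2
  list(macs = macs, shape = c(shape[1], m$out_channels, ho, wo))
}

#' Batch normalization over the channel axis
#'
#' @param num_features channel count
#' @param eps numerical stabilizer
#' @param momentum running-statistics update rate
#' @return a module
#' @export
nn_batchnorm2d <- function(num_features, eps = 1e-5, momentum = 0.1) {
  m <- new_module("nn_batchnorm2d", num_features = num_features,
                  eps = eps, momentum = momentum)
  add_param(m, "gamma", rep(1, num_features))
  add_param(m, "beta", numeric(num_features))
  m$buffers$running_mean <- numeric(num_features)
  m$buffers$running_var <- rep(1, num_features)
  m
}

# Broadcast a length-C vector over a (B, C, H, W) array.
bc_chan <- function(v, d) rep(rep(v, each = d[1]), times = d[3] * d[4])

#' @export
nn_forward.nn_batchnorm2d <- function(m, x, ...) {
  d <- dim(x)
  n <- d[1] * d[3] * d[4]
  xm <- matrix(aperm(x, c(1, 3, 4, 2)), ncol = d[2])
  if (m$training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    m$buffers$running_mean <- (1 - m$momentum) * m$buffers$running_mean +
      m$momentum * mu
    # unbiased running variance, biased batch variance in the normalizer
    m$buffers$running_var <- (1 - m$momentum) * m$buffers$running_var +
      m$momentum * va * n / max(n - 1, 1)
  } else {
    mu <- m$buffers$running_mean
    va <- m$buffers$running_var
  }
  istd <- 1 / sqrt(va + m$eps)
  xhat <- (x - bc_chan(mu, d)) * bc_chan(istd, d)
  m$cache <- list(xhat = xhat, istd = istd, d = d, n = n)
  xhat * bc_chan(m$params$gamma, d) + bc_chan(m$params$beta, d)
}

#' @export
nn_backward.nn_batchnorm2d <- function(m, gy, ...) {
  cc <- m$cache
  d <- cc$d
  gym <- matrix(aperm(gy, c(1, 3, 4, 2)), ncol = d[2])
  xhm <- matrix(aperm(cc$xhat, c(1, 3, 4, 2)), ncol = d[2])
  m$grads$gamma <- m$grads$gamma + colSums(gym * xhm)
  m$grads$beta <- m$grads$beta + colSums(gym)
  if (!m$training) {
    return(gy * bc_chan(m$params$gamma * cc$istd, d))
  }
  n <- cc$n
  gxhat_sum <- colSums(gym) * m$params$gamma
  gxhat_dot <- colSums(gym * xhm) * m$params$gamma
  gxhat <- gy * bc_chan(m$params$gamma, d)
  (gxhat - bc_chan(gxhat_sum / n, d) -
     cc$xhat * bc_chan(gxhat_dot / n, d)) * bc_chan(cc$istd, d)
}

#' @export
nn_complexity.nn_batchnorm2d <- function(m, shape) list(macs = 0, shape = shape)

#' Rectified linear activation
#' @return a module
#' @export
nn_relu <- function() new_module("nn_relu")

#' @export
nn_forward.nn_relu <- function(m, x, ...) {
  m$cache <- list(mask = x > 0)
  x * (x > 0)
}

#' @export
nn_backward.nn_relu <- function(m, gy, ...) gy * m$cache$mask

#' @export
nn_complexity.nn_relu <- function(m, shape) list(macs = 0, shape = shape)

#' Average pooling layer
#'
#' `count_include_pad = FALSE` (the default) divides border windows by their
#' number of valid taps, so constant maps are preserved at borders.
#'
#' @param kernel_size,stride,padding pooling geometry
#' @param count_include_pad divide by `k^2` even where the window overlaps
#'   the padding
#' @return a module
#' @export
nn_avgpool2d <- function(kernel_size, stride = kernel_size, padding = 0,
                         count_include_pad = FALSE) {
  new_module("nn_avgpool2d", kernel_size = kernel_size, stride = stride,
             padding = padding, include_pad = count_include_pad)
}

#' @export
nn_forward.nn_avgpool2d <- function(m, x, ...) {
  m$cache <- list(d = dim(x))
  avgpool2d_fwd_cpp(x, m$kernel_size, m$stride, m$padding, m$include_pad)
}

#' @export
nn_backward.nn_avgpool2d <- function(m, gy, ...) {
  avgpool2d_bwd_cpp(gy, m$cache$d[3], m$cache$d[4], m$kernel_size, m$stride,
                    m$padding, m$include_pad)
}

#' @export
nn_complexity.nn_avgpool2d <- function(m, shape) {
  ho <- (shape[3] + 2 * m$padding - m$kernel_size) %/% m$stride + 1
  wo <- (shape[4] + 2 * m$padding - m$kernel_size) %/% m$stride + 1
  list(macs = 0, shape = c(shape[1], shape[2], ho, wo))
}

#' Max pooling layer
#' @param kernel_size,stride,padding pooling geometry
#' @return a module
#' @export
nn_maxpool2d <- function(kernel_size, stride = kernel_size, padding = 0) {
  new_module("nn_maxpool2d", kernel_size = kernel_size, stride = stride,
             padding = padding)
}

#' @export
nn_forward.nn_maxpool2d <- function(m, x, ...) {
  r <- maxpool2d_fwd_cpp(x, m$kernel_size, m$stride, m$padding)
  m$cache <- list(argmax = r$argmax, d = dim(x))
  r$y
}

#' @export
nn_backward.nn_maxpool2d <- function(m, gy, ...) {
  maxpool2d_bwd_cpp(gy, m$cache$argmax, m$cache$d)
}

#' @export
nn_complexity.nn_maxpool2d <- function(m, shape) {
  ho <- (shape[3] + 2 * m$padding - m$kernel_size) %/% m$stride + 1
  wo <- (shape[4] + 2 * m$padding - m$kernel_size) %/% m$stride + 1
  list(macs = 0, shape = c(shape[1], shape[2], ho, wo))
}

#' Adaptive average pooling to a fixed output size
#' @param output_size target spatial size (scalar, square output)
#' @return a module
#' @export
nn_adaptive_avgpool2d <- function(output_size) {
  new_module("nn_adaptive_avgpool2d", output_size = output_size)
}

#' @export
nn_forward.nn_adaptive_avgpool2d <- function(m, x, ...) {
  m$cache <- list(d = dim(x))
  adaptive_avgpool_fwd_cpp(x, m$output_size, m$output_size)
}

#' @export
nn_backward.nn_adaptive_avgpool2d <- function(m, gy, ...) {
  adaptive_avgpool_bwd_cpp(gy, m$cache$d[3], m$cache$d[4])
}

#' @export
nn_complexity.nn_adaptive_avgpool2d <- function(m, shape) {
  list(macs = 0, shape = c(shape[1], shape[2], m$output_size, m$output_size))
}

#' Bilinear spatial resize (no corner alignment)
#' @param size target spatial size, either scalar or `c(H, W)`; `NULL`
#'   means "resize to the size recorded at forward time by the caller"
#' @return a module
#' @export
nn_upsample_bilinear <- function(size = NULL) {
  new_module("nn_upsample_bilinear", size = size)
}

#' @export
nn_forward.nn_upsample_bilinear <- function(m, x, size = NULL, ...) {
  tgt <- size %||% m$size
  if (length(tgt) == 1) tgt <- c(tgt, tgt)
  m$cache <- list(d = dim(x))
  bilinear_fwd_cpp(x, tgt[1], tgt[2])
}

#' @export
nn_backward.nn_upsample_bilinear <- function(m, gy, ...) {
  bilinear_bwd_cpp(gy, m$cache$d[3], m$cache$d[4])
}

#' @export
nn_complexity.nn_upsample_bilinear <- function(m, shape) {
  tgt <- m$size
  if (length(tgt) == 1) tgt <- c(tgt, tgt)
  list(macs = 0, shape = c(shape[1], shape[2], tgt[1], tgt[2]))
}

#' Fully connected layer on flattened features
#' @param in_features,out_features dimensions
#' @return a module
#' @export
nn_linear <- function(in_features, out_features) {
  m <- new_module("nn_linear", in_features = in_features,
                  out_features = out_features)
  add_param(m, "weight",
            array(stats::rnorm(out_features * in_features) *
                    sqrt(1 / in_features),
                  dim = c(out_features, in_features)))
  add_param(m, "bias", numeric(out_features))
  m
}

#' @export
nn_forward.nn_linear <- function(m, x, ...) {
  # x: (B, in_features)
  m$cache <- list(x = x)
  x %*% t(m$params$weight) + matrix(m$params$bias, nrow(x),
                                    m$out_features, byrow = TRUE)
}

#' @export
nn_backward.nn_linear <- function(m, gy, ...) {
  m$grads$weight <- m$grads$weight + t(gy) %*% m$cache$x
  m$grads$bias <- m$grads$bias + colSums(gy)
  gy %*% m$params$weight
}

#' @export
nn_complexity.nn_linear <- function(m, shape) {
  list(macs = shape[1] * m$in_features * m$out_features,
       shape = c(shape[1], m$out_features))
}

#' Sequential container
#' @param ... child modules, applied in order
#' @return a module
#' @export
nn_sequential <- function(...) {
  ch <- list(...)
  if (is.null(names(ch)) || any(names(ch) == "")) {
    names(ch) <- as.character(seq_along(ch) - 1L)
  }
  m <- new_module("nn_sequential")
  m$children <- ch
  m
}

#' @export
nn_forward.nn_sequential <- function(m, x, ...) {
  for (ch in m$children) x <- nn_forward(ch, x)
  x
}

#' @export
nn_backward.nn_sequential <- function(m, gy, ...) {
  for (ch in rev(m$children)) gy <- nn_backward(ch, gy)
  gy
}

#' @export
nn_complexity.nn_sequential <- function(m, shape) {
  macs <- 0
  for (ch in m$children) {
    r <- nn_complexity(ch, shape)
    macs <- macs + r$macs
    shape <- r$shape
  }
  list(macs = macs, shape = shape)
}

#' Identity layer
#' @return a module
#' @export
nn_identity <- function() new_module("nn_identity")

#' @export
nn_forward.nn_identity <- function(m, x, ...) x

#' @export
nn_backward.nn_identity <- function(m, gy, ...) gy

#' @export
nn_complexity.nn_identity <- function(m, shape) list(macs = 0, shape = shape)
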