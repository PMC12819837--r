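# Efficient channel attention: global average pooling, a 1-D cross-channel
# convolution whose odd kernel size adapts to the channel count, and a
# sigmoid gate applied channel-wise.

#' Adaptive kernel size of the channel-attention convolution
#'
#' `t = floor(|log2(C)/gamma + b/gamma|)`; even values are bumped to the
#' next odd, with a floor of 3. Equivalent to rounding `|log2(C)/gamma +
#' b/gamma|` to the nearest odd integer (ties upward).
#'
#' @param channels channel count `C`
#' @param gamma,b rule constants
#' @return an odd integer kernel size
#' @export
eca_kernel_size <- function(channels, gamma = 2, b = 1) {
  t <- floor(abs(log2(channels) / gamma + b / gamma))
  k <- ifelse(t %% 2 == 1, t, t + 1)
  as.integer(pmax(k, 3))
}

#' Channel recalibration layer
#' @param channels channel count of the gated feature map
#' @param gamma,b adaptive kernel size constants
#' @return a module
#' @export
nn_eca <- function(channels, gamma = 2, b = 1) {
  ks <- eca_kernel_size(channels, gamma, b)
  m <- new_module("nn_eca", channels = channels, ksize = ks,
                  pad = (ks - 1) %/% 2)
  add_param(m, "weight", stats::rnorm(ks) * sqrt(1 / ks))
  m
}

# 1-D zero-padded cross-channel convolution of a (B, C) matrix.
conv1d_chan <- function(y, w, pad) {
  ks <- length(w)
  C <- ncol(y)
  z <- matrix(0, nrow(y), C)
  for (j in seq_len(ks)) {
    off <- j - 1L - pad
    tgt <- seq.int(max(1L, 1L - off), min(C, C - off))
    if (length(tgt)) z[, tgt] <- z[, tgt] + w[j] * y[, tgt + off]
  }
  z
}

#' @export
nn_forward.nn_eca <- function(m, x, ...) {
  d <- dim(x)
  y <- matrix(rowMeans(matrix(x, nrow = d[1] * d[2])), d[1], d[2])
  z <- conv1d_chan(y, m$params$weight, m$pad)
  s <- sigmoid(z)
  m$cache <- list(x = x, y = y, s = s, d = d)
  x * as.vector(s)
}

#' @export
nn_backward.nn_eca <- function(m, gy, ...) {
  cc <- m$cache
  d <- cc$d
  gs <- matrix(rowSums(matrix(gy * cc$x, nrow = d[1] * d[2])), d[1], d[2])
  gz <- gs * cc$s * (1 - cc$s)
  ks <- m$ksize
  C <- d[2]
  gw <- numeric(ks)
  gyc <- matrix(0, d[1], C)
  for (j in seq_len(ks)) {
    off <- j - 1L - m$pad
    tgt <- seq.int(max(1L, 1L - off), min(C, C - off))
    if (length(tgt)) {
      gw[j] <- sum(gz[, tgt] * cc$y[, tgt + off])
      gyc[, tgt + off] <- gyc[, tgt + off] + m$params$weight[j] * gz[, tgt]
    }
  }
  m$grads$weight <- m$grads$weight + gw
  gy * as.vector(cc$s) + array(as.vector(gyc) / (d[3] * d[4]), dim = d)
}

#' @export
nn_complexity.nn_eca <- function(m, shape) {
  list(macs = shape[1] * shape[2] * m$ksize, shape = shape)
}

#' Channel-attention gating of a feature map
#'
#' Functional form of the recalibration used inside the receptive-field
#' attention branch: global average pooling over space, a 1-D cross-channel
#' convolution of adaptive odd size, a sigmoid, and channel-wise scaling.
#'
#' @param x feature map, `dim = c(B, C, H, W)`
#' @param weights numeric vector of 1-D convolution taps whose length must
#'   equal [eca_kernel_size()] of `C`; when `NULL`, taps are drawn from the
#'   current RNG stream
#' @param gamma,b adaptive kernel size constants
#' @return gated feature map, same shape as `x`
#' @export
eca_gate <- function(x, weights = NULL, gamma = 2, b = 1) {
  check_feature_map(x)
  C <- dim(x)[2]
  ks <- eca_kernel_size(C, gamma, b)
  if (is.null(weights)) weights <- stats::rnorm(ks) * sqrt(1 / ks)
  if (length(weights) != ks) {
    stop("weights must have length ", ks, " for ", C, " channels")
  }
  m <- nn_eca(C, gamma, b)
  m$params$weight[] <- weights
  nn_forward(m, x)
}
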