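# MEFE: multi-scale edge feature enhancement.
#
# Per pyramid scale s_i: adaptive average pooling to s_i x s_i, a 1x1
# channel reduction C -> C/r, a depthwise-separable 3x3 convolution, and a
# bilinear upsample back to the input resolution gives F_i. The edge
# response E_i = F_i - AvgPool3x3(F_i) (valid-tap averaging, so constants
# map exactly to zero) is refined by a bias-free depthwise-separable stack
# phi and added back: F^_i = F_i + phi(E_i). All F^_i are concatenated on
# channels and fused by a 1x1 convolution to C_out.

#' High-pass edge response of a feature map
#'
#' Subtracts a 3x3 moving average from the map. Border windows average only
#' their valid taps, so a constant map yields an exactly zero response
#' everywhere, including borders, and the operator is linear.
#'
#' @param f feature map, `dim = c(B, C, H, W)`
#' @return array of the same shape
#' @export
edge_response <- function(f) {
  check_feature_map(f)
  highpass3_cpp(f)
}

ds_conv <- function(channels, bias_pw = TRUE) {
  # depthwise 3x3 (replicate-padded so constants propagate, no bias)
  # followed by a pointwise 1x1
  list(dw = nn_conv2d(channels, channels, 3, padding = 1, groups = channels,
                      bias = FALSE, padding_mode = "replicate"),
       pw = nn_conv2d(channels, channels, 1, bias = bias_pw))
}

#' Build a MEFE layer
#'
#' @param spec a [mefe_spec()], or `in_channels` for the shorthand form
#' @param ... when `spec` is numeric, further arguments to [mefe_spec()]
#' @param seed integer seed for parameter initialization
#' @return a module
#' @export
mefe_layer <- function(spec, ..., seed = 42) {
  if (!inherits(spec, "mefe_spec")) spec <- mefe_spec(spec, ...)
  C <- spec$in_channels
  Cr <- C / spec$reduction_ratio
  n <- length(spec$pool_sizes)
  with_seed(seed, {
    m <- new_module("nn_mefe", spec = spec, n = n, cr = Cr, warned = FALSE)
    ch <- list()
    for (i in seq_len(n)) {
      pre <- paste0("b", i, "_")
      ds <- ds_conv(Cr)
      ch[[paste0(pre, "pool")]] <- nn_adaptive_avgpool2d(spec$pool_sizes[i])
      ch[[paste0(pre, "reduce")]] <- nn_conv2d(C, Cr, 1, bias = TRUE)
      ch[[paste0(pre, "dw")]] <- ds$dw
      ch[[paste0(pre, "pw")]] <- ds$pw
      ch[[paste0(pre, "up")]] <- nn_upsample_bilinear()
      # bias-free refinement stack: refinement_depth DS layers, ReLU between
      phi <- list()
      for (dth in seq_len(spec$refinement_depth)) {
        if (dth > 1) phi[[length(phi) + 1]] <- nn_relu()
        dsr <- ds_conv(Cr, bias_pw = FALSE)
        phi[[length(phi) + 1]] <- dsr$dw
        phi[[length(phi) + 1]] <- dsr$pw
      }
      ch[[paste0(pre, "phi")]] <- do.call(nn_sequential, phi)
    }
    ch$fuse <- nn_conv2d(n * Cr, spec$out_channels, 1, bias = FALSE)
    if (spec$stride > 1) {
      ch$down <- nn_avgpool2d(spec$stride, spec$stride, 0, FALSE)
    }
    m$children <- ch
    m
  })
}

#' @export
nn_forward.nn_mefe <- function(m, x, ...) {
  check_feature_map(x)
  if (dim(x)[2] != m$spec$in_channels) {
    stop("input has ", dim(x)[2], " channels; spec expects ",
         m$spec$in_channels)
  }
  ch <- m$children
  d <- dim(x)
  H <- d[3]; W <- d[4]
  Cr <- m$cr
  out <- array(0, dim = c(d[1], m$n * Cr, H, W))
  for (i in seq_len(m$n)) {
    pre <- paste0("b", i, "_")
    s_eff <- min(m$spec$pool_sizes[i], H, W)
    if (s_eff < m$spec$pool_sizes[i] && !m$warned) {
      warning("pool size ", m$spec$pool_sizes[i],
              " exceeds the input spatial size; clamped to ", s_eff,
              call. = FALSE)
      m$warned <- TRUE
    }
    ch[[paste0(pre, "pool")]]$output_size <- s_eff
    p <- nn_forward(ch[[paste0(pre, "pool")]], x)
    r <- nn_forward(ch[[paste0(pre, "pw")]],
           nn_forward(ch[[paste0(pre, "dw")]],
             nn_forward(ch[[paste0(pre, "reduce")]], p)))
    Fi <- nn_forward(ch[[paste0(pre, "up")]], r, size = c(H, W))
    Ei <- edge_response(Fi)
    Fhat <- Fi + nn_forward(ch[[paste0(pre, "phi")]], Ei)
    out[, (i - 1) * Cr + seq_len(Cr), , ] <- Fhat
  }
  y <- nn_forward(ch$fuse, out)
  if (m$spec$stride > 1) {
    s <- m$spec$stride
    ch$down$padding <- as.integer(ceiling((ceiling(H / s) * s - H) / 2))
    y <- nn_forward(ch$down, y)
  }
  m$cache <- list(d = d)
  y
}

#' @export
nn_backward.nn_mefe <- function(m, gy, ...) {
  ch <- m$children
  d <- m$cache$d
  Cr <- m$cr
  if (m$spec$stride > 1) gy <- nn_backward(ch$down, gy)
  gcat <- nn_backward(ch$fuse, gy)
  gx <- array(0, dim = d)
  for (i in seq_len(m$n)) {
    pre <- paste0("b", i, "_")
    gFhat <- gcat[, (i - 1) * Cr + seq_len(Cr), , , drop = FALSE]
    dim(gFhat) <- c(d[1], Cr, d[3], d[4])
    gEi <- nn_backward(ch[[paste0(pre, "phi")]], gFhat)
    # E = F - AvgPool3(F)  =>  gF += gE - AvgPool3^T(gE)
    gFi <- gFhat + gEi -
      avgpool2d_bwd_cpp(gEi, d[3], d[4], 3L, 1L, 1L, FALSE)
    gr <- nn_backward(ch[[paste0(pre, "up")]], gFi)
    gp <- nn_backward(ch[[paste0(pre, "reduce")]],
            nn_backward(ch[[paste0(pre, "dw")]],
              nn_backward(ch[[paste0(pre, "pw")]], gr)))
    gx <- gx + nn_backward(ch[[paste0(pre, "pool")]], gp)
  }
  gx
}

#' @export
nn_complexity.nn_mefe <- function(m, shape) {
  ch <- m$children
  Cr <- m$cr
  macs <- 0
  for (i in seq_len(m$n)) {
    pre <- paste0("b", i, "_")
    s_eff <- min(m$spec$pool_sizes[i], shape[3], shape[4])
    pshape <- c(shape[1], shape[2], s_eff, s_eff)
    r1 <- nn_complexity(ch[[paste0(pre, "reduce")]], pshape)
    r2 <- nn_complexity(ch[[paste0(pre, "dw")]], r1$shape)
    r3 <- nn_complexity(ch[[paste0(pre, "pw")]], r2$shape)
    up <- c(shape[1], Cr, shape[3], shape[4])
    r4 <- nn_complexity(ch[[paste0(pre, "phi")]], up)
    macs <- macs + r1$macs + r2$macs + r3$macs + r4$macs
  }
  cat_shape <- c(shape[1], m$n * Cr, shape[3], shape[4])
  r5 <- nn_complexity(ch$fuse, cat_shape)
  macs <- macs + r5$macs
  out <- r5$shape
  if (m$spec$stride > 1) {
    out <- c(out[1], out[2], ceiling(out[3] / m$spec$stride),
             ceiling(out[4] / m$spec$stride))
  }
  list(macs = macs, shape = out)
}

#' Forward pass of the multi-scale edge-enhancement branch
#'
#' @param x feature map, `dim = c(B, C, H, W)`
#' @param layer a layer from [mefe_layer()], or a [mefe_spec()]
#' @param seed seed used when `layer` is a spec
#' @return feature map, `dim = c(B, C_out, H/stride, W/stride)`
#' @export
mefe_forward <- function(x, layer, seed = 42) {
  if (inherits(layer, "mefe_spec")) layer <- mefe_layer(layer, seed = seed)
  nn_forward(layer, x)
}
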