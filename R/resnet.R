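# Residual classification backbones. Layer geometry follows the standard
# ResNet family: a 7x7 stem, four stages of residual blocks, global average
# pooling and a linear head. The segmentation backbone variant keeps the
# final two stages at 1/8 resolution using dilated 3x3 convolutions.

basic_block <- function(inplanes, planes, stride = 1) {
  m <- new_module("nn_basicblock", stride = stride)
  ch <- list(
    conv1 = nn_conv2d(inplanes, planes, 3, stride = stride, padding = 1,
                      bias = FALSE),
    bn1 = nn_batchnorm2d(planes),
    relu1 = nn_relu(),
    conv2 = nn_conv2d(planes, planes, 3, padding = 1, bias = FALSE),
    bn2 = nn_batchnorm2d(planes)
  )
  if (stride != 1 || inplanes != planes) {
    ch$downsample <- nn_sequential(
      conv = nn_conv2d(inplanes, planes, 1, stride = stride, bias = FALSE),
      bn = nn_batchnorm2d(planes))
  }
  ch$relu2 <- nn_relu()
  m$children <- ch
  m
}

#' @export
nn_forward.nn_basicblock <- function(m, x, ...) {
  ch <- m$children
  out <- nn_forward(ch$bn2, nn_forward(ch$conv2,
           nn_forward(ch$relu1, nn_forward(ch$bn1,
             nn_forward(ch$conv1, x)))))
  idt <- if (!is.null(ch$downsample)) nn_forward(ch$downsample, x) else x
  nn_forward(ch$relu2, out + idt)
}

#' @export
nn_backward.nn_basicblock <- function(m, gy, ...) {
  ch <- m$children
  g <- nn_backward(ch$relu2, gy)
  gmain <- nn_backward(ch$conv1, nn_backward(ch$bn1,
             nn_backward(ch$relu1, nn_backward(ch$conv2,
               nn_backward(ch$bn2, g)))))
  gid <- if (!is.null(ch$downsample)) nn_backward(ch$downsample, g) else g
  gmain + gid
}

#' @export
nn_complexity.nn_basicblock <- function(m, shape) {
  ch <- m$children
  r1 <- nn_complexity(ch$conv1, shape)
  r2 <- nn_complexity(ch$conv2, r1$shape)
  macs <- r1$macs + r2$macs
  if (!is.null(ch$downsample)) {
    macs <- macs + nn_complexity(ch$downsample, shape)$macs
  }
  list(macs = macs, shape = r2$shape)
}

bottleneck_block <- function(inplanes, planes, stride = 1, dilation = 1) {
  expansion <- 4L
  m <- new_module("nn_bottleneck", stride = stride)
  ch <- list(
    conv1 = nn_conv2d(inplanes, planes, 1, bias = FALSE),
    bn1 = nn_batchnorm2d(planes),
    relu1 = nn_relu(),
    conv2 = nn_conv2d(planes, planes, 3, stride = stride,
                      padding = dilation, dilation = dilation, bias = FALSE),
    bn2 = nn_batchnorm2d(planes),
    relu2 = nn_relu(),
    conv3 = nn_conv2d(planes, planes * expansion, 1, bias = FALSE),
    bn3 = nn_batchnorm2d(planes * expansion)
  )
  if (stride != 1 || inplanes != planes * expansion) {
    ch$downsample <- nn_sequential(
      conv = nn_conv2d(inplanes, planes * expansion, 1, stride = stride,
                       bias = FALSE),
      bn = nn_batchnorm2d(planes * expansion))
  }
  ch$relu3 <- nn_relu()
  m$children <- ch
  m
}

#' @export
nn_forward.nn_bottleneck <- function(m, x, ...) {
  ch <- m$children
  out <- nn_forward(ch$relu1, nn_forward(ch$bn1, nn_forward(ch$conv1, x)))
  out <- nn_forward(ch$relu2, nn_forward(ch$bn2, nn_forward(ch$conv2, out)))
  out <- nn_forward(ch$bn3, nn_forward(ch$conv3, out))
  idt <- if (!is.null(ch$downsample)) nn_forward(ch$downsample, x) else x
  nn_forward(ch$relu3, out + idt)
}

#' @export
nn_backward.nn_bottleneck <- function(m, gy, ...) {
  ch <- m$children
  g <- nn_backward(ch$relu3, gy)
  gm <- nn_backward(ch$bn3, g)
  gm <- nn_backward(ch$conv3, gm)
  gm <- nn_backward(ch$relu2, gm)
  gm <- nn_backward(ch$conv2, nn_backward(ch$bn2, gm))
  gm <- nn_backward(ch$relu1, gm)
  gm <- nn_backward(ch$conv1, nn_backward(ch$bn1, gm))
  gid <- if (!is.null(ch$downsample)) nn_backward(ch$downsample, g) else g
  gm + gid
}

#' @export
nn_complexity.nn_bottleneck <- function(m, shape) {
  ch <- m$children
  r1 <- nn_complexity(ch$conv1, shape)
  r2 <- nn_complexity(ch$conv2, r1$shape)
  r3 <- nn_complexity(ch$conv3, r2$shape)
  macs <- r1$macs + r2$macs + r3$macs
  if (!is.null(ch$downsample)) {
    macs <- macs + nn_complexity(ch$downsample, shape)$macs
  }
  list(macs = macs, shape = r3$shape)
}

resnet_stages <- function(block, layers, dilate34 = FALSE) {
  expansion <- if (block == "basic") 1L else 4L
  make_block <- function(inp, pl, st, dil) {
    if (block == "basic") basic_block(inp, pl, st)
    else bottleneck_block(inp, pl, st, dil)
  }
  stages <- list()
  inplanes <- 64L
  dilation <- 1L
  planes_per <- c(64L, 128L, 256L, 512L)
  strides <- c(1L, 2L, 2L, 2L)
  for (s in 1:4) {
    stride <- strides[s]
    prev_dil <- dilation
    if (dilate34 && s >= 3) {
      dilation <- dilation * stride
      stride <- 1L
    }
    blocks <- list()
    blocks[["0"]] <- make_block(inplanes, planes_per[s], stride, prev_dil)
    inplanes <- planes_per[s] * expansion
    for (b in seq_len(layers[s] - 1)) {
      blocks[[as.character(b)]] <- make_block(inplanes, planes_per[s], 1L,
                                              dilation)
    }
    st <- nn_sequential()
    st$children <- blocks
    stages[[paste0("layer", s)]] <- st
  }
  stages
}

#' Build a ResNet-18 image classifier
#'
#' Standard topology: 7x7/2 stem, max pool, four stages of two two-conv
#' residual blocks (64/128/256/512 channels), global average pooling and a
#' linear head.
#'
#' @param num_classes output dimension of the linear head
#' @param seed integer seed for parameter initialization
#' @return a classification model; [nn_forward()] maps a `(B, 3, H, W)`
#'   array to `(B, num_classes)` scores
#' @export
resnet18 <- function(num_classes = 1000, seed = 42) {
  with_seed(seed, {
    m <- new_module("nn_resnet", num_classes = num_classes,
                    feat_dim = 512L)
    m$children <- c(
      list(conv1 = nn_conv2d(3, 64, 7, stride = 2, padding = 3,
                             bias = FALSE),
           bn1 = nn_batchnorm2d(64),
           relu = nn_relu(),
           maxpool = nn_maxpool2d(3, 2, 1)),
      resnet_stages("basic", c(2L, 2L, 2L, 2L)),
      list(gap = nn_adaptive_avgpool2d(1),
           fc = nn_linear(512, num_classes))
    )
    m
  })
}

resnet50_backbone <- function(seed = 42, dilate34 = TRUE) {
  with_seed(seed, {
    m <- new_module("nn_resnet_backbone", feat_dim = 2048L)
    m$children <- c(
      list(conv1 = nn_conv2d(3, 64, 7, stride = 2, padding = 3,
                             bias = FALSE),
           bn1 = nn_batchnorm2d(64),
           relu = nn_relu(),
           maxpool = nn_maxpool2d(3, 2, 1)),
      resnet_stages("bottleneck", c(3L, 4L, 6L, 3L), dilate34 = dilate34)
    )
    m
  })
}

resnet_trunk_forward <- function(m, x) {
  ch <- m$children
  h <- nn_forward(ch$maxpool, nn_forward(ch$relu,
         nn_forward(ch$bn1, nn_forward(ch$conv1, x))))
  for (s in paste0("layer", 1:4)) h <- nn_forward(ch[[s]], h)
  h
}

resnet_trunk_backward <- function(m, g) {
  ch <- m$children
  for (s in paste0("layer", 4:1)) g <- nn_backward(ch[[s]], g)
  nn_backward(ch$conv1, nn_backward(ch$bn1,
    nn_backward(ch$relu, nn_backward(ch$maxpool, g))))
}

resnet_trunk_complexity <- function(m, shape) {
  ch <- m$children
  macs <- 0
  for (nm in c("conv1", "bn1", "relu", "maxpool",
               paste0("layer", 1:4))) {
    r <- nn_complexity(ch[[nm]], shape)
    macs <- macs + r$macs
    shape <- r$shape
  }
  list(macs = macs, shape = shape)
}

#' @export
nn_forward.nn_resnet <- function(m, x, ...) {
  h <- resnet_trunk_forward(m, x)
  h <- nn_forward(m$children$gap, h)
  B <- dim(h)[1]
  nn_forward(m$children$fc, matrix(h, nrow = B))
}

#' @export
nn_backward.nn_resnet <- function(m, gy, ...) {
  g <- nn_backward(m$children$fc, gy)
  g <- array(g, dim = c(nrow(gy), m$feat_dim, 1, 1))
  g <- nn_backward(m$children$gap, g)
  resnet_trunk_backward(m, g)
}

#' @export
nn_complexity.nn_resnet <- function(m, shape) {
  r <- resnet_trunk_complexity(m, shape)
  f <- nn_complexity(m$children$fc, c(shape[1], m$feat_dim))
  list(macs = r$macs + f$macs, shape = f$shape)
}

#' @export
nn_forward.nn_resnet_backbone <- function(m, x, ...) {
  resnet_trunk_forward(m, x)
}

#' @export
nn_backward.nn_resnet_backbone <- function(m, gy, ...) {
  resnet_trunk_backward(m, gy)
}

#' @export
nn_complexity.nn_resnet_backbone <- function(m, shape) {
  resnet_trunk_complexity(m, shape)
}
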