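# SEAFEC fusion: Y = alpha * SCARF(X) + (1 - alpha) * MEFE(X), with alpha
# the sigmoid of a single learnable logit per operator instance,
# initialized to the inverse sigmoid of the configured alpha_init.

#' Build a SEAFEC layer
#'
#' @param spec a [seafec_spec()], or `in_channels` for the shorthand form
#' @param ... when `spec` is numeric, further arguments to [seafec_spec()]
#' @param seed integer seed; the same seed reproduces bit-identical
#'   parameters in both branches
#' @return a module with children `scarf` and `mefe` and a learnable
#'   `alpha_logit`
#' @export
seafec_layer <- function(spec, ..., seed = 42) {
  if (!inherits(spec, "seafec_spec")) spec <- seafec_spec(spec, ...)
  m <- new_module("nn_seafec", spec = spec)
  m$children <- list(scarf = scarf_layer(spec$scarf, seed = seed),
                     mefe = mefe_layer(spec$mefe, seed = seed + 1))
  add_param(m, "alpha_logit", logit(spec$alpha_init))
  m
}

#' Current fusion weight of a SEAFEC layer
#' @param layer a module from [seafec_layer()]
#' @return `sigmoid(alpha_logit)`, strictly inside (0, 1)
#' @export
seafec_alpha <- function(layer) {
  stopifnot(inherits(layer, "nn_seafec"))
  as.numeric(sigmoid(layer$params$alpha_logit))
}

#' @export
nn_forward.nn_seafec <- function(m, x, ...) {
  ys <- nn_forward(m$children$scarf, x)
  ym <- nn_forward(m$children$mefe, x)
  if (!identical(dim(ys), dim(ym))) {
    stop("branch output shapes disagree: scarf ",
         paste(dim(ys), collapse = "x"), " vs mefe ",
         paste(dim(ym), collapse = "x"))
  }
  a <- as.numeric(sigmoid(m$params$alpha_logit))
  m$cache <- list(ys = ys, ym = ym, a = a)
  a * ys + (1 - a) * ym
}

#' @export
nn_backward.nn_seafec <- function(m, gy, ...) {
  cc <- m$cache
  a <- cc$a
  m$grads$alpha_logit <- m$grads$alpha_logit +
    sum(gy * (cc$ys - cc$ym)) * a * (1 - a)
  nn_backward(m$children$scarf, a * gy) +
    nn_backward(m$children$mefe, (1 - a) * gy)
}

#' @export
nn_complexity.nn_seafec <- function(m, shape) {
  s <- nn_complexity(m$children$scarf, shape)
  e <- nn_complexity(m$children$mefe, shape)
  list(macs = s$macs + e$macs, shape = s$shape)
}

#' Forward pass of the fused dual-branch operator
#'
#' @param x feature map, `dim = c(B, C, H, W)`
#' @param layer a module from [seafec_layer()], or a [seafec_spec()]
#' @param seed seed used when `layer` is a spec
#' @return feature map with the shape of either branch output
#' @export
seafec_forward <- function(x, layer, seed = 42) {
  if (inherits(layer, "seafec_spec")) layer <- seafec_layer(layer, seed = seed)
  nn_forward(layer, x)
}
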