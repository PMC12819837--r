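# Structural complexity accounting. Parameter counts enumerate learnable
# scalars (convolution/linear weights and biases, normalization affine
# pairs, fusion logits). Multiply-accumulate counts are computed by shape
# propagation over convolution and linear layers only (one MAC per
# multiply-add; normalization, pooling and activations excluded) -- the
# convention under which the standard 1000-class ResNet-18 measures 11.69M
# parameters and 1.81G MACs on a 224x224 input.

#' Count learnable parameters of a model
#' @param model a module
#' @return integer-valued count of learnable scalars
#' @export
count_parameters <- function(model) {
  ps <- nn_parameters(model)
  s <- 0
  for (p in ps) s <- s + length(p$module$params[[p$name]])
  s
}

#' Count multiply-accumulate operations for an input shape
#'
#' @param model a module
#' @param input_shape `c(C, H, W)` or `c(B, C, H, W)` for spatial models
#'   (a batch of one is assumed when omitted); `n_features` or
#'   `c(B, n_features)` for a bare linear layer
#' @return MAC count as a double (counts exceed 2^31)
#' @export
count_macs <- function(model, input_shape = c(3, 224, 224)) {
  if (length(input_shape) %in% c(1, 3)) input_shape <- c(1, input_shape)
  stopifnot(length(input_shape) %in% c(2, 4))
  nn_complexity(model, as.numeric(input_shape))$macs
}

#' Parameter/MAC report with deltas against a baseline
#'
#' @param model the model under report
#' @param baseline optional baseline model; when given, signed percentage
#'   deltas `100 * (variant - baseline) / baseline` are included
#' @param input_shape input shape for the MAC count
#' @return an object of class `complexity_report` with fields `params`,
#'   `macs`, and (with a baseline) `delta_params_pct`, `delta_macs_pct`
#' @export
complexity_report <- function(model, baseline = NULL,
                              input_shape = c(3, 224, 224)) {
  r <- list(params = count_parameters(model),
            macs = count_macs(model, input_shape),
            input_shape = input_shape,
            convention = "MACs over conv/linear layers; one per multiply-add")
  if (!is.null(baseline)) {
    bp <- count_parameters(baseline)
    bm <- count_macs(baseline, input_shape)
    r$baseline_params <- bp
    r$baseline_macs <- bm
    r$delta_params_pct <- 100 * (r$params - bp) / bp
    r$delta_macs_pct <- 100 * (r$macs - bm) / bm
  }
  structure(r, class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("Complexity report (", x$convention, ")\n", sep = "")
  cat(sprintf("  params: %s (%.2fM)\n",
              format(x$params, big.mark = ","), x$params / 1e6))
  cat(sprintf("  MACs @ %s: %s (%.2fG)\n",
              paste(x$input_shape, collapse = "x"),
              format(x$macs, big.mark = ",", scientific = FALSE),
              x$macs / 1e9))
  if (!is.null(x$delta_params_pct)) {
    cat(sprintf("  vs baseline: params %+0.1f%%, MACs %+0.1f%%\n",
                x$delta_params_pct, x$delta_macs_pct))
  }
  invisible(x)
}
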