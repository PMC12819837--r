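# Operator configuration records. Specs are plain validated lists; layers
# are built from specs so that a configuration can be serialized to YAML,
# shared, and rebuilt bit-identically under the same seed.

#' SCARF branch configuration
#'
#' @param in_channels,out_channels channel counts of the replaced convolution
#' @param kernel_size odd receptive-field size `k` (>= 3)
#' @param stride output subsampling factor
#' @param attention_groups group count of the 1x1 attention-expansion
#'   convolution; must divide `in_channels` (default: depthwise)
#' @param activation nonlinearity after batch normalization in the feature
#'   path; `"relu"` (default) or `"identity"`
#' @param eca_gamma,eca_b constants of the adaptive channel-attention kernel
#'   size rule
#' @return an object of class `scarf_spec`
#' @export
scarf_spec <- function(in_channels, out_channels = in_channels,
                       kernel_size = 3, stride = 1,
                       attention_groups = in_channels,
                       activation = c("relu", "identity"),
                       eca_gamma = 2, eca_b = 1) {
  activation <- match.arg(activation)
  if (kernel_size %% 2 != 1 || kernel_size < 3) {
    stop("kernel_size must be odd and >= 3")
  }
  if (in_channels %% attention_groups != 0) {
    stop("attention_groups must divide in_channels")
  }
  if (stride < 1) stop("stride must be >= 1")
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 kernel_size = kernel_size, stride = stride,
                 attention_groups = attention_groups,
                 activation = activation,
                 eca_gamma = eca_gamma, eca_b = eca_b),
            class = "scarf_spec")
}

#' MEFE branch configuration
#'
#' @param in_channels,out_channels channel counts of the replaced convolution
#' @param pool_sizes target output sizes of the adaptive pooling pyramid
#'   (one branch per entry); entries larger than the input are clamped at
#'   forward time
#' @param reduction_ratio channel shrink factor of the per-branch 1x1
#'   reduction; must divide `in_channels`
#' @param refinement_depth number of depthwise-separable layers in the
#'   bias-free edge-refinement stack
#' @param stride output subsampling factor, realized by an output average
#'   pool
#' @return an object of class `mefe_spec`
#' @export
mefe_spec <- function(in_channels, out_channels = in_channels,
                      pool_sizes = c(20, 18, 8), reduction_ratio = 4,
                      refinement_depth = 2, stride = 1) {
  if (length(pool_sizes) < 1 || any(pool_sizes < 1)) {
    stop("pool_sizes must be a non-empty vector of sizes >= 1")
  }
  if (reduction_ratio < 1) stop("reduction_ratio must be >= 1")
  if (in_channels %% reduction_ratio != 0) {
    stop("in_channels must be divisible by reduction_ratio")
  }
  if (stride < 1) stop("stride must be >= 1")
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 pool_sizes = as.integer(pool_sizes),
                 reduction_ratio = reduction_ratio,
                 refinement_depth = refinement_depth, stride = stride),
            class = "mefe_spec")
}

#' Full dual-branch operator configuration
#'
#' Task-level defaults for `pool_sizes` and `alpha_init`: classification
#' uses pools (20, 18, 8) and alpha 0.6; detection (18, 14, 8) and 0.5;
#' segmentation (20, 15, 8) and 0.4.
#'
#' @param in_channels,out_channels channel counts
#' @param kernel_size SCARF receptive-field size
#' @param stride shared stride of both branches
#' @param pool_sizes MEFE pooling pyramid sizes
#' @param reduction_ratio MEFE channel reduction
#' @param alpha_init initial value in (0, 1) of the sigmoid fusion weight
#' @param attention_groups,activation,eca_gamma,eca_b passed to
#'   [scarf_spec()]
#' @param refinement_depth passed to [mefe_spec()]
#' @return an object of class `seafec_spec` with `$scarf`, `$mefe` and
#'   `$alpha_init` fields
#' @export
seafec_spec <- function(in_channels, out_channels = in_channels,
                        kernel_size = 3, stride = 1,
                        pool_sizes = c(20, 18, 8), reduction_ratio = 4,
                        alpha_init = 0.6,
                        attention_groups = in_channels,
                        activation = "relu",
                        eca_gamma = 2, eca_b = 1,
                        refinement_depth = 2) {
  if (alpha_init <= 0 || alpha_init >= 1) {
    stop("alpha_init must lie strictly in (0, 1)")
  }
  sc <- scarf_spec(in_channels, out_channels, kernel_size, stride,
                   attention_groups, activation, eca_gamma, eca_b)
  me <- mefe_spec(in_channels, out_channels, pool_sizes, reduction_ratio,
                  refinement_depth, stride)
  structure(list(scarf = sc, mefe = me, alpha_init = alpha_init),
            class = "seafec_spec")
}

#' Write a SEAFEC configuration to YAML
#' @param spec a `seafec_spec`
#' @param path file path; when `NULL` the YAML text is returned
#' @return `path` invisibly, or the YAML string when `path` is `NULL`
#' @export
seafec_spec_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "seafec_spec"))
  x <- list(in_channels = spec$scarf$in_channels,
            out_channels = spec$scarf$out_channels,
            kernel_size = spec$scarf$kernel_size,
            stride = spec$scarf$stride,
            pool_sizes = as.integer(spec$mefe$pool_sizes),
            reduction_ratio = spec$mefe$reduction_ratio,
            alpha_init = spec$alpha_init,
            attention_groups = spec$scarf$attention_groups,
            activation = spec$scarf$activation,
            eca_gamma = spec$scarf$eca_gamma,
            eca_b = spec$scarf$eca_b,
            refinement_depth = spec$mefe$refinement_depth)
  txt <- yaml::as.yaml(x)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a SEAFEC configuration from YAML
#' @param path file path (or a YAML string containing a newline)
#' @return a `seafec_spec`
#' @export
seafec_spec_from_yaml <- function(path) {
  x <- if (grepl("\n", path)) yaml::yaml.load(path) else yaml::read_yaml(path)
  seafec_spec(in_channels = x$in_channels,
              out_channels = x$out_channels %||% x$in_channels,
              kernel_size = x$kernel_size %||% 3,
              stride = x$stride %||% 1,
              pool_sizes = unlist(x$pool_sizes) %||% c(20, 18, 8),
              reduction_ratio = x$reduction_ratio %||% 4,
              alpha_init = x$alpha_init %||% 0.6,
              attention_groups = x$attention_groups %||% x$in_channels,
              activation = x$activation %||% "relu",
              eca_gamma = x$eca_gamma %||% 2,
              eca_b = x$eca_b %||% 1,
              refinement_depth = x$refinement_depth %||% 2)
}
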