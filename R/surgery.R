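# Backbone surgery: replace selected 2-D convolutions of a built model with
# SCARF / MEFE / SEAFEC operators that preserve the in/out channels and the
# stride of the replaced layer.

#' Describe a backbone surgery
#'
#' @param target_model `"resnet18"` or `"deeplabv3_resnet50"`
#' @param variant `"baseline"`, `"scarf"`, `"mefe"` or `"seafec"`
#' @param num_classes classifier width / per-pixel class count
#' @param alpha_init initial fusion weight of SEAFEC instances
#' @param pool_sizes MEFE pooling pyramid
#' @param reduction_ratio MEFE channel reduction
#' @param kernel_size SCARF receptive-field size
#' @param seed seed used to initialize the model and replacement modules
#' @return an object of class `surgery_plan`
#' @export
surgery_plan <- function(target_model = c("resnet18", "deeplabv3_resnet50"),
                         variant = c("baseline", "scarf", "mefe", "seafec"),
                         num_classes = NULL,
                         alpha_init = NULL, pool_sizes = NULL,
                         reduction_ratio = 4, kernel_size = 3, seed = 42) {
  target_model <- match.arg(target_model)
  variant <- match.arg(variant)
  if (is.null(num_classes)) {
    num_classes <- if (target_model == "resnet18") 1000L else 21L
  }
  if (is.null(alpha_init)) {
    alpha_init <- if (target_model == "resnet18") 0.6 else 0.4
  }
  if (is.null(pool_sizes)) {
    pool_sizes <- if (target_model == "resnet18") c(20, 18, 8)
                  else c(20, 15, 8)
  }
  structure(list(target_model = target_model, variant = variant,
                 num_classes = num_classes, alpha_init = alpha_init,
                 pool_sizes = pool_sizes, reduction_ratio = reduction_ratio,
                 kernel_size = kernel_size, seed = seed),
            class = "surgery_plan")
}

walk_modules <- function(m, fn, prefix = "") {
  for (nm in names(m$children)) {
    path <- paste0(prefix, nm)
    fn(path, m, nm, m$children[[nm]])
    walk_modules(m$children[[nm]], fn, paste0(path, "."))
  }
}

#' Replace matched convolutions in a model
#'
#' Walks the module tree; every module whose path matches `selector` is
#' replaced by `factory(in_channels, out_channels, stride)`. A match on a
#' module that is not a plain 2-D convolution is an error, so re-applying a
#' surgery fails on the already-replaced layers. The replacement count is
#' stored in `model$surgery_count`.
#'
#' @param model a built model (modified in place and returned)
#' @param selector a regular expression on dot-separated module paths, or a
#'   `function(path, module)` returning `TRUE` for layers to replace
#' @param factory `function(in_channels, out_channels, stride)` returning a
#'   replacement module
#' @return the model, invisibly
#' @export
replace_convs <- function(model, selector, factory) {
  sel <- if (is.character(selector)) {
    function(path, mod) grepl(selector, path)
  } else {
    selector
  }
  count <- 0L
  walk_modules(model, function(path, parent, name, mod) {
    if (!sel(path, mod)) return(invisible())
    if (!inherits(mod, "nn_conv2d")) {
      stop("surgery selector matched '", path,
           "', which is not a plain 2-D convolution (already replaced?)")
    }
    rep <- factory(mod$in_channels, mod$out_channels, mod$stride)
    if (!inherits(rep, "nn_module")) stop("factory must return a module")
    parent$children[[name]] <- rep
    count <<- count + 1L
  })
  model$surgery_count <- count
  invisible(model)
}

variant_factory <- function(plan) {
  i <- 0L
  function(cin, cout, stride) {
    i <<- i + 1L
    s <- plan$seed + 1000L + i * 17L
    switch(plan$variant,
      scarf = scarf_layer(scarf_spec(cin, cout, plan$kernel_size, stride),
                          seed = s),
      mefe = mefe_layer(mefe_spec(cin, cout, plan$pool_sizes,
                                  plan$reduction_ratio, stride = stride),
                        seed = s),
      seafec = seafec_layer(seafec_spec(cin, cout, plan$kernel_size, stride,
                                        plan$pool_sizes,
                                        plan$reduction_ratio,
                                        plan$alpha_init),
                            seed = s),
      stop("unknown variant: ", plan$variant))
  }
}

#' Build a (possibly modified) ResNet-18 classifier
#'
#' For non-baseline variants the first 3x3 convolution of each of the eight
#' residual blocks is replaced by the selected operator with matching
#' channels and stride (eight replacements in total).
#'
#' @param plan a [surgery_plan()] with `target_model = "resnet18"`, or a
#'   variant string for the shorthand form
#' @param ... when `plan` is a string, further arguments to [surgery_plan()]
#' @return the model; `model$surgery_count` holds the replacement count
#'   (0 for the baseline)
#' @export
build_seafec_resnet18 <- function(plan = "baseline", ...) {
  if (!inherits(plan, "surgery_plan")) {
    plan <- surgery_plan("resnet18", variant = plan, ...)
  }
  stopifnot(plan$target_model == "resnet18")
  model <- resnet18(plan$num_classes, seed = plan$seed)
  model$surgery_count <- 0L
  if (plan$variant != "baseline") {
    replace_convs(model, "^layer[1-4]\\.[01]\\.conv1$",
                  variant_factory(plan))
  }
  model$plan <- plan
  model
}

#' Build a (possibly modified) DeepLabV3-ResNet50 segmentation network
#'
#' For non-baseline variants the 3x3 convolutions of the final backbone
#' stage's bottleneck blocks are replaced by the selected operator (three
#' replacements).
#'
#' @param plan a [surgery_plan()] with `target_model =
#'   "deeplabv3_resnet50"`, or a variant string for the shorthand form
#' @param ... when `plan` is a string, further arguments to [surgery_plan()]
#' @return the model; `model$surgery_count` holds the replacement count
#' @export
build_seafec_deeplabv3 <- function(plan = "baseline", ...) {
  if (!inherits(plan, "surgery_plan")) {
    plan <- surgery_plan("deeplabv3_resnet50", variant = plan, ...)
  }
  stopifnot(plan$target_model == "deeplabv3_resnet50")
  model <- deeplabv3_resnet50(plan$num_classes, seed = plan$seed)
  model$surgery_count <- 0L
  if (plan$variant != "baseline") {
    replace_convs(model, "^backbone\\.layer4\\.[0-2]\\.conv2$",
                  variant_factory(plan))
  }
  model$plan <- plan
  model
}

#' Save model parameters to a checkpoint file
#' @param model a model
#' @param path destination file
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(state_dict(model), path)
  invisible(path)
}

#' Load model parameters from a checkpoint file
#' @param model a model with matching architecture
#' @param path checkpoint produced by [save_checkpoint()]
#' @export
load_checkpoint <- function(model, path) {
  load_state_dict(model, readRDS(path))
  invisible(model)
}
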