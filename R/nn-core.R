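#' @useDynLib seafec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- module framework -------------------------------------------------------
#
# Modules are environments so parameters can be updated in place during
# training. Each module holds:
#   $params   named list of numeric arrays (learnable)
#   $grads    named list, same shapes, accumulated by nn_backward()
#   $buffers  named list of non-learnable state (running stats, ...)
#   $children named list of sub-modules
#   $training logical flag
#   $cache    forward-pass intermediates consumed by nn_backward()

new_module <- function(class, ...) {
  m <- new.env(parent = emptyenv())
  m$params <- list()
  m$grads <- list()
  m$buffers <- list()
  m$children <- list()
  m$training <- TRUE
  m$cache <- NULL
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  class(m) <- c(class, "nn_module")
  m
}

add_param <- function(m, name, value) {
  m$params[[name]] <- value
  m$grads[[name]] <- array(0, dim = dim(value) %||% length(value))
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a module forward
#'
#' Dispatches on the module class; stores whatever the backward pass needs
#' in the module's cache.
#'
#' @param m a module created by one of the layer constructors
#' @param x input array, `dim = c(B, C, H, W)` for spatial layers
#' @param ... passed to methods
#' @return the layer output
#' @export
nn_forward <- function(m, x, ...) UseMethod("nn_forward")

#' Backpropagate through a module
#'
#' Accumulates parameter gradients into the module and returns the gradient
#' with respect to the module input. Must follow a [nn_forward()] call on
#' the same module.
#'
#' @param m a module
#' @param gy gradient of the loss w.r.t. the module output
#' @param ... passed to methods
#' @return gradient w.r.t. the module input
#' @export
nn_backward <- function(m, gy, ...) UseMethod("nn_backward")

#' List learnable parameters of a module tree
#'
#' @param m a module
#' @param prefix path prefix used in the returned names
#' @return a named list; each element is `list(module, name)` locating one
#'   learnable array, names are dot-separated paths
#' @export
nn_parameters <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) {
    out[[paste0(prefix, nm)]] <- list(module = m, name = nm)
  }
  for (nm in names(m$children)) {
    out <- c(out, nn_parameters(m$children[[nm]],
                                prefix = paste0(prefix, nm, ".")))
  }
  out
}

#' Zero all accumulated gradients in a module tree
#' @param m a module
#' @export
nn_zero_grad <- function(m) {
  for (nm in names(m$grads)) m$grads[[nm]][] <- 0
  for (ch in m$children) nn_zero_grad(ch)
  invisible(m)
}

#' Switch a module tree between training and evaluation mode
#' @param m a module
#' @param training logical; affects batch-normalization statistics
#' @export
nn_set_training <- function(m, training = TRUE) {
  m$training <- training
  for (ch in m$children) nn_set_training(ch, training)
  invisible(m)
}

#' Extract all parameters and buffers as a flat named list
#'
#' The returned list round-trips through `saveRDS()`/`readRDS()` and
#' [load_state_dict()], the package's checkpoint container.
#'
#' @param m a module
#' @param prefix internal path prefix
#' @return named list of numeric arrays
#' @export
state_dict <- function(m, prefix = "") {
  out <- list()
  for (nm in names(m$params)) out[[paste0(prefix, nm)]] <- m$params[[nm]]
  for (nm in names(m$buffers)) {
    out[[paste0(prefix, "buffers.", nm)]] <- m$buffers[[nm]]
  }
  for (nm in names(m$children)) {
    out <- c(out, state_dict(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

#' Load a flat state list produced by [state_dict()]
#' @param m a module
#' @param sd named list as returned by [state_dict()]
#' @export
load_state_dict <- function(m, sd, prefix = "") {
  for (nm in names(m$params)) {
    key <- paste0(prefix, nm)
    if (!key %in% names(sd)) stop("missing parameter in state dict: ", key)
    stopifnot(length(sd[[key]]) == length(m$params[[nm]]))
    m$params[[nm]][] <- sd[[key]]
  }
  for (nm in names(m$buffers)) {
    key <- paste0(prefix, "buffers.", nm)
    if (key %in% names(sd)) m$buffers[[nm]][] <- sd[[key]]
  }
  for (nm in names(m$children)) {
    load_state_dict(m$children[[nm]], sd, paste0(prefix, nm, "."))
  }
  invisible(m)
}

# Complexity accounting: every module class reports its multiply-accumulate
# count for a given input shape by pure shape propagation (no data touched).
# Returns list(macs = <double>, shape = <output shape>).
nn_complexity <- function(m, shape) UseMethod("nn_complexity")

#' @export
print.nn_module <- function(x, ...) {
  cat("<", class(x)[1], "> params: ",
      format(count_parameters(x), big.mark = ","), "\n", sep = "")
  invisible(x)
}

# ---- small numeric helpers --------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Inverse sigmoid
#' @param p probability in (0, 1)
#' @return the logit `log(p / (1 - p))`
#' @export
logit <- function(p) {
  stopifnot(all(p > 0), all(p < 1))
  log(p / (1 - p))
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_feature_map <- function(x, what = "input") {
  if (!is.numeric(x) || length(dim(x)) != 4) {
    stop(what, " must be a rank-4 numeric array (B, C, H, W)")
  }
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}
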