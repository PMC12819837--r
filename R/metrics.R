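# Task metric suites: one-vs-rest classification rates with macro
# averaging, pixel-pooled IoU for segmentation, and COCO-style mean average
# precision over IoU thresholds for detection.

#' Classification metrics from label vectors
#'
#' Per-class one-vs-rest precision, recall, specificity and F1 are macro-
#' averaged; accuracy is the overall fraction correct. A class absent from
#' both truth and prediction has its undefined rates reported as 0 and is
#' listed in `$flags$undefined_classes`.
#'
#' @param truth,pred integer label vectors (0-based, values `< n_classes`)
#' @param n_classes number of classes
#' @return a `metrics_report` for task `"cls"` with `$metrics` (accuracy,
#'   precision, recall, specificity, f1), `$per_class`, `$support`
#' @export
classification_metrics <- function(truth, pred, n_classes) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (any(truth < 0 | truth >= n_classes) ||
      any(pred < 0 | pred >= n_classes)) {
    stop("labels must lie in [0, n_classes)")
  }
  n <- length(truth)
  per <- data.frame(class = 0:(n_classes - 1), precision = 0, recall = 0,
                    specificity = 0, f1 = 0, support = 0)
  undef <- integer(0)
  for (k in 0:(n_classes - 1)) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    tn <- n - tp - fp - fn
    i <- k + 1
    per$support[i] <- tp + fn
    if (tp + fn == 0 && tp + fp == 0) undef <- c(undef, k)
    per$precision[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    per$recall[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    per$specificity[i] <- if (tn + fp > 0) tn / (tn + fp) else 0
    per$f1[i] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  }
  structure(list(task = "cls",
                 metrics = c(accuracy = mean(truth == pred),
                             precision = mean(per$precision),
                             recall = mean(per$recall),
                             specificity = mean(per$specificity),
                             f1 = mean(per$f1)),
                 per_class = per,
                 support = n,
                 flags = list(undefined_classes = undef)),
            class = "metrics_report")
}

#' Segmentation metrics from mask stacks
#'
#' Intersections and unions are pooled over all pixels of all images
#' before forming per-class IoU; mIoU is their unweighted mean. Mean
#' precision and recall are averaged over classes.
#'
#' @param truth,pred lists of integer matrices (or single matrices) with
#'   values in `[0, n_classes)`
#' @param n_classes number of classes
#' @return a `metrics_report` for task `"seg"` with per-class IoU, `miou`,
#'   `mean_precision`, `mean_recall`
#' @export
segmentation_metrics <- function(truth, pred, n_classes) {
  if (is.matrix(truth)) truth <- list(truth)
  if (is.matrix(pred)) pred <- list(pred)
  stopifnot(length(truth) == length(pred))
  inter <- un <- tpx <- ppx <- tppx <- numeric(n_classes)
  for (i in seq_along(truth)) {
    tt <- as.integer(truth[[i]]); pp <- as.integer(pred[[i]])
    if (length(tt) != length(pp)) stop("mask shapes differ")
    if (any(tt < 0 | tt >= n_classes | pp < 0 | pp >= n_classes)) {
      stop("mask values must lie in [0, n_classes)")
    }
    for (k in 0:(n_classes - 1)) {
      a <- tt == k; b <- pp == k
      inter[k + 1] <- inter[k + 1] + sum(a & b)
      un[k + 1] <- un[k + 1] + sum(a | b)
      tpx[k + 1] <- tpx[k + 1] + sum(a)
      ppx[k + 1] <- ppx[k + 1] + sum(b)
      tppx[k + 1] <- tppx[k + 1] + sum(a & b)
    }
  }
  iou <- ifelse(un > 0, inter / un, 0)
  prec <- ifelse(ppx > 0, tppx / ppx, 0)
  rec <- ifelse(tpx > 0, tppx / tpx, 0)
  structure(list(task = "seg",
                 metrics = c(miou = mean(iou),
                             mean_precision = mean(prec),
                             mean_recall = mean(rec)),
                 per_class = data.frame(class = 0:(n_classes - 1),
                                        iou = iou, precision = prec,
                                        recall = rec, support = tpx),
                 support = sum(tpx),
                 flags = list(undefined_classes =
                                which(un == 0 & ppx == 0) - 1L)),
            class = "metrics_report")
}

#' Intersection-over-union of two half-open boxes
#' @param a,b numeric vectors `(x_min, y_min, x_max, y_max)`
#' @return scalar IoU in \[0, 1\]
#' @export
box_iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) return(0)
  inter / ua
}

ap_from_ranked <- function(is_tp, n_truth) {
  if (n_truth == 0) return(NA_real_)
  if (length(is_tp) == 0) return(0)
  tp <- cumsum(is_tp)
  fp <- cumsum(!is_tp)
  recall <- tp / n_truth
  precision <- tp / (tp + fp)
  # all-point interpolation: precision envelope from the right
  mrec <- c(0, recall, 1)
  mpre <- c(0, precision, 0)
  for (i in (length(mpre) - 1):1) mpre[i] <- max(mpre[i], mpre[i + 1])
  idx <- which(mrec[-1] != mrec[-length(mrec)])
  sum((mrec[idx + 1] - mrec[idx]) * mpre[idx + 1])
}

#' Mean average precision over IoU thresholds
#'
#' Predictions are matched greedily in score order (ties broken by input
#' order): each prediction claims the unmatched ground-truth box of its
#' class and image with the highest IoU at or above the threshold. AP is
#' the area under the all-point interpolated precision-recall curve,
#' averaged over classes present in the ground truth; `map50_95` averages
#' thresholds 0.50 to 0.95 in steps of 0.05.
#'
#' @param truth list (one element per image) of box data.frames with
#'   columns x_min, y_min, x_max, y_max, class
#' @param pred like `truth` but with an additional `score` column in
#'   \[0, 1\]
#' @param iou_thresholds IoU thresholds to evaluate
#' @return a `metrics_report` for task `"det"` with `map50`, `map50_95`
#'   and `$ap` (per class x threshold)
#' @export
detection_map <- function(truth, pred,
                          iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(length(truth) == length(pred))
  norm_df <- function(df, score) {
    if (is.null(df) || nrow(df) == 0) {
      df <- data.frame(x_min = numeric(0), y_min = numeric(0),
                       x_max = numeric(0), y_max = numeric(0),
                       class = integer(0))
      if (score) df$score <- numeric(0)
    }
    if (any(df$x_max < df$x_min) || any(df$y_max < df$y_min)) {
      stop("invalid box extents")
    }
    if (score && (any(df$score < 0) || any(df$score > 1))) {
      stop("scores must lie in [0, 1]")
    }
    df
  }
  truth <- lapply(truth, norm_df, score = FALSE)
  pred <- lapply(pred, norm_df, score = TRUE)
  classes <- sort(unique(unlist(lapply(truth, function(d) d$class))))
  if (length(classes) == 0) stop("no ground-truth boxes")
  ap <- matrix(NA_real_, length(classes), length(iou_thresholds),
               dimnames = list(as.character(classes),
                               sprintf("%.2f", iou_thresholds)))
  for (ci in seq_along(classes)) {
    k <- classes[ci]
    # flatten predictions of class k, keeping image ids; stable order
    pim <- integer(0); pbox <- list(); pscore <- numeric(0)
    for (im in seq_along(pred)) {
      d <- pred[[im]]
      sel <- which(d$class == k)
      for (j in sel) {
        pim <- c(pim, im)
        pbox[[length(pbox) + 1]] <- as.numeric(d[j, c("x_min", "y_min",
                                                      "x_max", "y_max")])
        pscore <- c(pscore, d$score[j])
      }
    }
    ord <- order(-pscore)  # stable: equal scores keep input order
    n_truth <- sum(vapply(truth, function(d) sum(d$class == k), numeric(1)))
    for (ti in seq_along(iou_thresholds)) {
      thr <- iou_thresholds[ti]
      used <- lapply(truth, function(d) rep(FALSE, nrow(d)))
      is_tp <- logical(length(ord))
      for (oi in seq_along(ord)) {
        j <- ord[oi]
        d <- truth[[pim[j]]]
        cand <- which(d$class == k & !used[[pim[j]]])
        if (length(cand)) {
          ious <- vapply(cand, function(q)
            box_iou(pbox[[j]], as.numeric(d[q, c("x_min", "y_min",
                                                 "x_max", "y_max")])),
            numeric(1))
          best <- which.max(ious)
          if (ious[best] >= thr) {
            is_tp[oi] <- TRUE
            used[[pim[j]]][cand[best]] <- TRUE
          }
        }
      }
      ap[ci, ti] <- ap_from_ranked(is_tp, n_truth)
    }
  }
  map_at <- function(ti) mean(ap[, ti], na.rm = TRUE)
  structure(list(task = "det",
                 metrics = c(map50 = map_at(1),
                             map50_95 = mean(apply(ap, 2, mean,
                                                   na.rm = TRUE))),
                 ap = ap,
                 support = sum(vapply(truth, nrow, numeric(1))),
                 flags = list()),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics report [", x$task, "], support ", x$support, "\n", sep = "")
  print(round(x$metrics, 4))
  invisible(x)
}
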