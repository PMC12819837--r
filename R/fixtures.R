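# Seeded synthetic imagery emulating the visual regimes of agricultural
# disease/weed datasets: dispersed near-circular lesion spots vs. elongated
# strip lesions (classification), intertwined crop-weed foliage over soil
# (segmentation), and dense-small vs. sparse-large lesion targets
# (detection). Images are H x W x 3 arrays of integers in [0, 255]; masks
# use {0 background, 1 crop, 2 weed}; boxes are 0-based half-open
# (x_min, y_min, x_max, y_max).

px_grid <- function(size) {
  list(r = matrix(rep(seq_len(size), size), size, size),
       c = matrix(rep(seq_len(size), each = size), size, size))
}

disc_mask <- function(size, cy, cx, radius, g = px_grid(size)) {
  (g$r - cy)^2 + (g$c - cx)^2 <= radius^2
}

# thick line segment: points within `halfwidth` of the segment (y1,x1)-(y2,x2)
streak_mask <- function(size, y1, x1, y2, x2, halfwidth, g = px_grid(size)) {
  vy <- y2 - y1; vx <- x2 - x1
  len2 <- vy^2 + vx^2
  t <- ((g$r - y1) * vy + (g$c - x1) * vx) / len2
  t <- pmin(pmax(t, 0), 1)
  dy <- g$r - (y1 + t * vy); dx <- g$c - (x1 + t * vx)
  dy^2 + dx^2 <= halfwidth^2
}

smooth_field <- function(size, scale = 8, amp = 1) {
  k <- max(2, ceiling(size / scale))
  coarse <- matrix(stats::rnorm(k * k), k, k)
  ri <- pmin(k, pmax(1, ceiling(seq_len(size) / size * k)))
  amp * coarse[ri, ri]
}

gauss_blur_mat <- function(m, sigma) {
  r <- max(1L, ceiling(2.5 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  pad_filter <- function(v) stats::filter(v, w, sides = 2)
  blur1 <- function(mm) {
    out <- apply(mm, 2, function(col) {
      ext <- c(rep(col[1], r), col, rep(col[length(col)], r))
      as.numeric(pad_filter(ext))[(r + 1):(r + length(col))]
    })
    matrix(out, nrow(mm), ncol(mm))
  }
  t(blur1(t(blur1(m))))
}

compose_rgb <- function(size, base, field_amp = 10, noise_sd = 5) {
  img <- array(0, dim = c(size, size, 3))
  f <- smooth_field(size, amp = field_amp)
  for (ch in 1:3) {
    img[, , ch] <- base[ch] + f + stats::rnorm(size^2, sd = noise_sd)
  }
  img
}

paint <- function(img, mask, color, alpha = 1) {
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[mask > 0] <- (1 - alpha * mask[mask > 0]) * pl[mask > 0] +
      alpha * mask[mask > 0] * color[ch]
    img[, , ch] <- pl
  }
  img
}

finalize_img <- function(img) {
  storage.mode(img) <- "double"
  array(as.integer(pmin(255, pmax(0, round(img)))), dim = dim(img))
}

new_sample <- function(image, seed, label = NULL, mask = NULL,
                       boxes = NULL, class_name = NULL) {
  structure(list(image = image, label = label, mask = mask, boxes = boxes,
                 class_name = class_name, seed = seed),
            class = "synthetic_sample")
}

LEAF_GREEN <- c(70, 150, 75)
LESION_BROWN <- c(150, 95, 45)
SOIL_BROWN <- c(105, 82, 58)
CROP_GREEN <- c(45, 165, 70)
WEED_GREEN <- c(120, 175, 45)

#' Generate a balanced spot-vs-strip lesion classification fixture
#'
#' "spot" images carry dispersed near-circular lesions on a leaf-like
#' background; "strip" images carry elongated oriented streaks. Lesions are
#' warm-toned (red channel above green), the background the reverse, so
#' lesion pixels are recoverable by thresholding.
#'
#' @param n_per_class samples per class
#' @param classes character vector, a subset of `c("spot", "strip")`,
#'   at least 2 entries
#' @param image_size square image side, at least 32
#' @param blur_halo render blurred lesion halos (diffuse boundary regime)
#' @param seed integer; sample `i` uses stream `seed + i`, so regeneration
#'   is bit-identical
#' @return list of samples, each with `$image`, `$label` (0-based class
#'   id), `$class_name`, `$seed`
#' @export
gen_classification_fixture <- function(n_per_class, classes = c("spot",
                                       "strip"), image_size = 64,
                                       blur_halo = FALSE, seed = 42) {
  stopifnot(n_per_class >= 1, length(classes) >= 2)
  if (image_size < 32) stop("image_size must be at least 32")
  samples <- list()
  idx <- 0L
  for (ci in seq_along(classes)) {
    for (j in seq_len(n_per_class)) {
      idx <- idx + 1L
      s_seed <- seed + idx
      samples[[idx]] <- with_seed(s_seed, {
        img <- compose_rgb(image_size, LEAF_GREEN)
        g <- px_grid(image_size)
        lesion <- matrix(0, image_size, image_size)
        if (classes[ci] == "spot") {
          nb <- sample(3:6, 1)
          for (b in seq_len(nb)) {
            r <- stats::runif(1, image_size * 0.03, image_size * 0.06)
            cy <- stats::runif(1, r + 1, image_size - r)
            cx <- stats::runif(1, r + 1, image_size - r)
            lesion <- pmax(lesion, disc_mask(image_size, cy, cx, r, g))
          }
        } else {
          nb <- sample(2:4, 1)
          for (b in seq_len(nb)) {
            len <- stats::runif(1, 0.45, 0.75) * image_size
            ang <- stats::runif(1, 0, pi)
            cy <- stats::runif(1, 0.25, 0.75) * image_size
            cx <- stats::runif(1, 0.25, 0.75) * image_size
            hw <- stats::runif(1, 1.5, 2.5)
            lesion <- pmax(lesion,
              streak_mask(image_size, cy - sin(ang) * len / 2,
                          cx - cos(ang) * len / 2,
                          cy + sin(ang) * len / 2,
                          cx + cos(ang) * len / 2, hw, g))
          }
        }
        a <- lesion
        if (blur_halo) a <- pmin(1, gauss_blur_mat(lesion, 1.5) * 1.6)
        img <- paint(img, a, LESION_BROWN)
        new_sample(finalize_img(img), s_seed, label = ci - 1L,
                   class_name = classes[ci])
      })
    }
  }
  samples
}

#' Generate a crop/weed segmentation fixture
#'
#' Draws broad crop leaves over soil, then thin weed blades (which may
#' overlap the crop, yielding intertwined boundaries) until the weed pixel
#' share reaches the requested fraction. Masks use 0 = background,
#' 1 = crop, 2 = weed.
#'
#' @param n number of samples
#' @param image_size square image side
#' @param weed_fraction target weed pixel share, in (0, 0.5)
#' @param seed integer seed (per-sample streams `seed + i`)
#' @return list of samples with `$image` and `$mask`
#' @export
gen_segmentation_fixture <- function(n, image_size = 64,
                                     weed_fraction = 0.1, seed = 42) {
  stopifnot(n >= 1)
  if (weed_fraction <= 0 || weed_fraction >= 0.5) {
    stop("weed_fraction must lie in (0, 0.5)")
  }
  lapply(seq_len(n), function(i) {
    s_seed <- seed + i
    with_seed(s_seed, {
      sz <- image_size
      g <- px_grid(sz)
      mask <- matrix(0L, sz, sz)
      nleaf <- sample(2:4, 1)
      for (b in seq_len(nleaf)) {
        len <- stats::runif(1, 0.5, 0.9) * sz
        ang <- stats::runif(1, 0, pi)
        cy <- stats::runif(1, 0.2, 0.8) * sz
        cx <- stats::runif(1, 0.2, 0.8) * sz
        hw <- stats::runif(1, 0.06, 0.1) * sz
        leaf <- streak_mask(sz, cy - sin(ang) * len / 2,
                            cx - cos(ang) * len / 2,
                            cy + sin(ang) * len / 2,
                            cx + cos(ang) * len / 2, hw, g)
        mask[leaf] <- 1L
      }
      target <- weed_fraction * sz^2
      tries <- 0L
      while (sum(mask == 2L) < target && tries < 400L) {
        tries <- tries + 1L
        len <- stats::runif(1, 0.2, 0.45) * sz
        ang <- stats::runif(1, 0, pi)
        cy <- stats::runif(1, 0.1, 0.9) * sz
        cx <- stats::runif(1, 0.1, 0.9) * sz
        blade <- streak_mask(sz, cy - sin(ang) * len / 2,
                             cx - cos(ang) * len / 2,
                             cy + sin(ang) * len / 2,
                             cx + cos(ang) * len / 2, 1.2, g)
        mask[blade] <- 2L
      }
      img <- compose_rgb(sz, SOIL_BROWN)
      img <- paint(img, (mask == 1L) * 1, CROP_GREEN)
      img <- paint(img, (mask == 2L) * 1, WEED_GREEN)
      new_sample(finalize_img(img), s_seed, mask = mask)
    })
  })
}

#' Generate a lesion detection fixture
#'
#' The dense regime scatters at least 10 small, possibly overlapping boxes
#' per image; the sparse regime places at most 3 large boxes. Boxes are
#' 0-based half-open and always lie inside the image.
#'
#' @param n number of samples
#' @param image_size square image side
#' @param density `"sparse"` or `"dense"`
#' @param seed integer seed (per-sample streams `seed + i`)
#' @return list of samples with `$image` and `$boxes` (data.frame with
#'   columns x_min, y_min, x_max, y_max, class)
#' @export
gen_detection_fixture <- function(n, image_size = 64,
                                  density = c("sparse", "dense"),
                                  seed = 42) {
  density <- match.arg(density)
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    s_seed <- seed + i
    with_seed(s_seed, {
      sz <- image_size
      g <- px_grid(sz)
      img <- compose_rgb(sz, LEAF_GREEN)
      if (density == "dense") {
        nb <- sample(10:16, 1)
        side_lo <- max(3, round(sz * 0.05)); side_hi <- round(sz * 0.12)
      } else {
        nb <- sample(1:3, 1)
        side_lo <- round(sz * 0.25); side_hi <- round(sz * 0.4)
      }
      bx <- matrix(0, nb, 4)
      for (b in seq_len(nb)) {
        w <- sample(side_lo:side_hi, 1)
        h <- sample(side_lo:side_hi, 1)
        x0 <- sample(0:(sz - w), 1)
        y0 <- sample(0:(sz - h), 1)
        bx[b, ] <- c(x0, y0, x0 + w, y0 + h)
        cy <- y0 + h / 2 + 0.5
        cx <- x0 + w / 2 + 0.5
        img <- paint(img, disc_mask(sz, cy, cx, min(w, h) / 2, g) * 1,
                     LESION_BROWN)
      }
      boxes <- data.frame(x_min = bx[, 1], y_min = bx[, 2],
                          x_max = bx[, 3], y_max = bx[, 4],
                          class = 0L)
      new_sample(finalize_img(img), s_seed, boxes = boxes)
    })
  })
}

#' Augmentation policy
#' @param operations subset of rotation, cropping, scaling, blurring, noise
#' @param copies_per_image transformed copies per original (1 doubles the
#'   set)
#' @return an `augmentation_policy`
#' @export
augmentation_policy <- function(operations = c("rotation", "cropping",
                                "scaling", "blurring", "noise"),
                                copies_per_image = 1L) {
  operations <- match.arg(operations, several.ok = TRUE)
  if (length(operations) < 1) stop("at least one operation must be enabled")
  stopifnot(copies_per_image >= 1)
  structure(list(operations = operations,
                 copies_per_image = as.integer(copies_per_image)),
            class = "augmentation_policy")
}

# ---- geometric helpers ------------------------------------------------------

nn_resize_plane <- function(m, oh, ow) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(h, pmax(1, floor((seq_len(oh) - 0.5) * h / oh) + 1))
  ci <- pmin(w, pmax(1, floor((seq_len(ow) - 0.5) * w / ow) + 1))
  m[ri, ci, drop = FALSE]
}

apply_planes <- function(image, fn) {
  out <- NULL
  for (ch in 1:3) {
    p <- fn(image[, , ch])
    if (is.null(out)) out <- array(0, dim = c(nrow(p), ncol(p), 3))
    out[, , ch] <- p
  }
  out
}

rot90_plane <- function(m, kturn) {
  kturn <- kturn %% 4
  for (i in seq_len(kturn)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

rot_any_plane <- function(m, angle_deg, fill) {
  h <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  g <- list(r = matrix(rep(seq_len(h), w), h, w),
            c = matrix(rep(seq_len(w), each = h), h, w))
  # inverse map: source = R(-th) * (target - center) + center
  sy <- cos(th) * (g$r - cy) + sin(th) * (g$c - cx) + cy
  sx <- -sin(th) * (g$r - cy) + cos(th) * (g$c - cx) + cx
  ri <- round(sy); ci <- round(sx)
  ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
  out <- matrix(fill, h, w)
  out[ok] <- m[cbind(ri[ok], ci[ok])]
  out
}

rot_boxes <- function(boxes, angle_deg, size) {
  if (is.null(boxes) || nrow(boxes) == 0) return(boxes)
  th <- -angle_deg * pi / 180  # image-plane rotation of content
  cx <- size / 2; cy <- size / 2
  out <- boxes
  for (i in seq_len(nrow(boxes))) {
    xs <- c(boxes$x_min[i], boxes$x_max[i])
    ys <- c(boxes$y_min[i], boxes$y_max[i])
    corners <- expand.grid(x = xs, y = ys)
    rx <- cos(th) * (corners$x - cx) - sin(th) * (corners$y - cy) + cx
    ry <- sin(th) * (corners$x - cx) + cos(th) * (corners$y - cy) + cy
    out$x_min[i] <- max(0, min(rx)); out$x_max[i] <- min(size, max(rx))
    out$y_min[i] <- max(0, min(ry)); out$y_max[i] <- min(size, max(ry))
  }
  out[out$x_max > out$x_min & out$y_max > out$y_min, , drop = FALSE]
}

augment_one <- function(s, op) {
  sz <- nrow(s$image)
  img <- s$image
  mask <- s$mask
  boxes <- s$boxes
  if (op == "rotation") {
    ang <- sample(c(90, 180, 270, 15, -15), 1)
    if (ang %% 90 == 0) {
      kturn <- ang / 90
      img <- apply_planes(img, function(p) rot90_plane(p, kturn))
      if (!is.null(mask)) mask <- rot90_plane(mask, kturn)
      if (!is.null(boxes)) boxes <- rot_boxes(boxes, ang, sz)
    } else {
      img <- apply_planes(img, function(p) rot_any_plane(p, ang,
                                                         mean(p)))
      if (!is.null(mask)) mask <- rot_any_plane(mask, ang, 0L)
      if (!is.null(boxes)) boxes <- rot_boxes(boxes, ang, sz)
    }
  } else if (op == "cropping") {
    f <- stats::runif(1, 0.8, 1.0)
    cs <- max(8, round(sz * f))
    y0 <- sample(0:(sz - cs), 1); x0 <- sample(0:(sz - cs), 1)
    crop <- function(p) p[(y0 + 1):(y0 + cs), (x0 + 1):(x0 + cs),
                          drop = FALSE]
    img <- apply_planes(img, function(p) nn_resize_plane(crop(p), sz, sz))
    if (!is.null(mask)) mask <- nn_resize_plane(crop(mask), sz, sz)
    if (!is.null(boxes) && nrow(boxes) > 0) {
      sc <- sz / cs
      boxes$x_min <- pmax(0, (boxes$x_min - x0) * sc)
      boxes$x_max <- pmin(sz, (boxes$x_max - x0) * sc)
      boxes$y_min <- pmax(0, (boxes$y_min - y0) * sc)
      boxes$y_max <- pmin(sz, (boxes$y_max - y0) * sc)
      boxes <- boxes[boxes$x_max > boxes$x_min &
                       boxes$y_max > boxes$y_min, , drop = FALSE]
    }
  } else if (op == "scaling") {
    f <- stats::runif(1, 0.8, 1.2)
    ns <- max(8, round(sz * f))
    fit <- function(p, fill) {
      p <- nn_resize_plane(p, ns, ns)
      if (ns >= sz) {
        o <- (ns - sz) %/% 2
        p[(o + 1):(o + sz), (o + 1):(o + sz), drop = FALSE]
      } else {
        o <- (sz - ns) %/% 2
        out <- matrix(fill, sz, sz)
        out[(o + 1):(o + ns), (o + 1):(o + ns)] <- p
        out
      }
    }
    off <- if (ns >= sz) -((ns - sz) %/% 2) else (sz - ns) %/% 2
    img <- apply_planes(img, function(p) fit(p, mean(p)))
    if (!is.null(mask)) mask <- fit(mask, 0L)
    if (!is.null(boxes) && nrow(boxes) > 0) {
      sc <- ns / sz
      for (cl in c("x_min", "x_max", "y_min", "y_max")) {
        boxes[[cl]] <- boxes[[cl]] * sc + off
      }
      boxes$x_min <- pmax(0, boxes$x_min); boxes$y_min <- pmax(0, boxes$y_min)
      boxes$x_max <- pmin(sz, boxes$x_max); boxes$y_max <- pmin(sz, boxes$y_max)
      boxes <- boxes[boxes$x_max > boxes$x_min &
                       boxes$y_max > boxes$y_min, , drop = FALSE]
    }
  } else if (op == "blurring") {
    sg <- stats::runif(1, 0.5, 1.5)
    img <- apply_planes(img, function(p) gauss_blur_mat(p, sg))
  } else if (op == "noise") {
    img <- img + array(stats::rnorm(length(img), sd = 8), dim = dim(img))
  } else {
    stop("unknown operation: ", op)
  }
  s$image <- finalize_img(img)
  s$mask <- mask
  s$boxes <- boxes
  s
}

#' Double a sample set by randomized augmentation
#'
#' Returns the originals followed by `copies_per_image` transformed copies
#' of each (one per original under the default policy, exactly doubling
#' per-class counts). The operation for each copy is drawn uniformly from
#' the policy's enabled set; masks and boxes follow the geometry.
#'
#' @param samples list of samples
#' @param policy an [augmentation_policy()]
#' @param seed integer seed
#' @return augmented sample list
#' @export
augment_double <- function(samples, policy = augmentation_policy(),
                           seed = 42) {
  stopifnot(inherits(policy, "augmentation_policy"))
  if (length(samples) == 0) return(samples)
  copies <- with_seed(seed, {
    out <- list()
    for (i in seq_along(samples)) {
      for (k in seq_len(policy$copies_per_image)) {
        op <- if (length(policy$operations) == 1) policy$operations else
          sample(policy$operations, 1)
        out[[length(out) + 1L]] <- augment_one(samples[[i]], op)
      }
    }
    out
  })
  c(samples, copies)
}

#' Split samples into train/validation/test partitions
#'
#' Ratios are applied per class (when labels exist) with floor rounding;
#' the remainder goes to the training split. The three parts partition the
#' input exactly.
#'
#' @param samples list of samples
#' @param ratios length-3 numeric summing to 1 (train, val, test); the
#'   customary ratios are `c(0.7, 0.2, 0.1)` for classification/detection
#'   and `c(0.6, 0.2, 0.2)` for segmentation
#' @param seed shuffle seed
#' @return list with elements `train`, `val`, `test`
#' @export
split_samples <- function(samples, ratios = c(0.7, 0.2, 0.1), seed = 42) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  labels <- vapply(samples, function(s) s$label %||% 0L, numeric(1))
  out <- list(train = list(), val = list(), test = list())
  with_seed(seed, {
    for (lb in unique(labels)) {
      idx <- sample(which(labels == lb))
      n <- length(idx)
      nv <- floor(ratios[2] * n)
      nt <- floor(ratios[3] * n)
      ntr <- n - nv - nt
      out$train <- c(out$train, samples[idx[seq_len(ntr)]])
      if (nv > 0) out$val <- c(out$val, samples[idx[ntr + seq_len(nv)]])
      if (nt > 0) out$test <- c(out$test, samples[idx[ntr + nv + seq_len(nt)]])
    }
  })
  out
}

#' Pseudo-color rendering of a segmentation mask
#' @param mask integer matrix with values in `{0, 1, 2}`
#' @return H x W x 3 array in \[0, 255\]: black background, red crop,
#'   green weed
#' @export
mask_to_pseudocolor <- function(mask) {
  stopifnot(all(mask %in% 0:2))
  pal <- rbind(c(0L, 0L, 0L), c(255L, 0L, 0L), c(0L, 255L, 0L))
  out <- array(0L, dim = c(nrow(mask), ncol(mask), 3))
  for (ch in 1:3) out[, , ch] <- matrix(pal[mask + 1L, ch], nrow(mask))
  out
}

#' Recover a class mask from its pseudo-color rendering
#' @param img H x W x 3 pseudo-color array
#' @return integer mask with values in `{0, 1, 2}`
#' @export
pseudocolor_to_mask <- function(img) {
  r <- img[, , 1] > 127
  g <- img[, , 2] > 127
  out <- matrix(0L, dim(img)[1], dim(img)[2])
  out[r] <- 1L
  out[g & !r] <- 2L
  out
}

#' Write a fixture to disk as PNG images plus JSON annotations
#'
#' Images go to `dir/images/NNNN.png`; segmentation masks to
#' `dir/masks/NNNN.png` as black/red/green pseudo-color; labels and boxes
#' to `dir/annotations.json` (fields `file`, `label`, `boxes`).
#'
#' @param samples list of samples
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  ann <- list()
  has_mask <- any(vapply(samples, function(s) !is.null(s$mask), logical(1)))
  if (has_mask) {
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  }
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    fn <- sprintf("%04d.png", i)
    png::writePNG(s$image / 255, file.path(dir, "images", fn))
    if (!is.null(s$mask)) {
      png::writePNG(mask_to_pseudocolor(s$mask) / 255,
                    file.path(dir, "masks", fn))
    }
    ann[[i]] <- list(file = fn, label = s$label,
                     boxes = if (!is.null(s$boxes)) s$boxes else NULL)
  }
  jsonlite::write_json(ann, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
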