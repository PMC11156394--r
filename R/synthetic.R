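# Procedural synthetic pest scenes with exact ground truth.
#
# Instances are parameterized blobs: a rotated textured ellipse body with
# class-specific hue, aspect ratio and appendage (leg) count, so class
# identity is genuinely learnable from pixels. Ground-truth boxes are the
# exact pixel extent of the drawn instance.

#' Specification of one synthetic scene
#'
#' @param width,height image size in pixels (>= 64).
#' @param n_instances number of pest instances to place (>= 0).
#' @param class_weights probability vector over classes; must sum to 1.
#' @param size_range `(min_px, max_px)` range for the instance longest side;
#'   `min_px >= 4`.
#' @param density_mode if `TRUE`, instances may form overlapping clusters
#'   (placement overlap cap is relaxed).
#' @param seed integer seed; the scene is a pure function of spec + seed.
#' @param classes optional explicit integer vector (0-based class ids, length
#'   `n_instances`) overriding `class_weights`.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(width = 256L, height = 256L, n_instances = 8L,
                       class_weights = rep(1 / 3, 3), size_range = c(16, 64),
                       density_mode = FALSE, seed = 1L, classes = NULL) {
  if (width < 64 || height < 64) stopf("width/height must be >= 64")
  if (abs(sum(class_weights) - 1) > 1e-9)
    stopf("class_weights must sum to 1 (got %g)", sum(class_weights))
  if (size_range[1] < 4) stopf("min instance size must be >= 4 px")
  if (n_instances < 0) stopf("n_instances must be >= 0")
  if (!is.null(classes) && length(classes) != n_instances)
    stopf("classes must have length n_instances")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_instances = as.integer(n_instances),
                 class_weights = class_weights, size_range = size_range,
                 density_mode = isTRUE(density_mode), seed = as.integer(seed),
                 classes = classes),
            class = "scene_spec")
}

# smooth field-like background texture (vectorized)
render_background <- function(h, w) {
  ii <- matrix(rep(seq_len(h), w), h, w)
  jj <- matrix(rep(seq_len(w), each = h), h, w)
  f1 <- sin(ii / 23 + jj / 31) * 0.5 + sin(ii / 7 - jj / 11) * 0.25
  f2 <- cos(ii / 17 - jj / 13) * 0.5
  grain <- matrix(stats::runif(h * w, -0.03, 0.03), h, w)
  img <- array(0, c(h, w, 3))
  img[, , 1] <- clamp(0.32 + 0.05 * f1 + grain, 0, 1)
  img[, , 2] <- clamp(0.45 + 0.07 * f2 + grain, 0, 1)
  img[, , 3] <- clamp(0.22 + 0.04 * f1 + grain, 0, 1)
  img
}

# class appearance code: hue + aspect + appendage count encode class identity
class_style <- function(class_id, n_classes) {
  hue <- 0.9 * class_id / max(1L, n_classes)
  list(hue = hue,
       aspect = 1.3 + 0.5 * (class_id %% 3L),
       n_legs = 2L + (class_id %% 4L))
}

# Render one instance on its own tight patch. Returns pixels, alpha mask and
# patch size; the tight pixel extent defines the ground-truth box.
render_instance <- function(longest, class_id, n_classes) {
  st <- class_style(class_id, n_classes)
  angle <- stats::runif(1, 0, pi)
  a <- longest / 2
  b <- max(1.6, a / st$aspect)
  leg_len <- 0.25 * longest
  ext <- ceiling(a + leg_len) + 1L
  n <- 2L * ext + 1L
  cx <- ext + 1; cy <- ext + 1
  xs <- matrix(rep(seq_len(n) - cx, each = n), n, n)   # column offsets
  ys <- matrix(rep(seq_len(n) - cy, times = n), n, n)  # row offsets
  ca <- cos(angle); sa <- sin(angle)
  u <- xs * ca + ys * sa
  v <- -xs * sa + ys * ca
  body <- (u / a)^2 + (v / b)^2 <= 1
  mask <- body
  # appendage strokes radiating from the body along its major axis flanks
  for (k in seq_len(st$n_legs)) {
    t <- -0.6 + 1.2 * (k - 1) / max(1L, st$n_legs - 1L)
    side <- if (k %% 2L == 0L) 1 else -1
    px <- t * a; py <- side * b * sqrt(max(0, 1 - t^2)) * 0.95
    qx <- px * 1.1; qy <- side * (b + leg_len)
    du <- u - px; dv <- v - py
    sx <- qx - px; sy <- qy - py
    seg2 <- sx^2 + sy^2
    tt <- clamp((du * sx + dv * sy) / seg2, 0, 1)
    d2 <- (du - tt * sx)^2 + (dv - tt * sy)^2
    mask <- mask | (d2 <= max(0.8, longest / 28)^2)
  }
  col <- grDevices::hsv(st$hue, 0.85, 0.75)
  rgbv <- grDevices::col2rgb(col)[, 1] / 255
  shade <- 1 - 0.55 * clamp((u / a)^2 + (v / b)^2, 0, 1)  # darker rim
  pix <- array(0, c(n, n, 3))
  for (c in 1:3) pix[, , c] <- rgbv[c] * (0.55 + 0.45 * shade)
  # head spot at the +u tip for orientation cue
  head <- ((u - 0.8 * a)^2 + v^2) <= (0.18 * longest)^2 & body
  for (c in 1:3) { pc <- pix[, , c]; pc[head] <- pc[head] * 0.35; pix[, , c] <- pc }
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  list(pix = pix[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
       mask = mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE])
}

paste_masked <- function(img, pix, mask, top, left) {
  ph <- nrow(mask); pw <- ncol(mask)
  ri <- top:(top + ph - 1L); ci <- left:(left + pw - 1L)
  for (c in 1:3) {
    sub <- img[ri, ci, c]
    sub[mask] <- pix[, , c][mask]
    img[ri, ci, c] <- sub
  }
  img
}

#' Generate one synthetic scene with exact ground-truth boxes
#'
#' Deterministic: the same spec (including its seed) always yields bitwise
#' identical pixels and boxes. Boxes use 0-based continuous corner
#' coordinates `(x1, y1, x2, y2)` with `x2 > x1`, `y2 > y1`; pixel `(i, j)`
#' (1-based row/col) covers `[j-1, j] x [i-1, i]`.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H x W x 3 array in `[0, 1]`) and `annotations`
#'   (data.frame with `image_id`, `class_id`, `x1`, `y1`, `x2`, `y2`,
#'   `iscrowd`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    img <- render_background(h, w)
    nc <- length(spec$class_weights)
    n <- spec$n_instances
    ann <- list()
    boxes <- matrix(numeric(0), 0, 4)
    cap <- if (spec$density_mode) 0.7 else 0.2
    cls <- spec$classes %||%
      (sample.int(nc, n, replace = TRUE, prob = spec$class_weights) - 1L)
    for (k in seq_len(n)) {
      longest <- stats::runif(1, spec$size_range[1], spec$size_range[2])
      inst <- render_instance(longest, cls[k], nc)
      ph <- nrow(inst$mask); pw <- ncol(inst$mask)
      if (ph > h || pw > w)
        stopf("instance %d (%d x %d px) does not fit a %d x %d image",
              k, pw, ph, w, h)
      placed <- FALSE
      for (try in 1:100) {
        top <- sample.int(h - ph + 1L, 1L)
        left <- sample.int(w - pw + 1L, 1L)
        bb <- c(left - 1, top - 1, left - 1 + pw, top - 1 + ph)
        if (nrow(boxes) == 0 || max(box_iou(matrix(bb, 1), boxes)) <= cap) {
          img <- paste_masked(img, inst$pix, inst$mask, top, left)
          boxes <- rbind(boxes, bb)
          ann[[k]] <- data.frame(image_id = 1L, class_id = cls[k],
                                 x1 = bb[1], y1 = bb[2], x2 = bb[3],
                                 y2 = bb[4], iscrowd = 0L)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("infeasible scene: could not place instance %d within the retry budget", k)
    }
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(image_id = integer(0), class_id = integer(0),
                 x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                 y2 = numeric(0), iscrowd = integer(0))
    list(image = img, annotations = annotations)
  })
}

#' Monotone head-to-tail class count profile
#'
#' Linear interpolation from a frequent head class down to a rare tail class,
#' emulating the long-tailed instance counts of real pest surveys (head
#' species with hundreds of instances, tail species with a handful).
#'
#' @param n_classes number of classes (>= 2).
#' @param head_count instance count of the most frequent class.
#' @param tail_count instance count of the rarest class
#'   (`head_count >= tail_count >= 1`).
#' @return integer vector of length `n_classes`, non-increasing.
#' @export
make_imbalanced_counts <- function(n_classes, head_count, tail_count) {
  if (n_classes < 2) stopf("n_classes must be >= 2")
  if (!(head_count >= tail_count && tail_count >= 1))
    stopf("need head_count >= tail_count >= 1")
  v <- as.integer(round(seq(head_count, tail_count, length.out = n_classes)))
  cummax_rev <- rev(cummax(rev(v)))  # guard monotonicity under rounding
  cummax_rev
}

#' Generate an in-memory synthetic detection dataset
#'
#' @param n_images number of scenes.
#' @param spec_template a [scene_spec()]; per-image seeds are derived from
#'   `seed`, the template's own seed is ignored.
#' @param seed master seed.
#' @param class_counts optional integer vector of exact per-class instance
#'   totals; when given, instances are distributed across images (at most
#'   `spec_template$n_instances` per image, extra images appended as needed)
#'   and `class_weights` is ignored.
#' @return a `pest_dataset`: list with `images` (list of H x W x 3 arrays),
#'   `annotations` (data.frame as in [generate_scene()] with `image_id`
#'   indexing `images`), and `n_classes`.
#' @export
generate_scenes <- function(n_images, spec_template, seed = 1L,
                            class_counts = NULL) {
  nc <- length(spec_template$class_weights)
  per_image_classes <- NULL
  if (!is.null(class_counts)) {
    stopifnot(length(class_counts) == nc)
    inst <- rep(seq_len(nc) - 1L, times = class_counts)
    inst <- with_seed(seed, sample(inst))
    cap <- max(1L, spec_template$n_instances)
    n_images <- max(n_images, ceiling(length(inst) / cap))
    per_image_classes <- split(inst, ceiling(seq_along(inst) / cap))
  }
  seeds <- with_seed(seed, sample.int(2147483646L, n_images))
  images <- vector("list", n_images)
  anns <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- spec_template
    sp$seed <- seeds[i]
    if (!is.null(per_image_classes)) {
      cls <- if (i <= length(per_image_classes)) per_image_classes[[i]]
      else integer(0)
      sp$classes <- cls
      sp$n_instances <- length(cls)
    }
    sc <- generate_scene(sp)
    images[[i]] <- sc$image
    if (nrow(sc$annotations)) sc$annotations$image_id <- i
    anns[[i]] <- sc$annotations
  }
  structure(list(images = images, annotations = do.call(rbind, anns),
                 n_classes = nc), class = "pest_dataset")
}

#' Generate a dataset on disk (PNG images + COCO JSON + sidecar config)
#'
#' @param n_images number of scenes.
#' @param spec_template a [scene_spec()] template.
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @return invisibly, the dataset root path.
#' @export
generate_dataset <- function(n_images, spec_template, out_dir, seed = 1L) {
  ds <- generate_scenes(n_images, spec_template, seed)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  for (i in seq_along(ds$images)) {
    p <- file.path(out_dir, "images", sprintf("img_%05d.png", i))
    ok <- tryCatch({ png::writePNG(ds$images[[i]], p); TRUE },
                   error = function(e) FALSE)
    if (!ok) stopf("failed to write image %s", p)
  }
  write_coco(ds, file.path(out_dir, "annotations.json"),
             file_names = sprintf("images/img_%05d.png", seq_along(ds$images)))
  side <- list(n_images = n_images, seed = seed,
               spec = spec_template[c("width", "height", "n_instances",
                                      "class_weights", "size_range",
                                      "density_mode")])
  yaml::write_yaml(side, file.path(out_dir, "generation.yaml"))
  invisible(out_dir)
}
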