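# Copy-paste class balancing and online photometric augmentation.
#
# Rare-class instances are cut out of their source images as rectangular
# patches and pasted (hard, unblended) onto background images until every
# class reaches a target instance count; online augmentation jitters color,
# erases random rectangles, adds gaussian noise and flips horizontally.

#' Augmentation policy
#'
#' @param color_jitter max deltas `(brightness, contrast, saturation, hue)`;
#'   brightness/contrast/saturation are multiplicative half-ranges, hue is an
#'   additive shift on the `[0, 1)` hue circle.
#' @param mask_prob probability of applying one random rectangular erase.
#' @param mask_area_frac max fraction of image area a mask may cover.
#' @param noise_sigma gaussian pixel noise standard deviation (on `[0, 1]`
#'   intensities).
#' @param flip_prob probability of horizontal flip.
#' @return an `augment_policy` list.
#' @export
augment_policy <- function(color_jitter = c(0.2, 0.2, 0.2, 0.05),
                           mask_prob = 0.3, mask_area_frac = 0.1,
                           noise_sigma = 0.02, flip_prob = 0.5) {
  stopifnot(all(c(mask_prob, flip_prob) >= 0), all(c(mask_prob, flip_prob) <= 1),
            noise_sigma >= 0, mask_area_frac >= 0, mask_area_frac <= 1)
  structure(list(color_jitter = color_jitter, mask_prob = mask_prob,
                 mask_area_frac = mask_area_frac, noise_sigma = noise_sigma,
                 flip_prob = flip_prob), class = "augment_policy")
}

round_box <- function(b) {
  c(round(b[1]), round(b[2]), round(b[3]), round(b[4]))
}

#' Cut annotated instances out of an image
#'
#' @param image H x W x 3 array.
#' @param annotations data.frame with `class_id`, `x1`, `y1`, `x2`, `y2`.
#' @return list of target patches, each with `pixels` (h x w x 3), `class_id`
#'   and `source_image_id`.
#' @export
extract_targets <- function(image, annotations) {
  h <- dim(image)[1]; w <- dim(image)[2]
  lapply(seq_len(nrow(annotations)), function(k) {
    a <- annotations[k, ]
    if (a$x1 < 0 || a$y1 < 0 || a$x2 > w || a$y2 > h)
      stopf("annotation %d box outside image bounds", k)
    rb <- round_box(c(a$x1, a$y1, a$x2, a$y2))
    if (rb[3] <= rb[1] || rb[4] <= rb[2])
      stopf("annotation %d has zero area after rounding", k)
    list(pixels = image[(rb[2] + 1L):rb[4], (rb[1] + 1L):rb[3], , drop = FALSE],
         class_id = a$class_id,
         source_image_id = a$image_id %||% NA_integer_)
  })
}

# nearest-neighbour resize of an h x w x 3 patch
resize_patch <- function(pix, new_h, new_w) {
  h <- dim(pix)[1]; w <- dim(pix)[2]
  ri <- pmin(h, pmax(1L, ceiling(seq_len(new_h) * h / new_h)))
  ci <- pmin(w, pmax(1L, ceiling(seq_len(new_w) * w / new_w)))
  pix[ri, ci, , drop = FALSE]
}

#' Paste target patches onto a background image
#'
#' Hard rectangular paste (no blending) so a cut/paste round trip is
#' pixel-exact. Placement is rejection-sampled so that pasted boxes overlap
#' each other and any pre-existing boxes with IoU at most `overlap_cap`.
#'
#' @param background H x W x 3 array.
#' @param patches list of target patches (see [extract_targets()]).
#' @param rng_seed integer seed; output is deterministic given the seed.
#' @param overlap_cap max pairwise IoU between pasted/pre-existing boxes.
#' @param existing_boxes optional n x 4 matrix of boxes already on the
#'   background.
#' @param scale_jitter relative size jitter applied to each patch before
#'   pasting (0 disables).
#' @param flip if `TRUE`, each patch is horizontally flipped with
#'   probability 0.5.
#' @param max_retry placement attempts per patch before failing.
#' @return list with `image` and `annotations` (one row per pasted patch).
#' @export
paste_targets <- function(background, patches, rng_seed = 1L,
                          overlap_cap = 0.2, existing_boxes = NULL,
                          scale_jitter = 0.2, flip = TRUE, max_retry = 100L) {
  h <- dim(background)[1]; w <- dim(background)[2]
  with_seed(rng_seed, {
    img <- background
    placed <- if (is.null(existing_boxes)) matrix(numeric(0), 0, 4)
    else matrix(as.numeric(existing_boxes), ncol = 4)
    n_fixed <- nrow(placed)
    ann <- list()
    for (k in seq_along(patches)) {
      p <- patches[[k]]
      pix <- p$pixels
      if (scale_jitter > 0) {
        f <- stats::runif(1, 1 - scale_jitter, 1 + scale_jitter)
        nh <- max(2L, round(dim(pix)[1] * f))
        nw <- max(2L, round(dim(pix)[2] * f))
        pix <- resize_patch(pix, nh, nw)
      }
      if (flip && stats::runif(1) < 0.5)
        pix <- pix[, rev(seq_len(dim(pix)[2])), , drop = FALSE]
      ph <- dim(pix)[1]; pw <- dim(pix)[2]
      if (ph > h || pw > w)
        stopf("patch %d (%d x %d) larger than background (%d x %d)",
              k, pw, ph, w, h)
      done <- FALSE
      for (try in seq_len(max_retry)) {
        top <- sample.int(h - ph + 1L, 1L)
        left <- sample.int(w - pw + 1L, 1L)
        bb <- c(left - 1, top - 1, left - 1 + pw, top - 1 + ph)
        if (nrow(placed) == 0 ||
            max(box_iou(matrix(bb, 1), placed)) <= overlap_cap) {
          img[top:(top + ph - 1L), left:(left + pw - 1L), ] <- pix
          placed <- rbind(placed, bb)
          ann[[length(ann) + 1L]] <-
            data.frame(image_id = NA_integer_, class_id = p$class_id,
                       x1 = bb[1], y1 = bb[2], x2 = bb[3], y2 = bb[4],
                       iscrowd = 0L)
          done <- TRUE
          break
        }
      }
      if (!done)
        stopf("could not place patch %d within %d retries", k, max_retry)
    }
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(image_id = integer(0), class_id = integer(0),
                 x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                 y2 = numeric(0), iscrowd = integer(0))
    list(image = img, annotations = annotations)
  })
}

#' Offline copy-paste class balancing
#'
#' Every class whose instance count is below `target_count` gains pasted
#' copies of its own instances (cycled, scale-jittered, flipped) on new
#' background images until it reaches the target exactly; classes at or above
#' the target are left untouched, and original images are never modified.
#'
#' @param dataset a `pest_dataset`.
#' @param target_count desired per-class instance count.
#' @param backgrounds list of H x W x 3 background arrays.
#' @param rng_seed integer seed.
#' @param per_image max pasted instances per generated image.
#' @param overlap_cap IoU cap between pasted boxes.
#' @return the expanded `pest_dataset` (new images appended after the
#'   originals).
#' @export
balance_classes <- function(dataset, target_count, backgrounds, rng_seed = 1L,
                            per_image = 8L, overlap_cap = 0.2) {
  stopifnot(length(backgrounds) >= 1)
  ann <- dataset$annotations
  counts <- tabulate(ann$class_id + 1L, nbins = dataset$n_classes)
  deficit <- pmax(0L, target_count - counts)
  if (any(counts == 0L & deficit > 0L))
    stopf("class %s has no source instances to copy",
          paste(which(counts == 0L & deficit > 0L) - 1L, collapse = ", "))
  if (sum(deficit) == 0L) return(dataset)
  # per-class source patch pools, cycled deterministically
  pools <- vector("list", dataset$n_classes)
  for (c in which(deficit > 0L)) {
    rows <- which(ann$class_id == c - 1L)
    pools[[c]] <- lapply(rows, function(r) {
      a <- ann[r, ]
      extract_targets(dataset$images[[a$image_id]], a)[[1]]
    })
  }
  todo <- unlist(lapply(which(deficit > 0L), function(c) {
    pool_n <- length(pools[[c]])
    vapply(seq_len(deficit[c]), function(i)
      c * 1000000L + ((i - 1L) %% pool_n + 1L), integer(1))
  }))
  todo <- with_seed(rng_seed, sample(todo))
  sub_seeds <- with_seed(rng_seed + 1L, sample.int(2147483646L,
                                                   ceiling(length(todo) / per_image) + 1L))
  images <- dataset$images
  new_ann <- list()
  chunk_id <- 0L
  while (length(todo)) {
    chunk_id <- chunk_id + 1L
    take <- seq_len(min(per_image, length(todo)))
    codes <- todo[take]
    todo <- todo[-take]
    patches <- lapply(codes, function(code)
      pools[[code %/% 1000000L]][[code %% 1000000L]])
    bg_i <- with_seed(sub_seeds[chunk_id],
                      sample.int(length(backgrounds), 1L))
    res <- paste_targets(backgrounds[[bg_i]], patches,
                         rng_seed = sub_seeds[chunk_id] + 1L,
                         overlap_cap = overlap_cap)
    images[[length(images) + 1L]] <- res$image
    res$annotations$image_id <- length(images)
    new_ann[[chunk_id]] <- res$annotations
  }
  structure(list(images = images,
                 annotations = rbind(ann, do.call(rbind, new_ann)),
                 n_classes = dataset$n_classes),
            class = "pest_dataset")
}

# multiplicative/additive color jitter in HSV-ish space, vectorized
jitter_color <- function(img, deltas) {
  if (all(deltas == 0)) return(img)
  b <- 1 + stats::runif(1, -deltas[1], deltas[1])
  ct <- 1 + stats::runif(1, -deltas[2], deltas[2])
  st <- 1 + stats::runif(1, -deltas[3], deltas[3])
  hu <- stats::runif(1, -deltas[4], deltas[4])
  img <- clamp(img * b, 0, 1)
  mu <- mean(img)
  img <- clamp((img - mu) * ct + mu, 0, 1)
  # saturation/hue via per-pixel HSV on the flattened 3 x N matrix
  if (st != 1 || hu != 0) {
    d <- dim(img)
    m <- t(matrix(img, d[1] * d[2], 3))
    hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
    hsv[2, ] <- clamp(hsv[2, ] * st, 0, 1)
    hsv[1, ] <- (hsv[1, ] + hu) %% 1
    rgb <- grDevices::col2rgb(grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])) / 255
    img <- array(t(rgb), d)
  }
  img
}

#' Online augmentation: color dithering, random masking, noise, flip
#'
#' Photometric operations never move boxes; the only geometric operation is a
#' horizontal flip, whose x-coordinate remap is exact. With an all-zero
#' policy the input is returned bit-identical.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param annotations annotation data.frame (boxes in corner convention).
#' @param policy an [augment_policy()].
#' @param rng_seed integer seed.
#' @return list with `image` and `annotations`.
#' @export
online_augment <- function(image, annotations, policy = augment_policy(),
                           rng_seed = 1L) {
  stopifnot(inherits(policy, "augment_policy"))
  h <- dim(image)[1]; w <- dim(image)[2]
  with_seed(rng_seed, {
    img <- jitter_color(image, policy$color_jitter)
    if (policy$mask_prob > 0 && stats::runif(1) < policy$mask_prob) {
      gt <- as.matrix(annotations[, c("x1", "y1", "x2", "y2"), drop = FALSE])
      fill <- apply(img, 3, mean)
      for (try in 1:10) {
        mw <- sample.int(max(1L, floor(w * sqrt(policy$mask_area_frac))), 1L)
        mh <- sample.int(max(1L, floor(h * sqrt(policy$mask_area_frac))), 1L)
        left <- sample.int(w - mw + 1L, 1L); top <- sample.int(h - mh + 1L, 1L)
        mb <- c(left - 1, top - 1, left - 1 + mw, top - 1 + mh)
        # a mask may not erase more than half of any ground-truth box
        if (nrow(gt)) {
          ix <- pmax(0, pmin(mb[3], gt[, 3]) - pmax(mb[1], gt[, 1]))
          iy <- pmax(0, pmin(mb[4], gt[, 4]) - pmax(mb[2], gt[, 2]))
          frac <- (ix * iy) / ((gt[, 3] - gt[, 1]) * (gt[, 4] - gt[, 2]))
          if (any(frac > 0.5)) next
        }
        for (c in 1:3) img[top:(top + mh - 1L), left:(left + mw - 1L), c] <- fill[c]
        break
      }
    }
    if (policy$noise_sigma > 0)
      img <- clamp(img + array(stats::rnorm(length(img), 0, policy$noise_sigma),
                               dim(img)), 0, 1)
    ann <- annotations
    if (policy$flip_prob > 0 && stats::runif(1) < policy$flip_prob) {
      img <- img[, rev(seq_len(w)), , drop = FALSE]
      if (nrow(ann)) {
        x1 <- w - ann$x2
        ann$x2 <- w - ann$x1
        ann$x1 <- x1
      }
    }
    list(image = img, annotations = ann)
  })
}
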