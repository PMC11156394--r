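# Detection metrics: per-class average precision (101-point interpolation at
# IoU 0.5), precision and recall at the score floor.

# greedy matching of detections (descending score) to ground truth
match_detections <- function(dets, gts, iou_thresh = 0.5) {
  nd <- nrow(dets)
  tp <- logical(nd)
  used <- logical(nrow(gts))
  for (k in seq_len(nd)) {
    g_rows <- which(gts$image_id == dets$image_id[k] & !used)
    if (!length(g_rows)) next
    ious <- as.numeric(box_iou(as.matrix(dets[k, c("x1", "y1", "x2", "y2")]),
                               as.matrix(gts[g_rows, c("x1", "y1", "x2", "y2")])))
    j <- which.max(ious)
    if (ious[j] >= iou_thresh) {
      tp[k] <- TRUE
      used[g_rows[j]] <- TRUE
    }
  }
  tp
}

# 101-point interpolated AP from matched detections
average_precision <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (!length(tp)) return(0)
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_gt
  mean(vapply(seq(0, 1, by = 0.01), function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1)))
}

#' Evaluate detections against ground truth
#'
#' @param detections data.frame with `image_id`, `class_id`, `score`, `x1`,
#'   `y1`, `x2`, `y2`.
#' @param annotations ground-truth data.frame (same box columns).
#' @param n_classes number of classes.
#' @param iou_thresh matching IoU threshold (0.5 for mAP_0.5).
#' @param score_floor operating point for precision/recall.
#' @return list: `map50`, `precision`, `recall`, `per_class_ap`.
#' @export
evaluate_detections <- function(detections, annotations, n_classes,
                                iou_thresh = 0.5, score_floor = 0.05) {
  aps <- rep(NA_real_, n_classes)
  total_tp <- 0L; total_det <- 0L; total_gt <- nrow(annotations)
  for (c in seq_len(n_classes) - 1L) {
    gts <- annotations[annotations$class_id == c, , drop = FALSE]
    dets <- detections[detections$class_id == c &
                         detections$score >= score_floor, , drop = FALSE]
    # deterministic order: score desc, ties broken by box coordinates
    if (nrow(dets))
      dets <- dets[order(-dets$score, dets$x1, dets$y1, dets$x2, dets$y2), ,
                   drop = FALSE]
    tp <- match_detections(dets, gts, iou_thresh)
    aps[c + 1L] <- average_precision(tp, nrow(gts))
    total_tp <- total_tp + sum(tp)
    total_det <- total_det + nrow(dets)
  }
  list(map50 = mean(aps, na.rm = TRUE),
       precision = if (total_det > 0) total_tp / total_det else 0,
       recall = if (total_gt > 0) total_tp / total_gt else 0,
       per_class_ap = aps)
}

#' Run a model over a dataset and evaluate it
#'
#' @param dataset a `pest_dataset` with in-memory images.
#' @param model a `pest_model`.
#' @param score_floor detection score floor.
#' @return list as in [evaluate_detections()], plus `detections`.
#' @export
evaluate_detector <- function(dataset, model, score_floor = 0.05) {
  dets <- list()
  for (i in seq_along(dataset$images)) {
    d <- detect(dataset$images[[i]], model, score_floor = score_floor)
    if (nrow(d)) {
      d$image_id <- i
      dets[[length(dets) + 1L]] <- d
    }
  }
  detections <- if (length(dets)) do.call(rbind, dets) else
    data.frame(image_id = integer(0), class_id = integer(0),
               score = numeric(0), x1 = numeric(0), y1 = numeric(0),
               x2 = numeric(0), y2 = numeric(0))
  res <- evaluate_detections(detections, dataset$annotations,
                             dataset$n_classes, score_floor = score_floor)
  res$detections <- detections
  res
}

#' Draw detection boxes into an image
#'
#' @param image H x W x 3 array.
#' @param detections data.frame with box columns and `class_id`.
#' @return the image with 2-px box outlines painted in class colors.
#' @export
draw_detections <- function(image, detections) {
  h <- dim(image)[1]; w <- dim(image)[2]
  for (k in seq_len(nrow(detections))) {
    d <- detections[k, ]
    col <- grDevices::col2rgb(grDevices::hsv((d$class_id * 0.37) %% 1, 1, 1))[, 1] / 255
    x1 <- clamp(round(d$x1) + 1L, 1L, w); x2 <- clamp(round(d$x2), 1L, w)
    y1 <- clamp(round(d$y1) + 1L, 1L, h); y2 <- clamp(round(d$y2), 1L, h)
    for (c in 1:3) {
      image[y1:min(y1 + 1L, h), x1:x2, c] <- col[c]
      image[max(y2 - 1L, 1L):y2, x1:x2, c] <- col[c]
      image[y1:y2, x1:min(x1 + 1L, w), c] <- col[c]
      image[y1:y2, max(x2 - 1L, 1L):x2, c] <- col[c]
    }
  }
  image
}

#' Run inference on an image file
#'
#' @param image_path PNG image path.
#' @param checkpoint_path checkpoint from [save_checkpoint()].
#' @param out_json path for COCO-style results JSON.
#' @param out_png path for the annotated visualization PNG.
#' @param score_floor detection score floor.
#' @return the detection data.frame, invisibly.
#' @export
infer <- function(image_path, checkpoint_path, out_json = "detections.json",
                  out_png = "detections.png", score_floor = 0.05) {
  if (!file.exists(image_path)) stopf("unreadable image: %s", image_path)
  img <- tryCatch(png::readPNG(image_path),
                  error = function(e) stopf("unreadable image: %s", image_path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  model <- load_checkpoint(checkpoint_path)
  d <- detect(img, model, score_floor = score_floor)
  d$image_id <- 1L
  write_coco_results(d, out_json)
  png::writePNG(draw_detections(img, d), out_png)
  invisible(d)
}
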