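# Two-stage detection on the P3-P6 pyramid: anchor-based region proposals,
# three cascade refinement stages with rising IoU thresholds (0.5/0.6/0.7),
# classifier-ensemble scoring (mean of the three stage classifiers) on the
# final boxes B3, and per-class linear soft-NMS.

#' Cascade head configuration
#'
#' @param iou_thresholds per-stage positive-assignment IoU thresholds,
#'   strictly increasing.
#' @param soft_nms_Nt overlap threshold of the linear soft-NMS penalty.
#' @param score_floor minimum retained detection score.
#' @param ensemble `"reeval"` re-runs all three stage classifiers on the
#'   final B3 boxes before averaging; `"stagewise"` averages each stage's
#'   scores from its own box trajectory.
#' @return a `cascade_config` list.
#' @export
cascade_config <- function(iou_thresholds = c(0.5, 0.6, 0.7),
                           soft_nms_Nt = 0.5, score_floor = 0.05,
                           ensemble = c("reeval", "stagewise")) {
  if (any(diff(iou_thresholds) <= 0))
    stopf("cascade IoU thresholds must be strictly increasing")
  structure(list(iou_thresholds = iou_thresholds,
                 stages = length(iou_thresholds),
                 soft_nms_Nt = soft_nms_Nt, score_floor = score_floor,
                 ensemble = match.arg(ensemble)),
            class = "cascade_config")
}

# ---- anchors ----------------------------------------------------------------

# anchors for one pyramid level: (H*W*A) x 4, row index r + HW*(a-1) with
# r the column-major pixel index (matches feature-map row order); anchor
# index a runs over (ratio, scale) pairs, ratio fastest
level_anchors <- function(h, w, stride, base, ratios = c(0.5, 1, 2),
                          scales = 2^((0:2) / 3)) {
  key <- sprintf("anch_%d_%d_%d_%g_%s_%s", h, w, stride, base,
                 paste(ratios, collapse = "_"), paste(scales, collapse = "_"))
  cache_get(key, function() {
    ii <- rep(seq_len(h), times = w)
    jj <- rep(seq_len(w), each = h)
    cx <- (jj - 0.5) * stride
    cy <- (ii - 0.5) * stride
    A <- length(ratios) * length(scales)
    out <- matrix(0, h * w * A, 4)
    a <- 0L
    for (sc in scales) for (r in ratios) {
      a <- a + 1L
      bw <- base * sc * sqrt(r)
      bh <- base * sc / sqrt(r)
      rows <- ((a - 1L) * h * w + 1L):(a * h * w)
      out[rows, ] <- cbind(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
    }
    out
  })
}

# anchor layout implied by the head width: always 3 aspect ratios, the
# remaining factor sub-octave scales centred on the level's base size
anchor_layout <- function(n_anchors) {
  n_sc <- as.integer(n_anchors / 3L)
  stopifnot(n_sc * 3L == n_anchors, n_sc >= 1L)
  scales <- if (n_sc == 1L) 1 else 2^(seq(-0.5, 0.5, length.out = n_sc))
  list(ratios = c(0.5, 1, 2), scales = scales)
}

pyramid_anchors <- function(pyramid, n_anchors = 9L, base0 = 4) {
  lay <- anchor_layout(n_anchors)
  lapply(pyramid, function(p)
    level_anchors(p$h, p$w, p$stride, base0 * p$stride, lay$ratios,
                  lay$scales))
}

# ---- RPN --------------------------------------------------------------------

init_rpn <- function(C, n_anchors = 9L) {
  list(conv = init_conv(3L, C, C),
       obj = init_linear(C, n_anchors, zero = TRUE),
       reg = init_linear(C, 4L * n_anchors, zero = TRUE))
}

# per-level RPN head: objectness (HW*A x 1) and deltas (HW*A x 4)
rpn_head_level <- function(p, params, n_anchors) {
  z <- ag_relu(conv_fwd(p$x, params$conv, p$h, p$w, 3L))
  obj <- linear_fwd(z, params$obj)                    # HW x A
  reg <- linear_fwd(z, params$reg)                    # HW x 4A
  hw <- p$h * p$w
  obj_v <- ag_reshape(obj, c(hw * n_anchors, 1L))     # r fastest, a slower
  reg_a <- ag_reshape(reg, c(hw, 4L, n_anchors))
  reg_a <- ag_aperm(reg_a, c(1L, 3L, 2L))
  reg_v <- ag_reshape(reg_a, c(hw * n_anchors, 4L))
  list(obj = obj_v, reg = reg_v)
}

#' Generate class-agnostic region proposals from the pyramid
#'
#' Anchor objectness and box deltas are predicted per level by a shared 3x3
#' conv head; decoded proposals are clipped to the image, filtered per level
#' by top-k and hard NMS, merged across levels and truncated.
#'
#' @param pyramid P3-P6 list (plain values).
#' @param params RPN parameters (anchor count is read from the objectness
#'   head width).
#' @param img_w,img_h image size in pixels.
#' @param pre_nms,post_nms per-level keep counts before/after NMS.
#' @param nms_thresh hard-NMS IoU threshold.
#' @param max_total overall proposal cap.
#' @param min_size minimum proposal side in pixels.
#' @return list with `boxes` (n x 4) and `scores` (objectness logits'
#'   sigmoid), sorted by descending score.
#' @export
rpn_propose <- function(pyramid, params, img_w, img_h,
                        pre_nms = 600L, post_nms = 150L, nms_thresh = 0.7,
                        max_total = 300L, min_size = 2) {
  if (!length(pyramid)) stopf("empty feature pyramid")
  params <- detach_params(params)
  n_anchors <- ncol(params$obj$w)
  anchors <- pyramid_anchors(pyramid, n_anchors)
  all_boxes <- list(); all_scores <- list()
  for (l in seq_along(pyramid)) {
    head <- rpn_head_level(pyramid[[l]], params, n_anchors)
    sc <- as.numeric(ag_value(head$obj))
    boxes <- decode_boxes(anchors[[l]], ag_value(head$reg))
    boxes <- clip_boxes(boxes, img_w, img_h)
    ok <- (boxes[, 3] - boxes[, 1]) >= min_size &
      (boxes[, 4] - boxes[, 2]) >= min_size
    boxes <- boxes[ok, , drop = FALSE]; sc <- sc[ok]
    if (!nrow(boxes)) next
    top <- utils::head(order(sc, decreasing = TRUE), pre_nms)
    boxes <- boxes[top, , drop = FALSE]; sc <- sc[top]
    keep <- utils::head(hard_nms(boxes, sc, nms_thresh), post_nms)
    all_boxes[[l]] <- boxes[keep, , drop = FALSE]
    all_scores[[l]] <- sc[keep]
  }
  boxes <- do.call(rbind, all_boxes)
  scores <- unlist(all_scores)
  if (is.null(boxes))
    return(list(boxes = matrix(numeric(0), 0, 4), scores = numeric(0)))
  ord <- utils::head(order(scores, decreasing = TRUE), max_total)
  list(boxes = boxes[ord, , drop = FALSE],
       scores = 1 / (1 + exp(-scores[ord])))
}

# ---- proposal/GT assignment -------------------------------------------------

#' Assign proposals to ground truth at a stage IoU threshold
#'
#' A proposal is positive iff its best IoU against any ground-truth box is at
#' least `iou_threshold`; it is then matched to the argmax ground truth.
#' Everything else is background.
#'
#' @param proposals n x 4 matrix.
#' @param gt_boxes m x 4 matrix.
#' @param gt_labels length-m 0-based class ids.
#' @param iou_threshold stage threshold in (0, 1).
#' @param reg_wts delta scaling weights used when encoding targets.
#' @return list: `labels` (length n; 0 = background, else class id + 1),
#'   `matched` (gt index or NA), `reg_targets` (n x 4 encoded deltas, NA
#'   rows for background).
#' @export
assign_stage_targets <- function(proposals, gt_boxes, gt_labels,
                                 iou_threshold, reg_wts = c(1, 1, 1, 1)) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  n <- nrow(proposals)
  labels <- integer(n)
  matched <- rep(NA_integer_, n)
  reg <- matrix(NA_real_, n, 4)
  if (n == 0 || is.null(gt_boxes) || nrow(gt_boxes) == 0)
    return(list(labels = labels, matched = matched, reg_targets = reg))
  ious <- box_iou(proposals, gt_boxes)
  best <- max.col(ious, ties.method = "first")
  best_iou <- ious[cbind(seq_len(n), best)]
  pos <- best_iou >= iou_threshold
  labels[pos] <- gt_labels[best[pos]] + 1L
  matched[pos] <- best[pos]
  if (any(pos))
    reg[pos, ] <- encode_boxes(proposals[pos, , drop = FALSE],
                               gt_boxes[best[pos], , drop = FALSE], reg_wts)
  list(labels = labels, matched = matched, reg_targets = reg)
}

# RPN anchor assignment with low/high thresholds and per-GT force matching
assign_rpn_targets <- function(anchors, gt_boxes, lo = 0.3, hi = 0.5) {
  n <- nrow(anchors)
  labels <- rep(-1L, n)  # -1 ignore, 0 negative, 1 positive
  matched <- rep(NA_integer_, n)
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0) {
    labels[] <- 0L
    return(list(labels = labels, matched = matched))
  }
  ious <- box_iou(anchors, gt_boxes)
  best <- max.col(ious, ties.method = "first")
  best_iou <- ious[cbind(seq_len(n), best)]
  labels[best_iou < lo] <- 0L
  labels[best_iou >= hi] <- 1L
  # every GT gets its best anchor even below the threshold
  for (g in seq_len(ncol(ious))) {
    a <- which.max(ious[, g])
    labels[a] <- 1L
    best[a] <- g
  }
  matched[labels == 1L] <- best[labels == 1L]
  list(labels = labels, matched = matched)
}

# ---- ROI feature extraction -------------------------------------------------

# map each ROI to a pyramid level by scale: sqrt(area) 32 -> P3, 64 -> P4 ...
roi_levels <- function(rois, n_levels = 4L, base = 32) {
  sz <- sqrt(pmax(1e-6, (rois[, 3] - rois[, 1]) * (rois[, 4] - rois[, 2])))
  clamp(floor(log2(sz / base) + 0.5) + 1L, 1L, n_levels)
}

# bilinear interpolation gather plan for a set of ROIs on one level:
# returns 4 index vectors + weights, rows ordered roi fastest, bin slower
roi_gather_plan <- function(rois, h, w, stride, grid = 7L) {
  n <- nrow(rois)
  bx <- (seq_len(grid) - 0.5) / grid
  # sample points in feature coordinates (half-pixel centers)
  x1 <- rois[, 1]; y1 <- rois[, 2]
  rw <- rois[, 3] - rois[, 1]; rh <- rois[, 4] - rois[, 2]
  px <- matrix(0, n, grid); py <- matrix(0, n, grid)
  for (b in seq_len(grid)) {
    px[, b] <- (x1 + bx[b] * rw) / stride - 0.5
    py[, b] <- (y1 + bx[b] * rh) / stride - 0.5
  }
  # bins ordered column-major (by y fastest? use bin = (byi, bxi) x-major)
  idx <- matrix(0L, n * grid * grid, 4L)
  wt <- matrix(0, n * grid * grid, 4L)
  row0 <- 0L
  for (bxi in seq_len(grid)) for (byi in seq_len(grid)) {
    fx <- clamp(px[, bxi], 0, w - 1)
    fy <- clamp(py[, byi], 0, h - 1)
    x0 <- floor(fx); y0 <- floor(fy)
    x1f <- pmin(x0 + 1, w - 1); y1f <- pmin(y0 + 1, h - 1)
    ax <- fx - x0; ay <- fy - y0
    rows <- (row0 + 1L):(row0 + n)
    idx[rows, 1] <- (y0 + 1) + h * x0
    idx[rows, 2] <- (y1f + 1) + h * x0
    idx[rows, 3] <- (y0 + 1) + h * x1f
    idx[rows, 4] <- (y1f + 1) + h * x1f
    wt[rows, 1] <- (1 - ax) * (1 - ay)
    wt[rows, 2] <- (1 - ax) * ay
    wt[rows, 3] <- ax * (1 - ay)
    wt[rows, 4] <- ax * ay
    row0 <- row0 + n
  }
  list(idx = idx, wt = wt, n = n)
}

# pooled features for ROIs across levels: (n) x (grid^2 * C)
roi_pool <- function(pyramid, rois, grid = 7L) {
  n <- nrow(rois)
  C <- ncol(ag_value(pyramid[[1]]$x))
  lv <- roi_levels(rois, n_levels = length(pyramid))
  parts <- list(); orders <- list()
  for (l in sort(unique(lv))) {
    sel <- which(lv == l)
    p <- pyramid[[l]]
    plan <- roi_gather_plan(rois[sel, , drop = FALSE], p$h, p$w, p$stride,
                            grid)
    acc <- NULL
    for (t in 1:4) {
      g <- ag_gather_rows(p$x, plan$idx[, t])
      g <- ag_mul(g, matrix(plan$wt[, t], nrow(plan$idx), C))
      acc <- if (is.null(acc)) g else ag_add(acc, g)
    }
    pooled <- ag_reshape(acc, c(length(sel), grid * grid * C))
    parts[[length(parts) + 1L]] <- pooled
    orders[[length(orders) + 1L]] <- sel
  }
  combined <- if (length(parts) == 1L) parts[[1]] else do.call(ag_rbind, parts)
  ord <- unlist(orders)
  perm <- integer(n); perm[ord] <- seq_len(n)
  ag_gather_rows(combined, perm[seq_len(n)])
}

# ---- cascade heads ----------------------------------------------------------

init_cascade_heads <- function(C, n_classes, hidden = 256L, grid = 7L,
                               stages = 3L) {
  lapply(seq_len(stages), function(s) {
    list(fc1 = init_linear(grid * grid * C, hidden, sd = NULL),
         fc2 = init_linear(hidden, hidden, sd = NULL),
         cls = init_linear(hidden, n_classes + 1L, zero = TRUE),
         reg = init_linear(hidden, 4L, zero = TRUE))
  })
}

stage_head_fwd <- function(pooled, head) {
  z <- ag_relu(linear_fwd(pooled, head$fc1))
  z <- ag_relu(linear_fwd(z, head$fc2))
  list(cls = linear_fwd(z, head$cls), reg = linear_fwd(z, head$reg))
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

#' Cascade refinement forward pass (inference)
#'
#' Stage s refines the previous stage's boxes (B0 = proposals); the final
#' boxes are B3. Classification ensembles the three stage classifiers: with
#' `ensemble = "reeval"` all three heads are re-run on the B3 boxes and their
#' class probabilities averaged, `(C1 + C2 + C3) / 3`.
#'
#' @param pyramid P3-P6 list (plain values).
#' @param proposals n x 4 matrix from [rpn_propose()].
#' @param heads cascade head parameters (plain values or nodes).
#' @param img_w,img_h image size for clipping.
#' @param cfg a [cascade_config()].
#' @return list: `stage_outputs` (`C1..C3` probability matrices, `B1..B3`
#'   boxes), `scores` (n x (n_classes+1) averaged probabilities), `boxes`
#'   (B3).
#' @export
cascade_forward <- function(pyramid, proposals, heads, img_w, img_h,
                            cfg = cascade_config()) {
  heads <- detach_params(heads)
  boxes <- proposals
  B <- list(); C_own <- list()
  for (s in seq_len(cfg$stages)) {
    pooled <- roi_pool(pyramid, boxes)
    out <- stage_head_fwd(pooled, heads[[s]])
    C_own[[s]] <- softmax_rows(ag_value(out$cls))
    boxes <- clip_boxes(decode_boxes(boxes, ag_value(out$reg),
                                     stage_reg_wts(s)), img_w, img_h)
    B[[s]] <- boxes
  }
  if (cfg$ensemble == "reeval") {
    pooled3 <- roi_pool(pyramid, B[[cfg$stages]])
    Cs <- lapply(seq_len(cfg$stages), function(s)
      softmax_rows(ag_value(stage_head_fwd(pooled3, heads[[s]])$cls)))
  } else {
    Cs <- C_own
  }
  avg <- Reduce(`+`, Cs) / length(Cs)
  list(stage_outputs = list(C1 = Cs[[1]], C2 = Cs[[2]], C3 = Cs[[3]],
                            B1 = B[[1]], B2 = B[[2]], B3 = B[[3]]),
       scores = avg, boxes = B[[cfg$stages]])
}

#' Detect objects in one image
#'
#' Full pipeline: backbone, neck, RPN proposals, cascade refinement, per-class
#' linear soft-NMS. Deterministic for fixed weights.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param model a `pest_model` (see [pest_model()]).
#' @param score_floor minimum detection score (defaults to the model's
#'   cascade config).
#' @return data.frame with `class_id`, `score`, `x1`, `y1`, `x2`, `y2`,
#'   sorted by descending score.
#' @export
detect <- function(image, model, score_floor = NULL) {
  cfg <- model$cascade
  score_floor <- score_floor %||% cfg$score_floor
  h <- dim(image)[1]; w <- dim(image)[2]
  feats <- forward_backbone(image, model$params$backbone, model$backbone,
                            train = FALSE)
  pyr <- forward_neck(feats, model$params$neck, model$neck, train = FALSE)
  prop <- rpn_propose(pyr, model$params$rpn, w, h,
                      pre_nms = 800L, post_nms = 150L, max_total = 200L)
  empty <- data.frame(class_id = integer(0), score = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0))
  if (!nrow(prop$boxes)) return(empty)
  casc <- cascade_forward(pyr, prop$boxes, model$params$heads, w, h, cfg)
  out <- list()
  for (c in seq_len(model$n_classes)) {
    sc <- casc$scores[, c + 1L]
    keep <- sc >= score_floor
    if (!any(keep)) next
    res <- soft_nms(casc$boxes[keep, , drop = FALSE], sc[keep],
                    Nt = cfg$soft_nms_Nt, score_floor = score_floor)
    if (!length(res$scores)) next
    out[[length(out) + 1L]] <-
      data.frame(class_id = c - 1L, score = res$scores,
                 x1 = res$boxes[, 1], y1 = res$boxes[, 2],
                 x2 = res$boxes[, 3], y2 = res$boxes[, 4])
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$score, decreasing = TRUE), , drop = FALSE]
}
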