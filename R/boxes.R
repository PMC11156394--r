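# Axis-aligned box geometry. Boxes are rows (x1, y1, x2, y2), 0-based
# continuous pixel coordinates with x2 > x1 and y2 > y1.

#' Pairwise intersection-over-union between two box sets
#'
#' @param a n x 4 matrix of boxes.
#' @param b m x 4 matrix of boxes.
#' @return n x m matrix of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 4)
  b <- matrix(as.numeric(b), ncol = 4)
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  ix1 <- outer(a[, 1], b[, 1], pmax)
  iy1 <- outer(a[, 2], b[, 2], pmax)
  ix2 <- outer(a[, 3], b[, 3], pmin)
  iy2 <- outer(a[, 4], b[, 4], pmin)
  iw <- pmax(0, ix2 - ix1)
  ih <- pmax(0, iy2 - iy1)
  inter <- iw * ih
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- outer(area_a, area_b, "+") - inter
  ifelse(un > 0, inter / un, 0)
}

#' Intersection-over-union of two boxes
#'
#' @param box_a,box_b length-4 numeric vectors `(x1, y1, x2, y2)`.
#' @return scalar IoU in `[0, 1]`; symmetric in its arguments.
#' @export
iou <- function(box_a, box_b) {
  as.numeric(box_iou(matrix(box_a, 1), matrix(box_b, 1)))
}

clip_boxes <- function(boxes, width, height) {
  boxes[, 1] <- clamp(boxes[, 1], 0, width)
  boxes[, 3] <- clamp(boxes[, 3], 0, width)
  boxes[, 2] <- clamp(boxes[, 2], 0, height)
  boxes[, 4] <- clamp(boxes[, 4], 0, height)
  boxes
}

# (dx, dy, dw, dh) parameterization of a target box relative to a source box.
# `wts` rescales the deltas so regression outputs live near unit variance
# (the usual (10, 10, 5, 5)-style weights; decode divides them back out).
encode_boxes <- function(src, dst, wts = c(1, 1, 1, 1)) {
  sw <- src[, 3] - src[, 1]; sh <- src[, 4] - src[, 2]
  sx <- src[, 1] + 0.5 * sw; sy <- src[, 2] + 0.5 * sh
  dw <- dst[, 3] - dst[, 1]; dh <- dst[, 4] - dst[, 2]
  dx <- dst[, 1] + 0.5 * dw; dy <- dst[, 2] + 0.5 * dh
  cbind(wts[1] * (dx - sx) / sw, wts[2] * (dy - sy) / sh,
        wts[3] * log(dw / sw), wts[4] * log(dh / sh))
}

decode_boxes <- function(src, deltas, wts = c(1, 1, 1, 1), clip_exp = 4) {
  sw <- src[, 3] - src[, 1]; sh <- src[, 4] - src[, 2]
  sx <- src[, 1] + 0.5 * sw; sy <- src[, 2] + 0.5 * sh
  cx <- sx + deltas[, 1] / wts[1] * sw
  cy <- sy + deltas[, 2] / wts[2] * sh
  w <- sw * exp(clamp(deltas[, 3] / wts[3], -clip_exp, clip_exp))
  h <- sh * exp(clamp(deltas[, 4] / wts[4], -clip_exp, clip_exp))
  cbind(cx - 0.5 * w, cy - 0.5 * h, cx + 0.5 * w, cy + 0.5 * h)
}

# per-stage delta scalings, the conventional cascade schedule
stage_reg_wts <- function(s) {
  list(c(10, 10, 5, 5), c(20, 20, 10, 10), c(30, 30, 15, 15))[[s]]
}

#' Hard non-maximum suppression
#'
#' Greedy suppression: keep the highest-scoring box, drop every remaining box
#' whose IoU with it exceeds `thresh`, repeat.
#'
#' @param boxes n x 4 matrix.
#' @param scores length-n numeric.
#' @param thresh IoU suppression threshold.
#' @return integer indices of kept boxes, in descending score order.
#' @export
hard_nms <- function(boxes, scores, thresh = 0.5) {
  if (nrow(boxes) == 0) return(integer(0))
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1]
    ious <- as.numeric(box_iou(boxes[i, , drop = FALSE],
                               boxes[rest, , drop = FALSE]))
    ord <- rest[ious <= thresh]
  }
  keep
}

#' Linear soft non-maximum suppression
#'
#' Greedy recurrence: repeatedly freeze the current highest-scoring box M and
#' rescale every remaining score
#' \deqn{s_i \leftarrow \cases{s_i & iou(M, b_i) < N_t \cr
#'       s_i (1 - iou(M, b_i)) & iou(M, b_i) \ge N_t}}
#' so that heavily overlapping boxes are down-weighted rather than deleted —
#' important for densely packed pests. Boxes whose final score falls below
#' `score_floor` are dropped.
#'
#' @param boxes n x 4 matrix.
#' @param scores length-n numeric in `[0, 1]`.
#' @param Nt overlap threshold above which the linear penalty applies.
#' @param score_floor minimum retained score.
#' @return list with `boxes`, `scores` (descending) and `index` (original row
#'   of each kept box).
#' @export
soft_nms <- function(boxes, scores, Nt = 0.5, score_floor = 0.05) {
  boxes <- matrix(as.numeric(boxes), ncol = 4)
  n <- nrow(boxes)
  if (n == 0)
    return(list(boxes = boxes, scores = numeric(0), index = integer(0)))
  s <- as.numeric(scores)
  alive <- seq_len(n)
  kept <- integer(0); kept_s <- numeric(0)
  while (length(alive)) {
    j <- which.max(s[alive])
    m <- alive[j]
    kept <- c(kept, m); kept_s <- c(kept_s, s[m])
    alive <- alive[-j]
    if (!length(alive)) break
    ov <- as.numeric(box_iou(boxes[m, , drop = FALSE],
                             boxes[alive, , drop = FALSE]))
    pen <- ov >= Nt
    s[alive[pen]] <- s[alive[pen]] * (1 - ov[pen])
  }
  keep <- kept_s >= score_floor
  list(boxes = boxes[kept[keep], , drop = FALSE], scores = kept_s[keep],
       index = kept[keep])
}
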