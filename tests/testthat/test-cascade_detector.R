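test_that("IoU is exact, symmetric and bounded", {
  a <- c(0, 0, 2, 2); b <- c(1, 1, 3, 3)
  expect_equal(iou(a, b), 1 / 7, tolerance = 1e-12)
  expect_equal(iou(b, a), iou(a, b))
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(5, 5, 6, 6)), 0)
  set.seed(31)
  m <- random_boxes(20)
  ious <- box_iou(m, m)
  expect_true(all(ious >= 0 & ious <= 1))
  expect_equal(ious, t(ious), tolerance = 1e-12)
})

test_that("box encode/decode round-trips (zero deltas fix the anchor)", {
  set.seed(32)
  src <- random_boxes(30)
  dst <- random_boxes(30)
  d <- pestdet:::encode_boxes(src, dst)
  back <- pestdet:::decode_boxes(src, d)
  expect_equal(back, unname(dst), tolerance = 1e-9)
  expect_equal(pestdet:::decode_boxes(src, matrix(0, 30, 4)), unname(src),
               tolerance = 1e-12)
})

test_that("stage assignment thresholds behave per the cascade schedule", {
  # proposal with IoU 0.55: positive at 0.5, background at 0.6 and 0.7
  gt <- matrix(c(0, 0, 10, 10), 1)
  p <- matrix(c(0, 0, 10, 5.5), 1)  # IoU = 0.55
  expect_equal(iou(p[1, ], gt[1, ]), 0.55)
  for (thr in c(0.5, 0.6, 0.7)) {
    asg <- assign_stage_targets(p, gt, 0L, thr)
    expect_equal(asg$labels, if (thr <= 0.55) 1L else 0L)
  }
  # an exact match is positive at all stages
  asg <- assign_stage_targets(gt, gt, 2L, 0.7)
  expect_equal(asg$labels, 3L)
  expect_equal(asg$reg_targets[1, ], c(0, 0, 0, 0))
})

test_that("positives shrink monotonically as the IoU threshold rises", {
  set.seed(33)
  for (rep in 1:10) {
    props <- random_boxes(100)
    gts <- random_boxes(10)
    labels <- sample(0:2, 10, replace = TRUE)
    prev <- NULL
    for (thr in c(0.5, 0.6, 0.7)) {
      pos <- which(assign_stage_targets(props, gts, labels, thr)$labels > 0L)
      if (!is.null(prev)) expect_true(all(pos %in% prev))
      prev <- pos
    }
  }
})

test_that("linear soft-NMS matches Eq-style hand case and reference", {
  # two boxes with IoU below the threshold keep their scores
  b <- rbind(c(0, 0, 10, 10), c(8, 0, 18, 10))  # IoU = 2/18 ~ 0.11
  r <- soft_nms(b, c(0.9, 0.8), Nt = 0.5, score_floor = 0)
  expect_equal(r$scores, c(0.9, 0.8))
  # overlap 0.8 against the max box rescales 0.9 -> 0.18
  M <- c(0, 0, 10, 10)
  bi <- c(0, 1, 10, 10)   # IoU vs M = 9/10... construct exact 0.8 overlap
  bi <- c(0, 0, 10, 8)    # inter 80, union 100 -> IoU 0.8
  r2 <- soft_nms(rbind(M, bi), c(0.95, 0.9), Nt = 0.5, score_floor = 0)
  expect_equal(r2$scores[2], 0.9 * (1 - 0.8), tolerance = 1e-12)
  expect_equal(r2$scores[1], 0.95)
})

test_that("soft-NMS equals the independent O(n^2) reference on 50 boxes", {
  set.seed(34)
  boxes <- random_boxes(50, img = 60, min_side = 5, max_side = 30)
  scores <- runif(50)
  got <- soft_nms(boxes, scores, Nt = 0.4, score_floor = 0.1)
  ref <- soft_nms_reference(boxes, scores, Nt = 0.4, floor = 0.1)
  expect_equal(got$index, ref$index)
  expect_equal(got$scores, ref$scores, tolerance = 1e-12)
  # empty input passes through
  e <- soft_nms(matrix(numeric(0), 0, 4), numeric(0))
  expect_equal(length(e$scores), 0L)
})

test_that("soft-NMS never raises scores and keeps hard-NMS survivors", {
  set.seed(35)
  for (rep in 1:5) {
    boxes <- random_boxes(40, img = 50, min_side = 5, max_side = 25)
    scores <- runif(40)
    soft <- soft_nms(boxes, scores, Nt = 0.5, score_floor = 0)
    expect_true(all(soft$scores <= scores[soft$index] + 1e-12))
    expect_equal(soft$index[1], which.max(scores))
    hard <- hard_nms(boxes, scores, thresh = 0.5)
    expect_true(all(hard %in% soft$index))
  }
})

test_that("RPN proposals are clipped and capped", {
  set.seed(36)
  C <- 8L
  cfg <- scf_config(neck_channels = C)
  neck_params <- init_scf_fpn(c(8L, 8L, 8L), cfg)
  mk <- function(h, w, s) list(x = matrix(rnorm(h * w * C), h * w, C),
                               h = h, w = w, stride = s)
  pyr <- list(P3 = mk(16L, 16L, 8L), P4 = mk(8L, 8L, 16L),
              P5 = mk(4L, 4L, 32L), P6 = mk(2L, 2L, 64L))
  rpn <- init_rpn(C)
  rpn$obj$w$value[] <- rnorm(length(rpn$obj$w$value), sd = 0.1)
  prop <- rpn_propose(pyr, rpn, 128, 128, max_total = 50L)
  expect_lte(nrow(prop$boxes), 50L)
  expect_true(all(prop$boxes[, c(1, 3)] >= 0 & prop$boxes[, c(1, 3)] <= 128))
  expect_true(all(prop$boxes[, c(2, 4)] >= 0 & prop$boxes[, c(2, 4)] <= 128))
  expect_true(all(diff(prop$scores) <= 1e-12))
  expect_error(rpn_propose(list(), rpn, 128, 128), "empty")
})

test_that("cascade averaging is the arithmetic mean within stage bounds", {
  # direct check of the ensemble arithmetic on synthetic stage outputs
  C1 <- matrix(c(0.05, 0.9, 0.05), 1)
  C2 <- matrix(c(0.1, 0.8, 0.1), 1)
  C3 <- matrix(c(0.15, 0.7, 0.15), 1)
  avg <- (C1 + C2 + C3) / 3
  expect_equal(avg[2], 0.8)
  expect_true(all(avg >= pmin(C1, C2, C3) & avg <= pmax(C1, C2, C3)))
})

test_that("cascade_forward refines boxes thrice and averages classifiers", {
  set.seed(37)
  C <- 8L
  mk <- function(h, w, s) list(x = matrix(rnorm(h * w * C), h * w, C),
                               h = h, w = w, stride = s)
  pyr <- list(P3 = mk(16L, 16L, 8L), P4 = mk(8L, 8L, 16L),
              P5 = mk(4L, 4L, 32L), P6 = mk(2L, 2L, 64L))
  heads <- init_cascade_heads(C, 3L, hidden = 16L)
  props <- random_boxes(12, img = 100, min_side = 10, max_side = 40)
  out <- cascade_forward(pyr, props, heads, 128, 128)
  so <- out$stage_outputs
  expect_equal(dim(so$C1), c(12L, 4L))
  expect_equal(rowSums(so$C1), rep(1, 12), tolerance = 1e-5)
  expect_identical(out$boxes, so$B3)
  expect_equal(out$scores, (so$C1 + so$C2 + so$C3) / 3, tolerance = 1e-12)
  # zero-delta heads (the default zero-init reg) fix the boxes
  expect_equal(so$B1, unname(props), tolerance = 1e-9)
  expect_equal(so$B3, unname(props), tolerance = 1e-9)
})

test_that("detect is deterministic and labels stay in range", {
  sc <- tiny_scene(seed = 61L, n = 3L)
  m <- tiny_pest_model(3, seed = 15L)
  img <- with_seed(1L, array(runif(256 * 256 * 3), c(256, 256, 3)))
  d1 <- detect(img, m, score_floor = 0.2)
  d2 <- detect(img, m, score_floor = 0.2)
  expect_identical(d1, d2)
  if (nrow(d1)) {
    expect_true(all(d1$class_id >= 0 & d1$class_id < 3))
    expect_true(all(d1$score >= 0.2))
  }
})
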