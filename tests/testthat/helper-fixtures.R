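# Small shared fixtures, generated in code.

tiny_scene <- function(seed = 42L, n = 5L, n_classes = 3L) {
  generate_scene(scene_spec(width = 128L, height = 128L, n_instances = n,
                            class_weights = rep(1 / n_classes, n_classes),
                            size_range = c(12, 40), seed = seed))
}

random_boxes <- function(n, img = 100, min_side = 2, max_side = 40) {
  x1 <- stats::runif(n, 0, img - max_side)
  y1 <- stats::runif(n, 0, img - max_side)
  w <- stats::runif(n, min_side, max_side)
  h <- stats::runif(n, min_side, max_side)
  cbind(x1, y1, x1 + w, y1 + h)
}

# independent O(n^2) reference for linear soft-NMS (direct transcription of
# the greedy rescoring recurrence, kept separate from the implementation)
soft_nms_reference <- function(boxes, scores, Nt, floor) {
  n <- nrow(boxes)
  s <- scores
  active <- rep(TRUE, n)
  sel <- integer(0); sel_s <- numeric(0)
  for (step in seq_len(n)) {
    cand <- which(active)
    if (!length(cand)) break
    m <- cand[which.max(s[cand])]
    sel <- c(sel, m); sel_s <- c(sel_s, s[m])
    active[m] <- FALSE
    for (i in which(active)) {
      o <- iou(boxes[m, ], boxes[i, ])
      if (o >= Nt) s[i] <- s[i] * (1 - o)
    }
  }
  keep <- sel_s >= floor
  list(index = sel[keep], scores = sel_s[keep])
}
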