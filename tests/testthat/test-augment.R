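test_that("extract_targets crops exactly one patch per annotation", {
  sc <- tiny_scene(seed = 31L, n = 3L)
  patches <- extract_targets(sc$image, sc$annotations)
  expect_length(patches, 3L)
  expect_equal(vapply(patches, function(p) p$class_id, numeric(1)),
               sc$annotations$class_id)
  # crop arithmetic: box (10,10,20,30) -> 10 x 20 (w x h) patch
  ann <- data.frame(image_id = 1L, class_id = 0L, x1 = 10, y1 = 10,
                    x2 = 20, y2 = 30, iscrowd = 0L)
  p <- extract_targets(sc$image, ann)[[1]]
  expect_equal(dim(p$pixels)[1:2], c(20L, 10L))
  bad <- ann; bad$x2 <- bad$x1 + 0.2
  expect_error(extract_targets(sc$image, bad), "zero area")
  oob <- ann; oob$x2 <- 1e4
  expect_error(extract_targets(sc$image, oob), "bounds")
})

test_that("cut/paste round trip is pixel-exact at the source location", {
  sc <- tiny_scene(seed = 32L, n = 2L)
  a <- sc$annotations[1, ]
  p <- extract_targets(sc$image, a)[[1]]
  rb <- round(c(a$x1, a$y1, a$x2, a$y2))
  img2 <- sc$image
  img2[(rb[2] + 1):rb[4], (rb[1] + 1):rb[3], ] <- p$pixels
  expect_identical(img2, sc$image)
})

test_that("paste_targets places patches under the overlap cap", {
  bg <- with_seed(5L, render_background(160L, 160L))
  sc <- tiny_scene(seed = 33L, n = 5L)
  patches <- extract_targets(sc$image, sc$annotations)
  patches <- c(patches, patches)  # 10 pastes
  res <- paste_targets(bg, patches, rng_seed = 9L, overlap_cap = 0.2)
  expect_equal(nrow(res$annotations), 10L)
  b <- as.matrix(res$annotations[, c("x1", "y1", "x2", "y2")])
  # exhaustive pairwise IoU check
  for (i in 1:9) for (j in (i + 1):10)
    expect_lte(iou(b[i, ], b[j, ]), 0.2)
  # determinism
  res2 <- paste_targets(bg, patches, rng_seed = 9L, overlap_cap = 0.2)
  expect_identical(res, res2)
  # pasted pixels equal the (unjittered) patch inside the new box
  one <- paste_targets(bg, patches[1], rng_seed = 2L, scale_jitter = 0,
                       flip = FALSE)
  bb <- as.numeric(one$annotations[1, c("x1", "y1", "x2", "y2")])
  expect_identical(one$image[(bb[2] + 1):bb[4], (bb[1] + 1):bb[3], ],
                   patches[[1]]$pixels)
  # zero patches: background unchanged
  none <- paste_targets(bg, list(), rng_seed = 1L)
  expect_identical(none$image, bg)
  expect_equal(nrow(none$annotations), 0L)
})

test_that("balance_classes reaches per-class targets without touching originals", {
  # 3-class toy set with counts (5, 100, 200) -> target 150 gives (150, 150, 200)
  counts <- c(5L, 100L, 200L)
  spec <- scene_spec(width = 192L, height = 192L, n_instances = 8L,
                     class_weights = rep(1 / 3, 3), size_range = c(10, 24))
  ds <- generate_scenes(5, spec, seed = 44L, class_counts = counts)
  expect_equal(tabulate(ds$annotations$class_id + 1L, 3L), counts)
  bgs <- lapply(1:3, function(i) with_seed(100L + i,
                                           render_background(192L, 192L)))
  out <- balance_classes(ds, 150L, bgs, rng_seed = 6L)
  expect_equal(tabulate(out$annotations$class_id + 1L, 3L),
               c(150L, 150L, 200L))
  # original images and annotations are unchanged
  n0 <- length(ds$images)
  expect_identical(out$images[seq_len(n0)], ds$images)
  expect_identical(out$annotations[seq_len(nrow(ds$annotations)), ],
                   ds$annotations)
  # class counts never decrease
  expect_true(all(tabulate(out$annotations$class_id + 1L, 3L) >= counts))
  # all pasted boxes inside bounds
  expect_true(all(out$annotations$x2 <= 192 & out$annotations$y2 <= 192 &
                    out$annotations$x1 >= 0 & out$annotations$y1 >= 0))
})

test_that("balance_classes errors on a class with no sources", {
  spec <- scene_spec(width = 128L, height = 128L, n_instances = 4L,
                     class_weights = c(0.5, 0.5, 0), size_range = c(10, 24))
  ds <- generate_scenes(3, spec, seed = 2L)
  ds$n_classes <- 3L
  bgs <- list(with_seed(9L, render_background(128L, 128L)))
  expect_error(balance_classes(ds, 10L, bgs), "no source")
})

test_that("identity augmentation policy is bit-exact", {
  sc <- tiny_scene(seed = 51L, n = 3L)
  pol <- augment_policy(color_jitter = c(0, 0, 0, 0), mask_prob = 0,
                        noise_sigma = 0, flip_prob = 0)
  out <- online_augment(sc$image, sc$annotations, pol, rng_seed = 1L)
  expect_identical(out$image, sc$image)
  expect_identical(out$annotations, sc$annotations)
})

test_that("horizontal flip remaps x-coordinates exactly", {
  sc <- tiny_scene(seed = 52L, n = 2L)
  ann <- data.frame(image_id = 1L, class_id = 0L, x1 = 10, y1 = 5,
                    x2 = 20, y2 = 15, iscrowd = 0L)
  pol <- augment_policy(color_jitter = c(0, 0, 0, 0), mask_prob = 0,
                        noise_sigma = 0, flip_prob = 1)
  # image is 128 wide -> (10, 20) maps to (108, 118)
  out <- online_augment(sc$image, ann, pol, rng_seed = 1L)
  expect_equal(out$annotations$x1, 108)
  expect_equal(out$annotations$x2, 118)
  expect_equal(out$annotations$y1, 5)
  expect_identical(out$image[, 128:1, ], sc$image)
})

test_that("stochastic augmentations are deterministic under a fixed seed", {
  sc <- tiny_scene(seed = 53L, n = 4L)
  pol <- augment_policy(noise_sigma = 5 / 255)
  a <- online_augment(sc$image, sc$annotations, pol, rng_seed = 77L)
  b <- online_augment(sc$image, sc$annotations, pol, rng_seed = 77L)
  expect_identical(a, b)
  expect_equal(dim(a$image), dim(sc$image))
  # boxes survive any photometric policy
  expect_true(all(a$annotations$x2 <= 128 & a$annotations$x1 >= 0))
})
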