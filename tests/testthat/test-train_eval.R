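test_that("step schedule: 0.01 until epoch 80, 0.001 until 90, then 1e-4", {
  tc <- train_config()
  expect_equal(lr_at_epoch(tc, 0), 0.01)
  expect_equal(lr_at_epoch(tc, 79), 0.01)
  expect_equal(lr_at_epoch(tc, 80), 0.001)
  expect_equal(lr_at_epoch(tc, 89), 0.001)
  expect_equal(lr_at_epoch(tc, 90), 1e-4)
  expect_equal(lr_at_epoch(tc, 99), 1e-4)
  flat <- train_config(lr_gamma = 1)
  expect_true(all(vapply(c(0, 50, 99), function(e) lr_at_epoch(flat, e),
                         numeric(1)) == 0.01))
  expect_error(train_config(lr_milestones = c(80, 120)), "below epochs")
  expect_error(lr_at_epoch(tc, 100))
})

test_that("two runs with the same seed give identical loss trajectories", {
  spec <- scene_spec(width = 128L, height = 128L, n_instances = 3L,
                     class_weights = rep(1 / 3, 3), size_range = c(12, 32))
  ds <- generate_scenes(3, spec, seed = 71L)
  tc <- train_config(base_lr = 0.01, weight_decay = 1e-4, epochs = 2L,
                     batch_size = 1L, lr_milestones = 1L, input_size = 128L,
                     seed = 9L, max_iters = 4L, train_backbone = FALSE)
  m1 <- tiny_pest_model(3, seed = 5L)
  r1 <- train_detector(ds, m1, tc)
  m2 <- tiny_pest_model(3, seed = 5L)
  r2 <- train_detector(ds, m2, tc)
  expect_equal(r1$log$loss, r2$log$loss, tolerance = 1e-12)
  expect_equal(nrow(r1$log), 4L)
  # logged lr matches the schedule pointwise
  expect_equal(r1$log$lr,
               vapply(r1$log$epoch, function(e) lr_at_epoch(tc, e),
                      numeric(1)))
})

test_that("training rejects class ids beyond the model head", {
  spec <- scene_spec(width = 128L, height = 128L, n_instances = 2L,
                     class_weights = rep(1 / 4, 4), size_range = c(12, 30))
  ds <- generate_scenes(2, spec, seed = 3L)
  ds$annotations$class_id <- 3L
  m <- tiny_pest_model(2, seed = 1L)
  expect_error(train_detector(ds, m, train_config(epochs = 1L,
                                                  lr_milestones = c(),
                                                  max_iters = 1L)),
               "class ids")
})

test_that("perfect predictions score precision = recall = mAP = 1", {
  sc <- tiny_scene(seed = 81L, n = 5L)
  ann <- sc$annotations
  dets <- data.frame(image_id = ann$image_id, class_id = ann$class_id,
                     score = 0.9, x1 = ann$x1, y1 = ann$y1, x2 = ann$x2,
                     y2 = ann$y2)
  res <- evaluate_detections(dets, ann, 3L)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 1)
  expect_equal(res$map50, 1)
})

test_that("empty predictions give zero recall", {
  sc <- tiny_scene(seed = 82L, n = 4L)
  dets <- data.frame(image_id = integer(0), class_id = integer(0),
                     score = numeric(0), x1 = numeric(0), y1 = numeric(0),
                     x2 = numeric(0), y2 = numeric(0))
  res <- evaluate_detections(dets, sc$annotations, 3L)
  expect_equal(res$recall, 0)
  expect_equal(res$map50, 0)
})

test_that("AP matches a hand-computed interpolated PR curve", {
  # one class, 2 ground truths, 3 detections: hit, miss, hit
  gt <- data.frame(image_id = c(1L, 1L), class_id = 0L,
                   x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60),
                   y2 = c(10, 60), iscrowd = 0L)
  dets <- data.frame(image_id = 1L, class_id = 0L,
                     score = c(0.9, 0.8, 0.7),
                     x1 = c(0, 30, 50), y1 = c(0, 30, 50),
                     x2 = c(10, 40, 60), y2 = c(10, 40, 60))
  res <- evaluate_detections(dets, gt, 1L)
  # precision at recalls: det1 TP (p=1, r=0.5), det2 FP, det3 TP (p=2/3, r=1)
  # 101-pt AP = mean over r in 0..1 of max precision at recall >= r
  # r <= 0.5 -> 1; r > 0.5 -> 2/3  => (51 * 1 + 50 * 2/3) / 101
  expect_equal(res$map50, (51 + 50 * 2 / 3) / 101, tolerance = 1e-9)
  expect_equal(res$precision, 2 / 3)
  expect_equal(res$recall, 1)
})

test_that("evaluation is invariant to detection order at equal scores", {
  gt <- data.frame(image_id = 1L, class_id = 0L, x1 = 0, y1 = 0,
                   x2 = 10, y2 = 10, iscrowd = 0L)
  d1 <- data.frame(image_id = 1L, class_id = 0L, score = 0.5,
                   x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30),
                   y2 = c(10, 30))
  d2 <- d1[2:1, ]
  r1 <- evaluate_detections(d1, gt, 1L)
  r2 <- evaluate_detections(d2, gt, 1L)
  expect_equal(r1$map50, r2$map50)
  expect_equal(r1$precision, r2$precision)
})

test_that("checkpoint save/load round-trips weights and detections", {
  m <- tiny_pest_model(3, seed = 23L)
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  img <- with_seed(2L, array(runif(256 * 256 * 3), c(256, 256, 3)))
  expect_identical(detect(img, m, score_floor = 0.2),
                   detect(img, m2, score_floor = 0.2))
  expect_error(load_checkpoint(tempfile()), "not a valid checkpoint")
  unlink(tmp)
})

test_that("CLI inference writes results JSON and visualization", {
  m <- tiny_pest_model(3, seed = 24L)
  ck <- tempfile(fileext = ".rds"); save_checkpoint(m, ck)
  sc <- generate_scene(scene_spec(n_instances = 2L, seed = 5L,
                                  class_weights = rep(1 / 3, 3)))
  ip <- tempfile(fileext = ".png"); png::writePNG(sc$image, ip)
  oj <- tempfile(fileext = ".json"); op <- tempfile(fileext = ".png")
  d_cli <- infer(ip, ck, out_json = oj, out_png = op, score_floor = 0.2)
  expect_true(file.exists(oj) && file.exists(op))
  # CLI/API parity
  d_api <- detect(sc$image, m, score_floor = 0.2)
  expect_equal(d_cli[, c("class_id", "score", "x1", "y1", "x2", "y2")],
               d_api[, c("class_id", "score", "x1", "y1", "x2", "y2")],
               tolerance = 1e-6)
  expect_error(infer(tempfile(), ck), "unreadable image")
  bad <- tempfile(); writeLines("junk", bad)
  expect_error(infer(ip, bad), "checkpoint")
  unlink(c(ck, ip, oj, op))
})
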