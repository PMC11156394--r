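# Training: per-image multi-task loss (RPN + three cascade stages), momentum
# SGD with a step learning-rate schedule, gradient accumulation for large
# effective batches.

#' Training configuration
#'
#' Defaults follow the reference optimization schedule: momentum SGD
#' (momentum 0.9), base learning rate 0.01, weight decay 0.05, 100 epochs
#' with the rate stepped down by 0.1 at epochs 80 and 90, input 1280 px,
#' effective batch 64 (realized by gradient accumulation).
#'
#' @param base_lr initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty on weight matrices.
#' @param epochs training epochs.
#' @param batch_size effective batch size (gradient-accumulated).
#' @param lr_milestones epochs at which the rate is multiplied by `lr_gamma`.
#' @param lr_gamma step factor.
#' @param input_size nominal input side in pixels.
#' @param seed master seed for data order and augmentation.
#' @param max_iters optional hard cap on update iterations.
#' @param augment optional [augment_policy()] applied online.
#' @param grad_clip global gradient-norm clip.
#' @param stage_loss_weights per-stage loss weights.
#' @param train_backbone if `FALSE`, backbone weights stay at their
#'   initialization and per-image backbone features are cached across
#'   epochs (only neck and heads are optimized) — much faster on CPU and
#'   often sufficient to fit small scenes.
#' @param optimizer `"sgd"` (momentum SGD, the reference schedule) or
#'   `"adamw"` (decoupled weight decay; far better conditioned for short
#'   CPU runs, where a few hundred updates must span layers with very
#'   different gradient scales).
#' @param warmup_iters linear learning-rate warmup over this many updates.
#' @param head_lr_mult learning-rate multiplier for the cascade heads.
#' @param rpn_lr_mult learning-rate multiplier for the RPN (objectness over
#'   thousands of anchors tolerates and benefits from larger steps than the
#'   neck or the classification heads).
#' @param train_neck if `FALSE` (with `train_backbone = FALSE`), the neck is
#'   also frozen and per-image feature pyramids are cached, so an update
#'   touches only the RPN and cascade heads. The heads then face a
#'   stationary feature distribution, which makes very short training
#'   budgets far more effective.
#' @param roi_replay if `TRUE` (requires a frozen pyramid), pooled ROI
#'   features of each visited image are kept in a replay buffer and every
#'   update trains the cascade heads on the whole buffer rather than only
#'   the current image's handful of proposals. With features frozen the
#'   cached activations stay exact, so this turns the head optimization
#'   into near-full-batch learning and makes a few hundred updates go a
#'   long way. The RPN still trains on the current image.
#' @param rpn_images_per_step in replay mode, how many cached images
#'   contribute to each RPN update (anchor losses over cached pyramids are
#'   cheap, and a larger RPN batch sharpens objectness ranking).
#' @param reg_loss_mult extra multiplier on the cascade box-regression
#'   losses; raising it sharpens localization when classification is
#'   already easy (e.g. strongly color-coded targets).
#' @return a `train_config` list.
#' @export
train_config <- function(base_lr = 0.01, momentum = 0.9, weight_decay = 0.05,
                         epochs = 100L, batch_size = 64L,
                         lr_milestones = c(80L, 90L), lr_gamma = 0.1,
                         input_size = 1280L, seed = 1L, max_iters = NULL,
                         augment = NULL, grad_clip = 5,
                         stage_loss_weights = c(1, 0.5, 0.25),
                         train_backbone = TRUE,
                         optimizer = c("sgd", "adamw"),
                         warmup_iters = 0L, head_lr_mult = 1,
                         rpn_lr_mult = head_lr_mult, train_neck = TRUE,
                         roi_replay = FALSE, rpn_images_per_step = 12L,
                         reg_loss_mult = 1) {
  optimizer <- match.arg(optimizer)
  if (!train_neck && train_backbone)
    stopf("train_neck = FALSE requires train_backbone = FALSE")
  if (roi_replay && train_neck)
    stopf("roi_replay requires a frozen pyramid (train_neck = FALSE)")
  if (any(lr_milestones >= epochs))
    stopf("lr_milestones must be below epochs")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(base_lr = base_lr, momentum = momentum,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_milestones = as.integer(lr_milestones),
                 lr_gamma = lr_gamma, input_size = as.integer(input_size),
                 seed = as.integer(seed), max_iters = max_iters,
                 augment = augment, grad_clip = grad_clip,
                 stage_loss_weights = stage_loss_weights,
                 train_backbone = isTRUE(train_backbone),
                 optimizer = optimizer,
                 warmup_iters = as.integer(warmup_iters),
                 head_lr_mult = head_lr_mult, rpn_lr_mult = rpn_lr_mult,
                 train_neck = isTRUE(train_neck),
                 roi_replay = isTRUE(roi_replay),
                 rpn_images_per_step = as.integer(rpn_images_per_step),
                 reg_loss_mult = reg_loss_mult),
            class = "train_config")
}

#' Learning rate at a given (0-based) epoch
#'
#' `base_lr * lr_gamma ^ (number of milestones <= epoch)`.
#'
#' @param config a [train_config()].
#' @param epoch 0-based epoch index in `[0, epochs)`.
#' @return numeric learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot(epoch >= 0, epoch < config$epochs)
  config$base_lr * config$lr_gamma ^ sum(config$lr_milestones <= epoch)
}

# ---- loss -------------------------------------------------------------------

# Jittered copies of GT boxes guarantee positive proposals at every stage
# and, with a range of jitter amplitudes, teach the regression heads to pull
# moderately misplaced boxes (IoU roughly 0.4-0.9) onto the target — the
# correction the cascade must apply to real proposals.
jitter_gt <- function(gt, img_w, img_h, n_per = 6L, frac = 0.25) {
  if (nrow(gt) == 0 || n_per == 0) return(matrix(numeric(0), 0, 4))
  out <- do.call(rbind, lapply(seq_len(n_per), function(k) {
    f <- frac * k / n_per
    w <- gt[, 3] - gt[, 1]; h <- gt[, 4] - gt[, 2]
    d <- matrix(stats::runif(4 * nrow(gt), -f, f), ncol = 4)
    cbind(gt[, 1] + d[, 1] * w, gt[, 2] + d[, 2] * h,
          gt[, 3] + d[, 3] * w, gt[, 4] + d[, 4] * h)
  }))
  clip_boxes(out, img_w, img_h)
}

# RPN-only loss for one image (balanced objectness + positive-anchor
# regression); shared by the standard and replay training paths.
rpn_image_loss <- function(model, pyr, gt_boxes) {
  anchors <- pyramid_anchors(pyr, model$n_anchors)
  rpn_obj <- list(); rpn_reg <- list()
  for (l in seq_along(pyr)) {
    hd <- rpn_head_level(pyr[[l]], model$params$rpn, model$n_anchors)
    rpn_obj[[l]] <- hd$obj
    rpn_reg[[l]] <- hd$reg
  }
  obj_all <- do.call(ag_rbind, rpn_obj)
  reg_all <- do.call(ag_rbind, rpn_reg)
  anch_all <- do.call(rbind, anchors)
  asg <- assign_rpn_targets(anch_all, gt_boxes)
  pos <- which(asg$labels == 1L)
  neg <- which(asg$labels == 0L)
  nb <- length(pos) + length(neg)
  wts <- numeric(nb)
  if (length(pos)) wts[seq_along(pos)] <- 0.5 / length(pos)
  if (length(neg)) wts[length(pos) + seq_along(neg)] <-
    (if (length(pos)) 0.5 else 1) / length(neg)
  loss_obj <- ag_bce_logits(ag_gather_rows(obj_all, c(pos, neg)),
                            c(rep(1, length(pos)), rep(0, length(neg))),
                            weights = wts)
  loss_reg <- if (length(pos)) {
    tgt <- encode_boxes(anch_all[pos, , drop = FALSE],
                        gt_boxes[asg$matched[pos], , drop = FALSE])
    ag_smooth_l1(ag_gather_rows(reg_all, pos), tgt, beta = 1 / 9)
  } else NULL
  list(obj = loss_obj, reg = loss_reg)
}

# Replay-buffer training step: refresh this image's cached ROI features and
# per-stage targets, then compute the cascade-head loss over the whole
# buffer. Requires a frozen (plain) pyramid so cached activations stay
# exact. All three stage heads are trained on the shared proposal set with
# their own assignment thresholds; box-refinement chaining still happens at
# inference.
# refresh one image's replay entry: current RPN proposals + GT + jitters
replay_fill <- function(model, pyr, gt_boxes, gt_labels, buffer, ix,
                        img_w, img_h) {
  prop <- rpn_propose(pyr, model$params$rpn, img_w, img_h,
                      pre_nms = 400L, post_nms = 64L, max_total = 64L)
  boxes <- rbind(prop$boxes, gt_boxes, jitter_gt(gt_boxes, img_w, img_h))
  entry <- list(
    pooled = ag_value(roi_pool(pyr, boxes)),
    stages = lapply(seq_along(model$cascade$iou_thresholds), function(s)
      assign_stage_targets(boxes, gt_boxes, gt_labels,
                           model$cascade$iou_thresholds[s],
                           stage_reg_wts(s))))
  buffer[[as.character(ix)]] <- entry
  entry
}

replay_step <- function(model, pyr, gt_boxes, gt_labels, tcfg, buffer, ix,
                        img_w, img_h, max_rows = 2500L) {
  replay_fill(model, pyr, gt_boxes, gt_labels, buffer, ix, img_w, img_h)
  keys <- as.character(sort(as.integer(ls(buffer))))  # deterministic order
  entries <- lapply(keys, function(k) buffer[[k]])
  P <- do.call(rbind, lapply(entries, `[[`, "pooled"))
  n <- nrow(P)
  sel <- if (n > max_rows) sample.int(n, max_rows) else seq_len(n)
  Pn <- new_node(P[sel, , drop = FALSE])
  total <- NULL
  comp <- c()
  swt <- tcfg$stage_loss_weights
  for (s in seq_along(model$params$heads)) {
    labels <- unlist(lapply(entries, function(e) e$stages[[s]]$labels))[sel]
    regs <- do.call(rbind, lapply(entries, function(e)
      e$stages[[s]]$reg_targets))[sel, , drop = FALSE]
    out <- stage_head_fwd(Pn, model$params$heads[[s]])
    l_cls <- ag_softmax_ce(out$cls, labels + 1L)
    term <- ag_scale(l_cls, swt[s])
    posr <- which(labels > 0L)
    l_reg <- NULL
    if (length(posr)) {
      l_reg <- ag_smooth_l1(ag_gather_rows(out$reg, posr),
                            regs[posr, , drop = FALSE], beta = 1)
      term <- ag_add(term, ag_scale(l_reg, swt[s] * (tcfg$reg_loss_mult %||% 1)))
    }
    total <- if (is.null(total)) term else ag_add(total, term)
    comp[paste0("s", s, "_cls")] <- ag_value(l_cls)
    comp[paste0("s", s, "_reg")] <- if (is.null(l_reg)) 0 else ag_value(l_reg)
  }
  list(loss = total, components = comp)
}

# multi-task loss for one image; returns the scalar loss node + components.
# feats / pyr_pre: optional precomputed (plain) backbone features or full
# feature pyramid.
detector_loss <- function(model, image, gt_boxes, gt_labels, tcfg,
                          feats = NULL, pyr_pre = NULL) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (is.null(pyr_pre)) {
    if (is.null(feats))
      feats <- forward_backbone(image, model$params$backbone, model$backbone,
                                train = isTRUE(tcfg$train_backbone))
    pyr <- forward_neck(feats, model$params$neck, model$neck,
                        train = isTRUE(tcfg$train_neck %||% TRUE))
  } else {
    pyr <- pyr_pre
  }
  # ---- RPN loss over all labelled anchors
  anchors <- pyramid_anchors(pyr, model$n_anchors)
  rpn_obj <- list(); rpn_reg <- list()
  for (l in seq_along(pyr)) {
    hd <- rpn_head_level(pyr[[l]], model$params$rpn, model$n_anchors)
    rpn_obj[[l]] <- hd$obj
    rpn_reg[[l]] <- hd$reg
  }
  obj_all <- do.call(ag_rbind, rpn_obj)
  reg_all <- do.call(ag_rbind, rpn_reg)
  anch_all <- do.call(rbind, anchors)
  asg <- assign_rpn_targets(anch_all, gt_boxes)
  pos <- which(asg$labels == 1L)
  neg <- which(asg$labels == 0L)
  # balanced objectness loss over all labelled anchors (mean of means)
  nb <- length(pos) + length(neg)
  wts <- numeric(nb)
  if (length(pos)) wts[seq_along(pos)] <- 0.5 / length(pos)
  if (length(neg)) wts[length(pos) + seq_along(neg)] <-
    (if (length(pos)) 0.5 else 1) / length(neg)
  sel <- c(pos, neg)
  loss_obj <- ag_bce_logits(ag_gather_rows(obj_all, sel),
                            c(rep(1, length(pos)), rep(0, length(neg))),
                            weights = wts)
  loss_rpn_reg <- if (length(pos)) {
    tgt <- encode_boxes(anch_all[pos, , drop = FALSE],
                        gt_boxes[asg$matched[pos], , drop = FALSE])
    ag_smooth_l1(ag_gather_rows(reg_all, pos), tgt, beta = 1 / 9)
  } else 0
  # ---- proposals for the cascade (detached RPN output + jittered GT)
  pyr_det <- lapply(pyr, function(p) { p$x <- ag_detach(p$x); p })
  prop <- rpn_propose(pyr_det, model$params$rpn, w, h,
                      pre_nms = 400L, post_nms = 64L, max_total = 64L)
  proposals <- rbind(prop$boxes, gt_boxes, jitter_gt(gt_boxes, w, h))
  stage_losses <- list()
  swt <- tcfg$stage_loss_weights
  total <- ag_add(loss_obj, if (is.numeric(loss_rpn_reg)) 0 else loss_rpn_reg)
  if (is.numeric(loss_rpn_reg)) total <- loss_obj
  comp <- c(obj = ag_value(loss_obj),
            rpn_reg = if (is.numeric(loss_rpn_reg)) 0 else ag_value(loss_rpn_reg))
  for (s in seq_along(model$params$heads)) {
    thr <- model$cascade$iou_thresholds[s]
    asg_s <- assign_stage_targets(proposals, gt_boxes, gt_labels, thr,
                                  reg_wts = stage_reg_wts(s))
    pooled <- roi_pool(pyr, proposals)
    out <- stage_head_fwd(pooled, model$params$heads[[s]])
    target <- asg_s$labels + 1L  # 1 = background column
    l_cls <- ag_softmax_ce(out$cls, target)
    posr <- which(asg_s$labels > 0L)
    l_reg <- if (length(posr)) {
      ag_smooth_l1(ag_gather_rows(out$reg, posr),
                   asg_s$reg_targets[posr, , drop = FALSE], beta = 1)
    } else NULL
    total <- ag_add(total, ag_scale(l_cls, swt[s]))
    if (!is.null(l_reg)) total <- ag_add(total, ag_scale(l_reg, swt[s]))
    comp[paste0("s", s, "_cls")] <- ag_value(l_cls)
    comp[paste0("s", s, "_reg")] <- if (is.null(l_reg)) 0 else ag_value(l_reg)
    # next stage refines this stage's (detached) boxes
    proposals <- clip_boxes(decode_boxes(proposals, ag_value(out$reg),
                                         stage_reg_wts(s)), w, h)
  }
  list(loss = total, components = comp)
}

# ---- optimizer --------------------------------------------------------------

optim_update <- function(params_flat, lr, cfg, micro = 1L) {
  # average accumulated micro-batch gradients, then clip by global norm
  sq <- 0
  for (p in params_flat) if (!is.null(p$grad)) {
    p$grad <- p$grad / micro
    sq <- sq + sum(p$grad^2)
  }
  gn <- sqrt(sq)
  scale <- if (cfg$grad_clip > 0 && gn > cfg$grad_clip) cfg$grad_clip / gn
  else 1
  for (p in params_flat) {
    if (is.null(p$grad)) next
    lr_p <- lr * (p$lr_mult %||% 1)
    g <- p$grad * scale
    decay_this <- cfg$weight_decay > 0 && !is.null(dim(p$value))
    if (cfg$optimizer == "sgd") {
      if (decay_this) g <- g + cfg$weight_decay * p$value
      p$m <- if (is.null(p$m)) g else cfg$momentum * p$m + g
      p$value <- p$value - lr_p * p$m
    } else {  # adamw, decoupled decay
      p$t <- (p$t %||% 0L) + 1L
      p$m <- if (is.null(p$m)) 0.1 * g else 0.9 * p$m + 0.1 * g
      p$v <- if (is.null(p$v)) 0.001 * g * g else 0.999 * p$v + 0.001 * g * g
      mhat <- p$m / (1 - 0.9^p$t)
      vhat <- p$v / (1 - 0.999^p$t)
      upd <- mhat / (sqrt(vhat) + 1e-8)
      if (decay_this) upd <- upd + cfg$weight_decay * p$value
      p$value <- p$value - lr_p * upd
    }
    p$grad <- NULL
  }
  gn
}

#' Train a detector
#'
#' Iterates over the dataset image by image (micro-batch 1), accumulating
#' gradients to the configured effective batch size, with momentum SGD and
#' the step schedule of [lr_at_epoch()]. Fully seeded: data order,
#' augmentation and any sampling derive from `config$seed`, so two runs with
#' the same seed produce identical loss trajectories.
#'
#' @param dataset a `pest_dataset` with images in memory.
#' @param model a `pest_model` (updated in place and returned).
#' @param config a [train_config()].
#' @param log_path optional JSONL file receiving one record per iteration.
#' @param verbose print progress lines.
#' @return list: `model`, `log` (data.frame of per-iteration loss components
#'   and learning rate).
#' @export
train_detector <- function(dataset, model, config = train_config(),
                           log_path = NULL, verbose = FALSE) {
  ann <- dataset$annotations
  if (max(ann$class_id, na.rm = TRUE) >= model$n_classes)
    stopf("dataset has class ids >= model n_classes (%d)", model$n_classes)
  trained <- if (config$train_backbone) c("backbone", "neck", "rpn", "heads")
  else if (config$train_neck) c("neck", "rpn", "heads")
  else c("rpn", "heads")
  params_flat <- collect_params(model$params[trained])
  for (nm in names(params_flat)) {
    if (startsWith(nm, "heads.") && config$head_lr_mult != 1)
      params_flat[[nm]]$lr_mult <- config$head_lr_mult
    if (startsWith(nm, "rpn.") && config$rpn_lr_mult != 1)
      params_flat[[nm]]$lr_mult <- config$rpn_lr_mult
  }
  n_img <- length(dataset$images)
  replay_buf <- if (config$roi_replay) new.env(parent = emptyenv())
  feat_cache <- NULL; pyr_cache <- NULL
  if (!config$train_backbone && is.null(config$augment)) {
    feat_cache <- lapply(dataset$images, function(im)
      forward_backbone(im, model$params$backbone, model$backbone,
                       train = FALSE))
    if (!config$train_neck) {
      pyr_cache <- lapply(feat_cache, function(f)
        forward_neck(f, model$params$neck, model$neck, train = FALSE))
      feat_cache <- NULL
      if (config$roi_replay) {
        # prefill the ROI replay buffer so the first updates already see
        # every image's proposals (anchor-derived boxes + jittered GT)
        for (j in seq_len(n_img)) {
          aj <- dataset$annotations[dataset$annotations$image_id == j, ,
                                    drop = FALSE]
          gbj <- as.matrix(aj[, c("x1", "y1", "x2", "y2"), drop = FALSE])
          with_seed(config$seed + 7919L * j, {
            d <- dim(dataset$images[[j]])
            invisible(replay_fill(model, pyr_cache[[j]], gbj, aj$class_id,
                                  replay_buf, j, d[2], d[1]))
          })
        }
      }
    }
  }
  micro_per_step <- max(1L, min(config$batch_size, n_img))
  logs <- list()
  iter <- 0L
  done <- FALSE
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(config, epoch)
    order_ep <- with_seed(config$seed + epoch * 131L, sample.int(n_img))
    micro <- 0L
    for (ix in order_ep) {
      img <- dataset$images[[ix]]
      a <- ann[ann$image_id == ix, , drop = FALSE]
      if (!is.null(config$augment)) {
        aug <- online_augment(img, a, config$augment,
                              rng_seed = config$seed + iter * 7L + ix)
        img <- aug$image; a <- aug$annotations
      }
      gt_boxes <- as.matrix(a[, c("x1", "y1", "x2", "y2"), drop = FALSE])
      gt_labels <- a$class_id
      res <- with_seed(config$seed + 100003L * iter + ix, {
        if (config$roi_replay) {
          extra <- setdiff(seq_len(n_img), ix)
          k <- min(length(extra), config$rpn_images_per_step - 1L)
          rpn_imgs <- c(ix, if (k > 0L) sample(extra, k))
          loss <- NULL; obj_v <- 0; reg_v <- 0
          for (j in rpn_imgs) {
            aj <- ann[ann$image_id == j, , drop = FALSE]
            gbj <- as.matrix(aj[, c("x1", "y1", "x2", "y2"), drop = FALSE])
            rl <- rpn_image_loss(model, pyr_cache[[j]], gbj)
            term <- ag_scale(rl$obj, 1 / length(rpn_imgs))
            if (!is.null(rl$reg))
              term <- ag_add(term, ag_scale(rl$reg, 1 / length(rpn_imgs)))
            loss <- if (is.null(loss)) term else ag_add(loss, term)
            obj_v <- obj_v + ag_value(rl$obj) / length(rpn_imgs)
            reg_v <- reg_v + (if (is.null(rl$reg)) 0 else ag_value(rl$reg)) /
              length(rpn_imgs)
          }
          rp <- replay_step(model, pyr_cache[[ix]], gt_boxes, gt_labels,
                            config, replay_buf, ix,
                            dim(img)[2], dim(img)[1])
          loss <- ag_add(loss, rp$loss)
          list(loss = loss,
               components = c(obj = obj_v, rpn_reg = reg_v, rp$components))
        } else {
          detector_loss(model, img, gt_boxes, gt_labels, config,
                        feats = if (is.null(feat_cache)) NULL
                                else feat_cache[[ix]],
                        pyr_pre = if (is.null(pyr_cache)) NULL
                                  else pyr_cache[[ix]])
        }
      })
      ag_backward(res$loss)
      micro <- micro + 1L
      if (micro >= micro_per_step) {
        iter <- iter + 1L
        lr_eff <- if (config$warmup_iters > 0L && iter <= config$warmup_iters)
          lr * iter / config$warmup_iters else lr
        gn <- optim_update(params_flat, lr_eff, config, micro = micro)
        rec <- c(list(iter = iter, epoch = epoch, lr = lr,
                      loss = sum(res$components), grad_norm = gn),
                 as.list(res$components))
        logs[[length(logs) + 1L]] <- rec
        if (!is.null(log_path))
          cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6), "\n",
              file = log_path, append = TRUE)
        if (verbose && iter %% 10L == 0L)
          message(sprintf("iter %d epoch %d lr %.4g loss %.4f",
                          iter, epoch, lr, sum(res$components)))
        micro <- 0L
        if (!is.null(config$max_iters) && iter >= config$max_iters) {
          done <- TRUE
          break
        }
      }
    }
    if (done) break
  }
  log_df <- do.call(rbind, lapply(logs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  list(model = model, log = log_df)
}
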