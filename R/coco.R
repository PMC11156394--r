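# COCO JSON serialization. Internal box convention is 0-based continuous
# corners (x1, y1, x2, y2); the COCO (x, y, w, h) dialect exists only here.

#' Write a dataset's annotations as COCO JSON
#'
#' @param dataset a `pest_dataset` (see [generate_scenes()]).
#' @param path output JSON path.
#' @param file_names optional per-image file names recorded in the `images`
#'   section.
#' @return invisibly, `path`.
#' @export
write_coco <- function(dataset, path, file_names = NULL) {
  n_img <- length(dataset$images)
  file_names <- file_names %||% sprintf("img_%05d.png", seq_len(n_img))
  images <- lapply(seq_len(n_img), function(i) {
    im <- dataset$images[[i]]
    list(id = i, file_name = file_names[i],
         width = dim(im)[2], height = dim(im)[1])
  })
  ann <- dataset$annotations
  annotations <- lapply(seq_len(nrow(ann)), function(k) {
    a <- ann[k, ]
    list(id = k, image_id = a$image_id, category_id = a$class_id + 1L,
         bbox = c(a$x1, a$y1, a$x2 - a$x1, a$y2 - a$y1),
         area = (a$x2 - a$x1) * (a$y2 - a$y1), iscrowd = a$iscrowd)
  })
  categories <- lapply(seq_len(dataset$n_classes), function(c)
    list(id = c, name = sprintf("class_%02d", c - 1L), supercategory = "pest"))
  obj <- list(images = images, annotations = annotations,
              categories = categories)
  ok <- tryCatch({
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("failed to write COCO JSON to %s", path)
  invisible(path)
}

#' Read a COCO JSON dataset
#'
#' @param path JSON path.
#' @param image_dir optional directory containing the referenced PNG files;
#'   when given, images are loaded into memory.
#' @return a `pest_dataset`; `images` holds arrays when `image_dir` is given,
#'   otherwise the file names.
#' @export
read_coco <- function(path, image_dir = NULL) {
  if (!file.exists(path)) stopf("COCO JSON not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cat_ids <- vapply(obj$categories, function(c) as.integer(c$id), integer(1))
  n_classes <- length(cat_ids)
  id_to_class <- stats::setNames(seq_along(sort(cat_ids)) - 1L,
                                 as.character(sort(cat_ids)))
  img_ids <- vapply(obj$images, function(x) as.integer(x$id), integer(1))
  id_to_index <- stats::setNames(seq_along(img_ids), as.character(img_ids))
  ann <- do.call(rbind, lapply(obj$annotations, function(a) {
    bb <- as.numeric(unlist(a$bbox))
    data.frame(image_id = id_to_index[[as.character(a$image_id)]],
               class_id = id_to_class[[as.character(a$category_id)]],
               x1 = bb[1], y1 = bb[2], x2 = bb[1] + bb[3], y2 = bb[2] + bb[4],
               iscrowd = as.integer(a$iscrowd %||% 0L))
  })) %||% data.frame(image_id = integer(0), class_id = integer(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), iscrowd = integer(0))
  images <- lapply(obj$images, function(x) x$file_name)
  if (!is.null(image_dir)) {
    images <- lapply(images, function(fn) {
      p <- file.path(image_dir, fn)
      if (!file.exists(p)) stopf("image file missing: %s", p)
      im <- png::readPNG(p)
      if (length(dim(im)) == 2L) im <- array(rep(im, 3), c(dim(im), 3))
      im[, , 1:3, drop = FALSE]
    })
  }
  structure(list(images = images, annotations = ann, n_classes = n_classes),
            class = "pest_dataset")
}

#' Write detection results as COCO results JSON
#'
#' @param detections data.frame with `image_id`, `class_id`, `x1`, `y1`,
#'   `x2`, `y2`, `score`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_coco_results <- function(detections, path) {
  res <- lapply(seq_len(nrow(detections)), function(k) {
    d <- detections[k, ]
    list(image_id = d$image_id, category_id = d$class_id + 1L,
         bbox = c(d$x1, d$y1, d$x2 - d$x1, d$y2 - d$y1), score = d$score)
  })
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
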