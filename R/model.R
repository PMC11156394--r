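# Model assembly and checkpointing.

#' Build a detector model
#'
#' @param n_classes number of foreground classes.
#' @param backbone a [backbone_config()].
#' @param neck an [scf_config()].
#' @param cascade a [cascade_config()].
#' @param head_hidden hidden width of the cascade head MLPs.
#' @param n_anchors anchors per pyramid location.
#' @param seed seed for weight initialization (truncated normal, sd 0.02).
#' @return a `pest_model`: configs plus nested parameter list (`$params`
#'   with `backbone`, `neck`, `rpn`, `heads`).
#' @export
pest_model <- function(n_classes, backbone = backbone_config(),
                       neck = scf_config(), cascade = cascade_config(),
                       head_hidden = 256L, n_anchors = 9L, seed = 1L) {
  C <- neck$neck_channels
  in_ch <- backbone$embed_dim * c(2L, 4L, 8L)
  params <- with_seed(seed, list(
    backbone = init_backbone(backbone),
    neck = init_scf_fpn(in_ch, neck),
    rpn = init_rpn(C, n_anchors),
    heads = init_cascade_heads(C, n_classes, hidden = head_hidden)))
  structure(list(n_classes = as.integer(n_classes), backbone = backbone,
                 neck = neck, cascade = cascade,
                 head_hidden = as.integer(head_hidden),
                 n_anchors = as.integer(n_anchors), seed = as.integer(seed),
                 params = params),
            class = "pest_model")
}

#' A small CPU-friendly model profile
#'
#' Tiny backbone (width 32, depths 2/2/2/2, window 4), 64-channel neck and
#' 128-wide heads; suitable for quick experiments and tests on 256 px scenes.
#'
#' @param n_classes number of foreground classes.
#' @param seed weight-init seed.
#' @param ... overrides passed to [pest_model()].
#' @return a `pest_model`.
#' @export
tiny_pest_model <- function(n_classes, seed = 1L, ...) {
  pest_model(n_classes,
             backbone = backbone_config(profile = "tiny"),
             neck = scf_config(neck_channels = 64L),
             head_hidden = 128L, seed = seed, ...)
}

#' Save model weights and configuration to a checkpoint file
#' @param model a `pest_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  values <- detach_params(model$params)
  obj <- list(n_classes = model$n_classes, backbone = model$backbone,
              neck = model$neck, cascade = model$cascade,
              head_hidden = model$head_hidden, n_anchors = model$n_anchors,
              seed = model$seed, values = values, format = 1L)
  saveRDS(obj, path)
  invisible(path)
}

# rebuild parameter nodes from plain values
values_to_params <- function(x) {
  if (is.numeric(x)) return(ag_param(x))
  if (is.list(x)) return(lapply(x, values_to_params))
  x
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file.
#' @return a `pest_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, 1L))
    stopf("not a valid checkpoint: %s", path)
  structure(list(n_classes = obj$n_classes, backbone = obj$backbone,
                 neck = obj$neck, cascade = obj$cascade,
                 head_hidden = obj$head_hidden, n_anchors = obj$n_anchors,
                 seed = obj$seed, params = values_to_params(obj$values)),
            class = "pest_model")
}
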