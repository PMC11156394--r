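# Neighborhood-autocorrelation feature enhancement neck.
#
# Per backbone level: a 1x1 channel reduction to the neck width C, a
# Neighborhood Block that unfolds a sliding (U, V) window around every pixel
#   R[i,j,u,v,] = X[i + u - ctr, j + v - ctr, ]      (zero padded)
# and multiplies it elementwise against the broadcast center feature to form
# the autocorrelation tensor D (C' = U*V*C channels), an Embedding Block
#   G = [X; D],  I = conv1x1(G),  I' = conv1x1(I),  A = X + I'
# and a 3x3 output convolution. The enhanced maps are fused top-down into a
# feature pyramid P3-P6.

#' Neck configuration
#'
#' @param neck_channels per-level reduced channel count C.
#' @param windows list of three `(U, V)` window sides for feat1/feat2/feat3;
#'   all sides odd. Defaults `(7,7)/(5,5)/(3,3)`: larger windows on the
#'   high-resolution map where targets are small, smaller windows on the
#'   coarse map. Override with a uniform window to reproduce the
#'   window-size ablation axes.
#' @return an `scf_config` list.
#' @export
scf_config <- function(neck_channels = 256L,
                       windows = list(c(7L, 7L), c(5L, 5L), c(3L, 3L))) {
  stopifnot(neck_channels >= 1, length(windows) == 3)
  for (wv in windows)
    if (any(wv %% 2L == 0L) || any(wv < 1L))
      stopf("window sides must be odd and >= 1 (got %s)",
            paste(wv, collapse = "x"))
  structure(list(neck_channels = as.integer(neck_channels),
                 windows = lapply(windows, as.integer)),
            class = "scf_config")
}

# tap-offset gather index for a (U, V) neighborhood, zero padded (idx 0).
# tap order: "u_outer" = u slowest, v middle, i.e. tap t = (u-1)*V + v.
unfold_idx <- function(h, w, U, V) {
  cache_get(sprintf("unf_%d_%d_%d_%d", h, w, U, V), function() {
    cu <- (U + 1L) %/% 2L; cv <- (V + 1L) %/% 2L
    ii <- rep(seq_len(h), times = w)
    jj <- rep(seq_len(w), each = h)
    idx <- integer(h * w * U * V)
    t0 <- 0L
    for (u in seq_len(U)) for (v in seq_len(V)) {
      i2 <- ii + (u - cu); j2 <- jj + (v - cv)
      ok <- i2 >= 1L & i2 <= h & j2 >= 1L & j2 <= w
      vv <- integer(h * w)
      vv[ok] <- i2[ok] + h * (j2[ok] - 1L)
      idx[(t0 * h * w + 1L):((t0 + 1L) * h * w)] <- vv
      t0 <- t0 + 1L
    }
    idx
  })
}

# internal: (H*W) x (U*V*C) regional tensor, columns ordered u outer, v
# inner, channels fastest (c + C*(v-1) + C*V*(u-1)); works on nodes.
# one gather per tap + cbind keeps memory traffic linear (no transposes).
neighborhood_unfold_flat <- function(x, h, w, U, V) {
  idx <- unfold_idx(h, w, U, V)
  hw <- h * w
  taps <- lapply(seq_len(U * V), function(t)
    ag_gather_rows(x, idx[((t - 1L) * hw + 1L):(t * hw)]))
  do.call(ag_cbind, taps)
}

#' Reduce a feature map's channels with a 1x1 projection
#'
#' @param feat (H*W) x Cin matrix/node.
#' @param params `list(w, b)` with Cin x C weight.
#' @return (H*W) x C matrix/node.
#' @export
reduce_channels <- function(feat, params) linear_fwd(feat, params)

#' Sliding-window neighborhood unfold (regional tensor R)
#'
#' @param X H x W x C array.
#' @param U,V odd window sides.
#' @return H x W x U x V x C array; out-of-bounds neighbours are zero.
#' @export
neighborhood_unfold <- function(X, U, V) {
  if (U %% 2L == 0L || V %% 2L == 0L)
    stopf("window sides must be odd (center undefined for %dx%d)", U, V)
  d <- dim(X)
  h <- d[1]; w <- d[2]; C <- d[3]
  flat <- neighborhood_unfold_flat(matrix(X, h * w, C), h, w, U, V)
  # columns are (c fastest, v, u); rearrange to H x W x U x V x C
  arr <- array(flat, c(h, w, C, V, U))
  aperm(arr, c(1L, 2L, 5L, 4L, 3L))
}

#' Autocorrelation tensor D from the regional tensor and center features
#'
#' Elementwise (Hadamard) product of R against the center feature broadcast
#' over the window axes, flattened to C' = U*V*C channels with u outermost,
#' then v, channels fastest.
#'
#' @param R H x W x U x V x C array from [neighborhood_unfold()].
#' @param X H x W x C array.
#' @return H x W x C' array.
#' @export
autocorrelation <- function(R, X) {
  d <- dim(R)
  h <- d[1]; w <- d[2]; U <- d[3]; V <- d[4]; C <- d[5]
  D <- array(0, c(h, w, U * V * C))
  for (u in seq_len(U)) for (v in seq_len(V)) {
    sl <- ((u - 1L) * V * C + (v - 1L) * C + 1L):((u - 1L) * V * C + v * C)
    D[, , sl] <- R[, , u, v, ] * X
  }
  D
}

#' Embedding Block: fuse center and autocorrelation features
#'
#' `G = [X; D]` (channel concatenation, X first), compressed and refined by
#' two 1x1 projections, then added back to X: `A = X + I'`. The second
#' projection is zero-initialized by default so the block is an exact
#' identity at initialization.
#'
#' @param X (H*W) x C matrix/node.
#' @param D (H*W) x C' matrix/node.
#' @param params `list(i1, i2)` of linear parameter pairs
#'   ((C + C') x C and C x C).
#' @return A, (H*W) x C matrix/node (same shape as X).
#' @export
embed_fuse <- function(X, D, params) {
  G <- ag_cbind(X, D)
  I1 <- linear_fwd(G, params$i1)
  I2 <- linear_fwd(I1, params$i2)
  ag_add(X, I2)
}

#' Full per-level enhancement: reduce, unfold, autocorrelate, fuse, smooth
#'
#' @param feat feature map list (`x`, `h`, `w`) from the backbone.
#' @param params per-level neck parameters (see [init_scf_fpn()]).
#' @param window `(U, V)` window sides for this level.
#' @return enhanced (H*W) x C matrix/node.
#' @export
scf_enhance <- function(feat, params, window) {
  X <- reduce_channels(feat$x, params$reduce)
  C <- ncol(ag_value(X))
  U <- window[1]; V <- window[2]
  R <- neighborhood_unfold_flat(X, feat$h, feat$w, U, V)
  Xrep <- ag_tile_cols(X, U * V)
  D <- ag_mul(R, Xrep)
  A <- embed_fuse(X, D, params)
  conv_fwd(A, params$out3, feat$h, feat$w, 3L)
}

#' Top-down feature pyramid from the three enhanced maps
#'
#' `P5 = A3`, `P4 = A2 + up2(P5)`, `P3 = A1 + up2(P4)`, each merged map
#' passed through a 3x3 smoothing convolution; `P6` is a stride-2 max pool
#' of P5.
#'
#' @param A1,A2,A3 enhanced maps (lists with `x`, `h`, `w`) at strides
#'   8/16/32, equal channels.
#' @param params pyramid smoothing parameters (see [init_scf_fpn()]).
#' @return list of four feature maps `P3`..`P6` (each `x`, `h`, `w`,
#'   `stride`).
#' @export
build_pyramid <- function(A1, A2, A3, params) {
  m5 <- A3$x
  m4 <- ag_add(A2$x, upsample2_fwd(m5, A3$h, A3$w))
  m3 <- ag_add(A1$x, upsample2_fwd(m4, A2$h, A2$w))
  p5 <- conv_fwd(m5, params$s5, A3$h, A3$w, 3L)
  p4 <- conv_fwd(m4, params$s4, A2$h, A2$w, 3L)
  p3 <- conv_fwd(m3, params$s3, A1$h, A1$w, 3L)
  p6 <- maxpool2_fwd(p5, A3$h, A3$w)
  list(P3 = list(x = p3, h = A1$h, w = A1$w, stride = 8L),
       P4 = list(x = p4, h = A2$h, w = A2$w, stride = 16L),
       P5 = list(x = p5, h = A3$h, w = A3$w, stride = 32L),
       P6 = list(x = p6, h = A3$h %/% 2L, w = A3$w %/% 2L, stride = 64L))
}

#' Initialize neck parameters
#'
#' @param in_channels backbone output channels for feat1/feat2/feat3.
#' @param cfg an [scf_config()].
#' @return nested parameter list: per-level `reduce`, `i1`, `i2`
#'   (zero-initialized), `out3`; pyramid smoothers `s3`, `s4`, `s5`.
#' @export
init_scf_fpn <- function(in_channels, cfg) {
  C <- cfg$neck_channels
  levels <- lapply(1:3, function(l) {
    UV <- prod(cfg$windows[[l]])
    list(reduce = init_linear(in_channels[l], C, sd = NULL),
         i1 = init_linear(C + UV * C, C, sd = NULL),
         i2 = init_linear(C, C, zero = TRUE),
         out3 = init_conv(3L, C, C))
  })
  list(levels = levels,
       s3 = init_conv(3L, C, C), s4 = init_conv(3L, C, C),
       s5 = init_conv(3L, C, C))
}

#' Run the full neck: per-level enhancement then pyramid construction
#'
#' @param feats backbone output (feat1/feat2/feat3 lists).
#' @param params from [init_scf_fpn()].
#' @param cfg an [scf_config()].
#' @param train if `TRUE` keep the autodiff graph (parameters must be nodes).
#' @return pyramid list `P3`..`P6`.
#' @export
forward_neck <- function(feats, params, cfg, train = FALSE) {
  if (!train) params <- detach_params(params)
  enh <- lapply(1:3, function(l) {
    f <- feats[[l]]
    list(x = scf_enhance(f, params$levels[[l]], cfg$windows[[l]]),
         h = f$h, w = f$w, stride = f$stride)
  })
  build_pyramid(enh[[1]], enh[[2]], enh[[3]], params)
}
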