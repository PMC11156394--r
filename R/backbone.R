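# Hierarchical shifted-window self-attention backbone.
#
# Four stages; stage 1 = patch partition + linear embedding + blocks, stages
# 2-4 = patch merging + blocks. Blocks alternate plain windowed attention
# (W-MSA) and shifted windowed attention (SW-MSA, cyclic shift + zone mask):
#   zhat = Attn(LN(z_prev)) + z_prev
#   z    = MLP(LN(zhat)) + zhat
# The neck consumes the outputs of stages 2, 3 and 4 (feat1/feat2/feat3 at
# strides 8/16/32 with channels 2C/4C/8C).

#' Backbone configuration
#'
#' @param embed_dim channels after linear embedding (stage-1 width C); stage
#'   s has width `2^(s-1) * embed_dim`. The default 128 yields stage-2/3/4
#'   channels 256/512/1024.
#' @param depths blocks per stage (each even, so W-MSA/SW-MSA alternate in
#'   pairs).
#' @param num_heads attention heads per stage; must divide the stage width.
#' @param attn_window token window side M; spatial grids at every stage must
#'   be divisible by M, i.e. the input side by `4 * M * 8`.
#' @param input_size expected input side in pixels (informational; the
#'   forward pass checks the actual image).
#' @param profile `"default"` or `"tiny"` (small widths/depths for CPU work;
#'   overrides the other arguments).
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(embed_dim = 128L, depths = c(2L, 2L, 6L, 2L),
                            num_heads = c(4L, 8L, 16L, 32L),
                            attn_window = 8L, input_size = 1280L,
                            profile = c("default", "tiny")) {
  profile <- match.arg(profile)
  if (profile == "tiny") {
    embed_dim <- 32L
    depths <- c(2L, 2L, 2L, 2L)
    num_heads <- c(2L, 4L, 8L, 16L)
    attn_window <- 4L
    input_size <- 256L
  }
  if (any(depths %% 2L != 0L))
    stopf("stage depths must be even (W-MSA/SW-MSA alternate in pairs)")
  dims <- embed_dim * 2L^(0:3)
  if (any(dims %% num_heads != 0L))
    stopf("num_heads must divide the stage widths (%s)",
          paste(dims, collapse = ", "))
  structure(list(embed_dim = as.integer(embed_dim),
                 depths = as.integer(depths),
                 num_heads = as.integer(num_heads),
                 attn_window = as.integer(attn_window),
                 input_size = as.integer(input_size)),
            class = "backbone_config")
}

#' Partition an image into non-overlapping 4x4 patch tokens
#'
#' Each output vector is the lossless flattening of one 4x4x3 pixel block,
#' row-major within the patch with channels fastest.
#'
#' @param image H x W x 3 array; H and W must be divisible by 4.
#' @return H/4 x W/4 x 48 array.
#' @export
patch_partition <- function(image) {
  d <- dim(image)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stopf("image sides must be divisible by 4 (got %d x %d)", d[1], d[2])
  h4 <- d[1] %/% 4L; w4 <- d[2] %/% 4L
  x <- image
  dim(x) <- c(4L, h4, 4L, w4, 3L)          # (r, ti, cl, tj, ch)
  x <- aperm(x, c(5L, 3L, 1L, 2L, 4L))     # (ch, cl, r, ti, tj): ch fastest
  dim(x) <- c(48L, h4, w4)
  aperm(x, c(2L, 3L, 1L))
}

#' Invert [patch_partition()]
#' @param tokens H/4 x W/4 x 48 array.
#' @return H x W x 3 array.
#' @export
patch_unpartition <- function(tokens) {
  d <- dim(tokens)
  h4 <- d[1]; w4 <- d[2]
  x <- aperm(tokens, c(3L, 1L, 2L))
  dim(x) <- c(3L, 4L, 4L, h4, w4)          # (ch, cl, r, ti, tj)
  x <- aperm(x, c(3L, 4L, 2L, 5L, 1L))     # (r, ti, cl, tj, ch)
  dim(x) <- c(4L * h4, 4L * w4, 3L)
  x
}

#' Split a token grid into non-overlapping M x M windows
#'
#' @param x H x W x C array with H, W divisible by M.
#' @param M window side.
#' @return M x M x C x n_windows array (windows in column-major grid order);
#'   [window_reverse()] is the exact inverse.
#' @export
window_partition <- function(x, M) {
  d <- dim(x)
  if (d[1] %% M != 0L || d[2] %% M != 0L)
    stopf("grid %d x %d not divisible by window side %d", d[1], d[2], M)
  nh <- d[1] %/% M; nw <- d[2] %/% M
  dim(x) <- c(M, nh, M, nw, d[3])
  x <- aperm(x, c(1L, 3L, 5L, 2L, 4L))     # (mi, mj, c, wi, wj)
  dim(x) <- c(M, M, d[3], nh * nw)
  x
}

#' Reassemble windows produced by [window_partition()]
#' @param wins M x M x C x n_windows array.
#' @param h,w original grid size.
#' @return H x W x C array.
#' @export
window_reverse <- function(wins, h, w) {
  d <- dim(wins)
  M <- d[1]; C <- d[3]
  nh <- h %/% M; nw <- w %/% M
  dim(wins) <- c(M, M, C, nh, nw)
  x <- aperm(wins, c(1L, 4L, 2L, 5L, 3L))
  dim(x) <- c(h, w, C)
  x
}

# ---- internal index plumbing ------------------------------------------------

# flat row indices (column-major spatial order) rearranged window-major, with
# optional cyclic shift by (-s, -s) applied before partitioning
window_gather_idx <- function(h, w, M, s = 0L) {
  cache_get(sprintf("wgi_%d_%d_%d_%d", h, w, M, s), function() {
    ii <- rep(seq_len(h), times = w)
    jj <- rep(seq_len(w), each = h)
    si <- ((ii - 1L + s) %% h) + 1L      # source row after cyclic shift
    sj <- ((jj - 1L + s) %% w) + 1L
    src <- si + h * (sj - 1L)
    wi <- (ii - 1L) %/% M; wj <- (jj - 1L) %/% M
    mi <- (ii - 1L) %% M; mj <- (jj - 1L) %% M
    win <- wi + (h %/% M) * wj
    pos <- mi + M * mj
    ord <- order(win, pos)
    src[ord]
  })
}

# inverse permutation: rows in window-major shifted order -> flat grid order
window_scatter_idx <- function(h, w, M, s = 0L) {
  cache_get(sprintf("wsi_%d_%d_%d_%d", h, w, M, s), function() {
    fwd <- window_gather_idx(h, w, M, s)
    inv <- integer(length(fwd))
    inv[fwd] <- seq_along(fwd)
    inv
  })
}

# Shifted-window zone ids in post-shift (rolled) coordinates: rows 1..H-M
# hold contiguous pre-shift content, H-M+1..H-s and H-s+1..H hold the two
# wrapped strips. Tokens from different zones are non-adjacent in the
# original image and must not attend to each other; only windows touching
# the wrap margin carry a mask.
shift_zones <- function(h, w, M, s) {
  cache_get(sprintf("zones_%d_%d_%d_%d", h, w, M, s), function() {
    zone_axis <- function(n) {
      z <- integer(n)
      z[seq_len(n - M)] <- 0L
      if (M - s > 0L) z[(n - M + 1L):(n - s)] <- 1L
      z[(n - s + 1L):n] <- 2L
      z
    }
    zi <- zone_axis(h); zj <- zone_axis(w)
    as.integer(outer(zi, zj, function(a, b) 3L * a + b))
  })
}

# relative position bias lookup: (M^2 * M^2) index vector into the
# (2M-1)^2-row bias table, token pair (p, q) ordered p fastest
rel_pos_idx <- function(M) {
  cache_get(sprintf("rpb_%d", M), function() {
    pi <- rep(rep(seq_len(M), times = M), times = M * M)
    pj <- rep(rep(seq_len(M), each = M), times = M * M)
    qi <- rep(rep(seq_len(M), times = M), each = M * M)
    qj <- rep(rep(seq_len(M), each = M), each = M * M)
    ri <- pi - qi + M - 1L
    rj <- pj - qj + M - 1L
    ri * (2L * M - 1L) + rj + 1L
  })
}

# ---- parameter construction -------------------------------------------------

init_swin_block <- function(dim, heads, M, mlp_ratio = 4) {
  list(ln1 = init_layernorm(dim),
       qkv = init_linear(dim, 3L * dim),
       proj = init_linear(dim, dim),
       rpb = ag_param(matrix(trunc_normal((2L * M - 1L)^2 * heads, 0.02),
                             (2L * M - 1L)^2, heads)),
       ln2 = init_layernorm(dim),
       fc1 = init_linear(dim, mlp_ratio * dim),
       fc2 = init_linear(mlp_ratio * dim, dim))
}

init_patch_merge <- function(dim) {
  list(reduce = init_linear(4L * dim, 2L * dim))
}

#' Initialize backbone parameters
#'
#' Weights are drawn truncated-normal (sd 0.02) from the current RNG state;
#' wrap in a seeded context for reproducibility. No pretraining is used.
#'
#' @param config a [backbone_config()].
#' @return nested parameter list.
#' @export
init_backbone <- function(config) {
  M <- config$attn_window
  dims <- config$embed_dim * 2L^(0:3)
  stages <- lapply(1:4, function(s) {
    blocks <- lapply(seq_len(config$depths[s]), function(b)
      init_swin_block(dims[s], config$num_heads[s], M))
    st <- list(blocks = blocks)
    if (s > 1L) st$merge <- init_patch_merge(dims[s - 1L])
    st
  })
  list(embed = init_linear(48L, config$embed_dim), stages = stages)
}

# ---- forward ops ------------------------------------------------------------

#' Linear embedding of patch tokens
#'
#' Per-token affine map from the 48 raw patch channels to the model width.
#'
#' @param tokens (H4*W4) x 48 matrix or H4 x W4 x 48 array.
#' @param embed parameter pair `list(w, b)` (48 x C weight).
#' @return same spatial layout with C channels.
#' @export
linear_embed <- function(tokens, embed) {
  arr <- !is_node(tokens) && length(dim(ag_value(tokens))) == 3L
  if (arr) {
    d <- dim(tokens)
    out <- ag_value(linear_fwd(matrix(tokens, d[1] * d[2], d[3]), embed))
    return(array(out, c(d[1], d[2], ncol(out))))
  }
  linear_fwd(tokens, embed)
}

#' One shifted-window attention block
#'
#' Implements `zhat = Attn(LN(z)) + z; z_out = MLP(LN(zhat)) + zhat` with
#' windowed multi-head attention (cyclic shift + zone mask when
#' `shifted = TRUE`) and learned relative position bias.
#'
#' @param x (H*W) x C matrix (or node) in column-major spatial order.
#' @param h,w token grid size.
#' @param params block parameters from `init_swin_block`.
#' @param heads number of attention heads.
#' @param M window side.
#' @param shifted use SW-MSA (cyclic shift by `floor(M/2)` with mask).
#' @return (H*W) x C matrix or node.
#' @export
swin_block <- function(x, h, w, params, heads, M, shifted = FALSE) {
  if (h %% M != 0L || w %% M != 0L)
    stopf("token grid %d x %d not divisible by window %d", h, w, M)
  s <- if (shifted) M %/% 2L else 0L
  nw <- (h %/% M) * (w %/% M)
  m2 <- M * M
  gidx <- window_gather_idx(h, w, M, s)
  sidx <- window_scatter_idx(h, w, M, s)
  # zone map lives in post-shift coordinates: partition it without the shift
  zones <- if (shifted && nw > 1L)
    shift_zones(h, w, M, s)[window_gather_idx(h, w, M, 0L)] else NULL
  bias <- ag_gather_rows(params$rpb, rel_pos_idx(M))
  xn <- layernorm_fwd(x, params$ln1)
  qkv <- linear_fwd(xn, params$qkv)
  qkv_w <- ag_gather_rows(qkv, gidx)
  att <- ag_window_attention(qkv_w, nw, m2, heads, bias = bias, zones = zones)
  att <- ag_gather_rows(att, sidx)
  zhat <- ag_add(x, linear_fwd(att, params$proj))
  yn <- layernorm_fwd(zhat, params$ln2)
  mlp <- linear_fwd(ag_gelu(linear_fwd(yn, params$fc1)), params$fc2)
  ag_add(zhat, mlp)
}

#' Patch merging: halve resolution, double channels
#'
#' Concatenates each 2x2 token neighbourhood (4C channels, order: top-left,
#' bottom-left, top-right, bottom-right) and applies a linear projection to
#' 2C.
#'
#' @param x (H*W) x C matrix/node.
#' @param h,w token grid size (even).
#' @param params `init_patch_merge` parameters.
#' @return (H/2*W/2) x 2C matrix/node.
#' @export
patch_merge <- function(x, h, w, params) {
  if (h %% 2L != 0L || w %% 2L != 0L)
    stopf("patch merge needs even grid, got %d x %d", h, w)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  ii <- rep(seq_len(h2), times = w2)
  jj <- rep(seq_len(w2), each = h2)
  base <- function(di, dj) (2L * ii - 1L + di) + h * (2L * jj - 2L + dj)
  parts <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                  function(d) ag_gather_rows(x, base(d[1], d[2])))
  cat4 <- do.call(ag_cbind, parts)
  linear_fwd(cat4, params$reduce)
}

#' Full backbone forward pass
#'
#' @param image H x W x 3 array.
#' @param params parameters from [init_backbone()].
#' @param config the matching [backbone_config()].
#' @param train if `TRUE`, build the autodiff graph.
#' @return list of three feature maps `feat1`, `feat2`, `feat3`, each a list
#'   with `x` ((H*W) x C matrix or node), `h`, `w`, `stride`.
#' @export
forward_backbone <- function(image, params, config, train = FALSE) {
  d <- dim(image)
  M <- config$attn_window
  if (d[1] %% (4L * M * 8L) != 0L || d[2] %% (4L * M * 8L) != 0L)
    stopf("input %d x %d must be divisible by %d (4 * window * 8)",
          d[1], d[2], 4L * M * 8L)
  if (!train) params <- detach_params(params)
  tokens <- patch_partition(image)
  h <- dim(tokens)[1]; w <- dim(tokens)[2]
  x <- matrix(tokens, h * w, 48L)
  x <- linear_embed(x, params$embed)
  feats <- list()
  for (s in 1:4) {
    st <- params$stages[[s]]
    if (s > 1L) {
      x <- patch_merge(x, h, w, st$merge)
      h <- h %/% 2L; w <- w %/% 2L
    }
    for (b in seq_along(st$blocks)) {
      x <- swin_block(x, h, w, st$blocks[[b]], config$num_heads[s], M,
                      shifted = (b %% 2L == 0L))
    }
    if (s >= 2L)
      feats[[s - 1L]] <- list(x = x, h = h, w = w,
                              stride = as.integer(2^(s + 1)))
  }
  names(feats) <- c("feat1", "feat2", "feat3")
  feats
}
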