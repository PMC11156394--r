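# Layer primitives shared by the backbone, neck and heads.
#
# Feature maps are stored as (H*W) x C matrices with column-major spatial
# order (row index r = i + H*(j-1) for pixel (i,j)), matching how R linearizes
# an H x W x C array, so array(x, c(H*W, C)) and back are free reshapes.

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, fn) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- fn()
    .idx_cache[[key]] <- v
  }
  v
}

# truncated normal in [-2sd, 2sd], the standard transformer weight init
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

# sd = NULL gives He/Kaiming scaling (sqrt(2/fan_in)), appropriate for conv
# and MLP-head layers; transformer layers keep the fixed 0.02 convention.
init_linear <- function(fan_in, fan_out, sd = 0.02, zero = FALSE) {
  if (is.null(sd)) sd <- sqrt(2 / fan_in)
  w <- if (zero) matrix(0, fan_in, fan_out)
  else matrix(trunc_normal(fan_in * fan_out, sd), fan_in, fan_out)
  list(w = ag_param(w), b = ag_param(numeric(fan_out)))
}

init_layernorm <- function(dim) {
  list(gamma = ag_param(rep(1, dim)), beta = ag_param(numeric(dim)))
}

linear_fwd <- function(x, lin) ag_add_bias(ag_matmul(x, lin$w), lin$b)

layernorm_fwd <- function(x, ln) ag_layernorm(x, ln$gamma, ln$beta)

# ---- spatial index helpers --------------------------------------------------

# Gather index turning an (H*W) x C map into (H*W) x (K2*C) im2col form for a
# k x k kernel with zero padding; taps ordered tap-fastest so the reshape
# (H*W*K2) x C -> (H*W) x (K2*C) is a plain dim<- change.
conv_idx <- function(h, w, k) {
  cache_get(sprintf("conv_%d_%d_%d", h, w, k), function() {
    r <- (k - 1L) %/% 2L
    ii <- rep(seq_len(h), times = w)
    jj <- rep(seq_len(w), each = h)
    idx <- integer(h * w * k * k)
    t0 <- 0L
    for (dj in -r:r) for (di in -r:r) {
      i2 <- ii + di; j2 <- jj + dj
      ok <- i2 >= 1L & i2 <= h & j2 >= 1L & j2 <= w
      v <- integer(h * w)
      v[ok] <- i2[ok] + h * (j2[ok] - 1L)
      # rows ordered pixel-fastest within each tap block
      idx[(t0 * h * w + 1L):((t0 + 1L) * h * w)] <- v
      t0 <- t0 + 1L
    }
    idx
  })
}

# k x k convolution on an (H*W) x Cin map, zero padded, shape preserving.
# weights: (k2*Cin) x Cout with tap index fastest within each input channel.
conv_fwd <- function(x, conv, h, w, k) {
  cin <- ncol(ag_value(x))
  idx <- conv_idx(h, w, k)
  g <- ag_gather_rows(x, idx)                 # (H*W*k2) x Cin, tap-major rows
  g <- ag_reshape(g, c(h * w, k * k * cin))   # tap fastest, then channel
  ag_add_bias(ag_matmul(g, conv$w), conv$b)
}

init_conv <- function(k, cin, cout, sd = NULL, zero = FALSE) {
  init_linear(k * k * cin, cout, sd = sd, zero = zero)
}

# identity-initialized k x k conv: center tap of matching channel = 1
init_conv_identity <- function(k, cin) {
  w <- matrix(0, k * k * cin, cin)
  center <- (k * k + 1L) %/% 2L
  for (c in seq_len(cin)) w[(c - 1L) * k * k + center, c] <- 1
  list(w = ag_param(w), b = ag_param(numeric(cin)))
}

# nearest-neighbour 2x upsample index: output (2H*2W) rows gather from (H*W)
upsample2_idx <- function(h, w) {
  cache_get(sprintf("up2_%d_%d", h, w), function() {
    ii <- rep(seq_len(2L * h), times = 2L * w)
    jj <- rep(seq_len(2L * w), each = 2L * h)
    si <- (ii + 1L) %/% 2L
    sj <- (jj + 1L) %/% 2L
    si + h * (sj - 1L)
  })
}

upsample2_fwd <- function(x, h, w) ag_gather_rows(x, upsample2_idx(h, w))

# stride-2 2x2 max pool; argmax indices computed from the forward value so the
# gather routes gradients to the winning element
maxpool2_fwd <- function(x, h, w) {
  xv <- ag_value(x)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  ii <- rep(seq_len(h2), times = w2)
  jj <- rep(seq_len(w2), each = h2)
  cand <- cbind((2L * ii - 1L) + h * (2L * jj - 2L),
                (2L * ii) + h * (2L * jj - 2L),
                (2L * ii - 1L) + h * (2L * jj - 1L),
                (2L * ii) + h * (2L * jj - 1L))
  # per output pixel per channel argmax -> one gather per candidate with mask
  out <- NULL
  vals <- lapply(1:4, function(t) xv[cand[, t], , drop = FALSE])
  best <- vals[[1]]; which_t <- matrix(1L, h2 * w2, ncol(xv))
  for (t in 2:4) {
    upd <- vals[[t]] > best
    best[upd] <- vals[[t]][upd]
    which_t[upd] <- t
  }
  if (!is_node(x)) return(best)
  nc <- ncol(xv)
  ag_make(best, list(x), list(function(g) {
    gr <- matrix(0, nrow(xv), nc)
    for (t in 1:4) {
      m <- which_t == t
      if (!any(m)) next
      gm <- g * m
      rs <- rowsum(gm, group = cand[, t], reorder = FALSE)
      ridx <- as.integer(rownames(rs))
      gr[ridx, ] <- gr[ridx, ] + rs
    }
    gr
  }))
}

# ---- parameter collection / optimizer --------------------------------------

# replace every parameter node in a nested list by its plain value, so a
# forward pass through the result builds no graph (inference mode)
detach_params <- function(x) {
  if (is_node(x)) return(x$value)
  if (is.list(x)) return(lapply(x, detach_params))
  x
}

# depth-first collection of ag_param nodes from a nested list
collect_params <- function(x, prefix = "") {
  out <- list()
  if (is_node(x)) {
    if (!is.null(x$is_param)) out[[prefix]] <- x
    return(out)
  }
  if (is.list(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (i in seq_along(x)) {
      key <- if (prefix == "") nms[i] else paste0(prefix, ".", nms[i])
      out <- c(out, collect_params(x[[i]], key))
    }
  }
  out
}
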