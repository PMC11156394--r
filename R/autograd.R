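# Reverse-mode automatic differentiation over base-R numeric arrays.
#
# Design: an operation applied to plain arrays returns a plain array (inference
# mode, nothing retained); applied to at least one `ag_node` it returns a new
# node recording its parents and a per-parent gradient function (training
# mode). `ag_backward()` topologically sorts the tape and accumulates
# gradients. This keeps a single code path for forward math while letting
# evaluation run without graph overhead or memory retention.

#' Is the object an autodiff graph node?
#' @param x object.
#' @return logical.
#' @keywords internal
is_node <- function(x) inherits(x, "ag_node")

new_node <- function(value, parents = list(), grad_fns = list()) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$grad_fns <- grad_fns
  n$grad <- NULL
  class(n) <- "ag_node"
  n
}

#' Create a trainable parameter node
#' @param value numeric array initial value.
#' @return an `ag_node` flagged as a leaf parameter.
#' @keywords internal
ag_param <- function(value) {
  n <- new_node(value)
  n$is_param <- TRUE
  n
}

#' Extract the numeric value of a node or pass a plain array through
#'
#' Layer functions return autodiff nodes when called with trainable
#' parameters; `ag_value()` unwraps them to plain numeric arrays.
#'
#' @param x node or array.
#' @return numeric array.
#' @export
ag_value <- function(x) if (is_node(x)) x$value else x

# Build a node if any input is a node, else return the plain value.
ag_make <- function(value, inputs, grad_fns) {
  live <- vapply(inputs, is_node, logical(1))
  if (!any(live)) return(value)
  new_node(value, parents = inputs[live], grad_fns = grad_fns[live])
}

#' Run backpropagation from a scalar loss node
#'
#' @param loss an `ag_node` holding a length-1 value.
#' @return invisibly, the list of visited nodes (parameters carry `$grad`).
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$value) == 1L)
  # iterative topological sort (DFS), then reverse accumulation
  order <- list(); k <- 0L
  stack <- list(list(node = loss, stage = 1L))
  seen <- new.env(parent = emptyenv())
  addr <- function(n) format.default(n)  # environment identity string
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- top$node
    id <- addr(n)
    if (top$stage == 1L) {
      if (!is.null(seen[[id]])) next
      seen[[id]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = n, stage = 2L)
      for (p in n$parents)
        if (is.null(seen[[addr(p)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      k <- k + 1L
      order[[k]] <- n
    }
  }
  # reset intermediate grads only: parameter grads accumulate across calls
  # (gradient accumulation for micro-batching)
  for (n in order) if (is.null(n$is_param)) n$grad <- NULL
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (i in rev(seq_len(k))) {
    n <- order[[i]]
    g <- n$grad
    if (is.null(g) || !length(n$parents)) next
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      pg <- n$grad_fns[[j]](g)
      if (is.null(pg)) next
      p$grad <- if (is.null(p$grad)) pg else p$grad + pg
    }
    if (is.null(n$is_param)) n$grad <- NULL  # free intermediate grads early
  }
  invisible(order)
}

#' Detach a value from the graph
#' @param x node or array.
#' @return plain numeric array.
#' @keywords internal
ag_detach <- function(x) ag_value(x)

# ---- elementwise / linear ops -----------------------------------------------

ag_add <- function(a, b) {
  ag_make(ag_value(a) + ag_value(b), list(a, b),
          list(function(g) g, function(g) g))
}

ag_sub <- function(a, b) {
  ag_make(ag_value(a) - ag_value(b), list(a, b),
          list(function(g) g, function(g) -g))
}

ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_make(av * bv, list(a, b),
          list(function(g) g * bv, function(g) g * av))
}

ag_scale <- function(a, s) {
  ag_make(ag_value(a) * s, list(a), list(function(g) g * s))
}

# matrix product with optional transposes
ag_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  av <- ag_value(a); bv <- ag_value(b)
  v <- if (!ta && !tb) av %*% bv
  else if (ta && !tb) crossprod(av, bv)
  else if (!ta && tb) tcrossprod(av, bv)
  else t(bv %*% av)
  ag_make(v, list(a, b), list(
    function(g) {
      if (!ta && !tb) tcrossprod(g, bv)
      else if (ta && !tb) tcrossprod(bv, g)
      else if (!ta && tb) g %*% bv
      else t(tcrossprod(bv, g))
    },
    function(g) {
      if (!ta && !tb) crossprod(av, g)
      else if (ta && !tb) av %*% g
      else if (!ta && tb) crossprod(g, av)
      else t(av %*% g)
    }))
}

# add a bias row-vector to every row of a matrix
ag_add_bias <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_make(sweep(av, 2L, bv, "+"), list(a, b),
          list(function(g) g, function(g) colSums(g)))
}

ag_reshape <- function(a, dims) {
  av <- ag_value(a)
  old <- dim(av) %||% length(av)
  v <- av; dim(v) <- dims
  ag_make(v, list(a), list(function(g) { dim(g) <- old; g }))
}

ag_aperm <- function(a, perm) {
  av <- ag_value(a)
  inv <- order(perm)
  ag_make(aperm(av, perm), list(a), list(function(g) aperm(g, inv)))
}

# concatenate matrices along columns
ag_cbind <- function(...) {
  inputs <- list(...)
  vals <- lapply(inputs, ag_value)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols); starts <- ends - ncols + 1L
  grad_fns <- lapply(seq_along(inputs), function(j) {
    lo <- starts[j]; hi <- ends[j]
    function(g) g[, lo:hi, drop = FALSE]
  })
  ag_make(do.call(cbind, vals), inputs, grad_fns)
}

ag_slice_cols <- function(a, cols) {
  av <- ag_value(a)
  nc <- ncol(av)
  ag_make(av[, cols, drop = FALSE], list(a), list(function(g) {
    gr <- matrix(0, nrow(g), nc)
    if (anyDuplicated(cols)) {
      rs <- rowsum(t(g), group = cols, reorder = FALSE)  # accumulate dups
      gr[, as.integer(rownames(rs))] <- t(rs)
    } else {
      gr[, cols] <- g
    }
    gr
  }))
}

# tile all columns of a matrix k times: [X X ... X]; backward sums the tiles
ag_tile_cols <- function(a, k) {
  av <- ag_value(a)
  nc <- ncol(av)
  v <- av[, rep.int(seq_len(nc), k), drop = FALSE]
  ag_make(v, list(a), list(function(g) {
    acc <- g[, seq_len(nc), drop = FALSE]
    for (t in seq_len(k - 1L))
      acc <- acc + g[, (t * nc + 1L):((t + 1L) * nc), drop = FALSE]
    acc
  }))
}

ag_rbind <- function(...) {
  inputs <- list(...)
  vals <- lapply(inputs, ag_value)
  nr <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nr); starts <- ends - nr + 1L
  grad_fns <- lapply(seq_along(inputs), function(j) {
    lo <- starts[j]; hi <- ends[j]
    function(g) g[lo:hi, , drop = FALSE]
  })
  ag_make(do.call(rbind, vals), inputs, grad_fns)
}

# ---- gather / scatter -------------------------------------------------------

# Row gather from a matrix; idx == 0L yields a zero row (used for zero
# padding). Backward is scatter-add via rowsum().
ag_gather_rows <- function(a, idx) {
  av <- ag_value(a)
  nr <- nrow(av); nc <- ncol(av)
  pos <- idx > 0L
  if (all(pos)) {
    v <- av[idx, , drop = FALSE]
  } else {
    v <- matrix(0, length(idx), nc)
    v[pos, ] <- av[idx[pos], , drop = FALSE]
  }
  ag_make(v, list(a), list(function(g) {
    gr <- matrix(0, nr, nc)
    if (any(pos)) {
      gi <- idx[pos]
      rs <- rowsum(g[pos, , drop = FALSE], group = gi, reorder = FALSE)
      gr[as.integer(rownames(rs)), ] <- gr[as.integer(rownames(rs)), ] + rs
    }
    gr
  }))
}

# ---- nonlinearities ---------------------------------------------------------

ag_relu <- function(a) {
  av <- ag_value(a)
  mask <- av > 0
  ag_make(av * mask, list(a), list(function(g) g * mask))
}

# GELU via the sigmoid approximation x * sigmoid(1.702 x) (several times
# cheaper than the erf form on large activations; max abs deviation ~0.02)
ag_gelu <- function(a) {
  av <- ag_value(a)
  s <- 1 / (1 + exp(-1.702 * av))
  ag_make(av * s, list(a),
          list(function(g) g * (s + av * 1.702 * s * (1 - s))))
}

# row-wise softmax of a matrix, optional additive constant mask
ag_row_softmax <- function(a, mask = NULL) {
  av <- ag_value(a)
  if (!is.null(mask)) av <- av + mask
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  s <- e / rowSums(e)
  ag_make(s, list(a), list(function(g) {
    (g - rowSums(g * s)) * s
  }))
}

# ---- normalization ----------------------------------------------------------

# LayerNorm over columns of a matrix (each row is one token).
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- ag_value(a); gv <- ag_value(gamma); bv <- ag_value(beta)
  n <- ncol(av)
  mu <- rowMeans(av)
  xc <- av - mu
  var <- rowMeans(xc * xc)
  inv <- 1 / sqrt(var + eps)
  xhat <- xc * inv
  v <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ag_make(v, list(a, gamma, beta), list(
    function(g) {
      gx <- sweep(g, 2L, gv, "*")
      # d xhat -> d x for layer norm
      (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)) * inv
    },
    function(g) colSums(g * xhat),
    function(g) colSums(g)))
}

# ---- reductions and losses --------------------------------------------------

ag_sum <- function(a) {
  av <- ag_value(a)
  dims <- dim(av) %||% length(av)
  ag_make(sum(av), list(a), list(function(g) array(as.numeric(g), dims)))
}

ag_mean <- function(a) {
  av <- ag_value(a)
  dims <- dim(av) %||% length(av)
  n <- length(av)
  ag_make(mean(av), list(a),
          list(function(g) array(as.numeric(g) / n, dims)))
}

# Softmax cross-entropy, fused and numerically stable.
# logits: n x k matrix; target: integer vector in 1..k. Returns mean loss.
ag_softmax_ce <- function(logits, target) {
  lv <- ag_value(logits)
  n <- nrow(lv)
  m <- apply(lv, 1L, max)
  z <- lv - m
  lse <- log(rowSums(exp(z)))
  p <- exp(z - lse)
  picked <- z[cbind(seq_len(n), target)]
  loss <- mean(lse - picked)
  ag_make(loss, list(logits), list(function(g) {
    gr <- p
    gr[cbind(seq_len(n), target)] <- gr[cbind(seq_len(n), target)] - 1
    gr * (as.numeric(g) / n)
  }))
}

# Binary cross-entropy with logits; `weights` (default 1/n each) must sum to
# the desired normalization.
ag_bce_logits <- function(logits, target, weights = NULL) {
  lv <- ag_value(logits)
  n <- length(lv)
  if (is.null(weights)) weights <- rep(1 / n, n)
  p <- 1 / (1 + exp(-lv))
  elt <- pmax(lv, 0) - lv * target + log1p(exp(-abs(lv)))
  loss <- sum(weights * elt)
  ag_make(loss, list(logits),
          list(function(g) {
            gr <- (p - target) * weights * as.numeric(g)
            dim(gr) <- dim(lv) %||% NULL
            gr
          }))
}

# Smooth-L1 (Huber) loss, sum over elements divided by `norm`.
ag_smooth_l1 <- function(pred, target, beta = 1, norm = NULL) {
  pv <- ag_value(pred)
  d <- pv - target
  a <- abs(d)
  norm <- norm %||% length(pv)
  l <- ifelse(a < beta, 0.5 * d * d / beta, a - 0.5 * beta)
  ag_make(sum(l) / norm, list(pred), list(function(g) {
    gd <- ifelse(a < beta, d / beta, sign(d))
    gd * (as.numeric(g) / norm)
  }))
}

# ---- fused batched window attention ----------------------------------------
#
# qkv: (nw*m2) x (3*C) matrix, rows grouped by window (window-major), columns
#   [Q | K | V] with per-head sub-blocks of width hd = C/heads.
# bias: (m2*m2) x heads matrix of relative-position biases (same every window),
#   or NULL.
# zones: optional integer vector of length nw*m2; tokens in the same window
#   attend only to tokens with an equal zone id (shifted-window mask).
# Returns (nw*m2) x C attention output.
ag_window_attention <- function(qkv, nw, m2, heads, bias = NULL, zones = NULL) {
  qv <- ag_value(qkv)
  C <- ncol(qv) / 3L
  hd <- C / heads
  scalef <- 1 / sqrt(hd)
  bv <- if (is.null(bias)) NULL else ag_value(bias)
  out <- matrix(0, nrow(qv), C)
  keep_cache <- is_node(qkv) || is_node(bias)
  cache <- if (keep_cache) vector("list", nw * heads)
  neg <- -1e9
  for (w in seq_len(nw)) {
    rows <- ((w - 1L) * m2 + 1L):(w * m2)
    mask <- NULL
    if (!is.null(zones)) {
      zw <- zones[rows]
      mask <- matrix(0, m2, m2)
      mask[outer(zw, zw, "!=")] <- neg
    }
    for (h in seq_len(heads)) {
      qc <- ((h - 1L) * hd + 1L):(h * hd)
      q <- qv[rows, qc, drop = FALSE]
      k <- qv[rows, C + qc, drop = FALSE]
      v <- qv[rows, 2L * C + qc, drop = FALSE]
      s <- tcrossprod(q, k) * scalef
      if (!is.null(bv)) s <- s + matrix(bv[, h], m2, m2)
      if (!is.null(mask)) s <- s + mask
      s <- s - apply(s, 1L, max)
      e <- exp(s)
      attn <- e / rowSums(e)
      out[rows, qc] <- attn %*% v
      if (keep_cache)
        cache[[(w - 1L) * heads + h]] <- list(attn = attn, q = q, k = k, v = v)
    }
  }
  if (!keep_cache) return(out)
  ag_make(out, list(qkv, bias), list(
    function(g) {
      gq <- matrix(0, nrow(qv), 3L * C)
      for (w in seq_len(nw)) {
        rows <- ((w - 1L) * m2 + 1L):(w * m2)
        for (h in seq_len(heads)) {
          cc <- cache[[(w - 1L) * heads + h]]
          qc <- ((h - 1L) * hd + 1L):(h * hd)
          go <- g[rows, qc, drop = FALSE]
          gattn <- tcrossprod(go, cc$v)
          gv_ <- crossprod(cc$attn, go)
          gs <- (gattn - rowSums(gattn * cc$attn)) * cc$attn
          gq[rows, qc] <- (gs %*% cc$k) * scalef
          gq[rows, C + qc] <- crossprod(gs, cc$q) * scalef
          gq[rows, 2L * C + qc] <- gv_
        }
      }
      gq
    },
    function(g) {
      if (is.null(bv)) return(NULL)
      gb <- matrix(0, m2 * m2, heads)
      for (w in seq_len(nw)) {
        rows <- ((w - 1L) * m2 + 1L):(w * m2)
        for (h in seq_len(heads)) {
          cc <- cache[[(w - 1L) * heads + h]]
          qc <- ((h - 1L) * hd + 1L):(h * hd)
          go <- g[rows, qc, drop = FALSE]
          gattn <- tcrossprod(go, cc$v)
          gs <- (gattn - rowSums(gattn * cc$attn)) * cc$attn
          gb[, h] <- gb[, h] + as.numeric(gs)
        }
      }
      gb
    }))
}
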