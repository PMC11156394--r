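# Brute-force references for the neighborhood/autocorrelation path.

unfold_reference <- function(X, U, V) {
  d <- dim(X)
  R <- array(0, c(d[1], d[2], U, V, d[3]))
  cu <- (U + 1) %/% 2; cv <- (V + 1) %/% 2
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (u in seq_len(U)) for (v in seq_len(V)) {
      si <- i + u - cu; sj <- j + v - cv
      if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2])
        R[i, j, u, v, ] <- X[si, sj, ]
    }
  R
}

test_that("neighborhood unfold matches the nested-loop reference", {
  set.seed(21)
  X <- array(rnorm(6 * 5 * 3), c(6L, 5L, 3L))
  R <- neighborhood_unfold(X, 3L, 3L)
  expect_equal(dim(R), c(6L, 5L, 3L, 3L, 3L))
  expect_equal(R, unfold_reference(X, 3L, 3L), tolerance = 1e-12)
  # shape contract for a (4,4,2) input with 3x3 windows
  X2 <- array(rnorm(32), c(4L, 4L, 2L))
  expect_equal(dim(neighborhood_unfold(X2, 3L, 3L)), c(4L, 4L, 3L, 3L, 2L))
  expect_error(neighborhood_unfold(X, 2L, 3L), "odd")
})

test_that("constant input fills the interior, zero pads the border", {
  Xc <- array(2, c(5L, 5L, 1L))
  R <- neighborhood_unfold(Xc, 3L, 3L)
  expect_true(all(R[3, 3, , , ] == 2))   # interior: all neighbours present
  expect_equal(R[1, 1, 1, 1, 1], 0)      # top-left corner: padded
  expect_equal(R[1, 1, 2, 2, 1], 2)      # center tap always present
})

test_that("autocorrelation equals the pointwise loop oracle", {
  set.seed(22)
  X <- array(rnorm(6 * 5 * 3), c(6L, 5L, 3L))
  U <- 3L; V <- 3L; C <- 3L
  R <- neighborhood_unfold(X, U, V)
  D <- autocorrelation(R, X)
  expect_equal(dim(D), c(6L, 5L, U * V * C))
  cu <- 2L; cv <- 2L
  for (i in c(1L, 4L, 6L)) for (j in c(1L, 3L, 5L))
    for (u in seq_len(U)) for (v in seq_len(V)) for (c in seq_len(C)) {
      si <- i + u - cu; sj <- j + v - cv
      xn <- if (si >= 1 && si <= 6 && sj >= 1 && sj <= 5) X[si, sj, c] else 0
      flat <- (u - 1L) * V * C + (v - 1L) * C + c
      expect_equal(D[i, j, flat], xn * X[i, j, c], tolerance = 1e-5)
    }
  # multiplicative identity: X == 1 makes D the flattened R; and annihilation
  X1 <- array(1, c(4L, 4L, 2L))
  R1 <- neighborhood_unfold(X1, 3L, 3L)
  flatR <- array(aperm(R1, c(1, 2, 5, 4, 3)), c(4, 4, 18))
  expect_equal(autocorrelation(R1, X1), flatR, tolerance = 1e-12)
  expect_true(all(autocorrelation(R1, X1 * 0) == 0))
})

test_that("internal flattened unfold agrees with the array reference", {
  set.seed(23)
  h <- 6L; w <- 5L; C <- 3L; U <- 5L; V <- 5L
  X <- array(rnorm(h * w * C), c(h, w, C))
  flat <- pestdet:::neighborhood_unfold_flat(matrix(X, h * w, C), h, w, U, V)
  ref <- unfold_reference(X, U, V)
  for (i in c(1L, 3L, 6L)) for (j in c(2L, 5L))
    for (u in c(1L, 3L, 5L)) for (v in c(2L, 4L)) for (c in seq_len(C)) {
      col <- (u - 1L) * V * C + (v - 1L) * C + c
      expect_equal(flat[i + h * (j - 1L), col], ref[i, j, u, v, c],
                   tolerance = 1e-12)
    }
})

test_that("embed_fuse concatenation width and residual identity hold", {
  C <- 4L; UV <- 9L
  set.seed(24)
  params <- list(i1 = init_linear(C + UV * C, C, sd = NULL),
                 i2 = init_linear(C, C, zero = TRUE))
  X <- matrix(rnorm(10 * C), 10, C)
  D <- matrix(rnorm(10 * UV * C), 10, UV * C)
  # zero second projection (the default init) -> exact residual identity
  A <- ag_value(embed_fuse(X, D, params))
  expect_identical(A, X)
  # both projections zero -> still identity
  params$i1$w$value[] <- 0
  expect_identical(ag_value(embed_fuse(X, D, params)), X)
  # channel arithmetic: C = 256, 3x3 window -> G has 2560 channels
  expect_equal(256L + 9L * 256L, 2560L)
})

test_that("embed_fuse is the expected affine composition on a toy grid", {
  C <- 2L; UV <- 2L
  params <- list(i1 = init_linear(C + UV * C, C, zero = TRUE),
                 i2 = init_linear(C, C, zero = TRUE))
  params$i1$w$value <- matrix(seq(0.1, 1.2, by = 0.1), 6, 2)
  params$i1$b$value <- c(0.5, -0.5)
  params$i2$w$value <- matrix(c(1, 0.5, -0.5, 2), 2, 2)
  params$i2$b$value <- c(0.1, 0.2)
  X <- matrix(c(1, 2, 3, 4), 2, 2)
  D <- matrix(c(1, 0, 0, 1, 2, 2, 1, 1), 2, 4)
  G <- cbind(X, D)
  I1 <- sweep(G %*% params$i1$w$value, 2, params$i1$b$value, "+")
  I2 <- sweep(I1 %*% params$i2$w$value, 2, params$i2$b$value, "+")
  expect_equal(ag_value(embed_fuse(X, D, params)), X + I2, tolerance = 1e-12)
})

test_that("scf_enhance keeps spatial shape and neck width", {
  set.seed(25)
  cfg <- scf_config(neck_channels = 8L)
  params <- init_scf_fpn(c(16L, 32L, 64L), cfg)
  feat <- list(x = matrix(rnorm(12 * 12 * 16), 144, 16), h = 12L, w = 12L)
  out <- ag_value(scf_enhance(feat, params$levels[[1]], c(7L, 7L)))
  expect_equal(dim(out), c(144L, 8L))
  out3 <- ag_value(scf_enhance(list(x = matrix(rnorm(16 * 64), 16, 64),
                                    h = 4L, w = 4L),
                               params$levels[[3]], c(3L, 3L)))
  expect_equal(dim(out3), c(16L, 8L))
})

test_that("residual guarantee: zeroed SCF projections reduce to reduce+conv", {
  set.seed(26)
  cfg <- scf_config(neck_channels = 8L)
  params <- init_scf_fpn(c(16L, 32L, 64L), cfg)
  lv <- params$levels[[1]]
  lv$i1$w$value[] <- 0; lv$i1$b$value[] <- 0
  feat <- list(x = matrix(rnorm(8 * 8 * 16), 64, 16), h = 8L, w = 8L)
  X <- ag_value(reduce_channels(feat$x, lv$reduce))
  direct <- ag_value(conv_fwd(X, lv$out3, 8L, 8L, 3L))
  via_scf <- ag_value(scf_enhance(feat, lv, c(7L, 7L)))
  expect_identical(via_scf, direct)
})

test_that("pyramid shapes follow stride arithmetic and share channels", {
  set.seed(27)
  C <- 8L
  cfg <- scf_config(neck_channels = C)
  params <- init_scf_fpn(c(16L, 32L, 64L), cfg)
  mk <- function(h, w, cin) list(x = matrix(rnorm(h * w * cin), h * w, cin),
                                 h = h, w = w, stride = NA)
  feats <- list(mk(16L, 16L, 16L), mk(8L, 8L, 32L), mk(4L, 4L, 64L))
  feats[[1]]$stride <- 8L; feats[[2]]$stride <- 16L; feats[[3]]$stride <- 32L
  pyr <- forward_neck(feats, params, cfg)
  expect_equal(vapply(pyr, function(p) c(p$h, p$w), integer(2)),
               matrix(c(16L, 16L, 8L, 8L, 4L, 4L, 2L, 2L), 2,
                      dimnames = list(NULL, c("P3", "P4", "P5", "P6"))))
  expect_true(all(vapply(pyr, function(p) ncol(ag_value(p$x)), integer(1)) == C))
  # A2 == 0 and upsampled P5 == 0 -> merged P4 is bias-only
  z <- lapply(feats, function(f) list(x = matrix(0, f$h * f$w, C),
                                      h = f$h, w = f$w, stride = f$stride))
  pz <- build_pyramid(z[[1]], z[[2]], z[[3]], params)
  expect_equal(max(abs(sweep(ag_value(pz$P4$x), 2, params$s4$b$value, "-"))),
               0)
})

test_that("uniform window override reproduces the ablation configurations", {
  for (wv in list(c(3L, 3L), c(5L, 5L), c(7L, 7L))) {
    cfg <- scf_config(neck_channels = 4L,
                      windows = list(wv, wv, wv))
    expect_equal(cfg$windows[[1]], cfg$windows[[3]])
    params <- init_scf_fpn(c(8L, 8L, 8L), cfg)
    expect_equal(nrow(params$levels[[2]]$i1$w$value),
                 4L + prod(wv) * 4L)
  }
  expect_error(scf_config(windows = list(c(2L, 2L), c(5L, 5L), c(3L, 3L))),
               "odd")
})
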