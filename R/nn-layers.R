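# Layer primitives for the voxel classifier: each *_fwd returns list(out, cache)
# and each *_bwd returns list(dx, grads). Feature maps are either token
# matrices (N x K) or volumetric arrays (X x Y x Z x C); all heavy lifting is
# BLAS matrix multiplication. Volumetric convolutions use the shifted-matmul
# formulation: a 3^3 convolution is the sum over 27 kernel offsets of a
# zero-padded shift of the input times a Cin x Cout weight slice.

linear_fwd <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, "+"), cache = x)
}

linear_bwd <- function(dy, cache, W) {
  list(dx = dy %*% t(W),
       dW = crossprod(cache, dy),
       db = colSums(dy))
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat * rep(1, nrow(x)) %o% g, 2L, b, "+"),
       cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  K <- ncol(dy)
  dxhat <- sweep(dy, 2L, g, "*")
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

gelu_fwd <- function(x) {
  p <- stats::pnorm(x)
  list(out = x * p, cache = list(x = x, p = p))
}

gelu_bwd <- function(dy, cache) {
  dy * (cache$p + cache$x * stats::dnorm(cache$x))
}

leaky_relu_fwd <- function(x, slope = 0.01) {
  neg <- x < 0
  y <- x
  y[neg] <- slope * x[neg]
  list(out = y, cache = list(neg = neg, slope = slope))
}

leaky_relu_bwd <- function(dy, cache) {
  dy[cache$neg] <- cache$slope * dy[cache$neg]
  dy
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::rbinom(length(x), 1L, 1 - p) / (1 - p), dim(x) %||% length(x))
  list(out = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- multi-head self-attention ---------------------------------------------

attention_fwd <- function(x, p, heads) {
  K <- ncol(x); n <- nrow(x); dh <- K %/% heads
  q <- linear_fwd(x, p$Wq, p$bq)$out
  k <- linear_fwd(x, p$Wk, p$bk)$out
  v <- linear_fwd(x, p$Wv, p$bv)$out
  ctx <- matrix(0, n, K)
  att <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    s <- (q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE])) / sqrt(dh)
    a <- softmax_rows(s)
    att[[h]] <- a
    ctx[, cols] <- a %*% v[, cols, drop = FALSE]
  }
  out <- sweep(ctx %*% p$Wo, 2L, p$bo, "+")
  list(out = out,
       cache = list(x = x, q = q, k = k, v = v, ctx = ctx, att = att,
                    heads = heads, dh = dh))
}

attention_bwd <- function(dy, cache, p) {
  x <- cache$x; heads <- cache$heads; dh <- cache$dh
  n <- nrow(x); K <- ncol(x)
  dWo <- crossprod(cache$ctx, dy)
  dbo <- colSums(dy)
  dctx <- dy %*% t(p$Wo)
  dq <- matrix(0, n, K); dk <- matrix(0, n, K); dv <- matrix(0, n, K)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * dh + seq_len(dh)
    a <- cache$att[[h]]
    dv[, cols] <- crossprod(a, dctx[, cols, drop = FALSE])
    da <- dctx[, cols, drop = FALSE] %*% t(cache$v[, cols, drop = FALSE])
    ds <- a * (da - rowSums(da * a))          # softmax backward, row-wise
    ds <- ds / sqrt(dh)
    dq[, cols] <- ds %*% cache$k[, cols, drop = FALSE]
    dk[, cols] <- crossprod(ds, cache$q[, cols, drop = FALSE])
  }
  gq <- linear_bwd(dq, x, p$Wq)
  gk <- linear_bwd(dk, x, p$Wk)
  gv <- linear_bwd(dv, x, p$Wv)
  list(dx = gq$dx + gk$dx + gv$dx,
       grads = list(Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
                    Wv = gv$dW, bv = gv$db, Wo = dWo, bo = dbo))
}

# ---- volumetric ops ---------------------------------------------------------

# zero-padded shift: out[i] = x[i + d] (per axis), d in -1/0/1
shift3 <- function(x, d) {
  dm <- dim(x)
  out <- array(0, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- (1L + d[ax]):dm[ax]
      dst[[ax]] <- 1L:(dm[ax] - d[ax])
    } else {
      src[[ax]] <- 1L:(dm[ax] + d[ax])
      dst[[ax]] <- (1L - d[ax]):dm[ax]
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]], ] <-
    x[src[[1]], src[[2]], src[[3]], , drop = FALSE]
  out
}

as_mat <- function(x) {
  dm <- dim(x)
  matrix(x, prod(dm[1:3]), dm[4])
}

# 3^3 "same" convolution; W: array(3,3,3,Cin,Cout), b: Cout.
# Only the input is cached; shifts are recomputed in the backward pass to
# keep activation memory O(1) in the kernel size.
conv3_fwd <- function(x, W, b) {
  dm <- dim(x); cout <- dim(W)[5]
  y <- matrix(rep(b, each = prod(dm[1:3])), prod(dm[1:3]), cout)
  for (dz in -1:1) for (dy_ in -1:1) for (dx_ in -1:1) {
    xs <- shift3(x, c(dx_, dy_, dz))
    y <- y + as_mat(xs) %*% matrix(W[dx_ + 2L, dy_ + 2L, dz + 2L, , ], dm[4], cout)
  }
  list(out = array(y, c(dm[1:3], cout)), cache = list(x = x, dm = dm))
}

conv3_bwd <- function(dy, cache, W) {
  dm <- cache$dm; cout <- dim(W)[5]
  dy_mat <- as_mat(dy)
  dW <- array(0, dim(W))
  dx <- array(0, dm)
  for (dz in -1:1) for (dy_ in -1:1) for (dx_ in -1:1) {
    xs_mat <- as_mat(shift3(cache$x, c(dx_, dy_, dz)))
    dW[dx_ + 2L, dy_ + 2L, dz + 2L, , ] <- crossprod(xs_mat, dy_mat)
    wk <- matrix(W[dx_ + 2L, dy_ + 2L, dz + 2L, , ], dm[4], cout)
    # out[i] depends on x[i + d]  =>  dx[j] += shift by -d of (dy %*% t(W))
    dcontrib <- array(dy_mat %*% t(wk), c(dim(dy)[1:3], dm[4]))
    dx <- dx + shift3(dcontrib, c(-dx_, -dy_, -dz))
  }
  list(dx = dx, dW = dW, db = colSums(dy_mat))
}

# 1^3 convolution (channel mixing)
conv1_fwd <- function(x, W, b) {
  dm <- dim(x)
  y <- sweep(as_mat(x) %*% W, 2L, b, "+")
  list(out = array(y, c(dm[1:3], ncol(W))), cache = list(x_mat = as_mat(x), dm = dm))
}

conv1_bwd <- function(dy, cache, W) {
  dy_mat <- as_mat(dy)
  list(dx = array(dy_mat %*% t(W), cache$dm),
       dW = crossprod(cache$x_mat, dy_mat),
       db = colSums(dy_mat))
}

# transposed convolution, kernel 2 stride 2 (x2 upsampling);
# W: array(2,2,2,Cin,Cout), b: Cout
deconv2_fwd <- function(x, W, b) {
  dm <- dim(x); cout <- dim(W)[5]
  x_mat <- as_mat(x)
  out <- array(0, c(2L * dm[1:3], cout))
  for (dz in 1:2) for (dy_ in 1:2) for (dx_ in 1:2) {
    block <- array(x_mat %*% matrix(W[dx_, dy_, dz, , ], dm[4], cout),
                   c(dm[1:3], cout))
    out[seq(dx_, 2L * dm[1], by = 2L),
        seq(dy_, 2L * dm[2], by = 2L),
        seq(dz, 2L * dm[3], by = 2L), ] <- block
  }
  out <- sweep(out, 4L, b, "+")
  list(out = out, cache = list(x_mat = x_mat, dm = dm))
}

deconv2_bwd <- function(dy, cache, W) {
  dm <- cache$dm; cout <- dim(W)[5]
  dx_mat <- matrix(0, prod(dm[1:3]), dm[4])
  dW <- array(0, dim(W))
  db <- numeric(cout)
  for (dz in 1:2) for (dy_ in 1:2) for (dx_ in 1:2) {
    sub <- dy[seq(dx_, 2L * dm[1], by = 2L),
              seq(dy_, 2L * dm[2], by = 2L),
              seq(dz, 2L * dm[3], by = 2L), , drop = FALSE]
    sub_mat <- matrix(sub, prod(dm[1:3]), cout)
    db <- db + colSums(sub_mat)
    dW[dx_, dy_, dz, , ] <- crossprod(cache$x_mat, sub_mat)
    dx_mat <- dx_mat + sub_mat %*% t(matrix(W[dx_, dy_, dz, , ], dm[4], cout))
  }
  list(dx = array(dx_mat, dm), dW = dW, db = db)
}

# instance normalization over spatial dims, per channel, affine
instnorm_fwd <- function(x, g, b, eps = 1e-5) {
  dm <- dim(x)
  xm <- as_mat(x)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
  list(out = array(y, dm), cache = list(xhat = xhat, inv = inv, g = g, dm = dm))
}

instnorm_bwd <- function(dy, cache) {
  dm <- cache$dm
  dy_mat <- as_mat(dy)
  xhat <- cache$xhat
  dxhat <- sweep(dy_mat, 2L, cache$g, "*")
  m <- nrow(xhat)
  dx <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dxhat), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), m, ncol(xhat), byrow = TRUE),
              2L, cache$inv, "*")
  list(dx = array(dx, dm), dg = colSums(dy_mat * xhat), db = colSums(dy_mat))
}

concat4_fwd <- function(a, b) {
  dm <- dim(a)
  list(out = array(c(a, b), c(dm[1:3], dm[4] + dim(b)[4])),
       cache = list(ca = dm[4], cb = dim(b)[4]))
}

concat4_bwd <- function(dy, cache) {
  list(da = dy[, , , seq_len(cache$ca), drop = FALSE],
       db = dy[, , , cache$ca + seq_len(cache$cb), drop = FALSE])
}
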