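# Convolution primitives for the autodiff engine.
#
# Image tensors are H x W x C arrays (column-major). Convolutions are
# computed via im2col: patches are unrolled so the convolution becomes one
# matrix product, which is where almost all of the model's arithmetic lives.
# Weight layout: conv2d uses (kh, kw, c_in, c_out); conv2dt (transposed
# convolution) uses (kh, kw, c_out, c_in), making it the exact adjoint of a
# conv2d with the same geometry.

pad_spatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

unpad_spatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  x[p + seq_len(d[1] - 2L * p), p + seq_len(d[2] - 2L * p), , drop = FALSE]
}

# unroll kh x kw patches of a padded H x W x C array into an
# (oh*ow) x (kh*kw*C) matrix; column k = (c-1)*kh*kw + (dj-1)*kh + di
im2col <- function(xp, kh, kw, stride) {
  d <- dim(xp)
  oh <- (d[1] - kh) %/% stride + 1L
  ow <- (d[2] - kw) %/% stride + 1L
  C <- d[3]
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  out <- matrix(0, oh * ow, kh * kw * C)
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      blk <- xp[ri + (di - 1L), ci + (dj - 1L), , drop = FALSE]
      out[, (seq_len(C) - 1L) * kh * kw + (dj - 1L) * kh + di] <-
        matrix(blk, oh * ow, C)
    }
  }
  out
}

# adjoint of im2col: scatter-add patch columns back into an H x W x C array
col2im <- function(cols, H, W, C, kh, kw, stride) {
  oh <- (H - kh) %/% stride + 1L
  ow <- (W - kw) %/% stride + 1L
  ri <- seq.int(1L, by = stride, length.out = oh)
  ci <- seq.int(1L, by = stride, length.out = ow)
  xp <- array(0, c(H, W, C))
  for (dj in seq_len(kw)) {
    for (di in seq_len(kh)) {
      blk <- array(cols[, (seq_len(C) - 1L) * kh * kw + (dj - 1L) * kh + di],
                   c(oh, ow, C))
      xp[ri + (di - 1L), ci + (dj - 1L), ] <-
        xp[ri + (di - 1L), ci + (dj - 1L), , drop = FALSE] + blk
    }
  }
  xp
}

# strided 2-d convolution; x: H x W x Cin node, w: (kh,kw,Cin,Cout) node,
# b: length-Cout node
ad_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  dw <- dim(w$value)
  kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  stopifnot(dim(x$value)[3] == cin)
  xp <- pad_spatial(x$value, pad)
  dp <- dim(xp)
  oh <- (dp[1] - kh) %/% stride + 1L
  ow <- (dp[2] - kw) %/% stride + 1L
  cols <- im2col(xp, kh, kw, stride)
  wm <- w$value
  dim(wm) <- c(kh * kw * cin, cout)
  ym <- cols %*% wm
  ym <- sweep(ym, 2L, b$value, "+")
  y <- ym
  dim(y) <- c(oh, ow, cout)
  ad_node(y, list(x, w, b), function(g) {
    gm <- g
    dim(gm) <- c(oh * ow, cout)
    dwm <- crossprod(cols, gm)
    dim(dwm) <- c(kh, kw, cin, cout)
    db <- colSums(gm)
    dcols <- gm %*% t(wm)
    dxp <- col2im(dcols, dp[1], dp[2], cin, kh, kw, stride)
    list(unpad_spatial(dxp, pad), dwm, db)
  })
}

# transposed convolution (fractionally strided); output size
# (H-1)*stride + kh - 2*pad per axis
ad_conv2dt <- function(x, w, b, stride = 1L, pad = 0L) {
  dw <- dim(w$value)
  kh <- dw[1]; kw <- dw[2]; cout <- dw[3]; cin <- dw[4]
  dx <- dim(x$value)
  stopifnot(dx[3] == cin)
  Hp <- (dx[1] - 1L) * stride + kh
  Wp <- (dx[2] - 1L) * stride + kw
  xm <- x$value
  dim(xm) <- c(dx[1] * dx[2], cin)
  wm <- w$value
  dim(wm) <- c(kh * kw * cout, cin)
  cols <- xm %*% t(wm)
  yp <- col2im(cols, Hp, Wp, cout, kh, kw, stride)
  y <- unpad_spatial(yp, pad)
  y <- sweep(y, 3L, b$value, "+")
  dy <- dim(y)
  ad_node(y, list(x, w, b), function(g) {
    gp <- pad_spatial(g, pad)
    gcols <- im2col(gp, kh, kw, stride)
    dxm <- gcols %*% wm
    dim(dxm) <- dx
    dwm <- crossprod(gcols, xm)
    dim(dwm) <- c(kh, kw, cout, cin)
    db <- apply(g, 3L, sum)
    list(dxm, dwm, db)
  })
}

# row interpolation matrix for bilinear resampling (half-pixel centers)
bilinear_matrix <- function(n_in, n_out) {
  R <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    R[, 1L] <- 1
    return(R)
  }
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * n_in / n_out - 0.5
    s <- min(max(s, 0), n_in - 1)
    lo <- floor(s)
    hi <- min(lo + 1, n_in - 1)
    f <- s - lo
    R[i, lo + 1L] <- R[i, lo + 1L] + (1 - f)
    R[i, hi + 1L] <- R[i, hi + 1L] + f
  }
  R
}

# bilinear spatial resize of an H x W x C node (linear map, exact adjoint)
ad_resize_bilinear <- function(x, oh, ow) {
  d <- dim(x$value)
  Rh <- bilinear_matrix(d[1], oh)
  Rw <- bilinear_matrix(d[2], ow)
  y <- array(0, c(oh, ow, d[3]))
  for (c in seq_len(d[3])) y[, , c] <- Rh %*% x$value[, , c] %*% t(Rw)
  ad_node(y, list(x), function(g) {
    dx <- array(0, d)
    for (c in seq_len(d[3])) dx[, , c] <- t(Rh) %*% g[, , c] %*% Rw
    list(dx)
  })
}

# transpose the two spatial axes of an H x W x C node
ad_transpose_hw <- function(x) {
  d <- dim(x$value)
  y <- aperm(x$value, c(2L, 1L, 3L))
  ad_node(y, list(x), function(g) list(aperm(g, c(2L, 1L, 3L))))
}
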