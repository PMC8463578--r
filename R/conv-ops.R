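# Array primitives for the simulator: 2-D convolution (stride 1, zero "same"
# padding) via im2col + BLAS matmul, 2x2 average pooling, global average
# pooling, and their backward passes. All feature maps are arrays with
# dimensions (channels, rows, cols, batch); channel is the fastest index so
# im2col blocks are contiguous.

pad_spatial <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  xp
}

# Patch matrix: rows ordered (channel fastest, then kernel row, then kernel
# col) to match the flattened (Cin, kh, kw) layout of the weight matrix.
im2col <- function(xp, kh, kw, hout, wout) {
  cin <- dim(xp)[1]
  b <- dim(xp)[4]
  P <- matrix(0, cin * kh * kw, hout * wout * b)
  r <- 0L
  for (dx in seq_len(kw)) {
    for (dy in seq_len(kh)) {
      blk <- xp[, dy:(dy + hout - 1), dx:(dx + wout - 1), , drop = FALSE]
      P[(r + 1):(r + cin), ] <- blk
      r <- r + cin
    }
  }
  P
}

# W is a (Cout) x (Cin*kh*kw) matrix; returns list(out, P) with out of
# dimension (Cout, H, W, B). P is kept for the backward pass.
conv2d_forward <- function(x, W, kh, kw) {
  d <- dim(x)
  pad <- (kh - 1L) %/% 2L
  xp <- pad_spatial(x, pad)
  P <- im2col(xp, kh, kw, d[2], d[3])
  out <- W %*% P
  dim(out) <- c(nrow(W), d[2], d[3], d[4])
  list(out = out, P = P, indim = d)
}

conv2d_backward <- function(dout, W, P, indim, kh, kw) {
  cout <- nrow(W)
  dm <- matrix(dout, nrow = cout)
  dW <- dm %*% t(P)
  dP <- crossprod(W, dm)
  pad <- (kh - 1L) %/% 2L
  cin <- indim[1]
  hout <- indim[2]
  wout <- indim[3]
  dxp <- array(0, c(cin, hout + 2 * pad, wout + 2 * pad, indim[4]))
  r <- 0L
  for (dx in seq_len(kw)) {
    for (dy in seq_len(kh)) {
      blk <- dP[(r + 1):(r + cin), ]
      dim(blk) <- c(cin, hout, wout, indim[4])
      dxp[, dy:(dy + hout - 1), dx:(dx + wout - 1), ] <-
        dxp[, dy:(dy + hout - 1), dx:(dx + wout - 1), , drop = FALSE] + blk
      r <- r + cin
    }
  }
  dx <- if (pad == 0) dxp else dxp[, (pad + 1):(pad + hout), (pad + 1):(pad + wout), , drop = FALSE]
  dim(dx) <- indim
  list(dx = dx, dW = dW)
}

# 2x2 average pooling, stride 2; spatial dims must be even.
avgpool2_forward <- function(x) {
  d <- dim(x)
  if (d[2] %% 2L != 0L || d[3] %% 2L != 0L) {
    stopf("average pooling needs even spatial dimensions, got %dx%d", d[2], d[3])
  }
  ri <- seq(1, d[2], by = 2)
  ci <- seq(1, d[3], by = 2)
  (x[, ri, ci, , drop = FALSE] + x[, ri + 1, ci, , drop = FALSE] +
     x[, ri, ci + 1, , drop = FALSE] + x[, ri + 1, ci + 1, , drop = FALSE]) / 4
}

avgpool2_backward <- function(dout, indim) {
  dx <- array(0, indim)
  ri <- seq(1, indim[2], by = 2)
  ci <- seq(1, indim[3], by = 2)
  g <- dout / 4
  dx[, ri, ci, ] <- g
  dx[, ri + 1, ci, ] <- g
  dx[, ri, ci + 1, ] <- g
  dx[, ri + 1, ci + 1, ] <- g
  dx
}

# Global average pooling (C,H,W,B) -> C x B matrix.
gap_forward <- function(x) {
  d <- dim(x)
  out <- apply(x, 4, function(s) rowMeans(matrix(s, nrow = d[1])))
  matrix(out, nrow = d[1], ncol = d[4])
}

gap_backward <- function(dout, indim) {
  hw <- indim[2] * indim[3]
  dx <- apply(dout, 2, function(col) rep(col, times = hw)) / hw
  array(dx, indim)
}

flatten_forward <- function(x) {
  d <- dim(x)
  matrix(x, nrow = prod(d[-length(d)]), ncol = d[length(d)])
}
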