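# Minimal convolutional-network machinery in base R.
#
# Feature tensors are arrays (H, W, C); convolution weights are arrays
# (k, k, Cin, Cout) and are applied through im2col matrix multiplication.
# Column ordering of the im2col matrix follows R's column-major flattening
# of the weight array: ky fastest, then kx, then cin — so the forward pass
# is a single `cols %*% matrix(W)`.

conv_pad <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

im2col <- function(xp, k, stride, h_out, w_out) {
  cin <- dim(xp)[3]
  cols <- matrix(0, h_out * w_out, k * k * cin)
  col <- 0L
  for (ci in seq_len(cin)) {
    for (kx in seq_len(k)) {
      for (ky in seq_len(k)) {
        col <- (ci - 1L) * k * k + (kx - 1L) * k + ky
        sl <- xp[ky + stride * (seq_len(h_out) - 1L),
                 kx + stride * (seq_len(w_out) - 1L), ci]
        cols[, col] <- as.vector(sl)
      }
    }
  }
  cols
}

conv_forward <- function(x, w, b, stride = 1L, pad = (dim(w)[1] - 1L) %/% 2L) {
  k <- dim(w)[1]
  if (dim(x)[3] != dim(w)[3]) {
    stopf("conv channel mismatch: input has %d channels, weights expect %d",
          dim(x)[3], dim(w)[3], class = "strawdetect_shape_error")
  }
  xp <- conv_pad(x, pad)
  h_out <- (dim(xp)[1] - k) %/% stride + 1L
  w_out <- (dim(xp)[2] - k) %/% stride + 1L
  cols <- im2col(xp, k, stride, h_out, w_out)
  wm <- matrix(w, ncol = dim(w)[4])
  out_m <- cols %*% wm
  out_m <- sweep(out_m, 2L, b, "+")
  list(out = array(out_m, dim = c(h_out, w_out, dim(w)[4])),
       cache = list(cols = cols, x_dim = dim(x), k = k, stride = stride,
                    pad = pad, h_out = h_out, w_out = w_out, w = w))
}

conv_backward <- function(d_out, cache) {
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  h_out <- cache$h_out; w_out <- cache$w_out
  w <- cache$w
  cout <- dim(w)[4]; cin <- dim(w)[3]
  d_out_m <- matrix(d_out, h_out * w_out, cout)
  dw <- array(crossprod(cache$cols, d_out_m), dim = dim(w))
  db <- colSums(d_out_m)
  dcols <- tcrossprod(d_out_m, matrix(w, ncol = cout))
  hp <- cache$x_dim[1] + 2L * pad
  wp <- cache$x_dim[2] + 2L * pad
  dxp <- array(0, dim = c(hp, wp, cin))
  for (ci in seq_len(cin)) {
    for (kx in seq_len(k)) {
      for (ky in seq_len(k)) {
        col <- (ci - 1L) * k * k + (kx - 1L) * k + ky
        ri <- ky + stride * (seq_len(h_out) - 1L)
        cj <- kx + stride * (seq_len(w_out) - 1L)
        dxp[ri, cj, ci] <- dxp[ri, cj, ci] + matrix(dcols[, col], h_out, w_out)
      }
    }
  }
  dx <- if (pad > 0L) {
    dxp[pad + seq_len(cache$x_dim[1]), pad + seq_len(cache$x_dim[2]), ,
        drop = FALSE]
  } else {
    dxp
  }
  list(dx = dx, dw = dw, db = db)
}

fc_forward <- function(x, w, b) {
  list(out = as.vector(x %*% w) + b, cache = list(x = x, w = w))
}

fc_backward <- function(d_out, cache) {
  list(dx = as.vector(cache$w %*% d_out),
       dw = outer(cache$x, d_out),
       db = d_out)
}

he_init_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

he_init_fc <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

smooth_l1 <- function(d) ifelse(abs(d) < 1, 0.5 * d^2, abs(d) - 0.5)

smooth_l1_grad <- function(d) ifelse(abs(d) < 1, d, sign(d))

# soft dice loss on probabilities p with binary targets t; returns the loss
# 1 - dice and its gradient with respect to p
dice_loss <- function(p, t, eps = 1e-6) {
  i <- sum(p * t)
  u <- sum(p) + sum(t)
  dice <- (2 * i + eps) / (u + eps)
  grad <- -(2 * t * (u + eps) - (2 * i + eps)) / (u + eps)^2
  list(loss = 1 - dice, grad = grad)
}
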