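# Shared fixture builders. Everything is generated in code; no binary data.

mk_disc <- function(h, w, cy, cx, rx, ry = rx) {
  m <- matrix(FALSE, h, w)
  m[((row(m) - cy) / ry)^2 + ((col(m) - cx) / rx)^2 <= 1] <- TRUE
  m
}

binarize_matrix_for_test <- function(m) {
  strawdetect:::region_mask_from_binary(m > 0)
}

grey_image <- function(h = 16, w = 16, level = 0.5) {
  array(level, dim = c(h, w, 3))
}

noisy_image <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), dim = c(h, w, 3))
}

# brute-force windowed median with reflection padding (oracle for
# median_denoise)
median_oracle <- function(image, window = 3L) {
  k <- (window - 1L) %/% 2L
  h <- dim(image)[1]; w <- dim(image)[2]
  ridx <- c(rev(seq_len(k) + 1L), seq_len(h), h - seq_len(k))
  cidx <- c(rev(seq_len(k) + 1L), seq_len(w), w - seq_len(k))
  out <- image
  for (ch in 1:3) {
    p <- image[, , ch][ridx, cidx]
    o <- matrix(0, h, w)
    for (i in seq_len(h)) {
      for (j in seq_len(w)) {
        o[i, j] <- stats::median(p[i:(i + 2 * k), j:(j + 2 * k)])
      }
    }
    out[, , ch] <- o
  }
  out
}

# direct-summation convolution oracle (zero padding, stride 1)
conv_loop_oracle <- function(x, w, b) {
  k <- dim(w)[1]; p <- (k - 1) %/% 2
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]; cout <- dim(w)[4]
  xp <- array(0, dim = c(h + 2 * p, wd + 2 * p, cin))
  xp[p + seq_len(h), p + seq_len(wd), ] <- x
  out <- array(0, dim = c(h, wd, cout))
  for (i in seq_len(h)) for (j in seq_len(wd)) for (co in seq_len(cout)) {
    s <- b[co]
    for (ki in seq_len(k)) for (kj in seq_len(k)) for (ci in seq_len(cin)) {
      s <- s + xp[i + ki - 1, j + kj - 1, ci] * w[ki, kj, ci, co]
    }
    out[i, j, co] <- s
  }
  out
}

# exhaustive optimal one-to-one assignment TP count (oracle for greedy
# matching); feasible for <= ~6 predictions
optimal_tp <- function(pm, tm, thr) {
  np <- nrow(pm); nt <- nrow(tm)
  if (np == 0 || nt == 0) return(0L)
  ious <- outer(seq_len(np), seq_len(nt),
                Vectorize(function(i, j) iou(pm[i, ], tm[j, ])))
  ok <- ious >= thr
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    recurse(i + 1, used, count)
    for (j in which(ok[i, ] & !used)) {
      used2 <- used; used2[j] <- TRUE
      recurse(i + 1, used2, count + 1L)
    }
  }
  recurse(1L, rep(FALSE, nt), 0L)
  best
}
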