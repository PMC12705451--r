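# Minimal convolutional-network machinery: im2col convolutions with manual
# backpropagation and an Adam optimiser. Arrays are single images (H x W x C);
# weights are arrays (k x k x Cin x Cout). Everything is deterministic given
# the seeds used at initialisation. Kept internal: users interact with the
# transform/classifier constructors, not with these primitives.

zero_pad <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  xp
}

# Linear-index matrix mapping output positions x kernel offsets to positions
# in the padded input; cached per (dims, k, stride) since shapes repeat
# thousands of times during training and cycling.
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(dims, k, stride) {
  key <- paste(c(dims, k, stride), collapse = "_")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  i0 <- seq.int(1L, dims[1] - k + 1L, stride)
  j0 <- seq.int(1L, dims[2] - k + 1L, stride)
  base <- as.vector(outer(i0, (j0 - 1L) * dims[1], "+"))
  offs <- as.vector(outer(outer(0:(k - 1L), (0:(k - 1L)) * dims[1], "+"),
                          (seq_len(dims[3]) - 1L) * dims[1] * dims[2], "+"))
  idx <- outer(as.integer(base), as.integer(offs), "+")
  storage.mode(idx) <- "integer"
  .im2col_cache[[key]] <- idx
  idx
}

# Column matrix (Ho*Wo, k*k*C); column order matches matrix(W, k*k*Cin, Cout).
im2col <- function(xp, k, stride) {
  idx <- im2col_index(dim(xp), k, stride)
  cols <- xp[idx]
  dim(cols) <- dim(idx)
  cols
}

# Scatter-add by kernel offset: for a fixed offset the target positions of
# all channels are distinct, so each of the k*k iterations is a single
# vectorised gather/add/scatter.
col2im <- function(dcols, dims, k, stride) {
  idx <- im2col_index(dims, k, stride)
  kk <- k * k
  dxp <- numeric(prod(dims))
  for (o in seq_len(kk)) {
    cols <- seq.int(o, ncol(idx), by = kk)
    ii <- idx[, cols]
    dxp[ii] <- dxp[ii] + dcols[, cols]
  }
  array(dxp, dims)
}

conv_fwd <- function(x, W, b, stride = 1L, pad = 1L) {
  k <- dim(W)[1]
  xp <- zero_pad(x, pad)
  cols <- im2col(xp, k, stride)
  Wm <- W
  dim(Wm) <- c(k * k * dim(W)[3], dim(W)[4])
  ym <- cols %*% Wm
  ym <- ym + rep(b, each = nrow(ym))
  ho <- length(seq.int(1L, dim(xp)[1] - k + 1L, stride))
  wo <- length(seq.int(1L, dim(xp)[2] - k + 1L, stride))
  dim(ym) <- c(ho, wo, dim(W)[4])
  list(y = ym,
       cache = list(cols = cols, dims = dim(xp), k = k, stride = stride,
                    pad = pad, W = W, xdim = dim(x)))
}

conv_bwd <- function(dy, cache) {
  k <- cache$k
  Wm <- matrix(cache$W, k * k * dim(cache$W)[3], dim(cache$W)[4])
  dym <- matrix(dy, ncol = dim(cache$W)[4])
  dW <- array(crossprod(cache$cols, dym), dim(cache$W))
  db <- colSums(dym)
  dcols <- dym %*% t(Wm)
  dxp <- col2im(dcols, cache$dims, k, cache$stride)
  p <- cache$pad
  dx <- if (p > 0)
    dxp[p + seq_len(cache$xdim[1]), p + seq_len(cache$xdim[2]), , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(dy, mask) dy * mask

sigmoid_fwd <- function(x) 1 / (1 + exp(-x))
sigmoid_bwd <- function(dy, y) dy * y * (1 - y)

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq.int(1L, d[1], 2L); o2 <- seq.int(1L, d[2], 2L)
  dy[o1, o2, , drop = FALSE] + dy[o1 + 1L, o2, , drop = FALSE] +
    dy[o1, o2 + 1L, , drop = FALSE] + dy[o1 + 1L, o2 + 1L, , drop = FALSE]
}

gap_fwd <- function(x) apply(x, 3L, mean)

gap_bwd <- function(df, xdim) {
  n <- xdim[1] * xdim[2]
  array(rep(df / n, each = n), xdim)
}

# Per-image standardisation to zero mean, unit variance (population sd),
# with the exact gradient used during backpropagation through an upstream
# transform.
std_fwd <- function(x) {
  mu <- mean(x)
  sig <- sqrt(mean((x - mu)^2))
  s <- sig + 1e-6
  z <- (x - mu) / s
  list(z = z, cache = list(s = s, sig = sig, z = z, n = length(x)))
}

std_bwd <- function(dz, cache) {
  s <- cache$s; z <- cache$z; n <- cache$n
  g <- dz
  if (cache$sig < 1e-12) return((g - mean(g)) / s)
  (g - mean(g)) / s - z * (sum(g * z) / (n * s)) * (cache$sig / s)
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

new_conv_param <- function(k, cin, cout) {
  list(W = he_init(k, cin, cout), b = numeric(cout))
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  flat <- rapply(params, function(p) p * 0, how = "replace")
  list(m = flat, v = flat, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- Map(walk, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}
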