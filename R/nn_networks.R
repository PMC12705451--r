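# Network definitions built on the layer primitives: a 2-level encoder-decoder
# generator with a skip connection (desk-scale default; the full-scale preset
# of the method is a five-level U-net, which this architecture miniaturises),
# a 4-layer strided convolutional discriminator ending in a scalar probability,
# and a small frozen convolutional feature backbone.

gen_init_params <- function(cin, cout, base = 8L, seed = 1L) {
  with_seed(seed, list(
    c1 = new_conv_param(3L, cin, base),
    c2 = new_conv_param(3L, base, 2L * base),
    c3 = new_conv_param(3L, 2L * base, 2L * base),
    c4 = new_conv_param(3L, 2L * base, base),
    c5 = new_conv_param(3L, 2L * base, base),
    c6 = new_conv_param(3L, base, cout)
  ))
}

gen_forward <- function(params, x, keep_cache = FALSE) {
  st <- std_fwd(x)
  f1 <- conv_fwd(st$z, params$c1$W, params$c1$b, 1L, 1L)
  r1 <- relu_fwd(f1$y)
  f2 <- conv_fwd(r1$y, params$c2$W, params$c2$b, 2L, 1L)
  r2 <- relu_fwd(f2$y)
  f3 <- conv_fwd(r2$y, params$c3$W, params$c3$b, 1L, 1L)
  r3 <- relu_fwd(f3$y)
  up <- upsample2_fwd(r3$y)
  f4 <- conv_fwd(up, params$c4$W, params$c4$b, 1L, 1L)
  r4 <- relu_fwd(f4$y)
  cc <- array(c(r4$y, r1$y), c(dim(r4$y)[1], dim(r4$y)[2],
                               dim(r4$y)[3] + dim(r1$y)[3]))
  f5 <- conv_fwd(cc, params$c5$W, params$c5$b, 1L, 1L)
  r5 <- relu_fwd(f5$y)
  f6 <- conv_fwd(r5$y, params$c6$W, params$c6$b, 1L, 1L)
  y <- f6$y  # linear output head; [0,1] clipping happens at inference
  cache <- if (keep_cache)
    list(st = st, f1 = f1, r1 = r1, f2 = f2, r2 = r2, f3 = f3, r3 = r3,
         f4 = f4, r4 = r4, f5 = f5, r5 = r5, f6 = f6, y = y,
         nch4 = dim(r4$y)[3])
  list(y = y, cache = cache)
}

gen_backward <- function(params, cache, dy) {
  b6 <- conv_bwd(dy, cache$f6$cache)
  g5 <- relu_bwd(b6$dx, cache$r5$mask)
  b5 <- conv_bwd(g5, cache$f5$cache)
  n4 <- cache$nch4
  d4 <- b5$dx[, , seq_len(n4), drop = FALSE]
  dskip <- b5$dx[, , n4 + seq_len(dim(b5$dx)[3] - n4), drop = FALSE]
  g4 <- relu_bwd(d4, cache$r4$mask)
  b4 <- conv_bwd(g4, cache$f4$cache)
  dup <- upsample2_bwd(b4$dx)
  g3 <- relu_bwd(dup, cache$r3$mask)
  b3 <- conv_bwd(g3, cache$f3$cache)
  g2 <- relu_bwd(b3$dx, cache$r2$mask)
  b2 <- conv_bwd(g2, cache$f2$cache)
  g1 <- relu_bwd(b2$dx + dskip, cache$r1$mask)
  b1 <- conv_bwd(g1, cache$f1$cache)
  dx <- std_bwd(b1$dx, cache$st$cache)
  list(grads = list(c1 = list(W = b1$dW, b = b1$db),
                    c2 = list(W = b2$dW, b = b2$db),
                    c3 = list(W = b3$dW, b = b3$db),
                    c4 = list(W = b4$dW, b = b4$db),
                    c5 = list(W = b5$dW, b = b5$db),
                    c6 = list(W = b6$dW, b = b6$db)),
       dx = dx)
}

disc_init_params <- function(cin, base = 8L, seed = 1L) {
  with_seed(seed, list(
    c1 = new_conv_param(3L, cin, base),
    c2 = new_conv_param(3L, base, 2L * base),
    c3 = new_conv_param(3L, 2L * base, 4L * base),
    c4 = new_conv_param(3L, 4L * base, 4L * base),
    fc = list(W = matrix(stats::rnorm(4L * base, 0, sqrt(1 / (4 * base))),
                         1L, 4L * base),
              b = 0)
  ))
}

disc_forward <- function(params, x, keep_cache = FALSE) {
  st <- std_fwd(x)
  f1 <- conv_fwd(st$z, params$c1$W, params$c1$b, 2L, 1L); r1 <- relu_fwd(f1$y)
  f2 <- conv_fwd(r1$y, params$c2$W, params$c2$b, 2L, 1L); r2 <- relu_fwd(f2$y)
  f3 <- conv_fwd(r2$y, params$c3$W, params$c3$b, 2L, 1L); r3 <- relu_fwd(f3$y)
  f4 <- conv_fwd(r3$y, params$c4$W, params$c4$b, 2L, 1L); r4 <- relu_fwd(f4$y)
  v <- gap_fwd(r4$y)
  z <- as.numeric(params$fc$W %*% v + params$fc$b)
  p <- sigmoid_fwd(z)
  cache <- if (keep_cache)
    list(st = st, f1 = f1, r1 = r1, f2 = f2, r2 = r2, f3 = f3, r3 = r3,
         f4 = f4, r4 = r4, v = v, p = p, xdim4 = dim(r4$y))
  list(p = p, cache = cache)
}

# dp: scalar dL/dp. Returns weight grads and dL/dx (for the generator's
# adversarial term).
disc_backward <- function(params, cache, dp) {
  dz <- sigmoid_bwd(dp, cache$p)
  dW_fc <- dz * matrix(cache$v, 1L)
  db_fc <- dz
  dv <- as.numeric(dz * params$fc$W)
  d4 <- gap_bwd(dv, cache$xdim4)
  g4 <- relu_bwd(d4, cache$r4$mask); b4 <- conv_bwd(g4, cache$f4$cache)
  g3 <- relu_bwd(b4$dx, cache$r3$mask); b3 <- conv_bwd(g3, cache$f3$cache)
  g2 <- relu_bwd(b3$dx, cache$r2$mask); b2 <- conv_bwd(g2, cache$f2$cache)
  g1 <- relu_bwd(b2$dx, cache$r1$mask); b1 <- conv_bwd(g1, cache$f1$cache)
  dx <- std_bwd(b1$dx, cache$st$cache)
  list(grads = list(c1 = list(W = b1$dW, b = b1$db),
                    c2 = list(W = b2$dW, b = b2$db),
                    c3 = list(W = b3$dW, b = b3$db),
                    c4 = list(W = b4$dW, b = b4$db),
                    fc = list(W = dW_fc, b = db_fc)),
       dx = dx)
}

# ---- frozen feature backbone ---------------------------------------------

#' Construct the frozen feature backbone
#'
#' A small seeded convolutional feature extractor: three strided 3x3
#' convolution + ReLU stages followed by global average pooling, producing a
#' `n_features`-dimensional descriptor per frame. Parameters are fixed at
#' construction and never trained; only the voting heads learn. Random
#' convolutional features of this kind preserve local-contrast and brightness
#' statistics, which is what the cycle-divergence signature lives in. The
#' full-scale preset of the method uses a pretrained deep residual backbone
#' instead; the backbone is pluggable through this constructor.
#'
#' @param in_channels input channel count (frames with fewer channels are
#'   replicated to match).
#' @param n_features output feature dimension (final channel count).
#' @param seed seed for the frozen random initialisation.
#' @return an object of class `aqua_backbone`.
#' @export
backbone <- function(in_channels = 3L, n_features = 64L, seed = 11L) {
  c2 <- max(8L, n_features %/% 4L)
  c3 <- max(8L, n_features %/% 2L)
  params <- with_seed(seed, list(
    c1 = new_conv_param(3L, in_channels, c2),
    c2 = new_conv_param(3L, c2, c3),
    c3 = new_conv_param(3L, c3, n_features)
  ))
  structure(list(params = params, in_channels = as.integer(in_channels),
                 n_features = as.integer(n_features), seed = as.integer(seed)),
            class = "aqua_backbone")
}

#' Pre-train the feature backbone by autoencoding fixture images
#'
#' The method's full-scale preset uses a deep backbone pretrained on a large
#' external corpus; the desk-scale counterpart trains the small convolutional
#' encoder briefly as an autoencoder on (unlabelled) fixture images, so that
#' the frozen features align with the structures that matter here - nuclei,
#' cytoplasm texture, stain colour - rather than being random projections.
#' The decoder is discarded; the returned backbone is frozen.
#'
#' @param images list of [image_fov]s (any domain; 1-channel frames are
#'   replicated to 3 channels).
#' @param n_features output feature dimension.
#' @param seed seed for initialisation and image order.
#' @param steps optimisation steps (one image per step).
#' @param lr Adam learning rate.
#' @return an `aqua_backbone` with `pretrained = TRUE`.
#' @export
pretrain_backbone <- function(images, n_features = 64L, seed = 11L,
                              steps = 300L, lr = 1e-3) {
  bb <- backbone(3L, n_features, seed)
  c2 <- dim(bb$params$c2$W)[4]
  c1 <- dim(bb$params$c1$W)[4]
  dec <- with_seed(derive_seed(seed, 1L), list(
    d1 = new_conv_param(3L, n_features, c2),
    d2 = new_conv_param(3L, c2, c1),
    d3 = new_conv_param(3L, c1, 3L)
  ))
  params <- c(bb$params, dec)
  state <- adam_init(params)
  px_of <- function(f) {
    px <- as_pixels(f)
    if (dim(px)[3] < 3L) px <- px[, , rep(1L, 3L), drop = FALSE]
    px
  }
  ord <- with_seed(derive_seed(seed, 2L),
                   sample(rep_len(seq_along(images), steps)))
  for (s in seq_len(steps)) {
    x <- px_of(images[[ord[s]]])
    p <- params
    f1 <- conv_fwd(x, p$c1$W, p$c1$b, 2L, 1L); r1 <- relu_fwd(f1$y)
    f2 <- conv_fwd(r1$y, p$c2$W, p$c2$b, 2L, 1L); r2 <- relu_fwd(f2$y)
    f3 <- conv_fwd(r2$y, p$c3$W, p$c3$b, 2L, 1L); r3 <- relu_fwd(f3$y)
    u1 <- upsample2_fwd(r3$y)
    g1 <- conv_fwd(u1, p$d1$W, p$d1$b, 1L, 1L); s1 <- relu_fwd(g1$y)
    u2 <- upsample2_fwd(s1$y)
    g2 <- conv_fwd(u2, p$d2$W, p$d2$b, 1L, 1L); s2 <- relu_fwd(g2$y)
    u3 <- upsample2_fwd(s2$y)
    g3 <- conv_fwd(u3, p$d3$W, p$d3$b, 1L, 1L)
    dy <- 2 * (g3$y - x) / length(x)
    b3 <- conv_bwd(dy, g3$cache)
    db2 <- upsample2_bwd(b3$dx)
    b2 <- conv_bwd(relu_bwd(db2, s2$mask), g2$cache)
    db1 <- upsample2_bwd(b2$dx)
    b1 <- conv_bwd(relu_bwd(db1, s1$mask), g1$cache)
    de3 <- upsample2_bwd(b1$dx)
    e3 <- conv_bwd(relu_bwd(de3, r3$mask), f3$cache)
    e2 <- conv_bwd(relu_bwd(e3$dx, r2$mask), f2$cache)
    e1 <- conv_bwd(relu_bwd(e2$dx, r1$mask), f1$cache)
    grads <- list(c1 = list(W = e1$dW, b = e1$db),
                  c2 = list(W = e2$dW, b = e2$db),
                  c3 = list(W = e3$dW, b = e3$db),
                  d1 = list(W = b1$dW, b = b1$db),
                  d2 = list(W = b2$dW, b = b2$db),
                  d3 = list(W = b3$dW, b = b3$db))
    up <- adam_step(params, grads, state, lr)
    params <- up$params; state <- up$state
  }
  bb$params <- params[c("c1", "c2", "c3")]
  bb$pretrained <- TRUE
  bb
}

# Forward pass for one frame; returns the pooled feature vector and, on
# request, the final activation maps (for Grad-CAM).
backbone_forward <- function(bb, px, keep_activations = FALSE) {
  if (dim(px)[3] < bb$in_channels)
    px <- array(px[, , rep(seq_len(dim(px)[3]),
                           length.out = bb$in_channels)],
                c(dim(px)[1], dim(px)[2], bb$in_channels))
  p <- bb$params
  a1 <- relu_fwd(conv_fwd(px, p$c1$W, p$c1$b, 2L, 1L)$y)$y
  a2 <- relu_fwd(conv_fwd(a1, p$c2$W, p$c2$b, 2L, 1L)$y)$y
  a3 <- relu_fwd(conv_fwd(a2, p$c3$W, p$c3$b, 2L, 1L)$y)$y
  f <- gap_fwd(a3)
  if (keep_activations) list(f = f, activations = a3) else list(f = f)
}
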