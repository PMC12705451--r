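# Composite training losses for the staining transforms. Values follow the
# printed formulas exactly, including the base-10 logarithms in the SSIM
# reward and the binary cross entropy. The *_grad helpers are the analytic
# pixel gradients used by the training loop; they are internal.

#' Mean absolute error between two images
#'
#' Mean of `|a - b|` over all pixels and channels.
#' @param a,b images ([image_fov] or numeric arrays) of identical shape.
#' @return non-negative scalar.
#' @export
l1_loss <- function(a, b) {
  a <- as_pixels(a); b <- as_pixels(b)
  stop_if_shape_mismatch(a, b)
  mean(abs(a - b))
}

l1_grad <- function(a, b) sign(a - b) / length(a)

#' Global structural similarity index
#'
#' Whole-image SSIM computed from image-wide means, variances (population
#' convention) and covariance:
#' `((2 mu_a mu_b + c1) (2 cov + c2)) / ((mu_a^2 + mu_b^2 + c1)
#' (var_a + var_b + c2))`. Multi-channel images are averaged over channels.
#' The constants are absolute (no luminance-range rescaling).
#'
#' @param a,b images of identical shape.
#' @param c1,c2 stabilising constants (defaults 0.01 and 0.03).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, c1 = 0.01, c2 = 0.03) {
  a <- as_pixels(a); b <- as_pixels(b)
  stop_if_shape_mismatch(a, b)
  stopifnot(c1 > 0, c2 > 0)
  vals <- vapply(seq_len(dim(a)[3]), function(ch)
    ssim_channel(a[, , ch], b[, , ch], c1, c2), numeric(1))
  mean(vals)
}

ssim_channel <- function(x, y, c1, c2) {
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cv <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * cv + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

# Gradient of SSIM(a, b) with respect to a (channel-averaged).
ssim_grad <- function(a, b, c1, c2) {
  d <- dim(a); C <- d[3]; n <- d[1] * d[2]
  g <- array(0, d)
  for (ch in seq_len(C)) {
    x <- a[, , ch]; y <- b[, , ch]
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cv <- mean((x - mx) * (y - my))
    A1 <- 2 * mx * my + c1; A2 <- 2 * cv + c2
    B1 <- mx^2 + my^2 + c1; B2 <- vx + vy + c2
    g[, , ch] <- ((2 * my * A2 + 2 * A1 * (y - my)) / (B1 * B2) -
                  (A1 * A2) * (2 * mx * B2 + 2 * B1 * (x - mx)) /
                  (B1 * B2)^2) / (n * C)
  }
  g
}

#' Total variation of an image
#'
#' Sum of absolute forward differences along rows and columns over valid
#' interior indices only (no wrapping, no padding); channels are summed.
#'
#' @param a an image with height and width at least 2.
#' @return non-negative scalar.
#' @export
tv_loss <- function(a) {
  a <- as_pixels(a)
  d <- dim(a)
  if (d[1] < 2 || d[2] < 2)
    stop("too-small-image: total variation needs height, width >= 2",
         call. = FALSE)
  dv <- a[-1, , , drop = FALSE] - a[-d[1], , , drop = FALSE]
  dh <- a[, -1, , drop = FALSE] - a[, -d[2], , drop = FALSE]
  sum(abs(dv)) + sum(abs(dh))
}

tv_grad <- function(a) {
  d <- dim(a)
  g <- array(0, d)
  dv <- sign(a[-1, , , drop = FALSE] - a[-d[1], , , drop = FALSE])
  dh <- sign(a[, -1, , drop = FALSE] - a[, -d[2], , drop = FALSE])
  g[-1, , ] <- g[-1, , , drop = FALSE] + dv
  g[-d[1], , ] <- g[-d[1], , , drop = FALSE] - dv
  g[, -1, ] <- g[, -1, , drop = FALSE] + dh
  g[, -d[2], ] <- g[, -d[2], , drop = FALSE] - dh
  g
}

#' Binary cross entropy with base-10 logarithm
#'
#' `-(q log10(p) + (1 - q) log10(1 - p))` with `p` clamped to
#' `[eps, 1 - eps]` for numerical safety. The base-10 logarithm follows the
#' printed loss definition (so `bce_loss(0.1, 1)` is exactly 1).
#'
#' @param p predicted probability in `[0, 1]`.
#' @param q label, 0 or 1.
#' @param eps clamping constant.
#' @return non-negative scalar.
#' @export
bce_loss <- function(p, q, eps = 1e-7) {
  stopifnot(q %in% c(0, 1))
  p <- clamp_prob(p, eps)
  -(q * log10(p) + (1 - q) * log10(1 - p))
}

bce_grad_p <- function(p, q, eps = 1e-7) {
  p <- clamp_prob(p, eps)
  (-(q / p) + (1 - q) / (1 - p)) / log(10)
}

# -beta * log10((1 + ssim)/2): the SSIM reward term and its gradient wrt a.
ssim_term <- function(a, b, beta, c1, c2) {
  -beta * log10((1 + ssim(a, b, c1, c2)) / 2)
}

ssim_term_grad <- function(a, b, beta, c1, c2) {
  s <- ssim(a, b, c1, c2)
  -beta / ((1 + s) * log(10)) * ssim_grad(a, b, c1, c2)
}

#' Composite generator loss of the forward staining transform
#'
#' `alpha * L1 - beta * log10((1 + SSIM)/2) + gamma * TV +
#' delta * BCE(disc_prob, 1)`, composed from [l1_loss], [ssim], [tv_loss]
#' and [bce_loss] with the weights of `cfg`.
#'
#' @param vs_out generated stain image.
#' @param hs_target ground-truth stain image of the same shape.
#' @param disc_prob discriminator probability assigned to `vs_out`.
#' @param cfg a [training_config].
#' @return scalar loss.
#' @export
vs_generator_loss <- function(vs_out, hs_target, disc_prob,
                              cfg = training_config()) {
  w <- cfg$vs_weights
  w[["alpha"]] * l1_loss(vs_out, hs_target) +
    ssim_term(as_pixels(vs_out), as_pixels(hs_target), w[["beta"]],
              cfg$c1, cfg$c2) +
    w[["gamma"]] * tv_loss(vs_out) +
    w[["delta"]] * bce_loss(disc_prob, 1)
}

#' Discriminator loss of the forward staining transform
#'
#' `(BCE(d_vs, 0) + BCE(d_hs, 1)) / 2`.
#' @param d_vs discriminator probability on the generated image.
#' @param d_hs discriminator probability on the real stained image.
#' @return non-negative scalar.
#' @export
vs_discriminator_loss <- function(d_vs, d_hs) {
  (bce_loss(d_vs, 0) + bce_loss(d_hs, 1)) / 2
}

#' Composite loss of the backward (stain to autofluorescence) transform
#'
#' Five terms: fidelity of the virtual autofluorescence image to the measured
#' one (L1, SSIM reward, TV smoothness), plus two physical-consistency terms
#' comparing the re-stained image (the forward transform applied to the
#' backward output, supplied by the caller as `recycled_stain`) against the
#' original stained input.
#'
#' @param vaf_out generated autofluorescence image.
#' @param aaf_target measured autofluorescence image.
#' @param recycled_stain forward transform applied to `vaf_out`.
#' @param hs_input the stained image fed to the backward transform.
#' @param cfg a [training_config].
#' @return scalar loss.
#' @export
vaf_generator_loss <- function(vaf_out, aaf_target, recycled_stain, hs_input,
                               cfg = training_config()) {
  w <- cfg$vaf_weights
  w[["alpha"]] * l1_loss(vaf_out, aaf_target) +
    ssim_term(as_pixels(vaf_out), as_pixels(aaf_target), w[["beta"]],
              cfg$c1, cfg$c2) +
    w[["gamma"]] * tv_loss(vaf_out) +
    w[["delta"]] * l1_loss(recycled_stain, hs_input) +
    ssim_term(as_pixels(recycled_stain), as_pixels(hs_input), w[["epsilon"]],
              cfg$c1, cfg$c2)
}
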