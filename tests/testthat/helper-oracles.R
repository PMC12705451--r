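# Independent brute-force oracles, written directly from the printed
# formulas as plain scalar loops. They deliberately share no code with the
# package implementations they check.

oracle_l1 <- function(a, b) {
  s <- 0; n <- 0
  for (i in seq_along(a)) { s <- s + abs(a[i] - b[i]); n <- n + 1 }
  s / n
}

oracle_ssim <- function(a, b, c1 = 0.01, c2 = 0.03) {
  # single channel; caller averages channels
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  va <- sum((a - ma)^2) / n; vb <- sum((b - mb)^2) / n
  cab <- sum((a - ma) * (b - mb)) / n
  ((2 * ma * mb + c1) * (2 * cab + c2)) /
    ((ma^2 + mb^2 + c1) * (va + vb + c2))
}

oracle_tv <- function(a) {
  # a: H x W x C array; valid forward differences, summed over channels
  s <- 0
  d <- dim(a)
  for (c in seq_len(d[3])) for (m in seq_len(d[1])) for (n in seq_len(d[2])) {
    if (m < d[1]) s <- s + abs(a[m + 1, n, c] - a[m, n, c])
    if (n < d[2]) s <- s + abs(a[m, n + 1, c] - a[m, n, c])
  }
  s
}

oracle_bce <- function(p, q) -(q * log10(p) + (1 - q) * log10(1 - p))

oracle_mse <- function(x, y, scale = 255) {
  s <- 0
  for (i in seq_along(x)) s <- s + (scale * x[i] - scale * y[i])^2
  s / length(x)
}

oracle_pcc <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_psnr <- function(x, y) 20 * log10(255 / sqrt(oracle_mse(x, y)))

oracle_pooled_t <- function(s1, s2) {
  n1 <- length(s1); n2 <- length(s2)
  sp <- sqrt(((n1 - 1) * var(s1) + (n2 - 1) * var(s2)) / (n1 + n2 - 2))
  (mean(s1) - mean(s2)) / (sp * sqrt(1 / n1 + 1 / n2))
}

oracle_kl <- function(pn, pp, eps = 0.001) {
  s <- 0
  for (i in seq_along(pn)) s <- s + log((pn[i] + eps) / (pp[i] + eps)) * pn[i]
  s
}

oracle_hellinger <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + sqrt(p[i] * q[i])
  sqrt(1 - s)
}

oracle_g <- function(o, e) {
  s <- 0
  for (i in seq_along(o)) if (o[i] > 0) s <- s + o[i] * log(o[i] / e[i])
  2 * s
}

# Residual of the equal-density condition (for root checking).
oracle_lda_residual <- function(beta, mu1, s1, mu2, s2) {
  (log(s1) + (beta - mu1)^2 / (2 * s1^2)) -
    (log(s2) + (beta - mu2)^2 / (2 * s2^2))
}

random_image <- function(h = 8, w = 8, c = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * c), c(h, w, c))
}
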