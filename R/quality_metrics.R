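# Scalar quality metrics and distribution comparisons: mean squared error,
# Pearson correlation and peak signal-to-noise ratio on the 8-bit scale,
# pooled two-sample t statistics, binned score distributions with the
# Kullback-Leibler divergence, classification rates, ROC/PR curves, the
# Hellinger distance and the G-test.

#' Mean squared error on the 8-bit scale
#'
#' Mean of `(x - y)^2` after mapping the unit-range pixels to `[0, scale]`;
#' with the default `scale = 255` two images that differ everywhere by the
#' full dynamic range score 65025. Multi-channel images are flattened across
#' channels.
#'
#' @param x,y images ([image_fov] or arrays in `[0, 1]`) of identical shape.
#' @param scale dynamic range (255 for 8-bit).
#' @return non-negative scalar.
#' @export
mse <- function(x, y, scale = 255) {
  x <- as_pixels(x); y <- as_pixels(y)
  stop_if_shape_mismatch(x, y)
  mean((scale * (x - y))^2)
}

#' Pearson correlation coefficient between two images
#'
#' @param x,y non-constant images of identical shape.
#' @return scalar in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  x <- as.numeric(as_pixels(x)); y <- as.numeric(as_pixels(y))
  if (length(x) != length(y))
    stop("shape-mismatch: inputs differ in size", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation: constant image", call. = FALSE)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

#' Peak signal-to-noise ratio in dB
#'
#' `20 log10(255 / sqrt(mse))`; identical images yield `Inf` as the
#' distinguished perfect-match value.
#'
#' @inheritParams mse
#' @return scalar dB value, possibly `Inf`.
#' @export
psnr <- function(x, y, scale = 255) {
  m <- mse(x, y, scale)
  if (m == 0) return(Inf)
  20 * log10(255 / sqrt(m))
}

#' Pooled-variance two-sample t statistic
#'
#' `t = (mean1 - mean2) / (s_p sqrt(1/n1 + 1/n2))` with the pooled standard
#' deviation `s_p` from the unbiased per-group variances. When both samples
#' lie in `[0, 1]` the binned Kullback-Leibler divergence between them
#' (first group treated as the reference) is reported alongside; otherwise it
#' is `NA`.
#'
#' @param sample1,sample2 numeric vectors with at least 2 values each.
#' @return an object of class `separation_stats` with fields `t_statistic`,
#'   `kl_divergence`, `n1`, `n2`, `pooled_sd`.
#' @export
pooled_t <- function(sample1, sample2) {
  n1 <- length(sample1); n2 <- length(sample2)
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * stats::var(sample1) + (n2 - 1) * stats::var(sample2)) /
    (n1 + n2 - 2)
  if (sp2 <= 0)
    stop("zero-pooled-variance: t statistic undefined", call. = FALSE)
  t <- (mean(sample1) - mean(sample2)) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  kl <- if (all(sample1 >= 0 & sample1 <= 1) && all(sample2 >= 0 & sample2 <= 1))
    kl_divergence(bin_scores(sample1), bin_scores(sample2)) else NA_real_
  structure(list(t_statistic = t, kl_divergence = kl, n1 = n1, n2 = n2,
                 pooled_sd = sqrt(sp2)),
            class = "separation_stats")
}

#' @export
print.separation_stats <- function(x, ...) {
  cat(sprintf("<separation_stats t=%.4f, KL=%s, n=%d/%d>\n", x$t_statistic,
              if (is.na(x$kl_divergence)) "NA" else sprintf("%.4f", x$kl_divergence),
              x$n1, x$n2))
  invisible(x)
}

#' Bin confidence scores on the unit interval
#'
#' Histograms scores into uniform bins of width 0.01 on `[0, 1]` (100 bins by
#' default); bins are half-open `[b_i, b_{i+1})` with the last bin closed so
#' a score of exactly 1 lands in bin 100. Masses sum to 1.
#'
#' @param scores numeric vector in `[0, 1]`.
#' @param n_bins number of bins.
#' @return an object of class `binned_distribution` with `edges`, `counts`,
#'   `mass`, `n`.
#' @export
bin_scores <- function(scores, n_bins = 100L) {
  if (any(scores < 0 | scores > 1))
    stop("out-of-range score: values must lie in [0, 1]", call. = FALSE)
  edges <- seq.int(0L, n_bins) / n_bins
  idx <- findInterval(scores, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(edges = edges, counts = counts,
                 mass = counts / length(scores), n = length(scores)),
            class = "binned_distribution")
}

#' Kullback-Leibler divergence between two binned score distributions
#'
#' `sum_i log((p_n(b_i) + eps) / (p_p(b_i) + eps)) * p_n(b_i)` with the
#' natural logarithm and `eps = 0.001` guarding empty bins; `p_n` is the
#' first (reference, typically negative-class) distribution. The divergence
#' is directed: swapping the arguments changes the value.
#'
#' @param p_neg,p_pos [bin_scores] results on the same grid (or bare mass
#'   vectors of equal length).
#' @param epsilon stabilising constant.
#' @return non-negative scalar.
#' @export
kl_divergence <- function(p_neg, p_pos, epsilon = 0.001) {
  pn <- if (inherits(p_neg, "binned_distribution")) p_neg$mass else p_neg
  pp <- if (inherits(p_pos, "binned_distribution")) p_pos$mass else p_pos
  if (inherits(p_neg, "binned_distribution") &&
      inherits(p_pos, "binned_distribution") &&
      !isTRUE(all.equal(p_neg$edges, p_pos$edges)))
    stop("grid-mismatch: distributions use different bin edges", call. = FALSE)
  if (length(pn) != length(pp))
    stop("grid-mismatch: distributions have different bin counts",
         call. = FALSE)
  sum(log((pn + epsilon) / (pp + epsilon)) * pn)
}

#' Classification rates from a confusion summary
#'
#' Accuracy `(TP + TN) / (P + N)`, sensitivity `TP / P`, specificity
#' `TN / N`, plus TPR (= sensitivity), FPR (= 1 - specificity), precision
#' `TP / (TP + FP)` and recall (= TPR). Rates whose denominator is empty are
#' `NA` without affecting the others.
#'
#' @param tp,tn true positive and true negative counts.
#' @param p,n actual positive and negative counts.
#' @return named list of rates.
#' @export
classification_rates <- function(tp, tn, p, n) {
  stopifnot(tp >= 0, tn >= 0, tp <= p, tn <= n)
  fp <- n - tn
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe(tp, p)
  spec <- safe(tn, n)
  list(accuracy = safe(tp + tn, p + n),
       sensitivity = sens,
       specificity = spec,
       tpr = sens,
       fpr = if (is.na(spec)) NA_real_ else 1 - spec,
       precision = safe(tp, tp + fp),
       recall = sens)
}

#' ROC and precision-recall curves
#'
#' Sweeps the decision rule `positive iff score >= threshold` over every
#' distinct score (plus the endpoints) and reports the rates at each
#' threshold, with trapezoid areas under both curves.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return list with data frames `roc` (`threshold`, `fpr`, `tpr`) and `pr`
#'   (`threshold`, `recall`, `precision`), and scalars `auc_roc`, `auc_pr`.
#' @export
curve_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  p <- sum(labels == 1); n <- sum(labels == 0)
  if (p == 0 || n == 0)
    stop("single-class: both classes are required", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  tpr <- tp / p; fpr <- fp / n
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  auc <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       pr = data.frame(threshold = thr, recall = tpr, precision = precision),
       auc_roc = auc(fpr, tpr),
       auc_pr = auc(tpr, precision))
}

#' Hellinger distance between two discrete distributions
#'
#' `sqrt(1 - sum(sqrt(p_i q_i)))` over a common set of bins; 0 for identical
#' distributions, 1 for disjoint supports.
#'
#' @param p,q probability mass vectors of equal length, each summing to 1.
#' @return scalar in `[0, 1]`.
#' @export
hellinger <- function(p, q) {
  if (length(p) != length(q))
    stop("length-mismatch: distributions differ in bin count", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("non-normalized: masses must sum to 1", call. = FALSE)
  sqrt(max(0, 1 - sum(sqrt(pmax(p, 0) * pmax(q, 0)))))
}

#' Log-likelihood-ratio goodness-of-fit test (G-test)
#'
#' `G = 2 sum_i O_i ln(O_i / E_i)` with the convention `0 ln 0 = 0`;
#' `bins - 1` degrees of freedom and a chi-square tail p-value.
#'
#' @param observed observed counts.
#' @param expected expected counts, strictly positive wherever the observed
#'   count is positive.
#' @return list with `G`, `dof`, `p_value`.
#' @export
g_test <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("length-mismatch", call. = FALSE)
  if (any(observed > 0 & expected <= 0))
    stop("invalid-expected: expected must be > 0 where observed > 0",
         call. = FALSE)
  pos <- observed > 0
  G <- 2 * sum(observed[pos] * log(observed[pos] / expected[pos]))
  dof <- length(observed) - 1L
  list(G = G, dof = dof,
       p_value = stats::pchisq(G, df = dof, lower.tail = FALSE))
}
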