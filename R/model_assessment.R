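# Model-level gating: fit class-conditional Gaussians to the logits of
# image confidence scores, solve the equal-density condition for the
# discriminant threshold beta, and accept or reject a whole staining model
# from the mean score of N of its images. Includes the sampling-repetition
# experiment harness.

#' Fit the linear-discriminant threshold between two score populations
#'
#' Scores are logit-transformed (after clamping away from 0 and 1); each
#' class's logits are summarised by sample mean and unbiased variance, and
#' the equal-probability-density condition
#' `log(sigma1) + (beta - mu1)^2 / (2 sigma1^2) = log(sigma2) +
#' (beta - mu2)^2 / (2 sigma2^2)` is solved for the discriminant point. With
#' unequal variances the condition is quadratic; the root lying between the
#' two class means is the decision boundary (the other root is a far-tail
#' crossing). `beta` is the inverse-logit of that root.
#'
#' @param pos_scores,neg_scores confidence scores in `[0, 1]` of the
#'   positive (hallucinated) and negative (clean) training images, at least
#'   2 each.
#' @return an object of class `lda_threshold` with `mu1`, `sigma1`, `mu2`,
#'   `sigma2`, `beta_logit`, `beta`.
#' @export
fit_lda_threshold <- function(pos_scores, neg_scores) {
  stopifnot(length(pos_scores) >= 2, length(neg_scores) >= 2)
  t1 <- logit(pos_scores); t2 <- logit(neg_scores)
  mu1 <- mean(t1); mu2 <- mean(t2)
  s1 <- stats::sd(t1); s2 <- stats::sd(t2)
  if (s1 == 0 || s2 == 0)
    stop("zero-variance-class: cannot fit class Gaussian", call. = FALSE)
  roots <- lda_roots(mu1, s1, mu2, s2)
  lo <- min(mu1, mu2); hi <- max(mu1, mu2)
  between <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
  if (!length(between))
    stop("no-root-between-means: equal-density roots at ",
         paste(sprintf("%.6g", roots), collapse = ", "),
         " lie outside (", sprintf("%.6g", lo), ", ", sprintf("%.6g", hi),
         ")", call. = FALSE)
  beta_logit <- between[1]
  structure(list(mu1 = mu1, sigma1 = s1, mu2 = mu2, sigma2 = s2,
                 beta_logit = beta_logit, beta = inv_logit(beta_logit)),
            class = "lda_threshold")
}

# Roots of the equal-density condition in logit space.
lda_roots <- function(mu1, s1, mu2, s2) {
  if (abs(s1 - s2) < 1e-12) return((mu1 + mu2) / 2)
  a <- 1 / (2 * s1^2) - 1 / (2 * s2^2)
  b <- -(mu1 / s1^2 - mu2 / s2^2)
  c <- mu1^2 / (2 * s1^2) - mu2^2 / (2 * s2^2) + log(s1) - log(s2)
  disc <- b^2 - 4 * a * c
  if (disc < 0) return(numeric(0))
  sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
}

# Residual of the equal-density condition at a point (diagnostic).
lda_residual <- function(th, at = th$beta_logit) {
  (log(th$sigma1) + (at - th$mu1)^2 / (2 * th$sigma1^2)) -
    (log(th$sigma2) + (at - th$mu2)^2 / (2 * th$sigma2^2))
}

#' @export
print.lda_threshold <- function(x, ...) {
  cat(sprintf(
    "<lda_threshold beta=%.4f (logit %.4f); pos N(%.3f, %.3f^2), neg N(%.3f, %.3f^2)>\n",
    x$beta, x$beta_logit, x$mu1, x$sigma1, x$mu2, x$sigma2))
  invisible(x)
}

#' Accept or reject a staining model from image scores
#'
#' The mean confidence score over the N images is compared with `beta`;
#' the model is rejected iff the mean is at or above `beta` (the boundary is
#' assigned to rejection, the conservative choice).
#'
#' @param scores confidence scores in `[0, 1]` of N >= 1 images from the
#'   model under investigation.
#' @param beta decision threshold in score space (an [fit_lda_threshold]
#'   object or a bare number).
#' @param model_id optional identifier.
#' @return an object of class `model_verdict` with `model_id`, `n`,
#'   `scores`, `s_bar`, `beta`, `decision`.
#' @export
assess_model <- function(scores, beta, model_id = NA_character_) {
  if (!length(scores)) stop("empty-scores", call. = FALSE)
  stopifnot(all(scores >= 0 & scores <= 1))
  if (inherits(beta, "lda_threshold")) beta <- beta$beta
  s_bar <- mean(scores)
  structure(list(model_id = model_id, n = length(scores), scores = scores,
                 s_bar = s_bar, beta = beta,
                 decision = if (s_bar >= beta) "reject" else "accept"),
            class = "model_verdict")
}

#' @export
print.model_verdict <- function(x, ...) {
  cat(sprintf("<model_verdict %s: s_bar=%.4f %s beta=%.4f -> %s (N=%d)>\n",
              x$model_id, x$s_bar, if (x$s_bar >= x$beta) ">=" else "<",
              x$beta, x$decision, x$n))
  invisible(x)
}

#' Sampling-repetition experiment over a model zoo
#'
#' For every model and every N, draws N of the model's image scores without
#' replacement, R times, records the mean and standard deviation of the
#' average score `s_bar`, the overall model-classification accuracy at
#' `beta` (good models should be accepted, poor models rejected), and the
#' Kullback-Leibler divergence between the good-group and poor-group `s_bar`
#' distributions.
#'
#' @param model_scores named list: per model, the vector of its image
#'   confidence scores (each at least `max(N_values)` long).
#' @param labels character vector (`"good"` / `"poor"`) aligned with
#'   `model_scores`; at least one of each.
#' @param beta decision threshold ([fit_lda_threshold] object or number).
#' @param N_values sample sizes to test.
#' @param R repetitions per (model, N).
#' @param seed integer seed.
#' @return list with `table` (one row per model and N: `model_id`, `label`,
#'   `N`, `R`, `mean_sbar`, `std_sbar`, `reject_rate`, `decision`) and
#'   `summary` (one row per N: `accuracy`, `kl_divergence`).
#' @export
maqua_experiment <- function(model_scores, labels, beta,
                             N_values = c(2L, 5L, 10L, 20L), R = 20L,
                             seed = 1L) {
  stopifnot(length(model_scores) == length(labels))
  if (!any(labels == "good") || !any(labels == "poor"))
    stop("zoo must contain at least one good and one poor model",
         call. = FALSE)
  short <- vapply(model_scores, length, integer(1)) < max(N_values)
  if (any(short))
    stop("insufficient-images: models ",
         paste(names(model_scores)[short], collapse = ", "),
         " have fewer than max(N) scores", call. = FALSE)
  if (inherits(beta, "lda_threshold")) beta <- beta$beta
  ids <- names(model_scores) %||% paste0("model", seq_along(model_scores))

  rows <- list(); summaries <- list()
  for (N in N_values) {
    sbars <- matrix(NA_real_, length(model_scores), R)
    for (m in seq_along(model_scores)) {
      sc <- model_scores[[m]]
      for (r in seq_len(R)) {
        pick <- with_seed(derive_seed(seed, m * 100003L + N * 131L + r),
                          sample(length(sc), N))
        sbars[m, r] <- mean(sc[pick])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = ids[m], label = labels[m], N = N, R = R,
        mean_sbar = mean(sbars[m, ]),
        std_sbar = stats::sd(sbars[m, ]),
        reject_rate = mean(sbars[m, ] >= beta),
        decision = if (mean(sbars[m, ]) >= beta) "reject" else "accept",
        stringsAsFactors = FALSE)
    }
    correct <- (labels == "poor") == (sbars >= beta)
    good_s <- as.numeric(sbars[labels == "good", ])
    poor_s <- as.numeric(sbars[labels == "poor", ])
    summaries[[length(summaries) + 1L]] <- data.frame(
      N = N, accuracy = mean(correct),
      kl_divergence = kl_divergence(bin_scores(clamp01(good_s)),
                                    bin_scores(clamp01(poor_s))))
  }
  list(table = do.call(rbind, rows), summary = do.call(rbind, summaries),
       beta = beta)
}
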