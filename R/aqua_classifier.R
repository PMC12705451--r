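# Ensemble temporal classifier over cycle sequences: a frozen feature
# backbone maps each of the 2T frames to a feature vector; each voting head
# collapses the temporal axis with two 1x1 temporal convolutions and projects
# to two class logits through two dense layers; C independently seeded heads
# are soft-voted into a single confidence score in [0, 1] (higher = more
# likely hallucinated), thresholded at the 100%-sensitivity point alpha.

#' Extract per-frame features from a cycle sequence
#'
#' Each frame is passed independently through the frozen backbone
#' (single-channel autofluorescence frames are replicated to the backbone's
#' input channel count) and spatially pooled, giving one row per frame in
#' sequence order.
#'
#' @param seq a `cycle_sequence`.
#' @param bb an [backbone] object.
#' @return numeric matrix `(2T, n_features)`.
#' @export
extract_features <- function(seq, bb) {
  stopifnot(inherits(seq, "cycle_sequence"), inherits(bb, "aqua_backbone"))
  t(vapply(seq$frames,
           function(f) backbone_forward(bb, as_pixels(f))$f,
           numeric(bb$n_features)))
}

new_head <- function(n_frames, n_features, t_hidden = 8L, hidden = 128L,
                     seed = 1L, zero = FALSE) {
  init <- function(nr, nc, sd) {
    if (zero) matrix(0, nr, nc) else matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  }
  params <- with_seed(seed, list(
    W1 = init(t_hidden, n_frames, sqrt(2 / n_frames)), b1 = numeric(t_hidden),
    W2 = init(1L, t_hidden, sqrt(2 / t_hidden)), b2 = 0,
    A1 = init(hidden, n_features, sqrt(2 / n_features)), c1 = numeric(hidden),
    A2 = init(2L, hidden, sqrt(2 / hidden)), c2 = numeric(2L)
  ))
  list(params = params, seed = as.integer(seed), n_frames = as.integer(n_frames),
       n_features = as.integer(n_features), best_epoch = NA_integer_,
       val_acc = NA_real_, val_loss = NA_real_)
}

# Batched head forward. farr: (2T, C_f, n) array (or a (2T, C_f) matrix).
head_forward_batch <- function(params, farr, keep_cache = FALSE) {
  if (is.matrix(farr)) farr <- array(farr, c(dim(farr), 1L))
  d <- dim(farr)
  Fm <- matrix(farr, d[1], d[2] * d[3])
  T1 <- params$W1 %*% Fm + params$b1
  R1 <- pmax(T1, 0)
  T2 <- params$W2 %*% R1 + params$b2
  Fst <- matrix(T2, d[2], d[3])
  H <- params$A1 %*% Fst + params$c1
  RH <- pmax(H, 0)
  L <- params$A2 %*% RH + params$c2
  s <- 1 / (1 + exp(L[1, ] - L[2, ]))
  cache <- if (keep_cache) list(Fm = Fm, T1 = T1, R1 = R1, Fst = Fst, H = H,
                                RH = RH, d = d)
  list(logits = L, s = s, cache = cache)
}

# dL2: gradient of the loss wrt the positive-class logit, per sample (the
# negative-class logit receives the opposite). Returns parameter grads and,
# optionally, the gradient wrt the input features.
head_backward_batch <- function(params, cache, dL2, want_dinput = FALSE) {
  dL <- rbind(-dL2, dL2)
  dA2 <- dL %*% t(cache$RH); dc2 <- rowSums(dL)
  dH <- (t(params$A2) %*% dL) * (cache$H > 0)
  dA1 <- dH %*% t(cache$Fst); dc1 <- rowSums(dH)
  dFst <- t(params$A1) %*% dH
  dT2 <- matrix(dFst, 1L, length(dFst))
  dW2 <- dT2 %*% t(cache$R1); db2 <- sum(dT2)
  dT1 <- (t(params$W2) %*% dT2) * (cache$T1 > 0)
  dW1 <- dT1 %*% t(cache$Fm); db1 <- rowSums(dT1)
  out <- list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                           A1 = dA1, c1 = dc1, A2 = dA2, c2 = dc2))
  if (want_dinput)
    out$dinput <- array(t(params$W1) %*% dT1, cache$d)
  out
}

#' Soft-vote an ensemble of confidence scores
#'
#' The voted confidence score is the arithmetic mean of the per-head scores.
#' @param scores numeric vector of per-head scores in `[0, 1]`, length >= 1.
#' @return scalar voted score.
#' @export
vote <- function(scores) {
  if (!length(scores)) stop("empty-list: no scores to vote on", call. = FALSE)
  mean(scores)
}

#' Select the 100%-sensitivity threshold
#'
#' The largest threshold `alpha` such that every validation positive scores
#' at or above it (decision rule: positive iff score >= alpha), i.e. the
#' minimum voted score among validation positives. This maximises specificity
#' subject to validation sensitivity 1.
#'
#' @param scores voted validation scores in `[0, 1]`.
#' @param labels 0/1 validation labels (1 = positive/hallucinated).
#' @return scalar `alpha`.
#' @export
select_threshold_alpha <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (!any(labels == 1))
    stop("no-positives: alpha needs at least one validation positive",
         call. = FALSE)
  min(scores[labels == 1])
}

stack_features <- function(feats) {
  d <- dim(feats[[1]])
  array(unlist(feats, use.names = FALSE), c(d[1], d[2], length(feats)))
}

# Per-(frame, channel) standardisation statistics over a feature stack.
feature_stats <- function(farr) {
  ctr <- apply(farr, c(1, 2), mean)
  sdv <- apply(farr, c(1, 2), stats::sd)
  sdv[!is.finite(sdv) | sdv < 1e-9] <- 1
  list(center = ctr, scale = sdv)
}

standardize_stack <- function(farr, stats) {
  if (is.null(stats)) return(farr)
  (farr - c(stats$center)) / c(stats$scale)
}

head_eval <- function(params, farr, labels) {
  s <- head_forward_batch(params, farr)$s
  acc <- mean((s >= 0.5) == (labels == 1))
  loss <- mean(bce_loss_vec(s, labels))
  list(acc = acc, loss = loss)
}

bce_loss_vec <- function(p, q, eps = 1e-7) {
  p <- clamp_prob(p, eps)
  -(q * log10(p) + (1 - q) * log10(1 - p))
}

#' Train an ensemble of voting heads
#'
#' Each head is trained independently from its own seed on the same data
#' (identical splits and hyperparameters, different initialisation and batch
#' order), minimising the base-10 binary cross entropy between its confidence
#' score and the 0/1 label with Adam; the backbone is never updated. For each
#' head the checkpoint with the best validation accuracy (at threshold 0.5)
#' is kept, earliest epoch on ties.
#'
#' @param train_feats,val_feats lists of `(2T, n_features)` feature matrices
#'   from [extract_features].
#' @param train_labels,val_labels 0/1 labels (1 = positive/hallucinated);
#'   both splits need both classes.
#' @param bb the frozen [backbone] used to extract the features.
#' @param C ensemble size (>= 1).
#' @param seeds per-head seeds (defaults to `1:C`).
#' @param epochs training epochs per head.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param t_hidden,hidden temporal and dense hidden widths.
#' @param standardize standardise every feature (per frame position and
#'   channel) by its training-set mean and standard deviation; the statistics
#'   are stored in the ensemble and applied to all later inputs.
#' @return an object of class `aqua_ensemble` (alpha unset; see
#'   [select_threshold_alpha] and [classify]).
#' @export
train_heads <- function(train_feats, train_labels, val_feats, val_labels,
                        bb, C = 3L, seeds = NULL, epochs = 75L, lr = 1e-3,
                        batch_size = 30L, t_hidden = 8L, hidden = 128L,
                        standardize = TRUE) {
  if (length(unique(train_labels)) < 2 || length(unique(val_labels)) < 2)
    stop("single-class-split: both classes are required in train and val",
         call. = FALSE)
  if (is.null(seeds)) seeds <- seq_len(C)
  stopifnot(length(seeds) == C)
  ftr <- stack_features(train_feats)
  fstats <- if (standardize) feature_stats(ftr)
  ftr <- standardize_stack(ftr, fstats)
  fva <- standardize_stack(stack_features(val_feats), fstats)
  n <- length(train_labels)
  d <- dim(ftr)

  heads <- lapply(seq_len(C), function(i) {
    head <- new_head(d[1], d[2], t_hidden, hidden, seed = seeds[i])
    params <- head$params
    state <- adam_init(params)
    best <- list(acc = -Inf, loss = Inf, epoch = NA_integer_, params = params)
    for (ep in seq_len(epochs)) {
      ord <- with_seed(derive_seed(seeds[i], 1000L + ep), sample(n))
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fb <- ftr[, , idx, drop = FALSE]
        fw <- head_forward_batch(params, fb, keep_cache = TRUE)
        g2 <- (fw$s - train_labels[idx]) / (log(10) * length(idx))
        grads <- head_backward_batch(params, fw$cache, g2)$grads
        up <- adam_step(params, grads, state, lr)
        params <- up$params; state <- up$state
      }
      ev <- head_eval(params, fva, val_labels)
      # best validation accuracy; ties broken by lower validation loss so a
      # better-calibrated checkpoint wins an accuracy plateau
      if (ev$acc > best$acc + 1e-12 ||
          (abs(ev$acc - best$acc) <= 1e-12 && ev$loss < best$loss - 1e-12)) {
        best <- list(acc = ev$acc, loss = ev$loss, epoch = ep, params = params)
      }
    }
    head$params <- best$params
    head$best_epoch <- best$epoch
    head$val_acc <- best$acc
    head$val_loss <- best$loss
    head
  })
  structure(list(backbone = bb, heads = heads, C = as.integer(C),
                 T = d[1] %/% 2L, alpha = NA_real_, feat_stats = fstats),
            class = "aqua_ensemble")
}

#' @export
print.aqua_ensemble <- function(x, ...) {
  cat(sprintf("<aqua_ensemble C=%d, T=%d, alpha=%s>\n", x$C, x$T,
              if (is.na(x$alpha)) "unset" else sprintf("%.4f", x$alpha)))
  invisible(x)
}

#' Pick the best subset of heads by validation accuracy
#'
#' Exhaustive search over all size-`C` subsets of a trained head pool,
#' maximising voted validation accuracy (threshold 0.5); ties are broken by
#' lower mean per-head validation loss, then by lexicographic seed order.
#'
#' @param heads list of trained heads (from an `aqua_ensemble`).
#' @param val_feats,val_labels validation features and labels.
#' @param C subset size.
#' @param feat_stats the pool ensemble's stored feature statistics (applied
#'   to `val_feats` before scoring), or `NULL`.
#' @return integer indices of the selected heads.
#' @export
select_head_subset <- function(heads, val_feats, val_labels, C,
                               feat_stats = NULL) {
  stopifnot(C >= 1, C <= length(heads))
  fva <- standardize_stack(stack_features(val_feats), feat_stats)
  svals <- t(vapply(heads, function(h) head_forward_batch(h$params, fva)$s,
                    numeric(length(val_labels))))
  combs <- utils::combn(length(heads), C, simplify = FALSE)
  best <- NULL
  for (cb in combs) {
    voted <- colMeans(svals[cb, , drop = FALSE])
    acc <- mean((voted >= 0.5) == (val_labels == 1))
    loss <- mean(vapply(heads[cb], `[[`, numeric(1), "val_loss"))
    seeds <- vapply(heads[cb], `[[`, integer(1), "seed")
    key <- list(acc = acc, loss = loss, seeds = seeds, idx = cb)
    if (is.null(best) || acc > best$acc + 1e-12 ||
        (abs(acc - best$acc) <= 1e-12 && loss < best$loss - 1e-12) ||
        (abs(acc - best$acc) <= 1e-12 && abs(loss - best$loss) <= 1e-12 &&
         paste(seeds, collapse = ",") < paste(best$seeds, collapse = ",")))
      best <- key
  }
  best$idx
}

#' Classify a cycle sequence
#'
#' Runs feature extraction, every voting head, soft voting and the alpha
#' threshold. The decision is `"reject"` (positive, hallucination suspected)
#' iff the voted score is at least `alpha`.
#'
#' @param seq a `cycle_sequence` of length `2T` matching the ensemble.
#' @param ensemble a trained `aqua_ensemble` with `alpha` set.
#' @return an object of class `confidence_report`: per-head scores, voted
#'   score, its logit, and the decision.
#' @export
classify <- function(seq, ensemble) {
  stopifnot(inherits(ensemble, "aqua_ensemble"))
  if (is.na(ensemble$alpha))
    stop("untrained-ensemble: alpha has not been set", call. = FALSE)
  if (length(seq$frames) != 2L * ensemble$T)
    stop("length-mismatch: sequence has ", length(seq$frames),
         " frames, ensemble expects ", 2L * ensemble$T, call. = FALSE)
  f <- extract_features(seq, ensemble$backbone)
  f <- standardize_stack(array(f, c(dim(f), 1L)),
                         ensemble$feat_stats)[, , 1]
  per_head <- vapply(ensemble$heads,
                     function(h) head_forward_batch(h$params, f)$s,
                     numeric(1))
  voted <- vote(per_head)
  structure(list(per_head_scores = per_head, voted_score = voted,
                 logit = logit(voted),
                 decision = if (voted >= ensemble$alpha) "reject" else "accept",
                 alpha = ensemble$alpha, mode = seq$mode,
                 provenance = seq$provenance),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat(sprintf("<confidence_report voted=%.4f (%s at alpha=%.4f), heads: %s>\n",
              x$voted_score, x$decision, x$alpha,
              paste(sprintf("%.3f", x$per_head_scores), collapse = " ")))
  invisible(x)
}

# Score a list of sequences; returns voted scores only (fast path used by the
# experiment harnesses).
score_sequences <- function(seqs, ensemble) {
  feats <- lapply(seqs, extract_features, bb = ensemble$backbone)
  score_features(feats, ensemble)
}

score_features <- function(feats, ensemble) {
  farr <- standardize_stack(stack_features(feats), ensemble$feat_stats)
  svals <- vapply(ensemble$heads,
                  function(h) head_forward_batch(h$params, farr)$s,
                  numeric(length(feats)))
  if (is.null(dim(svals))) svals <- matrix(svals, nrow = 1L)
  rowMeans(svals)
}

#' Temporal Grad-CAM maps for a cycle sequence
#'
#' Class-gradient-weighted activation maps of the backbone's final
#' convolution stage, one per frame, averaged over the ensemble's heads,
#' rectified, and upsampled to frame resolution; also returns the
#' time-averaged map. Uses the gradient of the positive-class logit.
#'
#' @param seq a `cycle_sequence`.
#' @param ensemble a trained `aqua_ensemble`.
#' @return list with `maps` (array `H x W x 2T`, non-negative) and
#'   `mean_map` (`H x W`).
#' @export
gradcam_sequence <- function(seq, ensemble) {
  if (!inherits(ensemble$backbone, "aqua_backbone"))
    stop("unsupported-feature: backbone does not expose activation maps",
         call. = FALSE)
  outs <- lapply(seq$frames, function(f)
    backbone_forward(ensemble$backbone, as_pixels(f), keep_activations = TRUE))
  f <- t(vapply(outs, `[[`, numeric(ensemble$backbone$n_features), "f"))
  fscale <- if (is.null(ensemble$feat_stats)) 1 else ensemble$feat_stats$scale
  f <- standardize_stack(array(f, c(dim(f), 1L)), ensemble$feat_stats)[, , 1]
  hw <- dim(as_pixels(seq$frames[[1]]))[1:2]
  adim <- dim(outs[[1]]$activations)
  maps <- array(0, c(adim[1], adim[2], length(outs)))
  for (h in ensemble$heads) {
    fw <- head_forward_batch(h$params, f, keep_cache = TRUE)
    dinput <- head_backward_batch(h$params, fw$cache, dL2 = 1,
                                  want_dinput = TRUE)$dinput[, , 1] / fscale
    for (t in seq_along(outs)) {
      wts <- dinput[t, ] / (adim[1] * adim[2])
      m <- outs[[t]]$activations
      cam <- matrix(0, adim[1], adim[2])
      for (c in seq_len(adim[3])) cam <- cam + wts[c] * m[, , c]
      maps[, , t] <- maps[, , t] + pmax(cam, 0) / length(ensemble$heads)
    }
  }
  up <- hw[1] %/% adim[1]
  big <- array(0, c(adim[1] * up, adim[2] * up, dim(maps)[3]))
  for (t in seq_len(dim(maps)[3]))
    big[, , t] <- maps[rep(seq_len(adim[1]), each = up),
                       rep(seq_len(adim[2]), each = up), t]
  if (!identical(dim(big)[1:2], as.integer(hw)))
    big <- big[seq_len(hw[1]), seq_len(hw[2]), , drop = FALSE]
  list(maps = big, mean_map = apply(big, c(1, 2), mean))
}

#' Save / load an ensemble archive
#'
#' Writes the backbone spec and alpha to a JSON file and the full ensemble
#' state to an `.rds` file inside `dir`.
#' @param ensemble an `aqua_ensemble`.
#' @param dir archive directory.
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ensemble, file.path(dir, "ensemble.rds"), version = 2)
  spec <- list(C = ensemble$C, T = ensemble$T, alpha = ensemble$alpha,
               backbone = list(in_channels = ensemble$backbone$in_channels,
                               n_features = ensemble$backbone$n_features,
                               seed = ensemble$backbone$seed),
               head_seeds = vapply(ensemble$heads, `[[`, integer(1), "seed"))
  jsonlite::write_json(spec, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  e <- readRDS(file.path(dir, "ensemble.rds"))
  stopifnot(inherits(e, "aqua_ensemble"))
  e
}
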