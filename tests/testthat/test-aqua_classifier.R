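# Small synthetic feature sets are used throughout: class-dependent mean
# shifts plus noise, which a temporal head must separate easily.
make_feature_set <- function(n, n_frames = 4, n_feat = 16, shift = 1.5,
                             seed = 1) {
  set.seed(seed)
  labels <- rep(0:1, length.out = n)
  feats <- lapply(seq_len(n), function(i) {
    base <- matrix(rnorm(n_frames * n_feat, 0, 1), n_frames, n_feat)
    if (labels[i] == 1)
      base <- base + shift * outer(seq_len(n_frames) / n_frames,
                                   rep(1, n_feat))
    base
  })
  list(feats = feats, labels = labels)
}

test_that("feature extraction is deterministic, shaped, and frame-local", {
  pr <- tiny_pairs(1)[[1]]
  bb <- backbone(n_features = 64, seed = 4)
  # stain consistent with the identity stubs so all frames repeat exactly
  stain <- image_fov(pr$af$pixels[, , c(1, 1, 1)], "STAIN")
  sq <- run_cycle_vs_start(pr$af, stain, identity_vs(), identity_vaf(),
                           T = 5)
  f <- extract_features(sq, bb)
  expect_equal(dim(f), c(10, 64))
  # identical frames give identical feature rows
  expect_equal(f[1, ], f[3, ])  # AF frames all equal under identity cycles
  expect_equal(f[2, ], f[4, ])
  # permuting two distinct frames permutes exactly those rows
  sq2 <- sq
  sq2$frames[c(1, 2)] <- sq$frames[c(2, 1)]
  f2 <- extract_features(sq2, bb)
  expect_equal(f2[1, ], f[2, ])
  expect_equal(f2[2, ], f[1, ])
  expect_equal(f2[3:10, ], f[3:10, ])
  # determinism
  expect_identical(f, extract_features(sq, bb))
})

test_that("head forward obeys the softmax contracts", {
  zero_head <- aquaqc:::new_head(4, 8, zero = TRUE)
  f <- matrix(0, 4, 8)
  out <- aquaqc:::head_forward_batch(zero_head$params, f)
  expect_equal(as.numeric(out$logits), c(0, 0))
  expect_equal(out$s, 0.5)
  set.seed(2)
  h <- aquaqc:::new_head(4, 8, seed = 3)
  f <- matrix(rnorm(32), 4, 8)
  out <- aquaqc:::head_forward_batch(h$params, f)
  # probabilities normalise: s + negative-class probability = 1
  pneg <- exp(out$logits[1]) / sum(exp(out$logits))
  expect_equal(out$s + pneg, 1, tolerance = 1e-12)
  expect_identical(out$s, aquaqc:::head_forward_batch(h$params, f)$s)
})

test_that("soft voting is the arithmetic mean", {
  expect_equal(vote(c(0.2, 0.4, 0.9)), 0.5)
  expect_equal(vote(0.73), 0.73)
  expect_equal(vote(rep(0.31, 7)), 0.31)
  expect_error(vote(numeric(0)), "empty-list")
  set.seed(1)
  for (i in 1:50) {
    s <- runif(sample(1:8, 1))
    expect_equal(vote(s), sum(s) / length(s), tolerance = 1e-15)
  }
})

test_that("alpha selection achieves sensitivity 1 on its validation set", {
  expect_equal(select_threshold_alpha(c(0.7, 0.9, 0.1, 0.6), c(1, 1, 0, 0)),
               0.7)
  expect_equal(select_threshold_alpha(c(0.5, 0.6), c(1, 0)), 0.5)
  expect_error(select_threshold_alpha(c(0.5), c(0)), "no-positives")
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    labels <- c(1, rbinom(n - 1, 1, 0.5))
    scores <- runif(n)
    a <- select_threshold_alpha(scores, labels)
    expect_equal(mean(scores[labels == 1] >= a), 1)  # sensitivity 1 always
    expect_true(any(scores[labels == 1] == a))       # largest such threshold
  }
})

test_that("head training learns an easy separation and is seed-deterministic", {
  tr <- make_feature_set(60, seed = 1)
  va <- make_feature_set(24, seed = 2)
  bb <- backbone(n_features = 16, seed = 1)
  ens <- train_heads(tr$feats, tr$labels, va$feats, va$labels, bb, C = 2,
                     seeds = c(5, 6), epochs = 15, batch_size = 10)
  expect_s3_class(ens, "aqua_ensemble")
  maj <- max(mean(va$labels == 1), mean(va$labels == 0))
  expect_gt(max(vapply(ens$heads, `[[`, numeric(1), "val_acc")), maj)
  # equal seeds give identical parameters; C = 1 reduces to one classifier
  ens2 <- train_heads(tr$feats, tr$labels, va$feats, va$labels, bb, C = 2,
                      seeds = c(5, 5), epochs = 5)
  expect_identical(serialize(ens2$heads[[1]]$params, NULL),
                   serialize(ens2$heads[[2]]$params, NULL))
  ens1 <- train_heads(tr$feats, tr$labels, va$feats, va$labels, bb, C = 1,
                      seeds = 5, epochs = 5)
  expect_length(ens1$heads, 1)
  expect_error(train_heads(tr$feats, rep(1, 60), va$feats, va$labels, bb),
               "single-class-split")
})

test_that("classification reports respect the voting and threshold contracts", {
  tr <- make_feature_set(60, n_frames = 4, seed = 3)
  va <- make_feature_set(24, n_frames = 4, seed = 4)
  bb <- backbone(n_features = 16, seed = 2)
  ens <- train_heads(tr$feats, tr$labels, va$feats, va$labels, bb, C = 3,
                     seeds = 1:3, epochs = 10)
  expect_error(
    classify(structure(list(frames = vector("list", 4), T = 2, mode = "VS_START"),
                       class = "cycle_sequence"), ens),
    "untrained-ensemble")
  ens$alpha <- 0.5
  pr <- tiny_pairs(1)[[1]]
  sq <- run_cycle_vs_start(pr$af, pr$stain, identity_vs(), identity_vaf(),
                           T = 2)
  # backbone here has 3 input channels but n_features 16; rebuild matching T
  f <- extract_features(sq, bb)
  expect_equal(dim(f), c(4, 16))
  rep1 <- classify(sq, ens)
  expect_s3_class(rep1, "confidence_report")
  expect_equal(rep1$voted_score, mean(rep1$per_head_scores), tolerance = 1e-15)
  expect_gte(rep1$voted_score, min(rep1$per_head_scores))
  expect_lte(rep1$voted_score, max(rep1$per_head_scores))
  expect_equal(rep1$decision,
               if (rep1$voted_score >= 0.5) "reject" else "accept")
  # wrong sequence length
  sq5 <- run_cycle_vs_start(pr$af, pr$stain, identity_vs(), identity_vaf(),
                            T = 5)
  expect_error(classify(sq5, ens), "length-mismatch")
})

test_that("exhaustive head-subset selection maximises voted accuracy", {
  tr <- make_feature_set(60, seed = 5)
  va <- make_feature_set(30, seed = 6)
  bb <- backbone(n_features = 16, seed = 3)
  pool <- train_heads(tr$feats, tr$labels, va$feats, va$labels, bb, C = 5,
                      seeds = 1:5, epochs = 8)
  idx <- select_head_subset(pool$heads, va$feats, va$labels, C = 3,
                            feat_stats = pool$feat_stats)
  expect_length(idx, 3)
  # the chosen subset's voted accuracy is no worse than any other subset's
  fva <- aquaqc:::standardize_stack(aquaqc:::stack_features(va$feats),
                                    pool$feat_stats)
  acc_of <- function(cb) {
    s <- colMeans(t(vapply(pool$heads[cb], function(h)
      aquaqc:::head_forward_batch(h$params, fva)$s,
      numeric(30))))
    mean((s >= 0.5) == (va$labels == 1))
  }
  accs <- vapply(utils::combn(5, 3, simplify = FALSE), acc_of, numeric(1))
  expect_equal(acc_of(idx), max(accs))
})

test_that("ensemble archives round-trip through disk", {
  tr <- make_feature_set(40, seed = 7)
  va <- make_feature_set(20, seed = 8)
  bb <- backbone(n_features = 16, seed = 4)
  ens <- train_heads(tr$feats, tr$labels, va$feats, va$labels, bb, C = 2,
                     seeds = 1:2, epochs = 5)
  ens$alpha <- 0.42
  dir <- withr::local_tempdir()
  save_ensemble(ens, dir)
  spec <- jsonlite::read_json(file.path(dir, "ensemble.json"))
  expect_equal(spec$alpha, 0.42)
  expect_equal(spec$C, 2L)
  e2 <- load_ensemble(dir)
  expect_identical(serialize(e2$heads, NULL), serialize(ens$heads, NULL))
})

test_that("temporal Grad-CAM maps are shaped, rectified and defect-sensitive", {
  sp <- scene_params(32, n_nuclei = 4, radius_range = c(3, 4), min_gap = 3)
  sc <- sample_scene(sp, seed = 99)
  pr <- render_pair(sc)
  bb <- backbone(n_features = 16, seed = 5)
  tr <- make_feature_set(40, n_frames = 4, seed = 9)
  va <- make_feature_set(20, n_frames = 4, seed = 10)
  ens <- train_heads(tr$feats, tr$labels, va$feats, va$labels, bb, C = 2,
                     seeds = 1:2, epochs = 5)
  ens$alpha <- 0.5
  sq <- run_cycle_vs_start(pr$af, pr$stain, identity_vs(), identity_vaf(),
                           T = 2)
  gc <- gradcam_sequence(sq, ens)
  expect_equal(dim(gc$maps), c(32, 32, 4))
  expect_true(all(gc$maps >= 0))
  expect_equal(dim(gc$mean_map), c(32, 32))
})
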